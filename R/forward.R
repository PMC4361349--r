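#' Predicted total catch from the survey index and catch ratio
#'
#' The deterministic core of the state-space model: total annual catch is
#' the survey biomass index scaled by the catch ratio Q_t (the product of
#' survey catchability and harvest rate) and filtered through the fleet's
#' capture selectivity,
#' C_t = u_t * Q_t * sum_i s'_i * pi_{i,t}.
#'
#' @param u_t latent survey biomass index (kg km^-2), > 0.
#' @param q_ratio catch ratio Q_t, > 0.
#' @param capture capture [selectivity_ogive()] (s').
#' @param pi_t length proportions for the year (sum to 1).
#' @param lengths length-class midpoints (cm) matching `pi_t`.
#' @return Catch in tonnes (units set by the index-landings scale absorbed
#'   into Q).
#' @export
predicted_catch <- function(u_t, q_ratio, capture, pi_t, lengths) {
  check_composition_row(pi_t, lengths)
  stopifnot(u_t > 0, q_ratio > 0)
  u_t * q_ratio * sum(ogive(lengths, capture) * pi_t)
}

#' Predicted discards from capture/retention selectivity and bulk discarding
#'
#' Discards combine the size-related component (captured fish falling below
#' the retention ogive) and the quantity-related component (a fraction q_t
#' of the catch discarded in bulk regardless of size):
#' D_t = u_t * Q_t * ( sum_i s'_i pi_{i,t} + (q_t - 1) sum_i r_i s'_i pi_{i,t} ).
#' The result always satisfies q_t * C_t <= D_t <= C_t.
#'
#' @inheritParams predicted_catch
#' @param retention retention [selectivity_ogive()] (r).
#' @param q_t bulk-discard fraction in `[0, 1]`.
#' @return Discards in tonnes.
#' @export
predicted_discards <- function(u_t, q_ratio, capture, retention, pi_t, lengths, q_t) {
  check_composition_row(pi_t, lengths)
  stopifnot(u_t > 0, q_ratio > 0, q_t >= 0, q_t <= 1)
  s <- ogive(lengths, capture)
  r <- ogive(lengths, retention)
  u_t * q_ratio * (sum(s * pi_t) + (q_t - 1) * sum(r * s * pi_t))
}

check_composition_row <- function(pi_t, lengths) {
  stopifnot(length(pi_t) == length(lengths))
  if (abs(sum(pi_t) - 1) > 1e-6) {
    stop("length proportions must sum to 1", call. = FALSE)
  }
  invisible(TRUE)
}

#' Partition discards into quantity- and size-related components
#'
#' The quantity-selected component is the bulk-discarded fraction of the
#' whole catch, q_t * C_t; the size-selected component is the remainder,
#' D_t - q_t * C_t. Both are non-negative whenever q_t C_t <= D_t <= C_t.
#'
#' @param c_t total catch (tonnes).
#' @param d_t total discards (tonnes).
#' @param q_t bulk-discard fraction in `[0, 1]`.
#' @param tol relative tolerance on the admissibility check.
#' @return Named list with `quantity` and `size` (tonnes).
#' @export
partition_discards <- function(c_t, d_t, q_t, tol = 1e-9) {
  stopifnot(q_t >= 0, q_t <= 1, c_t >= 0)
  if (d_t < q_t * c_t - tol * max(1, c_t) || d_t > c_t + tol * max(1, c_t)) {
    stop("discards must satisfy q*C <= D <= C", call. = FALSE)
  }
  quantity <- q_t * c_t
  list(quantity = quantity, size = max(d_t - quantity, 0))
}

#' Log-likelihood of the observed series under the observation model
#'
#' Observed survey index, landings and discards are the latent predictions
#' perturbed by multiplicative lognormal measurement error. The convention
#' used (and pinned down so the constants are testable) is the normal
#' density of the log-observation: each non-missing datum contributes
#' dnorm(log(obs), log(pred), sigma, log = TRUE). Missing observations are
#' skipped; non-positive observations are rejected because the model lives
#' on the log scale.
#'
#' @param obs a [fishery_observations()].
#' @param u latent index series u_t, > 0, one per year.
#' @param q_ratio latent catch ratio series Q_t, > 0.
#' @param q_t bulk-discard fractions in `[0, 1]`, one per year.
#' @param capture,retention [selectivity_ogive()] objects.
#' @param sigma_b,sigma_l,sigma_d log-scale observation standard deviations
#'   for index, landings and discards, > 0.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(obs, u, q_ratio, q_t, capture, retention,
                           sigma_b, sigma_l, sigma_d) {
  stopifnot(inherits(obs, "fishery_observations"))
  n <- length(obs$years)
  stopifnot(length(u) == n, length(q_ratio) == n, length(q_t) == n,
            all(u > 0), all(q_ratio > 0), all(q_t >= 0 & q_t <= 1),
            sigma_b > 0, sigma_l > 0, sigma_d > 0)
  for (v in list(obs$index, obs$landings, obs$discards)) {
    if (any(v <= 0, na.rm = TRUE)) {
      stop("observed values must be positive on the log scale", call. = FALSE)
    }
  }
  pi_mat <- length_proportions(obs$composition)
  lens <- obs$composition$lengths
  s <- ogive(lens, capture)
  r <- ogive(lens, retention)
  s1 <- drop(pi_mat %*% s)
  s2 <- drop(pi_mat %*% (r * s))
  c_pred <- u * q_ratio * s1
  d_pred <- u * q_ratio * (s1 + (q_t - 1) * s2)
  l_pred <- c_pred - d_pred
  ll_term <- function(observed, predicted, sigma) {
    keep <- !is.na(observed)
    sum(stats::dnorm(log(observed[keep]), log(predicted[keep]), sigma, log = TRUE))
  }
  ll_term(obs$index, u, sigma_b) +
    ll_term(obs$landings, l_pred, sigma_l) +
    ll_term(obs$discards, d_pred, sigma_d)
}

#' Dirichlet-weighted geometric mean of reference catch-ratio series
#'
#' The reduced model borrows the catch ratio for a landings-only species as
#' a weighted geometric mean of the reference species' series:
#' log(Q_t) = sum_k w_k log(Q_{k,t}) with simplex weights w.
#'
#' @param w non-negative weights summing to 1 (tolerance 1e-8), one per
#'   reference species.
#' @param log_q_reference numeric matrix, species x years, of reference
#'   log(Q) values.
#' @return Per-year weighted log(Q) series.
#' @export
weighted_logq <- function(w, log_q_reference) {
  log_q_reference <- as.matrix(log_q_reference)
  stopifnot(length(w) == nrow(log_q_reference), all(w >= 0))
  if (abs(sum(w) - 1) > 1e-8) stop("weights must sum to 1", call. = FALSE)
  drop(crossprod(log_q_reference, w))
}

#' Discards implied by a discard proportion and landings
#'
#' The traditional observer-expansion identity D = p L / (1 - p). As p
#' approaches 1 the inflation factor diverges, which is the instability the
#' state-space model is designed to avoid; p >= 1 is rejected.
#'
#' @param l_t landed weight (tonnes), >= 0.
#' @param p_t proportion of catch discarded, in `[0, 1)`.
#' @return Discarded weight (tonnes).
#' @examples
#' discards_from_proportion(90, 0.1)  # 10
#' @export
discards_from_proportion <- function(l_t, p_t) {
  stopifnot(all(l_t >= 0))
  if (any(p_t < 0 | p_t >= 1)) {
    stop("p must lie in [0, 1): the inflation factor p/(1-p) diverges at 1",
         call. = FALSE)
  }
  p_t * l_t / (1 - p_t)
}
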