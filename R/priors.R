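#' Priors for the full (reference-species) model
#'
#' Defaults follow the reference-case analysis: a common capture SL50 mean
#' with Uniform(5, 30) prior and Uniform(0, 100) hierarchical sd;
#' Normal(6, 1.414) selection intervals; Normal(MLS, 7.76) retention
#' midpoints; Beta(0.5, 3) annual bulk-discard fractions (mode at zero,
#' long right tail); Gamma(0.1, 0.1) precisions for all observation and
#' random-walk error terms; Normal(mean log observed index, 0.5) initial
#' log-index; Uniform(2, 14) initial log catch ratio. The second argument
#' of every Normal prior is a standard deviation (set
#' `normal_scale = "precision"` to read them as BUGS precisions instead).
#' Normal priors on lengths/intervals are truncated below at 0.5 cm, since
#' a non-positive selection interval is structurally impossible.
#'
#' @param sl50_star_range,sigma_sl50_max hierarchical capture-SL50 prior.
#' @param si,ri `c(mean, sd)` for the selection intervals (cm).
#' @param rl50_sd sd of the Normal(MLS, .) retention-midpoint prior (cm).
#' @param q_beta `c(a, b)` Beta shapes for q_t.
#' @param prec_gamma `c(shape, rate)` Gamma prior on precisions.
#' @param logu1_sd sd of the initial log-index prior.
#' @param logq1_range Uniform range for the initial log catch ratio
#'   (natural-log scale).
#' @param trunc_lower lower truncation (cm) for length/interval priors.
#' @param normal_scale `"sd"` or `"precision"`: how the second argument of
#'   Normal priors is interpreted.
#' @return A list of class `prior_set`.
#' @export
full_priors <- function(sl50_star_range = c(5, 30), sigma_sl50_max = 100,
                        si = c(6, 1.414), ri = c(6, 1.414), rl50_sd = 7.76,
                        q_beta = c(0.5, 3), prec_gamma = c(0.1, 0.1),
                        logu1_sd = 0.5, logq1_range = c(2, 14),
                        trunc_lower = 0.5, normal_scale = c("sd", "precision")) {
  normal_scale <- match.arg(normal_scale)
  structure(
    list(model = "full", sl50_star_range = sl50_star_range,
         sigma_sl50_max = sigma_sl50_max, si = si, ri = ri, rl50_sd = rl50_sd,
         q_beta = q_beta, prec_gamma = prec_gamma, logu1_sd = logu1_sd,
         logq1_range = logq1_range, trunc_lower = trunc_lower,
         normal_scale = normal_scale),
    class = "prior_set"
  )
}

#' Priors for the reduced (landings-only) model
#'
#' The capture SL50 prior is the reference-case posterior,
#' Normal(15.25, 4.93); the bulk-discard prior is Beta(1, 1) for low-value
#' species (no presumption against bulk discarding) or Beta(1.4, 12) for
#' high-value species (moment-matched to the reference-case posterior q
#' means); reference-series weights are Dirichlet(1, ..., 1).
#'
#' @param value_class `"high"` or `"low"`: selects the q_t prior.
#' @param sl50 `c(mean, sd)` capture SL50 prior (cm).
#' @param si,ri `c(mean, sd)` selection-interval priors (cm).
#' @param q_beta optional explicit `c(a, b)` overriding the value-class
#'   choice.
#' @param dirichlet_alpha Dirichlet concentration per reference series
#'   (recycled to the number of reference species at fit time).
#' @inheritParams full_priors
#' @return A list of class `prior_set`.
#' @export
reduced_priors <- function(value_class = c("high", "low"),
                           sl50 = c(15.25, 4.93),
                           si = c(6, 1.414), ri = c(6, 1.414),
                           q_beta = NULL, dirichlet_alpha = 1,
                           prec_gamma = c(0.1, 0.1), logu1_sd = 0.5,
                           trunc_lower = 0.5, normal_scale = c("sd", "precision")) {
  value_class <- match.arg(value_class)
  normal_scale <- match.arg(normal_scale)
  if (is.null(q_beta)) {
    q_beta <- if (value_class == "high") c(1.4, 12) else c(1, 1)
  }
  structure(
    list(model = "reduced", value_class = value_class, sl50 = sl50,
         si = si, ri = ri, q_beta = q_beta, dirichlet_alpha = dirichlet_alpha,
         prec_gamma = prec_gamma, logu1_sd = logu1_sd,
         trunc_lower = trunc_lower, normal_scale = normal_scale),
    class = "prior_set"
  )
}

#' Match a Beta distribution to a mean and variance
#'
#' Used to turn the distribution of posterior-mean q values from a
#' reference fit into an informative Beta prior for high-value species.
#'
#' @param mean,variance target moments; `0 < mean < 1` and
#'   `variance < mean(1-mean)`.
#' @return `c(a, b)` shape parameters.
#' @export
beta_from_moments <- function(mean, variance) {
  stopifnot(mean > 0, mean < 1, variance > 0)
  if (variance >= mean * (1 - mean)) {
    stop("variance too large for a Beta distribution with this mean", call. = FALSE)
  }
  nu <- mean * (1 - mean) / variance - 1
  c(a = mean * nu, b = (1 - mean) * nu)
}

#' MCMC settings
#'
#' The default is a multi-chain testing configuration (4 chains, 2,000
#' warm-up and 2,000 retained iterations each) sized for desk-scale
#' synthetic analyses with convergence diagnostics. `mode = "production_full"`
#' is the reference-case configuration: a single chain of 50,000
#' iterations with a 15,000-iteration burn-in. Reduced-model runs are
#' sometimes described with a burn-in of 50,000 and a chain length of
#' 15,000 — an inversion of the usual ordering; both readings are
#' available (`"production_reduced"` and `"production_reduced_swapped"`)
#' and neither is asserted as the intended one.
#'
#' @param n_chains number of chains (>= 2 enables split-R-hat).
#' @param n_adapt adaptation iterations.
#' @param n_burnin burn-in iterations after adaptation.
#' @param n_iter retained sampling iterations per chain.
#' @param thin thinning interval.
#' @param mode optional preset overriding the other arguments.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4, n_adapt = 500, n_burnin = 1500,
                        n_iter = 2000, thin = 1, mode = NULL) {
  if (!is.null(mode)) {
    preset <- switch(
      mode,
      production_full = list(n_chains = 1, n_adapt = 1000, n_burnin = 14000, n_iter = 35000, thin = 1),
      production_reduced = list(n_chains = 1, n_adapt = 1000, n_burnin = 49000, n_iter = 15000, thin = 1),
      production_reduced_swapped = list(n_chains = 1, n_adapt = 1000, n_burnin = 14000, n_iter = 50000, thin = 1),
      stop("unknown mcmc mode: ", mode, call. = FALSE)
    )
    n_chains <- preset$n_chains; n_adapt <- preset$n_adapt
    n_burnin <- preset$n_burnin; n_iter <- preset$n_iter; thin <- preset$thin
  }
  stopifnot(n_chains >= 1, n_adapt >= 100, n_burnin >= 0, n_iter >= 100, thin >= 1)
  structure(list(n_chains = n_chains, n_adapt = n_adapt, n_burnin = n_burnin,
                 n_iter = n_iter, thin = thin),
            class = "mcmc_config")
}
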