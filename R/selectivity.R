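#' Two-parameter logistic selectivity ogive
#'
#' Selectivity (capture by the fleet, or retention during on-board sorting)
#' is modelled as a logistic function of body length, parameterised by the
#' length at 50% selection (`l50`) and the selection interval (`interval`),
#' the distance between the 25% and 75% selection lengths. On the logit
#' scale the ogive is linear with slope log(9)/interval, so that
#' `ogive(l50 + interval)` = 0.9 and `ogive(l50 - interval)` = 0.1.
#'
#' @param l50 length at 50% selection (cm), > 0.
#' @param interval selection interval (cm), > 0.
#' @param se_l50,se_interval optional standard errors (from [fit_retention()]).
#' @return An object of class `selectivity_ogive`.
#' @examples
#' r <- selectivity_ogive(25, 6)
#' ogive(c(19, 22, 25, 31), r)  # 0.1, 0.25, 0.5, 0.9
#' @export
selectivity_ogive <- function(l50, interval, se_l50 = NA_real_, se_interval = NA_real_) {
  stopifnot(is.numeric(l50), is.numeric(interval), length(l50) == 1L, length(interval) == 1L)
  if (!is.finite(l50) || l50 <= 0) stop("l50 must be a positive length (cm)", call. = FALSE)
  if (!is.finite(interval) || interval <= 0) {
    stop("selection interval must be > 0 cm", call. = FALSE)
  }
  l50 <- unname(l50)
  interval <- unname(interval)
  structure(
    list(l50 = l50, interval = interval, se_l50 = se_l50, se_interval = se_interval),
    class = "selectivity_ogive"
  )
}

#' @export
print.selectivity_ogive <- function(x, ...) {
  cat(sprintf("<selectivity_ogive> L50 = %.2f cm, interval = %.2f cm\n",
              x$l50, x$interval))
  invisible(x)
}

#' Evaluate a selectivity ogive at length
#'
#' @param length numeric vector of body lengths (cm).
#' @param params a [selectivity_ogive()].
#' @return Selection probabilities in (0, 1), strictly increasing in length.
#' @export
ogive <- function(length, params) {
  stopifnot(inherits(params, "selectivity_ogive"))
  stats::plogis(log(9) / params$interval * (length - params$l50))
}

#' Fit a retention ogive to observed proportions landed at length
#'
#' Binomial maximum-likelihood fit of the logistic retention ogive to
#' observer data on the proportion of catch landed per length class
#' (weighted by numbers measured). Complete separation, a flat response or
#' a non-increasing fitted slope leave the likelihood without a finite
#' optimum; the fit then falls back on the crude bracketing rule of
#' [crude_retention()], with a warning.
#'
#' @param lengths numeric, length-class midpoints (cm), >= 4 classes.
#' @param proportion_landed numeric in `[0, 1]` per class.
#' @param weights numbers measured per class (binomial denominators);
#'   defaults to 1 per class.
#' @return A [selectivity_ogive()]; standard errors (delta method) in
#'   `se_l50` / `se_interval` when the ML fit succeeds.
#' @export
fit_retention <- function(lengths, proportion_landed, weights = NULL) {
  stopifnot(length(lengths) == length(proportion_landed))
  if (is.null(weights)) weights <- rep(1, length(lengths))
  stopifnot(length(weights) == length(lengths), all(weights > 0))
  if (length(lengths) < 4L) stop("need at least 4 length classes", call. = FALSE)
  if (any(proportion_landed < 0 | proportion_landed > 1)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  if (all(proportion_landed %in% c(0, 1))) {
    stop("proportions are all 0 or 1: no interval information", call. = FALSE)
  }

  fallback <- function(reason) {
    warning("retention ML fit failed (", reason,
            "); falling back on the crude bracketing rule", call. = FALSE)
    landed_any <- proportion_landed > 0
    discarded_any <- proportion_landed < 1
    crude_retention(min(lengths[landed_any]), max(lengths[discarded_any]))
  }

  fit <- suppressWarnings(
    stats::glm(proportion_landed ~ lengths, family = stats::binomial(), weights = weights)
  )
  beta <- stats::coef(fit)
  slope <- beta[["lengths"]]
  if (!all(is.finite(beta)) || slope <= 0) return(fallback("non-positive or infinite slope"))
  ri <- log(9) / slope
  rl50 <- -beta[[1L]] / slope
  if (!is.finite(rl50) || rl50 <= 0 || !is.finite(ri)) return(fallback("degenerate optimum"))
  vc <- stats::vcov(fit)
  if (any(!is.finite(vc)) || max(sqrt(diag(vc))) > 1e3) {
    return(fallback("unbounded standard errors (separation)"))
  }
  # delta method: RL50 = -b0/b1, RI = log(9)/b1
  g_rl50 <- c(-1 / slope, beta[[1L]] / slope^2)
  g_ri <- c(0, -log(9) / slope^2)
  se_rl50 <- sqrt(drop(t(g_rl50) %*% vc %*% g_rl50))
  se_ri <- sqrt(drop(t(g_ri) %*% vc %*% g_ri))
  selectivity_ogive(rl50, ri, se_l50 = se_rl50, se_interval = se_ri)
}

#' Crude retention ogive from the landed/discarded length overlap
#'
#' When only separately standardised landed and discarded length
#' distributions are available, the retention interval is approximated as
#' the distance between the minimum length of landed fish and the maximum
#' length of discarded fish, and the 50% retention length as the midpoint
#' of those limits.
#'
#' @param min_landed_length minimum length of landed fish (cm), > 0.
#' @param max_discarded_length maximum length of discarded fish (cm), > 0.
#' @return A [selectivity_ogive()].
#' @examples
#' crude_retention(24, 30)  # RL50 = 27, RI = 6
#' @export
crude_retention <- function(min_landed_length, max_discarded_length) {
  stopifnot(min_landed_length > 0, max_discarded_length > 0)
  ri <- abs(max_discarded_length - min_landed_length)
  if (ri == 0) {
    stop("landed and discarded limits coincide: selection interval must be > 0",
         call. = FALSE)
  }
  selectivity_ogive((max_discarded_length + min_landed_length) / 2, ri)
}

#' Ratio of fitted 50% retention lengths to minimum landing sizes
#'
#' The proportionality constant h linking retention to the minimum landing
#' size, computed as the ratio of the sum of fitted RL50 values to the sum
#' of MLS values over the reference species (a ratio of sums, not a mean of
#' per-species ratios).
#'
#' @param rl50_by_species numeric vector of fitted RL50 (cm), > 0.
#' @param mls_by_species numeric vector of MLS (cm), same length, >= 0 with
#'   positive sum.
#' @return Dimensionless scalar h.
#' @export
estimate_h <- function(rl50_by_species, mls_by_species) {
  stopifnot(length(rl50_by_species) == length(mls_by_species),
            all(rl50_by_species > 0), all(mls_by_species >= 0))
  if (sum(mls_by_species) <= 0) stop("MLS sum must be positive", call. = FALSE)
  sum(rl50_by_species) / sum(mls_by_species)
}

#' 50% retention length proxied from a minimum landing size
#'
#' For landings-only species the retention midpoint cannot be estimated and
#' is set proportional to the species' legal or de-facto minimum landing
#' size: RL50 = h * MLS.
#'
#' @param mls minimum landing size (cm), > 0.
#' @param h proportionality constant from [estimate_h()], > 0.
#' @return RL50 in cm.
#' @export
retention_from_mls <- function(mls, h) {
  stopifnot(is.numeric(mls), is.numeric(h), all(mls > 0), all(h > 0))
  h * mls
}
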