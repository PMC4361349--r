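#' Leave-discards-out cross-validation of the reduced model
#'
#' Refits each reference species with the reduced model using only its
#' landings and survey index — the discard series is withheld — while the
#' species' own catch-ratio series remains among the candidate reference
#' series. Recovery is measured by the Dirichlet weight matrix (each row a
#' simplex over reference series; diagonal dominance indicates the model
#' identifies the right catch ratio) and by coverage of the withheld
#' discard observations by the predictive credible intervals.
#'
#' @param obs_list reference-species [fishery_observations()] (with
#'   discards, which are withheld from the fits).
#' @param full_fit the completed full-model `discard_fit` supplying the
#'   reference log(Q) series and h.
#' @param mls named MLS vector (cm) for the reference species.
#' @param h retention-to-MLS ratio; default the full fit's posterior
#'   median h.
#' @param priors,mcmc,seed,quiet passed to [fit_reduced()] (seed is offset
#'   per species).
#' @return List: `weights` (species x reference-series matrix, rows sum to
#'   1), `coverage` (named per-species proportion of withheld discard
#'   observations inside the 95% interval), `fits` (the reduced fits).
#' @export
cross_validate <- function(obs_list, full_fit, mls, h = NULL,
                           priors = reduced_priors("high"),
                           mcmc = mcmc_config(), seed = 1, quiet = TRUE) {
  stopifnot(inherits(full_fit, "discard_fit"), full_fit$model == "full")
  sp <- vapply(obs_list, `[[`, character(1), "species")
  names(obs_list) <- sp
  if (is.null(h)) h <- full_fit$summary$median[full_fit$summary$variable == "h"]
  lq <- reference_logq(full_fit)
  weights <- matrix(NA_real_, length(sp), nrow(lq), dimnames = list(sp, rownames(lq)))
  coverage <- stats::setNames(rep(NA_real_, length(sp)), sp)
  fits <- vector("list", length(sp))
  names(fits) <- sp
  for (j in seq_along(sp)) {
    o <- obs_list[[j]]
    withheld <- o$discards
    o_blind <- fishery_observations(o$species, o$years, o$landings, o$index,
                                    discards = NULL, composition = o$composition)
    fit <- fit_reduced(o_blind, lq, rl50 = retention_from_mls(mls[[sp[j]]], h),
                       priors = priors, mcmc = mcmc, seed = seed + j,
                       quiet = quiet)
    d <- fit_series(fit, "D")
    ok <- !is.na(withheld)
    coverage[j] <- mean(withheld[ok] >= d$lower[ok] & withheld[ok] <= d$upper[ok])
    weights[j, ] <- fit_weights(fit)
    fits[[j]] <- fit
  }
  list(weights = weights, coverage = coverage, fits = fits)
}

#' Knife-edge estimate of the bulk-discard fraction from age compositions
#'
#' Discarding of fish above the minimum landing size cannot be
#' size-related, so the discard rate among supra-threshold fish
#' approximates the bulk-discard fraction q. The threshold is the MLS plus
#' a small increment (default 1 cm, roughly one selection-interval's
#' margin), converted to a body weight via the allometric length-weight
#' relation; landed and discarded weights are then summed over age classes
#' whose mean body weight exceeds the threshold.
#'
#' @param records data frame with columns `year`, `age`,
#'   `n_landed_thousands`, `w_landed_kg`, `n_discarded_thousands`,
#'   `w_discarded_kg` (component mean weights may be `NA` when absent).
#' @param mls minimum landing size (cm).
#' @param lw a [length_weight()].
#' @param increment threshold increment above MLS (cm).
#' @return Data frame `year`, `q_hat` (in `[0, 1]`, `NA` where no age
#'   class exceeds the threshold).
#' @examples
#' lw <- length_weight(0.01, 3)
#' rec <- data.frame(year = 2000, age = 1:2,
#'                   n_landed_thousands = c(0, 900), w_landed_kg = c(0.2, 0.5),
#'                   n_discarded_thousands = c(500, 100), w_discarded_kg = c(0.2, 0.5))
#' q_from_age(rec, mls = 30, lw = lw)  # q_hat = 0.1
#' @export
q_from_age <- function(records, mls, lw, increment = 1) {
  stopifnot(is.data.frame(records), inherits(lw, "length_weight"), mls > 0)
  needed <- c("year", "age", "n_landed_thousands", "w_landed_kg",
              "n_discarded_thousands", "w_discarded_kg")
  stopifnot(all(needed %in% names(records)))
  threshold_kg <- lw$a * (mls + increment)^lw$b / 1000
  years <- sort(unique(records$year))
  q_hat <- vapply(years, function(y) {
    r <- records[records$year == y, , drop = FALSE]
    wl <- ifelse(is.na(r$w_landed_kg), r$w_discarded_kg, r$w_landed_kg)
    wd <- ifelse(is.na(r$w_discarded_kg), r$w_landed_kg, r$w_discarded_kg)
    landed_supra <- sum(r$n_landed_thousands * wl * (wl > threshold_kg), na.rm = TRUE)
    disc_supra <- sum(r$n_discarded_thousands * wd * (wd > threshold_kg), na.rm = TRUE)
    catch_supra <- landed_supra + disc_supra
    if (catch_supra <= 0) {
      message("no age class above the ", round(threshold_kg, 3),
              " kg threshold in ", y, "; q_hat set NA")
      return(NA_real_)
    }
    disc_supra / catch_supra
  }, numeric(1))
  data.frame(year = years, q_hat = q_hat, row.names = NULL)
}

#' Compare modelled discard rates with sporadic observed fragments
#'
#' Observed discard-proportion fragments (sporadic national observer
#' estimates) are averaged on the logit scale per species and
#' back-transformed; the model's posterior-mean proportion discarded is
#' averaged on the natural scale over a comparison window. Fragments with
#' p = 1 (discard-only records) carry no logit information and are
#' excluded with a note; species with no usable fragments are omitted.
#'
#' @param model_p data frame with columns `species`, `year`, `p` (posterior
#'   mean proportion discarded).
#' @param observed_fragments data frame with columns `species`,
#'   `p_observed` in `(0, 1]`.
#' @param years comparison window (default 2001:2010).
#' @return Data frame per species: `p_model`, `p_observed` (inverse-logit
#'   of the mean logit), `n_obs`, `deviation` (model minus observed).
#' @export
compare_p <- function(model_p, observed_fragments, years = 2001:2010) {
  stopifnot(all(c("species", "year", "p") %in% names(model_p)),
            all(c("species", "p_observed") %in% names(observed_fragments)))
  frag <- observed_fragments
  if (any(frag$p_observed <= 0 | frag$p_observed > 1)) {
    stop("observed fragments must lie in (0, 1]", call. = FALSE)
  }
  drop_one <- frag$p_observed == 1
  if (any(drop_one)) {
    message(sum(drop_one), " fragment(s) with p = 1 (discard-only) excluded")
    frag <- frag[!drop_one, , drop = FALSE]
  }
  sp <- sort(unique(frag$species))
  rows <- lapply(sp, function(s) {
    p_obs_s <- frag$p_observed[frag$species == s]
    m <- model_p[model_p$species == s & model_p$year %in% years, , drop = FALSE]
    if (nrow(m) == 0) return(NULL)
    p_obs <- stats::plogis(mean(stats::qlogis(p_obs_s)))
    p_mod <- mean(m$p)
    data.frame(species = s, p_model = p_mod, p_observed = p_obs,
               n_obs = length(p_obs_s), deviation = p_mod - p_obs)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sensitivity of reduced-model discard estimates to key assumptions
#'
#' Perturbs one assumption at a time by a proportional `delta` and reports
#' the signed percent change in the mean total discards relative to a
#' baseline fit run with the same seed (so the delta isolates the
#' perturbation): the capture SL50 prior mean, the fixed retention length
#' RL50, the bulk-discard prior mean (Beta shapes rescaled at constant
#' concentration a+b), or the switch from geometric to arithmetic
#' averaging of the reference catch ratios.
#'
#' @param obs a [fishery_observations()] (landings-only view is used).
#' @param reference_logq reference log(Q) matrix.
#' @param rl50 baseline retention length (cm).
#' @param parameter one of `"SL50"`, `"RL50"`, `"q_prior"`, `"Q_mean"`.
#' @param delta proportional perturbation (ignored for `"Q_mean"`).
#' @param priors,mcmc,seed,quiet as in [fit_reduced()].
#' @return List: `percent_change` in mean total discards, `baseline_mean_d`,
#'   `perturbed_mean_d`, and the two fits.
#' @export
sensitivity <- function(obs, reference_logq, rl50,
                        parameter = c("RL50", "SL50", "q_prior", "Q_mean"),
                        delta = 0.1, priors = reduced_priors("high"),
                        mcmc = mcmc_config(), seed = 1, quiet = TRUE) {
  parameter <- match.arg(parameter)
  base_fit <- fit_reduced(obs, reference_logq, rl50, priors = priors,
                          mcmc = mcmc, seed = seed, quiet = quiet)
  pert_priors <- priors
  pert_rl50 <- rl50
  q_mean <- "geometric"
  if (parameter == "RL50") {
    pert_rl50 <- rl50 * (1 + delta)
  } else if (parameter == "SL50") {
    pert_priors$sl50[1] <- priors$sl50[1] * (1 + delta)
  } else if (parameter == "q_prior") {
    ab <- priors$q_beta
    mu <- ab[1] / sum(ab) * (1 + delta)
    if (mu <= 0 || mu >= 1) stop("perturbed q prior mean outside (0,1)", call. = FALSE)
    pert_priors$q_beta <- c(mu, 1 - mu) * sum(ab)
  } else if (parameter == "Q_mean") {
    q_mean <- "arithmetic"
  }
  pert_fit <- fit_reduced(obs, reference_logq, pert_rl50, priors = pert_priors,
                          mcmc = mcmc, q_mean = q_mean, seed = seed,
                          quiet = quiet)
  base_d <- mean(fit_series(base_fit, "D")$median)
  pert_d <- mean(fit_series(pert_fit, "D")$median)
  list(percent_change = 100 * (pert_d - base_d) / base_d,
       baseline_mean_d = base_d, perturbed_mean_d = pert_d,
       baseline = base_fit, perturbed = pert_fit)
}

#' Assemblage-level totals, discard rate and composition
#'
#' Combines per-species posterior draws of catch, discards and the
#' quantity-related component into assemblage totals. Propagation is
#' draw-wise: totals and the overall proportion discarded
#' p = sum(D)/sum(C) are computed per retained draw and only then
#' summarised, so the intervals are of sums, not sums of intervals.
#'
#' @param fits named list with one entry per species: either a
#'   reduced-model `discard_fit`, or `list(fit = <full fit>, species =
#'   <name>)` selecting one species from a joint full fit. All entries
#'   must cover the same years.
#' @param groups optional named character vector mapping species to groups
#'   (e.g. reference / non-TAC); group shares of total discards are
#'   reported per year.
#' @return List with `annual` (per-year totals: median and 95% interval of
#'   total C, D, L; overall p; size and quantity discard components),
#'   `group_shares` (per-year mean share of discards per group, rows
#'   summing to 1), and `decades` (decadal means of the annual medians).
#' @export
aggregate_assemblage <- function(fits, groups = NULL) {
  stopifnot(is.list(fits), length(fits) >= 1)
  sp <- names(fits)
  if (is.null(sp) || any(sp == "")) stop("fits must be a named list", call. = FALSE)
  the_fit <- function(entry) if (inherits(entry, "discard_fit")) entry else entry$fit
  years <- the_fit(fits[[1]])$years
  for (entry in fits) {
    f <- the_fit(entry)
    stopifnot(inherits(f, "discard_fit"))
    if (!identical(f$years, years)) stop("fits cover different years", call. = FALSE)
  }
  draw_mat <- function(entry, var) {
    if (inherits(entry, "discard_fit")) {
      extract_draw_matrix(entry, var)
    } else {
      extract_draw_matrix(entry$fit, var, species = entry$species)
    }
  }
  n_draws <- min(vapply(fits, function(e) nrow(as.matrix(the_fit(e)$draws)), numeric(1)))
  get <- function(var) {
    lapply(fits, function(e) draw_mat(e, var)[seq_len(n_draws), , drop = FALSE])
  }
  c_list <- get("C")
  d_list <- get("D")
  q_list <- get("q")
  qc_list <- Map(`*`, q_list, c_list)  # quantity-selected component per draw
  tot <- function(lst) Reduce(`+`, lst)
  c_tot <- tot(c_list); d_tot <- tot(d_list); qc_tot <- tot(qc_list)
  l_tot <- c_tot - d_tot
  p_tot <- d_tot / c_tot
  size_tot <- d_tot - qc_tot
  qtile <- function(m) apply(m, 2, stats::quantile, probs = c(0.025, 0.5, 0.975), names = FALSE)
  pack <- function(m, prefix) {
    qs <- qtile(m)
    stats::setNames(
      data.frame(qs[2, ], qs[1, ], qs[3, ]),
      paste0(prefix, c("_median", "_lower", "_upper"))
    )
  }
  annual <- cbind(
    data.frame(year = years),
    pack(c_tot, "catch"), pack(d_tot, "discards"), pack(l_tot, "landings"),
    pack(p_tot, "p"), pack(size_tot, "size_component"), pack(qc_tot, "quantity_component")
  )
  group_shares <- NULL
  if (!is.null(groups)) {
    stopifnot(all(sp %in% names(groups)))
    g_levels <- unique(unname(groups[sp]))
    shares <- sapply(g_levels, function(g) {
      member <- sp[groups[sp] == g]
      colMeans(tot(d_list[member]) / d_tot)
    })
    group_shares <- data.frame(year = years, shares, check.names = FALSE)
  }
  decade <- 10 * (years %/% 10)
  decades <- do.call(rbind, lapply(sort(unique(decade)), function(dc) {
    idx <- decade == dc
    data.frame(decade = dc,
               mean_discards = mean(annual$discards_median[idx]),
               mean_catch = mean(annual$catch_median[idx]),
               mean_p = mean(annual$p_median[idx]))
  }))
  list(annual = annual, group_shares = group_shares, decades = decades)
}

#' Coefficient of determination of observations on a model median series
#'
#' r^2 = 1 - SS_res / SS_tot with residuals taken against the model's
#' posterior median series. Under this definition r^2 can be negative when
#' the model median predicts worse than the observed mean.
#'
#' @param model_median numeric model series.
#' @param observed numeric observed series (same length; `NA` pairs
#'   dropped).
#' @return Scalar r^2, or `NA` (with a warning) when the observations have
#'   zero variance or fewer than 3 pairs remain.
#' @export
variance_explained <- function(model_median, observed) {
  stopifnot(length(model_median) == length(observed))
  ok <- !is.na(model_median) & !is.na(observed)
  if (sum(ok) < 3) {
    warning("fewer than 3 paired values; r^2 undefined", call. = FALSE)
    return(NA_real_)
  }
  obs <- observed[ok]; mod <- model_median[ok]
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) {
    warning("observed series has zero variance; r^2 undefined", call. = FALSE)
    return(NA_real_)
  }
  1 - sum((obs - mod)^2) / ss_tot
}

#' Regression of retention length on minimum landing size
#'
#' Supports the comparison of fitted or observer-derived RL50 values with
#' legal or de-facto minimum landing sizes: an ordinary linear regression
#' (optionally through the origin) with its slope, intercept and r^2.
#'
#' @param mls minimum landing sizes (cm).
#' @param rl50 retention lengths (cm), same length.
#' @param through_origin force a zero intercept.
#' @return List: `slope`, `intercept` (0 when through the origin), `r2`,
#'   and the `lm` fit.
#' @export
mls_retention_regression <- function(mls, rl50, through_origin = FALSE) {
  stopifnot(length(mls) == length(rl50), length(mls) >= 3)
  fit <- if (through_origin) stats::lm(rl50 ~ mls + 0) else stats::lm(rl50 ~ mls)
  cf <- stats::coef(fit)
  list(slope = unname(cf[length(cf)]),
       intercept = if (through_origin) 0 else unname(cf[1]),
       r2 = summary(fit)$r.squared,
       fit = fit)
}
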