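## Bayesian fitting of the full and reduced discard models via JAGS.
## The BUGS-language model code is authored here; rjags runs the Gibbs
## sampler and coda holds the draws.

norm_tau <- function(pair, scale) {
  if (scale == "sd") 1 / pair[2]^2 else pair[2]
}

full_model_code <- function() {
  "model {
  sl50_star ~ dunif(sl50_star_lo, sl50_star_hi)
  sigma_sl50 ~ dunif(0, sigma_sl50_hi)
  tau_sl50 <- pow(sigma_sl50, -2)
  for (k in 1:K) {
    SL50[k] ~ dnorm(sl50_star, tau_sl50) T(trunc_lo,)
    SI[k] ~ dnorm(si_mean, si_tau) T(trunc_lo,)
    RL50[k] ~ dnorm(MLS[k], rl50_tau) T(trunc_lo,)
    RI[k] ~ dnorm(ri_mean, ri_tau) T(trunc_lo,)
    for (i in 1:I) {
      s[k,i] <- ilogit(log(9) / SI[k] * (len[i] - SL50[k]))
      rs[k,i] <- ilogit(log(9) / RI[k] * (len[i] - RL50[k])) * s[k,i]
    }
    tau_q_rw[k] ~ dgamma(prec_a, prec_b)
    tau_u_rw[k] ~ dgamma(prec_a, prec_b)
    tau_b[k] ~ dgamma(prec_a, prec_b)
    tau_l[k] ~ dgamma(prec_a, prec_b)
    tau_d[k] ~ dgamma(prec_a, prec_b)
    sigma_b[k] <- pow(tau_b[k], -0.5)
    sigma_l[k] <- pow(tau_l[k], -0.5)
    sigma_d[k] <- pow(tau_d[k], -0.5)
    logQ[k,1] ~ dunif(logq1_lo, logq1_hi)
    logu[k,1] ~ dnorm(logu1_mean[k], logu1_tau)
    for (t in 2:T) {
      logQ[k,t] ~ dnorm(logQ[k,t-1], tau_q_rw[k])
      logu[k,t] ~ dnorm(logu[k,t-1], tau_u_rw[k])
    }
    for (t in 1:T) {
      q[k,t] ~ dbeta(q_a, q_b)
      S1[k,t] <- inprod(s[k,1:I], pi[k,t,1:I])
      S2[k,t] <- inprod(rs[k,1:I], pi[k,t,1:I])
      C[k,t] <- exp(logu[k,t] + logQ[k,t]) * S1[k,t]
      D[k,t] <- exp(logu[k,t] + logQ[k,t]) * (S1[k,t] + (q[k,t] - 1) * S2[k,t])
      L[k,t] <- C[k,t] - D[k,t]
      p[k,t] <- D[k,t] / C[k,t]
      logu_obs[k,t] ~ dnorm(logu[k,t], tau_b[k])
      logL_obs[k,t] ~ dnorm(log(L[k,t]), tau_l[k])
      logD_obs[k,t] ~ dnorm(log(D[k,t]), tau_d[k])
    }
  }
  h <- sum(RL50[1:K]) / sum(MLS[1:K])
}"
}

reduced_model_code <- function(q_mean = c("geometric", "arithmetic")) {
  q_mean <- match.arg(q_mean)
  logq_line <- if (q_mean == "geometric") {
    "logQ[t] <- inprod(w[1:K], logQref[1:K,t])"
  } else {
    "logQ[t] <- log(inprod(w[1:K], exp(logQref[1:K,t])))"
  }
  paste0("model {
  w[1:K] ~ ddirch(alpha[1:K])
  SL50 ~ dnorm(sl50_mean, sl50_tau) T(trunc_lo,)
  SI ~ dnorm(si_mean, si_tau) T(trunc_lo,)
  RI ~ dnorm(ri_mean, ri_tau) T(trunc_lo,)
  for (i in 1:I) {
    s[i] <- ilogit(log(9) / SI * (len[i] - SL50))
    rs[i] <- ilogit(log(9) / RI * (len[i] - RL50)) * s[i]
  }
  tau_u_rw ~ dgamma(prec_a, prec_b)
  tau_b ~ dgamma(prec_a, prec_b)
  tau_l ~ dgamma(prec_a, prec_b)
  sigma_b <- pow(tau_b, -0.5)
  sigma_l <- pow(tau_l, -0.5)
  logu[1] ~ dnorm(logu1_mean, logu1_tau)
  for (t in 2:T) {
    logu[t] ~ dnorm(logu[t-1], tau_u_rw)
  }
  for (t in 1:T) {
    ", logq_line, "
    q[t] ~ dbeta(q_a, q_b)
    S1[t] <- inprod(s[1:I], pi[t,1:I])
    S2[t] <- inprod(rs[1:I], pi[t,1:I])
    C[t] <- exp(logu[t] + logQ[t]) * S1[t]
    D[t] <- exp(logu[t] + logQ[t]) * (S1[t] + (q[t] - 1) * S2[t])
    L[t] <- C[t] - D[t]
    p[t] <- D[t] / C[t]
    logu_obs[t] ~ dnorm(logu[t], tau_b)
    logL_obs[t] ~ dnorm(log(L[t]), tau_l)
  }
}")
}

rng_inits <- function(n_chains, seed, extra = NULL) {
  lapply(seq_len(n_chains), function(ch) {
    c(list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = (seed * 101 + ch) %% 2147483646 + 1),
      extra)
  })
}

run_jags <- function(code, data, monitors, mcmc, inits, quiet = TRUE) {
  run <- function() {
    m <- rjags::jags.model(textConnection(code), data = data, inits = inits,
                           n.chains = mcmc$n_chains, n.adapt = mcmc$n_adapt,
                           quiet = TRUE)
    if (mcmc$n_burnin > 0) stats::update(m, mcmc$n_burnin, progress.bar = "none")
    rjags::coda.samples(m, monitors, n.iter = mcmc$n_iter, thin = mcmc$thin,
                        progress.bar = "none")
  }
  if (quiet) suppressWarnings(run()) else run()
}

#' Fit the full state-space discard model to the reference species
#'
#' Joint Bayesian fit to all species with observed landings, discard and
#' survey-index series. Capture SL50 values are pooled hierarchically
#' around a common mean; each species carries its own catch-ratio and
#' index random walks, observation precisions and annual bulk-discard
#' fractions. The retention-to-MLS ratio h is a tracked derived node.
#' Missing observations (`NA`) drop out of the likelihood.
#'
#' @param obs_list list of [fishery_observations()], one per reference
#'   species, on identical years; every species must carry discard
#'   observations.
#' @param mls named numeric vector of minimum landing sizes (cm), names
#'   matching the species.
#' @param priors a [full_priors()] set.
#' @param mcmc an [mcmc_config()].
#' @param seed integer seed driving all chains' RNG.
#' @param quiet suppress JAGS progress output.
#' @return A `discard_fit` object: `summary` (tidy per-parameter medians
#'   and 95% credible intervals), `draws` (coda `mcmc.list`),
#'   `diagnostics` (from [check_convergence()] when >= 2 chains),
#'   `converged` flag, and fit metadata.
#' @export
fit_full <- function(obs_list, mls, priors = full_priors(),
                     mcmc = mcmc_config(), seed = 1, quiet = TRUE) {
  stopifnot(is.list(obs_list), length(obs_list) >= 2,
            all(vapply(obs_list, inherits, logical(1), "fishery_observations")))
  if (!all(vapply(obs_list, has_discards, logical(1)))) {
    stop("every reference species needs at least one discard observation", call. = FALSE)
  }
  sp <- vapply(obs_list, `[[`, character(1), "species")
  names(obs_list) <- sp
  stopifnot(all(sp %in% names(mls)))
  years <- obs_list[[1]]$years
  for (o in obs_list) {
    if (!identical(o$years, years)) stop("species cover different years", call. = FALSE)
  }
  K <- length(obs_list)
  T_n <- length(years)
  grid <- sort(unique(unlist(lapply(obs_list, function(o) o$composition$lengths))))
  I <- length(grid)
  pi_arr <- array(0, c(K, T_n, I))
  for (k in seq_len(K)) {
    pm <- length_proportions(obs_list[[k]]$composition)
    pi_arr[k, , match(obs_list[[k]]$composition$lengths, grid)] <- pm
  }
  # zero observations carry no information on the log scale: drop like NA
  log_obs <- function(x) ifelse(is.na(x) | x <= 0, NA_real_, log(x))
  logu_obs <- t(vapply(obs_list, function(o) log_obs(o$index), numeric(T_n)))
  logl_obs <- t(vapply(obs_list, function(o) log_obs(o$landings), numeric(T_n)))
  logd_obs <- t(vapply(obs_list, function(o) log_obs(o$discards), numeric(T_n)))
  logu1_mean <- apply(logu_obs, 1, mean, na.rm = TRUE)

  data <- list(
    K = K, T = T_n, I = I, len = grid, pi = pi_arr, MLS = unname(mls[sp]),
    logu_obs = logu_obs, logL_obs = logl_obs, logD_obs = logd_obs,
    logu1_mean = logu1_mean,
    sl50_star_lo = priors$sl50_star_range[1], sl50_star_hi = priors$sl50_star_range[2],
    sigma_sl50_hi = priors$sigma_sl50_max,
    si_mean = priors$si[1], si_tau = norm_tau(priors$si, priors$normal_scale),
    ri_mean = priors$ri[1], ri_tau = norm_tau(priors$ri, priors$normal_scale),
    rl50_tau = norm_tau(c(0, priors$rl50_sd), priors$normal_scale),
    q_a = priors$q_beta[1], q_b = priors$q_beta[2],
    prec_a = priors$prec_gamma[1], prec_b = priors$prec_gamma[2],
    logu1_tau = 1 / priors$logu1_sd^2,
    logq1_lo = priors$logq1_range[1], logq1_hi = priors$logq1_range[2],
    trunc_lo = priors$trunc_lower
  )

  # data-driven starting points keep the chains near the posterior mass
  logq1_init <- vapply(seq_len(K), function(k) {
    catch1 <- sum(exp(logl_obs[k, 1]), exp(logd_obs[k, 1]), na.rm = TRUE)
    val <- log(max(catch1, 1e-6)) - logu_obs[k, 1] - log(0.5)
    min(max(val, priors$logq1_range[1] + 0.1), priors$logq1_range[2] - 0.1)
  }, numeric(1))
  logu_init <- logu_obs
  for (k in seq_len(K)) {
    v <- logu_init[k, ]
    if (anyNA(v)) v[is.na(v)] <- mean(v, na.rm = TRUE)
    logu_init[k, ] <- v
  }
  logq_init <- matrix(NA_real_, K, T_n)
  logq_init[, 1] <- logq1_init
  sl50_init <- mean(priors$sl50_star_range)
  extra <- list(logQ = logq_init, logu = logu_init,
                q = matrix(0.1, K, T_n),
                SL50 = rep(sl50_init, K), SI = rep(priors$si[1], K),
                RL50 = unname(mls[sp]), RI = rep(priors$ri[1], K),
                sl50_star = sl50_init,
                sigma_sl50 = min(3, priors$sigma_sl50_max / 2))
  monitors <- c("C", "D", "L", "p", "q", "logQ", "logu", "SL50", "SI",
                "RL50", "RI", "sl50_star", "sigma_sl50", "h",
                "sigma_b", "sigma_l", "sigma_d")
  draws <- run_jags(full_model_code(), data, monitors, mcmc,
                    rng_inits(mcmc$n_chains, seed, extra), quiet)
  build_fit(draws, model = "full", species = sp, years = years, mcmc = mcmc,
            priors = priors, seed = seed, mls = mls[sp])
}

#' Fit the reduced model to a landings-only species
#'
#' Single-species fit in which the catch ratio is a Dirichlet-weighted
#' geometric mean of reference-species log(Q) series (posterior medians
#' from a full fit), the retention midpoint is fixed at h * MLS, and only
#' landings and the survey index enter the likelihood. Years with a
#' missing survey index use the mean length composition and hold q_t at
#' its prior mean.
#'
#' @param obs a [fishery_observations()]; discard observations, if present,
#'   are ignored (withheld from the likelihood).
#' @param reference_logq matrix (reference species x years) of log catch
#'   ratios from [reference_logq()].
#' @param rl50 fixed 50% retention length (cm), normally
#'   [retention_from_mls()] output.
#' @param priors a [reduced_priors()] set.
#' @param mcmc an [mcmc_config()].
#' @param q_mean `"geometric"` (default) or `"arithmetic"` averaging of the
#'   reference catch ratios.
#' @inheritParams fit_full
#' @return A `discard_fit` object (model = "reduced"); the Dirichlet
#'   weights appear as parameters `w[k]`.
#' @export
fit_reduced <- function(obs, reference_logq, rl50,
                        priors = reduced_priors(), mcmc = mcmc_config(),
                        q_mean = c("geometric", "arithmetic"),
                        seed = 1, quiet = TRUE) {
  stopifnot(inherits(obs, "fishery_observations"))
  q_mean <- match.arg(q_mean)
  if (is.null(reference_logq) || !is.matrix(reference_logq)) {
    stop("reference_logq must be a species x years matrix from a full fit", call. = FALSE)
  }
  years <- obs$years
  T_n <- length(years)
  if (ncol(reference_logq) != T_n) {
    stop("reference_logq years do not match the observations", call. = FALSE)
  }
  K <- nrow(reference_logq)
  grid <- obs$composition$lengths
  pi_mat <- length_proportions(obs$composition)
  miss <- obs$composition$missing | is.na(obs$index)
  q_prior_mean <- priors$q_beta[1] / sum(priors$q_beta)
  q_data <- ifelse(miss, q_prior_mean, NA_real_)
  index_obs <- obs$index
  index_obs[miss] <- NA_real_
  all_index_missing <- all(miss)
  logu1_mean <- if (all_index_missing) {
    # no index at all: anchor the latent index scale roughly from landings
    # and the average reference catch ratio; the run completes but is flagged
    warning("survey index missing in every year; q fixed at its prior mean ",
            "throughout and the index scale anchored from landings", call. = FALSE)
    mean(log(obs$landings), na.rm = TRUE) - mean(colMeans(reference_logq))
  } else {
    mean(log(index_obs), na.rm = TRUE)
  }

  data <- list(
    K = K, T = T_n, I = length(grid), len = grid, pi = pi_mat,
    logQref = reference_logq, RL50 = rl50,
    alpha = rep_len(priors$dirichlet_alpha, K),
    logu_obs = ifelse(is.na(index_obs) | index_obs <= 0, NA_real_, log(index_obs)),
    logL_obs = ifelse(is.na(obs$landings) | obs$landings <= 0, NA_real_,
                      log(obs$landings)),
    logu1_mean = logu1_mean,
    sl50_mean = priors$sl50[1], sl50_tau = norm_tau(priors$sl50, priors$normal_scale),
    si_mean = priors$si[1], si_tau = norm_tau(priors$si, priors$normal_scale),
    ri_mean = priors$ri[1], ri_tau = norm_tau(priors$ri, priors$normal_scale),
    q_a = priors$q_beta[1], q_b = priors$q_beta[2],
    prec_a = priors$prec_gamma[1], prec_b = priors$prec_gamma[2],
    logu1_tau = 1 / priors$logu1_sd^2,
    trunc_lo = priors$trunc_lower,
    q = q_data
  )
  logu_init <- data$logu_obs
  if (anyNA(logu_init)) {
    fill <- if (all_index_missing) logu1_mean else mean(logu_init, na.rm = TRUE)
    logu_init[is.na(logu_init)] <- fill
  }
  q_init <- ifelse(miss, NA_real_, 0.1)
  extra <- list(w = rep(1 / K, K), logu = logu_init, q = q_init,
                SL50 = priors$sl50[1], SI = priors$si[1], RI = priors$ri[1])
  monitors <- c("C", "D", "L", "p", "q", "logQ", "logu", "w",
                "SL50", "SI", "RI", "sigma_b", "sigma_l")
  draws <- run_jags(reduced_model_code(q_mean), data, monitors, mcmc,
                    rng_inits(mcmc$n_chains, seed, extra), quiet)
  fit <- build_fit(draws, model = "reduced", species = obs$species,
                   years = years, mcmc = mcmc, priors = priors, seed = seed,
                   mls = NULL)
  fit$rl50 <- rl50
  fit$q_mean <- q_mean
  fit$reference_species <- rownames(reference_logq)
  fit$missing_years <- years[miss]
  fit
}

parse_parameter <- function(param) {
  base <- sub("\\[.*$", "", param)
  idx <- regmatches(param, regexpr("\\[[0-9,]+\\]", param))
  idx1 <- rep(NA_integer_, length(param))
  idx2 <- rep(NA_integer_, length(param))
  has <- lengths(regmatches(param, gregexpr("\\[", param))) > 0
  if (any(has)) {
    inner <- sub("\\]", "", sub(".*\\[", "", param[has]))
    parts <- strsplit(inner, ",")
    idx1[has] <- as.integer(vapply(parts, `[`, character(1), 1))
    idx2[has] <- suppressWarnings(as.integer(vapply(parts, function(p) {
      if (length(p) > 1) p[2] else NA_character_
    }, character(1))))
  }
  list(base = base, i = idx1, j = idx2)
}

build_fit <- function(draws, model, species, years, mcmc, priors, seed, mls) {
  summ <- summarize_posterior(draws)
  px <- parse_parameter(summ$parameter)
  summ$variable <- px$base
  if (model == "full") {
    summ$species <- ifelse(is.na(px$i), NA_character_, species[px$i])
    summ$year <- ifelse(is.na(px$j), NA_integer_, years[px$j])
    # species-level vectors (SL50[k], sigma_b[k], ...) have one index only
    one_idx <- !is.na(px$i) & is.na(px$j)
    summ$year[one_idx] <- NA_integer_
  } else {
    time_vars <- c("C", "D", "L", "p", "q", "logQ", "logu")
    summ$species <- species
    summ$year <- ifelse(summ$variable %in% time_vars & !is.na(px$i),
                        years[ifelse(is.na(px$i), 1L, px$i)], NA_integer_)
  }
  diag <- NULL
  converged <- NA
  if (mcmc$n_chains >= 2) {
    scalar_pars <- summ$parameter[!summ$variable %in% c("C", "D", "L", "p", "q", "logQ", "logu")]
    diag <- check_convergence(draws, parameters = scalar_pars)
    converged <- diag$pass
    if (!converged) {
      warning("convergence diagnostics failed for: ",
              paste(utils::head(diag$report$parameter[diag$report$rhat > diag$threshold], 5),
                    collapse = ", "),
              " (max R-hat ", round(max(diag$report$rhat, na.rm = TRUE), 3),
              "); treat the output with caution", call. = FALSE)
    }
  }
  structure(
    list(summary = summ, draws = draws, diagnostics = diag,
         converged = converged, model = model, species = species,
         years = years, mcmc = mcmc, priors = priors, seed = seed, mls = mls),
    class = "discard_fit"
  )
}

#' @export
print.discard_fit <- function(x, ...) {
  cat(sprintf(
    "<discard_fit> %s model: %s; %d years; %d chains x %d iterations%s\n",
    x$model, paste(x$species, collapse = ", "), length(x$years),
    x$mcmc$n_chains, x$mcmc$n_iter,
    if (isTRUE(x$converged)) "; converged" else if (isFALSE(x$converged))
      "; CONVERGENCE FLAGGED" else ""
  ))
  invisible(x)
}

#' Tidy posterior summary of MCMC draws
#'
#' Elementwise median and central 95% credible interval for every monitored
#' parameter, computed across all chains pooled.
#'
#' @param draws a coda `mcmc.list` (or matrix of draws) with at least 100
#'   retained draws.
#' @param probs interval probabilities (lower, upper).
#' @return Data frame: `parameter`, `median`, `lower`, `upper`.
#' @export
summarize_posterior <- function(draws, probs = c(0.025, 0.975)) {
  mat <- if (inherits(draws, "mcmc.list") || inherits(draws, "mcmc")) {
    as.matrix(draws)
  } else {
    as.matrix(draws)
  }
  if (nrow(mat) < 100) stop("need at least 100 retained draws", call. = FALSE)
  qs <- t(apply(mat, 2, stats::quantile, probs = c(probs[1], 0.5, probs[2]),
                names = FALSE))
  data.frame(parameter = colnames(mat), median = qs[, 2],
             lower = qs[, 1], upper = qs[, 3],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Split-R-hat and effective sample size diagnostics
#'
#' Computes the split-chain potential scale reduction factor (each chain
#' halved, between/within variance ratio) and the effective sample size
#' per parameter. Requires at least two chains.
#'
#' @param draws a coda `mcmc.list` with >= 2 chains.
#' @param parameters optional subset of parameter names to check.
#' @param threshold pass threshold on R-hat.
#' @return List with `report` (data frame: parameter, rhat, ess), `pass`,
#'   and `threshold`.
#' @export
check_convergence <- function(draws, parameters = NULL, threshold = 1.05) {
  stopifnot(inherits(draws, "mcmc.list"))
  if (length(draws) < 2) stop("need at least 2 chains for split-R-hat", call. = FALSE)
  pars <- colnames(draws[[1]])
  if (!is.null(parameters)) pars <- intersect(pars, parameters)
  rhat <- vapply(pars, function(p) {
    split_rhat(sapply(draws, function(ch) as.numeric(ch[, p])))
  }, numeric(1))
  n_total <- sum(vapply(draws, nrow, numeric(1)))
  ess <- vapply(pars, function(p) {
    # autocorrelation estimators can nominally exceed the draw count for
    # antithetic chains; the effective size is capped at the actual count
    min(n_total,
        sum(vapply(draws, function(ch) unname(coda::effectiveSize(ch[, p])),
                   numeric(1))))
  }, numeric(1))
  report <- data.frame(parameter = pars, rhat = rhat, ess = ess,
                       row.names = NULL, stringsAsFactors = FALSE)
  list(report = report, pass = all(is.na(rhat) | rhat < threshold),
       threshold = threshold)
}

split_rhat <- function(chains_mat) {
  n <- nrow(chains_mat)
  half <- floor(n / 2)
  halves <- do.call(cbind, lapply(seq_len(ncol(chains_mat)), function(j) {
    cbind(chains_mat[seq_len(half), j], chains_mat[(n - half + 1):n, j])
  }))
  m <- ncol(halves)
  w <- mean(apply(halves, 2, stats::var))
  if (!is.finite(w) || w == 0) return(1)
  b_over_n <- stats::var(colMeans(halves))
  sqrt((half - 1) / half + b_over_n / w)
}

#' Posterior median log catch-ratio matrix from a full fit
#'
#' The reference input to the reduced model: per reference species
#' and year, the posterior median of log(Q_t).
#'
#' @param fit a full-model `discard_fit`.
#' @return Matrix, species x years, with dimnames.
#' @export
reference_logq <- function(fit) {
  stopifnot(inherits(fit, "discard_fit"), fit$model == "full")
  s <- fit$summary[fit$summary$variable == "logQ", ]
  px <- parse_parameter(s$parameter)
  out <- matrix(NA_real_, length(fit$species), length(fit$years),
                dimnames = list(fit$species, fit$years))
  out[cbind(px$i, px$j)] <- s$median
  out
}

#' Annual posterior series for one variable from a fit
#'
#' @param fit a `discard_fit`.
#' @param variable monitored annual variable (`"C"`, `"D"`, `"L"`, `"p"`,
#'   `"q"`, `"logQ"`, `"logu"`).
#' @param species species name (full model only; ignored for reduced fits).
#' @return Data frame: `year`, `median`, `lower`, `upper`.
#' @export
fit_series <- function(fit, variable, species = NULL) {
  stopifnot(inherits(fit, "discard_fit"))
  s <- fit$summary[fit$summary$variable == variable & !is.na(fit$summary$year), ]
  if (fit$model == "full") {
    if (is.null(species)) stop("species required for a full-model fit", call. = FALSE)
    s <- s[s$species == species, ]
  }
  s <- s[order(s$year), ]
  data.frame(year = s$year, median = s$median, lower = s$lower, upper = s$upper,
             row.names = NULL)
}

#' Posterior draw matrix for an annual variable
#'
#' @inheritParams fit_series
#' @return Matrix draws x years (columns named by year).
#' @export
extract_draw_matrix <- function(fit, variable, species = NULL) {
  stopifnot(inherits(fit, "discard_fit"))
  mat <- as.matrix(fit$draws)
  if (fit$model == "full") {
    if (is.null(species)) stop("species required for a full-model fit", call. = FALSE)
    k <- match(species, fit$species)
    cols <- sprintf("%s[%d,%d]", variable, k, seq_along(fit$years))
  } else {
    cols <- sprintf("%s[%d]", variable, seq_along(fit$years))
  }
  out <- mat[, cols, drop = FALSE]
  colnames(out) <- fit$years
  out
}

#' Posterior mean Dirichlet weights of a reduced fit
#'
#' @param fit a reduced-model `discard_fit`.
#' @return Named numeric vector (reference species) summing to 1.
#' @export
fit_weights <- function(fit) {
  stopifnot(inherits(fit, "discard_fit"), fit$model == "reduced")
  mat <- as.matrix(fit$draws)
  cols <- grep("^w\\[", colnames(mat), value = TRUE)
  w <- colMeans(mat[, cols, drop = FALSE])
  names(w) <- if (!is.null(fit$reference_species)) fit$reference_species else cols
  w
}
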