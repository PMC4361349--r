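test_that("posterior summaries follow the documented quantile rules", {
  const <- matrix(5, 200, 2, dimnames = list(NULL, c("a", "b")))
  s <- summarize_posterior(const)
  expect_equal(s$median, c(5, 5))
  expect_equal(s$lower, s$upper)
  seqd <- matrix(1:100, 100, 1, dimnames = list(NULL, "x"))
  s2 <- summarize_posterior(seqd)
  expect_equal(s2$median, 50.5)
  expect_equal(s2$lower, unname(quantile(1:100, 0.025)))
  expect_equal(s2$upper, unname(quantile(1:100, 0.975)))
  # permutation invariance
  perm <- matrix(sample(1:100), 100, 1, dimnames = list(NULL, "x"))
  expect_equal(summarize_posterior(perm), s2)
  expect_true(all(s2$lower <= s2$median & s2$median <= s2$upper))
  expect_error(summarize_posterior(matrix(1, 50, 1)), "100")
})

test_that("split R-hat separates mixed from disjoint chains", {
  set.seed(8)
  base <- rnorm(1000)
  same <- coda::mcmc.list(coda::mcmc(cbind(x = base)), coda::mcmc(cbind(x = base)))
  cc <- check_convergence(same)
  expect_equal(cc$report$rhat, 1, tolerance = 0.02)
  expect_true(cc$pass)
  apart <- coda::mcmc.list(coda::mcmc(cbind(x = rnorm(1000))),
                           coda::mcmc(cbind(x = rnorm(1000, 50))))
  cc2 <- check_convergence(apart)
  expect_gt(cc2$report$rhat, 1.5)
  expect_false(cc2$pass)
  expect_lte(cc2$report$ess, 2000 + 1e-6)
  expect_error(check_convergence(coda::mcmc.list(coda::mcmc(cbind(x = base)))),
               "2 chains")
})

test_that("prior constructors validate and convert as documented", {
  pf <- full_priors()
  expect_equal(pf$q_beta, c(0.5, 3))
  expect_equal(pf$rl50_sd, 7.76)
  pr_high <- reduced_priors("high")
  expect_equal(pr_high$q_beta, c(1.4, 12))
  expect_equal(reduced_priors("low")$q_beta, c(1, 1))
  # Beta(1.4, 12) mean and variance round-trip through moment matching
  ab <- c(1.4, 12)
  m <- ab[1] / sum(ab)
  v <- prod(ab) / (sum(ab)^2 * (sum(ab) + 1))
  expect_equal(unname(beta_from_moments(m, v)), ab, tolerance = 1e-10)
  expect_error(beta_from_moments(0.5, 0.3), "variance")
  expect_error(mcmc_config(mode = "nope"), "unknown")
  cfg <- mcmc_config(mode = "production_full")
  expect_equal(cfg$n_chains, 1)
  expect_equal(cfg$n_adapt + cfg$n_burnin, 15000)
  expect_equal(cfg$n_iter, 35000)
})

test_that("full fit recovers the synthetic truth at study-condition noise", {
  sc <- scenario_fixture()
  fit <- full_fit_fixture()
  expect_s3_class(fit, "discard_fit")
  expect_true(all(fit$summary$lower <= fit$summary$median + 1e-12))
  expect_true(all(fit$summary$median <= fit$summary$upper + 1e-12))
  # posterior-predictive landings bracket the observations in most years
  mat_sig <- as.matrix(fit$draws)
  cover <- unlist(lapply(seq_along(sc$reference), function(k) {
    s <- sc$reference[k]
    l_draws <- extract_draw_matrix(fit, "L", s)
    sig <- mat_sig[, sprintf("sigma_l[%d]", k)]
    set.seed(100 + k)
    pred <- l_draws * exp(rnorm(length(l_draws), 0, sig))
    lo <- apply(pred, 2, quantile, 0.025)
    hi <- apply(pred, 2, quantile, 0.975)
    obs_l <- sc$species[[s]]$obs$landings
    obs_l >= lo & obs_l <= hi
  }))
  expect_gte(mean(cover), 0.8)
})

test_that("the near-noise-free limit concentrates on the generating process", {
  sc0 <- reference_scenario(seed = 42, sigma_b = 0.01, sigma_l = 0.01,
                            sigma_d = 0.01, sl50_sd = 0.01)
  obs0 <- lapply(sc0$reference, function(s) sc0$species[[s]]$obs)
  truths <- lapply(sc0$reference, function(s) sc0$species[[s]]$truth)
  # the limit isolates state-space recovery: selectivity pinned by tight
  # priors at its generating values, diffuse precision priors so the
  # posterior observation noise can approach zero
  rl_true <- sapply(truths, function(tr) tr$retention$l50)
  names(rl_true) <- sc0$reference
  pr <- full_priors(prec_gamma = c(0.001, 0.001), rl50_sd = 0.05,
                    si = c(6, 0.05), ri = c(6, 0.05),
                    sl50_star_range = c(15.2, 15.3), sigma_sl50_max = 0.1)
  fit0 <- suppressWarnings(fit_full(
    obs0, mls = rl_true, priors = pr,
    mcmc = mcmc_config(n_chains = 2, n_adapt = 1000, n_burnin = 4000,
                       n_iter = 2000), seed = 7
  ))
  rel <- unlist(lapply(sc0$reference, function(s) {
    d <- fit_series(fit0, "D", s)
    tr <- sc0$species[[s]]$truth
    abs(d$median - tr$discards) / tr$discards
  }))
  expect_lt(mean(rel), 0.02)
  expect_lt(max(rel), 0.06)
})

test_that("reduced fit handles missing-index years by fixing q at its prior mean", {
  sc <- scenario_fixture()
  fit <- full_fit_fixture()
  lq <- reference_logq(fit)
  o <- sc$species$other1$obs
  idx <- o$index
  idx[c(3, 10)] <- NA
  o_miss <- fishery_observations(o$species, o$years, o$landings, idx,
                                 discards = NULL, composition = o$composition)
  red <- suppressWarnings(fit_reduced(
    o_miss, lq, rl50 = retention_from_mls(sc$mls[["other1"]], sc$h),
    priors = reduced_priors("high"), mcmc = tiny_mcmc(), seed = 5
  ))
  expect_equal(red$missing_years, o$years[c(3, 10)])
  qd <- extract_draw_matrix(red, "q")
  prior_mean <- 1.4 / 13.4
  expect_equal(unname(qd[, 3]), rep(prior_mean, nrow(qd)))
  expect_gt(sd(qd[, 4]), 0)
  # weights are a simplex
  expect_equal(sum(fit_weights(red)), 1, tolerance = 1e-9)
})

test_that("reduced fit completes with flags when the index is never observed", {
  sc <- scenario_fixture()
  lq <- reference_logq(full_fit_fixture())
  o <- sc$species$other2$obs
  o_none <- fishery_observations(o$species, o$years, o$landings,
                                 rep(NA_real_, length(o$years)),
                                 discards = NULL, composition = o$composition)
  msgs <- character(0)
  red <- withCallingHandlers(
    fit_reduced(o_none, lq, rl50 = retention_from_mls(sc$mls[["other2"]], sc$h),
                priors = reduced_priors("high"), mcmc = tiny_mcmc(), seed = 5),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  expect_true(any(grepl("missing in every year", msgs)))
  expect_equal(length(red$missing_years), length(o$years))
  qd <- extract_draw_matrix(red, "q")
  expect_equal(max(apply(qd, 2, sd)), 0)
})

test_that("with uninformative data the posterior q tracks its informative prior", {
  sc <- scenario_fixture()
  fit <- full_fit_fixture()
  lq <- reference_logq(fit)
  o <- sc$species$other1$obs
  red <- suppressWarnings(fit_reduced(
    o, lq, rl50 = retention_from_mls(sc$mls[["other1"]], sc$h),
    priors = reduced_priors("high"), seed = 5
  ))
  prior_mean <- 1.4 / 13.4  # ~0.104
  expect_lt(abs(mean(extract_draw_matrix(red, "q")) - prior_mean), 0.05)
})

test_that("withholding discards widens the discard intervals", {
  fit <- full_fit_fixture()
  cv <- cross_validation_fixture()
  sp <- "ref2"
  full_d <- fit_series(fit, "D", sp)
  red_d <- fit_series(cv$fits[[sp]], "D")
  expect_gt(mean(red_d$upper - red_d$lower), mean(full_d$upper - full_d$lower))
})
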