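test_that("knife-edge q estimate matches the worked example and its bounds", {
  lw <- length_weight(0.01, 3)
  rec <- data.frame(year = 2000, age = 1:2,
                    n_landed_thousands = c(0, 900), w_landed_kg = c(0.2, 0.5),
                    n_discarded_thousands = c(500, 100), w_discarded_kg = c(0.2, 0.5))
  # threshold weight 0.01 * 31^3 = 297.9 g; only the 0.5 kg age counts
  out <- q_from_age(rec, mls = 30, lw = lw)
  expect_equal(out$q_hat, 0.1)
  # zero discards above threshold
  rec0 <- rec
  rec0$n_discarded_thousands <- c(500, 0)
  expect_equal(q_from_age(rec0, 30, lw)$q_hat, 0)
  # everything above threshold and discarded
  rec1 <- data.frame(year = 2000, age = 1, n_landed_thousands = 0,
                     w_landed_kg = 0.5, n_discarded_thousands = 100,
                     w_discarded_kg = 0.5)
  expect_equal(q_from_age(rec1, 30, lw)$q_hat, 1)
  # no supra-threshold class: NA with a note
  rec2 <- rec
  rec2$w_landed_kg <- rec2$w_discarded_kg <- c(0.1, 0.2)
  expect_message(out2 <- q_from_age(rec2, 30, lw), "threshold")
  expect_true(is.na(out2$q_hat))
  # always a proportion
  set.seed(12)
  recr <- data.frame(year = 2000, age = 1:6,
                     n_landed_thousands = rpois(6, 100),
                     w_landed_kg = runif(6, 0.05, 1),
                     n_discarded_thousands = rpois(6, 50),
                     w_discarded_kg = runif(6, 0.05, 1))
  qh <- q_from_age(recr, 25, lw)$q_hat
  expect_true(is.na(qh) || (qh >= 0 && qh <= 1))
})

test_that("logit-mean comparison of discard rates behaves as stated", {
  model_p <- data.frame(species = rep(c("a", "b", "c"), each = 10),
                        year = rep(2001:2010, 3),
                        p = rep(c(0.4, 0.6, 0.2), each = 10))
  frag <- data.frame(species = c("a", "a", "b", "b", "c"),
                     p_observed = c(0.5, 0.5, 0.1, 0.9, 0.3))
  out <- compare_p(model_p, frag)
  expect_equal(out$p_observed[out$species == "a"], 0.5)
  expect_equal(out$p_observed[out$species == "b"], 0.5)  # logit symmetry
  expect_equal(out$p_observed[out$species == "c"], 0.3)  # single observation
  expect_equal(out$deviation, out$p_model - out$p_observed)
  # p = 1 fragments excluded with a note; fragment-less species omitted
  frag2 <- rbind(frag, data.frame(species = "d", p_observed = 1))
  expect_message(out2 <- compare_p(model_p, frag2), "excluded")
  expect_false("d" %in% out2$species)
  expect_error(compare_p(model_p, data.frame(species = "a", p_observed = 0)),
               "\\(0, 1\\]")
})

test_that("variance explained follows 1 - SSres/SStot", {
  expect_equal(variance_explained(c(1, 2, 3), c(1, 2, 3)), 1)
  # hand-computed toy pairs
  r2 <- variance_explained(c(1, 2, 3), c(1.1, 1.9, 3.2))
  expect_equal(r2, 1 - 0.06 / 2.2466666666666666, tolerance = 1e-10)
  # a constant away from the mean can be worse than the mean
  expect_lt(variance_explained(rep(10, 5), c(1, 2, 3, 4, 5)), 0)
  expect_warning(variance_explained(c(1, 2, 3), c(2, 2, 2)), "zero variance")
  expect_warning(variance_explained(c(1, NA, 3), c(1, 2, NA)), "fewer than 3")
})

test_that("assemblage aggregation is draw-wise exact", {
  years <- 2001:2003
  n_draws <- 150
  mk <- function(d_const, c_const, q_const) {
    fake_reduced_fit("x", years, list(
      C = matrix(rep(c_const, each = n_draws), n_draws),
      D = matrix(rep(d_const, each = n_draws), n_draws),
      q = matrix(rep(q_const, each = n_draws), n_draws)
    ))
  }
  f1 <- mk(c(60, 50, 40), c(100, 90, 80), c(0.1, 0.1, 0.1))
  f2 <- mk(c(40, 30, 20), c(80, 70, 60), c(0.2, 0.2, 0.2))
  agg <- aggregate_assemblage(list(sp1 = f1, sp2 = f2),
                              groups = c(sp1 = "ref", sp2 = "other"))
  expect_equal(agg$annual$discards_median, c(100, 80, 60))
  expect_equal(agg$annual$discards_lower, agg$annual$discards_upper)  # constant draws
  expect_equal(agg$annual$catch_median, c(180, 160, 140))
  # overall p equals the draw-wise ratio of sums, not the mean of ratios
  expect_equal(agg$annual$p_median, c(100 / 180, 80 / 160, 60 / 140),
               tolerance = 1e-10)
  # quantity + size components reconstruct total discards
  expect_equal(agg$annual$quantity_component_median + agg$annual$size_component_median,
               agg$annual$discards_median, tolerance = 1e-10)
  # quantity component is the draw-wise sum of q*C
  expect_equal(agg$annual$quantity_component_median,
               c(0.1 * 100 + 0.2 * 80, 0.1 * 90 + 0.2 * 70, 0.1 * 80 + 0.2 * 60),
               tolerance = 1e-10)
  # group shares partition total discards
  shares <- agg$group_shares
  expect_equal(shares$ref + shares$other, rep(1, 3), tolerance = 1e-10)
  expect_equal(shares$ref, c(60 / 100, 50 / 80, 40 / 60), tolerance = 1e-10)
})

test_that("assemblage aggregation matches a naive per-draw oracle on random draws", {
  set.seed(77)
  years <- 1:4
  n_draws <- 120
  rand_fit <- function() {
    c_m <- matrix(runif(n_draws * 4, 50, 150), n_draws)
    q_m <- matrix(runif(n_draws * 4, 0, 0.3), n_draws)
    # D respecting q*C <= D <= C
    d_m <- q_m * c_m + matrix(runif(n_draws * 4), n_draws) * (c_m - q_m * c_m)
    fake_reduced_fit("x", years, list(C = c_m, D = d_m, q = q_m))
  }
  f1 <- rand_fit(); f2 <- rand_fit(); f3 <- rand_fit()
  agg <- aggregate_assemblage(list(a = f1, b = f2, c = f3))
  d_sum <- extract_draw_matrix(f1, "D") + extract_draw_matrix(f2, "D") +
    extract_draw_matrix(f3, "D")
  c_sum <- extract_draw_matrix(f1, "C") + extract_draw_matrix(f2, "C") +
    extract_draw_matrix(f3, "C")
  expect_equal(agg$annual$discards_median, unname(apply(d_sum, 2, median)),
               tolerance = 1e-10)
  expect_equal(agg$annual$p_median, unname(apply(d_sum / c_sum, 2, median)),
               tolerance = 1e-10)
  expect_equal(agg$annual$discards_lower,
               unname(apply(d_sum, 2, quantile, 0.025)), tolerance = 1e-10)
})

test_that("retention-vs-MLS regression reports slope and r-squared", {
  mls <- c(24, 27, 30, 35, 27)
  rl <- 0.9 * mls
  out <- suppressWarnings(mls_retention_regression(mls, rl, through_origin = TRUE))
  expect_equal(out$slope, 0.9, tolerance = 1e-10)
  expect_equal(out$r2, 1, tolerance = 1e-10)
  set.seed(2)
  rl_noisy <- 0.9 * mls + rnorm(5, 0, 0.5)
  out2 <- mls_retention_regression(mls, rl_noisy)
  expect_equal(out2$slope, unname(coef(lm(rl_noisy ~ mls))[2]), tolerance = 1e-12)
  expect_true(out2$r2 <= 1)
})

test_that("cross-validation recovers the matching catch-ratio series", {
  cv <- cross_validation_fixture()
  expect_equal(unname(rowSums(cv$weights)), rep(1, 5), tolerance = 1e-9)
  diag_hits <- sum(apply(cv$weights, 1, which.max) == seq_len(5))
  expect_gte(diag_hits, 4)
  # withheld discards are covered by the predictive intervals in most years
  expect_gte(mean(cv$coverage), 0.75)
})

test_that("a null perturbation leaves the discard estimate unchanged", {
  sc <- scenario_fixture()
  fit <- full_fit_fixture()
  lq <- reference_logq(fit)
  o <- sc$species$other1$obs
  sens <- suppressWarnings(sensitivity(
    o, lq, rl50 = retention_from_mls(sc$mls[["other1"]], sc$h),
    parameter = "RL50", delta = 0, mcmc = tiny_mcmc(), seed = 13
  ))
  expect_equal(sens$percent_change, 0, tolerance = 1e-12)
})

test_that("retention-length sensitivity is strongest for narrow length ranges", {
  # forward-model comparison: same +10% RL50 shift applied to a species
  # whose sizes sit tightly around the retention length versus one spread
  # far beyond it
  lens <- 5:80
  cap <- selectivity_ogive(15, 6)
  shift_pct <- function(mean_l, sd_l, rl50) {
    comp <- simulate_length_compositions(lens, mean_l, sd_l, 100, 1)
    pi_t <- length_proportions(comp)[1, ]
    d0 <- predicted_discards(100, 2, cap, selectivity_ogive(rl50, 6),
                             pi_t = pi_t, lengths = lens, q_t = 0.1)
    d1 <- predicted_discards(100, 2, cap, selectivity_ogive(rl50 * 1.1, 6),
                             pi_t = pi_t, lengths = lens, q_t = 0.1)
    100 * (d1 - d0) / d0
  }
  narrow <- shift_pct(mean_l = 26, sd_l = 3, rl50 = 25)
  wide <- shift_pct(mean_l = 45, sd_l = 18, rl50 = 25)
  expect_gt(narrow, 0)
  expect_gt(wide, 0)
  expect_gt(narrow, wide)
})
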