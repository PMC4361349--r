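test_that("predicted catch matches hand computation and is linear in Q", {
  cap <- selectivity_ogive(20, 4)
  # single class at L50: selection exactly 0.5
  expect_equal(predicted_catch(100, 2, cap, pi_t = 1, lengths = 20), 100)
  expect_equal(predicted_catch(100, 4, cap, pi_t = 1, lengths = 20), 200)
  # vanishing selectivity limit
  far <- selectivity_ogive(1e4, 4)
  expect_lt(predicted_catch(100, 2, far, pi_t = 1, lengths = 20), 1e-12)
  expect_error(predicted_catch(100, 2, cap, pi_t = c(0.6, 0.6), lengths = c(20, 21)),
               "sum to 1")
})

test_that("predicted discards reproduce limiting and hand cases", {
  cap <- selectivity_ogive(15, 5)
  ret <- selectivity_ogive(25, 6)
  lens <- 10:40
  pi_t <- rep(1 / length(lens), length(lens))
  c_t <- predicted_catch(80, 3, cap, pi_t, lens)
  # q = 1: everything caught is discarded
  expect_equal(predicted_discards(80, 3, cap, ret, pi_t = pi_t,
                                  lengths = lens, q_t = 1), c_t)
  # full retention, no bulk discarding: nothing discarded
  full_ret <- selectivity_ogive(1e-6, 1e-6)
  expect_equal(predicted_discards(80, 3, cap, full_ret, pi_t = pi_t,
                                  lengths = lens, q_t = 0), 0, tolerance = 1e-9)
  # near-knife-edge two-class case: s ~ (1,1), r ~ (0,1), uQ = 100, q = 0.2
  sharp_cap <- selectivity_ogive(1, 0.05)
  sharp_ret <- selectivity_ogive(25, 0.05)
  d <- predicted_discards(50, 2, sharp_cap, sharp_ret, pi_t = c(0.5, 0.5),
                          lengths = c(20, 30), q_t = 0.2)
  expect_equal(d, 60, tolerance = 1e-5)
})

test_that("forward model agrees with a naive oracle on random small instances", {
  set.seed(21)
  for (rep in 1:200) {
    n_len <- sample(2:5, 1)
    lens <- sort(sample(5:60, n_len))
    pi_t <- as.numeric(rexp(n_len)); pi_t <- pi_t / sum(pi_t)
    u <- runif(1, 1, 500); q_ratio <- runif(1, 0.1, 50)
    q_t <- runif(1)
    cap <- selectivity_ogive(runif(1, 5, 40), runif(1, 1, 10))
    ret <- selectivity_ogive(runif(1, 5, 40), runif(1, 1, 10))
    c_pkg <- predicted_catch(u, q_ratio, cap, pi_t, lens)
    d_pkg <- predicted_discards(u, q_ratio, cap, ret, pi_t = pi_t,
                                lengths = lens, q_t = q_t)
    expect_equal(c_pkg, naive_catch(u, q_ratio, cap$l50, cap$interval, pi_t, lens),
                 tolerance = 1e-10)
    expect_equal(d_pkg,
                 naive_discards(u, q_ratio, cap$l50, cap$interval,
                                ret$l50, ret$interval, pi_t, lens, q_t),
                 tolerance = 1e-10)
  }
})

test_that("discards always lie between q*C and C", {
  set.seed(31)
  n <- 10000
  for (batch in 1:4) {
    lens <- sort(sample(5:80, 6))
    cap <- selectivity_ogive(runif(1, 5, 50), runif(1, 0.5, 12))
    ret <- selectivity_ogive(runif(1, 5, 50), runif(1, 0.5, 12))
    s <- ogive(lens, cap); r <- ogive(lens, ret)
    pi_mat <- matrix(rexp(6 * (n / 4)), ncol = 6)
    pi_mat <- pi_mat / rowSums(pi_mat)
    uq <- runif(n / 4, 0.1, 1000)
    q_t <- runif(n / 4)
    s1 <- drop(pi_mat %*% s); s2 <- drop(pi_mat %*% (r * s))
    c_t <- uq * s1
    d_t <- uq * (s1 + (q_t - 1) * s2)
    expect_true(all(d_t >= q_t * c_t - 1e-9 * c_t))
    expect_true(all(d_t <= c_t + 1e-9 * c_t))
  }
})

test_that("discards are monotone in q and RL50, and homogeneous in u*Q", {
  set.seed(41)
  lens <- 5:50
  pi_t <- as.numeric(rexp(length(lens))); pi_t <- pi_t / sum(pi_t)
  cap <- selectivity_ogive(18, 6)
  for (rep in 1:20) {
    q1 <- runif(1, 0, 0.5); q2 <- q1 + runif(1, 0, 0.5)
    rl1 <- runif(1, 10, 30); rl2 <- rl1 * 1.1
    d_low <- predicted_discards(50, 2, cap, selectivity_ogive(rl1, 6),
                                pi_t = pi_t, lengths = lens, q_t = q1)
    expect_gte(predicted_discards(50, 2, cap, selectivity_ogive(rl1, 6),
                                  pi_t = pi_t, lengths = lens, q_t = q2), d_low)
    expect_gte(predicted_discards(50, 2, cap, selectivity_ogive(rl2, 6),
                                  pi_t = pi_t, lengths = lens, q_t = q1), d_low)
    # degree-1 homogeneity in u*Q
    expect_equal(predicted_discards(100, 2, cap, selectivity_ogive(rl1, 6),
                                    pi_t = pi_t, lengths = lens, q_t = q1),
                 2 * d_low, tolerance = 1e-12)
  }
})

test_that("discard partition splits quantity and size components", {
  pt <- partition_discards(100, 60, 0.2)
  expect_equal(pt$quantity, 20)
  expect_equal(pt$size, 40)
  expect_equal(partition_discards(100, 60, 0)$quantity, 0)
  expect_equal(partition_discards(100, 60, 0)$size, 60)
  expect_equal(partition_discards(100, 30, 0.3)$size, 0)
  expect_error(partition_discards(100, 10, 0.5), "q\\*C <= D <= C")
  expect_error(partition_discards(100, 120, 0.5), "q\\*C <= D <= C")
})

test_that("log-likelihood matches its stated convention and a brute-force oracle", {
  lens <- c(15, 16, 17)
  years <- 2001:2003
  comp <- length_composition("toy", years, lens,
                             matrix(c(2, 3, 5, 1, 1, 2, 4, 3, 3), 3, 3, byrow = TRUE))
  cap <- selectivity_ogive(14, 3)
  ret <- selectivity_ogive(16, 2)
  u <- c(10, 12, 9); q_ratio <- c(2, 2.5, 2.2); q_t <- c(0.1, 0.2, 0.15)
  pi_mat <- length_proportions(comp)
  c_pred <- d_pred <- numeric(3)
  for (t in 1:3) {
    c_pred[t] <- naive_catch(u[t], q_ratio[t], 14, 3, pi_mat[t, ], lens)
    d_pred[t] <- naive_discards(u[t], q_ratio[t], 14, 3, 16, 2, pi_mat[t, ], lens, q_t[t])
  }
  # zero-residual observations: each datum contributes -0.5*log(2*pi) at sigma = 1
  obs_exact <- fishery_observations("toy", years, landings = c_pred - d_pred,
                                    index = u, discards = d_pred, composition = comp)
  ll1 <- log_likelihood(obs_exact, u, q_ratio, q_t, cap, ret, 1, 1, 1)
  expect_equal(ll1, 9 * (-0.5 * log(2 * pi)), tolerance = 1e-10)
  # halving sigma at zero residual raises each contribution by log(2)
  ll_half <- log_likelihood(obs_exact, u, q_ratio, q_t, cap, ret, 0.5, 1, 1)
  expect_equal(ll_half - ll1, 3 * log(2), tolerance = 1e-10)
  # noisy observations with a missing discard year: brute-force oracle
  set.seed(5)
  land_obs <- (c_pred - d_pred) * exp(rnorm(3, 0, 0.2))
  idx_obs <- u * exp(rnorm(3, 0, 0.2))
  disc_obs <- d_pred * exp(rnorm(3, 0, 0.2))
  disc_obs[2] <- NA
  obs <- fishery_observations("toy", years, land_obs, idx_obs, disc_obs, comp)
  ll <- log_likelihood(obs, u, q_ratio, q_t, cap, ret, 0.3, 0.25, 0.4)
  brute <- 0
  for (t in 1:3) {
    brute <- brute + dnorm(log(idx_obs[t]), log(u[t]), 0.3, log = TRUE)
    brute <- brute + dnorm(log(land_obs[t]), log(c_pred[t] - d_pred[t]), 0.25, log = TRUE)
    if (!is.na(disc_obs[t])) {
      brute <- brute + dnorm(log(disc_obs[t]), log(d_pred[t]), 0.4, log = TRUE)
    }
  }
  expect_equal(ll, brute, tolerance = 1e-10)
  expect_error(log_likelihood(obs, u, q_ratio, q_t, cap, ret, -1, 0.2, 0.2))
})

test_that("weighted log-Q is a weighted geometric mean on the natural scale", {
  lq <- matrix(log(c(4, 8, 9, 2)), nrow = 2, byrow = TRUE)  # species x years
  expect_equal(weighted_logq(c(1, 0), lq), log(c(4, 8)))
  expect_equal(exp(weighted_logq(c(0.5, 0.5), lq))[1], 6)  # sqrt(4 * 9)
  expect_equal(weighted_logq(c(0.5, 0.5), lq),
               weighted_logq(c(0.5, 0.5), lq[2:1, ]))
  expect_error(weighted_logq(c(0.6, 0.6), lq), "sum to 1")
})

test_that("discards from a proportion follow D = pL/(1-p)", {
  expect_equal(discards_from_proportion(90, 0.1), 10)
  expect_equal(discards_from_proportion(90, 0), 0)
  expect_equal(discards_from_proportion(55, 0.5), 55)
  expect_error(discards_from_proportion(90, 1), "diverges")
  expect_error(discards_from_proportion(90, 1.2), "diverges")
})
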