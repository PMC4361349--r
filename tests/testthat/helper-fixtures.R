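# Shared, lazily built fixtures. The reference scenario and its full-model
# fit are expensive, so they are computed once per test session and reused
# across files. Seeds are fixed so every run sees the same synthetic study.

.fixtures <- new.env(parent = emptyenv())

scenario_fixture <- function() {
  if (is.null(.fixtures$scenario)) {
    .fixtures$scenario <- reference_scenario(seed = 42)
  }
  .fixtures$scenario
}

reference_obs_fixture <- function() {
  sc <- scenario_fixture()
  lapply(sc$reference, function(s) sc$species[[s]]$obs)
}

full_fit_fixture <- function() {
  if (is.null(.fixtures$full_fit)) {
    sc <- scenario_fixture()
    .fixtures$full_fit <- suppressWarnings(
      fit_full(reference_obs_fixture(), mls = sc$mls, seed = 7)
    )
  }
  .fixtures$full_fit
}

cross_validation_fixture <- function() {
  if (is.null(.fixtures$cv)) {
    sc <- scenario_fixture()
    .fixtures$cv <- suppressWarnings(
      cross_validate(reference_obs_fixture(), full_fit_fixture(),
                     mls = sc$mls, seed = 100)
    )
  }
  .fixtures$cv
}

# small MCMC settings for smoke-level fits where only correctness of the
# plumbing (not posterior quality) is under test
tiny_mcmc <- function() mcmc_config(n_chains = 2, n_adapt = 200, n_burnin = 300,
                                    n_iter = 500)

# independent naive implementations used as oracles ------------------------

naive_logistic <- function(l, l50, interval) {
  1 / (1 + exp(-(log(9) / interval) * (l - l50)))
}

naive_catch <- function(u, q_ratio, sl50, si, pi_t, lens) {
  acc <- 0
  for (i in seq_along(lens)) {
    acc <- acc + naive_logistic(lens[i], sl50, si) * pi_t[i]
  }
  u * q_ratio * acc
}

naive_discards <- function(u, q_ratio, sl50, si, rl50, ri, pi_t, lens, q_t) {
  acc1 <- 0
  acc2 <- 0
  for (i in seq_along(lens)) {
    s_i <- naive_logistic(lens[i], sl50, si)
    r_i <- naive_logistic(lens[i], rl50, ri)
    acc1 <- acc1 + s_i * pi_t[i]
    acc2 <- acc2 + r_i * s_i * pi_t[i]
  }
  u * q_ratio * (acc1 + (q_t - 1) * acc2)
}

# minimal hand-built fit object exposing the draw interface, for tests of
# draw-wise aggregation that should not depend on a sampler run
fake_reduced_fit <- function(species, years, draws_by_var) {
  n_draws <- nrow(draws_by_var[[1]])
  cols <- do.call(cbind, lapply(names(draws_by_var), function(v) {
    m <- draws_by_var[[v]]
    colnames(m) <- sprintf("%s[%d]", v, seq_along(years))
    m
  }))
  draws <- coda::mcmc.list(coda::mcmc(cols))
  structure(
    list(summary = NULL, draws = draws, diagnostics = NULL, converged = NA,
         model = "reduced", species = species, years = as.integer(years),
         mcmc = tiny_mcmc(), priors = reduced_priors(), seed = 0, mls = NULL),
    class = "discard_fit"
  )
}
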