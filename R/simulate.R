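#' Simulate a positive random walk with multiplicative lognormal error
#'
#' Generates the process the latent catch ratio Q_t and biomass index u_t
#' are assumed to follow: x_t = x_{t-1} * exp(e_t), e_t ~ N(0, sigma).
#'
#' @param initial starting value, > 0.
#' @param sigma process standard deviation on the log scale, >= 0.
#' @param n_years series length, >= 1.
#' @param seed integer seed; fixed seed gives identical output.
#' @return Numeric vector of length `n_years`, strictly positive.
#' @export
simulate_random_walk <- function(initial, sigma, n_years, seed = NULL) {
  if (!is.numeric(initial) || initial <= 0) stop("initial must be > 0", call. = FALSE)
  if (!is.numeric(sigma) || sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  stopifnot(n_years >= 1)
  if (!is.null(seed)) set.seed(seed)
  steps <- stats::rnorm(n_years - 1L, 0, sigma)
  initial * exp(cumsum(c(0, steps)))
}

#' Simulate annual length compositions with a drifting mean length
#'
#' Builds a [length_composition()] whose per-year shape is a discretised
#' normal length density (mass integrated over each 1-cm class centred on
#' its midpoint label), scaled by an annual total index. A custom shape
#' function may be supplied. The construction is deterministic: sampling
#' noise enters downstream via [simulate_haul_table()] or
#' [simulate_species_observations()].
#'
#' @param length_grid integer class midpoints (cm), contiguous, >= 3 classes.
#' @param mean_length_path mean length per year (cm); recycled if scalar.
#' @param sd_length length spread (cm), > 0.
#' @param total_index_path annual total index u'_t (kg km^-2), > 0; recycled
#'   if scalar.
#' @param n_years number of years.
#' @param years optional explicit year labels (default `1:n_years`).
#' @param species species label.
#' @param shape_fun optional function `(lengths, mean, sd) ->`
#'   non-negative weights replacing the discretised normal.
#' @return A [length_composition()]; each year's proportions sum to 1.
#' @export
simulate_length_compositions <- function(length_grid, mean_length_path, sd_length,
                                         total_index_path, n_years,
                                         years = seq_len(n_years),
                                         species = "synthetic",
                                         shape_fun = NULL) {
  if (length(length_grid) < 3L) {
    stop("length grid must have at least 3 classes", call. = FALSE)
  }
  stopifnot(sd_length > 0, n_years >= 1)
  mean_length_path <- rep_len(mean_length_path, n_years)
  total_index_path <- rep_len(total_index_path, n_years)
  stopifnot(all(total_index_path > 0))
  if (is.null(shape_fun)) {
    shape_fun <- function(l, m, s) {
      stats::pnorm(l + 0.5, m, s) - stats::pnorm(l - 0.5, m, s)
    }
  }
  dens <- t(vapply(seq_len(n_years), function(t) {
    w <- shape_fun(length_grid, mean_length_path[t], sd_length)
    if (any(w < 0) || sum(w) <= 0) stop("shape function produced no mass", call. = FALSE)
    total_index_path[t] * w / sum(w)
  }, numeric(length(length_grid))))
  length_composition(species, years, length_grid, dens)
}

#' Ground-truth record for one synthetic species
#'
#' Holds the latent paths and parameters from which observations are
#' generated, and (after [complete_truth()]) the exact catch, landings and
#' discard series they imply.
#'
#' @param species species label.
#' @param years integer years.
#' @param q_ratio catch ratio Q_t per year, > 0.
#' @param u latent biomass index u_t per year, > 0.
#' @param q bulk-discard fraction q_t per year, in `[0, 1]`.
#' @param capture,retention [selectivity_ogive()] objects.
#' @param sigma_b,sigma_l,sigma_d log-scale observation sds, > 0.
#' @param mls minimum landing size (cm), carried as metadata.
#' @return An object of class `truth_record`.
#' @export
truth_record <- function(species, years, q_ratio, u, q, capture, retention,
                         sigma_b, sigma_l, sigma_d, mls = NA_real_) {
  years <- as.integer(years)
  n <- length(years)
  stopifnot(
    length(q_ratio) == n, length(u) == n, length(q) == n,
    all(q_ratio > 0), all(u > 0), all(q >= 0 & q <= 1),
    inherits(capture, "selectivity_ogive"), inherits(retention, "selectivity_ogive"),
    sigma_b > 0, sigma_l > 0, sigma_d > 0
  )
  structure(
    list(species = species, years = years, q_ratio = q_ratio, u = u, q = q,
         capture = capture, retention = retention,
         sigma_b = sigma_b, sigma_l = sigma_l, sigma_d = sigma_d, mls = mls,
         catch = NULL, landings = NULL, discards = NULL),
    class = "truth_record"
  )
}

#' @export
print.truth_record <- function(x, ...) {
  cat(sprintf("<truth_record> %s: %d years, SL50 %.1f, RL50 %.1f cm%s\n",
              x$species, length(x$years), x$capture$l50, x$retention$l50,
              if (is.null(x$catch)) "" else " (forward series attached)"))
  invisible(x)
}

#' Attach exact catch, landings and discards to a truth record
#'
#' Runs the deterministic forward model ([predicted_catch()],
#' [predicted_discards()]) on the latent paths, so that
#' L_t = C_t - D_t and q_t C_t <= D_t <= C_t hold exactly before any
#' observation noise.
#'
#' @param truth a [truth_record()].
#' @param composition a [length_composition()] on the same years.
#' @return The truth record with `catch`, `landings`, `discards` filled.
#' @export
complete_truth <- function(truth, composition) {
  stopifnot(inherits(truth, "truth_record"), inherits(composition, "length_composition"))
  if (!identical(truth$years, composition$years)) {
    stop("truth and composition cover different years", call. = FALSE)
  }
  pi_mat <- length_proportions(composition)
  lens <- composition$lengths
  n <- length(truth$years)
  c_t <- vapply(seq_len(n), function(t) {
    predicted_catch(truth$u[t], truth$q_ratio[t], truth$capture, pi_mat[t, ], lens)
  }, numeric(1))
  d_t <- vapply(seq_len(n), function(t) {
    predicted_discards(truth$u[t], truth$q_ratio[t], truth$capture, truth$retention,
                       pi_mat[t, ], lens, truth$q[t])
  }, numeric(1))
  truth$catch <- c_t
  truth$discards <- d_t
  truth$landings <- c_t - d_t
  truth
}

#' Simulate observed landings, discards and index for one species
#'
#' Computes the exact forward series from the truth record, then perturbs
#' each with independent multiplicative lognormal observation error
#' (sds `sigma_b`, `sigma_l`, `sigma_d`). Landings-only species omit the
#' discard observations.
#'
#' @param truth a [truth_record()].
#' @param composition a [length_composition()] on the same years and from
#'   which the observed index is taken as its noisy total.
#' @param seed integer seed.
#' @param landings_only if `TRUE`, discard observations are withheld.
#' @return A [fishery_observations()] whose `attr(, "truth")` is the
#'   completed truth record.
#' @export
simulate_species_observations <- function(truth, composition, seed = NULL,
                                          landings_only = FALSE) {
  truth <- complete_truth(truth, composition)
  if (!is.null(seed)) set.seed(seed)
  n <- length(truth$years)
  index_obs <- truth$u * exp(stats::rnorm(n, 0, truth$sigma_b))
  landings_obs <- truth$landings * exp(stats::rnorm(n, 0, truth$sigma_l))
  discards_obs <- truth$discards * exp(stats::rnorm(n, 0, truth$sigma_d))
  if (landings_only) discards_obs <- rep(NA_real_, n)
  # the composition the fitting stage sees carries the observed index scale
  obs_density <- composition$density
  tot <- rowSums(obs_density)
  ok <- tot > 0
  obs_density[ok, ] <- obs_density[ok, , drop = FALSE] * (index_obs[ok] / tot[ok])
  obs_comp <- length_composition(truth$species, truth$years, composition$lengths,
                                 obs_density, missing = composition$missing)
  obs <- fishery_observations(truth$species, truth$years, landings_obs,
                              index_obs, discards_obs, obs_comp)
  attr(obs, "truth") <- truth
  obs
}

#' Simulate a haul-level survey table from a length composition
#'
#' Emulates the raw material of a bottom-trawl survey: per haul, counts in
#' each length class are Poisson with mean (number density x swept area),
#' where the per-year number density is `density_scale` times the
#' composition's density matrix. Haul geometry (tow distance, wing spread,
#' duration, depth) is generated so that swept area = distance x wing
#' spread, supporting the swept-area estimation and imputation steps.
#'
#' @param composition a [length_composition()]; its densities are taken as
#'   relative number densities.
#' @param density_scale multiplier converting composition densities to
#'   fish km^-2 cm^-1.
#' @param hauls_per_year number of hauls per year, >= 1.
#' @param swept_area_range length-2 numeric, uniform range of swept areas
#'   (km^2), positive.
#' @param seed integer seed.
#' @return List of two data frames in the package's survey dialect:
#'   `hauls` (haul_id, year, swept_area_km2, tow_distance_km,
#'   wing_spread_km, tow_duration_min, depth_m, region) and `lengths`
#'   (haul_id, species, length_cm, count).
#' @export
simulate_haul_table <- function(composition, density_scale, hauls_per_year,
                                swept_area_range = c(0.04, 0.08), seed = NULL) {
  stopifnot(inherits(composition, "length_composition"),
            density_scale >= 0, hauls_per_year >= 1,
            length(swept_area_range) == 2L, all(swept_area_range > 0))
  if (!is.null(seed)) set.seed(seed)
  years <- composition$years
  lens <- composition$lengths
  dens <- composition$density * density_scale
  n_hauls <- hauls_per_year * length(years)
  area <- stats::runif(n_hauls, swept_area_range[1], swept_area_range[2])
  distance <- stats::runif(n_hauls, 3, 5)
  hauls <- data.frame(
    haul_id = sprintf("H%05d", seq_len(n_hauls)),
    year = rep(years, each = hauls_per_year),
    swept_area_km2 = area,
    tow_distance_km = distance,
    wing_spread_km = area / distance,
    tow_duration_min = round(distance / 4 * 60),
    depth_m = round(stats::runif(n_hauls, 30, 150)),
    region = "IVb",
    stringsAsFactors = FALSE
  )
  counts <- lapply(seq_len(n_hauls), function(j) {
    t_idx <- match(hauls$year[j], years)
    mu <- dens[t_idx, ] * hauls$swept_area_km2[j]
    stats::rpois(length(lens), mu)
  })
  lengths_tab <- data.frame(
    haul_id = rep(hauls$haul_id, each = length(lens)),
    species = composition$species,
    length_cm = rep(lens, n_hauls),
    count = unlist(counts),
    stringsAsFactors = FALSE
  )
  lengths_tab <- lengths_tab[lengths_tab$count > 0, , drop = FALSE]
  rownames(lengths_tab) <- NULL
  list(hauls = hauls, lengths = lengths_tab)
}

#' Multi-species synthetic reference scenario
#'
#' Generates the study design the estimation machinery is exercised on:
#' `n_reference` species with observed discard series plus `n_other`
#' landings-only species, over `n_years` years (default 34, emulating a
#' 1978-2011 analysis window). Latent catch ratios and indices follow
#' multiplicative random walks; bulk-discard fractions are Beta draws;
#' species-specific capture SL50 values scatter around a common mean with a
#' hierarchical standard deviation; retention midpoints are `h` times the
#' species' minimum landing size. Observation noise is lognormal on index,
#' landings and discards.
#'
#' Defaults define the scenario's study conditions: observation sds 0.2
#' (index), 0.1 (landings), 0.15 (discards); process sds 0.15 for both
#' random walks; q_t ~ Beta(0.5, 3); h = 0.874; SL50* = 15.25 cm with
#' hierarchical sd 2 cm; capture/retention intervals 6 cm.
#'
#' @param n_reference number of species with observed discards, >= 2.
#' @param n_other number of landings-only species, >= 0.
#' @param n_years series length.
#' @param seed integer seed.
#' @param years year labels.
#' @param sigma_b,sigma_l,sigma_d lognormal observation sds.
#' @param sigma_q,sigma_u random-walk process sds (log scale).
#' @param q_beta length-2 shape parameters of the Beta law for q_t.
#' @param h retention-to-MLS ratio used to set true RL50.
#' @param sl50_mean,sl50_sd common capture SL50 mean and hierarchical sd (cm).
#' @param si,ri capture and retention selection intervals (cm).
#' @return List with elements `species` (named list per species of
#'   `truth` and `obs`), `reference` / `other` (species names), `mls`
#'   (named MLS vector), `h`, and `years`.
#' @export
reference_scenario <- function(n_reference = 5, n_other = 3, n_years = 34,
                               seed = 1, years = seq_len(n_years) + 1977L,
                               sigma_b = 0.2, sigma_l = 0.1, sigma_d = 0.15,
                               sigma_q = 0.15, sigma_u = 0.15,
                               q_beta = c(0.5, 3), h = 0.874,
                               sl50_mean = 15.25, sl50_sd = 2,
                               si = 6, ri = 6) {
  stopifnot(n_reference >= 2, n_other >= 0, n_years >= 2)
  set.seed(seed)
  n_sp <- n_reference + n_other
  # reference MLS values follow the legal sizes of the classic North Sea
  # demersal reference set; other species use de-facto market sizes
  mls_pool <- c(35, 30, 27, 27, 24, 25, 30, 25, 28, 30)
  mls <- rep_len(mls_pool, n_sp)
  ref_names <- paste0("ref", seq_len(n_reference))
  other_names <- if (n_other > 0) paste0("other", seq_len(n_other)) else character(0)
  sp_names <- c(ref_names, other_names)
  names(mls) <- sp_names
  grid <- 5:70
  # spread initial catch ratios so species' Q paths are distinguishable
  log_q1 <- seq(5, 8, length.out = n_sp)
  log_u1 <- log(stats::runif(n_sp, 80, 300))
  sl50_k <- pmax(stats::rnorm(n_sp, sl50_mean, sl50_sd), 6)
  species <- vector("list", n_sp)
  names(species) <- sp_names
  for (j in seq_len(n_sp)) {
    q_path <- simulate_random_walk(exp(log_q1[j]), sigma_q, n_years)
    u_path <- simulate_random_walk(exp(log_u1[j]), sigma_u, n_years)
    q_t <- stats::rbeta(n_years, q_beta[1], q_beta[2])
    capture <- selectivity_ogive(sl50_k[j], si)
    retention <- selectivity_ogive(retention_from_mls(mls[j], h), ri)
    truth <- truth_record(sp_names[j], years, q_path, u_path, q_t,
                          capture, retention, sigma_b, sigma_l, sigma_d,
                          mls = mls[j])
    comp <- simulate_length_compositions(
      grid, mean_length_path = mls[j] + 2, sd_length = 0.3 * mls[j],
      total_index_path = u_path, n_years = n_years, years = years,
      species = sp_names[j]
    )
    species[[j]] <- list(
      truth = NULL,
      obs = simulate_species_observations(truth, comp,
                                          landings_only = j > n_reference)
    )
    species[[j]]$truth <- attr(species[[j]]$obs, "truth")
  }
  list(species = species, reference = ref_names, other = other_names,
       mls = mls, h = h, years = years)
}
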