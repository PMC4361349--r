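#' Swept area of a haul, with regression imputation
#'
#' Swept area is the product of distance towed and wing spread. Where the
#' trawl geometry was not recorded, the area is imputed from a log-linear
#' regression on tow duration and seabed depth fitted to hauls with complete
#' geometry (see [fit_swept_area_model()]). Hauls with no usable inputs are
#' returned as `NA` with a warning so callers can exclude them.
#'
#' @param hauls data frame with columns `tow_distance_km`,
#'   `wing_spread_km` (either may be `NA`) and, for imputation,
#'   `tow_duration_min` and `depth_m`.
#' @param imputation_model optional fitted model from
#'   [fit_swept_area_model()].
#' @return Numeric vector of swept areas (km^2), `NA` where unrecoverable.
#' @export
swept_area <- function(hauls, imputation_model = NULL) {
  stopifnot(is.data.frame(hauls))
  dist <- hauls$tow_distance_km
  wing <- hauls$wing_spread_km
  if (is.null(dist) || is.null(wing)) {
    stop("hauls must carry tow_distance_km and wing_spread_km columns", call. = FALSE)
  }
  bad_geom <- !is.na(dist) & !is.na(wing) & (dist <= 0 | wing <= 0)
  if (any(bad_geom)) {
    warning(sum(bad_geom), " haul(s) with non-positive geometry excluded", call. = FALSE)
  }
  area <- ifelse(!is.na(dist) & !is.na(wing) & dist > 0 & wing > 0, dist * wing, NA_real_)
  needs <- is.na(area) & !bad_geom
  if (any(needs) && !is.null(imputation_model)) {
    sub <- hauls[needs, , drop = FALSE]
    usable <- !is.na(sub$tow_duration_min) & !is.na(sub$depth_m) &
      sub$tow_duration_min > 0 & sub$depth_m > 0
    pred <- rep(NA_real_, nrow(sub))
    if (any(usable)) {
      pred[usable] <- exp(stats::predict(imputation_model, newdata = sub[usable, , drop = FALSE]))
    }
    area[needs] <- pred
  }
  if (anyNA(area)) {
    warning(sum(is.na(area)),
            " haul(s) lack both geometry and imputation inputs; flagged NA",
            call. = FALSE)
  }
  area
}

#' Fit the swept-area imputation regression
#'
#' Log-linear regression of swept area on tow duration and seabed depth,
#' fitted to hauls where both the geometry (distance x wing spread) and the
#' covariates are recorded.
#'
#' @param hauls haul data frame (see [swept_area()]).
#' @return An `lm` object predicting `log(area)`.
#' @export
fit_swept_area_model <- function(hauls) {
  stopifnot(is.data.frame(hauls))
  complete <- !is.na(hauls$tow_distance_km) & !is.na(hauls$wing_spread_km) &
    hauls$tow_distance_km > 0 & hauls$wing_spread_km > 0 &
    !is.na(hauls$tow_duration_min) & !is.na(hauls$depth_m) &
    hauls$tow_duration_min > 0 & hauls$depth_m > 0
  if (sum(complete) < 10) {
    stop("need at least 10 hauls with complete geometry and covariates", call. = FALSE)
  }
  dat <- hauls[complete, , drop = FALSE]
  dat$log_area <- log(dat$tow_distance_km * dat$wing_spread_km)
  stats::lm(log_area ~ log(tow_duration_min) + log(depth_m), data = dat)
}

#' Collapse taxa to a common taxonomic resolution
#'
#' Survey and landings databases record taxa at differing resolutions;
#' counts are summed within mapped groups per haul and length class. Taxa
#' absent from the mapping are routed to a configurable catch-all group
#' (by default a 'discard-only' class assumed never to be landed). Total
#' fish count is conserved.
#'
#' @param lengths length-frequency data frame (`haul_id`, `species`,
#'   `length_cm`, `count`).
#' @param mapping data frame with columns `taxon`, `group`.
#' @param unmapped_group group assigned to unmapped taxa.
#' @return Aggregated length-frequency data frame with `species` replaced
#'   by the group label.
#' @export
aggregate_taxa <- function(lengths, mapping, unmapped_group = "discard-only") {
  stopifnot(is.data.frame(lengths), is.data.frame(mapping),
            all(c("taxon", "group") %in% names(mapping)))
  grp <- mapping$group[match(lengths$species, mapping$taxon)]
  grp[is.na(grp)] <- unmapped_group
  out <- stats::aggregate(count ~ haul_id + species + length_cm,
                          data = transform(lengths, species = grp), FUN = sum)
  out <- out[order(out$haul_id, out$species, out$length_cm), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("haul_id", "species", "length_cm", "count")]
}

#' Annual mean number density per length class
#'
#' For each year, the mean over hauls of count / swept area per 1-cm class;
#' hauls that caught nothing contribute zeros (they are part of the
#' denominator). Years with no hauls are flagged missing rather than set to
#' zero.
#'
#' @param hauls haul data frame; swept areas are taken from a
#'   `swept_area_km2` column if present, else computed by [swept_area()].
#' @param lengths length-frequency data frame (`haul_id`, `species`,
#'   `length_cm`, `count`).
#' @param species species/group to extract.
#' @param years integer years wanted (default: all in `hauls`).
#' @param region optional set of region codes to filter hauls on (column
#'   `region`).
#' @param imputation_model passed to [swept_area()].
#' @return List with `density` (years x lengths matrix, fish km^-2 cm^-1),
#'   `lengths`, `years`, and `missing` flags.
#' @export
density_at_length <- function(hauls, lengths, species, years = NULL,
                              region = NULL, imputation_model = NULL) {
  stopifnot(is.data.frame(hauls), is.data.frame(lengths))
  if (!is.null(region)) hauls <- hauls[hauls$region %in% region, , drop = FALSE]
  if (is.null(years)) years <- sort(unique(hauls$year))
  years <- as.integer(years)
  if (nrow(hauls) == 0) stop("no hauls pass the filter", call. = FALSE)
  if (is.null(hauls$swept_area_km2)) {
    hauls$swept_area_km2 <- swept_area(hauls, imputation_model)
  }
  excl <- is.na(hauls$swept_area_km2)
  if (any(excl)) {
    warning(sum(excl), " haul(s) without swept area excluded", call. = FALSE)
    hauls <- hauls[!excl, , drop = FALSE]
  }
  sp_len <- lengths[lengths$species == species, , drop = FALSE]
  grid <- if (nrow(sp_len) > 0) seq(min(sp_len$length_cm), max(sp_len$length_cm)) else integer(0)
  if (length(grid) < 3L) grid <- seq(min(c(grid, 5L)), max(c(grid, 7L)))
  dens <- matrix(0, length(years), length(grid), dimnames = list(years, grid))
  missing <- logical(length(years))
  for (ti in seq_along(years)) {
    hy <- hauls[hauls$year == years[ti], , drop = FALSE]
    if (nrow(hy) == 0) {
      missing[ti] <- TRUE
      next
    }
    ly <- sp_len[sp_len$haul_id %in% hy$haul_id, , drop = FALSE]
    per_haul <- matrix(0, nrow(hy), length(grid))
    if (nrow(ly) > 0) {
      idx <- cbind(match(ly$haul_id, hy$haul_id), match(ly$length_cm, grid))
      keep <- !is.na(idx[, 2])
      per_haul[idx[keep, , drop = FALSE]] <- ly$count[keep] / hy$swept_area_km2[idx[keep, 1]]
    }
    dens[ti, ] <- colMeans(per_haul)
  }
  list(density = dens, lengths = grid, years = years, missing = missing)
}

#' Length-weight parameter pair
#'
#' The allometric conversion body weight (g) = a * length(cm)^b.
#'
#' @param a coefficient (g cm^-b), > 0.
#' @param b exponent, in (1, 5).
#' @return An object of class `length_weight`.
#' @export
length_weight <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1L, length(b) == 1L)
  if (a <= 0) stop("length-weight coefficient a must be > 0", call. = FALSE)
  if (b <= 1 || b >= 5) stop("length-weight exponent b must lie in (1, 5)", call. = FALSE)
  structure(list(a = a, b = b), class = "length_weight")
}

#' Convert number density at length to a biomass index
#'
#' Applies the time-independent allometric length-weight conversion at the
#' class midpoint (w = a l^b grams, converted to kg) to each class of an
#' annual number-density matrix, producing the biomass-density-at-length
#' composition (kg km^-2 cm^-1) the model consumes. Years whose biomass is
#' all zero are flagged missing: a zero survey index is treated as a failed
#' observation, not a zero stock.
#'
#' @param density output of [density_at_length()], or a years x lengths
#'   numeric matrix (then `years`/`lengths` must be supplied).
#' @param lw a [length_weight()].
#' @param species species label for the result.
#' @param years,lengths used when `density` is a bare matrix.
#' @return A [length_composition()].
#' @export
biomass_index <- function(density, lw, species = "unknown",
                          years = NULL, lengths = NULL) {
  stopifnot(inherits(lw, "length_weight"))
  if (is.list(density) && !is.data.frame(density) && !is.null(density$density)) {
    years <- density$years
    lengths <- density$lengths
    miss_haul <- density$missing
    density <- density$density
  } else {
    density <- as.matrix(density)
    if (is.null(years) || is.null(lengths)) {
      stop("years and lengths required with a bare density matrix", call. = FALSE)
    }
    miss_haul <- rep(FALSE, length(years))
  }
  w_kg <- lw$a * lengths^lw$b / 1000
  biomass <- sweep(density, 2, w_kg, `*`)
  missing <- miss_haul | rowSums(biomass) == 0
  length_composition(species, years, lengths, biomass, missing = missing)
}
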