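#' Annual biomass-density-at-length composition for one species
#'
#' The central survey-derived input to the discard model: a year-by-length
#' matrix of biomass density (kg km^-2 cm^-1) on a contiguous grid of 1-cm
#' length classes. Length-class labels are treated as class midpoints
#' throughout (a class labelled 20 cm spans 19.5--20.5 cm); data recorded on
#' the cm-below convention should have 0.5 added to the labels on ingestion.
#' The annual total index u'_t is the sum of the densities over classes, and
#' the length proportions pi_{i,t} are the densities normalised within each
#' year.
#'
#' Years in which the survey recorded no biomass carry a missing flag rather
#' than a zero index: a zero survey index with non-zero landings is treated
#' as a failure to observe, not as absence of fish. For flagged years
#' [length_proportions()] substitutes the unweighted mean composition over
#' the non-missing years.
#'
#' @param species character scalar, species or species-group identifier.
#' @param years integer vector of survey years (strictly increasing).
#' @param lengths integer vector of 1-cm length-class midpoints (cm),
#'   contiguous and increasing, at least 3 classes.
#' @param density numeric matrix, `length(years)` x `length(lengths)`,
#'   biomass density in kg km^-2 cm^-1; non-negative.
#' @param missing logical vector per year; if `NULL`, years whose densities
#'   are all zero (or all `NA`) are flagged missing.
#'
#' @return An object of class `length_composition`.
#' @seealso [total_index()], [length_proportions()], [biomass_index()]
#' @export
length_composition <- function(species, years, lengths, density, missing = NULL) {
  stopifnot(is.character(species), length(species) == 1L)
  years <- as.integer(years)
  lengths <- as.integer(lengths)
  if (length(lengths) < 3L) {
    stop("length grid must have at least 3 classes", call. = FALSE)
  }
  if (any(diff(lengths) != 1L)) {
    stop("length grid must be contiguous 1-cm classes", call. = FALSE)
  }
  if (any(diff(years) <= 0L)) stop("years must be strictly increasing", call. = FALSE)
  density <- as.matrix(density)
  if (!all(dim(density) == c(length(years), length(lengths)))) {
    stop("density must be a years x lengths matrix", call. = FALSE)
  }
  if (any(density < 0, na.rm = TRUE)) stop("densities must be >= 0", call. = FALSE)
  density[is.na(density)] <- 0
  if (is.null(missing)) {
    missing <- unname(rowSums(density) == 0)
  } else {
    stopifnot(is.logical(missing), length(missing) == length(years))
    if (any(rowSums(density)[!missing] == 0)) {
      stop("a year with zero total density must be flagged missing", call. = FALSE)
    }
  }
  dimnames(density) <- list(years, lengths)
  structure(
    list(species = species, years = years, lengths = lengths,
         density = density, missing = missing),
    class = "length_composition"
  )
}

#' @export
print.length_composition <- function(x, ...) {
  cat(sprintf(
    "<length_composition> %s: %d years (%d-%d), lengths %d-%d cm, %d missing year(s)\n",
    x$species, length(x$years), min(x$years), max(x$years),
    min(x$lengths), max(x$lengths), sum(x$missing)
  ))
  invisible(x)
}

#' Annual total survey biomass index
#'
#' Sums biomass density over length classes: u'_t in kg km^-2. Missing years
#' return `NA`.
#'
#' @param x a [length_composition()].
#' @return Named numeric vector per year.
#' @export
total_index <- function(x) {
  stopifnot(inherits(x, "length_composition"))
  u <- rowSums(x$density)
  u[x$missing] <- NA_real_
  names(u) <- x$years
  u
}

#' Annual length proportions pi_{i,t}
#'
#' Normalises each year's densities to sum to one. Missing years receive the
#' unweighted mean composition over non-missing years (the model's stated
#' handling of zero survey indices).
#'
#' @param x a [length_composition()].
#' @return Numeric matrix, years x lengths; each row sums to 1.
#' @export
length_proportions <- function(x) {
  stopifnot(inherits(x, "length_composition"))
  if (all(x$missing)) stop("all years missing: no composition available", call. = FALSE)
  pi_mat <- x$density
  tot <- rowSums(pi_mat)
  ok <- !x$missing
  pi_mat[ok, ] <- pi_mat[ok, , drop = FALSE] / tot[ok]
  if (any(x$missing)) {
    mean_pi <- colMeans(pi_mat[ok, , drop = FALSE])
    mean_pi <- mean_pi / sum(mean_pi)
    pi_mat[x$missing, ] <- matrix(mean_pi, sum(x$missing), length(x$lengths), byrow = TRUE)
  }
  pi_mat
}

#' Observed series for one species: landings, optional discards, survey index
#'
#' @param species character scalar.
#' @param years integer vector.
#' @param landings numeric, observed landed weight L'_t (tonnes); `NA` allowed.
#' @param index numeric, observed survey index u'_t (kg km^-2); `NA` allowed.
#' @param discards numeric or `NULL`, observed discarded weight D'_t (tonnes).
#'   `NULL` (or all-`NA`) marks a landings-only species.
#' @param composition the species' [length_composition()] (same years).
#'
#' @return An object of class `fishery_observations`.
#' @export
fishery_observations <- function(species, years, landings, index,
                                 discards = NULL, composition) {
  years <- as.integer(years)
  stopifnot(
    is.character(species), length(species) == 1L,
    length(landings) == length(years), length(index) == length(years),
    inherits(composition, "length_composition")
  )
  if (!identical(composition$years, years)) {
    stop("composition years do not match observation years", call. = FALSE)
  }
  if (is.null(discards)) discards <- rep(NA_real_, length(years))
  stopifnot(length(discards) == length(years))
  for (v in list(landings, index, discards)) {
    if (any(v < 0, na.rm = TRUE)) {
      stop("observed weights and indices cannot be negative", call. = FALSE)
    }
  }
  structure(
    list(species = species, years = years,
         landings = as.numeric(landings), index = as.numeric(index),
         discards = as.numeric(discards), composition = composition),
    class = "fishery_observations"
  )
}

#' @export
print.fishery_observations <- function(x, ...) {
  cat(sprintf(
    "<fishery_observations> %s: %d years, %d landings, %d discard, %d index obs\n",
    x$species, length(x$years), sum(!is.na(x$landings)),
    sum(!is.na(x$discards)), sum(!is.na(x$index))
  ))
  invisible(x)
}

#' Does a species carry observed discards?
#' @param x a [fishery_observations()].
#' @return `TRUE` if at least one non-missing discard observation exists.
#' @export
has_discards <- function(x) {
  stopifnot(inherits(x, "fishery_observations"))
  any(!is.na(x$discards))
}
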