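#' Read survey haul and length-frequency tables
#'
#' Reads the package's two-table survey dialect: a haul table (one row per
#' haul, with geometry and metadata) and a length-frequency table (one row
#' per haul x species x length class). Exports from other survey databases
#' can be ingested by supplying a column map from their header names to
#' the dialect's names.
#'
#' Expected haul columns: `haul_id`, `year`, and optionally
#' `swept_area_km2`, `tow_distance_km`, `wing_spread_km`,
#' `tow_duration_min`, `depth_m`, `region`. Length columns: `haul_id`,
#' `species`, `length_cm`, `count`. Counts are assumed already raised to
#' haul totals; set `subsample_factor_column` to multiply counts up by a
#' recorded raising factor instead.
#'
#' @param hauls_path,lengths_path CSV paths.
#' @param column_map optional named character vector, `c(dialect_name =
#'   source_name, ...)`, applied to both tables.
#' @param subsample_factor_column optional name of a raising-factor column
#'   in the length table.
#' @return List with `hauls` and `lengths` data frames.
#' @export
read_survey_tables <- function(hauls_path, lengths_path, column_map = NULL,
                               subsample_factor_column = NULL) {
  remap <- function(df) {
    if (!is.null(column_map)) {
      idx <- match(unname(column_map), names(df))
      names(df)[idx[!is.na(idx)]] <- names(column_map)[!is.na(idx)]
    }
    df
  }
  hauls <- remap(utils::read.csv(hauls_path, stringsAsFactors = FALSE))
  lengths <- remap(utils::read.csv(lengths_path, stringsAsFactors = FALSE))
  stopifnot(all(c("haul_id", "year") %in% names(hauls)),
            all(c("haul_id", "species", "length_cm", "count") %in% names(lengths)))
  if (!is.null(subsample_factor_column)) {
    fac <- lengths[[subsample_factor_column]]
    stopifnot(!is.null(fac), all(fac > 0, na.rm = TRUE))
    lengths$count <- lengths$count * ifelse(is.na(fac), 1, fac)
  }
  if (any(lengths$count < 0, na.rm = TRUE)) stop("counts must be >= 0", call. = FALSE)
  list(hauls = hauls, lengths = lengths)
}

#' Read a length-weight parameter table
#'
#' CSV with columns `species`, `a`, `b` (weight in g = a * length_cm^b).
#'
#' @param path CSV path.
#' @return Named list of [length_weight()] objects keyed by species.
#' @export
read_length_weight <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "a", "b") %in% names(df)))
  out <- lapply(seq_len(nrow(df)), function(i) length_weight(df$a[i], df$b[i]))
  names(out) <- df$species
  out
}

#' Read a minimum landing size table
#'
#' CSV with columns `species`, `mls_cm`, and optionally `basis`
#' (`legal` / `de-facto`) and `effective_date`. When a species has several
#' eras, the value in force for the longest stretch of the analysis window
#' is chosen (a single time-independent MLS per species is required by the
#' model's constant-retention assumption); override per species via the
#' `choose` argument.
#'
#' @param path CSV path.
#' @param window integer years of the analysis window (used to pick among
#'   eras when `effective_date` is present).
#' @param choose optional named numeric vector of per-species overrides.
#' @return Named numeric vector of MLS (cm).
#' @export
read_mls_table <- function(path, window = 1978:2011, choose = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "mls_cm") %in% names(df)))
  pick <- function(rows) {
    if (nrow(rows) == 1L || is.null(rows$effective_date)) return(rows$mls_cm[1])
    yr <- as.integer(substr(rows$effective_date, 1, 4))
    yr[is.na(yr)] <- min(window)
    span <- vapply(seq_len(nrow(rows)), function(i) {
      from <- max(yr[i], min(window))
      to <- if (i < nrow(rows)) min(yr[i + 1] - 1, max(window)) else max(window)
      max(0, to - from + 1)
    }, numeric(1))
    rows$mls_cm[which.max(span)]
  }
  sp <- unique(df$species)
  out <- vapply(sp, function(s) {
    rows <- df[df$species == s, , drop = FALSE]
    if (!is.null(rows$effective_date)) rows <- rows[order(rows$effective_date), , drop = FALSE]
    pick(rows)
  }, numeric(1))
  if (!is.null(choose)) out[names(choose)] <- choose
  out
}

#' Read a taxon-to-group mapping table
#'
#' CSV with columns `taxon`, `group`, for [aggregate_taxa()].
#'
#' @param path CSV path.
#' @return Data frame with `taxon` and `group`.
#' @export
read_taxon_mapping <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("taxon", "group") %in% names(df)))
  df[, c("taxon", "group")]
}

#' Write a length composition as tidy CSV
#'
#' One row per year x length class: `species`, `year`, `length_cm`,
#' `kg_km2_cm`, `missing`.
#'
#' @param x a [length_composition()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_length_composition <- function(x, path) {
  stopifnot(inherits(x, "length_composition"))
  df <- data.frame(
    species = x$species,
    year = rep(x$years, times = length(x$lengths)),
    length_cm = rep(x$lengths, each = length(x$years)),
    kg_km2_cm = as.vector(x$density),
    missing = rep(x$missing, times = length(x$lengths))
  )
  df <- df[order(df$year, df$length_cm), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a tidy length-composition CSV back into an object
#'
#' @param path CSV written by [write_length_composition()].
#' @return A [length_composition()].
#' @export
read_length_composition <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "year", "length_cm", "kg_km2_cm") %in% names(df)))
  years <- sort(unique(df$year))
  lens <- sort(unique(df$length_cm))
  dens <- matrix(0, length(years), length(lens))
  dens[cbind(match(df$year, years), match(df$length_cm, lens))] <- df$kg_km2_cm
  missing <- NULL
  if (!is.null(df$missing)) {
    missing <- unname(vapply(years, function(y) any(df$missing[df$year == y]),
                             logical(1)))
  }
  length_composition(df$species[1], years, lens, dens, missing = missing)
}

#' Write a posterior summary as tidy CSV
#'
#' @param fit a `discard_fit`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_posterior_csv <- function(fit, path) {
  stopifnot(inherits(fit, "discard_fit"))
  utils::write.csv(fit$summary, path, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic truth bundle as JSON
#'
#' Serialises the latent paths, selectivity parameters and exact forward
#' series of a [truth_record()] for archiving alongside generated CSVs.
#'
#' @param truth a [truth_record()] (ideally after [complete_truth()]).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "truth_record"))
  payload <- list(
    species = truth$species, years = truth$years,
    Q = truth$q_ratio, u = truth$u, q = truth$q,
    capture = list(l50 = truth$capture$l50, interval = truth$capture$interval),
    retention = list(l50 = truth$retention$l50, interval = truth$retention$interval),
    sigma = list(b = truth$sigma_b, l = truth$sigma_l, d = truth$sigma_d),
    mls = truth$mls,
    catch = truth$catch, landings = truth$landings, discards = truth$discards
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model-run configuration file
#'
#' YAML (or JSON) configuration with optional blocks `priors_full`,
#' `priors_reduced`, and `mcmc`, whose entries override the corresponding
#' argument defaults of [full_priors()], [reduced_priors()] and
#' [mcmc_config()].
#'
#' @param path YAML or JSON path.
#' @return List with `priors_full`, `priors_reduced`, `mcmc` objects.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  apply_args <- function(fun, args) do.call(fun, if (is.null(args)) list() else args)
  list(
    priors_full = apply_args(full_priors, cfg$priors_full),
    priors_reduced = apply_args(reduced_priors, cfg$priors_reduced),
    mcmc = apply_args(mcmc_config, cfg$mcmc)
  )
}

#' Write haul and length-frequency tables as CSV
#'
#' @param tables list with `hauls` and `lengths` (as from
#'   [simulate_haul_table()]).
#' @param hauls_path,lengths_path output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_haul_tables <- function(tables, hauls_path, lengths_path) {
  stopifnot(is.list(tables), !is.null(tables$hauls), !is.null(tables$lengths))
  utils::write.csv(tables$hauls, hauls_path, row.names = FALSE)
  utils::write.csv(tables$lengths, lengths_path, row.names = FALSE)
  invisible(c(hauls = hauls_path, lengths = lengths_path))
}
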