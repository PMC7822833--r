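#' Apply study inclusion filters to per-population heterozygosity records
#'
#' Screens a table of published population records against the inclusion
#' rules used for the global compilation: populations genotyped on fewer
#' than `min_sample_size` individuals are dropped, marine populations are
#' dropped (the analysis targets terrestrial and freshwater systems),
#' records flagged as introduced, invasive or cultivated material are
#' dropped, and records without usable coordinates are dropped.
#'
#' Each excluded row receives exactly one reason code, assigned in the
#' order: `missing_coordinates`, `min_sample_size`, `marine_habitat`,
#' `provenance_flag`.
#'
#' @param records A data frame of population records with at least
#'   `population_id`, `sample_size`, `habitat`, `latitude`, `longitude` and
#'   `provenance_flags` columns. `provenance_flags` holds `""`/`NA` for
#'   natural populations, otherwise a comma-separated subset of
#'   `introduced`, `invasive`, `cultivar`.
#' @param min_sample_size Minimum number of genotyped individuals for a
#'   population to be retained (inclusive bound). Default 10.
#' @return A list with `retained` (tibble of kept rows) and `exclusions`
#'   (tibble with `population_id` and `reason`).
#' @examples
#' recs <- tibble::tibble(
#'   population_id = c("a", "b", "c"),
#'   sample_size = c(25, 9, 30),
#'   habitat = c("terrestrial", "terrestrial", "marine"),
#'   latitude = c(45, 46, 47), longitude = c(5, 6, 7),
#'   provenance_flags = ""
#' )
#' apply_inclusion_filters(recs)$exclusions
#' @export
apply_inclusion_filters <- function(records, min_sample_size = 10) {
  stopifnot(is.data.frame(records))
  needed <- c("population_id", "sample_size", "habitat",
              "latitude", "longitude")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  records <- tibble::as_tibble(records)
  flags <- if ("provenance_flags" %in% names(records)) {
    records$provenance_flags
  } else {
    rep("", nrow(records))
  }
  flags[is.na(flags)] <- ""

  reason <- rep(NA_character_, nrow(records))
  no_coords <- is.na(records$latitude) | is.na(records$longitude)
  reason[no_coords] <- "missing_coordinates"
  too_small <- is.na(reason) & records$sample_size < min_sample_size
  reason[too_small] <- "min_sample_size"
  marine <- is.na(reason) & records$habitat == "marine"
  reason[marine] <- "marine_habitat"
  flagged <- is.na(reason) & nzchar(trimws(flags))
  reason[flagged] <- "provenance_flag"

  retained <- records[is.na(reason), , drop = FALSE]
  exclusions <- tibble::tibble(
    population_id = records$population_id[!is.na(reason)],
    reason = reason[!is.na(reason)]
  )
  if (nrow(retained) == 0) {
    abort("no records retained after inclusion filters")
  }
  list(retained = retained, exclusions = exclusions)
}

#' Precision weight for a heterozygosity estimate
#'
#' Meta-regression weight giving more influence to more precise
#' heterozygosity estimates: `1 / sqrt(log(n_loci * sample_size))`. The
#' logarithm defaults to the natural log; `base` makes the choice explicit.
#' The weight is strictly decreasing in the loci-by-individuals product and
#' enters the mixed models as a residual precision multiplier
#' (`Var(e_i) = sigma^2 / w_i`).
#'
#' @param n_loci Positive integer vector, number of genotyped loci.
#' @param sample_size Positive integer vector, number of individuals.
#' @param base Logarithm base; default `exp(1)`.
#' @return Numeric vector of positive weights.
#' @examples
#' precision_weight(10, 20) # 1 / sqrt(log(200))
#' @export
precision_weight <- function(n_loci, sample_size, base = exp(1)) {
  if (any(n_loci < 1) || any(sample_size < 1)) {
    abort("n_loci and sample_size must be >= 1")
  }
  prod_ <- as.numeric(n_loci) * as.numeric(sample_size)
  if (any(log(prod_, base = base) <= 0)) {
    abort("n_loci * sample_size must exceed the log base's unit (log > 0)")
  }
  1 / sqrt(log(prod_, base = base))
}

#' Harmonize raw expected heterozygosity across marker types
#'
#' Raw expected heterozygosity is bounded differently by marker system
#' (e.g. at 0.5 for dominant AFLP-type markers but 1 for codominant
#' microsatellites), so values are made comparable in two affine stages:
#' a z-score within each marker type (sample standard deviation), then a
#' min-max rescale of the pooled standardized values to `[0, 1]`. The
#' pooled rescale keeps both kingdoms on one scale; set
#' `pool = "kingdom"` to rescale within kingdom instead.
#'
#' The returned table adds `gdp` (the harmonized response), `abs_latitude`
#' and the precision `weight` (see [precision_weight()]).
#'
#' @param records Data frame with `he_raw`, `marker_type`, `latitude`,
#'   `n_loci` and `sample_size` columns (e.g. the `retained` element of
#'   [apply_inclusion_filters()]).
#' @param pool `"all"` (default) to min-max normalize over the pooled
#'   dataset, `"kingdom"` to normalize within each kingdom.
#' @param log_base Base of the logarithm in the precision weight.
#' @return A tibble: the input plus `gdp_z` (intermediate standardized
#'   value), `gdp`, `abs_latitude` and `weight`.
#' @export
harmonize_gdp <- function(records, pool = c("all", "kingdom"),
                          log_base = exp(1)) {
  pool <- match.arg(pool)
  stopifnot(is.data.frame(records))
  needed <- c("he_raw", "marker_type", "latitude", "n_loci", "sample_size")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(records$he_raw < 0 | records$he_raw > 1)) {
    abort("he_raw must lie in [0, 1]")
  }

  sds <- tapply(records$he_raw, records$marker_type, sd)
  degenerate <- names(sds)[is.na(sds) | sds == 0]
  if (length(degenerate) > 0) {
    abort(paste0("constant he_raw within marker type(s): ",
                 paste(degenerate, collapse = ", ")))
  }

  out <- records |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$marker_type) |>
    dplyr::mutate(gdp_z = as.numeric(scale(.data$he_raw))) |>
    dplyr::ungroup()

  rescale01 <- function(z) (z - min(z)) / (max(z) - min(z))
  if (pool == "all") {
    out <- dplyr::mutate(out, gdp = rescale01(.data$gdp_z))
  } else {
    if (!"kingdom" %in% names(out)) {
      abort("pool = \"kingdom\" requires a kingdom column")
    }
    out <- out |>
      dplyr::group_by(.data$kingdom) |>
      dplyr::mutate(gdp = rescale01(.data$gdp_z)) |>
      dplyr::ungroup()
  }
  dplyr::mutate(
    out,
    abs_latitude = abs(.data$latitude),
    weight = precision_weight(.data$n_loci, .data$sample_size,
                              base = log_base)
  )
}
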