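#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end analysis: input location (a
#' CSV path or an in-memory data frame), output directory, seed, the
#' inclusion and harmonization options, the per-kingdom dredge
#' specifications, the AICc window and RI threshold, and the diagnostic
#' settings.
#'
#' When `dredge_specs` is `NULL` a desk-scale default is used per
#' kingdom: mains `position`, `temperature_pc`, `precipitation_pc`,
#' `elevation_std` and `mh_stability` (plus, for animals,
#' `pc_size_longevity` and `pc_fecundity`), chosen to keep the exhaustive
#' enumeration small while exercising categorical, continuous and
#' interaction selection. Pass explicit [model_spec()]s (e.g.
#' [build_full_kingdom_spec()]) for larger spaces.
#'
#' @param input CSV path or data frame of population records.
#' @param out_dir Output directory.
#' @param seed Integer seed driving all stochastic stages.
#' @param min_sample_size Inclusion threshold on sample size (default 10).
#' @param pool Min-max normalization pool (`"all"` or `"kingdom"`).
#' @param log_base Logarithm base of the precision weight.
#' @param delta AICc window for the candidate set (default 4).
#' @param ri_threshold RI threshold in percent (default 50).
#' @param dredge_specs Named list (`animal`, `plant`) of [model_spec()]s,
#'   or `NULL` for the default described above.
#' @param correlogram_bin_km,correlogram_max_km,correlogram_n_perm
#'   Correlogram settings (defaults 250 km, 3000 km, 199).
#' @param jackknife_units Character subset of `c("species", "grid3deg")`;
#'   empty vector disables the jackknife stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input, out_dir, seed,
                            min_sample_size = 10,
                            pool = "all", log_base = exp(1),
                            delta = 4, ri_threshold = 50,
                            dredge_specs = NULL,
                            correlogram_bin_km = 250,
                            correlogram_max_km = 3000,
                            correlogram_n_perm = 199,
                            jackknife_units = c("species", "grid3deg")) {
  if (is.character(input) && !file.exists(input)) {
    abort(paste0("input file does not exist: ", input))
  }
  if (delta <= 0) abort("delta must be > 0")
  if (ri_threshold <= 0 || ri_threshold >= 100) {
    abort("ri_threshold must lie in (0, 100)")
  }
  structure(
    list(input = input, out_dir = out_dir, seed = as.integer(seed),
         min_sample_size = min_sample_size, pool = pool,
         log_base = log_base, delta = delta, ri_threshold = ri_threshold,
         dredge_specs = dredge_specs,
         correlogram_bin_km = correlogram_bin_km,
         correlogram_max_km = correlogram_max_km,
         correlogram_n_perm = correlogram_n_perm,
         jackknife_units = jackknife_units),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' All fields of [pipeline_config()] may appear as top-level YAML keys;
#' missing keys fall back to the defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, y)
}

default_dredge_spec <- function(kingdom) {
  mains <- c("position", "temperature_pc", "precipitation_pc",
             "elevation_std", "mh_stability")
  if (kingdom == "animal") {
    mains <- c(mains, "pc_size_longevity", "pc_fecundity")
  }
  model_spec("gdp", mains, random = c("species", "marker_type"),
             weights = "weight")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ",
                 conditionMessage(e)))
  })
}

#' Run the full diversity-gradient analysis
#'
#' Sequences the whole analysis: inclusion filtering, marker
#' harmonization, the kingdom and phylum latitude models with per-group
#' slopes, the per-kingdom exhaustive dredge with candidate set, relative
#' importance and REML-refit final model, Moran's I correlograms of the
#' final-model residuals and of the raw harmonized response, the
#' delete-group jackknives, and a reproducibility manifest. All outputs
#' are CSV/JSON files under `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`harmonized`,
#'   `latitude_fits`, `phylum_slopes`, per-kingdom `dredge`, `ri`,
#'   `final_fit`, `correlograms`, `jackknives`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)

  records <- stage("read_input", {
    if (is.character(config$input)) {
      tibble::as_tibble(utils::read.csv(config$input,
                                        stringsAsFactors = FALSE))
    } else {
      tibble::as_tibble(config$input)
    }
  })
  required <- c("population_id", "species", "phylum", "kingdom",
                "latitude", "longitude", "marker_type", "n_loci",
                "sample_size", "he_raw", "habitat")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }

  filt <- stage("inclusion_filters",
                apply_inclusion_filters(records, config$min_sample_size))
  utils::write.csv(filt$exclusions, out("exclusions.csv"),
                   row.names = FALSE)

  harmonized <- stage("harmonize", {
    h <- harmonize_gdp(filt$retained, pool = config$pool,
                       log_base = config$log_base)
    # the synthetic path carries a pre-simulated harmonized response;
    # re-deriving it from he_raw would double-transform, so keep gdp
    # as provided when present in the input
    if ("gdp" %in% names(filt$retained)) h$gdp <- filt$retained$gdp
    h
  })
  utils::write.csv(harmonized, out("harmonized.csv"), row.names = FALSE)

  lat_fits <- stage("latitude_models", {
    fits <- list(kingdom = fit_weighted_lmm(harmonized,
                                            build_latitude_spec("kingdom")))
    if (length(unique(harmonized$phylum)) >= 2) {
      fits$phylum <- fit_weighted_lmm(harmonized,
                                      build_latitude_spec("phylum"))
    }
    fits
  })
  lat_glance <- purrr::map_dfr(lat_fits, glance, .id = "model")
  utils::write.csv(lat_glance, out("latitude_models.csv"),
                   row.names = FALSE)
  phylum_slopes <- NULL
  if (!is.null(lat_fits$phylum)) {
    phylum_slopes <- extract_group_slopes(lat_fits$phylum, "phylum")
    utils::write.csv(phylum_slopes, out("phylum_slopes.csv"),
                     row.names = FALSE)
  }
  kingdom_slopes <- extract_group_slopes(lat_fits$kingdom, "kingdom")
  utils::write.csv(kingdom_slopes, out("kingdom_slopes.csv"),
                   row.names = FALSE)

  kingdoms <- intersect(c("animal", "plant"), unique(harmonized$kingdom))
  per_kingdom <- list()
  for (kg in kingdoms) {
    kd <- harmonized[harmonized$kingdom == kg, , drop = FALSE]
    spec <- config$dredge_specs[[kg]] %||% default_dredge_spec(kg)
    spec$fixed <- intersect_terms_with_data(spec$fixed, kd)
    dm <- stage(paste0("dredge_", kg), dredge_models(kd, spec))
    cs <- candidate_set(dm, delta = config$delta)
    ri <- relative_importance(cs)
    final_spec <- select_final_terms(ri, threshold = config$ri_threshold)
    final_fit <- stage(paste0("final_model_", kg),
                       fit_weighted_lmm(kd, final_spec, method = "REML",
                                        boundary_fallback = TRUE))
    utils::write.csv(dm, out(paste0("dredge_", kg, ".csv")),
                     row.names = FALSE)
    utils::write.csv(cs, out(paste0("candidate_set_", kg, ".csv")),
                     row.names = FALSE)
    utils::write.csv(ri, out(paste0("relative_importance_", kg, ".csv")),
                     row.names = FALSE)
    jsonlite::write_json(
      list(terms = final_spec$fixed,
           coefficients = tidy(final_fit, conf.int = TRUE),
           glance = glance(final_fit)),
      out(paste0("final_model_", kg, ".json")),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")

    cg_res <- stage(paste0("correlogram_resid_", kg), {
      kd2 <- dplyr::mutate(kd, .residual = resid(final_fit$fit))
      correlogram(kd2, ".residual",
                  bin_width_km = config$correlogram_bin_km,
                  max_km = config$correlogram_max_km,
                  n_perm = config$correlogram_n_perm,
                  seed = derive_seed(config$seed,
                                     paste0("correlogram_resid_", kg)))
    })
    cg_raw <- stage(paste0("correlogram_raw_", kg), {
      correlogram(kd, "gdp",
                  bin_width_km = config$correlogram_bin_km,
                  max_km = config$correlogram_max_km,
                  n_perm = config$correlogram_n_perm,
                  seed = derive_seed(config$seed,
                                     paste0("correlogram_raw_", kg)))
    })
    utils::write.csv(cg_res, out(paste0("correlogram_residuals_", kg,
                                        ".csv")), row.names = FALSE)
    utils::write.csv(cg_raw, out(paste0("correlogram_raw_", kg, ".csv")),
                     row.names = FALSE)

    jk <- list()
    for (u in config$jackknife_units) {
      jk[[u]] <- stage(paste0("jackknife_", u, "_", kg),
                       jackknife(kd, final_spec, unit = u))
      utils::write.csv(jk[[u]],
                       out(paste0("jackknife_", u, "_", kg, ".csv")),
                       row.names = FALSE)
    }
    per_kingdom[[kg]] <- list(dredge = dm, candidate_set = cs, ri = ri,
                              final_spec = final_spec,
                              final_fit = final_fit,
                              correlogram_residuals = cg_res,
                              correlogram_raw = cg_raw, jackknives = jk)
  }

  manifest <- list(
    package = "popgendiv",
    version = as.character(utils::packageVersion("popgendiv")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    n_input = nrow(records), n_retained = nrow(harmonized),
    kingdoms = kingdoms,
    settings = config[c("min_sample_size", "pool", "delta",
                        "ri_threshold", "correlogram_bin_km",
                        "correlogram_max_km", "correlogram_n_perm",
                        "jackknife_units")]
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)

  invisible(list(harmonized = harmonized, latitude_fits = lat_fits,
                 kingdom_slopes = kingdom_slopes,
                 phylum_slopes = phylum_slopes,
                 kingdoms = per_kingdom, manifest = manifest))
}

# drop dredge terms whose columns are absent or degenerate in the data
intersect_terms_with_data <- function(terms, data) {
  ok <- vapply(terms, function(tm) {
    cols <- strsplit(tm, ":", fixed = TRUE)[[1]]
    all(cols %in% names(data)) &&
      all(vapply(cols, function(cc) {
        length(unique(na.omit(data[[cc]]))) >= 2
      }, logical(1)))
  }, logical(1))
  terms[ok]
}
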