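#' Configuration of the synthetic diversity study
#'
#' Parameters of the synthetic data model mirroring the structure of the
#' global compilation: species nested in phyla nested in kingdoms, 2-50
#' populations per species scattered around a species range center,
#' marker-type-dependent heterozygosity scales, biogeographic position
#' classes, current and past site temperatures, species traits, and a
#' Gaussian response with species and marker random intercepts and
#' residual variance inversely proportional to the precision weight.
#'
#' Fixed effects are given as a named vector over design columns: a plain
#' name refers to a (standardized) continuous covariate column, a
#' `"factor=level"` name to a 0/1 indicator, and `"a:b"` to the product
#' of two such columns. The defaults encode the reference study
#' conditions used throughout the package's recovery tests: 250 species,
#' a mean of six populations each (about 1500 populations), a
#' standardized distance-from-equator slope of -0.05, a plant deficit of
#' -0.15, species variance equal to half the residual variance, and a
#' small marker variance.
#'
#' @param n_species Total number of species (allocated round-robin over
#'   the nine phyla).
#' @param pops_per_species Integer bounds (min, max) on populations per
#'   species; counts are drawn from a negative binomial with mean
#'   `pops_mean` truncated to these bounds.
#' @param pops_mean Mean populations per species (default 6).
#' @param marker_freq Named frequencies of marker types (sum to 1).
#' @param position_freq Named frequencies of position classes (sum to 1).
#' @param lat_range Latitudinal band of species range centers (degrees).
#' @param cluster_scale_deg SD of population scatter around the range
#'   center (degrees).
#' @param true_beta Named true fixed effects (see above).
#' @param tau2_species,tau2_marker Random-intercept variances.
#' @param sigma2 Residual variance at unit weight.
#' @param marine_frac,flagged_frac,small_sample_frac Fractions of rows
#'   made marine / provenance-flagged / under-sampled, to exercise the
#'   inclusion filters. All 0 by default (a "clean" dataset).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_species = 250,
                             pops_per_species = c(2, 50),
                             pops_mean = 6,
                             marker_freq = c(codominant = 0.60,
                                             dominant = 0.25,
                                             enzyme = 0.15),
                             position_freq = c(core = 0.35, subedge = 0.20,
                                               edge = 0.20, endemic = 0.10,
                                               island = 0.10, isle = 0.05),
                             lat_range = c(-55, 70),
                             cluster_scale_deg = 1.5,
                             true_beta = c("(Intercept)" = 0.55,
                                           "kingdom=plant" = -0.15,
                                           "abs_latitude_std" = -0.05),
                             tau2_species = 0.01,
                             tau2_marker = 0.002,
                             sigma2 = 0.02,
                             marine_frac = 0, flagged_frac = 0,
                             small_sample_frac = 0) {
  cfg <- list(n_species = n_species, pops_per_species = pops_per_species,
              pops_mean = pops_mean, marker_freq = marker_freq,
              position_freq = position_freq, lat_range = lat_range,
              cluster_scale_deg = cluster_scale_deg, true_beta = true_beta,
              tau2_species = tau2_species, tau2_marker = tau2_marker,
              sigma2 = sigma2, marine_frac = marine_frac,
              flagged_frac = flagged_frac,
              small_sample_frac = small_sample_frac)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n_species < 1) abort("n_species must be >= 1")
  if (cfg$pops_per_species[1] < 1 ||
      cfg$pops_per_species[2] < cfg$pops_per_species[1]) {
    abort("pops_per_species bounds must be >= 1 and ordered")
  }
  for (nm in c("marker_freq", "position_freq")) {
    f <- cfg[[nm]]
    if (any(f < 0) || abs(sum(f) - 1) > 1e-8) {
      abort(paste0(nm, " must be non-negative and sum to 1"))
    }
  }
  if (cfg$tau2_species < 0 || cfg$tau2_marker < 0 || cfg$sigma2 < 0) {
    abort("variances must be >= 0")
  }
  invisible(cfg)
}

synthetic_phyla <- function() {
  tibble::tibble(
    phylum = c("eudicot", "magnolid", "monocot", "pine",
               "amphibian", "reptile", "mollusc", "mammal", "bird"),
    kingdom = c(rep("plant", 4), rep("animal", 5))
  )
}

#' Generate synthetic species and population tables
#'
#' Draws the taxonomic and spatial skeleton of a synthetic study:
#' species allocated over phyla and kingdoms with traits and range sizes,
#' and populations with coordinates, elevation, marker metadata,
#' sampling effort, position class and site temperatures. Fully
#' reproducible from `seed`.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return A list with `species` and `populations` tibbles.
#' @export
generate_metadata <- function(config = synthetic_config(), seed) {
  validate_synthetic_config(config)
  if (missing(seed)) abort("a seed is required")

  ph <- synthetic_phyla()
  species <- withr::with_seed(derive_seed(seed, "species"), {
    idx <- rep(seq_len(nrow(ph)), length.out = config$n_species)
    sp <- tibble::tibble(
      species = sprintf("sp%03d", seq_len(config$n_species)),
      phylum = ph$phylum[idx], kingdom = ph$kingdom[idx]
    )
    n <- nrow(sp)
    # slow-fast continuum couples size and longevity against fecundity
    slow <- rnorm(n)
    sp$size <- exp(1.0 + 1.2 * slow + rnorm(n, sd = 0.4))
    sp$longevity <- exp(2.0 + 1.0 * slow + rnorm(n, sd = 0.4))
    sp$fecundity <- exp(3.0 - 1.1 * slow + rnorm(n, sd = 0.6))
    is_plant <- sp$kingdom == "plant"
    sp$size[is_plant] <- NA; sp$longevity[is_plant] <- NA
    sp$fecundity[is_plant] <- NA
    draw <- function(freq, n) {
      sample(names(freq), n, replace = TRUE, prob = freq)
    }
    np <- sum(is_plant)
    sp$pollen <- NA_character_; sp$seed <- NA_character_
    sp$mating <- NA_character_; sp$lifeform <- NA_character_
    if (np > 0) {
      sp$pollen[is_plant] <- draw(c(biotic = .55, abiotic = .45), np)
      sp$seed[is_plant] <- draw(c(animal = .33, wind = .42,
                                  water = .12, local = .13), np)
      sp$mating[is_plant] <- draw(c(self_incompatible = .41,
                                    self_compatible = .33,
                                    clonal = .17, non_clonal = .09), np)
      sp$lifeform[is_plant] <- draw(c(annual = .04, perennial = .33,
                                      shrub = .08, tree = .55), np)
    }
    sp$range_area <- rlnorm(n, meanlog = log(2e5), sdlog = 1.8)
    sp$center_lat <- runif(n, config$lat_range[1], config$lat_range[2])
    sp$center_lon <- runif(n, -180, 180)
    sp
  })

  populations <- withr::with_seed(derive_seed(seed, "populations"), {
    lo <- config$pops_per_species[1]; hi <- config$pops_per_species[2]
    npop <- pmin(hi, pmax(lo, rnbinom(nrow(species), size = 2,
                                      mu = config$pops_mean)))
    pop <- species[rep(seq_len(nrow(species)), npop),
                   c("species", "phylum", "kingdom", "range_area")]
    n <- nrow(pop)
    ctr_lat <- rep(species$center_lat, npop)
    ctr_lon <- rep(species$center_lon, npop)
    pop$latitude <- pmin(89.9, pmax(-89.9,
      ctr_lat + rnorm(n, sd = config$cluster_scale_deg)))
    pop$longitude <- ((ctr_lon + rnorm(n, sd = config$cluster_scale_deg) +
                         180) %% 360) - 180
    pop$elevation <- pmax(0, rnorm(n, mean = 600, sd = 500))
    pop$marker_type <- sample(names(config$marker_freq), n, replace = TRUE,
                              prob = config$marker_freq)
    pop$n_loci <- dplyr::case_when(
      pop$marker_type == "codominant" ~ sample(5:30, n, replace = TRUE),
      pop$marker_type == "dominant" ~ sample(50:300, n, replace = TRUE),
      TRUE ~ sample(5:25, n, replace = TRUE)
    )
    pop$sample_size <- sample(10:100, n, replace = TRUE)
    pop$position <- factor(
      sample(names(config$position_freq), n, replace = TRUE,
             prob = config$position_freq),
      levels = c("core", "subedge", "edge", "endemic", "island", "isle"))
    pop$habitat <- sample(c("terrestrial", "freshwater"), n,
                          replace = TRUE, prob = c(.8, .2))
    pop$provenance_flags <- ""
    # site temperatures: latitude-driven, past epochs drift away
    pop$temp_current <- 27 - 0.43 * abs(pop$latitude) + rnorm(n, sd = 2)
    pop$temp_mh <- pop$temp_current + rnorm(n, sd = 1.2)
    pop$temp_lgm <- pop$temp_current - 4 + rnorm(n, sd = 2.5)

    if (config$marine_frac > 0) {
      i <- sample(n, round(config$marine_frac * n))
      pop$habitat[i] <- "marine"
    }
    if (config$flagged_frac > 0) {
      i <- sample(n, round(config$flagged_frac * n))
      pop$provenance_flags[i] <- sample(c("introduced", "invasive",
                                          "cultivar"),
                                        length(i), replace = TRUE)
    }
    if (config$small_sample_frac > 0) {
      i <- sample(n, round(config$small_sample_frac * n))
      pop$sample_size[i] <- sample(3:9, length(i), replace = TRUE)
    }
    pop$population_id <- sprintf("pop%05d", seq_len(n))
    tibble::as_tibble(pop[, c("population_id",
                              setdiff(names(pop), "population_id"))])
  })

  list(species = species, populations = populations)
}

# design columns named like the true-beta entries
build_truth_design <- function(data, beta_names) {
  col_of <- function(nm) {
    if (nm == "(Intercept)") return(rep(1, nrow(data)))
    if (grepl(":", nm, fixed = TRUE)) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      return(col_of(parts[1]) * col_of(parts[2]))
    }
    if (grepl("=", nm, fixed = TRUE)) {
      fl <- strsplit(nm, "=", fixed = TRUE)[[1]]
      if (!fl[1] %in% names(data)) abort(paste0("unknown factor: ", fl[1]))
      return(as.numeric(data[[fl[1]]] == fl[2]))
    }
    if (!nm %in% names(data)) abort(paste0("unknown design column: ", nm))
    as.numeric(data[[nm]])
  }
  X <- vapply(beta_names, col_of, numeric(nrow(data)))
  dimnames(X) <- list(NULL, beta_names)
  X
}

#' Simulate the harmonized diversity response
#'
#' Draws `y = X beta + sum_f Z_f u_f + e` with independent random
#' intercepts `u_f ~ N(0, tau2_f)` per grouping factor and heteroscedastic
#' residuals `e_i ~ N(0, sigma2 / w_i)`. With all variances zero the
#' response equals `X beta` exactly. An optional clipped-to-`[0, 1]`
#' variant is available but off by default.
#'
#' @param X Design matrix whose columns match `names(truth$beta)`.
#' @param truth List with `beta` (named), `tau2` (named by grouping
#'   factor) and `sigma2`.
#' @param weights Positive precision weights (default all 1).
#' @param seed Integer seed.
#' @param groups Named list of grouping factors (one per `tau2` entry),
#'   each of length `nrow(X)`.
#' @param clip Clip the response into `[0, 1]` (default FALSE).
#' @return Numeric response vector; realized group effects are attached
#'   as attribute `"ranef"`.
#' @export
simulate_gdp <- function(X, truth, weights = NULL, seed, groups = list(),
                         clip = FALSE) {
  if (missing(seed)) abort("a seed is required")
  X <- as.matrix(X)
  if (!identical(colnames(X), names(truth$beta))) {
    abort("design columns must match names(truth$beta)")
  }
  n <- nrow(X)
  weights <- weights %||% rep(1, n)
  if (length(weights) != n || any(weights <= 0)) {
    abort("weights must be positive and match nrow(X)")
  }
  if (!identical(sort(names(truth$tau2)), sort(names(groups)))) {
    abort("groups must carry one factor per tau2 entry")
  }
  for (g in groups) {
    if (length(g) != n) abort("each grouping factor must have nrow(X) values")
  }
  withr::with_seed(seed, {
    y <- drop(X %*% truth$beta)
    ranef <- list()
    for (nm in names(truth$tau2)) {
      f <- factor(groups[[nm]])
      u <- rnorm(nlevels(f), sd = sqrt(truth$tau2[[nm]]))
      ranef[[nm]] <- setNames(u, levels(f))
      y <- y + u[as.integer(f)]
    }
    y <- y + rnorm(n, sd = sqrt(truth$sigma2 / weights))
    if (clip) y <- pmin(1, pmax(0, y))
    attr(y, "ranef") <- ranef
    y
  })
}

# marker-specific affine map from the harmonized scale back to a
# plausible raw-He scale (dominant markers are bounded at 0.5)
backtransform_he <- function(gdp, marker_type) {
  a <- c(codominant = 0.10, dominant = 0.05, enzyme = 0.05)
  b <- c(codominant = 0.60, dominant = 0.30, enzyme = 0.25)
  g <- pmin(1, pmax(0, gdp))
  unname(a[marker_type] + b[marker_type] * g)
}

#' Generate a complete analysis-ready synthetic dataset
#'
#' Joins the synthetic metadata, derived covariates (standardized
#' distance from equator, elevation and log range size; synthetic climate
#' axes; past-temperature stability scores; species trait principal
#' components for animals), precision weights and the simulated response,
#' together with the ground truth behind it. With the default (clean)
#' configuration the result passes [apply_inclusion_filters()] with zero
#' exclusions. A plausible raw-He column (`he_raw`) is provided via a
#' marker-specific affine back-transform for I/O realism.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; all sub-streams derive from it.
#' @return A list with `data` (population-level tibble including `gdp`,
#'   `weight` and all covariates), `species`, and `truth` (a
#'   `ground_truth` list: `beta`, `tau2`, `sigma2`, `linpred`, `ranef`,
#'   `seed`).
#' @export
make_dataset <- function(config = synthetic_config(), seed) {
  if (missing(seed)) abort("a seed is required")
  meta <- generate_metadata(config, seed)
  sp <- meta$species
  d <- meta$populations

  d$abs_latitude <- abs(d$latitude)
  zsc <- function(x) as.numeric(scale(x))
  d$abs_latitude_std <- zsc(d$abs_latitude)
  d$elevation_std <- zsc(d$elevation)
  d$range_area_std <- zsc(log10(d$range_area))
  d$mh_stability <- temperature_stability(d$temp_current, d$temp_mh)
  d$lgm_stability <- temperature_stability(d$temp_current, d$temp_lgm)

  clim <- withr::with_seed(derive_seed(seed, "climate"), {
    n <- nrow(d)
    tibble::tibble(
      temperature_pc = zsc(d$temp_current),
      precipitation_pc = zsc(0.6 * zsc(-d$abs_latitude) + rnorm(n)),
      humidity_pc = zsc(rnorm(n))
    )
  })
  d <- dplyr::bind_cols(d, clim)

  anim <- sp[sp$kingdom == "animal", ]
  if (nrow(anim) >= 3) {
    pcs <- lifehistory_pcs(anim)
    d <- dplyr::left_join(d, pcs, by = "species")
  } else {
    d$pc_size_longevity <- NA_real_
    d$pc_fecundity <- NA_real_
  }
  d <- dplyr::left_join(
    d, sp[, c("species", "pollen", "seed", "mating", "lifeform")],
    by = "species")

  d$weight <- precision_weight(d$n_loci, d$sample_size)

  X <- build_truth_design(d, names(config$true_beta))
  truth <- list(beta = config$true_beta,
                tau2 = c(species = config$tau2_species,
                         marker_type = config$tau2_marker),
                sigma2 = config$sigma2, seed = seed)
  y <- simulate_gdp(X, truth, weights = d$weight,
                    seed = derive_seed(seed, "response"),
                    groups = list(species = d$species,
                                  marker_type = d$marker_type))
  truth$ranef <- attr(y, "ranef")
  truth$linpred <- drop(X %*% truth$beta)
  class(truth) <- "ground_truth"
  d$gdp <- as.numeric(y)
  d$he_raw <- backtransform_he(d$gdp, d$marker_type)

  list(data = d, species = sp, truth = truth)
}

#' Write / read a synthetic dataset bundle
#'
#' Serializes a [make_dataset()] result as plain-text files: population
#' and species tables as CSV, ground truth as JSON.
#'
#' @param ds A [make_dataset()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset_bundle <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  # doubles serialized at %.17g so the text round-trips bit-exactly
  full_precision <- function(df) {
    df[] <- lapply(df, function(col) {
      if (is.double(col)) sprintf("%.17g", col) else col
    })
    df
  }
  readr::write_csv(full_precision(ds$data),
                   file.path(dir, "populations.csv"))
  readr::write_csv(full_precision(ds$species),
                   file.path(dir, "species.csv"))
  tr <- ds$truth
  jsonlite::write_json(
    list(beta = as.list(tr$beta), tau2 = as.list(tr$tau2),
         sigma2 = tr$sigma2, seed = tr$seed,
         ranef = lapply(tr$ranef, as.list)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
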