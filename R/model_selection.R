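#' Full kingdom model specification
#'
#' The exhaustive fixed-effect structure for one kingdom: all main
#' predictors (biogeographic position, life-history descriptors, range
#' size, elevation, the three current-climate axes, the two past-climate
#' stability scores, and phylum), the pairwise interactions between
#' position and each life-history descriptor, and the pairwise
#' interactions of phylum with every other predictor. Species and marker
#' type enter as random intercepts, rows are precision-weighted.
#'
#' Animal life history is carried by the two trait principal components
#' ([lifehistory_pcs()]); plant life history by the four categorical
#' traits (pollen, seed, mating, lifeform).
#'
#' @param kingdom `"animal"` or `"plant"`.
#' @return A [model_spec()].
#' @export
build_full_kingdom_spec <- function(kingdom = c("animal", "plant")) {
  kingdom <- match.arg(kingdom)
  lifehist <- if (kingdom == "animal") {
    c("pc_size_longevity", "pc_fecundity")
  } else {
    c("pollen", "seed", "mating", "lifeform")
  }
  shared <- c("range_area", "elevation", "temperature_pc",
              "precipitation_pc", "humidity_pc", "mh_stability",
              "lgm_stability")
  mains <- c("position", lifehist, shared, "phylum")
  ints <- c(paste("position", lifehist, sep = ":"),
            paste("phylum", setdiff(mains, "phylum"), sep = ":"))
  model_spec("gdp", c(mains, ints),
             random = c("species", "marker_type"), weights = "weight")
}

#' Enumerate all marginality-respecting submodels
#'
#' Every subset of the full specification's fixed terms in which each
#' interaction is accompanied by both parent mains, from the
#' intercept-only model up to the full model. Random factors, weights and
#' method are identical across all variants; the ordering is
#' deterministic (mains subsets in binary counting order, then
#' interaction subsets likewise).
#'
#' @param full A [model_spec()] (the full model).
#' @param cap Maximum number of submodels to materialize; exceeding it is
#'   an error advising term reduction. Default `1e5`.
#' @return List of [model_spec()] objects.
#' @export
enumerate_submodels <- function(full, cap = 1e5) {
  stopifnot(inherits(full, "model_spec"))
  ints <- full$fixed[grepl(":", full$fixed, fixed = TRUE)]
  mains <- setdiff(full$fixed, ints)
  parents <- lapply(ints, function(tm) strsplit(tm, ":", fixed = TRUE)[[1]])
  nm <- length(mains)

  main_subsets <- if (nm == 0) list(character()) else {
    lapply(0:(2^nm - 1), function(code) mains[bitwAnd(code, 2^(seq_len(nm) - 1)) > 0])
  }
  total <- sum(vapply(main_subsets, function(ms) {
    avail <- sum(vapply(parents, function(p) all(p %in% ms), logical(1)))
    2^avail
  }, numeric(1)))
  if (total > cap) {
    abort(sprintf(paste0("submodel space has %.0f models, above the cap of ",
                         "%.0f; reduce terms or raise `cap`"), total, cap))
  }

  out <- vector("list", total)
  pos <- 1L
  for (ms in main_subsets) {
    avail <- ints[vapply(parents, function(p) all(p %in% ms), logical(1))]
    na <- length(avail)
    int_subsets <- if (na == 0) list(character()) else {
      lapply(0:(2^na - 1),
             function(code) avail[bitwAnd(code, 2^(seq_len(na) - 1)) > 0])
    }
    for (is_ in int_subsets) {
      out[[pos]] <- model_spec(full$response, c(ms, is_),
                               random = full$random, weights = full$weights,
                               method = full$method)
      pos <- pos + 1L
    }
  }
  out
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1) / (n - k - 1)`.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters (fixed coefficients plus
#'   variance components, including the residual variance).
#' @param n Number of observations; must exceed `k + 1`.
#' @return The AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (any(n <= k + 1)) abort("AICc requires n > k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit every submodel of a full specification
#'
#' Enumerates the marginality-respecting submodels of `full`
#' ([enumerate_submodels()]) and fits each by maximum likelihood with
#' [fit_weighted_lmm()], collecting the information-criterion table.
#'
#' @param data Data frame passed to every fit.
#' @param full The full [model_spec()].
#' @param cap Enumeration cap (see [enumerate_submodels()]).
#' @return A tibble with one row per submodel: `model_id`, `terms`
#'   (`" + "`-joined fixed terms), `logLik`, `k`, `n`, `AICc`, plus the
#'   list of specs as attribute `"specs"` and `full` as attribute
#'   `"full_spec"`.
#' @export
dredge_models <- function(data, full, cap = 1e5) {
  specs <- enumerate_submodels(full, cap = cap)
  rows <- purrr::map2_dfr(specs, seq_along(specs), function(sp, i) {
    f <- fit_weighted_lmm(data, sp, method = "ML")
    tibble::tibble(model_id = i,
                   terms = paste(sp$fixed, collapse = " + "),
                   logLik = f$loglik, k = f$k, n = f$n, AICc = f$aicc)
  })
  attr(rows, "specs") <- specs
  attr(rows, "full_spec") <- full
  rows
}

#' Candidate model set within a AICc window
#'
#' Retains the models whose AICc lies within `delta` of the best model
#' and attaches Akaike weights renormalized over the retained set:
#' `w_i = exp(-d_i / 2) / sum_j exp(-d_j / 2)`.
#'
#' @param models Tibble with at least an `AICc` column (e.g. from
#'   [dredge_models()]).
#' @param delta AICc window (default 4).
#' @return The retained rows with `delta_aicc` and `weight` columns,
#'   ordered by AICc; class `candidate_set`. Attributes of `models`
#'   (`"specs"`, `"full_spec"`) are carried over.
#' @export
candidate_set <- function(models, delta = 4) {
  stopifnot(is.data.frame(models), "AICc" %in% names(models),
            nrow(models) >= 1, delta > 0)
  out <- models |>
    tibble::as_tibble() |>
    dplyr::mutate(delta_aicc = .data$AICc - min(.data$AICc)) |>
    dplyr::filter(.data$delta_aicc < .env$delta) |>
    dplyr::arrange(.data$delta_aicc) |>
    dplyr::mutate(weight = exp(-.data$delta_aicc / 2) /
                    sum(exp(-.data$delta_aicc / 2)))
  attr(out, "specs") <- attr(models, "specs")
  attr(out, "full_spec") <- attr(models, "full_spec")
  class(out) <- c("candidate_set", class(out))
  out
}

#' Per-term relative importance from a candidate set
#'
#' The relative importance (RI) of a fixed term is the sum of the Akaike
#' weights of the candidate models containing it, expressed in percent.
#' Because weights are renormalized over the candidate set, a term
#' present in every candidate model has RI = 100% and a term in none has
#' RI = 0%.
#'
#' @param cs A [candidate_set()].
#' @return Tibble with `term`, `ri` (percent) and `n_models` (number of
#'   supporting candidate models), ordered by decreasing RI; class
#'   `ri_table`, carrying the full spec as attribute.
#' @export
relative_importance <- function(cs) {
  stopifnot(inherits(cs, "candidate_set"), nrow(cs) >= 1)
  full <- attr(cs, "full_spec")
  all_terms <- if (!is.null(full)) full$fixed else {
    unique(unlist(strsplit(cs$terms, " + ", fixed = TRUE)))
  }
  all_terms <- all_terms[nzchar(all_terms)]
  model_terms <- lapply(strsplit(cs$terms, " + ", fixed = TRUE),
                        canonical_term)
  out <- purrr::map_dfr(all_terms, function(tm) {
    ct <- canonical_term(tm)
    hit <- vapply(model_terms, function(ts) ct %in% ts, logical(1))
    tibble::tibble(term = tm, ri = 100 * sum(cs$weight[hit]),
                   n_models = sum(hit))
  }) |>
    dplyr::arrange(dplyr::desc(.data$ri))
  attr(out, "full_spec") <- full
  class(out) <- c("ri_table", class(out))
  out
}

#' Select final-model terms by relative importance
#'
#' Keeps the terms whose RI strictly exceeds `threshold` (percent) and
#' closes the selection under marginality: a selected interaction pulls
#' both parent mains into the final model even if their own RI falls at
#' or below the threshold.
#'
#' @param ri An [relative_importance()] table.
#' @param threshold RI threshold in percent (default 50; strict
#'   inequality).
#' @return A [model_spec()] with the selected fixed terms and the
#'   candidate set's random / weight structure. An empty selection
#'   returns the intercept-only spec with a warning.
#' @export
select_final_terms <- function(ri, threshold = 50) {
  stopifnot(inherits(ri, "ri_table"))
  full <- attr(ri, "full_spec")
  if (is.null(full)) abort("ri table lacks the full model spec attribute")
  keep <- ri$term[ri$ri > threshold]
  ints <- keep[grepl(":", keep, fixed = TRUE)]
  keep <- unique(c(keep, unlist(strsplit(ints, ":", fixed = TRUE))))
  keep <- full$fixed[canonical_term(full$fixed) %in% canonical_term(keep)]
  if (length(keep) == 0) {
    warn("no term exceeds the RI threshold; returning intercept-only model")
  }
  model_spec(full$response, keep, random = full$random,
             weights = full$weights, method = full$method)
}
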