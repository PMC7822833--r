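#' Life-history principal components for animal species
#'
#' Collapses the three correlated animal life-history traits -- lifetime
#' fecundity, average body size and maximum longevity -- into two principal
#' components computed on centered, unit-variance (log10) traits. Component
#' signs are fixed so that the first component loads positively on size and
#' longevity (slow, large, long-lived species score high) and the second
#' loads positively on fecundity.
#'
#' @param traits Data frame with `species`, `fecundity`, `size`,
#'   `longevity` columns. Rows with missing traits are dropped.
#' @param log10_transform Log10-transform the traits before the PCA
#'   (default TRUE; set FALSE if they are already on a log scale).
#' @return A tibble with `species`, `pc_size_longevity`, `pc_fecundity`.
#'   The full loading matrix (traits x components, all three components)
#'   is attached as attribute `"loadings"`, the standardized trait matrix
#'   as `"scaled_traits"`, and all (sign-fixed) scores as `"scores"`.
#' @export
lifehistory_pcs <- function(traits, log10_transform = TRUE) {
  stopifnot(is.data.frame(traits))
  needed <- c("species", "fecundity", "size", "longevity")
  missing_cols <- setdiff(needed, names(traits))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  tr <- traits[stats::complete.cases(traits[, c("fecundity", "size",
                                                "longevity")]), ]
  if (nrow(tr) < 3) abort("need >= 3 species with complete trait data")
  m <- as.matrix(tr[, c("fecundity", "size", "longevity")])
  if (log10_transform) {
    if (any(m <= 0)) abort("traits must be positive for log10 transform")
    m <- log10(m)
  }
  if (any(apply(m, 2, sd) == 0)) {
    abort("constant trait column; cannot standardize for PCA")
  }
  pca <- prcomp(m, center = TRUE, scale. = TRUE)
  rot <- pca$rotation
  scores <- pca$x

  # orient PC1 along size+longevity, PC2 along fecundity
  flip <- rep(1, ncol(rot))
  if (sum(rot[c("size", "longevity"), 1]) < 0) flip[1] <- -1
  if (rot["fecundity", 2] < 0) flip[2] <- -1
  rot <- sweep(rot, 2, flip, `*`)
  scores <- sweep(scores, 2, flip, `*`)

  out <- tibble::tibble(
    species = tr$species,
    pc_size_longevity = scores[, 1],
    pc_fecundity = scores[, 2]
  )
  attr(out, "loadings") <- rot
  attr(out, "scaled_traits") <- scale(m)
  attr(out, "scores") <- scores
  attr(out, "sdev") <- pca$sdev
  out
}

#' Synthetic current-climate axes from site-level climate variables
#'
#' Reduces a table of current-climate variables to three orthogonal
#' synthetic predictors via PCA on standardized columns. The three retained
#' components are labeled `temperature_pc`, `precipitation_pc` and
#' `humidity_pc` according to the variable *family* carrying each
#' component's dominant loading. Families are either supplied explicitly
#' (named character vector `variable -> family`) or inferred from column
#' name prefixes (`temp*`, `prec*`/`rain*`, `humid*`/`vap*`).
#'
#' @param climate Data frame of numeric climate columns (>= 4 variables,
#'   >= 4 sites). Non-numeric columns are ignored.
#' @param families Optional named character vector mapping column names to
#'   one of `"temperature"`, `"precipitation"`, `"humidity"`.
#' @return Tibble with `temperature_pc`, `precipitation_pc`, `humidity_pc`
#'   (one row per site); attributes `"loadings"` (all components, sign
#'   fixed so the dominant loading is positive), `"explained_variance"`
#'   and `"component_families"`.
#' @export
climate_pcs <- function(climate, families = NULL) {
  stopifnot(is.data.frame(climate))
  num <- vapply(climate, is.numeric, logical(1))
  m <- as.matrix(climate[, num, drop = FALSE])
  if (ncol(m) < 4) abort("need >= 4 numeric climate variables")
  if (nrow(m) < 4) abort("need >= 4 sites")
  if (any(!stats::complete.cases(m))) abort("climate table has missing values")
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("constant (collinear) columns: ",
                 paste(colnames(m)[sds == 0], collapse = ", ")))
  }
  qrr <- qr(scale(m))
  if (qrr$rank < ncol(m)) {
    bad <- colnames(m)[qrr$pivot[(qrr$rank + 1):ncol(m)]]
    abort(paste0("rank-deficient climate table; collinear columns: ",
                 paste(bad, collapse = ", ")))
  }

  if (is.null(families)) {
    families <- infer_climate_family(colnames(m))
  }
  unknown <- setdiff(colnames(m), names(families))
  if (length(unknown) > 0) {
    abort(paste0("cannot infer climate family for: ",
                 paste(unknown, collapse = ", "),
                 "; pass `families` explicitly"))
  }

  pca <- prcomp(m, center = TRUE, scale. = TRUE)
  rot <- pca$rotation
  scores <- pca$x
  # sign convention: dominant loading positive
  for (j in seq_len(ncol(rot))) {
    dom <- which.max(abs(rot[, j]))
    if (rot[dom, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }

  k <- min(3, ncol(rot))
  comp_family <- vapply(seq_len(k), function(j) {
    unname(families[[colnames(m)[which.max(abs(rot[, j]))]]])
  }, character(1))

  pick <- function(fam) {
    j <- match(fam, comp_family)
    if (is.na(j)) rep(NA_real_, nrow(scores)) else scores[, j]
  }
  out <- tibble::tibble(
    temperature_pc = pick("temperature"),
    precipitation_pc = pick("precipitation"),
    humidity_pc = pick("humidity")
  )
  if (anyNA(out)) {
    warn(paste0("retained components map to families: ",
                paste(comp_family, collapse = ", "),
                "; axes without a matching family are NA"))
  }
  attr(out, "loadings") <- rot
  attr(out, "scores") <- scores
  attr(out, "explained_variance") <- pca$sdev^2 / sum(pca$sdev^2)
  attr(out, "component_families") <- comp_family
  out
}

infer_climate_family <- function(vars) {
  fam <- rep(NA_character_, length(vars))
  fam[grepl("^temp|^tmean|^tmin|^tmax|^bio_?0?[1-9]$", vars,
            ignore.case = TRUE)] <- "temperature"
  fam[grepl("^prec|^rain|^ppt|^bio_?1[2-9]$", vars,
            ignore.case = TRUE)] <- "precipitation"
  fam[grepl("^humid|^vap|^aridity|^pet", vars,
            ignore.case = TRUE)] <- "humidity"
  setNames(fam, vars)[!is.na(fam)]
}

#' Past-temperature stability score
#'
#' Stability of local temperature relative to a past reference epoch
#' (Mid-Holocene, ~6 kyr BP, or Last Glacial Maximum, ~22 kyr BP). The raw
#' score is the negated absolute current-past difference, `-|t_now -
#' t_past|`, so that sites whose temperature changed least score highest;
#' it is then z-standardized across the dataset (sample SD). Scores are
#' invariant to a common additive shift of both epochs.
#'
#' @param temp_current,temp_past Numeric vectors of site temperatures
#'   (same length, any common unit).
#' @return Standardized stability scores (mean 0, sample variance 1);
#'   larger = more stable.
#' @export
temperature_stability <- function(temp_current, temp_past) {
  if (length(temp_current) != length(temp_past)) {
    abort("temperature vectors must have the same length")
  }
  if (length(temp_current) < 2) abort("need >= 2 sites")
  raw <- -abs(temp_current - temp_past)
  if (sd(raw) == 0) {
    abort("all current-past differences identical; stability is degenerate")
  }
  as.numeric(scale(raw))
}
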