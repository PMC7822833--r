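#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param lon1,lat1,lon2,lat2 Coordinate vectors in WGS84 decimal degrees
#'   (recycled to a common length).
#' @return Distances in km.
#' @examples
#' great_circle_km(0, 0, 0, 180) # half the 6371-km sphere's circumference
#' @export
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  check_coords <- function(lon, lat) {
    if (any(!is.finite(lon)) || any(!is.finite(lat)) ||
        any(abs(lat) > 90) || any(abs(lon) > 180)) {
      abort("coordinates must be finite, |lat| <= 90, |lon| <= 180")
    }
  }
  check_coords(lon1, lat1); check_coords(lon2, lat2)
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371)
}

pairwise_km <- function(lon, lat) {
  m <- geosphere::distm(cbind(lon, lat),
                        fun = function(a, b) {
                          geosphere::distHaversine(a, b, r = 6371)
                        })
  dimnames(m) <- NULL
  m
}

#' Moran's I spatial autocorrelation statistic
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2`, with `z` the
#' mean-centered values and `S0` the total weight. Expectation under no
#' autocorrelation is `-1 / (n - 1)`.
#'
#' @param values Numeric vector (length >= 3, not constant).
#' @param weights An `n x n` non-negative spatial weight matrix with zero
#'   diagonal and positive total.
#' @return Moran's I.
#' @export
morans_i <- function(values, weights) {
  n <- length(values)
  if (n < 3) abort("need >= 3 values")
  if (!is.matrix(weights) || any(dim(weights) != n)) {
    abort("weights must be an n x n matrix")
  }
  if (any(weights < 0)) abort("weights must be non-negative")
  if (any(diag(weights) != 0)) abort("weight matrix diagonal must be zero")
  s0 <- sum(weights)
  if (s0 <= 0) abort("all-zero weight matrix")
  z <- values - mean(values)
  denom <- sum(z^2)
  if (denom == 0) abort("constant values; Moran's I undefined")
  (n / s0) * drop(t(z) %*% weights %*% z) / denom
}

#' Moran's I autocorrelogram over geographic distance classes
#'
#' Bins all point pairs into half-open great-circle distance classes
#' `[lower, upper)` of width `bin_width_km` up to `max_km`, computes
#' Moran's I per class with binary membership weights, and attaches a
#' one-sided permutation p-value per class (probability of an equal or
#' larger I under random relabelling of the values). Classes with fewer
#' than two pairs are flagged empty and carry no statistic.
#'
#' @param data Data frame with `longitude` and `latitude` columns and the
#'   value column named by `value`.
#' @param value Name of the column to test (e.g. `"residual"` or
#'   `"gdp"`).
#' @param bin_width_km Distance-class width in km (default 100).
#' @param max_km Largest class upper edge in km (default 5000).
#' @param n_perm Number of permutations (default 999).
#' @param seed Seed for the permutation stream (required).
#' @return A tibble of class `correlogram`: `lower_km`, `upper_km`,
#'   `n_pairs`, `morans_i`, `p_value`, `empty`; the no-autocorrelation
#'   expectation `-1/(n-1)` is attached as attribute `"expectation"`.
#' @export
correlogram <- function(data, value, bin_width_km = 100, max_km = 5000,
                        n_perm = 999, seed) {
  stopifnot(is.data.frame(data))
  if (missing(seed)) abort("a seed is required for the permutation test")
  if (!all(c("longitude", "latitude", value) %in% names(data))) {
    abort(paste0("data needs longitude, latitude and ", value, " columns"))
  }
  vals <- data[[value]]
  n <- length(vals)
  if (n < 10) abort("need >= 10 points for a correlogram")
  D <- pairwise_km(data$longitude, data$latitude)
  edges <- seq(0, max_km, by = bin_width_km)
  n_class <- length(edges) - 1

  # pair-list form of the binary-weight Moran's I: for class c with
  # n_p pairs, I = n * sum_pairs(z_i z_j) / (n_p * sum z^2)
  ut <- which(upper.tri(D))
  ii <- row(D)[ut]; jj <- col(D)[ut]; dd <- D[ut]
  cls <- findInterval(dd, edges, left.open = FALSE, rightmost.closed = FALSE)
  cls[dd >= max_km] <- 0L
  pair_idx <- lapply(seq_len(n_class), function(c) which(cls == c))
  n_pairs <- lengths(pair_idx)

  z <- vals - mean(vals)
  denom <- sum(z^2)
  if (denom == 0) abort("constant values; Moran's I undefined")
  valid <- n_pairs >= 2
  class_i <- function(zv) {
    out <- rep(NA_real_, n_class)
    for (c in which(valid)) {
      idx <- pair_idx[[c]]
      out[c] <- n * sum(zv[ii[idx]] * zv[jj[idx]]) / (n_pairs[c] * denom)
    }
    out
  }
  obs <- class_i(z)
  exceed <- rep(0L, n_class)
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      zp <- z[sample.int(n)]
      hit <- class_i(zp) >= obs
      exceed <- exceed + ifelse(is.na(hit), 0L, hit)
    }
  })

  rows <- tibble::tibble(
    lower_km = edges[-length(edges)], upper_km = edges[-1],
    n_pairs = n_pairs,
    morans_i = ifelse(n_pairs < 2, NA_real_, obs),
    p_value = ifelse(n_pairs < 2, NA_real_,
                     (1 + exceed) / (n_perm + 1)),
    empty = n_pairs < 2
  )
  attr(rows, "expectation") <- -1 / (n - 1)
  attr(rows, "value") <- value
  class(rows) <- c("correlogram", class(rows))
  rows
}

#' 3-degree geographic grid cell of a coordinate
#'
#' Cells are half-open `[a, a + cell_deg)` intervals in longitude and
#' latitude anchored at (-180, -90); points on the antimeridian
#' (longitude exactly 180) belong to the westernmost adjacent cell.
#'
#' @param lon,lat Coordinates in decimal degrees.
#' @param cell_deg Cell size in degrees (default 3).
#' @return Character cell identifiers `"ix_iy"` (zero-based indices).
#' @examples
#' grid_cell(4.9, 50.2) # cell [3, 6) x [48, 51)
#' @export
grid_cell <- function(lon, lat, cell_deg = 3) {
  ix <- floor((lon + 180) / cell_deg)
  iy <- floor((lat + 90) / cell_deg)
  ix[lon >= 180] <- floor((180 - 1e-9 + 180) / cell_deg)
  iy[lat >= 90] <- floor((90 - 1e-9 + 90) / cell_deg)
  paste0(ix, "_", iy)
}

#' Delete-group jackknife over species or geographic cells
#'
#' Refits the model once per left-out unit -- every distinct species, or
#' every occupied 3-degree longitude x latitude cell -- and summarizes
#' the sensitivity of each fixed coefficient with the delete-group
#' jackknife standard error `sqrt((m - 1) / m * sum((b_-i - mean(b_-i))^2))`
#' over the `m` leave-out estimates, and the normal 95% CI centered on
#' the full-data estimate. Leave-out fits that fail (e.g. a dropped
#' factor level) are skipped with a warning.
#'
#' @param data Data frame with the model columns plus `species` or
#'   `longitude`/`latitude` depending on `unit`.
#' @param spec A [model_spec()].
#' @param unit `"species"` or `"grid3deg"`.
#' @param conf.level Confidence level (default 0.95).
#' @return A tibble of class `jackknife_result` with `term`, `estimate`
#'   (full data), `se_jack`, `conf.low`, `conf.high`; attributes
#'   `"unit"`, `"n_units"`, `"n_failed"` and `"replicates"` (units x
#'   terms matrix of leave-out estimates).
#' @export
jackknife <- function(data, spec, unit = c("species", "grid3deg"),
                      conf.level = 0.95) {
  unit <- match.arg(unit)
  stopifnot(is.data.frame(data), inherits(spec, "model_spec"))
  id <- if (unit == "species") {
    as.character(data$species)
  } else {
    grid_cell(data$longitude, data$latitude)
  }
  units <- sort(unique(id))
  if (length(units) < 3) abort("need >= 3 distinct units to jackknife")

  full <- fit_weighted_lmm(data, spec)
  full_beta <- setNames(full$coefficients$estimate, full$coefficients$term)

  reps <- matrix(NA_real_, nrow = length(units), ncol = length(full_beta),
                 dimnames = list(units, names(full_beta)))
  failed <- character()
  for (u in units) {
    est <- tryCatch({
      f <- fit_weighted_lmm(data[id != u, , drop = FALSE], spec)
      setNames(f$coefficients$estimate, f$coefficients$term)
    }, error = function(e) NULL)
    if (is.null(est) || !setequal(names(est), names(full_beta))) {
      failed <- c(failed, u)
    } else {
      reps[u, names(est)] <- est
    }
  }
  if (length(failed) > 0) {
    warn(sprintf("%d of %d leave-out refits failed and were skipped",
                 length(failed), length(units)))
    reps <- reps[!rownames(reps) %in% failed, , drop = FALSE]
  }
  m <- nrow(reps)
  if (m < 3) abort("fewer than 3 successful leave-out refits")

  zq <- qnorm(1 - (1 - conf.level) / 2)
  se <- apply(reps, 2, function(b) {
    sqrt((m - 1) / m * sum((b - mean(b))^2))
  })
  out <- tibble::tibble(
    term = names(full_beta), estimate = unname(full_beta),
    se_jack = unname(se),
    conf.low = unname(full_beta - zq * se),
    conf.high = unname(full_beta + zq * se)
  )
  attr(out, "unit") <- unit
  attr(out, "n_units") <- length(units)
  attr(out, "n_failed") <- length(failed)
  attr(out, "replicates") <- reps
  class(out) <- c("jackknife_result", class(out))
  out
}
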