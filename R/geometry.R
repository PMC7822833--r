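#' Species range geometry
#'
#' Container for a species' distribution range: one or more WGS84 polygons
#' (optionally with holes), the total range area, and the insular context
#' of the populations it covers. Geometry is evaluated in a Lambert
#' azimuthal equal-area projection centered on the range's vertex centroid,
#' so area shares are faithful for ranges of realistic extent.
#'
#' @param polygons A single two-column matrix (lon, lat), or a list of
#'   polygons, each either a matrix (outer ring only) or a list of rings
#'   (first ring = exterior, others = holes).
#' @param insular_context `"mainland"` (default) or `"insular"`.
#' @param landmass_area_km2 Area of the inhabited landmass, required when
#'   `insular_context = "insular"` (distinguishes islands from isles).
#' @return An object of class `range_geometry` with elements `polygons`
#'   (normalized ring lists), `area_km2`, `insular_context`,
#'   `landmass_area_km2`, `center` (lon/lat used for projection).
#' @export
range_geometry <- function(polygons, insular_context = c("mainland", "insular"),
                           landmass_area_km2 = NULL) {
  insular_context <- match.arg(insular_context)
  polys <- normalize_polygons(polygons)
  verts <- do.call(rbind, unlist(polys, recursive = FALSE))
  if (any(abs(verts[, 2]) > 90) || any(abs(verts[, 1]) > 180)) {
    abort("polygon vertices outside WGS84 bounds")
  }
  center <- c(lon = mean(verts[, 1]), lat = mean(verts[, 2]))
  area <- range_area_km2(polys, center)
  if (!is.finite(area) || area <= 0) abort("invalid geometry: area <= 0")
  if (insular_context == "insular" && is.null(landmass_area_km2)) {
    abort("insular ranges need landmass_area_km2")
  }
  structure(
    list(polygons = polys, area_km2 = area,
         insular_context = insular_context,
         landmass_area_km2 = landmass_area_km2, center = center),
    class = "range_geometry"
  )
}

#' @export
print.range_geometry <- function(x, ...) {
  cat(sprintf("<range_geometry> %d polygon(s), area %.0f km^2, %s\n",
              length(x$polygons), x$area_km2, x$insular_context))
  invisible(x)
}

#' Circular range polygon (testing and calibration aid)
#'
#' Builds a `range_geometry` approximating a geodesic circle of given
#' radius around a center point, using destination points along `n_vertices`
#' bearings on the 6371-km sphere.
#'
#' @param lon,lat Center coordinates (WGS84 degrees).
#' @param radius_km Circle radius in km.
#' @param n_vertices Number of polygon vertices (default 720).
#' @inheritParams range_geometry
#' @export
circular_range <- function(lon, lat, radius_km, n_vertices = 720,
                           insular_context = "mainland",
                           landmass_area_km2 = NULL) {
  brg <- seq(0, 360, length.out = n_vertices + 1)[-(n_vertices + 1)]
  pts <- geosphere::destPoint(c(lon, lat), brg, radius_km * 1000,
                              r = 6371000)
  range_geometry(pts, insular_context = insular_context,
                 landmass_area_km2 = landmass_area_km2)
}

#' Read a species range from GeoJSON
#'
#' Reads WGS84 Polygon / MultiPolygon geometry (a bare geometry, a Feature
#' or the first feature of a FeatureCollection). Feature properties
#' `insular_context` and `landmass_area_km2`, when present, populate the
#' corresponding `range_geometry` fields.
#'
#' @param path Path to a GeoJSON file.
#' @return A [range_geometry()].
#' @export
read_range_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  props <- list()
  geom <- gj
  if (identical(gj$type, "FeatureCollection")) {
    if (length(gj$features) == 0) abort("empty FeatureCollection")
    geom <- gj$features[[1]]$geometry
    props <- gj$features[[1]]$properties %||% list()
  } else if (identical(gj$type, "Feature")) {
    geom <- gj$geometry
    props <- gj$properties %||% list()
  }
  ring_to_matrix <- function(ring) {
    do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
  }
  polys <- switch(
    geom$type,
    Polygon = list(lapply(geom$coordinates, ring_to_matrix)),
    MultiPolygon = lapply(geom$coordinates,
                          function(pg) lapply(pg, ring_to_matrix)),
    abort(paste0("unsupported GeoJSON geometry: ", geom$type))
  )
  range_geometry(
    polys,
    insular_context = props$insular_context %||% "mainland",
    landmass_area_km2 = props$landmass_area_km2
  )
}

#' Classify populations by position within the species range
#'
#' Assigns each population one biogeographic position class. Precedence:
#' species confined to less than `endemic_area_km2` (10,000 km^2 by
#' default) are `endemic` wherever the point lies; populations on an
#' insular landmass are `isle` (landmass below the same threshold) or
#' `island`; mainland populations are banded by range-area share --
#' `core` inside the inner region holding 50% of the range area, `subedge`
#' between 50% and 75%, `edge` in the outer 25%.
#'
#' Bands are realized by inward erosion: the inner region at erosion
#' distance `d` is the set of in-range points at least `d` from the range
#' boundary, and `d` is found by binary search until the eroded area is
#' within 0.5% of the target share (area measured on a `grid_n x grid_n`
#' equal-area sampling grid).
#'
#' @param points Data frame with `longitude` and `latitude` columns.
#' @param range A [range_geometry()].
#' @param grid_n Resolution of the area-sampling grid (default 400).
#' @param tol_km Tolerance for points falling just outside the range
#'   polygon (snapped to `edge`); beyond it an error is raised. Default 1.
#' @param endemic_area_km2 Area threshold for the endemic/isle rules.
#' @return The input tibble with a `position` factor column (levels
#'   `core`, `subedge`, `edge`, `endemic`, `island`, `isle`).
#' @export
classify_position <- function(points, range, grid_n = 400, tol_km = 1,
                              endemic_area_km2 = 1e4) {
  stopifnot(is.data.frame(points), inherits(range, "range_geometry"))
  if (!all(c("longitude", "latitude") %in% names(points))) {
    abort("points needs longitude and latitude columns")
  }
  points <- tibble::as_tibble(points)
  lev <- c("core", "subedge", "edge", "endemic", "island", "isle")

  if (range$area_km2 < endemic_area_km2) {
    return(dplyr::mutate(points, position = factor("endemic", levels = lev)))
  }
  if (range$insular_context == "insular") {
    cls <- if (range$landmass_area_km2 < endemic_area_km2) "isle" else "island"
    return(dplyr::mutate(points, position = factor(cls, levels = lev)))
  }

  rings <- project_rings(range)
  pxy <- project_laea(points$longitude, points$latitude,
                      range$center["lon"], range$center["lat"])
  inside <- point_in_rings(pxy[, 1], pxy[, 2], rings)
  depth <- dist_to_rings(pxy[, 1], pxy[, 2], rings)
  outside_far <- !inside & depth > tol_km
  if (any(outside_far)) {
    abort(sprintf("%d point(s) fall > %g km outside the range polygon",
                  sum(outside_far), tol_km))
  }
  depth[!inside] <- 0

  thr <- erosion_thresholds(range, rings, grid_n = grid_n)
  cls <- unname(ifelse(depth >= thr[["e50"]], "core",
                       ifelse(depth >= thr[["e25"]], "subedge", "edge")))
  dplyr::mutate(points, position = factor(cls, levels = lev))
}

# erosion distances leaving 50% / 75% of the range area, by binary search
# on a depth sample over an equal-area grid
erosion_thresholds <- function(range, rings = NULL, grid_n = 400,
                               area_tol = 5e-4) {
  if (is.null(rings)) rings <- project_rings(range)
  verts <- do.call(rbind, unlist(rings, recursive = FALSE))
  gx <- seq(min(verts[, 1]), max(verts[, 1]), length.out = grid_n)
  gy <- seq(min(verts[, 2]), max(verts[, 2]), length.out = grid_n)
  g <- expand.grid(x = gx, y = gy)
  inside <- point_in_rings(g$x, g$y, rings)
  depths <- dist_to_rings(g$x[inside], g$y[inside], rings)
  n_in <- length(depths)

  solve_d <- function(frac) {
    lo <- 0; hi <- max(depths)
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      share <- sum(depths >= mid) / n_in
      if (abs(share - frac) <= area_tol) return(mid)
      if (share > frac) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  c(e50 = solve_d(0.50), e25 = solve_d(0.75))
}

normalize_polygons <- function(polygons) {
  as_ring <- function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 2 || nrow(m) < 3) abort("each ring needs >= 3 lon/lat rows")
    # drop an explicit closing vertex
    if (all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    if (nrow(m) < 3) abort("degenerate ring")
    unname(m)
  }
  if (is.matrix(polygons) || is.data.frame(polygons)) {
    polygons <- list(list(as_ring(polygons)))
  } else if (is.list(polygons)) {
    polygons <- lapply(polygons, function(pg) {
      if (is.matrix(pg) || is.data.frame(pg)) list(as_ring(pg))
      else lapply(pg, as_ring)
    })
  } else {
    abort("polygons must be a matrix or a list of polygons")
  }
  polygons
}

# spherical Lambert azimuthal equal-area projection, km units
project_laea <- function(lon, lat, lon0, lat0, R = 6371) {
  lam <- lon * pi / 180; phi <- lat * pi / 180
  lam0 <- lon0 * pi / 180; phi0 <- lat0 * pi / 180
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  kp <- sqrt(2 / denom)
  cbind(x = R * kp * cos(phi) * sin(lam - lam0),
        y = R * kp * (cos(phi0) * sin(phi) -
                        sin(phi0) * cos(phi) * cos(lam - lam0)))
}

project_rings <- function(range) {
  lapply(range$polygons, function(pg) {
    lapply(pg, function(ring) {
      project_laea(ring[, 1], ring[, 2],
                   range$center["lon"], range$center["lat"])
    })
  })
}

shoelace_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

range_area_km2 <- function(polys, center) {
  sum(vapply(polys, function(pg) {
    rings <- lapply(pg, function(ring) {
      project_laea(ring[, 1], ring[, 2], center["lon"], center["lat"])
    })
    outer_a <- shoelace_area(rings[[1]])
    holes <- if (length(rings) > 1) {
      sum(vapply(rings[-1], shoelace_area, numeric(1)))
    } else 0
    outer_a - holes
  }, numeric(1)))
}

# even-odd rule over all rings (holes handled naturally)
point_in_rings <- function(px, py, rings) {
  crossings <- rep(0L, length(px))
  for (pg in rings) for (ring in pg) {
    x <- ring[, 1]; y <- ring[, 2]
    xj <- c(x[-1], x[1]); yj <- c(y[-1], y[1])
    for (s in seq_along(x)) {
      cond <- ((y[s] > py) != (yj[s] > py))
      if (any(cond)) {
        xint <- x[s] + (py[cond] - y[s]) / (yj[s] - y[s]) * (xj[s] - x[s])
        hit <- xint > px[cond]
        idx <- which(cond)[hit]
        crossings[idx] <- crossings[idx] + 1L
      }
    }
  }
  crossings %% 2L == 1L
}

# min distance from each point to any ring segment (projected km)
dist_to_rings <- function(px, py, rings) {
  d <- rep(Inf, length(px))
  for (pg in rings) for (ring in pg) {
    ax <- ring[, 1]; ay <- ring[, 2]
    bx <- c(ax[-1], ax[1]); by <- c(ay[-1], ay[1])
    for (s in seq_along(ax)) {
      vx <- bx[s] - ax[s]; vy <- by[s] - ay[s]
      len2 <- vx * vx + vy * vy
      if (len2 == 0) {
        ds <- sqrt((px - ax[s])^2 + (py - ay[s])^2)
      } else {
        t <- pmin(1, pmax(0, ((px - ax[s]) * vx + (py - ay[s]) * vy) / len2))
        ds <- sqrt((px - (ax[s] + t * vx))^2 + (py - (ay[s] + t * vy))^2)
      }
      d <- pmin(d, ds)
    }
  }
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
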