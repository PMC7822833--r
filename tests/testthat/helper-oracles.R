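# Independent oracles and small fixture builders used across tests.

# Moran's I by explicit double loop (reference for the matrix form)
brute_moran <- function(values, w) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- num + w[i, j] * z[i] * z[j]
  }
  (n / sum(w)) * num / sum(z^2)
}

# submodel count by filtering all subsets of the full term list
brute_count_submodels <- function(mains, ints) {
  terms <- c(mains, ints)
  nt <- length(terms)
  count <- 0L
  for (code in 0:(2^nt - 1)) {
    sel <- terms[bitwAnd(code, 2^(seq_len(nt) - 1)) > 0]
    ok <- TRUE
    for (tm in intersect(sel, ints)) {
      parents <- strsplit(tm, ":", fixed = TRUE)[[1]]
      if (!all(parents %in% sel)) { ok <- FALSE; break }
    }
    if (ok) count <- count + 1L
  }
  count
}

# random marginality-respecting term structure
random_term_structure <- function(n_mains = sample(2:5, 1)) {
  mains <- LETTERS[seq_len(n_mains)]
  pairs <- utils::combn(mains, 2)
  possible <- apply(pairs, 2, paste, collapse = ":")
  ints <- possible[runif(length(possible)) < 0.4]
  list(mains = mains, ints = ints)
}

# small population-record table with known violations
tiny_records <- function() {
  tibble::tibble(
    population_id = paste0("p", 1:6),
    species = "sp1", phylum = "bird", kingdom = "animal",
    latitude = c(10, 20, 30, 40, NA, 60),
    longitude = c(5, 5, 5, 5, 5, 5),
    marker_type = "codominant", n_loci = 10,
    sample_size = c(25, 9, 30, 40, 50, 60),
    he_raw = c(0.5, 0.6, 0.7, 0.4, 0.3, 0.2),
    habitat = c("terrestrial", "terrestrial", "marine", "terrestrial",
                "terrestrial", "freshwater"),
    provenance_flags = c("", "", "", "invasive", "", "")
  )
}

# compact mixed-model dataset with two random factors
small_lmm_data <- function(n = 120, seed = 1) {
  withr::with_seed(seed, {
    sp <- sample(paste0("s", 1:12), n, replace = TRUE)
    mk <- sample(c("codominant", "dominant", "enzyme"), n, replace = TRUE)
    x <- rnorm(n)
    tibble::tibble(
      gdp = 0.5 - 0.05 * x +
        rnorm(12, sd = 0.1)[match(sp, paste0("s", 1:12))] +
        rnorm(n, sd = 0.12),
      x = x, species = sp, marker_type = mk,
      kingdom = sample(c("animal", "plant"), n, replace = TRUE),
      weight = runif(n, 0.3, 0.6)
    )
  })
}

# deterministic square range polygon of given side (km) centered on a point
square_range <- function(lon0 = 0, lat0 = 45, side_km = 400) {
  half_deg_lat <- (side_km / 2) / 111.19
  half_deg_lon <- (side_km / 2) / (111.19 * cos(lat0 * pi / 180))
  m <- rbind(
    c(lon0 - half_deg_lon, lat0 - half_deg_lat),
    c(lon0 + half_deg_lon, lat0 - half_deg_lat),
    c(lon0 + half_deg_lon, lat0 + half_deg_lat),
    c(lon0 - half_deg_lon, lat0 + half_deg_lat)
  )
  range_geometry(m)
}
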