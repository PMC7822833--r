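test_that("great-circle distances follow the 6371-km haversine", {
  expect_equal(great_circle_km(0, 0, 0, 0), 0)
  # antipodal points: half the sphere circumference, pi * 6371
  expect_equal(great_circle_km(0, 0, 180, 0), pi * 6371, tolerance = 1e-6)
  expect_equal(great_circle_km(0, -90, 0, 90), pi * 6371, tolerance = 1e-6)
  withr::with_seed(31, {
    lon <- runif(100, -180, 180); lat <- runif(100, -90, 90)
    lon2 <- runif(100, -180, 180); lat2 <- runif(100, -90, 90)
    expect_equal(great_circle_km(lon, lat, lon2, lat2),
                 great_circle_km(lon2, lat2, lon, lat), tolerance = 1e-9)
  })
  expect_error(great_circle_km(0, 91, 0, 0), "coordinates")
  expect_error(great_circle_km(NA, 0, 0, 0), "coordinates")
})

test_that("Moran's I matches brute force, ape, and its permutation expectation", {
  # alternating values on a 4-cycle: perfect negative autocorrelation
  ring <- rbind(c(0, 1, 0, 1), c(1, 0, 1, 0), c(0, 1, 0, 1), c(1, 0, 1, 0))
  expect_equal(morans_i(c(1, -1, 1, -1), ring), -1, tolerance = 1e-12)

  withr::with_seed(32, {
    for (rep in 1:50) {
      n <- sample(5:30, 1)
      v <- rnorm(n)
      w <- matrix(runif(n * n), n); diag(w) <- 0
      expect_equal(morans_i(v, w), brute_moran(v, w), tolerance = 1e-12)
    }
    # ape row-standardizes its weight matrix; feed it the same form
    n <- 15; v <- rnorm(n)
    w <- matrix(runif(n * n), n); diag(w) <- 0
    w_row <- w / rowSums(w)
    expect_equal(morans_i(v, w_row), ape::Moran.I(v, w)$observed,
                 tolerance = 1e-10)

    # mean over random permutations approaches -1/(n-1)
    n <- 12; v <- rnorm(n)
    w <- matrix(1, n, n); diag(w) <- 0
    w[upper.tri(w)] <- rbinom(n * (n - 1) / 2, 1, 0.4)
    w[lower.tri(w)] <- t(w)[lower.tri(w)]
    sims <- replicate(10000, morans_i(sample(v), w))
    mc_se <- sd(sims) / sqrt(length(sims))
    expect_lt(abs(mean(sims) - (-1 / (n - 1))), 3 * mc_se)
  })

  expect_error(morans_i(rep(1, 5), matrix(1, 5, 5) - diag(5)), "constant")
  expect_error(morans_i(rnorm(5), matrix(0, 5, 5)), "all-zero")
  expect_error(morans_i(rnorm(5), matrix(1, 5, 5)), "diagonal")
})

test_that("correlogram classes agree with explicit binary-weight Moran's I", {
  withr::with_seed(33, {
    n <- 25
    d <- tibble::tibble(longitude = runif(n, 0, 20),
                        latitude = runif(n, 40, 55),
                        val = rnorm(n))
    cg <- correlogram(d, "val", bin_width_km = 400, max_km = 2000,
                      n_perm = 99, seed = 99)
    D <- popgendiv:::pairwise_km(d$longitude, d$latitude)
    for (i in which(!cg$empty)) {
      W <- (D >= cg$lower_km[i] & D < cg$upper_km[i]) * 1
      diag(W) <- 0
      expect_equal(cg$morans_i[i], morans_i(d$val, W), tolerance = 1e-12)
    }
    expect_equal(attr(cg, "expectation"), -1 / (n - 1))
    ok <- !cg$empty
    expect_true(all(cg$p_value[ok] >= 1 / 100 & cg$p_value[ok] <= 1))
    # sparse far-distance classes are flagged, not reported
    expect_true(all(is.na(cg$morans_i[cg$empty])))
    # determinism under the same seed
    cg2 <- correlogram(d, "val", bin_width_km = 400, max_km = 2000,
                       n_perm = 99, seed = 99)
    expect_identical(cg$p_value, cg2$p_value)
  })
  expect_error(correlogram(tibble::tibble(longitude = 1:5, latitude = 1:5,
                                          val = rnorm(5)),
                           "val", seed = 1), ">= 10 points")
})

test_that("spatially independent values show no spurious correlogram structure", {
  hits <- 0; total <- 0
  for (s in 1:3) {
    withr::with_seed(300 + s, {
      n <- 60
      d <- tibble::tibble(longitude = runif(n, -30, 30),
                          latitude = runif(n, -20, 40),
                          val = rnorm(n))
    })
    cg <- correlogram(d, "val", bin_width_km = 500, max_km = 4000,
                      n_perm = 199, seed = 300 + s)
    ok <- !cg$empty
    total <- total + sum(ok)
    hits <- hits + sum(cg$p_value[ok] > 0.05)
  }
  expect_gte(hits / total, 0.9)
})

test_that("grid cells use floor arithmetic anchored at (-180, -90)", {
  # (4.9 E, 50.2 N) -> lon band [3, 6), lat band [48, 51)
  id <- grid_cell(4.9, 50.2)
  parts <- as.integer(strsplit(id, "_")[[1]])
  expect_equal(parts[1] * 3 - 180, 3)
  expect_equal(parts[2] * 3 - 90, 48)
  # edges are half-open
  expect_equal(grid_cell(6, 50), grid_cell(6.1, 50))
  expect_false(grid_cell(6, 50) == grid_cell(5.9, 50))
  # the antimeridian folds into the westernmost adjacent cell
  expect_equal(grid_cell(180, 0), grid_cell(179.9, 0))
})

test_that("jackknife refits once per unit and matches the delete-group closed form", {
  withr::with_seed(34, {
    groups <- rep(paste0("g", 1:8), each = 10)
    d <- tibble::tibble(
      gdp = rnorm(80, mean = 0.5, sd = 0.1),
      species = groups,
      longitude = rep(seq(-50, 55, length.out = 8), each = 10),
      latitude = rep(seq(-30, 40, length.out = 8), each = 10))
  })
  sp <- model_spec("gdp", weights = NULL)
  jk <- jackknife(d, sp, unit = "species")
  expect_equal(attr(jk, "n_units"), 8)
  expect_equal(nrow(attr(jk, "replicates")), 8)

  # closed form for the grouped mean: leave-out mean from group sums
  th <- vapply(unique(d$species),
               function(g) mean(d$gdp[d$species != g]), numeric(1))
  se_ref <- sqrt(7 / 8 * sum((th - mean(th))^2))
  expect_equal(jk$se_jack, se_ref, tolerance = 1e-8)
  expect_equal(jk$estimate, mean(d$gdp), tolerance = 1e-12)
  expect_equal(jk$conf.low, jk$estimate - 1.959964 * jk$se_jack,
               tolerance = 1e-6)

  # the geographic unit drives the refit count
  jk_g <- jackknife(d, sp, unit = "grid3deg")
  expect_equal(attr(jk_g, "n_units"),
               length(unique(grid_cell(d$longitude, d$latitude))))

  expect_error(jackknife(d[d$species %in% c("g1", "g2"), ], sp,
                         unit = "species"), ">= 3")
})

test_that("jackknife intervals behave sensibly on exchangeable data", {
  covered <- 0
  for (s in 1:100) {
    withr::with_seed(4000 + s, {
      d <- tibble::tibble(gdp = rnorm(60, 0.5, 0.1),
                          species = rep(paste0("g", 1:6), each = 10))
    })
    jk <- jackknife(d, model_spec("gdp", weights = NULL), unit = "species")
    # the interval is anchored on the full-data estimate by construction
    expect_true(jk$conf.low[1] <= jk$estimate[1] &&
                  jk$estimate[1] <= jk$conf.high[1])
    covered <- covered + (jk$conf.low[1] <= 0.5 && 0.5 <= jk$conf.high[1])
  }
  # normal-quantile CI on a 5-df variance estimate undershoots nominal
  # 95% coverage somewhat; it should still cover the truth most of the time
  expect_gte(covered, 85)
})
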