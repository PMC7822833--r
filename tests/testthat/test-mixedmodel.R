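test_that("model specs enforce marginality and build the right formulas", {
  sp <- model_spec("gdp", c("a", "b", "a:b"), random = c("species"))
  expect_equal(deparse1(spec_formula(sp)),
               "gdp ~ a + b + a:b + (1 | species)")
  expect_error(model_spec("gdp", c("a", "a:b")), "marginality")
  expect_error(model_spec("gdp", c("a", "b", "a:b"), random = "a"),
               "disjoint")
  expect_equal(deparse1(spec_formula(model_spec("gdp"))), "gdp ~ 1")
})

test_that("latitude model specs match the kingdom and phylum designs", {
  kg <- build_latitude_spec("kingdom")
  expect_setequal(kg$fixed,
                  c("abs_latitude", "kingdom", "abs_latitude:kingdom"))
  expect_setequal(kg$random, c("species", "marker_type"))
  ph <- build_latitude_spec("phylum")
  expect_setequal(ph$fixed,
                  c("abs_latitude", "phylum", "abs_latitude:phylum"))
  expect_true("kingdom" %in% ph$random)
  # marginality holds by construction
  expect_silent(model_spec("gdp", kg$fixed, random = kg$random))
})

test_that("the no-random, equal-weight limit reproduces closed-form OLS", {
  d <- small_lmm_data(n = 90, seed = 2)
  sp <- model_spec("gdp", c("x", "kingdom"), random = character(),
                   weights = NULL)
  f <- fit_weighted_lmm(d, sp)
  X <- model.matrix(~ x + kingdom, d)
  beta_ols <- drop(solve(crossprod(X), crossprod(X, d$gdp)))
  expect_equal(setNames(f$coefficients$estimate, f$coefficients$term),
               beta_ols, tolerance = 1e-8)
  # conditional equals marginal R2 without random terms
  r2 <- r2_nakagawa(f)
  expect_equal(r2$r2c, r2$r2m, tolerance = 1e-12)

  # intercept-only: estimate is the sample mean
  f0 <- fit_weighted_lmm(d, model_spec("gdp", weights = NULL))
  expect_equal(f0$coefficients$estimate, mean(d$gdp), tolerance = 1e-12)
})

test_that("duplicating rows at half weight leaves the weighted fit unchanged", {
  d <- small_lmm_data(n = 100, seed = 3)
  d2 <- dplyr::bind_rows(d, d)
  d2$weight <- d2$weight / 2

  # exact for the penalized-least-squares coefficients at fixed variance
  # parameters; here the no-random weighted fit, where it is exact
  spw <- model_spec("gdp", c("x", "kingdom"), random = character())
  f1 <- fit_weighted_lmm(d, spw)
  f2 <- fit_weighted_lmm(d2, spw)
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-10)

  # with random intercepts the variance components are re-estimated under
  # the doubled n, so equivalence holds to O(1/n)
  spr <- model_spec("gdp", "x", random = c("species", "marker_type"))
  g1 <- fit_weighted_lmm(d, spr)
  g2 <- fit_weighted_lmm(d2, spr)
  expect_equal(g1$coefficients$estimate, g2$coefficients$estimate,
               tolerance = 0.02)
})

test_that("weights act as residual precision multipliers", {
  # Var(e_i) = sigma^2 / w_i: scaling all weights rescales sigma2 only
  d <- small_lmm_data(n = 150, seed = 4)
  sp <- model_spec("gdp", "x", random = "species")
  f1 <- fit_weighted_lmm(d, sp)
  d5 <- dplyr::mutate(d, weight = weight * 5)
  f5 <- fit_weighted_lmm(d5, sp)
  expect_equal(f1$coefficients$estimate, f5$coefficients$estimate,
               tolerance = 1e-6)
  # the data's residual spread is fixed, so sigma2 = Var(e_i) * w_i
  # grows with the weights
  expect_equal(f5$sigma2 / f1$sigma2, 5, tolerance = 1e-4)
})

test_that("degenerate designs fail loudly", {
  d <- small_lmm_data(n = 60, seed = 5)
  d$x2 <- d$x
  expect_error(
    fit_weighted_lmm(d, model_spec("gdp", c("x", "x2"), weights = NULL)),
    "aliased")
  d$one_level <- "a"
  expect_error(
    fit_weighted_lmm(d, model_spec("gdp", "x", random = "one_level")),
    "< 2 levels")
  d$weight[1] <- -1
  expect_error(fit_weighted_lmm(d, model_spec("gdp", "x",
                                              random = "species")),
               "positive")
  expect_error(fit_weighted_lmm(d, model_spec("missing_y", "x")),
               "missing required columns")
})

test_that("variance-partition R2 follows the Nakagawa decomposition", {
  # var(Xb) = 1, sum tau2 = 1, sigma2 = 2 -> R2m 0.25, R2c 0.5
  ff <- as.numeric(scale(rnorm(50)))  # sample variance exactly 1
  r2 <- popgendiv:::nakagawa_r2(ff, c(g = 1), 2)
  expect_equal(unname(r2["r2m"]), 0.25, tolerance = 1e-12)
  expect_equal(unname(r2["r2c"]), 0.50, tolerance = 1e-12)

  # all non-intercept coefficients zero -> R2m = 0
  d <- small_lmm_data(n = 80, seed = 6)
  f0 <- fit_weighted_lmm(d, model_spec("gdp", random = "species"))
  expect_equal(f0$r2m, 0, tolerance = 1e-12)
  expect_gt(f0$r2c, 0)
  expect_true(f0$r2m <= f0$r2c && f0$r2c <= 1)
})

test_that("refitting at the solution reproduces the likelihood", {
  d <- small_lmm_data(n = 120, seed = 8)
  sp <- model_spec("gdp", "x", random = c("species", "marker_type"))
  f1 <- fit_weighted_lmm(d, sp)
  f2 <- fit_weighted_lmm(d, sp)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f1$aicc, aicc(f1$loglik, f1$k, f1$n), tolerance = 1e-12)
  expect_equal(f1$k, 2 + 2 + 1)  # 2 fixed + 2 tau2 + sigma2
})

test_that("tidy and glance expose the fit in broom shape", {
  d <- small_lmm_data(n = 80, seed = 9)
  f <- fit_weighted_lmm(d, model_spec("gdp", "x", random = "species"))
  td <- tidy(f, conf.int = TRUE)
  expect_true(all(c("term", "estimate", "std.error", "conf.low",
                    "conf.high") %in% names(td)))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(f)
  expect_equal(gl$nobs, 80)
  expect_s3_class(gl, "tbl_df")
})

test_that("group slopes equal covariance-weighted contrasts", {
  d <- small_lmm_data(n = 200, seed = 10)
  d$abs_latitude <- abs(rnorm(200, sd = 20))
  d$gdp <- d$gdp - 0.002 * d$abs_latitude * (d$kingdom == "plant")
  sp <- model_spec("gdp",
                   c("abs_latitude", "kingdom", "abs_latitude:kingdom"),
                   random = "species")
  f <- fit_weighted_lmm(d, sp)
  gs <- extract_group_slopes(f, "kingdom")

  beta <- setNames(f$coefficients$estimate, f$coefficients$term)
  V <- as.matrix(vcov(f$fit))
  # reference level: slope is the bare covariate coefficient
  expect_equal(gs$slope[gs$level == "animal"],
               unname(beta["abs_latitude"]), tolerance = 1e-12)
  # non-reference level: independent contrast computation c'b, sqrt(c'Vc)
  cvec <- setNames(numeric(length(beta)), names(beta))
  cvec["abs_latitude"] <- 1
  cvec["abs_latitude:kingdomplant"] <- 1
  expect_equal(gs$slope[gs$level == "plant"], sum(cvec * beta),
               tolerance = 1e-12)
  expect_equal(gs$std.error[gs$level == "plant"],
               sqrt(drop(t(cvec) %*% V %*% cvec)), tolerance = 1e-12)
  expect_true(all(gs$conf.low <= gs$slope & gs$slope <= gs$conf.high))

  f_noint <- fit_weighted_lmm(
    d, model_spec("gdp", c("abs_latitude", "kingdom"), random = "species"))
  expect_error(extract_group_slopes(f_noint, "kingdom"), "interaction")
})
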