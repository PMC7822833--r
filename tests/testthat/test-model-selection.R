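test_that("submodel enumeration respects marginality and is exhaustive", {
  full <- model_spec("y", c("A", "B", "A:B"), weights = NULL)
  subs <- enumerate_submodels(full)
  expect_length(subs, 5)
  got <- sort(vapply(subs, function(s) paste(sort(s$fixed), collapse = "+"),
                     character(1)))
  expect_equal(got, sort(c("", "A", "B", "A+B", "A+A:B+B")))
  # closure: every submodel's terms are a subset of the full terms
  for (s in subs) expect_true(all(s$fixed %in% full$fixed))
  # single main: null and the main itself
  expect_length(enumerate_submodels(model_spec("y", "A", weights = NULL)), 2)
  # random structure carried through unchanged
  fullr <- model_spec("y", c("A", "B"), random = "g", weights = NULL)
  expect_true(all(vapply(enumerate_submodels(fullr),
                         function(s) identical(s$random, "g"), logical(1))))
})

test_that("enumeration counts match a brute-force subset filter on random structures", {
  withr::with_seed(14, {
    for (rep in 1:20) {
      st <- random_term_structure()
      full <- model_spec("y", c(st$mains, st$ints), weights = NULL)
      expect_length(enumerate_submodels(full),
                    brute_count_submodels(st$mains, st$ints))
    }
  })
  expect_error(enumerate_submodels(
    model_spec("y", LETTERS[1:10], weights = NULL), cap = 100), "cap")
})

test_that("AICc follows the small-sample closed form", {
  expect_equal(aicc(-10, 3, 20), 26 + 2 * 3 * 4 / 16)
  expect_equal(aicc(-10, 3, 20), 27.5)
  # correction vanishes for large n
  expect_lt(aicc(-10, 3, 1e8) - 26, 1e-5)
  expect_error(aicc(-10, 3, 4), "n > k")
})

test_that("candidate sets renormalize Akaike weights over the AICc window", {
  models <- tibble::tibble(model_id = 1:3, AICc = c(100, 102, 105))
  cs <- candidate_set(models, delta = 4)
  expect_equal(nrow(cs), 2)
  expect_equal(cs$weight, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(round(cs$weight, 4), c(0.7311, 0.2689))
  expect_lt(abs(sum(cs$weight) - 1), 1e-12)
  expect_true(all(cs$delta_aicc >= 0))
  # single model carries all the weight
  expect_equal(candidate_set(models[1, ])$weight, 1)
})

test_that("relative importance sums candidate weights per term", {
  full <- model_spec("y", c("A", "B"), weights = NULL)
  models <- tibble::tibble(
    model_id = 1:3,
    terms = c("A + B", "A", "B"),
    AICc = c(100, 100, 110))
  attr(models, "full_spec") <- full
  ri <- relative_importance(candidate_set(models))
  # the two retained models tie on AICc; A sits in both (RI 100%),
  # B in exactly one (RI 50%)
  expect_equal(ri$ri[ri$term == "A"], 100, tolerance = 1e-12)
  expect_equal(ri$ri[ri$term == "B"], 50, tolerance = 1e-12)

  # a term absent from every candidate has RI 0
  full2 <- model_spec("y", c("A", "B", "C"), weights = NULL)
  attr(models, "full_spec") <- full2
  ri2 <- relative_importance(candidate_set(models))
  expect_equal(ri2$ri[ri2$term == "C"], 0)
  expect_equal(ri2$n_models[ri2$term == "C"], 0)
})

test_that("RI matches an explicit-loop recomputation on randomized model spaces", {
  withr::with_seed(15, {
    for (rep in 1:10) {
      st <- random_term_structure(n_mains = sample(2:4, 1))
      terms_all <- c(st$mains, st$ints)
      if (length(terms_all) > 6) st$ints <- st$ints[1:2]
      full <- model_spec("y", c(st$mains, st$ints), weights = NULL)
      subs <- enumerate_submodels(full)
      models <- tibble::tibble(
        model_id = seq_along(subs),
        terms = vapply(subs, function(s) paste(s$fixed, collapse = " + "),
                       character(1)),
        AICc = 200 + 8 * runif(length(subs)))
      attr(models, "full_spec") <- full
      cs <- candidate_set(models)
      ri <- relative_importance(cs)
      # brute force: loop candidate models, accumulate weights per term
      for (tm in full$fixed) {
        acc <- 0
        for (i in seq_len(nrow(cs))) {
          in_model <- tm %in% strsplit(cs$terms[i], " + ", fixed = TRUE)[[1]]
          if (in_model) acc <- acc + cs$weight[i]
        }
        expect_equal(ri$ri[ri$term == tm], 100 * acc, tolerance = 1e-12)
      }
      # shifting every AICc by a constant changes nothing downstream
      models2 <- dplyr::mutate(models, AICc = AICc + 123.45)
      attr(models2, "full_spec") <- full
      ri2 <- relative_importance(candidate_set(models2))
      expect_equal(ri2$ri, ri$ri, tolerance = 1e-10)
    }
  })
})

test_that("final-model selection is strict at the threshold and repairs marginality", {
  full <- model_spec("y", c("A", "B", "A:B"), random = "g")
  mk_ri <- function(vals) {
    ri <- tibble::tibble(term = names(vals), ri = unname(vals),
                         n_models = 1L)
    attr(ri, "full_spec") <- full
    class(ri) <- c("ri_table", class(ri))
    ri
  }
  # exactly 50% is excluded (strict inequality)
  sel <- select_final_terms(mk_ri(c(A = 50, B = 80)))
  expect_equal(sel$fixed, "B")
  # simple filter
  expect_equal(select_final_terms(mk_ri(c(A = 80, B = 20)))$fixed, "A")
  # a selected interaction pulls in its mains
  sel3 <- select_final_terms(mk_ri(c(`A:B` = 60, A = 30, B = 70)))
  expect_setequal(sel3$fixed, c("A", "B", "A:B"))
  # structure carried from the full spec
  expect_equal(sel3$random, "g")
  # empty selection collapses to intercept-only with a warning
  expect_warning(sel0 <- select_final_terms(mk_ri(c(A = 10, B = 20))),
                 "intercept-only")
  expect_length(sel0$fixed, 0)
})

test_that("dredging a small dataset produces a coherent model table", {
  d <- small_lmm_data(n = 150, seed = 16)
  d$z <- withr::with_seed(17, rnorm(150))
  full <- model_spec("gdp", c("x", "z"), random = "species")
  dm <- dredge_models(d, full)
  expect_equal(nrow(dm), 4)
  expect_true(all(dm$n == 150))
  cs <- candidate_set(dm)
  expect_lt(abs(sum(cs$weight) - 1), 1e-12)
  ri <- relative_importance(cs)
  expect_setequal(ri$term, c("x", "z"))
  # x carries a real effect in this generator; it should dominate z
  expect_gt(ri$ri[ri$term == "x"], ri$ri[ri$term == "z"])
})

test_that("full kingdom specs carry the position and phylum interaction structure", {
  an <- build_full_kingdom_spec("animal")
  canon <- popgendiv:::canonical_term(an$fixed)
  expect_true("pc_fecundity:position" %in% canon)
  expect_true("lgm_stability:phylum" %in% canon)
  expect_true(all(c("pc_size_longevity", "range_area", "elevation",
                    "mh_stability") %in% an$fixed))
  pl <- build_full_kingdom_spec("plant")
  expect_true(all(c("pollen", "seed", "mating", "lifeform") %in% pl$fixed))
  expect_true("position:seed" %in% popgendiv:::canonical_term(pl$fixed) ||
                "seed:position" %in% popgendiv:::canonical_term(pl$fixed))
  expect_setequal(pl$random, c("species", "marker_type"))
  # both satisfy marginality by construction
  expect_silent(model_spec("gdp", an$fixed, random = an$random))
  # and their submodel spaces are deliberately too large to enumerate
  expect_error(enumerate_submodels(an), "cap")
})
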