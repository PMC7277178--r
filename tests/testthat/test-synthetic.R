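test_that("generated hierarchies respect shape counts and are seed-deterministic", {
  spec <- synthetic_spec(seed = 7, shape = c(9, 5))
  h <- gen_hierarchy(spec)
  expect_equal(unname(level_counts(h)), c(9, 45))
  expect_equal(nrow(leaves(h)), 45)
  # same seed twice -> identical document
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_hierarchy(gen_hierarchy(spec), p1)
  write_hierarchy(gen_hierarchy(spec), p2)
  expect_identical(readLines(p1), readLines(p2))
  # a different seed redraws leaf typing
  h2 <- gen_hierarchy(synthetic_spec(seed = 8, shape = c(9, 5)))
  expect_equal(unname(level_counts(h2)), c(9, 45))
})

test_that("invalid synthetic specs are rejected", {
  expect_error(synthetic_spec(shape = integer(0)), class = "mcda4hta_spec_invalid")
  expect_error(synthetic_spec(sigma = -0.1), class = "mcda4hta_spec_invalid")
  expect_error(synthetic_spec(n_respondents = 0), class = "mcda4hta_spec_invalid")
  expect_error(synthetic_spec(kind_mix = c(numeric = 0.9, binary = 0.2, linguistic = 0)),
               class = "mcda4hta_spec_invalid")
})

test_that("noiseless judgments are exactly consistent and recover planted weights", {
  spec <- synthetic_spec(seed = 13, shape = c(4, 3), sigma = 0, n_respondents = 3)
  h <- gen_hierarchy(spec)
  gj <- gen_judgments(spec, h)
  expect_length(gj$judgments, 3)
  for (js in gj$judgments) {
    for (mid in names(js)) {
      expect_equal(consistency_ratio(js[[mid]]), 0, tolerance = 1e-9)
      w <- principal_weights(js[[mid]])$weights
      expect_equal(w, gj$true_locals[[mid]][names(w)], tolerance = 1e-9)
    }
  }
})

test_that("a 12-person panel yields 12 judgment sets covering the whole plan", {
  spec <- synthetic_spec(seed = 17, shape = c(3, 2), n_respondents = 12)
  h <- gen_hierarchy(spec)
  gj <- gen_judgments(spec, h)
  expect_length(gj$judgments, 12)
  plan <- plan_elicitation(h)
  for (js in gj$judgments) {
    expect_setequal(names(js), plan$matrices$matrix_id)
  }
  # snapped entries come from the Saaty set
  a <- unclass(gj$judgments[[1]][[1]])
  off <- a[upper.tri(a)]
  saaty <- c(1 / (9:2), 1:9)
  expect_true(all(vapply(off, function(v) any(abs(v - saaty) < 1e-12), TRUE)))
})

test_that("aggregated weights from a noisy 9-criterion panel stay near truth", {
  # max-norm error within 0.05 at sigma = 0.1 with 12 respondents
  doc <- list(goal = "g", criteria = lapply(1:9, function(i)
    list(id = paste0("C", i), direction = "benefit", data_kind = "numeric")))
  h <- load_hierarchy(doc)
  spec <- synthetic_spec(seed = 19, shape = c(9), sigma = 0.1, n_respondents = 12)
  gj <- gen_judgments(spec, h)
  w <- suppressMessages(suppressWarnings(compute_weights(h, gj$judgments)))
  truth <- gj$true_locals[["M_goal"]]
  expect_lt(max(abs(w$global[names(truth)] - truth)), 0.05)
})

test_that("generated performance tables obey their column kinds", {
  spec <- synthetic_spec(seed = 23, shape = c(4, 3), n_alternatives = 4)
  h <- gen_hierarchy(spec)
  pt <- gen_performance(spec, h)
  lf <- leaves(h)
  sc <- default_scale7()
  for (k in seq_len(nrow(lf))) {
    cells <- pt$cells[, lf$id[k]]
    if (lf$data_kind[k] == "binary") {
      expect_true(all(cells %in% c("yes", "no")))
    } else if (lf$data_kind[k] == "linguistic") {
      expect_true(all(tolower(cells) %in% tolower(sc$terms)))
    } else {
      expect_false(anyNA(suppressWarnings(as.numeric(cells))))
      if (lf$direction[k] == "cost") expect_true(all(as.numeric(cells) > 0))
    }
  }
})

test_that("planted dominance makes every method rank alternative 1 first", {
  for (seed in c(29, 31, 37)) {
    spec <- synthetic_spec(seed = seed, shape = c(4, 2), n_alternatives = 3,
                           planted_dominance = TRUE)
    h <- gen_hierarchy(spec)
    study_w <- gen_true_locals(spec, plan_elicitation(h))
    gw <- synthesize_global_weights(h, study_w)
    pt <- gen_performance(spec, h)
    f <- normalize_matrix(suppressMessages(fuzzify_table(pt, gw$global)))
    expect_equal(unname(rank_fuzzy_topsis(f)$rank[1]), 1L)
    expect_equal(unname(rank_fuzzy_vikor(f, 0.5)$rank[1]), 1L)
    expect_equal(unname(rank_goal_programming(f)$rank[1]), 1L)
  }
})

test_that("all generated artifacts pass their validators across seeds", {
  for (seed in c(41, 43, 47, 53, 59)) {
    spec <- synthetic_spec(seed = seed, shape = c(3, 2, 2), n_respondents = 4,
                           sigma = 0.15)
    study <- gen_study(spec)
    expect_s3_class(study$hierarchy, "criteria_hierarchy")
    expect_s3_class(study$performance, "performance_table")
    expect_equal(sum(study$true_global), 1, tolerance = 1e-9)
    for (js in study$judgments) for (m in js) expect_s3_class(m, "pcm")
  }
})

test_that("weight recovery error shrinks monotonically as judgment noise vanishes", {
  doc <- list(goal = "g", criteria = lapply(1:6, function(i)
    list(id = paste0("C", i), direction = "benefit", data_kind = "numeric")))
  h <- load_hierarchy(doc)
  err_at <- function(sigma) {
    # average over a few seeded panels to damp Monte-Carlo noise
    mean(vapply(1:5, function(r) {
      spec <- synthetic_spec(seed = 500 + r, shape = c(6), sigma = sigma,
                             n_respondents = 12, saaty_snap = FALSE)
      gj <- gen_judgments(spec, h)
      w <- suppressMessages(suppressWarnings(compute_weights(h, gj$judgments)))
      truth <- gj$true_locals[["M_goal"]]
      max(abs(w$global[names(truth)] - truth))
    }, 0))
  }
  errs <- vapply(c(0.2, 0.1, 0.05, 0), err_at, 0)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[4], 1e-9)
})
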