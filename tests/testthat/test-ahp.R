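# Frozen oracle values for the 3x3 judgment matrix [[1,2,5],[1/2,1,3],[1/5,1/3,1]],
# computed from an independent eigen-decomposition (base::eigen) before the
# power-iteration implementation was wired in:
ORACLE_M3 <- matrix(c(1, 1 / 2, 1 / 5, 2, 1, 1 / 3, 5, 3, 1), 3, 3)
ORACLE_W3 <- c(0.581552066852, 0.308995643633, 0.109452289516)
ORACLE_LAMBDA3 <- 3.003694598064
ORACLE_CR3 <- 0.003184998331 # ((lambda - 3)/2) / RI(3), RI(3) = 0.58

test_that("pairwise matrices enforce reciprocity and positivity", {
  expect_error(pcm(matrix(1, 3, 2)), class = "mcda4hta_pcm_invalid")
  expect_error(pcm(matrix(c(1, 2, 2, 1), 2, 2)), class = "mcda4hta_pcm_reciprocity")
  m <- matrix(c(1, 1 / 3, 3, 1), 2, 2)
  expect_s3_class(pcm(m), "pcm")
  bad <- ORACLE_M3; bad[1, 1] <- 2
  expect_error(pcm(bad), class = "mcda4hta_pcm_invalid")
})

test_that("judgment aggregation is the reciprocity-preserving geometric mean", {
  m <- pcm(ORACLE_M3, matrix_id = "M_x")
  # identity and idempotence
  expect_equal(unclass(aggregate_judgments(list(m))), unclass(m))
  expect_equal(unclass(aggregate_judgments(rep(list(m), 12))), unclass(m))
  # symmetry: 3 and 1/3 average to 1
  a <- pcm(matrix(c(1, 1 / 3, 3, 1), 2, 2))
  b <- pcm(matrix(c(1, 3, 1 / 3, 1), 2, 2))
  agg <- aggregate_judgments(list(a, b))
  expect_equal(agg[1, 2], 1)
  # reciprocity preserved exactly (algebraic identity, random matrices)
  set.seed(5)
  for (k in 1:20) {
    ms <- lapply(1:4, function(i) rand_consistent_pcm(4)$pcm)
    g <- aggregate_judgments(ms)
    expect_equal(unclass(g) * t(unclass(g)), matrix(1, 4, 4),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  expect_error(aggregate_judgments(list()), class = "mcda4hta_ahp_empty")
  expect_error(aggregate_judgments(list(a, m)), class = "mcda4hta_ahp_order_mismatch")
})

test_that("principal weights recover consistent-matrix generators exactly", {
  # all-ones matrix
  pw <- principal_weights(pcm(matrix(1, 3, 3) + diag(0, 3)))
  expect_equal(unname(pw$weights), rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(pw$lambda_max, 3, tolerance = 1e-9)
  # consistent matrix built from (0.6, 0.3, 0.1)
  w0 <- c(0.6, 0.3, 0.1)
  m <- pcm(outer(w0, w0, `/`))
  pw <- principal_weights(m)
  expect_equal(unname(pw$weights), w0, tolerance = 1e-9)
  expect_equal(pw$lambda_max, 3, tolerance = 1e-9)
  expect_equal(consistency_ratio(m), 0, tolerance = 1e-9)
  # geometric-mean route agrees on consistent matrices
  pg <- principal_weights(m, method = "geometric")
  expect_equal(unname(pg$weights), w0, tolerance = 1e-12)
})

test_that("the 3x3 derived fixture matches the frozen eigen oracle", {
  pw <- principal_weights(pcm(ORACLE_M3))
  expect_equal(unname(pw$weights), ORACLE_W3, tolerance = 1e-9)
  expect_equal(pw$lambda_max, ORACLE_LAMBDA3, tolerance = 1e-9)
  expect_equal(consistency_ratio(pcm(ORACLE_M3)), ORACLE_CR3, tolerance = 1e-9)
})

test_that("consistency ratio is zero for 2x2 and consistent matrices", {
  set.seed(31)
  for (k in 1:20) {
    expect_equal(consistency_ratio(rand_consistent_pcm(sample(3:9, 1))$pcm), 0,
                 tolerance = 1e-9)
  }
  expect_equal(consistency_ratio(pcm(matrix(c(1, 1 / 7, 7, 1), 2, 2))), 0)
  big <- outer(rep(1, 11), rep(1, 11))
  expect_error(consistency_ratio(pcm(big)), class = "mcda4hta_ahp_order_unsupported")
})

test_that("permuting matrix indices permutes the weights identically", {
  set.seed(41)
  for (k in 1:10) {
    n <- sample(3:7, 1)
    m <- rand_consistent_pcm(n)$pcm
    noisy <- unclass(m) * exp(stats::rnorm(n * n, 0, 0.05))
    noisy[lower.tri(noisy)] <- 1 / t(noisy)[lower.tri(noisy)]
    diag(noisy) <- 1
    m <- pcm(noisy)
    p <- sample(n)
    w1 <- principal_weights(m)$weights
    w2 <- principal_weights(pcm(unclass(m)[p, p]))$weights
    expect_equal(unname(w2), unname(w1[p]), tolerance = 1e-9)
  }
})

test_that("global weights multiply local weights down the tree and sum to 1", {
  h <- two_level_hier()
  gw <- synthesize_global_weights(h, list(
    M_goal = c(M1 = 0.5, M2 = 0.5),
    M_M1 = c(S1 = 0.4, S2 = 0.6)
  ))
  expect_equal(gw$global, c(S1 = 0.2, S2 = 0.3, M2 = 0.5))
  expect_equal(sum(gw$global), 1)

  # chain: single child inherits weight 1
  gw2 <- synthesize_global_weights(chain_hier(), list())
  expect_equal(gw2$global, c(A1 = 1))

  expect_error(synthesize_global_weights(h, list(M_goal = c(M1 = 0.5, M2 = 0.5))),
               class = "mcda4hta_ahp_missing_local")

  # property: random hierarchies, random local sets -> leaf sum 1, and each
  # leaf's global weight equals the brute-force product along its path
  set.seed(51)
  for (k in 1:10) {
    h <- gen_hierarchy(synthetic_spec(seed = sample.int(1e6, 1),
                                      shape = sample(2:4, 3, replace = TRUE)))
    plan <- plan_elicitation(h)
    locals <- gen_true_locals(synthetic_spec(seed = sample.int(1e6, 1)), plan)
    gw <- synthesize_global_weights(h, locals)
    expect_equal(sum(gw$global), 1, tolerance = 1e-9)
    path_product <- function(id) {
      prod <- 1
      while (id != ".goal") {
        prod <- prod * gw$local[[id]]
        id <- h$nodes$parent_id[h$nodes$id == id]
      }
      prod
    }
    for (leaf in sample(names(gw$global), 5)) {
      expect_equal(gw$global[[leaf]], path_product(leaf), tolerance = 1e-12)
    }
  }
})

test_that("responses round-trip through CSV with auto-filled reciprocals", {
  h <- two_level_hier()
  plan <- plan_elicitation(h)
  spec <- synthetic_spec(seed = 99, n_respondents = 3, sigma = 0.2)
  gj <- gen_judgments(spec, h)
  path <- withr::local_tempfile(fileext = ".csv")
  write_judgments(gj$judgments, path)
  back <- read_judgments(path, plan)
  expect_equal(names(back), names(gj$judgments))
  for (r in names(back)) for (mid in names(back[[r]])) {
    expect_equal(unclass(back[[r]][[mid]]), unclass(gj$judgments[[r]][[mid]]),
                 tolerance = 1e-12)
  }
  # conflicting duplicate pair rejected
  df <- read.csv(path, stringsAsFactors = FALSE)
  clash <- df[1, ]
  clash$saaty_value <- if (trimws(df$saaty_value[1]) == "9") "7" else "9"
  df2 <- rbind(df, clash)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df2, path2, row.names = FALSE)
  expect_error(read_judgments(path2, plan), class = "mcda4hta_responses_conflict")
})

test_that("compute_weights flags inconsistent matrices without aborting by default", {
  h <- two_level_hier()
  # build a deliberately inconsistent 2-respondent panel on the goal matrix
  inconsistent <- pcm(matrix(c(1, 1 / 9, 9, 1), 2, 2,
                             dimnames = list(c("M1", "M2"), c("M1", "M2"))),
                      matrix_id = "M_goal")
  judg <- list(
    R1 = list(M_goal = inconsistent,
              M_M1 = pcm(matrix(c(1, 1 / 3, 3, 1), 2, 2,
                                dimnames = list(c("S1", "S2"), c("S1", "S2"))),
                         matrix_id = "M_M1"))
  )
  w <- suppressMessages(compute_weights(h, judg))
  expect_equal(sum(w$global), 1, tolerance = 1e-9)
  expect_true(all(w$cr_table$cr <= 0.1 + 1e-12)) # both matrices are 2x2: CR 0
  # strict mode aborts on a genuinely inconsistent 3x3
  h3 <- load_hierarchy(list(goal = "g", criteria = lapply(1:3, function(i)
    list(id = paste0("C", i), direction = "benefit", data_kind = "numeric"))))
  bad3 <- matrix(c(1, 1 / 9, 9, 9, 1, 1 / 9, 1 / 9, 9, 1), 3, 3,
                 dimnames = list(paste0("C", 1:3), paste0("C", 1:3)))
  judg3 <- list(R1 = list(M_goal = pcm(bad3, matrix_id = "M_goal")))
  expect_error(suppressWarnings(compute_weights(h3, judg3, strict_cr = TRUE)),
               class = "mcda4hta_cr_exceeded")
  expect_warning(compute_weights(h3, judg3), class = "mcda4hta_cr_exceeded")
})
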