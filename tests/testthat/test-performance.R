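test_that("performance tables validate columns, cells and labels", {
  h <- tiny_hier() # leaves A (benefit numeric), B (cost numeric)
  ok <- performance_table(
    data.frame(alternative = c("x", "y"), A = c("10", "5"), B = c("2", "4")), h)
  expect_s3_class(ok, "performance_table")
  expect_equal(ok$alternatives, c("x", "y"))

  expect_error(performance_table(
    data.frame(alternative = c("x", "y"), A = 1:2, Z = 1:2), h),
    class = "mcda4hta_table_unknown_column")
  err <- expect_error(performance_table(
    data.frame(alternative = c("x", "y"), A = c("10", "not a number"), B = c("2", "4")), h),
    class = "mcda4hta_table_cell_type")
  expect_match(conditionMessage(err), "y")
  expect_match(conditionMessage(err), "A")
  expect_error(performance_table(
    data.frame(alternative = c("x", "x"), A = c("1", "2"), B = c("2", "4")), h),
    class = "mcda4hta_table_duplicate_alternative")
  expect_error(performance_table(
    data.frame(alternative = c("x", "y"), A = c("1", "2"), B = c(NA, NA)), h),
    class = "mcda4hta_table_empty_column")
})

test_that("tables round-trip through CSV and #kind/#direction headers must match", {
  h <- tiny_hier()
  t1 <- performance_table(
    data.frame(alternative = c("x", "y"), A = c("10", "5"), B = c("2", "4")), h)
  path <- withr::local_tempfile(fileext = ".csv")
  write_table(t1, path)
  t2 <- load_table(path, h)
  expect_equal(t2$cells, t1$cells)
  expect_equal(t2$kinds, t1$kinds)
  # forge a wrong #direction header
  txt <- readLines(path)
  txt[3] <- sub("cost", "benefit", txt[3])
  writeLines(txt, path)
  expect_error(load_table(path, h), class = "mcda4hta_table_meta_mismatch")
})

test_that("fuzzification encodes all three kinds and renormalizes after drops", {
  h <- load_hierarchy(list(goal = "g", criteria = list(
    list(id = "N", direction = "benefit", data_kind = "numeric"),
    list(id = "B", direction = "benefit", data_kind = "binary"),
    list(id = "L", direction = "benefit", data_kind = "linguistic")
  )))
  pt <- performance_table(data.frame(
    alternative = c("x", "y"),
    N = c("10", "5"), B = c("yes", "no"), L = c("good", "poor")), h)
  w <- c(N = 0.2, B = 0.3, L = 0.5)
  f <- fuzzify_table(pt, w)
  expect_equal(f$l[, "N"], c(x = 10, y = 5))
  expect_equal(f$l[, "B"], c(x = 1, y = 0))
  expect_equal(f$u[, "B"], c(x = 1, y = 0))
  sc <- default_scale7()
  expect_equal(unname(f$m["x", "L"]), sc$tfns[match("good", sc$terms), "m"][[1]])
  expect_equal(sum(f$weights), 1)

  # missing cell for one alternative drops the column and renormalizes:
  # hand-computed renormalization of (0.2, 0.3, 0.5) without B -> (2/7, 5/7)
  pt2 <- performance_table(data.frame(
    alternative = c("x", "y"),
    N = c("10", "5"), B = c("yes", NA), L = c("good", "poor")), h)
  f2 <- suppressMessages(fuzzify_table(pt2, w))
  expect_equal(f2$dropped, "B")
  expect_equal(unname(f2$weights), c(0.2, 0.5) / 0.7)
  expect_equal(sum(f2$weights), 1)
})

test_that("normalization follows the benefit and cost rules with [0,1] supports", {
  h <- tiny_hier()
  pt <- performance_table(
    data.frame(alternative = c("x", "y"), A = c("10", "5"), B = c("2", "4")), h)
  f <- normalize_matrix(fuzzify_table(pt, c(A = 0.5, B = 0.5)))
  # benefit column: 10 -> 1, 5 -> 0.5; cost column: 2 -> 1, 4 -> 0.5
  expect_equal(unname(f$m[, "A"]), c(1, 0.5))
  expect_equal(unname(f$m[, "B"]), c(1, 0.5))
  expect_true(all(f$l >= 0 & f$u <= 1 + 1e-12))
  expect_true(all(f$directions == "benefit"))

  # mixed fuzzy benefit column, hand-normalized 2x2 instance:
  # cells (1,2,3) and (2,4,6); c* = 6 -> (1/6,1/3,1/2) and (1/3,2/3,1)
  h2 <- load_hierarchy(list(goal = "g", criteria = list(
    list(id = "L1", direction = "benefit", data_kind = "linguistic"),
    list(id = "N1", direction = "benefit", data_kind = "numeric")
  )))
  f2 <- crisp_fdm(matrix(c(1, 2, 5, 4), 2, 2,
                         dimnames = list(c("x", "y"), c("L1", "N1"))),
                  weights = c(0.5, 0.5), normalized = FALSE)
  f2$l[, "L1"] <- c(1, 2); f2$m[, "L1"] <- c(2, 4); f2$u[, "L1"] <- c(3, 6)
  f2$l[, "N1"] <- c(5, 4); f2$m[, "N1"] <- c(5, 4); f2$u[, "N1"] <- c(5, 4)
  nf <- normalize_matrix(f2)
  expect_equal(unname(nf$l[, "L1"]), c(1, 2) / 6)
  expect_equal(unname(nf$m[, "L1"]), c(2, 4) / 6)
  expect_equal(unname(nf$u[, "L1"]), c(3, 6) / 6)
  # per column at least one alternative attains upper support 1
  expect_equal(max(nf$u[, "L1"]), 1)
  expect_equal(max(nf$u[, "N1"]), 1)

  # zero/negative raw values in a cost column are rejected with guidance
  ptz <- performance_table(
    data.frame(alternative = c("x", "y"), A = c("1", "2"), B = c("0", "4")), h)
  err <- expect_error(normalize_matrix(fuzzify_table(ptz, c(A = 0.5, B = 0.5))),
                      class = "mcda4hta_normalize_zero_divisor")
  expect_match(conditionMessage(err), "pre-shift")
})

test_that("normalization is invariant to positive rescaling of numeric columns", {
  h <- tiny_hier()
  set.seed(61)
  for (rep in 1:10) {
    vals <- round(runif(4, 1, 20), 3)
    k <- runif(1, 0.1, 50)
    pt1 <- performance_table(data.frame(
      alternative = c("x", "y"),
      A = format(vals[1:2], digits = 15, trim = TRUE), B = format(vals[3:4], digits = 15, trim = TRUE)), h)
    pt2 <- performance_table(data.frame(
      alternative = c("x", "y"),
      A = format(vals[1:2] * k, digits = 15, trim = TRUE), B = format(vals[3:4] * k, digits = 15, trim = TRUE)), h)
    w <- c(A = 0.4, B = 0.6)
    n1 <- normalize_matrix(fuzzify_table(pt1, w))
    n2 <- normalize_matrix(fuzzify_table(pt2, w))
    expect_equal(n2$m, n1$m, tolerance = 1e-9)
    expect_equal(n2$l, n1$l, tolerance = 1e-9)
    expect_equal(n2$u, n1$u, tolerance = 1e-9)
  }
})

test_that("a zero-weight criterion never affects any ranking", {
  set.seed(71)
  f <- rand_fdm(3, 4)
  g <- f
  g$weights <- c(f$weights * 0.999 / sum(f$weights[1:4]), extra = 0)
  g$weights <- g$weights / sum(g$weights)
  # append a wild zero-weight column
  g$l <- cbind(f$l, extra = c(0.9, 0.1, 0.5))
  g$m <- cbind(f$m, extra = c(0.95, 0.2, 0.6))
  g$u <- cbind(f$u, extra = c(1, 0.3, 0.7))
  g$columns <- c(f$columns, "extra")
  g$directions <- c(f$directions, extra = "benefit")
  names(g$weights) <- g$columns
  g$weights[seq_along(f$columns)] <- f$weights
  g$weights["extra"] <- 0
  for (fun in list(rank_fuzzy_topsis,
                   function(x) rank_fuzzy_vikor(x, 0.5),
                   rank_goal_programming)) {
    r1 <- fun(f); r2 <- fun(g)
    expect_equal(unname(r2$index), unname(r1$index), tolerance = 1e-9)
  }
})
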