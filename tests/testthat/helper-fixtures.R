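# Shared in-code fixtures: tiny hierarchies, random consistent matrices and
# random fuzzy decision matrices with known structure.

# goal + 2 main-criterion leaves: the smallest valid tree
tiny_hier <- function() {
  load_hierarchy(list(
    goal = "tiny",
    criteria = list(
      list(id = "A", label = "A", direction = "benefit", data_kind = "numeric"),
      list(id = "B", label = "B", direction = "cost", data_kind = "numeric")
    )
  ))
}

# goal -> A -> A1: single-child chain, no sibling pairs anywhere
chain_hier <- function() {
  load_hierarchy(list(
    goal = "chain",
    criteria = list(
      list(id = "A", label = "A", children = list(
        list(id = "A1", label = "A1", direction = "benefit", data_kind = "numeric")
      ))
    )
  ))
}

# mains (M1, M2); M1 has sub-leaves S1, S2; M2 is itself a leaf
two_level_hier <- function() {
  load_hierarchy(list(
    goal = "two-level",
    criteria = list(
      list(id = "M1", label = "M1", children = list(
        list(id = "S1", label = "S1", direction = "benefit", data_kind = "numeric"),
        list(id = "S2", label = "S2", direction = "benefit", data_kind = "numeric")
      )),
      list(id = "M2", label = "M2", direction = "benefit", data_kind = "numeric")
    )
  ))
}

# perfectly consistent pairwise matrix generated from a random weight vector
rand_consistent_pcm <- function(n, id = NULL) {
  w <- stats::runif(n, 0.05, 1)
  w <- w / sum(w)
  a <- outer(w, w, `/`)
  dimnames(a) <- list(paste0("c", 1:n), paste0("c", 1:n))
  list(pcm = pcm(a, matrix_id = id), w = w)
}

# random (flagged-normalized, all-benefit) fuzzy decision matrix built directly
rand_fdm <- function(n_alt, n_col) {
  a <- matrix(stats::runif(n_alt * n_col), n_alt, n_col)
  b <- matrix(stats::runif(n_alt * n_col), n_alt, n_col)
  c_ <- matrix(stats::runif(n_alt * n_col), n_alt, n_col)
  L <- pmin(a, b, c_); U <- pmax(a, b, c_); M <- a + b + c_ - L - U
  alts <- paste0("alt", seq_len(n_alt))
  cols <- paste0("crit", seq_len(n_col))
  dimnames(L) <- dimnames(M) <- dimnames(U) <- list(alts, cols)
  w <- stats::runif(n_col, 0.1, 1); w <- w / sum(w)
  structure(
    list(l = L, m = M, u = U, alternatives = alts, columns = cols,
         weights = stats::setNames(w, cols),
         directions = stats::setNames(rep("benefit", n_col), cols),
         dropped = character(0), scale_name = "default7", normalized = TRUE),
    class = "fuzzy_decision_matrix"
  )
}

# plant component-wise weak dominance of alternative 1 (strict in column 1),
# keeping every support inside [0, 1]
plant_dominance <- function(f) {
  for (j in seq_along(f$columns)) {
    f$l[1, j] <- max(f$l[, j]); f$m[1, j] <- max(f$m[, j]); f$u[1, j] <- max(f$u[, j])
    if (j == 1L) { # strict: bump all three components, staying below 1
      eps <- 0.5 * (1 - f$u[1, j])
      f$l[1, j] <- f$l[1, j] + eps; f$m[1, j] <- f$m[1, j] + eps
      f$u[1, j] <- f$u[1, j] + eps
    }
  }
  f
}

# crisp decision matrix wrapped as degenerate TFNs, normalized flag set
crisp_fdm <- function(X, weights, directions = NULL, normalized = TRUE) {
  cols <- colnames(X) %||% paste0("crit", seq_len(ncol(X)))
  alts <- rownames(X) %||% paste0("alt", seq_len(nrow(X)))
  dimnames(X) <- list(alts, cols)
  if (is.null(directions)) directions <- rep("benefit", ncol(X))
  structure(
    list(l = X, m = X, u = X, alternatives = alts, columns = cols,
         weights = stats::setNames(weights / sum(weights), cols),
         directions = stats::setNames(directions, cols),
         dropped = character(0), scale_name = "default7", normalized = normalized),
    class = "fuzzy_decision_matrix"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent brute-force TOPSIS recomputation used as an oracle: plain
# loops, no shared code path with rank_fuzzy_topsis
brute_topsis_index <- function(f) {
  n <- length(f$alternatives)
  idx <- numeric(n)
  for (i in seq_len(n)) {
    dp <- 0; dm <- 0
    for (j in seq_along(f$columns)) {
      w <- f$weights[[j]]
      v <- c(w * f$l[i, j], w * f$m[i, j], w * f$u[i, j])
      dp <- dp + sqrt(sum((v - c(w, w, w))^2) / 3)
      dm <- dm + sqrt(sum((v - c(0, 0, 0))^2) / 3)
    }
    idx[i] <- if (dp + dm > 0) dp / (dp + dm) else 0.5
  }
  idx
}
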