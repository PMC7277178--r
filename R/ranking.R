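# The three ranking engines. All report LOWER-IS-BETTER indices: rank 1 is
# the minimal index. For TOPSIS this means reporting d+/(d+ + d-) — the
# complement of the classical closeness coefficient — so the three methods
# share one orientation.

new_ranking_result <- function(method, index, intermediates, config) {
  rk <- rank(index, ties.method = "first") # ties broken by document order
  structure(
    list(method = method,
         index = index,
         rank = stats::setNames(as.integer(rk), names(index)),
         intermediates = intermediates,
         config = config),
    class = "ranking_result"
  )
}

#' @export
print.ranking_result <- function(x, ...) {
  cat(sprintf("<ranking_result: %s (lower index = better)>\n", x$method))
  df <- data.frame(alternative = names(x$index),
                   index = round(x$index, 3), rank = x$rank)
  print(df[order(df$rank), ], row.names = FALSE)
  invisible(x)
}

#' Fuzzy TOPSIS ranking
#'
#' On the weighted normalized matrix \eqn{v_{ij} = w_j r_{ij}}, the fuzzy
#' positive ideal is \eqn{(w_j, w_j, w_j)} per column and the fuzzy negative
#' ideal \eqn{(0,0,0)}. Distances are vertex distances summed over columns;
#' the reported index is \eqn{d^+/(d^+ + d^-)} so the alternative closest to
#' the ideal gets the smallest value.
#'
#' @param f A normalized \code{fuzzy_decision_matrix} (see
#'   [normalize_matrix()]).
#' @return A \code{ranking_result} with per-alternative \code{d_plus} /
#'   \code{d_minus} intermediates.
#' @export
rank_fuzzy_topsis <- function(f) {
  if (!f$normalized) {
    mcda_stop("not_normalized", "fuzzy TOPSIS requires a normalized decision matrix")
  }
  n <- length(f$alternatives)
  dplus <- dminus <- stats::setNames(numeric(n), f$alternatives)
  for (j in seq_along(f$columns)) {
    w <- f$weights[[j]]
    v <- tfn_scale(tfn(f$l[, j], f$m[, j], f$u[, j]), w)
    dplus <- dplus + vertex_distance(v, tfn(w, w, w))
    dminus <- dminus + vertex_distance(v, tfn(0, 0, 0))
  }
  tot <- dplus + dminus
  idx <- ifelse(tot > 0, dplus / tot, 0.5)
  if (any(tot == 0)) {
    mcda_log("topsis", "degenerate single-point matrix for: %s (index 0.5 by convention)",
             paste(f$alternatives[tot == 0], collapse = ", "))
  }
  inter <- data.frame(alternative = f$alternatives, d_plus = as.numeric(dplus),
                      d_minus = as.numeric(dminus), stringsAsFactors = FALSE)
  new_ranking_result("fuzzy_topsis", stats::setNames(idx, f$alternatives), inter,
                     list(scale = f$scale_name))
}

#' Fuzzy VIKOR compromise ranking
#'
#' Computes group utility S, individual regret R and the compromise index
#' \eqn{Q = v (S - S^*)/(S^- - S^*) + (1 - v)(R - R^*)/(R^- - R^*)}
#' per alternative; lower Q is better. The default route defuzzifies each
#' cell and runs crisp VIKOR on the resulting matrix (direction-aware best
#' \eqn{f^*_j} and worst \eqn{f^-_j} per column); \code{fuzzy_arith = TRUE}
#' instead keeps S and R as triangular fuzzy numbers (component-wise ideal,
#' fuzzy subtraction) and defuzzifies them only before the Q blend.
#'
#' A column whose best and worst coincide contributes zero regret; when all
#' alternatives are identical every Q is 0 by convention (logged). The
#' classical acceptable-advantage and acceptable-stability conditions are
#' reported as booleans but never alter the indices.
#'
#' @param f A \code{fuzzy_decision_matrix} (normalized or raw; best/worst are
#'   direction-aware).
#' @param v Trade-off between group utility and individual regret, in \[0,1\];
#'   0.5 ("consensus") by default.
#' @param defuzz Defuzzification method, see [defuzzify()].
#' @param fuzzy_arith Use the fuzzy-arithmetic route for S and R.
#' @return A \code{ranking_result} with S, R, Q intermediates and the
#'   advantage/stability flags in \code{config}.
#' @export
rank_fuzzy_vikor <- function(f, v = 0.5, defuzz = "graded_mean", fuzzy_arith = FALSE) {
  if (v < 0 || v > 1) mcda_stop("config_invalid", "VIKOR v must lie in [0, 1]")
  n <- length(f$alternatives)
  if (n < 2L) mcda_stop("config_invalid", "VIKOR needs at least 2 alternatives")
  nj <- length(f$columns)

  if (!fuzzy_arith) {
    X <- defuzzify_matrix(f, defuzz)
    S <- stats::setNames(numeric(n), f$alternatives)
    R <- stats::setNames(numeric(n), f$alternatives)
    for (j in seq_len(nj)) {
      benefit <- f$directions[[j]] == "benefit"
      fstar <- if (benefit) max(X[, j]) else min(X[, j])
      fminus <- if (benefit) min(X[, j]) else max(X[, j])
      span <- fstar - fminus
      term <- if (abs(span) < 1e-15) rep(0, n) else f$weights[[j]] * (fstar - X[, j]) / span
      S <- S + term
      R <- pmax(R, term)
    }
  } else {
    Szero <- tfn(0, 0, 0)
    Sf <- rep(list(Szero), n)
    Rf <- rep(list(Szero), n)
    Rval <- rep(-Inf, n)
    for (j in seq_len(nj)) {
      col <- tfn(f$l[, j], f$m[, j], f$u[, j])
      benefit <- f$directions[[j]] == "benefit"
      span <- max(f$u[, j]) - min(f$l[, j])
      for (i in seq_len(n)) {
        d <- if (benefit) {
          tfn(max(f$l[, j]) - f$u[i, j], max(f$m[, j]) - f$m[i, j], max(f$u[, j]) - f$l[i, j])
        } else {
          tfn(f$l[i, j] - min(f$u[, j]), f$m[i, j] - min(f$m[, j]), f$u[i, j] - min(f$l[, j]))
        }
        d <- if (span < 1e-15) Szero else tfn(d[, "l"] / span, d[, "m"] / span, d[, "u"] / span)
        wd <- tfn(f$weights[[j]] * d[, "l"], f$weights[[j]] * d[, "m"], f$weights[[j]] * d[, "u"])
        Sf[[i]] <- tfn(Sf[[i]][, "l"] + wd[, "l"], Sf[[i]][, "m"] + wd[, "m"],
                       Sf[[i]][, "u"] + wd[, "u"])
        dv <- defuzzify(wd, defuzz)
        if (dv > Rval[i]) { Rval[i] <- dv; Rf[[i]] <- wd }
      }
    }
    S <- stats::setNames(vapply(Sf, defuzzify, 0, method = defuzz), f$alternatives)
    R <- stats::setNames(vapply(Rf, defuzzify, 0, method = defuzz), f$alternatives)
  }

  Sstar <- min(S); Sminus <- max(S); Rstar <- min(R); Rminus <- max(R)
  qs <- if (Sminus - Sstar < 1e-15) rep(0, n) else (S - Sstar) / (Sminus - Sstar)
  qr <- if (Rminus - Rstar < 1e-15) rep(0, n) else (R - Rstar) / (Rminus - Rstar)
  Q <- v * qs + (1 - v) * qr
  if (Sminus - Sstar < 1e-15 && Rminus - Rstar < 1e-15) {
    mcda_log("vikor", "all alternatives identical; Q = 0 by convention")
  }
  Q <- stats::setNames(as.numeric(Q), f$alternatives)

  ord <- order(Q)
  adv <- if (n > 2) Q[ord[2]] - Q[ord[1]] >= 1 / (n - 1) else Q[ord[2]] - Q[ord[1]] >= 1
  stab <- which.min(S) == ord[1] || which.min(R) == ord[1]
  inter <- data.frame(alternative = f$alternatives, S = as.numeric(S),
                      R = as.numeric(R), Q = as.numeric(Q), stringsAsFactors = FALSE)
  new_ranking_result("fuzzy_vikor", Q, inter,
                     list(v = v, defuzz = defuzz, fuzzy_arith = fuzzy_arith,
                          scale = f$scale_name,
                          acceptable_advantage = as.logical(adv)[[1]],
                          acceptable_stability = as.logical(stab)[[1]]))
}

#' Goal-programming ranking
#'
#' Per column the goal \eqn{g_j} is the direction-aware best defuzzified
#' value and \eqn{b_j} the worst; the index of alternative i is the weighted
#' normalized absolute deviation
#' \eqn{\sum_j w_j |g_j - \hat x_{ij}| / (g_j - b_j)} (a column with
#' \eqn{g_j = b_j} contributes zero). Because the deviation variables of the
#' underlying goal program \eqn{\hat x + d^- - d^+ = g_j}, \eqn{d^\pm \ge 0}
#' decouple across criteria and alternatives, this closed form equals the LP
#' optimum of the weighted goal program.
#'
#' @param f A \code{fuzzy_decision_matrix}; the pipeline supplies the
#'   normalized matrix so deviations are commensurable.
#' @param defuzz Defuzzification method, see [defuzzify()].
#' @return A \code{ranking_result} with a per-criterion deviation matrix in
#'   \code{intermediates}.
#' @export
rank_goal_programming <- function(f, defuzz = "graded_mean") {
  X <- defuzzify_matrix(f, defuzz)
  n <- length(f$alternatives)
  dev <- matrix(0, n, length(f$columns), dimnames = dimnames(X))
  for (j in seq_along(f$columns)) {
    benefit <- f$directions[[j]] == "benefit"
    g <- if (benefit) max(X[, j]) else min(X[, j])
    b <- if (benefit) min(X[, j]) else max(X[, j])
    span <- abs(g - b)
    dev[, j] <- if (span < 1e-15) 0 else f$weights[[j]] * abs(g - X[, j]) / span
  }
  idx <- stats::setNames(rowSums(dev), f$alternatives)
  inter <- data.frame(alternative = f$alternatives, index = as.numeric(idx),
                      stringsAsFactors = FALSE)
  new_ranking_result("goal_programming", idx, inter,
                     list(defuzz = defuzz, scale = f$scale_name, deviations = dev))
}
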