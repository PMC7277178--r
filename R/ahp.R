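# AHP: Saaty-scale pairwise judgment matrices -> local and global weights.
#
# Weights come from the principal right eigenvector, found by power iteration
# (tolerance 1e-12, cap 10,000 iterations); the geometric-mean row method is
# available as a cheaper alternative. Group judgments are pooled by
# element-wise geometric mean (aggregation of individual judgments) before
# eigen-extraction, or by arithmetic mean of the individual eigenvectors
# (aggregation of individual priorities).

#' Saaty random consistency indices, orders 1..10
#'
#' Literature constants used in the consistency ratio; orders above 10 are
#' rejected (split such a criteria group in the hierarchy instead).
#' @keywords internal
SAATY_RI <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)

#' Pairwise comparison matrix
#'
#' A reciprocal positive ratio matrix: \code{a[i,i] == 1} and
#' \code{a[i,j] * a[j,i] == 1} (tolerance 1e-9). Questionnaire matrices carry
#' Saaty-set entries; aggregated group matrices may hold arbitrary positive
#' ratios.
#'
#' @param m A square numeric matrix of positive ratios. Row/col names, if
#'   present, name the compared criteria.
#' @param matrix_id Token tying the matrix to an elicitation-plan entry.
#' @return An object of class \code{"pcm"}.
#' @export
pcm <- function(m, matrix_id = NULL) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (n < 2L || ncol(m) != n) {
    mcda_stop("pcm_invalid", "a pairwise matrix must be square of order >= 2")
  }
  if (any(!is.finite(m)) || any(m <= 0)) {
    mcda_stop("pcm_invalid", "pairwise entries must be finite positive ratios")
  }
  if (any(abs(diag(m) - 1) > 1e-9)) {
    mcda_stop("pcm_invalid", "pairwise matrix diagonal must be 1")
  }
  if (any(abs(m * t(m) - 1) > 1e-9)) {
    mcda_stop("pcm_reciprocity", "reciprocity violated: a_ij * a_ji must equal 1")
  }
  structure(m, class = c("pcm", "matrix"), matrix_id = matrix_id)
}

#' @export
print.pcm <- function(x, ...) {
  id <- attr(x, "matrix_id")
  cat(sprintf("<pcm%s: order %d>\n", if (is.null(id)) "" else paste0(" ", id), nrow(x)))
  print(round(unclass(x), 4), ...)
  invisible(x)
}

#' Pool pairwise judgments across respondents
#'
#' Element-wise geometric mean of matrices with the same id and order; the
#' standard aggregation-of-individual-judgments rule for AHP groups.
#' Reciprocity is preserved exactly: the mean is taken on the upper triangle
#' and mirrored.
#'
#' @param judgments A list of \code{pcm} objects of identical order (and id).
#' @return A single \code{pcm}.
#' @export
aggregate_judgments <- function(judgments) {
  if (length(judgments) == 0L) mcda_stop("ahp_empty", "no judgment matrices to aggregate")
  ords <- vapply(judgments, nrow, 0L)
  if (length(unique(ords)) != 1L) {
    mcda_stop("ahp_order_mismatch", "judgment matrices have mismatched orders: %s",
              paste(unique(ords), collapse = ", "))
  }
  ids <- unique(unlist(lapply(judgments, function(j) attr(j, "matrix_id") %||% NA_character_)))
  ids <- ids[!is.na(ids)]
  if (length(ids) > 1L) {
    mcda_stop("ahp_order_mismatch", "judgment matrices belong to different plan entries: %s",
              paste(ids, collapse = ", "))
  }
  n <- ords[1]
  logsum <- Reduce(`+`, lapply(judgments, function(j) log(unclass(j))))
  g <- exp(logsum / length(judgments))
  out <- diag(n)
  ut <- upper.tri(g)
  out[ut] <- g[ut]
  out[lower.tri(out)] <- 1 / t(out)[lower.tri(out)]
  dimnames(out) <- dimnames(unclass(judgments[[1]]))
  pcm(out, matrix_id = if (length(ids)) ids else NULL)
}

#' Local weights from a pairwise matrix
#'
#' The normalized principal right eigenvector, by power iteration, together
#' with the principal eigenvalue \eqn{\lambda_{max}}. The geometric-mean row
#' method (normalized row geometric means) is available via \code{method};
#' for perfectly consistent matrices the two coincide.
#'
#' @param m A \code{pcm}.
#' @param method \code{"eigen"} (power iteration, default) or
#'   \code{"geometric"}.
#' @param tol Convergence tolerance on the iterate (default 1e-12).
#' @param max_iter Iteration cap (default 10000).
#' @return List with \code{weights} (named, positive, sums to 1),
#'   \code{lambda_max}, and \code{iterations}.
#' @export
principal_weights <- function(m, method = c("eigen", "geometric"),
                              tol = 1e-12, max_iter = 10000L) {
  method <- match.arg(method)
  a <- unclass(pcm(m, attr(m, "matrix_id")))
  n <- nrow(a)
  nm <- rownames(a)
  if (method == "geometric") {
    w <- exp(rowMeans(log(a)))
    w <- w / sum(w)
    lam <- mean((a %*% w) / w)
    return(list(weights = stats::setNames(as.numeric(w), nm), lambda_max = lam, iterations = 0L))
  }
  w <- rep(1 / n, n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    v <- as.numeric(a %*% w)
    v <- v / sum(v)
    if (max(abs(v - w)) < tol) { w <- v; break }
    w <- v
    if (iter >= max_iter) {
      mcda_stop("ahp_no_convergence",
                "power iteration did not converge within %d iterations", max_iter)
    }
  }
  lam <- mean(as.numeric(a %*% w) / w)
  list(weights = stats::setNames(w, nm), lambda_max = lam, iterations = iter)
}

#' Consistency ratio of a pairwise matrix
#'
#' \eqn{CI = (\lambda_{max} - n)/(n - 1)}; \eqn{CR = CI / RI(n)} with Saaty's
#' random-index table. Orders 1-2 are consistent by construction (CR = 0);
#' CR <= 0.1 is the conventional acceptance threshold.
#'
#' @param m A \code{pcm}.
#' @return The consistency ratio (non-negative real; tiny negative rounding
#'   is clipped to 0).
#' @export
consistency_ratio <- function(m) {
  n <- nrow(m)
  if (n <= 2L) return(0)
  if (n > length(SAATY_RI)) {
    mcda_stop("ahp_order_unsupported",
              "no random index for order %d (> 10); restructure the criteria group", n)
  }
  lam <- principal_weights(m)$lambda_max
  ci <- (lam - n) / (n - 1)
  max(ci / SAATY_RI[n], 0)
}

#' Global leaf weights from local sibling weights
#'
#' The global weight of a leaf is the product of local weights along the path
#' from the goal; single children carry local weight 1. Global leaf weights
#' sum to 1 by construction.
#'
#' @param h A \code{criteria_hierarchy}.
#' @param locals Named list: matrix_id -> named local weight vector (names are
#'   child ids), one per matrix of [plan_elicitation()].
#' @return List with \code{global} (named leaf weights, summing to 1) and
#'   \code{local} (named local weight of every node among its siblings).
#' @export
synthesize_global_weights <- function(h, locals) {
  plan <- plan_elicitation(h)
  missing_ids <- setdiff(plan$matrices$matrix_id, names(locals))
  if (length(missing_ids)) {
    mcda_stop("ahp_missing_local", "no local weight vector for planned matrix(es): %s",
              paste(missing_ids, collapse = ", "))
  }
  nodes <- h$nodes
  local_w <- stats::setNames(rep(1, nrow(nodes)), nodes$id) # single children keep 1
  for (k in seq_len(nrow(plan$matrices))) {
    mid <- plan$matrices$matrix_id[k]
    kids <- plan$matrices$child_ids[[k]]
    w <- locals[[mid]]
    if (is.null(names(w))) names(w) <- kids
    if (!setequal(names(w), kids)) {
      mcda_stop("ahp_missing_local", "local vector for %s does not cover children %s",
                mid, paste(kids, collapse = ", "))
    }
    if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
      mcda_stop("weights_invalid", "local weights for %s must be >= 0 and sum to 1", mid)
    }
    local_w[kids] <- w[kids]
  }
  global_w <- stats::setNames(rep(NA_real_, nrow(nodes)), nodes$id)
  for (i in seq_len(nrow(nodes))) { # document order: parents precede children
    n <- nodes[i, ]
    pg <- if (n$parent_id == ROOT_ID) 1 else global_w[[n$parent_id]]
    global_w[n$id] <- pg * local_w[[n$id]]
  }
  leaf_ids <- nodes$id[nodes$is_leaf]
  list(global = global_w[leaf_ids], local = local_w)
}

# ---- questionnaire-response I/O and the full weighting step ------------------

parse_saaty <- function(x) {
  x <- trimws(as.character(x))
  out <- numeric(length(x))
  frac <- grepl("^1\\s*/\\s*[0-9.]+$", x)
  out[frac] <- 1 / as.numeric(sub("^1\\s*/\\s*", "", x[frac]))
  out[!frac] <- suppressWarnings(as.numeric(x[!frac]))
  if (anyNA(out) || any(out <= 0)) {
    mcda_stop("responses_invalid", "unparseable Saaty value(s): %s",
              paste(unique(x[is.na(out) | out <= 0]), collapse = ", "))
  }
  out
}

#' Read questionnaire responses
#'
#' CSV columns: \code{respondent_id, matrix_id, row_node, col_node,
#' saaty_value} with values in 1..9 or \code{"1/k"} text. Only one triangle
#' need be given; reciprocals are auto-filled. A pair judged twice with
#' conflicting values is rejected.
#'
#' @param path Responses CSV path.
#' @param plan The [plan_elicitation()] output the matrices must match.
#' @return Named list: respondent_id -> named list of \code{pcm} by matrix_id.
#' @export
read_judgments <- function(path, plan) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE,
                        colClasses = "character")
  need <- c("respondent_id", "matrix_id", "row_node", "col_node", "saaty_value")
  if (!all(need %in% names(df))) {
    mcda_stop("responses_invalid", "responses file must have columns: %s",
              paste(need, collapse = ", "))
  }
  df$value <- parse_saaty(df$saaty_value)
  kids_of <- stats::setNames(plan$matrices$child_ids, plan$matrices$matrix_id)
  out <- list()
  for (rid in unique(df$respondent_id)) {
    sub <- df[df$respondent_id == rid, , drop = FALSE]
    mats <- list()
    for (mid in unique(sub$matrix_id)) {
      kids <- kids_of[[mid]]
      if (is.null(kids)) {
        mcda_stop("responses_invalid", "matrix_id '%s' is not in the elicitation plan", mid)
      }
      n <- length(kids)
      a <- matrix(NA_real_, n, n, dimnames = list(kids, kids))
      diag(a) <- 1
      rows <- sub[sub$matrix_id == mid, , drop = FALSE]
      for (r in seq_len(nrow(rows))) {
        i <- match(rows$row_node[r], kids); j <- match(rows$col_node[r], kids)
        if (is.na(i) || is.na(j)) {
          mcda_stop("responses_invalid", "matrix %s: node '%s' or '%s' is not a child of %s",
                    mid, rows$row_node[r], rows$col_node[r], rows$matrix_id[r])
        }
        v <- rows$value[r]
        if (!is.na(a[i, j]) && abs(a[i, j] - v) > 1e-9) {
          mcda_stop("responses_conflict",
                    "matrix %s, respondent %s: conflicting values for pair (%s, %s)",
                    mid, rid, kids[i], kids[j])
        }
        a[i, j] <- v
        a[j, i] <- 1 / v
      }
      if (anyNA(a)) {
        mcda_stop("responses_incomplete", "matrix %s, respondent %s: missing pair(s)", mid, rid)
      }
      mats[[mid]] <- pcm(a, matrix_id = mid)
    }
    out[[rid]] <- mats
  }
  out
}

#' Write judgment sets as a responses CSV
#'
#' Upper-triangle entries only; the inverse of [read_judgments()].
#'
#' @param judgments Named list respondent -> named list of \code{pcm}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_judgments <- function(judgments, path) {
  rows <- list()
  for (rid in names(judgments)) {
    for (mid in names(judgments[[rid]])) {
      a <- judgments[[rid]][[mid]]
      kids <- rownames(a)
      for (i in seq_len(nrow(a) - 1L)) for (j in (i + 1L):nrow(a)) {
        v <- a[i, j]
        txt <- if (v >= 1) format(v, digits = 15) else paste0("1/", format(1 / v, digits = 15))
        rows[[length(rows) + 1L]] <- data.frame(
          respondent_id = rid, matrix_id = mid,
          row_node = kids[i], col_node = kids[j], saaty_value = txt,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Full AHP weighting step: judgments to weights with consistency control
#'
#' Aggregates the group's matrices, extracts local weights, synthesizes
#' global leaf weights, and reports per-matrix consistency ratios. Matrices
#' with CR above \code{cr_threshold} raise a warning (or an error with
#' \code{strict_cr = TRUE}) and are flagged in the CR table; respondents
#' missing a matrix are tolerated with a logged count.
#'
#' @param h A \code{criteria_hierarchy}.
#' @param judgments Named list respondent -> named list of \code{pcm}
#'   (as from [read_judgments()] or [gen_judgments()]).
#' @param aggregation \code{"judgments"} (geometric mean of matrices, default)
#'   or \code{"priorities"} (arithmetic mean of individual eigenvectors).
#' @param weight_method Passed to [principal_weights()].
#' @param strict_cr If TRUE, any CR above threshold aborts.
#' @param cr_threshold Acceptance threshold (default 0.1).
#' @return List with \code{global}, \code{local} (as in
#'   [synthesize_global_weights()]), \code{locals} (per-matrix vectors) and
#'   \code{cr_table} (matrix_id, order, n_respondents, lambda_max, cr,
#'   acceptable).
#' @export
compute_weights <- function(h, judgments,
                            aggregation = c("judgments", "priorities"),
                            weight_method = "eigen",
                            strict_cr = FALSE, cr_threshold = 0.1) {
  aggregation <- match.arg(aggregation)
  plan <- plan_elicitation(h)
  locals <- list()
  crt <- list()
  for (k in seq_len(nrow(plan$matrices))) {
    mid <- plan$matrices$matrix_id[k]
    mats <- Filter(Negate(is.null), lapply(judgments, function(js) js[[mid]]))
    if (length(mats) == 0L) {
      mcda_stop("ahp_missing_local", "no respondent provided matrix %s", mid)
    }
    if (length(mats) < length(judgments)) {
      mcda_log("weights", "matrix %s: only %d of %d respondents answered",
               mid, length(mats), length(judgments))
    }
    agg <- aggregate_judgments(mats)
    if (aggregation == "judgments") {
      pw <- principal_weights(agg, method = weight_method)
      w <- pw$weights
    } else {
      ws <- vapply(mats, function(m) principal_weights(m, method = weight_method)$weights,
                   numeric(nrow(agg)))
      w <- rowMeans(ws)
      w <- w / sum(w)
      names(w) <- rownames(agg)
      pw <- principal_weights(agg, method = weight_method)
    }
    cr <- if (nrow(agg) <= 2L) 0 else consistency_ratio(agg)
    if (cr > cr_threshold) {
      if (strict_cr) {
        mcda_stop("cr_exceeded", "matrix %s: consistency ratio %.3f exceeds %.2f",
                  mid, cr, cr_threshold)
      }
      mcda_warn("cr_exceeded", "matrix %s: consistency ratio %.3f exceeds %.2f",
                mid, cr, cr_threshold)
    }
    locals[[mid]] <- w
    crt[[k]] <- data.frame(
      matrix_id = mid, order = nrow(agg), n_respondents = length(mats),
      lambda_max = pw$lambda_max, cr = cr, acceptable = cr <= cr_threshold,
      stringsAsFactors = FALSE
    )
  }
  gw <- synthesize_global_weights(h, locals)
  list(global = gw$global, local = gw$local, locals = locals,
       cr_table = do.call(rbind, crt))
}

#' Write local/global weights and the CR table as CSV files
#'
#' @param weights Output of [compute_weights()].
#' @param h The hierarchy the weights belong to.
#' @param path Output CSV path for weights (the CR table goes beside it with
#'   suffix \code{_cr.csv}).
#' @return \code{path}, invisibly.
#' @export
write_weights <- function(weights, h, path) {
  nodes <- h$nodes
  glob_all <- rep(NA_real_, nrow(nodes))
  names(glob_all) <- nodes$id
  glob_all[names(weights$global)] <- weights$global
  df <- data.frame(
    node_id = nodes$id, label = nodes$label, level = nodes$level,
    parent_id = nodes$parent_id, is_leaf = nodes$is_leaf,
    local_weight = as.numeric(weights$local[nodes$id]),
    global_leaf_weight = as.numeric(glob_all),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(weights$cr_table)) {
    utils::write.csv(weights$cr_table,
                     sub("\\.csv$", "_cr.csv", path), row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
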