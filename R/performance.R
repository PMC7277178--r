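# The evidence table: alternatives x leaf criteria, cells typed per the
# hierarchy leaf's data_kind (numeric / binary / linguistic). Directions and
# kinds live in the hierarchy — the single source of truth; the table file may
# restate them in comment headers but must agree.

#' Performance table of alternatives against leaf criteria
#'
#' @param cells Data.frame: rows = alternatives (row names or first column
#'   \code{alternative}), columns = leaf criterion ids, raw scores as
#'   character/numeric. \code{NA} or empty marks missing evidence.
#' @param h The \code{criteria_hierarchy} the columns bind to.
#' @return An object of class \code{"performance_table"} with fields
#'   \code{alternatives}, \code{columns}, \code{kinds}, \code{directions},
#'   \code{cells} (character matrix).
#' @export
performance_table <- function(cells, h) {
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  if ("alternative" %in% names(cells)) {
    alts <- as.character(cells$alternative)
    cells <- cells[, setdiff(names(cells), "alternative"), drop = FALSE]
  } else {
    alts <- rownames(cells)
  }
  if (anyDuplicated(alts)) {
    mcda_stop("table_duplicate_alternative", "duplicate alternative label(s): %s",
              paste(unique(alts[duplicated(alts)]), collapse = ", "))
  }
  lf <- leaves(h)
  unknown <- setdiff(names(cells), lf$id)
  if (length(unknown)) {
    mcda_stop("table_unknown_column",
              "column id(s) not a hierarchy leaf: %s", paste(unknown, collapse = ", "))
  }
  cols <- names(cells)
  kinds <- stats::setNames(lf$data_kind[match(cols, lf$id)], cols)
  dirs <- stats::setNames(lf$direction[match(cols, lf$id)], cols)
  raw <- matrix(NA_character_, length(alts), length(cols), dimnames = list(alts, cols))
  for (j in cols) {
    v <- as.character(cells[[j]])
    v[!nzchar(trimws(v)) | is.na(v)] <- NA_character_
    raw[, j] <- v
  }
  # type-check every non-missing cell, naming row and column on failure
  for (j in cols) for (i in seq_along(alts)) {
    v <- raw[i, j]
    if (is.na(v)) next
    ok <- tryCatch({ encode_score(v, kinds[[j]]); TRUE },
                   mcda4hta_error = function(e) FALSE)
    if (!ok) {
      mcda_stop("table_cell_type",
                "cell (%s, %s): '%s' is not a valid %s score", alts[i], j, v, kinds[[j]])
    }
  }
  allmiss <- cols[apply(raw, 2, function(x) all(is.na(x)))]
  if (length(allmiss)) {
    mcda_stop("table_empty_column", "column(s) missing for every alternative: %s",
              paste(allmiss, collapse = ", "))
  }
  absent <- setdiff(lf$id, cols)
  if (length(absent)) {
    mcda_log("table", "%d hierarchy leaf(s) have no evidence column and are excluded: %s%s",
             length(absent), paste(utils::head(absent, 5), collapse = ", "),
             if (length(absent) > 5) ", ..." else "")
  }
  structure(
    list(alternatives = alts, columns = cols, kinds = kinds,
         directions = dirs, cells = raw),
    class = "performance_table"
  )
}

#' @export
print.performance_table <- function(x, ...) {
  cat(sprintf("<performance_table: %d alternatives x %d criteria (%s)>\n",
              length(x$alternatives), length(x$columns),
              paste(sprintf("%s %d", names(table(x$kinds)), table(x$kinds)), collapse = ", ")))
  invisible(x)
}

#' Load a performance table from CSV
#'
#' First column is the alternative label, remaining columns are leaf ids.
#' Optional comment rows \code{#kind} and \code{#direction} (first cell) are
#' accepted but must match the hierarchy.
#'
#' @param path CSV path.
#' @param h The binding \code{criteria_hierarchy}.
#' @return A \code{performance_table}.
#' @export
load_table <- function(path, h) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  names(raw)[1] <- "alternative"
  meta <- raw[startsWith(raw$alternative, "#"), , drop = FALSE]
  body <- raw[!startsWith(raw$alternative, "#"), , drop = FALSE]
  pt <- performance_table(body, h)
  for (r in seq_len(nrow(meta))) {
    key <- sub("^#", "", meta$alternative[r])
    field <- switch(key, kind = pt$kinds, direction = pt$directions, NULL)
    if (is.null(field)) next
    declared <- unlist(meta[r, pt$columns, drop = TRUE])
    bad <- pt$columns[!is.na(declared) & nzchar(declared) & declared != field[pt$columns]]
    if (length(bad)) {
      mcda_stop("table_meta_mismatch",
                "#%s header disagrees with the hierarchy for column(s): %s",
                key, paste(bad, collapse = ", "))
    }
  }
  pt
}

#' Write a performance table as CSV (with #kind/#direction headers)
#'
#' @param t A \code{performance_table}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_table <- function(t, path) {
  df <- data.frame(alternative = c("#kind", "#direction", t$alternatives),
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (j in t$columns) df[[j]] <- c(t$kinds[[j]], t$directions[[j]], t$cells[, j])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Fuzzify a performance table
#'
#' Encodes every cell as a triangular fuzzy number via [encode_score()] and
#' attaches renormalized column weights. A column with a missing cell for any
#' alternative is dropped entirely (an MCDA comparison needs evidence on all
#' comparators) and the remaining weights are renormalized; the event is
#' logged and recorded.
#'
#' @param t A \code{performance_table}.
#' @param weights Named global leaf weights (from [compute_weights()] or
#'   supplied directly). Leaves absent from the table are ignored with
#'   renormalization.
#' @param scale Linguistic scale (name or object) for linguistic columns.
#' @return An object of class \code{"fuzzy_decision_matrix"}: list of three
#'   alternatives x columns matrices \code{l}, \code{m}, \code{u}, plus
#'   \code{weights}, \code{directions}, \code{alternatives}, \code{columns},
#'   \code{dropped}, \code{scale_name}, and the \code{normalized} flag.
#' @export
fuzzify_table <- function(t, weights, scale = "default7") {
  scale <- get_scale(scale)
  keep <- t$columns[apply(t$cells, 2, function(x) !any(is.na(x)))]
  dropped <- setdiff(t$columns, keep)
  if (length(dropped)) {
    mcda_log("fuzzify", "dropping column(s) with missing cells: %s",
             paste(dropped, collapse = ", "))
  }
  if (length(keep) == 0L) {
    mcda_stop("table_empty_column", "no complete evidence columns remain")
  }
  w <- weights[keep]
  if (anyNA(w)) {
    mcda_stop("weights_invalid", "no weight for column(s): %s",
              paste(keep[is.na(w)], collapse = ", "))
  }
  if (sum(w) <= 0) mcda_stop("weights_invalid", "weights over present columns sum to 0")
  w <- w / sum(w)
  na <- length(t$alternatives)
  L <- M <- U <- matrix(NA_real_, na, length(keep),
                        dimnames = list(t$alternatives, keep))
  for (j in keep) for (i in seq_len(na)) {
    f <- tryCatch(encode_score(t$cells[i, j], t$kinds[[j]], scale),
                  mcda4hta_error = function(e) {
                    mcda_stop("encode_cell", "cell (%s, %s): %s",
                              t$alternatives[i], j, conditionMessage(e))
                  })
    L[i, j] <- f[, "l"]; M[i, j] <- f[, "m"]; U[i, j] <- f[, "u"]
  }
  structure(
    list(l = L, m = M, u = U,
         alternatives = t$alternatives, columns = keep,
         weights = w, directions = t$directions[keep],
         dropped = dropped, scale_name = scale$name, normalized = FALSE),
    class = "fuzzy_decision_matrix"
  )
}

#' @export
print.fuzzy_decision_matrix <- function(x, ...) {
  cat(sprintf("<fuzzy_decision_matrix: %d x %d%s, scale '%s'>\n",
              length(x$alternatives), length(x$columns),
              if (x$normalized) ", normalized" else "", x$scale_name))
  invisible(x)
}

#' Linear max/min normalization of a fuzzy decision matrix
#'
#' Benefit column j with \eqn{c^* = \max_i u_{ij}}: each cell becomes
#' \eqn{(l/c^*, m/c^*, u/c^*)}. Cost column j with \eqn{a^- = \min_i l_{ij}}:
#' each cell becomes \eqn{(a^-/u, a^-/m, a^-/l)} — the reciprocal form keeps
#' TFN ordering valid without sign flips. All outputs lie in \[0, 1\] and every
#' column is benefit-oriented afterwards.
#'
#' Cost columns require strictly positive raw supports; pre-shift data that
#' cross zero before ranking.
#'
#' @param f A \code{fuzzy_decision_matrix} (not yet normalized).
#' @return The normalized \code{fuzzy_decision_matrix}.
#' @export
normalize_matrix <- function(f) {
  if (f$normalized) return(f)
  L <- f$l; M <- f$m; U <- f$u
  for (j in f$columns) {
    if (f$directions[[j]] == "benefit") {
      cstar <- max(U[, j])
      if (cstar <= 0) {
        mcda_stop("normalize_zero_divisor",
                  "benefit column '%s' has max upper support <= 0; apply an affine pre-shift", j)
      }
      L[, j] <- f$l[, j] / cstar; M[, j] <- f$m[, j] / cstar; U[, j] <- f$u[, j] / cstar
    } else {
      aminus <- min(L[, j])
      if (aminus <= 0) {
        mcda_stop("normalize_zero_divisor",
                  "cost column '%s' has non-positive lower support; apply an affine pre-shift", j)
      }
      l <- aminus / f$u[, j]; m <- aminus / f$m[, j]; u <- aminus / f$l[, j]
      L[, j] <- l; M[, j] <- m; U[, j] <- u
    }
  }
  out <- f
  out$l <- L; out$m <- M; out$u <- U
  out$directions[] <- "benefit"
  out$normalized <- TRUE
  out
}

# Defuzzified crisp view of a fuzzy decision matrix (alternatives x columns).
defuzzify_matrix <- function(f, method = "graded_mean") {
  X <- matrix(NA_real_, length(f$alternatives), length(f$columns),
              dimnames = list(f$alternatives, f$columns))
  for (j in seq_along(f$columns)) {
    X[, j] <- defuzzify(tfn(f$l[, j], f$m[, j], f$u[, j]), method)
  }
  X
}
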