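# Triangular fuzzy numbers and the encodings from mixed-type evidence scores.
#
# A TFN (l, m, u) has linear membership rising l -> m and falling m -> u.
# Vectorised representation: an n x 3 numeric matrix with columns l, m, u and
# class "tfn", so whole decision-matrix columns move through arithmetic at once.

#' Triangular fuzzy numbers
#'
#' Construct a (vector of) triangular fuzzy number(s) from lower, modal and
#' upper support points. The invariant \code{l <= m <= u} is enforced.
#'
#' @param l,m,u Numeric vectors of equal length (recycled scalars allowed).
#' @return An object of class \code{"tfn"}: an n x 3 matrix with columns
#'   \code{l}, \code{m}, \code{u}.
#' @examples
#' tfn(1, 2, 3)
#' tfn(c(0, 1), c(0.5, 1), c(1, 1))
#' @export
tfn <- function(l, m = l, u = m) {
  x <- cbind(l = as.numeric(l), m = as.numeric(m), u = as.numeric(u))
  if (anyNA(x)) {
    mcda_stop("tfn_invalid", "TFN components must be non-missing numerics")
  }
  if (any(x[, "l"] > x[, "m"] + 1e-12) || any(x[, "m"] > x[, "u"] + 1e-12)) {
    mcda_stop("tfn_invalid", "TFN requires l <= m <= u for every element")
  }
  structure(x, class = "tfn")
}

is_tfn <- function(x) inherits(x, "tfn")

as_tfn <- function(x) {
  if (is_tfn(x)) return(x)
  if (is.numeric(x) && is.null(dim(x))) return(tfn(x, x, x))
  if (is.matrix(x) && ncol(x) == 3) return(tfn(x[, 1], x[, 2], x[, 3]))
  mcda_stop("tfn_invalid", "cannot interpret object of class '%s' as TFN", class(x)[1])
}

#' @export
print.tfn <- function(x, ...) {
  cat(sprintf("<tfn[%d]>\n", nrow(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' @export
`[.tfn` <- function(x, i, j, ..., drop = TRUE) {
  m <- unclass(x)
  if (missing(j)) { # x[i]: subset elements, stay a tfn
    if (missing(i)) return(x)
    return(structure(m[i, , drop = FALSE], class = "tfn"))
  }
  m[i, j, drop = drop] # x[, "l"] etc.: plain matrix indexing
}

#' @export
length.tfn <- function(x) nrow(unclass(x))

#' TFN arithmetic: addition and non-negative scaling
#'
#' \code{tfn_add} adds component-wise; \code{tfn_scale} multiplies all three
#' support points by a non-negative scalar \code{k}. Negative scaling is
#' rejected: cost criteria are handled by normalization direction, never by
#' sign flips, so scaled TFNs always remain valid.
#'
#' @param a,b \code{tfn} objects (equal length, or length 1 recycled).
#' @param k Non-negative scalar (or vector matching \code{length(a)}).
#' @return A \code{tfn}.
#' @examples
#' tfn_add(tfn(1, 2, 3), tfn(2, 4, 6)) # (3, 6, 9)
#' tfn_scale(tfn(1, 2, 3), 2)          # (2, 4, 6)
#' @export
tfn_add <- function(a, b) {
  a <- as_tfn(a); b <- as_tfn(b)
  if (length(a) != length(b)) {
    if (length(a) == 1L) a <- a[rep(1L, length(b))]
    else if (length(b) == 1L) b <- b[rep(1L, length(a))]
    else mcda_stop("tfn_length", "tfn_add: lengths %d and %d differ", length(a), length(b))
  }
  tfn(a[, "l"] + b[, "l"], a[, "m"] + b[, "m"], a[, "u"] + b[, "u"])
}

#' @rdname tfn_add
#' @export
tfn_scale <- function(a, k) {
  a <- as_tfn(a)
  k <- as.numeric(k)
  if (any(k < 0)) {
    mcda_stop("tfn_negative_scale", "tfn_scale requires k >= 0 (got %s)", min(k))
  }
  tfn(k * a[, "l"], k * a[, "m"], k * a[, "u"])
}

#' Vertex distance between triangular fuzzy numbers
#'
#' The vertex metric
#' \deqn{d(A,B) = \sqrt{((a_l-b_l)^2 + (a_m-b_m)^2 + (a_u-b_u)^2)/3},}
#' the standard distance in fuzzy TOPSIS. On degenerate (crisp) TFNs it
#' coincides with the absolute difference.
#'
#' @param a,b \code{tfn} objects (vectorised, recycled if length 1).
#' @return Numeric vector of distances.
#' @examples
#' vertex_distance(tfn(1, 2, 3), tfn(2, 4, 6)) # sqrt(14/3)
#' @export
vertex_distance <- function(a, b) {
  a <- as_tfn(a); b <- as_tfn(b)
  if (length(a) != length(b)) {
    if (length(a) == 1L) a <- a[rep(1L, length(b))]
    else if (length(b) == 1L) b <- b[rep(1L, length(a))]
    else mcda_stop("tfn_length", "vertex_distance: lengths differ")
  }
  as.numeric(
    sqrt(((a[, "l"] - b[, "l"])^2 + (a[, "m"] - b[, "m"])^2 + (a[, "u"] - b[, "u"])^2) / 3)
  )
}

#' Defuzzify a triangular fuzzy number
#'
#' Maps a TFN to a crisp value. \code{"centroid"} returns \eqn{(l+m+u)/3};
#' \code{"graded_mean"} returns \eqn{(l+4m+u)/6}, the graded mean integration
#' value common in the fuzzy VIKOR literature (the package default). Both
#' return \code{m} for symmetric TFNs.
#'
#' @param a A \code{tfn}.
#' @param method \code{"graded_mean"} (default) or \code{"centroid"}.
#' @return Numeric vector of crisp values.
#' @examples
#' defuzzify(tfn(0, 1, 5), "graded_mean") # 1.5
#' defuzzify(tfn(0, 1, 5), "centroid")    # 2
#' @export
defuzzify <- function(a, method = c("graded_mean", "centroid")) {
  method <- match.arg(method)
  a <- as_tfn(a)
  as.numeric(switch(method,
    centroid    = (a[, "l"] + a[, "m"] + a[, "u"]) / 3,
    graded_mean = (a[, "l"] + 4 * a[, "m"] + a[, "u"]) / 6
  ))
}

# ---- linguistic scales -------------------------------------------------------

#' Seven-level linguistic term scales
#'
#' A linguistic scale maps exactly 7 ordered terms to triangular fuzzy numbers
#' on a declared support range. The built-in \code{"default7"} scale places
#' term k (k = 1..7) at \eqn{((k-2)/6} clipped at 0, \eqn{(k-1)/6, k/6}
#' clipped at 1) on \[0, 1\].
#'
#' @param terms Character vector of 7 term labels, worst to best.
#' @param l,m,u Numeric vectors of 7 support points each.
#' @param range Declared support range (length-2 numeric).
#' @param name Scale name used in reports.
#' @return An object of class \code{"linguistic_scale"}.
#' @export
linguistic_scale <- function(terms, l, m, u, range = c(min(l), max(u)), name = "custom") {
  if (length(terms) != 7L || length(l) != 7L || length(m) != 7L || length(u) != 7L) {
    mcda_stop("scale_invalid", "a linguistic scale requires exactly 7 terms")
  }
  if (anyDuplicated(tolower(terms))) {
    mcda_stop("scale_invalid", "linguistic scale terms must be unique")
  }
  if (any(diff(m) <= 0)) {
    mcda_stop("scale_invalid", "modal points of a linguistic scale must be strictly increasing")
  }
  if (any(l < range[1] - 1e-12) || any(u > range[2] + 1e-12)) {
    mcda_stop("scale_invalid", "scale supports must lie within the declared range [%g, %g]",
              range[1], range[2])
  }
  tab <- tfn(l, m, u)
  structure(
    list(terms = as.character(terms), tfns = tab, range = as.numeric(range), name = name),
    class = "linguistic_scale"
  )
}

#' @rdname linguistic_scale
#' @export
default_scale7 <- function() {
  k <- 1:7
  linguistic_scale(
    terms = c("very poor", "poor", "medium poor", "fair",
              "medium good", "good", "very good"),
    l = pmax((k - 2) / 6, 0),
    m = (k - 1) / 6,
    u = pmin(k / 6, 1),
    range = c(0, 1),
    name = "default7"
  )
}

#' @rdname linguistic_scale
#' @param scale_name Name of a built-in scale (currently \code{"default7"}).
#' @export
get_scale <- function(scale_name = "default7") {
  if (inherits(scale_name, "linguistic_scale")) return(scale_name)
  switch(scale_name,
    default7 = default_scale7(),
    mcda_stop("scale_unknown", "unknown linguistic scale '%s'", scale_name)
  )
}

#' Load a linguistic scale from a tabular file
#'
#' Expects columns \code{term, l, m, u} (CSV), terms ordered worst to best.
#'
#' @param path Path to a CSV file.
#' @param name Scale name (defaults to the file name without extension).
#' @return A \code{linguistic_scale}.
#' @export
load_scale <- function(path, name = tools::file_path_sans_ext(basename(path))) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("term", "l", "m", "u")
  if (!all(need %in% names(df))) {
    mcda_stop("scale_invalid", "scale file must have columns term, l, m, u")
  }
  linguistic_scale(df$term, df$l, df$m, df$u, name = name)
}

#' @export
print.linguistic_scale <- function(x, ...) {
  cat(sprintf("<linguistic_scale '%s' on [%g, %g]>\n", x$name, x$range[1], x$range[2]))
  df <- data.frame(term = x$terms, unclass(x$tfns))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Encode a raw evidence score as a triangular fuzzy number
#'
#' Evidence cells come in three kinds: \code{numeric} values are embedded as
#' degenerate TFNs \eqn{(x, x, x)}; \code{binary} yes/no values map to
#' \eqn{(1,1,1)} and \eqn{(0,0,0)}; \code{linguistic} terms (case-insensitive)
#' look up their TFN on the 7-level scale.
#'
#' @param cell Raw score: a number, "yes"/"no", or a linguistic term.
#' @param kind One of \code{"numeric"}, \code{"binary"}, \code{"linguistic"}.
#' @param scale A \code{linguistic_scale} (used for linguistic cells).
#' @return A length-1 \code{tfn}.
#' @examples
#' encode_score("yes", "binary")                 # (1, 1, 1)
#' encode_score(7.25, "numeric")                 # (7.25, 7.25, 7.25)
#' encode_score("fair", "linguistic", default_scale7())
#' @export
encode_score <- function(cell, kind = c("numeric", "binary", "linguistic"),
                         scale = default_scale7()) {
  kind <- match.arg(kind)
  scale <- get_scale(scale)
  if (kind == "numeric") {
    x <- suppressWarnings(as.numeric(cell))
    if (is.na(x)) {
      mcda_stop("encode_numeric", "non-numeric text '%s' in a numeric cell", as.character(cell))
    }
    return(tfn(x, x, x))
  }
  if (kind == "binary") {
    v <- tolower(trimws(as.character(cell)))
    if (v %in% c("yes", "y", "1", "true")) return(tfn(1, 1, 1))
    if (v %in% c("no", "n", "0", "false")) return(tfn(0, 0, 0))
    mcda_stop("encode_binary", "cannot interpret '%s' as yes/no", as.character(cell))
  }
  v <- tolower(trimws(as.character(cell)))
  i <- match(v, tolower(scale$terms))
  if (is.na(i)) {
    mcda_stop("encode_linguistic",
              "unknown linguistic term '%s' (scale '%s' knows: %s)",
              as.character(cell), scale$name, paste(scale$terms, collapse = ", "))
  }
  scale$tfns[i]
}
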