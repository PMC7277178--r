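# Seeded synthetic-study generator: hierarchies, planted weights, noisy
# Saaty-scale judgment sets from a 12-person panel, and mixed-type
# performance tables — so every stage of the pipeline is testable against
# known ground truth.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

SAATY_SET <- c(1 / (9:2), 1:9)

snap_saaty <- function(x) {
  SAATY_SET[vapply(x, function(v) which.min(abs(log(SAATY_SET) - log(v))), 0L)]
}

#' Specification of a synthetic decision study
#'
#' Captures the generating conditions: hierarchy shape, panel size (12 by
#' default, matching a full multi-disciplinary HTA decision group), judgment
#' noise, alternative count and the mix of evidence kinds.
#'
#' @param seed Integer seed; every generated artifact is deterministic in it.
#' @param shape Integer vector of branching counts per level:
#'   \code{shape[1]} main criteria, then children per node at each deeper
#'   level (0 stops). Default \code{c(5, 3)}.
#' @param n_respondents Panel size (default 12).
#' @param sigma Log-scale noise on consistent judgment ratios
#'   (\eqn{a_{ij} = (w_i/w_j) e^\epsilon}, \eqn{\epsilon \sim N(0,\sigma^2)});
#'   0 gives exactly consistent matrices.
#' @param n_alternatives Number of technology alternatives (default 2).
#' @param kind_mix Named proportions for numeric/binary/linguistic leaf
#'   columns; must sum to 1.
#' @param planted_dominance If TRUE the first alternative weakly dominates
#'   all others, with strict dominance somewhere.
#' @param saaty_snap Snap noisy ratios to the nearest Saaty value
#'   (\code{{1/9..9}}), emulating questionnaire output; exact ratios are kept
#'   when \code{sigma = 0} so consistency is preserved.
#' @return An object of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(seed = 1L, shape = c(5L, 3L), n_respondents = 12L,
                           sigma = 0.1, n_alternatives = 2L,
                           kind_mix = c(numeric = 0.4, binary = 0.2, linguistic = 0.4),
                           planted_dominance = FALSE, saaty_snap = TRUE) {
  shape <- as.integer(shape[shape > 0])
  if (length(shape) < 1L || length(shape) > 4L) {
    mcda_stop("spec_invalid", "shape must give 1..4 positive branching counts")
  }
  if (n_respondents < 1L || n_alternatives < 1L) {
    mcda_stop("spec_invalid", "counts must be positive")
  }
  if (sigma < 0) mcda_stop("spec_invalid", "sigma must be >= 0")
  if (!setequal(names(kind_mix), c("numeric", "binary", "linguistic")) ||
      abs(sum(kind_mix) - 1) > 1e-9 || any(kind_mix < 0)) {
    mcda_stop("spec_invalid", "kind_mix must be named proportions over numeric/binary/linguistic summing to 1")
  }
  structure(
    list(seed = as.integer(seed), shape = shape,
         n_respondents = as.integer(n_respondents), sigma = sigma,
         n_alternatives = as.integer(n_alternatives), kind_mix = kind_mix,
         planted_dominance = isTRUE(planted_dominance),
         saaty_snap = isTRUE(saaty_snap)),
    class = "synthetic_spec"
  )
}

# Deterministic leaf typing given a spec: kinds cycle through a seeded draw;
# cost direction only on numeric leaves (reciprocal cost normalization needs
# strictly positive supports, which only numeric columns guarantee here).
assign_leaf_fields <- function(nodes, spec) {
  is_leaf <- !(nodes$id %in% nodes$parent_id)
  idx <- which(is_leaf)
  kinds <- sample(names(spec$kind_mix), length(idx), replace = TRUE, prob = spec$kind_mix)
  dirs <- rep("benefit", length(idx))
  numeric_ix <- which(kinds == "numeric")
  if (length(numeric_ix)) {
    dirs[numeric_ix] <- ifelse(stats::runif(length(numeric_ix)) < 0.3, "cost", "benefit")
  }
  nodes$direction[idx] <- dirs
  nodes$data_kind[idx] <- kinds
  nodes
}

#' Generate a synthetic criteria hierarchy
#'
#' Builds a tree with \code{spec$shape[1]} main criteria and uniform
#' branching below; leaf directions and data kinds are drawn per
#' \code{spec$kind_mix} (cost direction restricted to numeric leaves).
#' Deterministic for a fixed seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A \code{criteria_hierarchy}.
#' @export
gen_hierarchy <- function(spec) {
  with_seed(spec$seed, {
    rows <- list()
    emit <- function(parent_id, level, prefix) {
      count <- spec$shape[level]
      if (is.na(count) || count == 0L) return()
      for (i in seq_len(count)) {
        id <- if (level == 1L) sprintf("C%d", i) else sprintf("%s.%d", prefix, i)
        rows[[length(rows) + 1L]] <<- data.frame(
          id = id, label = paste("Criterion", id), level = level,
          parent_id = parent_id, direction = NA_character_,
          data_kind = NA_character_, stringsAsFactors = FALSE
        )
        emit(id, level + 1L, id)
      }
    }
    emit(ROOT_ID, 1L, "")
    nodes <- assign_leaf_fields(do.call(rbind, rows), spec)
    criteria_hierarchy(nodes, goal = sprintf("Synthetic HTA goal (seed %d)", spec$seed))
  })
}

#' Planted ground-truth local weights for every planned matrix
#'
#' Normalized Gamma draws per sibling group, bounded away from 0 so Saaty
#' ratios stay in a realistic range.
#'
#' @param spec A [synthetic_spec()].
#' @param plan The [plan_elicitation()] of the target hierarchy.
#' @return Named list matrix_id -> named local weight vector.
#' @export
gen_true_locals <- function(spec, plan) {
  with_seed(spec$seed + 1L, {
    out <- list()
    for (k in seq_len(nrow(plan$matrices))) {
      kids <- plan$matrices$child_ids[[k]]
      w <- stats::rgamma(length(kids), shape = 3, rate = 1) + 0.25
      w <- w / sum(w)
      out[[plan$matrices$matrix_id[k]]] <- stats::setNames(w, kids)
    }
    out
  })
}

#' Generate noisy judgment sets from planted weights
#'
#' For each respondent and each planned matrix, every upper-triangle ratio is
#' \eqn{a_{ij} = (w_i / w_j) e^{\epsilon}}, \eqn{\epsilon \sim N(0,
#' \sigma^2)}, mirrored to keep reciprocity exact; with
#' \code{spec$saaty_snap} the noisy ratio is snapped to the nearest Saaty
#' value. At \eqn{\sigma = 0} matrices are exactly consistent (CR = 0) and
#' [principal_weights()] recovers the planted weights.
#'
#' @param spec A [synthetic_spec()].
#' @param h The target hierarchy.
#' @param true_locals Planted local weights per matrix (default
#'   [gen_true_locals()]).
#' @return List with \code{judgments} (respondent -> matrix_id ->
#'   \code{pcm}) and \code{true_locals}.
#' @export
gen_judgments <- function(spec, h, true_locals = NULL) {
  plan <- plan_elicitation(h)
  if (is.null(true_locals)) true_locals <- gen_true_locals(spec, plan)
  judgments <- with_seed(spec$seed + 2L, {
    lapply(stats::setNames(seq_len(spec$n_respondents),
                           sprintf("R%02d", seq_len(spec$n_respondents))), function(r) {
      mats <- list()
      for (k in seq_len(nrow(plan$matrices))) {
        mid <- plan$matrices$matrix_id[k]
        w <- true_locals[[mid]]
        n <- length(w)
        a <- diag(n)
        dimnames(a) <- list(names(w), names(w))
        for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
          ratio <- w[i] / w[j]
          if (spec$sigma > 0) {
            ratio <- ratio * exp(stats::rnorm(1, 0, spec$sigma))
            if (spec$saaty_snap) ratio <- snap_saaty(ratio)
          }
          a[i, j] <- ratio
          a[j, i] <- 1 / ratio
        }
        mats[[mid]] <- pcm(a, matrix_id = mid)
      }
      mats
    })
  })
  list(judgments = judgments, true_locals = true_locals)
}

#' Generate a synthetic performance table
#'
#' Cells drawn per the leaf's data kind: numeric scores are log-normal
#' (strictly positive, so cost columns normalize), binary cells are yes/no,
#' linguistic cells use only the 7 scale terms. With
#' \code{spec$planted_dominance} the first alternative is set to the
#' direction-aware best value in every column, strictly better in at least
#' one.
#'
#' @param spec A [synthetic_spec()].
#' @param h The target hierarchy.
#' @param scale Linguistic scale used for term labels.
#' @return A \code{performance_table}.
#' @export
gen_performance <- function(spec, h, scale = default_scale7()) {
  scale <- get_scale(scale)
  lf <- leaves(h)
  with_seed(spec$seed + 3L, {
    alts <- sprintf("ALT%d", seq_len(spec$n_alternatives))
    cells <- matrix(NA_character_, length(alts), nrow(lf),
                    dimnames = list(alts, lf$id))
    for (k in seq_len(nrow(lf))) {
      kind <- lf$data_kind[k]
      if (kind == "numeric") {
        cells[, k] <- format(round(stats::rlnorm(length(alts), 1, 0.5), 4), trim = TRUE)
      } else if (kind == "binary") {
        v <- sample(c("yes", "no"), length(alts), replace = TRUE)
        if (all(v == "no")) v[1] <- "yes" # keep the column rankable
        cells[, k] <- v
      } else {
        cells[, k] <- sample(scale$terms, length(alts), replace = TRUE)
      }
    }
    if (spec$planted_dominance && length(alts) > 1L) {
      strict <- FALSE
      for (k in seq_len(nrow(lf))) {
        kind <- lf$data_kind[k]
        others <- cells[-1, k]
        if (kind == "numeric") {
          vals <- as.numeric(others)
          best <- if (lf$direction[k] == "benefit") max(vals) else min(vals)
          cells[1, k] <- format(best, trim = TRUE)
        } else if (kind == "binary") {
          cells[1, k] <- if (any(others == "yes")) "yes" else cells[1, k]
          if (all(cells[, k] == "no")) cells[1, k] <- "yes"
        } else {
          ranks <- match(tolower(others), tolower(scale$terms))
          cells[1, k] <- scale$terms[max(ranks)]
        }
      }
      # guarantee strictness somewhere: push the first numeric (or linguistic)
      # column, if none is already strict
      X <- vapply(seq_len(nrow(lf)), function(k) {
        sapply(cells[, k], function(v)
          defuzzify(encode_score(v, lf$data_kind[k], scale)))
      }, numeric(length(alts)))
      strict <- any(vapply(seq_len(ncol(X)), function(k) {
        if (lf$direction[k] == "benefit") all(X[1, k] > X[-1, k])
        else all(X[1, k] < X[-1, k])
      }, TRUE))
      if (!strict) {
        k <- which(lf$data_kind == "numeric")[1]
        if (!is.na(k)) {
          v <- as.numeric(cells[, k])
          cells[1, k] <- format(if (lf$direction[k] == "benefit") max(v) * 1.25
                                else min(v) * 0.8, trim = TRUE)
        } else {
          k <- which(lf$data_kind == "linguistic")[1]
          ranks <- match(tolower(cells[, k]), tolower(scale$terms))
          cells[1, k] <- scale$terms[min(max(ranks[-1]) + 1L, 7L)]
          cells[-1, k] <- scale$terms[pmin(ranks[-1], 6L)]
        }
      }
    }
    df <- data.frame(alternative = alts, cells, stringsAsFactors = FALSE,
                     check.names = FALSE)
    performance_table(df, h)
  })
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper: hierarchy, planted weights, judgment sets and
#' performance table in one call.
#'
#' @param spec A [synthetic_spec()].
#' @return List with \code{hierarchy}, \code{plan}, \code{true_locals},
#'   \code{judgments}, \code{performance} and the planted \code{true_global}
#'   leaf weights.
#' @export
gen_study <- function(spec) {
  h <- gen_hierarchy(spec)
  plan <- plan_elicitation(h)
  gj <- gen_judgments(spec, h)
  perf <- gen_performance(spec, h)
  truth <- synthesize_global_weights(h, gj$true_locals)
  list(hierarchy = h, plan = plan, true_locals = gj$true_locals,
       judgments = gj$judgments, performance = perf,
       true_global = truth$global)
}
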