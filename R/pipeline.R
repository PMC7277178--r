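# End-to-end pipeline: load -> weights -> fuzzify -> normalize -> rank ->
# report. Deterministic for fixed inputs and config; every defaulted config
# value is echoed in the report, and warnings (CR > 0.1, dropped columns)
# are duplicated into the report so the decision record is self-contained.

#' Pipeline run configuration
#'
#' All values are echoed into the decision report; defaults are never silent.
#'
#' @param hierarchy Path to a hierarchy document, or a
#'   \code{criteria_hierarchy}.
#' @param responses Path to a responses CSV, a judgment-set list, or
#'   \code{NULL} when \code{weights} are given directly.
#' @param table Path to a performance CSV or a \code{performance_table}.
#' @param weights Optional named global leaf weights (skips the AHP step).
#' @param methods Character subset of \code{c("topsis", "vikor", "gp")}.
#' @param vikor_v VIKOR trade-off parameter in \[0, 1\] (default 0.5).
#' @param defuzz \code{"graded_mean"} or \code{"centroid"}.
#' @param scale Linguistic scale name or object (default \code{"default7"}).
#' @param vikor_fuzzy_arith Use the fuzzy-arithmetic VIKOR route.
#' @param strict_cr Abort when any consistency ratio exceeds 0.1.
#' @param aggregation AHP group aggregation rule, see [compute_weights()].
#' @param out_dir Optional output directory for [write_report()].
#' @return An object of class \code{"run_config"}.
#' @export
run_config <- function(hierarchy, responses = NULL, table, weights = NULL,
                       methods = c("topsis", "vikor", "gp"),
                       vikor_v = 0.5, defuzz = "graded_mean", scale = "default7",
                       vikor_fuzzy_arith = FALSE, strict_cr = FALSE,
                       aggregation = "judgments", out_dir = NULL) {
  if (length(methods) == 0L) {
    mcda_stop("config_invalid", "at least one ranking method must be requested")
  }
  bad <- setdiff(methods, c("topsis", "vikor", "gp"))
  if (length(bad)) {
    mcda_stop("config_invalid", "unknown method(s): %s", paste(bad, collapse = ", "))
  }
  if (vikor_v < 0 || vikor_v > 1) mcda_stop("config_invalid", "vikor_v must lie in [0, 1]")
  if (!defuzz %in% c("graded_mean", "centroid")) {
    mcda_stop("config_invalid", "defuzz must be graded_mean or centroid")
  }
  if (is.null(responses) && is.null(weights)) {
    mcda_stop("config_invalid", "either responses or weights must be supplied")
  }
  for (p in list(hierarchy, responses, table)) {
    if (is.character(p) && length(p) == 1L && !file.exists(p)) {
      mcda_stop("io", "input path does not exist: %s", p)
    }
  }
  structure(
    list(hierarchy = hierarchy, responses = responses, table = table,
         weights = weights, methods = methods, vikor_v = vikor_v,
         defuzz = defuzz, scale = scale,
         vikor_fuzzy_arith = isTRUE(vikor_fuzzy_arith),
         strict_cr = isTRUE(strict_cr), aggregation = aggregation,
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full decision pipeline
#'
#' Executes load, AHP weighting (unless weights are supplied), fuzzification,
#' normalization and the requested ranking methods, collecting warnings into
#' a self-contained decision report. Any stage error is surfaced with the
#' stage name; no partial outputs are written.
#'
#' @param cfg A [run_config()] (or arguments forwarded to it).
#' @param ... Forwarded to [run_config()] when \code{cfg} is not one already.
#' @return An object of class \code{"decision_report"}.
#' @export
run_pipeline <- function(cfg, ...) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg, ...)
  warnings_log <- character(0)
  note <- function(stage, msg) {
    warnings_log <<- c(warnings_log, sprintf("[%s] %s", stage, msg))
  }
  stage <- function(name, expr) {
    withCallingHandlers(
      tryCatch(expr, mcda4hta_error = function(e) {
        mcda_stop("pipeline", "stage '%s' failed: %s", name, conditionMessage(e))
      }),
      mcda4hta_warning = function(w) {
        note(name, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        note(name, trimws(conditionMessage(m)))
        invokeRestart("muffleMessage")
      }
    )
  }

  h <- stage("load_hierarchy", {
    if (inherits(cfg$hierarchy, "criteria_hierarchy")) cfg$hierarchy
    else load_hierarchy(cfg$hierarchy)
  })
  cr_table <- NULL
  weights <- if (!is.null(cfg$weights)) {
    stage("weights", {
      if (is.list(cfg$weights) && !is.null(cfg$weights$global)) {
        cr_table <- cfg$weights$cr_table
        cfg$weights$global
      } else cfg$weights
    })
  } else {
    stage("weights", {
      judg <- if (is.character(cfg$responses)) {
        read_judgments(cfg$responses, plan_elicitation(h))
      } else cfg$responses
      cw <- compute_weights(h, judg, aggregation = cfg$aggregation,
                            strict_cr = cfg$strict_cr)
      cr_table <- cw$cr_table
      cw$global
    })
  }
  pt <- stage("load_table", {
    if (inherits(cfg$table, "performance_table")) cfg$table
    else load_table(cfg$table, h)
  })
  fdm <- stage("fuzzify", fuzzify_table(pt, weights, scale = cfg$scale))
  norm <- stage("normalize", normalize_matrix(fdm))

  results <- list()
  for (mth in cfg$methods) {
    results[[switch(mth, topsis = "fuzzy_topsis", vikor = "fuzzy_vikor",
                    gp = "goal_programming")]] <- switch(mth,
      topsis = stage("rank_topsis", rank_fuzzy_topsis(norm)),
      vikor = stage("rank_vikor",
                    rank_fuzzy_vikor(norm, v = cfg$vikor_v, defuzz = cfg$defuzz,
                                     fuzzy_arith = cfg$vikor_fuzzy_arith)),
      gp = stage("rank_gp", rank_goal_programming(norm, defuzz = cfg$defuzz))
    )
  }

  report <- structure(
    list(results = results,
         cr_table = cr_table,
         dropped_columns = fdm$dropped,
         warnings = warnings_log,
         config = cfg,
         version = as.character(utils::packageVersion("mcda4hta")),
         alternatives = pt$alternatives),
    class = "decision_report"
  )
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.decision_report <- function(x, ...) {
  cat(sprintf("<decision_report: %d method(s), %d alternative(s)>\n",
              length(x$results), length(x$alternatives)))
  for (res in x$results) {
    best <- names(res$index)[res$rank == 1L]
    cat(sprintf("  %-16s best: %-4s indices: %s\n", res$method, best,
                paste(sprintf("%s=%.3f", names(res$index), res$index), collapse = ", ")))
  }
  if (length(x$warnings)) cat(sprintf("  %d warning(s) recorded\n", length(x$warnings)))
  invisible(x)
}

#' Write a decision report to a directory
#'
#' One CSV per method (\code{alternative, index, rank} plus intermediates),
#' the CR table, and a markdown summary naming the winner per method, with
#' indices printed to 3 decimals (full precision is kept in the CSVs).
#' Result CSVs carry no timestamp, so identical inputs and config give
#' byte-identical files.
#'
#' @param report A \code{decision_report}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    mcda_stop("io", "cannot create output directory %s", dir)
  }
  for (res in report$results) {
    df <- data.frame(alternative = names(res$index),
                     index = format(res$index, digits = 15),
                     rank = res$rank, stringsAsFactors = FALSE)
    extra <- res$intermediates[, setdiff(names(res$intermediates),
                                         c("alternative", "index")), drop = FALSE]
    if (ncol(extra)) {
      extra[] <- lapply(extra, function(v) if (is.numeric(v)) format(v, digits = 15) else v)
      df <- cbind(df, extra)
    }
    utils::write.csv(df, file.path(dir, paste0(res$method, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  if (!is.null(report$cr_table)) {
    utils::write.csv(report$cr_table, file.path(dir, "consistency.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  cfg <- report$config
  lines <- c(
    "# Decision report",
    "",
    sprintf("mcda4hta version %s", report$version),
    "",
    "## Rankings (lower index = better)",
    ""
  )
  for (res in report$results) {
    best <- names(res$index)[res$rank == 1L]
    lines <- c(lines, sprintf("- %s: best = %s (%s)", res$method, best,
                              paste(sprintf("%s %.3f", names(res$index), res$index),
                                    collapse = ", ")))
  }
  lines <- c(lines, "", "## Configuration", "",
             sprintf("- methods: %s", paste(cfg$methods, collapse = ", ")),
             sprintf("- vikor_v: %g", cfg$vikor_v),
             sprintf("- defuzzification: %s", cfg$defuzz),
             sprintf("- linguistic scale: %s",
                     if (inherits(cfg$scale, "linguistic_scale")) cfg$scale$name else cfg$scale),
             sprintf("- vikor route: %s",
                     if (cfg$vikor_fuzzy_arith) "fuzzy arithmetic" else "defuzzify-then-crisp"),
             sprintf("- AHP aggregation: %s", cfg$aggregation),
             sprintf("- strict CR: %s", cfg$strict_cr))
  if (!is.null(report$cr_table)) {
    nbad <- sum(!report$cr_table$acceptable)
    lines <- c(lines, "", "## Consistency",
               sprintf("- %d of %d matrices exceed CR 0.1 (see consistency.csv)",
                       nbad, nrow(report$cr_table)))
  }
  if (length(report$dropped_columns)) {
    lines <- c(lines, "", "## Dropped evidence columns",
               paste("-", report$dropped_columns))
  }
  if (length(report$warnings)) {
    lines <- c(lines, "", "## Warnings", paste("-", report$warnings))
  }
  writeLines(lines, file.path(dir, "summary.md"))
  invisible(dir)
}
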