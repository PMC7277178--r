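# The criteria hierarchy: a goal, nine main criteria (the HTA Core Model
# domains in the packaged tree), and up to three levels of sub-criteria.
# Internally a node table in document order plus a children index; document
# order is the single ordering used everywhere (matrix indexing, leaves,
# reports) so runs are reproducible.

ROOT_ID <- ".goal"

#' Construct a criteria hierarchy from a node table
#'
#' Low-level constructor; most users call [load_hierarchy()]. Nodes must be in
#' document order with fields \code{id}, \code{label}, \code{level},
#' \code{parent_id}, and, for leaves only, \code{direction}
#' (\code{benefit}/\code{cost}) and \code{data_kind}
#' (\code{numeric}/\code{binary}/\code{linguistic}).
#'
#' @param nodes A data.frame with the fields above (non-leaf direction and
#'   data_kind are \code{NA}).
#' @param goal Human-readable goal label.
#' @return A validated object of class \code{"criteria_hierarchy"}.
#' @export
criteria_hierarchy <- function(nodes, goal = "Goal") {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  need <- c("id", "label", "level", "parent_id", "direction", "data_kind")
  for (f in setdiff(need, names(nodes))) nodes[[f]] <- NA_character_
  nodes <- nodes[, need]
  nodes$id <- as.character(nodes$id)
  nodes$parent_id <- as.character(nodes$parent_id)
  nodes$level <- as.integer(nodes$level)

  h <- structure(list(goal = goal, nodes = nodes), class = "criteria_hierarchy")
  validate_hierarchy(h)
}

validate_hierarchy <- function(h) {
  nodes <- h$nodes
  dup <- nodes$id[duplicated(nodes$id)]
  if (length(dup)) {
    mcda_stop("duplicate_id", "duplicate criterion id(s): %s", paste(unique(dup), collapse = ", "))
  }
  if (ROOT_ID %in% nodes$id) {
    mcda_stop("duplicate_id", "'%s' is reserved for the goal", ROOT_ID)
  }
  known <- c(ROOT_ID, nodes$id)
  orphan <- nodes$id[!(nodes$parent_id %in% known)]
  if (length(orphan)) {
    mcda_stop("orphan_node", "node(s) citing a missing parent: %s",
              paste(orphan, collapse = ", "))
  }
  # level consistency: parent's level + 1, root children at level 1
  plevel <- ifelse(nodes$parent_id == ROOT_ID, 0L,
                   nodes$level[match(nodes$parent_id, nodes$id)])
  bad <- nodes$id[is.na(plevel) | nodes$level != plevel + 1L]
  if (length(bad)) {
    mcda_stop("level_mismatch", "node(s) whose level is not parent level + 1: %s",
              paste(bad, collapse = ", "))
  }
  if (any(nodes$level > 4L)) {
    mcda_stop("depth_exceeded", "maximum depth below the goal is 4; offending node(s): %s",
              paste(nodes$id[nodes$level > 4L], collapse = ", "))
  }
  # reachability from root (levels are consistent, but check for cycles anyway)
  reach <- nodes$parent_id == ROOT_ID
  repeat {
    grow <- !reach & nodes$parent_id %in% nodes$id[reach]
    if (!any(grow)) break
    reach <- reach | grow
  }
  if (!all(reach)) {
    mcda_stop("orphan_node", "node(s) unreachable from the goal: %s",
              paste(nodes$id[!reach], collapse = ", "))
  }
  is_leaf <- !(nodes$id %in% nodes$parent_id)
  miss <- nodes$id[is_leaf & (is.na(nodes$direction) | is.na(nodes$data_kind))]
  if (length(miss)) {
    mcda_stop("leaf_missing_fields",
              "leaf node(s) missing direction or data_kind: %s", paste(miss, collapse = ", "))
  }
  extra <- nodes$id[!is_leaf & (!is.na(nodes$direction) | !is.na(nodes$data_kind))]
  if (length(extra)) {
    mcda_stop("internal_with_leaf_fields",
              "non-leaf node(s) carrying direction/data_kind: %s", paste(extra, collapse = ", "))
  }
  okd <- is.na(nodes$direction) | nodes$direction %in% c("benefit", "cost")
  if (!all(okd)) {
    mcda_stop("leaf_missing_fields", "invalid direction on: %s",
              paste(nodes$id[!okd], collapse = ", "))
  }
  okk <- is.na(nodes$data_kind) | nodes$data_kind %in% c("numeric", "binary", "linguistic")
  if (!all(okk)) {
    mcda_stop("leaf_missing_fields", "invalid data_kind on: %s",
              paste(nodes$id[!okk], collapse = ", "))
  }
  h$nodes$is_leaf <- is_leaf
  h
}

#' Load a criteria hierarchy from a JSON or YAML document
#'
#' The document nests criteria under the goal; \code{level} is derived from
#' nesting (an explicit \code{level} field, if present, must agree). Leaves
#' carry \code{direction} and \code{data_kind}.
#'
#' \preformatted{
#' goal: Select the best dialysis modality
#' criteria:
#'   - id: SAF
#'     label: Safety
#'     children:
#'       - {id: SAF1, label: Patient harm, direction: cost, data_kind: numeric}
#' }
#'
#' @param source Path to a \code{.json}/\code{.yaml}/\code{.yml} file, or an
#'   already-parsed nested list of the same shape.
#' @return A \code{criteria_hierarchy}.
#' @export
load_hierarchy <- function(source) {
  doc <- if (is.character(source) && length(source) == 1L) {
    if (!file.exists(source)) mcda_stop("io", "hierarchy file not found: %s", source)
    if (grepl("\\.ya?ml$", source, ignore.case = TRUE)) {
      yaml::read_yaml(source)
    } else {
      jsonlite::fromJSON(source, simplifyVector = FALSE)
    }
  } else if (is.list(source)) {
    source
  } else {
    mcda_stop("io", "hierarchy source must be a file path or a nested list")
  }
  if (is.null(doc$criteria)) {
    mcda_stop("schema", "hierarchy document must have a 'criteria' list under the goal")
  }
  rows <- list()
  walk <- function(node, parent_id, level) {
    if (is.null(node$id)) mcda_stop("schema", "criterion without an 'id' under parent '%s'", parent_id)
    if (!is.null(node$level) && as.integer(node$level) != level) {
      mcda_stop("level_mismatch", "node '%s' declares level %s but is nested at depth %d",
                node$id, node$level, level)
    }
    kids <- node$children
    rows[[length(rows) + 1L]] <<- data.frame(
      id = as.character(node$id),
      label = as.character(node$label %||% node$id),
      level = level,
      parent_id = parent_id,
      direction = as.character(node$direction %||% NA_character_),
      data_kind = as.character(node$data_kind %||% NA_character_),
      stringsAsFactors = FALSE
    )
    for (k in kids) walk(k, as.character(node$id), level + 1L)
  }
  for (top in doc$criteria) walk(top, ROOT_ID, 1L)
  criteria_hierarchy(do.call(rbind, rows), goal = doc$goal %||% "Goal")
}

#' Write a hierarchy back to JSON or YAML
#'
#' Round-trips with [load_hierarchy()]: re-reading yields identical node
#' tables and level counts.
#'
#' @param h A \code{criteria_hierarchy}.
#' @param path Output path; format chosen from the extension.
#' @return \code{path}, invisibly.
#' @export
write_hierarchy <- function(h, path) {
  build <- function(pid) {
    kids <- h$nodes[h$nodes$parent_id == pid, , drop = FALSE]
    lapply(seq_len(nrow(kids)), function(i) {
      n <- kids[i, ]
      out <- list(id = n$id, label = n$label)
      if (!is.na(n$direction)) out$direction <- n$direction
      if (!is.na(n$data_kind)) out$data_kind <- n$data_kind
      ch <- build(n$id)
      if (length(ch)) out$children <- ch
      out
    })
  }
  doc <- list(goal = h$goal, criteria = build(ROOT_ID))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(doc, path)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Node counts per hierarchy level
#'
#' @param h A \code{criteria_hierarchy}.
#' @return Named integer vector: count of nodes at each depth (goal excluded).
#' @examples
#' # the packaged synthetic core-model tree has counts 9/45/115/113
#' @export
level_counts <- function(h) {
  tab <- table(factor(h$nodes$level, levels = sort(unique(h$nodes$level))))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Leaf criteria in document order
#'
#' Depth-first document order, stable across runs; performance-table columns
#' bind to these ids.
#'
#' @param h A \code{criteria_hierarchy}.
#' @return Data.frame of leaf nodes (id, label, level, direction, data_kind).
#' @export
leaves <- function(h) {
  h$nodes[h$nodes$is_leaf, c("id", "label", "level", "direction", "data_kind"), drop = FALSE]
}

#' Plan the weight-elicitation campaign
#'
#' One pairwise-comparison matrix per parent with at least two children
#' (single children inherit local weight 1 and need no matrix). Matrices are
#' grouped into questionnaires: one instrument for the main criteria plus one
#' per main criterion covering its subtree — always \code{1 + n_main}
#' instruments, even when a domain contributes no internal matrices.
#'
#' @param h A \code{criteria_hierarchy}.
#' @return An \code{"elicitation_plan"}: list with \code{matrices} (data.frame
#'   matrix_id, parent_id, questionnaire_id and list-column child_ids) and
#'   \code{questionnaires} (data.frame questionnaire_id, scope, n_matrices).
#' @export
plan_elicitation <- function(h) {
  nodes <- h$nodes
  mains <- nodes$id[nodes$level == 1L]
  # domain of a node = its level-1 ancestor
  domain <- nodes$id
  names(domain) <- nodes$id
  for (i in seq_len(nrow(nodes))) {
    n <- nodes[i, ]
    domain[n$id] <- if (n$level == 1L) n$id else domain[[n$parent_id]]
  }
  parents <- c(ROOT_ID, nodes$id[!nodes$is_leaf])
  rows <- lapply(parents, function(pid) {
    kids <- nodes$id[nodes$parent_id == pid]
    if (length(kids) < 2L) return(NULL)
    qid <- if (pid == ROOT_ID) "Q0" else paste0("Q", match(domain[[pid]], mains))
    data.frame(
      matrix_id = paste0("M_", if (pid == ROOT_ID) "goal" else pid),
      parent_id = pid,
      questionnaire_id = qid,
      stringsAsFactors = FALSE
    )
  })
  mat <- do.call(rbind, rows)
  if (is.null(mat)) {
    mat <- data.frame(matrix_id = character(), parent_id = character(),
                      questionnaire_id = character(), stringsAsFactors = FALSE)
  }
  mat$child_ids <- lapply(mat$parent_id, function(pid) nodes$id[nodes$parent_id == pid])
  qids <- c("Q0", paste0("Q", seq_along(mains)))
  quest <- data.frame(
    questionnaire_id = qids,
    scope = c("main criteria", nodes$label[match(mains, nodes$id)]),
    n_matrices = as.integer(table(factor(mat$questionnaire_id, levels = qids))),
    stringsAsFactors = FALSE
  )
  structure(list(matrices = mat, questionnaires = quest), class = "elicitation_plan")
}

#' @export
print.elicitation_plan <- function(x, ...) {
  cat(sprintf("<elicitation_plan: %d pairwise matrices in %d questionnaires>\n",
              nrow(x$matrices), nrow(x$questionnaires)))
  print(x$questionnaires, row.names = FALSE)
  invisible(x)
}

#' Write an elicitation plan as CSV
#'
#' Columns: matrix_id, parent_id, child_ids (semicolon-joined),
#' questionnaire_id.
#'
#' @param plan An \code{elicitation_plan}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_plan <- function(plan, path) {
  df <- plan$matrices
  df$child_ids <- vapply(df$child_ids, paste, "", collapse = ";")
  df <- df[, c("matrix_id", "parent_id", "child_ids", "questionnaire_id")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.criteria_hierarchy <- function(x, ...) {
  lc <- level_counts(x)
  cat(sprintf("<criteria_hierarchy: '%s'>\n", x$goal))
  cat(sprintf("  %d nodes (%s), %d leaves\n", nrow(x$nodes),
              paste(sprintf("L%s: %d", names(lc), lc), collapse = ", "),
              sum(x$nodes$is_leaf)))
  invisible(x)
}
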