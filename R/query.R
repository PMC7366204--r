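#' Build a cohort query node / tree
#'
#' A cohort query is a tree of filters over the fact store: sibling nodes
#' are OR-ed, children are AND-ed with their parent. Each node filters
#' patients by a concept (ontology path, code set, or `DERIVED:` code), an
#' operator with optional numeric threshold, and an optional closed time
#' window. Complex eligibility criteria (temporal logic, exclusions) are
#' expected to be decomposed into such constituent criteria first; there is
#' no negation operator.
#'
#' @param node_id unique id within the query.
#' @param concept concept reference: an ontology path, a namespaced code, or
#'   a character vector of codes.
#' @param operator one of `>`, `<`, `>=`, `<=`, `=`, `exists`.
#' @param threshold numeric, required unless `operator = "exists"`.
#' @param window optional closed `[start, end]` timestamp pair.
#' @param children list of child `query_node`s (AND-ed).
#' @param label display label (defaults to `node_id`).
#' @return an object of class `query_node`.
#' @export
query_node <- function(node_id, concept, operator = "exists",
                       threshold = NULL, window = NULL, children = list(),
                       label = node_id) {
  op <- normalize_op(operator)
  if (op == "exists" && !is.null(threshold)) {
    stop("exists-operator nodes carry no threshold", call. = FALSE)
  }
  if (op != "exists" && (is.null(threshold) || !is.numeric(threshold))) {
    stop("node '", node_id, "': operator ", op,
         " needs a numeric threshold", call. = FALSE)
  }
  if (!is.null(window)) {
    window <- canon_ts(window)
    if (length(window) != 2L || window[1] > window[2]) {
      stop("window must be an ordered [start, end] pair", call. = FALSE)
    }
  }
  structure(list(node_id = node_id, label = label, concept = concept,
                 operator = op, threshold = threshold, window = window,
                 children = children),
            class = "query_node")
}

#' @rdname query_node
#' @param roots ordered list of top-level `query_node`s (OR-ed siblings).
#' @return `cohort_query`: an object of class `cohort_query`.
#' @export
cohort_query <- function(roots) {
  if (inherits(roots, "query_node")) roots <- list(roots)
  if (!length(roots)) stop("a query needs at least one root", call. = FALSE)
  q <- structure(list(roots = roots), class = "cohort_query")
  ids <- vapply(flatten_nodes(q), `[[`, "", "node_id")
  if (anyDuplicated(ids)) {
    stop("node_ids must be unique: ", ids[duplicated(ids)][1],
         call. = FALSE)
  }
  q
}

flatten_nodes <- function(query) {
  walk <- function(node) c(list(node), unlist(lapply(node$children, walk),
                                              recursive = FALSE))
  unlist(lapply(query$roots, walk), recursive = FALSE)
}

#' Evaluate a cohort query tree
#'
#' For every node, `matched` is the set of patients having at least one
#' fact in the node's expanded concept set that satisfies its
#' operator/threshold within its window. `cumulative` intersects `matched`
#' with the parent's cumulative set (roots: `cumulative = matched`), so
#' counts attrition down every path. The final cohort is the union of the
#' cumulative sets of the leaves — the union-of-path-conjunctions reading of
#' "sibling = OR, children = AND". Counts are distinct patients, never
#' facts or encounters. Evaluation is all-or-nothing: an unresolvable
#' concept fails the whole call naming the node.
#'
#' @param query a [cohort_query()].
#' @param store a [fact_store()].
#' @param hierarchy a [concept_hierarchy()] for concept expansion.
#' @return an object of class `cohort_result`: list with `nodes` (named
#'   list of per-node results: `matched`, `cumulative`, `count`, `label`,
#'   `parent`) and `cohort` (sorted patient ids).
#' @export
evaluate_query <- function(query, store, hierarchy = NULL) {
  stopifnot(inherits(query, "cohort_query"))
  results <- list()
  node_matched <- function(node) {
    codes <- tryCatch(resolve_codes(hierarchy, node$concept),
                      error = function(e) {
                        stop("node '", node$node_id, "': ",
                             conditionMessage(e), call. = FALSE)
                      })
    dt <- query_facts(store, codes, node$operator, node$threshold,
                      node$window)
    unique(dt$patient_id)
  }
  walk <- function(node, parent_cum, parent_id) {
    matched <- node_matched(node)
    cum <- if (is.null(parent_cum)) matched else
      intersect(matched, parent_cum)
    results[[node$node_id]] <<- list(
      node_id = node$node_id, label = node$label,
      matched = sort(matched), cumulative = sort(cum),
      count = length(cum), parent = parent_id,
      is_leaf = !length(node$children))
    for (ch in node$children) walk(ch, cum, node$node_id)
  }
  for (root in query$roots) walk(root, NULL, NA_character_)
  leaves <- Filter(function(r) r$is_leaf, results)
  cohort <- sort(unique(unlist(lapply(leaves, `[[`, "cumulative"))))
  structure(list(nodes = results, cohort = cohort %||% character(),
                 query = query),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort_result>", length(x$nodes), "nodes, cohort size",
      length(x$cohort), "\n")
  for (r in x$nodes) {
    cat(sprintf("  %s%s: %d\n",
                if (is.na(r$parent)) "" else "  ", r$label, r$count))
  }
  invisible(x)
}

find_node <- function(query, node_id) {
  for (node in flatten_nodes(query)) {
    if (node$node_id == node_id) return(node)
  }
  stop("unknown node: ", node_id, call. = FALSE)
}

#' Drill down into one evaluated node
#'
#' Lists, per patient in the node's cumulative set, the facts that satisfied
#' the node's own filter — the evidence behind the count. Ordered by
#' `patient_id`.
#'
#' @param result a [evaluate_query()] result.
#' @param node_id an evaluated node id.
#' @param store the [fact_store()] the query ran against.
#' @param hierarchy the [concept_hierarchy()] used for evaluation.
#' @return a data.table of supporting facts for the node's patients.
#' @export
drill_down <- function(result, node_id, store, hierarchy = NULL) {
  stopifnot(inherits(result, "cohort_result"))
  r <- result$nodes[[node_id]]
  if (is.null(r)) stop("unknown node: ", node_id, call. = FALSE)
  node <- find_node(result$query, node_id)
  codes <- resolve_codes(hierarchy, node$concept)
  dt <- query_facts(store, codes, node$operator, node$threshold,
                    node$window, patient_ids = r$cumulative)
  setorder(dt, patient_id, start_datetime, row_id)
  dt
}

#' Export an attrition flow diagram
#'
#' One diagram node per query node carrying its label and cumulative
#' patient count, one edge per parent-child link; counts along any
#' root-to-leaf path are non-increasing (attrition). Output is text-stable
#' (nodes sorted by id) for snapshot testing.
#'
#' @param result a [evaluate_query()] result.
#' @param format `"json"` (schema `{nodes:[{id,label,count}],
#'   edges:[{from,to}], cohort_size}`), `"dot"` (Graphviz) or `"mermaid"`.
#' @return a single string containing the diagram document.
#' @export
export_flow <- function(result, format = c("json", "dot", "mermaid")) {
  stopifnot(inherits(result, "cohort_result"))
  format <- match.arg(format)
  rs <- result$nodes[order(names(result$nodes))]
  nodes <- lapply(rs, function(r)
    list(id = r$node_id, label = r$label, count = r$count))
  edges <- lapply(Filter(function(r) !is.na(r$parent), rs), function(r)
    list(from = r$parent, to = r$node_id))
  names(nodes) <- NULL
  names(edges) <- NULL
  if (format == "json") {
    return(as.character(jsonlite::toJSON(
      list(nodes = nodes, edges = edges,
           cohort_size = length(result$cohort)),
      auto_unbox = TRUE)))
  }
  esc <- function(s) gsub("\"", "\\\"", s, fixed = TRUE)
  if (format == "dot") {
    lines <- c("digraph attrition {",
      vapply(nodes, function(n) sprintf("  \"%s\" [label=\"%s\\n%d\"];",
                                        n$id, esc(n$label), n$count), ""),
      vapply(edges, function(e) sprintf("  \"%s\" -> \"%s\";",
                                        e$from, e$to), ""),
      sprintf("  // cohort_size=%d", length(result$cohort)), "}")
    return(paste(lines, collapse = "\n"))
  }
  lines <- c("flowchart TD",
    vapply(nodes, function(n) sprintf("  %s[\"%s: %d\"]", n$id,
                                      esc(n$label), n$count), ""),
    vapply(edges, function(e) sprintf("  %s --> %s", e$from, e$to), ""),
    sprintf("  %%%% cohort_size=%d", length(result$cohort)))
  paste(lines, collapse = "\n")
}

# --- YAML definitions -------------------------------------------------------

#' Read Logic / query definitions from YAML
#'
#' The YAML schemas mirror [logic()], [derived_concept_def()] and
#' [query_node()] field-for-field. A query file holds `roots:`, a list of
#' nodes each with `node_id`, `concept` (scalar or list), optional
#' `operator`, `threshold`, `window`, `label` and nested `children`.
#'
#' @param file path to a YAML file.
#' @return `read_logic_yaml`: a [logic()]; `read_query_yaml`: a
#'   [cohort_query()].
#' @export
read_logic_yaml <- function(file) {
  y <- yaml::read_yaml(file)
  spec <- y$spec %||% list()
  if (!is.null(spec$def)) {
    spec$def <- do.call(derived_concept_def, spec$def)
  }
  logic(y$name, y$logic_type, y$logic_path, y$modality, spec)
}

#' @rdname read_logic_yaml
#' @export
read_query_yaml <- function(file) {
  y <- yaml::read_yaml(file)
  build <- function(n) {
    query_node(n$node_id, concept = unlist(n$concept),
               operator = n$operator %||% "exists",
               threshold = n$threshold,
               window = if (!is.null(n$window)) unlist(n$window),
               children = lapply(n$children %||% list(), build),
               label = n$label %||% n$node_id)
  }
  cohort_query(lapply(y$roots, build))
}
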