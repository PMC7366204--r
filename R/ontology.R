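#' Create an empty concept hierarchy
#'
#' The concept catalogue is a forest of nodes addressed by `/`-separated
#' paths (e.g. `Labs/Serum or Plasma/Serum Glucose`). Leaf nodes carry a
#' namespaced code; folder nodes carry none. Because a node's parent is
#' always its path prefix, the forest is acyclic by construction. Paths are
#' case-sensitive and matched exactly after whitespace trimming.
#'
#' @return an environment of class `concept_hierarchy`.
#' @seealso [hierarchy_from_tsv()], [add_local_mapping()], [expand_concept()]
#' @export
concept_hierarchy <- function() {
  h <- new.env(parent = emptyenv())
  h$nodes <- data.table(path = character(), code = character(),
                        name = character(), parent_path = character(),
                        is_local = logical())
  class(h) <- "concept_hierarchy"
  h
}

#' @export
print.concept_hierarchy <- function(x, ...) {
  coded <- sum(x$nodes$code != "")
  cat("<concept_hierarchy>", nrow(x$nodes), "nodes (", coded, "coded )\n")
  invisible(x)
}

clone_hierarchy <- function(h) {
  h2 <- concept_hierarchy()
  h2$nodes <- copy(h$nodes)
  h2
}

parent_of <- function(path) {
  parts <- strsplit(path, "/", fixed = TRUE)[[1]]
  if (length(parts) <= 1L) "" else paste(parts[-length(parts)],
                                         collapse = "/")
}

#' Add one concept node (auto-creating folder ancestors)
#'
#' @param h a [concept_hierarchy()].
#' @param path slash-separated concept path.
#' @param code namespaced code, or `""` for a folder node.
#' @param name display name (defaults to the last path segment).
#' @param is_local whether the node came from a local-code mapping.
#' @return the hierarchy, invisibly. Re-adding an identical node is a no-op;
#'   the same path with a different code is an error.
#' @export
add_concept <- function(h, path, code = "", name = NULL, is_local = FALSE) {
  stopifnot(inherits(h, "concept_hierarchy"))
  path <- paste(trimws(strsplit(trimws(path), "/", fixed = TRUE)[[1]]),
                collapse = "/")
  if (path == "") stop("empty concept path", call. = FALSE)
  code <- trimws(code %||% "")
  name <- name %||% basename(path)
  hit <- which(h$nodes$path == path)
  existing <- h$nodes[hit]
  if (nrow(existing)) {
    if (existing$code != code && code != "" && existing$code != "") {
      stop("path '", path, "' already has code ", existing$code,
           " (conflicts with ", code, ")", call. = FALSE)
    }
    if (existing$code == "" && code != "") {
      set(h$nodes, hit, "code", code)
      set(h$nodes, hit, "name", name)
    }
    return(invisible(h))
  }
  pp <- parent_of(path)
  if (pp != "" && !pp %in% h$nodes$path) add_concept(h, pp)
  h$nodes <- rbind(h$nodes,
    data.table(path = path, code = code, name = name, parent_path = pp,
               is_local = is_local))
  invisible(h)
}

#' Build a hierarchy from a tab-separated file
#'
#' The file has header `path<TAB>code<TAB>name`; rows may arrive in any
#' order, and missing intermediate folders are created with empty codes.
#' Loading the same file twice yields an identical hierarchy. Both `/` and
#' `\` path separators are accepted (`\` is the native i2b2 dialect).
#'
#' @param file path to the TSV file.
#' @param h optionally, an existing hierarchy to extend.
#' @return a [concept_hierarchy()].
#' @export
hierarchy_from_tsv <- function(file, h = concept_hierarchy()) {
  lines <- readLines(file, warn = FALSE)
  if (!length(lines)) stop("empty hierarchy file: ", file, call. = FALSE)
  for (i in seq_along(lines)[-1]) {
    if (lines[i] == "") next
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 3L) {
      stop(file, " line ", i, ": expected 3 tab-separated columns, got ",
           length(fields), call. = FALSE)
    }
    path <- gsub("\\", "/", fields[1], fixed = TRUE)
    path <- sub("^/", "", path)
    tryCatch(add_concept(h, path, fields[2], fields[3]),
             error = function(e) stop(file, " line ", i, ": ",
                                      conditionMessage(e), call. = FALSE))
  }
  h
}

#' Write a hierarchy to TSV
#'
#' @param h a [concept_hierarchy()] (or a data.frame with `path`, `code`,
#'   `name` columns).
#' @param file destination path.
#' @param sep path separator dialect: `"/"` (default) or `"\\"` (i2b2).
#' @return the path, invisibly.
#' @export
write_hierarchy_tsv <- function(h, file, sep = "/") {
  nodes <- if (inherits(h, "concept_hierarchy")) h$nodes else as.data.table(h)
  paths <- nodes$path
  if (sep != "/") paths <- gsub("/", sep, paths, fixed = TRUE)
  lines <- c("path\tcode\tname", paste(paths, nodes$code, nodes$name,
                                       sep = "\t"))
  writeLines(lines, file)
  invisible(file)
}

#' Map a local code under a standard code
#'
#' Creates a local-code child under every path bearing `standard_code`, so
#' that expanding the standard concept also matches facts coded with the
#' local code. Repeating an identical mapping is a no-op.
#'
#' @param h a [concept_hierarchy()].
#' @param local_code namespaced local code (e.g. `LOCAL:50931`).
#' @param standard_code a code already present in the hierarchy.
#' @return the hierarchy, invisibly.
#' @export
add_local_mapping <- function(h, local_code, standard_code) {
  stopifnot(inherits(h, "concept_hierarchy"))
  if (!grepl("^[^:]+:.+$", local_code)) {
    stop("local code must be namespaced (SYSTEM:code): ", local_code,
         call. = FALSE)
  }
  parents <- h$nodes$path[h$nodes$code == standard_code]
  if (!length(parents)) {
    stop("unknown standard code: ", standard_code, call. = FALSE)
  }
  seg <- sub("^[^:]+:", "", local_code)
  for (pp in parents) {
    add_concept(h, paste(pp, seg, sep = "/"), local_code, local_code,
                is_local = TRUE)
  }
  invisible(h)
}

#' Read and apply a local-to-standard code map TSV
#'
#' File header: `local_code<TAB>standard_code`.
#'
#' @param h a [concept_hierarchy()].
#' @param file path to the mapping TSV.
#' @return a data.table of the mappings applied, invisibly.
#' @export
apply_code_map_tsv <- function(h, file) {
  map <- fread(file, sep = "\t", colClasses = "character")
  if (!all(c("local_code", "standard_code") %in% names(map))) {
    stop("mapping file needs columns local_code, standard_code",
         call. = FALSE)
  }
  for (i in seq_len(nrow(map))) {
    add_local_mapping(h, map$local_code[i], map$standard_code[i])
  }
  invisible(map)
}

resolve_nodes <- function(h, ref) {
  hit <- h$nodes[h$nodes$path == ref]
  if (!nrow(hit)) hit <- h$nodes[h$nodes$code == ref & h$nodes$code != ""]
  hit
}

#' Expand a concept path or code to its matchable code set
#'
#' Returns the codes of the referenced node(s) and all descendants; folder
#' nodes contribute no code. A code borne by several paths expands through
#' every occurrence. The result is sorted, so expansion is deterministic.
#'
#' @param h a [concept_hierarchy()].
#' @param ref a concept path or a namespaced code.
#' @return sorted character vector of codes.
#' @export
expand_concept <- function(h, ref) {
  stopifnot(inherits(h, "concept_hierarchy"))
  roots <- resolve_nodes(h, ref)
  if (!nrow(roots)) stop("concept not found: ", ref, call. = FALSE)
  seen <- character()
  frontier <- roots$path
  while (length(frontier)) {
    seen <- c(seen, frontier)
    frontier <- h$nodes$path[h$nodes$parent_path %in% frontier]
  }
  codes <- h$nodes$code[h$nodes$path %in% seen]
  sort(unique(codes[codes != ""]))
}

# Resolve a concept reference that may be a hierarchy path, a hierarchy
# code, or an explicit namespaced code (set) absent from the hierarchy.
resolve_codes <- function(h, ref) {
  if (length(ref) > 1L) return(sort(unique(ref)))
  if (!is.null(h) && nrow(resolve_nodes(h, ref))) return(expand_concept(h, ref))
  if (grepl("^[^:]+:.+$", ref)) return(ref)
  stop("concept not found: ", ref, call. = FALSE)
}
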