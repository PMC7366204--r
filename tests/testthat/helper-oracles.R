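# Independent brute-force oracles. These deliberately avoid the package's
# query path: plain vector scans over a data.frame copy of the fact table.

# Linear-scan filter: codes, numeric predicate, closed window.
oracle_scan <- function(facts, codes, op = "exists", threshold = NULL,
                        window = NULL) {
  df <- as.data.frame(facts)
  keep <- df$concept_code %in% codes
  if (!is.null(window)) {
    keep <- keep & df$start_datetime >= window[1] &
      df$start_datetime <= window[2]
  }
  if (op != "exists") {
    cmp <- switch(op, ">" = `>`, "<" = `<`, ">=" = `>=`, "<=" = `<=`,
                  "=" = `==`)
    keep <- keep & df$value_kind == "numeric" &
      !is.na(df$numeric_value) & cmp(df$numeric_value, threshold)
  }
  df[keep, , drop = FALSE]
}

oracle_matched_patients <- function(facts, codes, op = "exists",
                                    threshold = NULL, window = NULL) {
  sort(unique(oracle_scan(facts, codes, op, threshold, window)$patient_id))
}

# Brute-force DNF evaluation of a query tree: for every leaf, intersect the
# matched sets of all nodes on its root path; the cohort is the union over
# leaves.
oracle_dnf <- function(query, facts, resolve) {
  leaves_paths <- list()
  walk <- function(node, path) {
    path <- c(path, list(node))
    if (!length(node$children)) {
      leaves_paths[[length(leaves_paths) + 1L]] <<- path
    } else for (ch in node$children) walk(ch, path)
  }
  for (root in query$roots) walk(root, list())
  sets <- lapply(leaves_paths, function(path) {
    Reduce(intersect, lapply(path, function(nd) {
      oracle_matched_patients(facts, resolve(nd$concept), nd$operator,
                              nd$threshold, nd$window)
    }))
  })
  sort(unique(unlist(sets)))
}

# Per-patient brute force for the derived operators: sort by (date,
# insertion), slice, compare.
# insertion order: row_id when the facts came from a store, file order
# otherwise (the generator emits facts in insertion order)
insertion_order <- function(df) {
  if (!is.null(df$row_id)) df$row_id else seq_len(nrow(df))
}

oracle_last_value <- function(facts, codes) {
  df <- as.data.frame(facts)
  df$ins <- insertion_order(df)
  df <- df[df$concept_code %in% codes & df$value_kind == "numeric", ]
  df <- df[order(df$patient_id, df$start_datetime, df$ins), ]
  out <- lapply(split(df, df$patient_id), function(g) g[nrow(g), ])
  do.call(rbind, out)
}

oracle_last_n_flag <- function(facts, codes, n, op, threshold) {
  df <- as.data.frame(facts)
  df$ins <- insertion_order(df)
  df <- df[df$concept_code %in% codes & df$value_kind == "numeric", ]
  df <- df[order(df$patient_id, df$start_datetime, df$ins), ]
  cmp <- switch(op, ">" = `>`, "<" = `<`, ">=" = `>=`, "<=" = `<=`)
  hits <- vapply(split(df, df$patient_id), function(g) {
    nrow(g) >= n && all(cmp(tail(g$numeric_value, n), threshold))
  }, NA)
  sort(names(hits)[hits])
}

# Exhaustive DFS code collection over a hierarchy's node table.
oracle_expand <- function(h, start_paths) {
  nodes <- as.data.frame(h$nodes)
  collect <- function(p) {
    kids <- nodes$path[nodes$parent_path == p]
    c(nodes$code[nodes$path == p], unlist(lapply(kids, collect)))
  }
  codes <- unlist(lapply(start_paths, collect))
  sort(unique(codes[codes != ""]))
}
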