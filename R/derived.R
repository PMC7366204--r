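#' Define a derived concept
#'
#' A derived concept materializes a clinically meaningful computation over
#' base (or other derived) facts as new per-patient facts, so complex
#' eligibility criteria decompose into simple filters. Built-in operators:
#' \describe{
#'   \item{last_value}{numeric: each patient's chronologically last numeric
#'     source fact is copied (value, unit and timestamp).}
#'   \item{last_n_consecutive_compare}{boolean: flag iff the patient has at
#'     least `n` numeric source facts and the final `n` of them all satisfy
#'     `value comparator threshold`; timestamped at the last source fact.}
#'   \item{any_code_present}{boolean: flag iff the patient has any fact in
#'     the expanded code set; timestamped at the earliest match.}
#'   \item{compare_derived}{boolean: flag iff the patient's (single) numeric
#'     fact under the source derived code satisfies the comparison.}
#'   \item{script}{a registered plugin called per patient with
#'     `(patient_id, chart)`; must return 0..n facts bearing the def's
#'     output code.}
#' }
#' Date ties within a patient are broken by insertion order, so "last" is
#' deterministic. Output facts carry code `DERIVED:<name>` and are ordinary
#' observation facts: the query engine needs no special casing for them.
#'
#' @param name derived concept name; output code is `DERIVED:<name>`.
#' @param concept_path catalogue path under which the derived concept is
#'   auto-registered (e.g. `Derived/Diagnosis/Diabetes`).
#' @param operator one of `last_value`, `last_n_consecutive_compare`,
#'   `any_code_present`, `compare_derived`, `script`.
#' @param source concept reference (ontology path, code, or `DERIVED:` code)
#'   read by `last_value`, `last_n_consecutive_compare`, `compare_derived`.
#' @param n window length for `last_n_consecutive_compare` (>= 1).
#' @param comparator one of `>`, `<`, `>=`, `<=` where applicable.
#' @param threshold numeric threshold where applicable.
#' @param codes explicit code set for `any_code_present`.
#' @param prefix path or code prefix for `any_code_present` (e.g.
#'   `ICD9:250` matches the whole diabetes family).
#' @param plugin registered plugin name for `script`.
#' @param result_kind `"boolean"` (emits flag facts) or `"numeric"`;
#'   inferred from the operator by default.
#' @return an object of class `derived_def`.
#' @export
derived_concept_def <- function(name, concept_path, operator, source = NULL,
                                n = NULL, comparator = NULL,
                                threshold = NULL, codes = NULL,
                                prefix = NULL, plugin = NULL,
                                result_kind = NULL) {
  ops <- c("last_value", "last_n_consecutive_compare", "any_code_present",
           "compare_derived", "script")
  if (!operator %in% ops) stop("unknown operator: ", operator,
                               call. = FALSE)
  result_kind <- result_kind %||%
    if (operator == "last_value") "numeric" else "boolean"
  if (operator %in% c("last_value", "last_n_consecutive_compare",
                      "compare_derived") && is.null(source)) {
    stop(operator, " needs a source concept ref", call. = FALSE)
  }
  if (operator == "last_n_consecutive_compare") {
    if (is.null(n) || n < 1) stop("n must be >= 1", call. = FALSE)
    n <- as.integer(n)
  }
  if (operator %in% c("last_n_consecutive_compare", "compare_derived")) {
    comparator <- normalize_op(comparator %||%
      stop(operator, " needs a comparator", call. = FALSE))
    if (comparator == "exists") stop("comparator cannot be 'exists'",
                                     call. = FALSE)
    if (!is.numeric(threshold)) stop("threshold must be numeric",
                                     call. = FALSE)
  }
  if (operator == "any_code_present" && is.null(codes) && is.null(prefix)) {
    stop("any_code_present needs codes or a prefix", call. = FALSE)
  }
  if (operator == "script" && is.null(plugin)) {
    stop("script operator needs a plugin ref", call. = FALSE)
  }
  structure(list(name = name, concept_path = concept_path,
                 output_code = paste0("DERIVED:", name),
                 result_kind = result_kind, operator = operator,
                 source = source, n = n, comparator = comparator,
                 threshold = threshold, codes = codes, prefix = prefix,
                 plugin = plugin),
            class = "derived_def")
}

# References from one def to another: a def depends on another when its
# source/codes/prefix names the other's output code, name or concept path.
def_refs <- function(def) {
  unique(c(def$source, def$codes, def$prefix))
}

#' Order derived definitions by dependency
#'
#' Derived concepts may read each other's output; execution must follow a
#' topological order of the "reads output of" graph. Ties are broken by
#' name, so the plan is deterministic. Any cycle refuses the whole plan —
#' nothing executes — with the cycle spelled out.
#'
#' @param defs list of [derived_concept_def()] objects.
#' @return the defs reordered so every def follows its dependencies.
#' @export
plan_execution <- function(defs) {
  nms <- vapply(defs, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate derived def names", call. = FALSE)
  names(defs) <- nms
  keys <- function(d) c(d$name, d$output_code, d$concept_path)
  deps <- lapply(defs, function(d) {
    refs <- def_refs(d)
    nms[vapply(defs, function(o) any(refs %in% keys(o)) && o$name != d$name,
               NA)]
  })
  ordered <- character()
  remaining <- sort(nms)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(nm)
      all(deps[[nm]] %in% ordered), NA)]
    if (!length(ready)) {
      cyc <- find_cycle(deps[remaining])
      stop("circular dependency among derived concepts: ",
           paste(cyc, collapse = " -> "), call. = FALSE)
    }
    ordered <- c(ordered, ready[1])
    remaining <- setdiff(remaining, ready[1])
  }
  defs[ordered]
}

find_cycle <- function(deps) {
  start <- sort(names(deps))[1]
  path <- start
  repeat {
    nxt <- intersect(sort(deps[[tail(path, 1)]]), names(deps))[1]
    if (is.na(nxt)) return(path)
    if (nxt %in% path) {
      return(c(path[seq(match(nxt, path), length(path))], nxt))
    }
    path <- c(path, nxt)
  }
}

# Chart-ordered numeric source facts per patient for a def.
source_facts <- function(def, store, hierarchy) {
  codes <- resolve_codes(hierarchy, def$source)
  dt <- query_facts(store, codes)
  setorder(dt, patient_id, start_datetime, row_id)
  dt
}

derived_fact <- function(def, patient_id, ts, value = NA_real_,
                         unit = NA_character_) {
  observation_facts(
    patient_id = patient_id, concept_code = def$output_code,
    start_datetime = ts,
    value_kind = if (def$result_kind == "numeric") "numeric" else "flag",
    numeric_value = if (def$result_kind == "numeric") value else NA_real_,
    unit = if (def$result_kind == "numeric") unit else NA_character_,
    source_logic = def$name)
}

#' Compute derived facts for one definition (without inserting)
#'
#' Exposed for inspection and testing; [run_derived()] is the usual entry
#' point and handles replace-on-recompute plus ontology registration.
#'
#' @param def a [derived_concept_def()].
#' @param store a [fact_store()].
#' @param hierarchy a [concept_hierarchy()] for concept resolution.
#' @param plugins named list of plugin functions (for `script` defs).
#' @return list with `facts` (data.table, at most one row per patient for
#'   the built-in operators) and `log` (character).
#' @export
compute_derived <- function(def, store, hierarchy = NULL, plugins = list()) {
  switch(def$operator,
    last_value = compute_last_value(def, store, hierarchy),
    last_n_consecutive_compare = compute_last_n(def, store, hierarchy),
    any_code_present = compute_any_code(def, store, hierarchy),
    compare_derived = compute_compare_derived(def, store, hierarchy),
    script = compute_script(def, store, plugins))
}

compute_last_value <- function(def, store, hierarchy) {
  dt <- source_facts(def, store, hierarchy)
  log <- character()
  skipped <- setdiff(unique(dt$patient_id),
                     unique(dt$patient_id[dt$value_kind == "numeric"]))
  if (length(skipped)) {
    log <- sprintf("patient %s: no numeric source facts, skipped", skipped)
  }
  dt <- dt[value_kind == "numeric"]
  last <- dt[, .SD[.N], by = patient_id]
  facts <- if (nrow(last)) {
    derived_fact(def, last$patient_id, last$start_datetime,
                 last$numeric_value, last$unit)
  } else observation_facts(character(), character(), character())[0]
  list(facts = facts, log = log)
}

compute_last_n <- function(def, store, hierarchy) {
  dt <- source_facts(def, store, hierarchy)[value_kind == "numeric"]
  hit <- dt[, {
    vals <- numeric_value
    ok <- .N >= def$n &&
      all(apply_op(tail(vals, def$n), def$comparator, def$threshold))
    if (ok) .(ts = start_datetime[.N]) else .(ts = character())
  }, by = patient_id]
  facts <- if (nrow(hit)) derived_fact(def, hit$patient_id, hit$ts) else
    observation_facts(character(), character(), character())[0]
  list(facts = facts, log = character())
}

compute_any_code <- function(def, store, hierarchy) {
  codes <- character()
  if (!is.null(def$codes)) codes <- def$codes
  if (!is.null(def$prefix)) {
    in_hier <- !is.null(hierarchy) && nrow(resolve_nodes(hierarchy,
                                                         def$prefix))
    codes <- c(codes, if (in_hier) expand_concept(hierarchy, def$prefix)
               else {
                 all_codes <- unique(store$facts$concept_code)
                 all_codes[startsWith(all_codes, def$prefix)]
               })
  }
  codes <- unique(codes)
  if (!length(codes)) {
    stop("any_code_present '", def$name, "': code expansion is empty",
         call. = FALSE)
  }
  dt <- query_facts(store, codes)
  setorder(dt, patient_id, start_datetime, row_id)
  first <- dt[, .SD[1L], by = patient_id]
  facts <- if (nrow(first)) {
    derived_fact(def, first$patient_id, first$start_datetime)
  } else observation_facts(character(), character(), character())[0]
  list(facts = facts, log = character())
}

compute_compare_derived <- function(def, store, hierarchy) {
  dt <- source_facts(def, store, hierarchy)[value_kind == "numeric"]
  last <- dt[, .SD[.N], by = patient_id]
  hit <- last[apply_op(last$numeric_value, def$comparator, def$threshold)]
  facts <- if (nrow(hit)) {
    derived_fact(def, hit$patient_id, hit$start_datetime)
  } else observation_facts(character(), character(), character())[0]
  list(facts = facts, log = character())
}

compute_script <- function(def, store, plugins) {
  fn <- plugins[[def$plugin]]
  if (is.null(fn)) stop("plugin not registered: ", def$plugin,
                        call. = FALSE)
  out <- list()
  for (pid in sort(store$patients$patient_id)) {
    chart <- patient_chart(store, pid)
    facts <- tryCatch(fn(pid, chart), error = function(e) {
      stop("script def '", def$name, "' failed for patient ", pid, ": ",
           conditionMessage(e), call. = FALSE)
    })
    if (is.null(facts) || NROW(facts) == 0L) next
    facts <- as.data.table(facts)
    foreign <- setdiff(unique(facts$concept_code), def$output_code)
    if (length(foreign)) {
      stop("script def '", def$name, "' emitted foreign concept code(s): ",
           paste(foreign, collapse = ", "), call. = FALSE)
    }
    facts[, source_logic := def$name]
    out[[pid]] <- facts
  }
  list(facts = rbindlist(out, fill = TRUE), log = character())
}

#' Compute and materialize a derived concept
#'
#' Recompute replaces: any prior facts produced by the same def (matched on
#' `source_logic` and output code) are deleted before the new ones are
#' inserted, so pipelines are re-entrant and recomputing on an unchanged
#' store is a fixed point. The derived concept is auto-registered in the
#' ontology at its `concept_path`, making it queryable by path like any
#' other concept. Derived facts carry no encounter linkage.
#'
#' @param engine a [cohort_engine()].
#' @param def a [derived_concept_def()].
#' @return list with `rows_read` (source facts scanned), `rows_written`
#'   (derived facts materialized) and `log`.
#' @export
run_derived <- function(engine, def) {
  res <- compute_derived(def, engine$store, engine$hierarchy,
                         engine$plugins)
  st <- engine$store
  st$facts <- st$facts[!(source_logic == def$name &
                           concept_code == def$output_code)]
  n <- insert_facts(st, res$facts)
  add_concept(engine$hierarchy, def$concept_path, def$output_code, def$name)
  list(rows_read = nrow(res$facts), rows_written = n, log = res$log)
}

#' Plan and run a set of derived definitions in dependency order
#'
#' @param engine a [cohort_engine()].
#' @param defs list of [derived_concept_def()] objects.
#' @return named list of [run_derived()] results, in execution order.
#' @export
run_derived_set <- function(engine, defs) {
  ordered <- plan_execution(defs)
  res <- lapply(ordered, function(d) run_derived(engine, d))
  names(res) <- vapply(ordered, `[[`, "", "name")
  res
}
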