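#' Create a cohort engine
#'
#' The engine bundles the fact store, the concept hierarchy, the Logic
#' catalogue, registered plugins, per-Logic watermarks and the run history —
#' a local orchestrator with the same run/trigger/log contract a managed
#' pipeline service would provide, executed synchronously.
#'
#' @param store a [fact_store()] (fresh by default).
#' @param hierarchy a [concept_hierarchy()] (empty by default).
#' @return an environment of class `cohort_engine`.
#' @export
cohort_engine <- function(store = fact_store(),
                          hierarchy = concept_hierarchy()) {
  en <- new.env(parent = emptyenv())
  en$store <- store
  en$hierarchy <- hierarchy
  en$logics <- list()
  en$catalogue_log <- list()
  en$plugins <- list()
  en$watermarks <- list()
  en$runs <- list()
  en$run_seq <- 0L
  class(en) <- "cohort_engine"
  en
}

#' @export
print.cohort_engine <- function(x, ...) {
  cat("<cohort_engine>", length(x$logics), "logics,", length(x$runs),
      "runs |", nrow(x$store$facts), "facts,", nrow(x$hierarchy$nodes),
      "concepts\n")
  invisible(x)
}

.logic_types <- c("import", "concept_hierarchy", "code_map",
                  "derived_concept")
.modalities <- c("sql", "cdi_file", "script")

# Which modalities each Logic type admits. Concept hierarchies and code maps
# are flat-file definitions; derived concepts are either declarative
# (catalogued as "sql", the declarative modality) or script plugins.
.valid_modality <- list(
  import = c("sql", "cdi_file", "script"),
  concept_hierarchy = "cdi_file",
  code_map = "cdi_file",
  derived_concept = c("sql", "script"))

#' Define a Logic
#'
#' A Logic is a named, typed, catalogued pipeline definition: `import`
#' (bring source rows into the fact store), `concept_hierarchy` (load the
#' concept catalogue), `code_map` (graft local codes under standard ones) or
#' `derived_concept` (compute per-patient derived facts).
#'
#' Modality-specific `spec` fields:
#' \describe{
#'   \item{sql import}{`source` (directory of delimited staging tables, or a
#'     named list of data.frames), `table`, optional `where` (a filter
#'     expression over source columns), `columns` (named map of fact fields
#'     to source columns; must cover `patient_id`, `concept_code`,
#'     `start_datetime`), optional `code_namespace` (prefix for bare source
#'     codes), optional `constants` (fixed fact-field values such as
#'     `value_kind`), optional `watermark_field`, `batch_count` (default
#'     1000), optional `concept_map` (`data.frame(local_code,
#'     standard_code)` + `map_direction`), optional `algorithm` (a
#'     registered per-row plugin: raw row -> 0..n facts).}
#'   \item{cdi_file}{`file`: a hierarchy TSV (for `concept_hierarchy`), a
#'     mapping TSV (for `code_map`), or an i2b2-cdi interchange file (for
#'     `import`; see [write_cdi_file()] for the dialect).}
#'   \item{script}{`plugin`: name of a registered plugin.}
#'   \item{derived_concept}{`def`: a [derived_concept_def()].}
#' }
#'
#' @param name unique Logic name.
#' @param logic_type one of `import`, `concept_hierarchy`, `code_map`,
#'   `derived_concept`.
#' @param logic_path slash-separated catalogue path (e.g.
#'   `Import/Diagnosis-import`).
#' @param modality one of `sql`, `cdi_file`, `script`.
#' @param spec modality-specific fields (list).
#' @return an object of class `cf_logic`.
#' @export
logic <- function(name, logic_type, logic_path, modality, spec = list()) {
  if (!nzchar(name)) stop("logic name must be non-empty", call. = FALSE)
  if (!logic_type %in% .logic_types) {
    stop("unknown logic_type: ", logic_type, call. = FALSE)
  }
  if (!nzchar(logic_path)) stop("logic_path must be non-empty", call. = FALSE)
  if (!modality %in% .modalities) {
    stop("unknown modality: ", modality, call. = FALSE)
  }
  if (!modality %in% .valid_modality[[logic_type]]) {
    stop("logic_type '", logic_type, "' does not admit modality '",
         modality, "'", call. = FALSE)
  }
  bc <- spec$batch_count
  if (!is.null(bc) && (!is.numeric(bc) || bc < 1)) {
    stop("batch_count must be >= 1", call. = FALSE)
  }
  structure(list(name = name, logic_type = logic_type,
                 logic_path = logic_path, modality = modality, spec = spec),
            class = "cf_logic")
}

#' Register, list and fetch Logics
#'
#' The catalogue indexes Logics by name and by `logic_path` prefix, the
#' "Logic hierarchy" that organizes pipeline code. Re-registering a name
#' replaces the definition and leaves a versioned entry in the catalogue
#' log.
#'
#' @param engine a [cohort_engine()].
#' @param lg a [logic()].
#' @return `register_logic`: the engine, invisibly.
#' @export
register_logic <- function(engine, lg) {
  stopifnot(inherits(engine, "cohort_engine"), inherits(lg, "cf_logic"))
  action <- if (lg$name %in% names(engine$logics)) "replaced" else "created"
  engine$logics[[lg$name]] <- lg
  engine$catalogue_log[[length(engine$catalogue_log) + 1L]] <-
    list(time = Sys.time(), name = lg$name, action = action)
  invisible(engine)
}

#' @rdname register_logic
#' @param prefix optional `logic_path` prefix filter (e.g. `"Import/"`).
#' @return `list_logics`: a data.table with one row per registered Logic.
#' @export
list_logics <- function(engine, prefix = NULL) {
  ls <- engine$logics
  dt <- data.table(
    name = vapply(ls, `[[`, "", "name"),
    logic_type = vapply(ls, `[[`, "", "logic_type"),
    logic_path = vapply(ls, `[[`, "", "logic_path"),
    modality = vapply(ls, `[[`, "", "modality"))
  if (!is.null(prefix)) dt <- dt[startsWith(logic_path, prefix)]
  dt[]
}

#' @rdname register_logic
#' @param name a registered Logic name.
#' @export
get_logic <- function(engine, name) {
  lg <- engine$logics[[name]]
  if (is.null(lg)) stop("logic not registered: ", name, call. = FALSE)
  lg
}

#' Register a named plugin
#'
#' Plugins back the `script` modality and the per-row `algorithm` hook of
#' table imports. An import algorithm receives one raw source row (as a
#' one-row data.frame) and returns 0..n facts; a derived-concept plugin
#' receives `(patient_id, chart)` and returns 0..n facts bearing the def's
#' output code.
#'
#' @param engine a [cohort_engine()].
#' @param name plugin name.
#' @param fn the plugin function.
#' @return the engine, invisibly.
#' @export
register_plugin <- function(engine, name, fn) {
  stopifnot(is.function(fn))
  engine$plugins[[name]] <- fn
  invisible(engine)
}

get_plugin <- function(engine, name) {
  fn <- engine$plugins[[name]]
  if (is.null(fn)) stop("plugin not registered: ", name, call. = FALSE)
  fn
}

new_run <- function(engine, lg, trigger) {
  engine$run_seq <- engine$run_seq + 1L
  list(run_id = engine$run_seq, logic = lg$name, trigger = trigger,
       status = "running", started = Sys.time(), finished = NULL,
       rows_read = 0L, rows_written = 0L, watermark_after = NULL,
       log = character())
}

finish_run <- function(engine, run, status, msgs = character()) {
  run$status <- status
  run$finished <- Sys.time()
  run$log <- c(run$log, msgs)
  if (status == "failed" && !length(run$log)) run$log <- "failed"
  engine$runs[[run$run_id]] <- run
  structure(run, class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<run %d> %s [%s] %s: read %d, written %d\n", x$run_id,
              x$logic, x$trigger, x$status, x$rows_read, x$rows_written))
  if (length(x$log)) cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Run a registered Logic
#'
#' Dispatches to the modality-specific executor and records a run with
#' counts and an ordered log. Import failures never leave a partial batch
#' (per-batch atomicity): batches written before the failure are retained,
#' the failing batch is rolled back whole.
#'
#' @param engine a [cohort_engine()].
#' @param name registered Logic name.
#' @param trigger one of `manual`, `scheduled`, `event`.
#' @return a `pipeline_run` record.
#' @export
run_logic <- function(engine, name, trigger = "manual") {
  stopifnot(trigger %in% c("manual", "scheduled", "event"))
  lg <- get_logic(engine, name)
  switch(lg$logic_type,
    import = if (lg$modality == "sql") {
      import_table_source(engine, lg, trigger)
    } else if (lg$modality == "cdi_file") {
      import_cdi_file(engine, lg, trigger)
    } else {
      run_script_import(engine, lg, trigger)
    },
    concept_hierarchy = run_hierarchy_logic(engine, lg, trigger),
    code_map = run_code_map_logic(engine, lg, trigger),
    derived_concept = run_derived_logic(engine, lg, trigger))
}

#' @rdname run_logic
#' @return `list_runs`: a data.table summarizing recorded runs.
#' @export
list_runs <- function(engine) {
  rs <- engine$runs
  data.table(
    run_id = vapply(rs, `[[`, 0L, "run_id"),
    logic = vapply(rs, `[[`, "", "logic"),
    trigger = vapply(rs, `[[`, "", "trigger"),
    status = vapply(rs, `[[`, "", "status"),
    rows_read = vapply(rs, `[[`, 0L, "rows_read"),
    rows_written = vapply(rs, `[[`, 0L, "rows_written"))
}

#' @rdname run_logic
#' @param run_id a recorded run id.
#' @export
get_run <- function(engine, run_id) {
  if (run_id < 1L || run_id > length(engine$runs)) {
    stop("unknown run: ", run_id, call. = FALSE)
  }
  structure(engine$runs[[run_id]], class = "pipeline_run")
}

run_hierarchy_logic <- function(engine, lg, trigger) {
  run <- new_run(engine, lg, trigger)
  tryCatch({
    before <- nrow(engine$hierarchy$nodes)
    hierarchy_from_tsv(lg$spec$file, engine$hierarchy)
    finish_run(engine, run, "succeeded",
               sprintf("hierarchy +%d nodes from %s",
                       nrow(engine$hierarchy$nodes) - before, lg$spec$file))
  }, error = function(e) {
    finish_run(engine, run, "failed", conditionMessage(e))
  })
}

run_code_map_logic <- function(engine, lg, trigger) {
  run <- new_run(engine, lg, trigger)
  tryCatch({
    map <- apply_code_map_tsv(engine$hierarchy, lg$spec$file)
    finish_run(engine, run, "succeeded",
               sprintf("%d local mappings applied", nrow(map)))
  }, error = function(e) {
    finish_run(engine, run, "failed", conditionMessage(e))
  })
}

run_script_import <- function(engine, lg, trigger) {
  run <- new_run(engine, lg, trigger)
  tryCatch({
    fn <- get_plugin(engine, lg$spec$plugin)
    facts <- as.data.table(fn(engine))
    if (nrow(facts)) facts[, source_logic := lg$name]
    run$rows_read <- nrow(facts)
    run$rows_written <- insert_facts(engine$store, facts)
    finish_run(engine, run, "succeeded")
  }, error = function(e) {
    finish_run(engine, run, "failed", conditionMessage(e))
  })
}

# --- table-source (declarative "sql") importer ------------------------------

load_source_table <- function(source, table) {
  if (is.character(source)) {
    path <- file.path(source, paste0(table, ".csv"))
    if (!file.exists(path)) stop("source table not found: ", path,
                                 call. = FALSE)
    # codes like ICD-9 250.00 must not be read as numbers
    fread(path, colClasses = "character")
  } else if (is.list(source)) {
    tbl <- source[[table]]
    if (is.null(tbl)) stop("source table not found: ", table, call. = FALSE)
    as.data.table(tbl)
  } else stop("source must be a directory path or a named list",
              call. = FALSE)
}

# Watermark values are compared on a canonical scale: numerically when the
# column is numeric, otherwise as canonical timestamps when they parse as
# such, otherwise as plain strings.
wm_canon <- function(x) {
  if (is.numeric(x)) return(x)
  tryCatch(canon_ts(x), error = function(e) as.character(x))
}

map_rows_to_facts <- function(rows, spec, logic_name) {
  cols <- spec$columns
  need <- c("patient_id", "concept_code", "start_datetime")
  missing <- setdiff(need, names(cols))
  if (length(missing)) {
    stop("column mapping must cover: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  absent <- setdiff(unlist(cols), names(rows))
  if (length(absent)) {
    stop("mapped column(s) absent from source: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  out <- data.table(row_seq = seq_len(nrow(rows)))
  for (field in names(cols)) out[, (field) := rows[[cols[[field]]]]]
  out[, row_seq := NULL]
  out[, concept_code := as.character(concept_code)]
  if (!is.null(spec$code_namespace)) {
    bare <- !grepl(":", out$concept_code, fixed = TRUE)
    out[bare, concept_code := paste0(spec$code_namespace, ":", concept_code)]
  }
  for (field in names(spec$constants)) {
    out[, (field) := spec$constants[[field]]]
  }
  if (!"value_kind" %in% names(out)) {
    out[, value_kind := if ("numeric_value" %in% names(out)) "numeric"
        else "flag"]
  }
  out[, source_logic := logic_name]
  out
}

apply_concept_map <- function(facts, spec) {
  if (is.null(spec$concept_map)) return(facts)
  map <- as.data.table(spec$concept_map)
  dir <- spec$map_direction %||% "local_to_standard"
  from <- if (dir == "local_to_standard") map$local_code else
    map$standard_code
  to <- if (dir == "local_to_standard") map$standard_code else
    map$local_code
  idx <- match(facts$concept_code, from)
  hit <- !is.na(idx)
  facts[hit, concept_code := to[idx[hit]]]
  facts
}

#' Import from a delimited staging source, incrementally and in batches
#'
#' Rows are extracted from the staging table (optionally filtered by the
#' `where` expression), restricted to watermark values strictly greater than
#' the stored per-Logic watermark, mapped to observation facts (or handed to
#' the per-row `algorithm` plugin), and written in batches of `batch_count`
#' rows. Each batch is atomic; on failure, prior batches stay and the
#' watermark advances only over rows actually written. Rows that tie with
#' the boundary watermark are the source's responsibility to avoid.
#'
#' @param engine a [cohort_engine()].
#' @param lg an import [logic()] with modality `sql`.
#' @param trigger trigger tag recorded on the run.
#' @return a `pipeline_run` record.
#' @export
import_table_source <- function(engine, lg, trigger = "manual") {
  run <- new_run(engine, lg, trigger)
  spec <- lg$spec
  rows <- tryCatch({
    tbl <- load_source_table(spec$source, spec$table)
    if (!is.null(spec$where)) {
      keep <- eval(parse(text = spec$where), envir = tbl,
                   enclos = baseenv())
      tbl <- tbl[which(keep)]
    }
    wmf <- spec$watermark_field
    if (!is.null(wmf)) {
      if (!wmf %in% names(tbl)) {
        stop("watermark_field '", wmf, "' not in extract result",
             call. = FALSE)
      }
      last <- engine$watermarks[[lg$name]]
      if (!is.null(last)) tbl <- tbl[wm_canon(tbl[[wmf]]) > last]
    }
    tbl
  }, error = function(e) e)
  if (inherits(rows, "error")) {
    return(finish_run(engine, run, "failed", conditionMessage(rows)))
  }
  run$rows_read <- nrow(rows)
  bc <- as.integer(spec$batch_count %||% 1000L)
  starts <- seq(1L, max(nrow(rows), 1L), by = bc)
  if (nrow(rows) == 0L) starts <- integer()
  msgs <- character()
  for (s in starts) {
    idx <- s:min(s + bc - 1L, nrow(rows))
    batch <- rows[idx]
    res <- tryCatch({
      facts <- if (!is.null(spec$algorithm)) {
        fn <- get_plugin(engine, spec$algorithm)
        out <- lapply(seq_len(nrow(batch)),
                      function(i) as.data.table(fn(batch[i])))
        fc <- rbindlist(out, fill = TRUE)
        if (nrow(fc)) fc[, source_logic := lg$name]
        fc
      } else {
        map_rows_to_facts(batch, spec, lg$name)
      }
      facts <- apply_concept_map(facts, spec)
      insert_facts(engine$store, facts)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      msgs <- c(msgs, sprintf("batch starting at source row %d failed: %s",
                              s, conditionMessage(res)))
      return(finish_run(engine, run, "failed", msgs))
    }
    run$rows_written <- run$rows_written + res
    if (!is.null(spec$watermark_field)) {
      wm <- max(wm_canon(batch[[spec$watermark_field]]))
      prev <- engine$watermarks[[lg$name]]
      if (is.null(prev) || wm > prev) engine$watermarks[[lg$name]] <- wm
      run$watermark_after <- engine$watermarks[[lg$name]]
    }
    msgs <- c(msgs, sprintf("batch %d: wrote %d rows",
                            which(starts == s), res))
  }
  run$watermark_after <- engine$watermarks[[lg$name]]
  finish_run(engine, run, "succeeded", msgs)
}

# --- i2b2-cdi flat-file importer --------------------------------------------

#' Import an i2b2-cdi interchange file
#'
#' The cdi dialect is a UTF-8 tab-separated file whose first column tags the
#' line type: `C<TAB>path<TAB>code<TAB>name` declares a concept,
#' `M<TAB>local_code<TAB>standard_code` a local mapping, and
#' `F<TAB>patient_id<TAB>encounter_id<TAB>concept_code<TAB>start_datetime<TAB>value_kind<TAB>value<TAB>unit`
#' a fact. Concept metadata extends the hierarchy before any fact is
#' inserted, and the whole file is atomic: a fact referencing a concept
#' declared nowhere (neither in the file nor in the existing hierarchy)
#' fails the run and leaves both store and hierarchy untouched.
#'
#' @param engine a [cohort_engine()].
#' @param lg an import [logic()] with modality `cdi_file`.
#' @param trigger trigger tag recorded on the run.
#' @return a `pipeline_run` record.
#' @export
import_cdi_file <- function(engine, lg, trigger = "manual") {
  run <- new_run(engine, lg, trigger)
  res <- tryCatch({
    lines <- readLines(lg$spec$file, warn = FALSE)
    lines <- lines[lines != ""]
    h2 <- clone_hierarchy(engine$hierarchy)
    fact_rows <- list()
    for (i in seq_along(lines)) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      tag <- f[1]
      if (tag == "C") {
        if (length(f) != 4L) stop("line ", i, ": C row needs 4 fields")
        add_concept(h2, f[2], f[3], f[4])
      } else if (tag == "M") {
        if (length(f) != 3L) stop("line ", i, ": M row needs 3 fields")
        add_local_mapping(h2, f[2], f[3])
      } else if (tag == "F") {
        # flag rows legitimately leave the trailing value/unit fields
        # empty; strsplit drops trailing empties, so pad back to 8
        if (length(f) < 6L) stop("line ", i, ": F row needs 6-8 fields")
        f <- c(f, rep("", 8L - length(f)))
        fact_rows[[length(fact_rows) + 1L]] <- data.table(
          patient_id = f[2],
          encounter_id = if (nzchar(f[3])) f[3] else NA_character_,
          concept_code = f[4], start_datetime = f[5], value_kind = f[6],
          numeric_value = if (f[6] == "numeric") as.numeric(f[7]) else
            NA_real_,
          text_value = if (f[6] == "text") f[7] else NA_character_,
          unit = if (length(f) >= 8L && nzchar(f[8])) f[8] else
            NA_character_,
          line = i)
      } else stop("line ", i, ": unknown cdi line tag '", tag, "'")
    }
    facts <- rbindlist(fact_rows)
    run$rows_read <- nrow(facts)
    if (nrow(facts)) {
      known <- h2$nodes$code[h2$nodes$code != ""]
      undeclared <- setdiff(facts$concept_code, known)
      if (length(undeclared)) {
        stop("fact rows reference undeclared concept(s): ",
             paste(undeclared, collapse = ", "))
      }
      facts[, line := NULL]
      facts[, source_logic := lg$name]
      run$rows_written <- insert_facts(engine$store, facts)
    }
    engine$hierarchy$nodes <- h2$nodes
    run
  }, error = function(e) e)
  if (inherits(res, "error")) {
    finish_run(engine, run, "failed", conditionMessage(res))
  } else {
    finish_run(engine, res, "succeeded",
               sprintf("cdi import: %d facts", res$rows_written))
  }
}

run_derived_logic <- function(engine, lg, trigger) {
  run <- new_run(engine, lg, trigger)
  res <- tryCatch(run_derived(engine, lg$spec$def), error = function(e) e)
  if (inherits(res, "error")) {
    return(finish_run(engine, run, "failed", conditionMessage(res)))
  }
  run$rows_read <- res$rows_read
  run$rows_written <- res$rows_written
  finish_run(engine, run, "succeeded", res$log)
}

#' Run every registered Logic whose schedule tag is due
#'
#' Scheduling is declarative: a Logic may carry `spec$schedule = "hourly"` /
#' `"daily"` etc.; nothing runs in the background. An explicit `run_due()`
#' call executes all scheduled Logics synchronously with trigger
#' `"scheduled"`.
#'
#' @param engine a [cohort_engine()].
#' @return list of `pipeline_run` records.
#' @export
run_due <- function(engine) {
  due <- Filter(function(lg) !is.null(lg$spec$schedule), engine$logics)
  lapply(names(due), function(nm) run_logic(engine, nm, "scheduled"))
}
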