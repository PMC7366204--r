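#' Create an empty i2b2-style fact store
#'
#' The store is the star-schema centre of the engine: an observation-fact
#' table plus patient and encounter dimensions, held in memory as data.tables
#' whose columns mirror the i2b2 roles (`patient_num` -> `patient_id`,
#' `concept_cd` -> `concept_code`, `nval_num` -> `numeric_value`,
#' `tval_char` -> `text_value`, `start_date` -> `start_datetime`).
#' Insertion is append-only; `row_id` records insertion order and is the
#' stable tie-break wherever timestamps collide.
#'
#' @return an environment of class `fact_store`.
#' @seealso [insert_facts()], [query_facts()], [patient_chart()]
#' @export
fact_store <- function() {
  st <- new.env(parent = emptyenv())
  st$facts <- data.table(
    row_id = integer(), patient_id = character(), encounter_id = character(),
    concept_code = character(), start_datetime = character(),
    value_kind = character(), numeric_value = numeric(), unit = character(),
    text_value = character(), provider_id = character(),
    source_logic = character())
  st$patients <- data.table(patient_id = character(), birth_date = character(),
                            sex = character())
  st$encounters <- data.table(encounter_id = character(),
                              patient_id = character(),
                              start_datetime = character(),
                              end_datetime = character())
  st$next_row_id <- 1L
  class(st) <- "fact_store"
  st
}

#' @export
print.fact_store <- function(x, ...) {
  cat("<fact_store>", nrow(x$facts), "facts,",
      nrow(x$patients), "patients,", nrow(x$encounters), "encounters\n")
  invisible(x)
}

.fact_cols <- c("patient_id", "encounter_id", "concept_code",
                "start_datetime", "value_kind", "numeric_value", "unit",
                "text_value", "provider_id", "source_logic")

#' Build a well-formed block of observation facts
#'
#' Vectorized constructor: fills optional fields with `NA` and normalizes
#' timestamps. Validation happens at insertion.
#'
#' @param patient_id,concept_code,start_datetime required fields; codes are
#'   namespaced `SYSTEM:code` strings (e.g. `ICD9:250.00`, `LOINC:2345-7`).
#' @param value_kind one of `"numeric"`, `"text"`, `"flag"` per row.
#' @param numeric_value,unit,text_value value payload; exactly one payload
#'   kind must match `value_kind` (flags carry none).
#' @param encounter_id,provider_id,source_logic optional provenance fields.
#' @return a data.table with one row per fact.
#' @export
observation_facts <- function(patient_id, concept_code, start_datetime,
                              value_kind = "flag", numeric_value = NA_real_,
                              unit = NA_character_, text_value = NA_character_,
                              encounter_id = NA_character_,
                              provider_id = NA_character_,
                              source_logic = NA_character_) {
  data.table(
    patient_id = as.character(patient_id),
    encounter_id = as.character(encounter_id),
    concept_code = as.character(concept_code),
    start_datetime = canon_ts(start_datetime),
    value_kind = as.character(value_kind),
    numeric_value = as.numeric(numeric_value),
    unit = as.character(unit),
    text_value = as.character(text_value),
    provider_id = as.character(provider_id),
    source_logic = as.character(source_logic))
}

# Row-level validation; returns character vector of error messages, one per
# offending row, naming the field at fault.
validate_facts <- function(dt) {
  errs <- character()
  bad <- function(rows, msg) {
    if (length(rows)) errs <<- c(errs, paste0("row ", rows, ": ", msg))
  }
  bad(which(is.na(dt$patient_id) | dt$patient_id == ""),
      "patient_id is empty")
  bad(which(is.na(dt$concept_code) | !grepl("^[^:]+:.+$", dt$concept_code)),
      "concept_code must be a non-empty namespaced SYSTEM:code string")
  bad(which(is.na(dt$start_datetime)), "start_datetime is missing")
  bad(which(!dt$value_kind %in% c("numeric", "text", "flag")),
      "value_kind must be numeric, text or flag")
  num <- dt$value_kind == "numeric"
  txt <- dt$value_kind == "text"
  flg <- dt$value_kind == "flag"
  bad(which(num & !is.finite(dt$numeric_value)),
      "numeric_value required for value_kind=numeric")
  bad(which(num & !is.na(dt$text_value)),
      "text_value must be empty for value_kind=numeric")
  bad(which(txt & (is.na(dt$text_value) | dt$text_value == "")),
      "text_value required for value_kind=text")
  bad(which(txt & !is.na(dt$numeric_value)),
      "numeric_value must be empty for value_kind=text")
  bad(which(flg & (!is.na(dt$numeric_value) | !is.na(dt$text_value))),
      "flag facts carry no value payload")
  errs
}

#' Insert observation facts (atomic batch)
#'
#' The batch is all-or-nothing: a single malformed row rejects the whole
#' call with row-level errors naming the offending field, and the store is
#' left untouched. Patients referenced by new facts but absent from the
#' patient dimension get stub records.
#'
#' @param store a [fact_store()].
#' @param facts a data.frame with at least `patient_id`, `concept_code`,
#'   `start_datetime`; see [observation_facts()] for the full column set.
#' @return number of rows inserted, invisibly equal to `nrow(facts)`.
#' @export
insert_facts <- function(store, facts) {
  stopifnot(inherits(store, "fact_store"))
  if (is.null(facts) || nrow(facts) == 0L) return(0L)
  dt <- as.data.table(facts)
  for (col in .fact_cols) {
    if (!col %in% names(dt)) {
      dt[, (col) := if (col == "numeric_value") NA_real_ else NA_character_]
    }
  }
  dt <- dt[, .fact_cols, with = FALSE]
  dt[, start_datetime := canon_ts(start_datetime)]
  dt[, numeric_value := as.numeric(numeric_value)]
  errs <- validate_facts(dt)
  if (length(errs)) {
    stop("insert_facts rejected (batch is atomic):\n  ",
         paste(utils::head(errs, 10L), collapse = "\n  "), call. = FALSE)
  }
  n <- nrow(dt)
  dt[, row_id := store$next_row_id + seq_len(n) - 1L]
  setcolorder(dt, c("row_id", .fact_cols))
  store$next_row_id <- store$next_row_id + n
  store$facts <- rbind(store$facts, dt)
  new_pat <- setdiff(unique(dt$patient_id), store$patients$patient_id)
  if (length(new_pat)) {
    store$patients <- rbind(store$patients,
      data.table(patient_id = new_pat, birth_date = NA_character_,
                 sex = NA_character_))
  }
  n
}

#' Register patients / encounters in the dimension tables
#'
#' @param store a [fact_store()].
#' @param patients data.frame with `patient_id` (unique), optional
#'   `birth_date`, `sex`.
#' @return number of new rows added.
#' @export
add_patients <- function(store, patients) {
  dt <- as.data.table(patients)
  if (anyDuplicated(dt$patient_id)) stop("patient_id must be unique")
  for (col in c("birth_date", "sex"))
    if (!col %in% names(dt)) dt[, (col) := NA_character_]
  dt <- dt[!patient_id %in% store$patients$patient_id,
           .(patient_id = as.character(patient_id),
             birth_date = as.character(birth_date),
             sex = as.character(sex))]
  store$patients <- rbind(store$patients, dt)
  nrow(dt)
}

#' @rdname add_patients
#' @param encounters data.frame with `encounter_id` (unique), `patient_id`
#'   (must exist), `start_datetime`, optional `end_datetime`.
#' @export
add_encounters <- function(store, encounters) {
  dt <- as.data.table(encounters)
  if (anyDuplicated(dt$encounter_id)) stop("encounter_id must be unique")
  missing <- setdiff(dt$patient_id, store$patients$patient_id)
  if (length(missing)) {
    stop("encounters reference unknown patients: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  if (!"end_datetime" %in% names(dt)) dt[, end_datetime := NA_character_]
  dt <- dt[!encounter_id %in% store$encounters$encounter_id,
           .(encounter_id = as.character(encounter_id),
             patient_id = as.character(patient_id),
             start_datetime = canon_ts(start_datetime),
             end_datetime = as.character(end_datetime))]
  store$encounters <- rbind(store$encounters, dt)
  nrow(dt)
}

#' Predicate-based fact retrieval
#'
#' Returns exactly the facts whose `concept_code` is in `concept_codes`,
#' whose timestamp lies in the closed `window` (both ends inclusive), and
#' whose numeric value satisfies `operator`/`threshold`. `"exists"` ignores
#' values entirely; any other operator matches only `value_kind = "numeric"`
#' facts. Provider is carried on facts but is not a filterable dimension.
#'
#' @param store a [fact_store()].
#' @param concept_codes character vector of namespaced codes.
#' @param operator one of `>`, `<`, `>=`, `<=`, `=`, `exists` (unicode
#'   `≥`/`≤` accepted).
#' @param threshold numeric scalar, required unless `operator = "exists"`.
#' @param window optional length-2 vector of timestamps, `[start, end]`.
#' @param patient_ids optional restriction to a patient subset.
#' @return a data.table of matching facts (copy; the store is untouched).
#' @export
query_facts <- function(store, concept_codes, operator = "exists",
                        threshold = NULL, window = NULL,
                        patient_ids = NULL) {
  stopifnot(inherits(store, "fact_store"))
  op <- normalize_op(operator)
  dt <- store$facts[concept_code %in% concept_codes]
  if (!is.null(patient_ids)) dt <- dt[patient_id %in% patient_ids]
  if (!is.null(window)) {
    w <- canon_ts(window)
    if (length(w) != 2L || w[1] > w[2]) {
      stop("window must be an ordered [start, end] pair", call. = FALSE)
    }
    dt <- dt[start_datetime >= w[1] & start_datetime <= w[2]]
  }
  if (op != "exists") {
    dt <- dt[value_kind == "numeric"]
    dt <- dt[apply_op(dt$numeric_value, op, threshold)]
  }
  copy(dt)
}

#' Full chart for one patient
#'
#' All facts for the patient sorted by `start_datetime` ascending; ties keep
#' insertion order (stable sort on `row_id`).
#'
#' @param store a [fact_store()].
#' @param patient_id a known patient.
#' @return a data.table of the patient's facts in chart order.
#' @export
patient_chart <- function(store, patient_id) {
  stopifnot(inherits(store, "fact_store"))
  if (!patient_id %in% store$patients$patient_id) {
    stop("unknown patient: ", patient_id, call. = FALSE)
  }
  pid <- patient_id
  dt <- store$facts[patient_id == pid]
  setorder(dt, start_datetime, row_id)
  dt
}

#' Export / import the fact table as CSV
#'
#' Plain-text round-trip of the fact table with the fixed header
#' `patient_id,encounter_id,concept_code,start_datetime,value_kind,numeric_value,unit,text_value,provider_id,source_logic`
#' and ISO-8601 timestamps.
#'
#' @param store a [fact_store()].
#' @param path file path.
#' @return `export_fact_csv`: the path, invisibly. `import_fact_csv`: rows
#'   inserted.
#' @export
export_fact_csv <- function(store, path) {
  fwrite(store$facts[, .fact_cols, with = FALSE], path)
  invisible(path)
}

#' @rdname export_fact_csv
#' @export
import_fact_csv <- function(store, path) {
  dt <- fread(path, colClasses = list(character = setdiff(.fact_cols,
                                                          "numeric_value")))
  for (col in setdiff(.fact_cols, "numeric_value")) {
    blank <- which(dt[[col]] == "")
    if (length(blank)) set(dt, blank, col, NA_character_)
  }
  insert_facts(store, dt)
}
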