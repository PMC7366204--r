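#' Configuration for the synthetic EHR generator
#'
#' The generator emulates what a critical-care EHR extract contributes to a
#' diabetes cohort study: ICD-9-coded diagnoses and LOINC-coded timestamped
#' numeric labs (serum glucose 2345-7, HbA1c 4548-4), with a planted
#' phenotype so the three-criterion diabetes cohort is recoverable with
#' known ground truth. Each case patient is planted into a non-empty subset
#' of the criteria; controls satisfy none. Value distributions are
#' truncated so membership is crisp at the clinical thresholds: case last
#' HbA1c is drawn from (6.4, 12.0] and control from [4.0, 6.4]; case
#' last-two glucose from (126, 300] and control last glucose from [70,
#' 126]. Thresholds are the clinical cut-points (HbA1c > 6.4 %, glucose >
#' 126 mg/dL); the distribution shapes are the generator's own. `fuzzy`
#' plants exact boundary values (6.4 and 126) on some controls for
#' strict-inequality boundary testing.
#'
#' @param n_patients number of patients.
#' @param prevalence fraction of patients planted as phenotype cases, in
#'   `[0, 1]`.
#' @param seed integer RNG seed; the whole dataset is a pure function of the
#'   config (integer-grid timestamps, quantized values), so equal seeds give
#'   byte-identical output.
#' @param glucose_per_patient,hba1c_per_patient,dx_per_patient inclusive
#'   `c(min, max)` ranges for per-patient fact counts.
#' @param date_range two dates bounding all fact timestamps.
#' @param criterion_prob probability that a case is planted into each
#'   individual criterion (at least one is always forced).
#' @param fuzzy plant boundary values on some controls.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_patients = 1000, prevalence = 0.3, seed = 1,
                         glucose_per_patient = c(3, 8),
                         hba1c_per_patient = c(1, 4),
                         dx_per_patient = c(1, 4),
                         date_range = c("2019-01-01", "2020-12-30"),
                         criterion_prob = 0.6, fuzzy = FALSE) {
  stopifnot(n_patients >= 1, prevalence >= 0, prevalence <= 1)
  structure(list(n_patients = as.integer(n_patients),
                 prevalence = prevalence, seed = as.integer(seed),
                 glucose_per_patient = glucose_per_patient,
                 hba1c_per_patient = hba1c_per_patient,
                 dx_per_patient = dx_per_patient,
                 date_range = as.Date(date_range),
                 criterion_prob = criterion_prob, fuzzy = fuzzy),
            class = "synth_config")
}

#' The ICD-9 diabetes mellitus code family
#'
#' All 250.xy codes (fourth digit 0-9 for manifestation, fifth digit 0-3
#' for type/control), namespaced — the enumerable family behind a
#' "diagnoses code of diabetes" criterion.
#'
#' @return character vector of 40 namespaced codes.
#' @export
icd9_diabetes_codes <- function() {
  sprintf("ICD9:250.%d%d", rep(0:9, each = 4), rep(0:3, 10))
}

.glucose_code <- "LOINC:2345-7"
.hba1c_code <- "LOINC:4548-4"
.dx_case_pool <- c("250.00", "250.01", "250.02", "250.40", "250.50",
                   "250.60")
.dx_control_pool <- c("401.9", "272.4", "414.01", "428.0", "486", "584.9",
                      "530.81", "311", "493.90", "599.0")

#' Generate a synthetic EHR dataset with planted ground truth
#'
#' @param config a [synth_config()].
#' @return an object of class `synth_ehr`: list with `patients`,
#'   `encounters`, `facts` (observation-fact table, `source_logic =
#'   "synth"`), `ground_truth` (per-criterion patient-id sets plus their
#'   union as `phenotype`) and `config`.
#' @export
generate_synth_ehr <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_patients
  pids <- sprintf("P%04d", seq_len(n))
  n_case <- round(config$prevalence * n)
  if (config$prevalence > 0 && n_case < 1) {
    warning("prevalence * n_patients < 1; forcing a single case")
    n_case <- 1L
  }
  case <- pids %in% sample(pids, n_case)

  # criterion membership: cases draw each criterion independently, at least
  # one forced; controls are in none.
  memb <- matrix(FALSE, n, 3, dimnames = list(pids, c("dx", "glu", "hba1c")))
  for (i in which(case)) {
    m <- runif(3) < config$criterion_prob
    if (!any(m)) m[sample.int(3, 1)] <- TRUE
    memb[i, ] <- m
  }

  day0 <- config$date_range[1]
  n_days <- as.integer(config$date_range[2] - day0) + 1L
  rint <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L
  lab_days <- function(k) sort(sample.int(n_days, k)) - 1L

  patients <- data.table(
    patient_id = pids,
    birth_date = format(day0 - sample(7000:30000, n, replace = TRUE)),
    sex = sample(c("F", "M"), n, replace = TRUE))

  enc_list <- vector("list", n)
  fact_list <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- pids[i]
    n_enc <- rint(1L, 3L)
    encs <- sprintf("%s-E%d", pid, seq_len(n_enc))
    enc_days <- sort(sample.int(n_days, n_enc)) - 1L
    enc_list[[i]] <- data.table(
      encounter_id = encs, patient_id = pid,
      start_datetime = paste0(format(day0 + enc_days), "T00:00:00"),
      end_datetime = NA_character_)

    # diagnoses: controls (and off-criterion cases) draw only from the
    # non-diabetes pool; dx-criterion members get one 250.x on top.
    n_dx <- rint(config$dx_per_patient[1], config$dx_per_patient[2])
    dx_codes <- sample(.dx_control_pool, n_dx, replace = TRUE)
    if (memb[i, "dx"]) dx_codes <- c(dx_codes,
                                     sample(.dx_case_pool, 1L))
    dx <- data.table(
      concept_code = paste0("ICD9:", dx_codes),
      start_datetime = paste0(
        format(day0 + sample.int(n_days, length(dx_codes),
                                 replace = TRUE) - 1L), "T12:00:00"),
      value_kind = "flag", numeric_value = NA_real_, unit = NA_character_)

    # serum glucose series: members' final two values exceed 126; everyone
    # else's last value is capped at 126 so the last pair never qualifies.
    n_glu <- rint(config$glucose_per_patient[1],
                  config$glucose_per_patient[2])
    if (memb[i, "glu"]) n_glu <- max(n_glu, 2L)
    glu_vals <- sample(70:300, n_glu, replace = TRUE)
    if (memb[i, "glu"]) {
      glu_vals[(n_glu - 1L):n_glu] <- sample(127:300, 2L, replace = TRUE)
    } else if (n_glu >= 1L) {
      glu_vals[n_glu] <- if (config$fuzzy && runif(1) < 0.3) 126L else
        sample(70:126, 1L)
    }
    glu <- data.table(
      concept_code = .glucose_code,
      start_datetime = paste0(format(day0 + lab_days(n_glu)), "T08:00:00"),
      value_kind = "numeric", numeric_value = as.numeric(glu_vals),
      unit = "mg/dL")

    # HbA1c series: only the last value decides the criterion.
    n_hb <- rint(config$hba1c_per_patient[1], config$hba1c_per_patient[2])
    hb_vals <- round(runif(n_hb, 4.5, 9.5), 1)
    hb_vals[n_hb] <- if (memb[i, "hba1c"]) {
      round(runif(1, 6.5, 12.0), 1)
    } else if (config$fuzzy && runif(1) < 0.3) 6.4 else {
      round(runif(1, 4.0, 6.35), 1)
    }
    hb <- data.table(
      concept_code = .hba1c_code,
      start_datetime = paste0(format(day0 + lab_days(n_hb)), "T09:00:00"),
      value_kind = "numeric", numeric_value = hb_vals, unit = "%")

    pf <- rbind(dx, glu, hb)
    pf[, patient_id := pid]
    pf[, encounter_id := sample(encs, nrow(pf), replace = TRUE)]
    fact_list[[i]] <- pf
  }
  facts <- rbindlist(fact_list)
  facts[, `:=`(text_value = NA_character_, provider_id = NA_character_,
               source_logic = "synth")]
  setcolorder(facts, .fact_cols)

  gt <- list(
    criterion_diagnosis = pids[memb[, "dx"]],
    criterion_glucose = pids[memb[, "glu"]],
    criterion_hba1c = pids[memb[, "hba1c"]])
  gt$phenotype <- sort(unique(unlist(gt)))
  structure(list(patients = patients, encounters = rbindlist(enc_list),
                 facts = facts, ground_truth = gt, config = config),
            class = "synth_ehr")
}

#' @export
print.synth_ehr <- function(x, ...) {
  cat("<synth_ehr>", nrow(x$patients), "patients,", nrow(x$facts),
      "facts,", length(x$ground_truth$phenotype), "phenotype cases\n")
  invisible(x)
}

#' Load a synthetic dataset straight into a store (direct-insert path)
#'
#' @param dataset a [generate_synth_ehr()] result.
#' @param store a [fact_store()] (fresh by default).
#' @return the store, invisibly.
#' @export
load_synth_ehr <- function(dataset, store = fact_store()) {
  add_patients(store, dataset$patients)
  add_encounters(store, dataset$encounters)
  insert_facts(store, dataset$facts)
  invisible(store)
}

#' Write MIMIC-style staging tables for the SQL-import path
#'
#' Emits `diagnoses_icd.csv` (`subject_id, hadm_id, icd9_code, charttime`)
#' and `labevents.csv` (`subject_id, hadm_id, loinc_code, charttime,
#' valuenum, valueuom`) with bare (un-namespaced) codes, as a source system
#' would hold them.
#'
#' @param dataset a [generate_synth_ehr()] result.
#' @param dir destination directory (created if missing).
#' @return named vector of row counts per table, invisibly.
#' @export
write_source_tables <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- dataset$facts
  dx <- f[startsWith(concept_code, "ICD9:"),
          .(subject_id = patient_id, hadm_id = encounter_id,
            icd9_code = sub("^ICD9:", "", concept_code),
            charttime = start_datetime)]
  lab <- f[startsWith(concept_code, "LOINC:"),
           .(subject_id = patient_id, hadm_id = encounter_id,
             loinc_code = sub("^LOINC:", "", concept_code),
             charttime = start_datetime, valuenum = numeric_value,
             valueuom = unit)]
  fwrite(dx, file.path(dir, "diagnoses_icd.csv"))
  fwrite(lab, file.path(dir, "labevents.csv"))
  invisible(c(diagnoses_icd = nrow(dx), labevents = nrow(lab)))
}

#' Concept-hierarchy rows covering a synthetic dataset
#'
#' Lab leaves sit under `Labs/Serum or Plasma/...`; diagnosis leaves under
#' `Diagnoses/Diabetes mellitus/...` (250.x) or `Diagnoses/Other/...`.
#'
#' @param dataset a [generate_synth_ehr()] result.
#' @return a data.table with `path`, `code`, `name` — ready for
#'   [write_hierarchy_tsv()] or cdi `C` rows.
#' @export
synth_hierarchy <- function(dataset) {
  codes <- sort(unique(dataset$facts$concept_code))
  rows <- lapply(codes, function(code) {
    bare <- sub("^[^:]+:", "", code)
    if (code == .glucose_code) {
      data.table(path = "Labs/Serum or Plasma/Serum Glucose", code = code,
                 name = "Glucose [Mass/volume]")
    } else if (code == .hba1c_code) {
      data.table(path = "Labs/Serum or Plasma/Hemoglobin A1c", code = code,
                 name = "Hemoglobin A1c")
    } else {
      folder <- if (startsWith(bare, "250")) "Diabetes mellitus" else
        "Other"
      data.table(path = paste0("Diagnoses/", folder, "/", bare),
                 code = code, name = paste("ICD-9", bare))
    }
  })
  rbindlist(rows)
}

#' Write a synthetic dataset as an i2b2-cdi interchange file
#'
#' Concept (`C`) rows for every concept in the dataset precede the fact
#' (`F`) rows, so the file is self-describing and loadable into an empty
#' engine; the writer round-trips bit-exactly with [import_cdi_file()].
#'
#' @param dataset a [generate_synth_ehr()] result.
#' @param path destination file.
#' @return the path, invisibly.
#' @export
write_cdi_file <- function(dataset, path) {
  hier <- synth_hierarchy(dataset)
  c_rows <- paste("C", hier$path, hier$code, hier$name, sep = "\t")
  f <- dataset$facts
  val <- ifelse(f$value_kind == "numeric", format(f$numeric_value,
                trim = TRUE, scientific = FALSE), "")
  f_rows <- paste("F", f$patient_id, f$encounter_id, f$concept_code,
                  f$start_datetime, f$value_kind, val,
                  ifelse(is.na(f$unit), "", f$unit), sep = "\t")
  writeLines(c(c_rows, f_rows), path)
  invisible(path)
}

#' Write ground truth as JSON
#'
#' @param dataset a [generate_synth_ehr()] result.
#' @param path destination file.
#' @return the path, invisibly.
#' @export
write_ground_truth_json <- function(dataset, path) {
  jsonlite::write_json(dataset$ground_truth, path)
  invisible(path)
}
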