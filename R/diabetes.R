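#' The diabetes-study Logic set
#'
#' Eight Logic definitions covering a diabetes cohort study over
#' MIMIC-style staging tables: two SQL imports (diagnoses, labs), two
#' concept-hierarchy loads, and four derived concepts — a diabetes
#' diagnosis-code flag (ICD-9 250.x family), last serum glucose, last
#' HbA1c, and the "last two consecutive serum glucose > 126" flag.
#'
#' @param staging_dir directory holding `diagnoses_icd.csv` and
#'   `labevents.csv` (see [write_source_tables()]).
#' @param hierarchy_dir directory holding `diagnosis_hierarchy.tsv` and
#'   `labs_hierarchy.tsv` (see [write_study_hierarchies()]).
#' @param glucose_threshold,hba1c_threshold clinical cut-points; defaults
#'   are the standard diagnostic values (126 mg/dL, 6.4 %).
#' @param batch_count import batch size.
#' @return named list of [logic()] objects.
#' @export
diabetes_logics <- function(staging_dir, hierarchy_dir,
                            glucose_threshold = 126,
                            hba1c_threshold = 6.4, batch_count = 500) {
  lg <- list(
    logic("Diagnosis-import", "import", "Import/Diagnosis-import", "sql",
      list(source = staging_dir, table = "diagnoses_icd",
           columns = list(patient_id = "subject_id",
                          encounter_id = "hadm_id",
                          concept_code = "icd9_code",
                          start_datetime = "charttime"),
           code_namespace = "ICD9",
           constants = list(value_kind = "flag"),
           watermark_field = "charttime", batch_count = batch_count)),
    logic("Labs-import", "import", "Import/Labs-import", "sql",
      list(source = staging_dir, table = "labevents",
           columns = list(patient_id = "subject_id",
                          encounter_id = "hadm_id",
                          concept_code = "loinc_code",
                          start_datetime = "charttime",
                          numeric_value = "valuenum", unit = "valueuom"),
           code_namespace = "LOINC",
           constants = list(value_kind = "numeric"),
           watermark_field = "charttime", batch_count = batch_count)),
    logic("Diagnosis-hierarchy", "concept_hierarchy",
      "Concept_Hierarchy/Diagnosis-hierarchy", "cdi_file",
      list(file = file.path(hierarchy_dir, "diagnosis_hierarchy.tsv"))),
    logic("Labs-hierarchy", "concept_hierarchy",
      "Concept_Hierarchy/Labs-hierarchy", "cdi_file",
      list(file = file.path(hierarchy_dir, "labs_hierarchy.tsv"))),
    logic("Diagnosis-Diabetes", "derived_concept",
      "Derived_Concept/Diagnosis-Diabetes", "sql",
      list(def = derived_concept_def("Diagnosis-Diabetes",
        "Derived/Diagnosis/Diabetes", "any_code_present",
        codes = icd9_diabetes_codes()))),
    logic("LastHbA1c", "derived_concept",
      "Labs/BloodTest/Chemistry/HbA1c/LastHbA1c", "sql",
      list(def = derived_concept_def("LastHbA1c",
        "Derived/Labs/Blood/Chemistry/HbA1c/LastHbA1c", "last_value",
        source = .hba1c_code))),
    logic("LastGlucose", "derived_concept",
      "Labs/BloodTest/Chemistry/Glucose/LastGlucose", "sql",
      list(def = derived_concept_def("LastGlucose",
        "Derived/Labs/Blood/Chemistry/Glucose/LastGlucose", "last_value",
        source = .glucose_code))),
    logic("LastTwoGlucose", "derived_concept",
      "Labs/BloodTest/Chemistry/Glucose/LastTwoGlucose", "sql",
      list(def = derived_concept_def("LastTwoGlucose",
        "Derived/Labs/Blood/Chemistry/Glucose/LastTwoGlucose",
        "last_n_consecutive_compare", source = .glucose_code, n = 2,
        comparator = ">", threshold = glucose_threshold))))
  names(lg) <- vapply(lg, `[[`, "", "name")
  lg
}

#' Write the study concept hierarchies as TSV files
#'
#' @param dataset a [generate_synth_ehr()] result.
#' @param dir destination directory.
#' @return the directory, invisibly.
#' @export
write_study_hierarchies <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hier <- synth_hierarchy(dataset)
  write_hierarchy_tsv(hier[startsWith(path, "Diagnoses")],
                      file.path(dir, "diagnosis_hierarchy.tsv"))
  write_hierarchy_tsv(hier[startsWith(path, "Labs")],
                      file.path(dir, "labs_hierarchy.tsv"))
  invisible(dir)
}

#' The three-criterion diabetes cohort query
#'
#' Three sibling roots (OR): a diabetes diagnosis-code flag, the
#' last-two-consecutive-glucose flag, and last HbA1c above the threshold.
#'
#' @param hba1c_threshold HbA1c cut-point in percent (default 6.4).
#' @return a [cohort_query()].
#' @export
diabetes_query <- function(hba1c_threshold = 6.4) {
  cohort_query(list(
    query_node("dx", "DERIVED:Diagnosis-Diabetes",
               label = "Diagnoses code of diabetes"),
    query_node("glucose", "DERIVED:LastTwoGlucose",
               label = "Last two consecutive serum glucose > 126"),
    query_node("hba1c", "DERIVED:LastHbA1c", ">", hba1c_threshold,
               label = paste("Last HbA1c >", hba1c_threshold))))
}

#' Run the whole diabetes study end-to-end on a synthetic dataset
#'
#' Writes staging tables and hierarchy files under `workdir`, registers the
#' Logic set, runs imports, derived computations and the three-criterion
#' query, and returns engine plus results.
#'
#' @param dataset a [generate_synth_ehr()] result.
#' @param workdir scratch directory for staging/hierarchy files.
#' @param hba1c_threshold HbA1c cut-point passed to [diabetes_query()].
#' @return list with `engine`, `result` (a `cohort_result`) and `runs`.
#' @export
run_diabetes_pipeline <- function(dataset, workdir = tempfile("cohort"),
                                  hba1c_threshold = 6.4) {
  staging <- file.path(workdir, "staging")
  hier_dir <- file.path(workdir, "hierarchy")
  write_source_tables(dataset, staging)
  write_study_hierarchies(dataset, hier_dir)
  en <- cohort_engine()
  add_patients(en$store, dataset$patients)
  add_encounters(en$store, dataset$encounters)
  for (lg in diabetes_logics(staging, hier_dir)) register_logic(en, lg)
  order <- c("Diagnosis-hierarchy", "Labs-hierarchy", "Diagnosis-import",
             "Labs-import", "Diagnosis-Diabetes", "LastHbA1c",
             "LastGlucose", "LastTwoGlucose")
  runs <- lapply(order, function(nm) run_logic(en, nm))
  names(runs) <- order
  failed <- Filter(function(r) r$status != "succeeded", runs)
  if (length(failed)) {
    stop("pipeline run(s) failed: ",
         paste(names(failed), collapse = ", "), call. = FALSE)
  }
  result <- evaluate_query(diabetes_query(hba1c_threshold), en$store,
                           en$hierarchy)
  list(engine = en, result = result, runs = runs)
}
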