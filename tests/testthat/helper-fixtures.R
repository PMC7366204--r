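# Small in-code fixtures shared across test files.

glucose_facts <- function(patient_id, values, days,
                          code = "LOINC:2345-7") {
  observation_facts(
    patient_id = patient_id, concept_code = code,
    start_datetime = sprintf("2020-01-%02dT08:00:00", days),
    value_kind = "numeric", numeric_value = values, unit = "mg/dL")
}

# A random fact store: n_pat patients with numeric labs across a handful of
# codes, plus coded diagnosis flags. Returns the store.
random_store <- function(n_pat = 50, n_facts = 400,
                         codes = c("LOINC:2345-7", "LOINC:4548-4",
                                   "LOINC:2160-0"),
                         dx_codes = c("ICD9:250.00", "ICD9:401.9",
                                      "ICD9:272.4")) {
  st <- fact_store()
  pids <- sprintf("P%03d", seq_len(n_pat))
  labs <- observation_facts(
    patient_id = sample(pids, n_facts, replace = TRUE),
    concept_code = sample(codes, n_facts, replace = TRUE),
    start_datetime = sprintf("2020-%02d-%02dT%02d:00:00",
                             sample(1:12, n_facts, replace = TRUE),
                             sample(1:28, n_facts, replace = TRUE),
                             sample(0:23, n_facts, replace = TRUE)),
    value_kind = "numeric",
    numeric_value = round(runif(n_facts, 50, 300), 1), unit = "mg/dL")
  n_dx <- max(10L, n_facts %/% 8L)
  dx <- observation_facts(
    patient_id = sample(pids, n_dx, replace = TRUE),
    concept_code = sample(dx_codes, n_dx, replace = TRUE),
    start_datetime = sprintf("2020-%02d-%02dT12:00:00",
                             sample(1:12, n_dx, replace = TRUE),
                             sample(1:28, n_dx, replace = TRUE)),
    value_kind = "flag")
  insert_facts(st, rbind(labs, dx))
  st
}

# Random query tree over the codes present in a store; depth <= max_depth,
# branching <= max_branch.
random_query <- function(store, max_depth = 4, max_branch = 3) {
  codes <- unique(store$facts$concept_code)
  counter <- 0L
  mk_node <- function(depth) {
    counter <<- counter + 1L
    op <- sample(c(">", "<", ">=", "<=", "exists"), 1L)
    n_kids <- if (depth >= max_depth) 0L else sample(0:max_branch, 1L,
      prob = c(0.5, 0.25, 0.15, 0.1)[seq_len(max_branch + 1L)])
    window <- if (runif(1) < 0.3) {
      d <- sort(sample(1:364, 2L))
      as.character(as.Date("2020-01-01") + c(d[1] - 1L, d[2]))
    }
    query_node(sprintf("n%03d", counter),
               concept = sample(codes, sample(1:2, 1L)),
               operator = op,
               threshold = if (op != "exists") round(runif(1, 60, 280)),
               window = window,
               children = lapply(seq_len(n_kids),
                                 function(i) mk_node(depth + 1L)))
  }
  cohort_query(lapply(seq_len(sample(1:max_branch, 1L)),
                      function(i) mk_node(1L)))
}

tiny_hierarchy <- function() {
  h <- concept_hierarchy()
  add_concept(h, "Labs/Serum or Plasma/Serum Glucose", "LOINC:2345-7",
              "Glucose [Mass/volume]")
  add_concept(h, "Labs/Serum or Plasma/Hemoglobin A1c", "LOINC:4548-4",
              "Hemoglobin A1c")
  add_concept(h, "Diagnoses/Diabetes mellitus/250.00", "ICD9:250.00",
              "ICD-9 250.00")
  h
}
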