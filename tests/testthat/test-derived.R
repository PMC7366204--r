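last_glu_def <- function(name = "LastGlucose") {
  derived_concept_def(name, "Derived/Labs/Glucose/LastGlucose",
                      "last_value", source = "LOINC:2345-7")
}

test_that("execution planning is topological with name-order tie-breaks", {
  a <- last_glu_def("LastHbA1c")
  a$source <- "LOINC:4548-4"
  b <- derived_concept_def("DiabetesByHbA1c", "Derived/Diabetes/ByHbA1c",
                           "compare_derived", source = "DERIVED:LastHbA1c",
                           comparator = ">", threshold = 6.4)
  ordered <- plan_execution(list(b, a))
  expect_equal(names(ordered), c("LastHbA1c", "DiabetesByHbA1c"))
  # independent defs come out in name order
  ind <- plan_execution(list(last_glu_def("B"), last_glu_def("A")))
  expect_equal(names(ind), c("A", "B"))
  # a cycle is refused, naming the full cycle
  x <- derived_concept_def("A", "D/A", "compare_derived",
                           source = "DERIVED:B", comparator = ">",
                           threshold = 1)
  y <- derived_concept_def("B", "D/B", "compare_derived",
                           source = "DERIVED:A", comparator = ">",
                           threshold = 1)
  expect_error(plan_execution(list(x, y)), "A -> B -> A")
})

test_that("last_value copies the chronologically last numeric fact", {
  st <- fact_store()
  insert_facts(st, glucose_facts("p1", c(100, 180), c(1, 2)))
  insert_facts(st, glucose_facts("p2", 95, 1))
  res <- compute_derived(last_glu_def(), st)
  f <- as.data.frame(res$facts)
  expect_equal(f$numeric_value[f$patient_id == "p1"], 180)
  expect_equal(f$start_datetime[f$patient_id == "p1"],
               "2020-01-02T08:00:00")
  expect_equal(f$numeric_value[f$patient_id == "p2"], 95)
  expect_equal(f$concept_code, rep("DERIVED:LastGlucose", 2))
  expect_equal(f$value_kind, rep("numeric", 2))
})

test_that("last_value matches max-by-date brute force on shuffled input", {
  set.seed(5)
  st <- fact_store()
  for (i in 1:100) {
    k <- sample(1:6, 1)
    days <- sample(1:28, k)
    insert_facts(st, glucose_facts(sprintf("q%03d", i),
                                   round(runif(k, 60, 280)), days))
  }
  res <- compute_derived(last_glu_def(), st)
  exp <- oracle_last_value(st$facts, "LOINC:2345-7")
  got <- as.data.frame(res$facts)
  got <- got[order(got$patient_id), ]
  expect_equal(got$patient_id, exp$patient_id)
  expect_equal(got$numeric_value, exp$numeric_value)
  expect_equal(got$start_datetime, exp$start_datetime)
  # at most one derived fact per patient
  expect_false(any(duplicated(got$patient_id)))
})

test_that("date ties resolve to the last-inserted fact", {
  st <- fact_store()
  insert_facts(st, glucose_facts("p1", c(111, 222), c(5, 5)))
  res <- compute_derived(last_glu_def(), st)
  expect_equal(res$facts$numeric_value, 222)
})

test_that("patients with only non-numeric source facts are skipped with log", {
  st <- fact_store()
  insert_facts(st, observation_facts("p1", "LOINC:2345-7", "2020-01-01",
                                     value_kind = "text",
                                     text_value = "hemolyzed"))
  insert_facts(st, glucose_facts("p2", 120, 1))
  res <- compute_derived(last_glu_def(), st)
  expect_equal(res$facts$patient_id, "p2")
  expect_match(res$log, "p1")
})

test_that("last_n tests exactly the final n measurements", {
  def <- derived_concept_def("LastTwo", "Derived/LastTwo",
                             "last_n_consecutive_compare",
                             source = "LOINC:2345-7", n = 2,
                             comparator = ">", threshold = 126)
  st <- fact_store()
  insert_facts(st, glucose_facts("hit", c(130, 140), c(1, 2)))
  insert_facts(st, glucose_facts("short", 130, 1))
  # an earlier qualifying pair must not count: last two are (100, 150)
  insert_facts(st, glucose_facts("stale", c(200, 100, 150), c(1, 2, 3)))
  res <- compute_derived(def, st)
  f <- as.data.frame(res$facts)
  expect_equal(f$patient_id, "hit")
  expect_equal(f$value_kind, "flag")
  expect_equal(f$start_datetime, "2020-01-02T08:00:00")
  expect_equal(oracle_last_n_flag(st$facts, "LOINC:2345-7", 2, ">", 126),
               "hit")
})

test_that("last_n agrees with brute force across random patients", {
  set.seed(9)
  st <- fact_store()
  for (i in 1:120) {
    k <- sample(1:5, 1)
    insert_facts(st, glucose_facts(sprintf("r%03d", i),
                                   sample(c(100, 120, 126, 127, 200), k,
                                          replace = TRUE),
                                   sort(sample(1:28, k))))
  }
  for (n in 1:3) {
    def <- derived_concept_def("L", "D/L", "last_n_consecutive_compare",
                               source = "LOINC:2345-7", n = n,
                               comparator = ">", threshold = 126)
    got <- sort(compute_derived(def, st)$facts$patient_id)
    expect_equal(got, oracle_last_n_flag(st$facts, "LOINC:2345-7", n, ">",
                                         126))
  }
})

test_that("any_code_present flags by code prefix and hierarchy path", {
  st <- fact_store()
  insert_facts(st, observation_facts("p1", "ICD9:250.00", "2020-01-05"))
  insert_facts(st, observation_facts("p1", "ICD9:250.40", "2020-01-02"))
  insert_facts(st, observation_facts("p2", "ICD9:401.9", "2020-01-01"))
  insert_facts(st, glucose_facts("p3", 100, 1))
  def <- derived_concept_def("DxDiabetes", "Derived/Diagnosis/Diabetes",
                             "any_code_present", prefix = "ICD9:250")
  res <- compute_derived(def, st)
  expect_equal(res$facts$patient_id, "p1")
  # timestamp is the earliest matching fact
  expect_equal(res$facts$start_datetime, "2020-01-02T00:00:00")
  # the same criterion via a hierarchy path expansion
  h <- concept_hierarchy()
  add_concept(h, "Diagnoses/Diabetes/250.00", "ICD9:250.00")
  add_concept(h, "Diagnoses/Diabetes/250.40", "ICD9:250.40")
  def2 <- derived_concept_def("DxDiabetes2", "Derived/Diagnosis/D2",
                              "any_code_present",
                              prefix = "Diagnoses/Diabetes")
  res2 <- compute_derived(def2, st, h)
  expect_equal(res2$facts$patient_id, "p1")
  expect_error(compute_derived(
    derived_concept_def("empty", "D/e", "any_code_present",
                        prefix = "ICD9:999"), st),
    "expansion is empty")
})

test_that("any_code_present recovers the planted diagnosis set exactly", {
  d <- generate_synth_ehr(synth_config(n_patients = 500, prevalence = 0.3,
                                       seed = 23))
  st <- load_synth_ehr(d)
  def <- derived_concept_def("DxDiabetes", "Derived/Diagnosis/Diabetes",
                             "any_code_present", prefix = "ICD9:250")
  got <- sort(compute_derived(def, st)$facts$patient_id)
  expect_equal(got, sort(d$ground_truth$criterion_diagnosis))
})

test_that("script plugins run per patient and are validated", {
  st <- fact_store()
  insert_facts(st, glucose_facts("p1", c(100, 180), c(1, 2)))
  insert_facts(st, glucose_facts("p2", 95, 3))
  # a plugin re-implementing last_value must reproduce the built-in
  plug <- function(pid, chart) {
    g <- chart[chart$concept_code == "LOINC:2345-7" &
                 chart$value_kind == "numeric", ]
    if (!nrow(g)) return(NULL)
    last <- g[nrow(g), ]
    observation_facts(pid, "DERIVED:ScriptLast", last$start_datetime,
                      value_kind = "numeric",
                      numeric_value = last$numeric_value)
  }
  def <- derived_concept_def("ScriptLast", "Derived/ScriptLast", "script",
                             plugin = "p", result_kind = "numeric")
  res <- compute_derived(def, st, plugins = list(p = plug))
  builtin <- compute_derived(last_glu_def(), st)
  expect_equal(res$facts$numeric_value, builtin$facts$numeric_value)
  expect_equal(res$facts$start_datetime, builtin$facts$start_datetime)
  # constant-flag plugin: one fact per patient
  const <- function(pid, chart) {
    observation_facts(pid, "DERIVED:Const", "2020-01-01")
  }
  cdef <- derived_concept_def("Const", "Derived/Const", "script",
                              plugin = "p")
  expect_equal(nrow(compute_derived(cdef, st,
                                    plugins = list(p = const))$facts), 2L)
  # foreign output code fails the run
  rogue <- function(pid, chart) {
    observation_facts(pid, "DERIVED:SomethingElse", "2020-01-01")
  }
  expect_error(compute_derived(cdef, st, plugins = list(p = rogue)),
               "foreign concept code")
  # a plugin exception names the patient
  bomb <- function(pid, chart) {
    if (pid == "p2") stop("boom")
    NULL
  }
  expect_error(compute_derived(cdef, st, plugins = list(p = bomb)), "p2")
})

test_that("recompute replaces prior output and registers the concept", {
  en <- cohort_engine()
  insert_facts(en$store, glucose_facts("p1", c(100, 180), c(1, 2)))
  def <- last_glu_def()
  r1 <- run_derived(en, def)
  expect_equal(r1$rows_written, 1L)
  # derived facts are ordinary facts, queryable through the same path
  q <- query_facts(en$store, "DERIVED:LastGlucose")
  expect_equal(q$numeric_value, 180)
  expect_true("Derived/Labs/Glucose/LastGlucose" %in%
                en$hierarchy$nodes$path)
  # determinism: recompute on an unchanged store is a fixed point
  before <- as.data.frame(en$store$facts[, -"row_id"])
  run_derived(en, def)
  expect_equal(as.data.frame(en$store$facts[, -"row_id"]), before)
  # new source data changes the derived fact, still one per patient
  insert_facts(en$store, glucose_facts("p1", 99, 9))
  run_derived(en, def)
  q2 <- query_facts(en$store, "DERIVED:LastGlucose")
  expect_equal(nrow(q2), 1L)
  expect_equal(q2$numeric_value, 99)
})

test_that("run_derived_set executes a dependent chain in order", {
  en <- cohort_engine()
  insert_facts(en$store, observation_facts(
    c("p1", "p1", "p2"), "LOINC:4548-4",
    c("2020-01-01", "2020-02-01", "2020-01-15"),
    value_kind = "numeric", numeric_value = c(6.0, 7.2, 5.5), unit = "%"))
  last <- derived_concept_def("LastHbA1c", "Derived/Labs/HbA1c/Last",
                              "last_value", source = "LOINC:4548-4")
  flag <- derived_concept_def("DiabetesByHbA1c",
                              "Derived/Diagnosis/Diabetes/lastHbA1c_gt_6.4",
                              "compare_derived",
                              source = "DERIVED:LastHbA1c",
                              comparator = ">", threshold = 6.4)
  res <- run_derived_set(en, list(flag, last))
  expect_equal(names(res), c("LastHbA1c", "DiabetesByHbA1c"))
  expect_equal(query_facts(en$store, "DERIVED:DiabetesByHbA1c")$patient_id,
               "p1")
})
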