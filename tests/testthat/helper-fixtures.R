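# Shared fixtures, built in code. The mapping and registry are loaded once
# per test run; extracts are generated randomly under fixed seeds.

.fixtures <- new.env(parent = emptyenv())

fixture_mapping <- function() {
  if (is.null(.fixtures$mapping)) .fixtures$mapping <- load_builtin_mapping()
  .fixtures$mapping
}

fixture_registry <- function() {
  if (is.null(.fixtures$registry)) .fixtures$registry <- builtin_registry()
  .fixtures$registry
}

# Desk-scale cohort: 10 allocated, 2 dropouts, 1 never-user -> 7 users.
small_config <- function(seed = 42L) {
  cohort_config(
    n_allocated = 10, dropouts = c(medical = 1, personal = 1),
    n_never_used = 1,
    se_total = 12, se_users = 5,
    activity_total = 20, activity_users = 6,
    start_date = "2021-01-01", end_date = "2021-03-31",
    seed = seed
  )
}

random_side_effect_entry <- function(mapping = fixture_mapping()) {
  finding <- sample(mapping$findings, 1)[[1]]
  severity <- sample(mapping$severities, 1)[[1]]
  values <- list(
    date = date_value(as.Date("2021-01-01") + sample.int(400, 1)),
    finding = binding_to_coded(finding),
    severity = binding_to_coded(severity)
  )
  if (stats::runif(1) < 0.5) values$value <- text_value("nota libre")
  build_entry("side_effect", values, fixture_registry())
}

random_activity_entry <- function() {
  build_entry("daily_activity", list(
    date = date_value(as.Date("2021-01-01") + sample.int(400, 1)),
    steps = quantity_value(sample(0:15000, 1), "steps"),
    calories = quantity_value(sample(0:900, 1), "kcal"),
    duration = quantity_value(sample(0:240, 1), "min")
  ), fixture_registry())
}

# A structurally valid extract with a random mix of entries of both types.
random_extract <- function(n_entries = sample(1:4, 1),
                           subject = sprintf("XR-%03d", sample.int(60, 1))) {
  entries <- lapply(seq_len(n_entries), function(i) {
    if (stats::runif(1) < 0.5) random_side_effect_entry() else
      random_activity_entry()
  })
  extract_document(
    extract_id = sprintf("x-test-%08d", sample.int(1e7, 1)),
    subject_id = subject,
    time_created = "2021-06-01T12:00:00Z",
    entries = entries
  )
}
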