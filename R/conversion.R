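# Conversion module: the app-side edge component that turns raw, uncoded app
# records into archetype-conformant, SNOMED CT-coded EHR extracts, batched
# per day. Extracts carry only the pseudonymous app-side patient id;
# hospital/study identifiers never enter an extract (communication toward
# the repository is unidirectional).

#' Side-effect app record
#'
#' One row of the app's side-effect table: uncoded literals plus a date.
#'
#' @param app_patient_id Pseudonymous app-side patient id.
#' @param date Report date (`Date` or `YYYY-MM-DD`).
#' @param finding_label Local literal naming the finding (non-empty).
#' @param severity_label Local literal naming the severity.
#' @param value_text Optional free-text elaboration (`NULL`/`NA` to omit).
#' @return A list of class `ehr_side_effect_record`.
#' @export
side_effect_record <- function(app_patient_id, date, finding_label,
                               severity_label, value_text = NULL) {
  stopifnot(is.character(app_patient_id), length(app_patient_id) == 1L,
            nzchar(app_patient_id))
  date <- parse_iso_date(date)
  stopifnot(is.character(finding_label), length(finding_label) == 1L)
  if (!nzchar(trimws(finding_label))) {
    stop("finding_label must be non-empty", call. = FALSE)
  }
  stopifnot(is.character(severity_label), length(severity_label) == 1L)
  if (!is.null(value_text) && (is.na(value_text) || !nzchar(value_text))) {
    value_text <- NULL
  }
  structure(list(app_patient_id = app_patient_id, date = date,
                 finding_label = finding_label, severity_label = severity_label,
                 value_text = value_text),
            class = "ehr_side_effect_record")
}

#' Daily-activity app record
#'
#' @param app_patient_id Pseudonymous app-side patient id.
#' @param date Activity date; at most one record per patient per date.
#' @param steps Step count (non-negative).
#' @param calories Energy expenditure in kcal (non-negative).
#' @param duration Active time in minutes (non-negative).
#' @return A list of class `ehr_activity_record`.
#' @export
activity_record <- function(app_patient_id, date, steps, calories, duration) {
  stopifnot(is.character(app_patient_id), length(app_patient_id) == 1L,
            nzchar(app_patient_id))
  date <- parse_iso_date(date)
  for (v in list(steps = steps, calories = calories, duration = duration)) {
    stopifnot(is.numeric(v), length(v) == 1L, is.finite(v))
  }
  if (steps < 0 || calories < 0 || duration < 0) {
    stop("activity magnitudes must be non-negative", call. = FALSE)
  }
  structure(list(app_patient_id = app_patient_id, date = date,
                 steps = as.numeric(steps), calories = as.numeric(calories),
                 duration = as.numeric(duration)),
            class = "ehr_activity_record")
}

# Deterministic extract id: a content hash of (subject, archetype, date,
# payload), so a re-sent record produces the same id and deduplicates at
# ingestion.
make_extract_id <- function(subject_id, archetype_id, payload_parts) {
  key <- paste(c(subject_id, archetype_id, payload_parts), collapse = "\x1f")
  paste0("x-", substr(rlang::hash(key), 1, 24))
}

#' Convert one side-effect record into a coded extract
#'
#' Produces a one-entry extract under the `side_effect` archetype: finding
#' and severity literals are resolved through the mapping config into coded
#' values; an unmapped literal raises an `ehr_unmapped_term` condition
#' (uncoded data is never emitted). The optional free-text value element is
#' omitted when the record carries none.
#'
#' @param record An [side_effect_record()].
#' @param mapping An [load_mapping()] config.
#' @param registry Archetype registry.
#' @return An [extract_document()] whose `subject_id` is the app patient id.
#' @export
#' @examples
#' m <- load_builtin_mapping()
#' x <- convert_side_effect(
#'   side_effect_record("XR-001", "2021-03-01", "Wakefulness", "Severo",
#'                      "poor sleep"),
#'   m)
#' x$entries[[1]]$elements[[2]]$value$concept_id # "365930002"
convert_side_effect <- function(record, mapping, registry = builtin_registry()) {
  stopifnot(inherits(record, "ehr_side_effect_record"))
  finding <- binding_to_coded(resolve_term(mapping, "findings", record$finding_label))
  severity <- binding_to_coded(resolve_term(mapping, "severities", record$severity_label))
  values <- list(date = date_value(record$date), finding = finding,
                 severity = severity)
  if (!is.null(record$value_text)) values$value <- text_value(record$value_text)
  entry <- build_entry("side_effect", values, registry = registry)
  date_str <- format(record$date, "%Y-%m-%d")
  extract_id <- make_extract_id(record$app_patient_id, "side_effect", c(
    date_str, finding$concept_id, severity$concept_id,
    if (is.null(record$value_text)) "" else record$value_text))
  canonicalize(extract_document(
    extract_id = extract_id,
    subject_id = record$app_patient_id,
    time_created = paste0(date_str, "T00:00:00Z"),
    entries = list(entry)
  ), registry)
}

#' Convert one daily-activity record into an extract
#'
#' One-entry extract under the `daily_activity` archetype with quantity
#' elements in steps, kcal and min.
#'
#' @param record An [activity_record()].
#' @param registry Archetype registry.
#' @return An [extract_document()].
#' @export
convert_activity <- function(record, registry = builtin_registry()) {
  stopifnot(inherits(record, "ehr_activity_record"))
  entry <- build_entry("daily_activity", list(
    date = date_value(record$date),
    steps = quantity_value(record$steps, "steps"),
    calories = quantity_value(record$calories, "kcal"),
    duration = quantity_value(record$duration, "min")
  ), registry = registry)
  date_str <- format(record$date, "%Y-%m-%d")
  extract_id <- make_extract_id(record$app_patient_id, "daily_activity", c(
    date_str, format_magnitude(record$steps), format_magnitude(record$calories),
    format_magnitude(record$duration)))
  canonicalize(extract_document(
    extract_id = extract_id,
    subject_id = record$app_patient_id,
    time_created = paste0(date_str, "T00:00:00Z"),
    entries = list(entry)
  ), registry)
}

#' Convert a day's worth of app records in batch
#'
#' One extract per (patient, date, record type), ordered deterministically by
#' patient id, date, then archetype. Per-record conversion failures (e.g. an
#' unmapped literal) are collected into the batch report instead of aborting
#' the batch: the production contract is unattended daily runs with partial
#' success and logged failures.
#'
#' @param side_effects Data frame with columns `app_patient_id`, `date`,
#'   `finding_label`, `severity_label`, optional `value_text`; or `NULL`.
#' @param activity Data frame with columns `app_patient_id`, `date`, `steps`,
#'   `calories`, `duration`; or `NULL`.
#' @param mapping An [load_mapping()] config.
#' @param registry Archetype registry.
#' @return List with `extracts` (list of [extract_document()]s) and
#'   `failures` (data frame: `record_type`, `app_patient_id`, `date`,
#'   `message`).
#' @export
batch_daily <- function(side_effects = NULL, activity = NULL,
                        mapping = load_builtin_mapping(),
                        registry = builtin_registry()) {
  jobs <- list()
  if (!is.null(side_effects) && nrow(side_effects) > 0L) {
    se <- side_effects
    if (!"value_text" %in% names(se)) se$value_text <- NA_character_
    for (i in seq_len(nrow(se))) {
      jobs[[length(jobs) + 1L]] <- list(
        type = "side_effect", patient = se$app_patient_id[[i]],
        date = as.character(se$date[[i]]),
        make = local({
          row <- se[i, , drop = FALSE]
          function() convert_side_effect(side_effect_record(
            row$app_patient_id, row$date, row$finding_label,
            row$severity_label,
            if (is.na(row$value_text)) NULL else row$value_text
          ), mapping, registry)
        })
      )
    }
  }
  if (!is.null(activity) && nrow(activity) > 0L) {
    dup <- duplicated(activity[c("app_patient_id", "date")])
    if (any(dup)) {
      stop("more than one activity record per patient per date: ",
           paste(activity$app_patient_id[dup], activity$date[dup],
                 collapse = "; "), call. = FALSE)
    }
    for (i in seq_len(nrow(activity))) {
      jobs[[length(jobs) + 1L]] <- list(
        type = "daily_activity", patient = activity$app_patient_id[[i]],
        date = as.character(activity$date[[i]]),
        make = local({
          row <- activity[i, , drop = FALSE]
          function() convert_activity(activity_record(
            row$app_patient_id, row$date, row$steps, row$calories, row$duration
          ), registry)
        })
      )
    }
  }
  if (length(jobs)) {
    key <- order(vapply(jobs, function(j) paste(j$patient, j$date, j$type,
                                                sep = "\x1f"), character(1)),
                 method = "radix")
    jobs <- jobs[key]
  }
  extracts <- list()
  failures <- data.frame(record_type = character(0), app_patient_id = character(0),
                         date = character(0), message = character(0),
                         stringsAsFactors = FALSE)
  for (j in jobs) {
    res <- tryCatch(j$make(), error = function(e) e)
    if (inherits(res, "error")) {
      failures <- rbind(failures, data.frame(
        record_type = j$type, app_patient_id = j$patient, date = j$date,
        message = conditionMessage(res), stringsAsFactors = FALSE))
    } else {
      extracts[[length(extracts) + 1L]] <- res
    }
  }
  list(extracts = extracts, failures = failures)
}

#' Read app records from a JSON file
#'
#' The document holds two arrays, `side_effects` and `daily_activity`, whose
#' objects mirror [side_effect_record()] and [activity_record()] fields.
#'
#' @param path JSON file path.
#' @return List with data frames `side_effects` and `activity`.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("records file not found: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  se <- doc$side_effects
  if (is.null(se) || length(se) == 0L) {
    se <- data.frame(app_patient_id = character(0), date = character(0),
                     finding_label = character(0), severity_label = character(0),
                     value_text = character(0), stringsAsFactors = FALSE)
  }
  act <- doc$daily_activity
  if (is.null(act) || length(act) == 0L) {
    act <- data.frame(app_patient_id = character(0), date = character(0),
                      steps = numeric(0), calories = numeric(0),
                      duration = numeric(0), stringsAsFactors = FALSE)
  }
  list(side_effects = as.data.frame(se), activity = as.data.frame(act))
}

#' Write app records to a JSON file
#'
#' @param side_effects,activity Data frames as in [batch_daily()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_records <- function(side_effects, activity, path) {
  jsonlite::write_json(
    list(side_effects = side_effects, daily_activity = activity),
    path, dataframe = "rows", auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a patient link table (app id to study id) from CSV
#'
#' The link table is repository-side only: it joins the pseudonymous app id
#' to the study id at ingestion time. Both columns must be free of
#' duplicates (the mapping is bijective).
#'
#' @param path CSV with columns `app_patient_id`, `study_id`.
#' @return Data frame of class `ehr_links`.
#' @export
read_links <- function(path) {
  if (!file.exists(path)) stop("link table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  patient_links(df)
}

#' Construct/validate a patient link table
#'
#' @param df Data frame with columns `app_patient_id`, `study_id`.
#' @return The validated data frame, classed `ehr_links`.
#' @export
patient_links <- function(df) {
  if (!all(c("app_patient_id", "study_id") %in% names(df))) {
    stop("link table needs columns app_patient_id, study_id", call. = FALSE)
  }
  if (anyDuplicated(df$app_patient_id) || anyDuplicated(df$study_id)) {
    stop("link table must be bijective: duplicate app_patient_id or study_id",
         call. = FALSE)
  }
  class(df) <- c("ehr_links", "data.frame")
  df
}

#' Write a patient link table to CSV
#'
#' @param links Data frame with columns `app_patient_id`, `study_id`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_links <- function(links, path) {
  utils::write.csv(links[c("app_patient_id", "study_id")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

lookup_study_id <- function(links, app_patient_id) {
  i <- match(app_patient_id, links$app_patient_id)
  if (is.na(i)) {
    rlang::abort(paste0("no study link for app patient '", app_patient_id, "'"),
                 class = "ehr_unlinked_subject", app_patient_id = app_patient_id)
  }
  links$study_id[[i]]
}
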