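# Archetype model: declarative constraint definitions for entry types, plus
# the validation engine that applies them to reference-model instances.
# Archetypes are bundled as JSON documents (one per concept) rather than ADL,
# keeping the dual-model separation: constraints live in data, not code.
# The content model is closed — an element the archetype does not declare is
# an error — and multi-occurrence elements are not supported.

#' Element constraint of an entry archetype
#'
#' @param name Element name.
#' @param value_kind One of `"coded"`, `"date"`, `"quantity"`, `"text"`.
#' @param required Is the element mandatory?
#' @param binding For coded elements only: name of the mapping-config section
#'   (`"findings"` or `"severities"`) whose codes are admissible.
#' @param unit For quantity elements only: the required unit string.
#' @return An object of class `ehr_constraint`.
#' @export
element_constraint <- function(name, value_kind,
                               required = TRUE, binding = NULL, unit = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  value_kind <- match.arg(value_kind, c("coded", "date", "quantity", "text"))
  stopifnot(is.logical(required), length(required) == 1L, !is.na(required))
  if (value_kind == "quantity") {
    if (is.null(unit) || !nzchar(unit)) {
      stop("quantity constraint '", name, "' requires a unit", call. = FALSE)
    }
  } else if (!is.null(unit)) {
    stop("unit only allowed when value_kind is 'quantity' ('", name, "')",
         call. = FALSE)
  }
  if (!is.null(binding) && value_kind != "coded") {
    stop("binding only allowed when value_kind is 'coded' ('", name, "')",
         call. = FALSE)
  }
  structure(list(name = name, value_kind = value_kind, required = required,
                 binding = binding, unit = unit),
            class = "ehr_constraint")
}

#' Entry archetype: the constraint model of one clinical concept
#'
#' @param archetype_id Identifier, e.g. `"side_effect"`.
#' @param concept Human-readable concept name.
#' @param constraints Ordered, non-empty list of [element_constraint()]s with
#'   unique names.
#' @param ontology_class Class name this concept takes in the ontology layer
#'   (defaults to the concept name with spaces replaced by underscores).
#' @return An object of class `ehr_archetype`.
#' @export
entry_archetype <- function(archetype_id, concept, constraints,
                            ontology_class = NULL) {
  stopifnot(is.character(archetype_id), length(archetype_id) == 1L, nzchar(archetype_id))
  stopifnot(is.character(concept), length(concept) == 1L, nzchar(concept))
  stopifnot(is.list(constraints), length(constraints) >= 1L)
  ok <- vapply(constraints, inherits, logical(1), what = "ehr_constraint")
  if (!all(ok)) stop("constraints must all be element_constraint objects", call. = FALSE)
  nms <- vapply(constraints, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("duplicate constraint names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  if (is.null(ontology_class)) ontology_class <- gsub("[^A-Za-z0-9]+", "_", concept)
  structure(list(archetype_id = archetype_id, concept = concept,
                 constraints = constraints, ontology_class = ontology_class),
            class = "ehr_archetype")
}

constraint_names <- function(archetype) {
  vapply(archetype$constraints, `[[`, character(1), "name")
}

#' Load an archetype definition from a JSON document
#'
#' The document mirrors [entry_archetype()]: fields `archetype_id`,
#' `concept`, optional `ontology_class`, and `constraints` (a list of
#' objects with `name`, `value_kind`, `required`, optional `binding`/`unit`).
#' New concepts can be added by dropping in new definition files — no code
#' change is needed, which is the point of the dual model.
#'
#' @param path Path to the JSON file.
#' @return An [entry_archetype()].
#' @export
load_archetype <- function(path) {
  if (!file.exists(path)) stop("archetype file not found: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (f in c("archetype_id", "concept", "constraints")) {
    if (is.null(doc[[f]])) stop("archetype document missing field '", f, "': ",
                                path, call. = FALSE)
  }
  constraints <- lapply(doc$constraints, function(cst) {
    element_constraint(
      name = cst$name,
      value_kind = cst$value_kind,
      required = isTRUE(cst$required),
      binding = cst$binding,
      unit = cst$unit
    )
  })
  entry_archetype(doc$archetype_id, doc$concept, constraints,
                  ontology_class = doc$ontology_class)
}

#' Registry of the bundled archetypes
#'
#' Loads the two entry archetypes this pipeline communicates:
#' `side_effect` (elements date, finding, value, severity; finding and
#' severity are SNOMED CT-bound coded values) and `daily_activity`
#' (elements date, steps, calories, duration as quantities in steps, kcal
#' and min).
#'
#' @param paths Optional character vector of additional archetype JSON files
#'   to load on top of the bundled ones.
#' @return Named list mapping archetype_id to [entry_archetype()].
#' @export
#' @examples
#' names(builtin_registry())
builtin_registry <- function(paths = character(0)) {
  dir <- system.file("extdata", "archetypes", package = "ehr13606")
  files <- c(
    file.path(dir, c("side_effect.json", "daily_activity.json")),
    paths
  )
  archs <- lapply(files, load_archetype)
  stats::setNames(archs, vapply(archs, `[[`, character(1), "archetype_id"))
}

#' Validation report
#'
#' @param issues List of issues, each a list with `severity` (`"error"` or
#'   `"warning"`), `path` (entry/element locator) and `message`.
#' @return Object of class `ehr_validation_report`; `$valid` is `TRUE` iff no
#'   error-severity issue is present.
#' @export
validation_report <- function(issues = list()) {
  sev <- vapply(issues, `[[`, character(1), "severity")
  structure(list(valid = !any(sev == "error"), issues = issues),
            class = "ehr_validation_report")
}

issue <- function(severity, path, message) {
  list(severity = severity, path = path, message = message)
}

#' @export
print.ehr_validation_report <- function(x, ...) {
  cat("<validation report> ", if (x$valid) "VALID" else "INVALID",
      " (", length(x$issues), " issue(s))\n", sep = "")
  for (is in x$issues) {
    cat("  [", is$severity, "] ", is$path, ": ", is$message, "\n", sep = "")
  }
  invisible(x)
}

report_errors <- function(report) {
  Filter(function(i) i$severity == "error", report$issues)
}

#' Validate one entry against its archetype
#'
#' Checks the closed content model: every required element present, no
#' undeclared element, value kinds matching the constraints, quantity units
#' matching, and coded values resolvable in the bound section of the mapping
#' config (a terminology miss is an error, not a warning — the pipeline
#' exists to emit coded data).
#'
#' @param entry An [entry_node()].
#' @param archetype The governing [entry_archetype()]; its id must equal the
#'   entry's `archetype_id` (a mismatch is a usage error, not a validation
#'   finding).
#' @param mapping A [load_mapping()] config supplying the bound value sets.
#' @return An `ehr_validation_report`.
#' @export
validate_entry <- function(entry, archetype, mapping) {
  stopifnot(inherits(entry, "ehr_entry"), inherits(archetype, "ehr_archetype"))
  if (!identical(entry$archetype_id, archetype$archetype_id)) {
    stop("archetype mismatch: entry cites '", entry$archetype_id,
         "' but archetype is '", archetype$archetype_id, "'", call. = FALSE)
  }
  issues <- list()
  base <- paste0("entry[", entry$archetype_id, "]")
  present <- entry_element_names(entry)
  declared <- constraint_names(archetype)

  for (cst in archetype$constraints) {
    path <- paste0(base, "/", cst$name)
    el <- entry_element(entry, cst$name)
    if (is.null(el)) {
      if (cst$required) {
        issues <- c(issues, list(issue("error", path, "required element missing")))
      }
      next
    }
    kind <- value_kind(el$value)
    if (kind != cst$value_kind) {
      issues <- c(issues, list(issue("error", path, paste0(
        "value kind mismatch: expected ", cst$value_kind, ", got ", kind))))
      next
    }
    if (kind == "quantity" && !identical(el$value$unit, cst$unit)) {
      issues <- c(issues, list(issue("error", path, paste0(
        "unit mismatch: expected '", cst$unit, "', got '", el$value$unit, "'"))))
    }
    if (kind == "coded" && !is.null(cst$binding)) {
      ids <- section_concept_ids(mapping, cst$binding)
      if (!el$value$concept_id %in% ids) {
        issues <- c(issues, list(issue("error", path, paste0(
          "concept_id ", el$value$concept_id,
          " not in bound value set '", cst$binding, "'"))))
      }
    }
  }
  for (nm in setdiff(present, declared)) {
    issues <- c(issues, list(issue("error", paste0(base, "/", nm),
                                   "unexpected element (closed content model)")))
  }
  validation_report(issues)
}

#' Validate a whole extract
#'
#' Extract-level checks (known archetype ids, non-empty entry list, subject
#' present) plus the union of the per-entry reports. All problems are
#' reported, none raised.
#'
#' @param extract An [extract_document()].
#' @param registry Archetype registry, see [builtin_registry()].
#' @param mapping A [load_mapping()] config.
#' @return An `ehr_validation_report`.
#' @export
validate_extract <- function(extract, registry = builtin_registry(),
                             mapping = load_builtin_mapping()) {
  stopifnot(inherits(extract, "ehr_extract"))
  issues <- list()
  if (!nzchar(extract$subject_id)) {
    issues <- c(issues, list(issue("error", "extract", "missing subject_id")))
  }
  if (length(extract$entries) == 0L) {
    issues <- c(issues, list(issue("error", "extract", "extract has no entries")))
  }
  for (i in seq_along(extract$entries)) {
    entry <- extract$entries[[i]]
    if (!entry$archetype_id %in% names(registry)) {
      issues <- c(issues, list(issue(
        "error", paste0("entry[", i, "]"),
        paste0("unknown archetype_id '", entry$archetype_id, "'"))))
      next
    }
    rep_i <- validate_entry(entry, registry[[entry$archetype_id]], mapping)
    issues <- c(issues, rep_i$issues)
  }
  validation_report(issues)
}
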