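# Reference-model subset: EHR_EXTRACT / ENTRY / ELEMENT plus four leaf data
# value kinds. The COMPOSITION/SECTION/CLUSTER layers of full EN/ISO 13606 are
# deliberately collapsed: the two entry types carried here need no
# intermediate hierarchy, so extracts hold entries directly.

#' Coded data value
#'
#' A terminology-coded value: a concept identifier within a coding scheme,
#' plus a human-readable display label (which may be a local-language literal,
#' e.g. Spanish). When the scheme is SNOMED CT the concept identifier must be
#' an all-digit SCTID.
#'
#' @param concept_id Concept identifier (non-empty string; all digits for
#'   SNOMED CT).
#' @param scheme_uri Coding-scheme URI, e.g. `"http://snomed.info/sct"`.
#' @param display Human-readable label.
#' @param code_uri Optional concept URI; defaults to the standard SNOMED CT
#'   form `<scheme-host>/id/<concept_id>` when the scheme is SNOMED CT.
#' @return An object of class `ehr_coded`.
#' @export
#' @examples
#' coded_value("365930002", "http://snomed.info/sct", "Wakefulness")
coded_value <- function(concept_id, scheme_uri, display, code_uri = NULL) {
  stopifnot(is.character(concept_id), length(concept_id) == 1L, nzchar(concept_id))
  stopifnot(is.character(scheme_uri), length(scheme_uri) == 1L, nzchar(scheme_uri))
  stopifnot(is.character(display), length(display) == 1L)
  if (is_snomed_scheme(scheme_uri) && !grepl("^[0-9]+$", concept_id)) {
    stop("SNOMED CT concept_id must be all digits, got: ", concept_id, call. = FALSE)
  }
  if (is.null(code_uri)) {
    code_uri <- if (is_snomed_scheme(scheme_uri)) {
      paste0("http://snomed.info/id/", concept_id)
    } else {
      paste0(sub("/+$", "", scheme_uri), "/", concept_id)
    }
  }
  structure(
    list(concept_id = concept_id, scheme_uri = scheme_uri,
         display = display, code_uri = code_uri),
    class = c("ehr_coded", "ehr_value")
  )
}

is_snomed_scheme <- function(scheme_uri) grepl("snomed", scheme_uri, ignore.case = TRUE)

#' Calendar-date data value (day precision, ISO 8601)
#'
#' @param value A `Date` or a string in `YYYY-MM-DD` form.
#' @return An object of class `ehr_date`.
#' @export
date_value <- function(value) {
  d <- parse_iso_date(value)
  structure(list(value = d), class = c("ehr_date", "ehr_value"))
}

parse_iso_date <- function(value) {
  if (inherits(value, "Date")) {
    if (is.na(value)) stop("date value is NA", call. = FALSE)
    return(value)
  }
  stopifnot(is.character(value), length(value) == 1L)
  if (!grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", value)) {
    stop("not an ISO 8601 date (YYYY-MM-DD): ", value, call. = FALSE)
  }
  d <- as.Date(value, format = "%Y-%m-%d")
  if (is.na(d) || format(d, "%Y-%m-%d") != value) {
    stop("not a valid calendar date: ", value, call. = FALSE)
  }
  d
}

#' Physical-quantity data value
#'
#' @param magnitude Non-negative number.
#' @param unit Non-empty unit string (e.g. `"steps"`, `"kcal"`, `"min"`).
#' @return An object of class `ehr_quantity`.
#' @export
quantity_value <- function(magnitude, unit) {
  stopifnot(is.numeric(magnitude), length(magnitude) == 1L, is.finite(magnitude))
  stopifnot(is.character(unit), length(unit) == 1L, nzchar(unit))
  if (magnitude < 0) stop("quantity magnitude must be >= 0, got ", magnitude, call. = FALSE)
  structure(list(magnitude = as.numeric(magnitude), unit = unit),
            class = c("ehr_quantity", "ehr_value"))
}

#' Free-text data value
#'
#' @param value A single string.
#' @return An object of class `ehr_text`.
#' @export
text_value <- function(value) {
  stopifnot(is.character(value), length(value) == 1L, !is.na(value))
  structure(list(value = value), class = c("ehr_text", "ehr_value"))
}

#' @export
print.ehr_value <- function(x, ...) {
  cat("<", class(x)[1], "> ", format_value_text(x), "\n", sep = "")
  invisible(x)
}

value_kind <- function(v) {
  if (inherits(v, "ehr_coded")) return("coded")
  if (inherits(v, "ehr_date")) return("date")
  if (inherits(v, "ehr_quantity")) return("quantity")
  if (inherits(v, "ehr_text")) return("text")
  stop("not a reference-model data value: ", paste(class(v), collapse = "/"),
       call. = FALSE)
}

format_value_text <- function(v) {
  switch(value_kind(v),
    coded = paste0(v$display, " [", v$concept_id, "]"),
    date = format(v$value, "%Y-%m-%d"),
    quantity = paste0(format_magnitude(v$magnitude), " ", v$unit),
    text = v$value
  )
}

# Canonical decimal rendering used by the XML layer: integers without a
# decimal point, otherwise up to 6 fractional digits with trailing zeros
# stripped. Never scientific notation.
format_magnitude <- function(x) {
  s <- sprintf("%.6f", x)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

#' Element node: a leaf of the record hierarchy holding one data value
#'
#' @param node_id Archetype node identifier (e.g. `"at0001"`).
#' @param name Element name, unique within its entry.
#' @param value One reference-model data value (see [coded_value()],
#'   [date_value()], [quantity_value()], [text_value()]).
#' @return An object of class `ehr_element`.
#' @export
element_node <- function(node_id, name, value) {
  stopifnot(is.character(node_id), length(node_id) == 1L, nzchar(node_id))
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  value_kind(value) # type check
  structure(list(node_id = node_id, name = name, value = value),
            class = "ehr_element")
}

#' Entry node: one observation or clinical action
#'
#' An entry is governed by an archetype and carries a non-empty list of
#' elements with unique names. `rc_id` is the repository-assigned record
#' identifier, absent until ingestion.
#'
#' @param archetype_id Identifier of the governing archetype.
#' @param elements List of [element_node()] objects, non-empty, names unique.
#' @param rc_id Optional repository record identifier (single string or
#'   `NULL`).
#' @return An object of class `ehr_entry`.
#' @export
entry_node <- function(archetype_id, elements, rc_id = NULL) {
  stopifnot(is.character(archetype_id), length(archetype_id) == 1L, nzchar(archetype_id))
  stopifnot(is.list(elements), length(elements) >= 1L)
  ok <- vapply(elements, inherits, logical(1), what = "ehr_element")
  if (!all(ok)) stop("elements must all be element_node objects", call. = FALSE)
  nms <- vapply(elements, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("duplicate element names within entry: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  ids <- vapply(elements, `[[`, character(1), "node_id")
  if (anyDuplicated(ids)) {
    stop("duplicate node_ids within entry: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (!is.null(rc_id)) {
    rc_id <- as.character(rc_id)
    stopifnot(length(rc_id) == 1L, nzchar(rc_id))
  }
  structure(list(archetype_id = archetype_id, elements = elements, rc_id = rc_id),
            class = "ehr_entry")
}

entry_element_names <- function(entry) {
  vapply(entry$elements, `[[`, character(1), "name")
}

entry_element <- function(entry, name) {
  i <- match(name, entry_element_names(entry))
  if (is.na(i)) NULL else entry$elements[[i]]
}

#' EHR extract document
#'
#' The unit of communication between the app side and the repository: one
#' pseudonymous subject, an audit timestamp, and one or more entries. The
#' subject identifier is the app-side pseudonym; hospital or study
#' identifiers never appear in an extract (unidirectional privacy contract).
#'
#' @param extract_id Globally unique extract identifier.
#' @param subject_id Pseudonymous app-side patient identifier.
#' @param time_created Creation timestamp: `POSIXct` or ISO 8601 string
#'   `YYYY-MM-DDTHH:MM:SSZ` (UTC, second precision).
#' @param entries Non-empty list of [entry_node()] objects.
#' @return An object of class `ehr_extract`.
#' @export
extract_document <- function(extract_id, subject_id, time_created, entries) {
  stopifnot(is.character(extract_id), length(extract_id) == 1L, nzchar(extract_id))
  stopifnot(is.character(subject_id), length(subject_id) == 1L, nzchar(subject_id))
  time_created <- canonical_timestamp(time_created)
  stopifnot(is.list(entries), length(entries) >= 1L)
  ok <- vapply(entries, inherits, logical(1), what = "ehr_entry")
  if (!all(ok)) stop("entries must all be entry_node objects", call. = FALSE)
  structure(
    list(extract_id = extract_id, subject_id = subject_id,
         time_created = time_created, entries = entries),
    class = "ehr_extract"
  )
}

canonical_timestamp <- function(x) {
  if (inherits(x, "POSIXt")) {
    return(format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  }
  stopifnot(is.character(x), length(x) == 1L)
  if (!grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}T[0-9]{2}:[0-9]{2}:[0-9]{2}Z$", x)) {
    stop("timestamp must be UTC ISO 8601 with seconds (YYYY-MM-DDTHH:MM:SSZ): ",
         x, call. = FALSE)
  }
  x
}

#' @export
print.ehr_extract <- function(x, ...) {
  cat("<ehr_extract> ", x$extract_id, "\n", sep = "")
  cat("  subject: ", x$subject_id, "   created: ", x$time_created, "\n", sep = "")
  for (e in x$entries) {
    cat("  entry [", e$archetype_id, "]",
        if (!is.null(e$rc_id)) paste0(" rc_id=", e$rc_id) else "", "\n", sep = "")
    for (el in e$elements) {
      cat("    ", el$node_id, " ", el$name, " = ", format_value_text(el$value),
          "\n", sep = "")
    }
  }
  invisible(x)
}

#' Build an entry from a name-to-value map
#'
#' Constructs an [entry_node()] with one element per named value. Node ids are
#' assigned deterministically (`at0001`, `at0002`, ...) from the governing
#' archetype's declaration order; names the archetype does not declare are
#' numbered after the declared ones, in alphabetical order.
#'
#' @param archetype_id Identifier of the governing archetype.
#' @param values Named list mapping element names to data values. Dates may be
#'   given as `Date` or `YYYY-MM-DD` strings, free text as plain strings;
#'   coded and quantity values must be built explicitly.
#' @param registry Archetype registry used for node-id and element ordering;
#'   defaults to [builtin_registry()].
#' @return An [entry_node()].
#' @export
#' @examples
#' build_entry("daily_activity", list(
#'   date = "2021-03-01",
#'   steps = quantity_value(8000, "steps"),
#'   calories = quantity_value(320, "kcal"),
#'   duration = quantity_value(75, "min")
#' ))
build_entry <- function(archetype_id, values, registry = builtin_registry()) {
  stopifnot(is.list(values), length(values) >= 1L)
  nms <- names(values)
  if (is.null(nms) || any(!nzchar(nms))) {
    stop("all values must be named", call. = FALSE)
  }
  if (anyDuplicated(nms)) {
    stop("duplicate element names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  declared <- character(0)
  if (archetype_id %in% names(registry)) {
    declared <- vapply(registry[[archetype_id]]$constraints, `[[`, character(1), "name")
  }
  ord <- order(element_order_key(nms, declared))
  nms <- nms[ord]
  values <- values[ord]
  node_ids <- node_id_for(nms, declared)
  elements <- vector("list", length(values))
  for (i in seq_along(values)) {
    elements[[i]] <- element_node(node_ids[[i]], nms[[i]], coerce_value(values[[i]]))
  }
  entry_node(archetype_id, elements)
}

# Declared names keep archetype order; undeclared names sort after them
# alphabetically. Returns a sortable numeric key.
element_order_key <- function(nms, declared) {
  key <- match(nms, declared)
  extra <- is.na(key)
  key[extra] <- length(declared) + rank(nms[extra], ties.method = "first")
  key
}

node_id_for <- function(nms, declared) {
  sprintf("at%04d", element_order_key(nms, declared))
}

coerce_value <- function(v) {
  if (inherits(v, "ehr_value")) return(v)
  if (inherits(v, "Date")) return(date_value(v))
  if (is.character(v) && length(v) == 1L) {
    if (grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", v)) return(date_value(v))
    return(text_value(v))
  }
  stop("cannot coerce to a reference-model data value: ",
       paste(class(v), collapse = "/"), call. = FALSE)
}

#' Canonicalize an extract for deterministic serialization
#'
#' Sorts entries by (archetype id, first date-valued element, rc_id-or-empty)
#' and, within each entry, orders elements by the governing archetype's
#' declared order (undeclared names last, alphabetically). Idempotent and
#' invariant under permutation of the input entry order.
#'
#' @param extract An [extract_document()].
#' @param registry Archetype registry supplying element order; defaults to
#'   [builtin_registry()].
#' @return The canonical-form extract.
#' @export
canonicalize <- function(extract, registry = builtin_registry()) {
  stopifnot(inherits(extract, "ehr_extract"))
  entries <- lapply(extract$entries, canonicalize_entry, registry = registry)
  keys <- vapply(entries, entry_sort_key, character(1))
  extract$entries <- entries[order(keys, method = "radix")]
  extract
}

canonicalize_entry <- function(entry, registry) {
  declared <- character(0)
  if (entry$archetype_id %in% names(registry)) {
    declared <- vapply(registry[[entry$archetype_id]]$constraints, `[[`,
                       character(1), "name")
  }
  nms <- entry_element_names(entry)
  entry$elements <- entry$elements[order(element_order_key(nms, declared))]
  entry
}

entry_sort_key <- function(entry) {
  first_date <- ""
  for (el in entry$elements) {
    if (inherits(el$value, "ehr_date")) {
      first_date <- format(el$value$value, "%Y-%m-%d")
      break
    }
  }
  paste(entry$archetype_id, first_date, rc_id_or_empty(entry), sep = "\x1f")
}

rc_id_or_empty <- function(entry) if (is.null(entry$rc_id)) "" else entry$rc_id

# Field-level equality of data values, used by round-trip tests and dedupe.
values_equal <- function(a, b) {
  if (value_kind(a) != value_kind(b)) return(FALSE)
  switch(value_kind(a),
    coded = identical(a[c("concept_id", "scheme_uri", "display", "code_uri")],
                      b[c("concept_id", "scheme_uri", "display", "code_uri")]),
    date = identical(format(a$value, "%Y-%m-%d"), format(b$value, "%Y-%m-%d")),
    quantity = isTRUE(all.equal(a$magnitude, b$magnitude)) &&
      identical(a$unit, b$unit),
    text = identical(a$value, b$value)
  )
}

#' Field-level equality of two extracts (in canonical form)
#'
#' @param a,b Extracts to compare.
#' @param registry Archetype registry used for canonicalization.
#' @return `TRUE` when ids, subject, timestamp and all entry/element fields
#'   agree.
#' @export
extracts_equal <- function(a, b, registry = builtin_registry()) {
  a <- canonicalize(a, registry)
  b <- canonicalize(b, registry)
  if (!identical(a$extract_id, b$extract_id)) return(FALSE)
  if (!identical(a$subject_id, b$subject_id)) return(FALSE)
  if (!identical(a$time_created, b$time_created)) return(FALSE)
  if (length(a$entries) != length(b$entries)) return(FALSE)
  for (i in seq_along(a$entries)) {
    ea <- a$entries[[i]]; eb <- b$entries[[i]]
    if (!identical(ea$archetype_id, eb$archetype_id)) return(FALSE)
    if (!identical(rc_id_or_empty(ea), rc_id_or_empty(eb))) return(FALSE)
    if (length(ea$elements) != length(eb$elements)) return(FALSE)
    for (j in seq_along(ea$elements)) {
      la <- ea$elements[[j]]; lb <- eb$elements[[j]]
      if (!identical(la$name, lb$name)) return(FALSE)
      if (!identical(la$node_id, lb$node_id)) return(FALSE)
      if (!values_equal(la$value, lb$value)) return(FALSE)
    }
  }
  TRUE
}
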