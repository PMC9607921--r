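# SNOMED CT binding layer. The app database stores uncoded local literals
# (Spanish names); this module loads the JSON mapping config and resolves
# literals to coded values. Resolution is a pure, total lookup over the
# config's label set: a miss raises a typed condition rather than letting
# uncoded data through.

#' Normalize a local label for lookup
#'
#' Accent-folds (Unicode Latin-ASCII transliteration), lowercases, trims and
#' collapses internal whitespace, so `"  Náusea "` and `"nausea"` meet.
#'
#' @param x Character vector of labels.
#' @return Normalized labels.
#' @export
normalize_label <- function(x) {
  x <- stringi::stri_trans_general(x, "Latin-ASCII")
  x <- stringi::stri_trans_tolower(x)
  gsub("[[:space:]]+", " ", trimws(x))
}

#' Term binding: one local literal bound to a SNOMED CT concept
#'
#' @param local_label App literal (e.g. a Spanish name).
#' @param concept_id All-digit concept identifier.
#' @param display Preferred term.
#' @param scheme_uri Coding-scheme URI.
#' @param code_uri Concept URI; defaults to the standard
#'   `http://snomed.info/id/<conceptId>` form and must end with the
#'   concept id.
#' @return Object of class `ehr_term_binding`.
#' @export
term_binding <- function(local_label, concept_id, display,
                         scheme_uri = "http://snomed.info/sct",
                         code_uri = NULL) {
  stopifnot(is.character(local_label), length(local_label) == 1L, nzchar(local_label))
  stopifnot(is.character(concept_id), length(concept_id) == 1L)
  if (!grepl("^[0-9]+$", concept_id)) {
    stop("concept_id must be all digits: '", concept_id, "'", call. = FALSE)
  }
  stopifnot(is.character(display), length(display) == 1L, nzchar(display))
  if (is.null(code_uri)) code_uri <- paste0("http://snomed.info/id/", concept_id)
  if (!endsWith(code_uri, concept_id)) {
    stop("code_uri must end with the concept_id: ", code_uri, call. = FALSE)
  }
  structure(list(local_label = local_label, concept_id = concept_id,
                 display = display, scheme_uri = scheme_uri, code_uri = code_uri),
            class = "ehr_term_binding")
}

#' Load a terminology mapping config from JSON
#'
#' The config is a JSON document with a `scheme_uri`, a `findings` section
#' and a `severities` section; each section maps a local label to an object
#' with `concept_id` and `display` (see the schema shipped under
#' `inst/extdata/schema/mapping-config.schema.json`). Duplicate labels
#' within a section — compared after normalization (case, accents,
#' whitespace) — are a config error. An empty section loads with a warning.
#' Each binding is additionally indexed under its normalized preferred term,
#' so both the app literal and the display term resolve.
#'
#' @param path Path to the JSON mapping file.
#' @return Object of class `ehr_mapping` with `$findings`, `$severities`
#'   (lists of [term_binding()]s) and `$scheme_uri`.
#' @export
load_mapping <- function(path) {
  if (!file.exists(path)) stop("mapping file not found: ", path, call. = FALSE)
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed JSON in mapping file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(doc$scheme_uri) || !nzchar(doc$scheme_uri)) {
    stop("mapping config missing 'scheme_uri' (", path, ")", call. = FALSE)
  }
  sections <- list()
  for (sec in c("findings", "severities")) {
    raw <- doc[[sec]]
    if (is.null(raw)) stop("mapping config missing section '", sec, "' (",
                           path, ")", call. = FALSE)
    if (length(raw) == 0L) {
      warning("mapping section '", sec, "' is empty (", path, ")", call. = FALSE)
      sections[[sec]] <- list()
      next
    }
    labels <- names(raw)
    dup <- duplicated(normalize_label(labels))
    if (any(dup)) {
      stop("duplicate local label(s) in section '", sec, "': ",
           paste(unique(labels[dup]), collapse = ", "), call. = FALSE)
    }
    sections[[sec]] <- lapply(seq_along(raw), function(i) {
      b <- raw[[i]]
      if (is.null(b$concept_id) || is.null(b$display)) {
        stop("binding '", sec, "/", labels[[i]],
             "' must have concept_id and display", call. = FALSE)
      }
      term_binding(labels[[i]], b$concept_id, b$display,
                   scheme_uri = doc$scheme_uri, code_uri = b$code_uri)
    })
    names(sections[[sec]]) <- labels
  }
  cfg <- structure(list(findings = sections$findings,
                        severities = sections$severities,
                        scheme_uri = doc$scheme_uri),
                   class = "ehr_mapping")
  cfg$index <- build_mapping_index(cfg)
  cfg
}

# Lookup index: normalized local label plus normalized display, per section.
# A key reachable through two routes must point at the same concept.
build_mapping_index <- function(cfg) {
  idx <- list()
  for (sec in c("findings", "severities")) {
    keys <- character(0)
    vals <- integer(0)
    bindings <- cfg[[sec]]
    for (i in seq_along(bindings)) {
      for (k in unique(normalize_label(c(bindings[[i]]$local_label,
                                         bindings[[i]]$display)))) {
        j <- match(k, keys)
        if (is.na(j)) {
          keys <- c(keys, k); vals <- c(vals, i)
        } else if (bindings[[vals[[j]]]]$concept_id != bindings[[i]]$concept_id) {
          stop("label '", k, "' in section '", sec,
               "' is ambiguous between concept_ids ",
               bindings[[vals[[j]]]]$concept_id, " and ",
               bindings[[i]]$concept_id, call. = FALSE)
        }
      }
    }
    idx[[sec]] <- stats::setNames(vals, keys)
  }
  idx
}

#' Path of the bundled synthetic mapping config
#'
#' @return File path under the installed package.
#' @export
builtin_mapping_path <- function() {
  system.file("extdata", "mapping", "app-mapping-synthetic.json",
              package = "ehr13606", mustWork = TRUE)
}

#' Load the bundled synthetic mapping config
#'
#' Twelve side-effect findings and three severities. Only the
#' Wakefulness finding (365930002) and the mild/moderate/severe qualifiers
#' carry real SNOMED CT codes; the rest are clearly marked placeholders.
#'
#' @return An `ehr_mapping`.
#' @export
load_builtin_mapping <- function() load_mapping(builtin_mapping_path())

#' Resolve a local literal to its term binding
#'
#' @param config An `ehr_mapping` from [load_mapping()].
#' @param section `"findings"` or `"severities"`.
#' @param label The literal to resolve; matched case-insensitively after
#'   accent folding and trimming, against local labels and display terms.
#' @return The matching [term_binding()].
#' @export
#' @examples
#' m <- load_builtin_mapping()
#' resolve_term(m, "findings", "Wakefulness")$concept_id
resolve_term <- function(config, section = c("findings", "severities"), label) {
  stopifnot(inherits(config, "ehr_mapping"))
  section <- match.arg(section)
  stopifnot(is.character(label), length(label) == 1L)
  key <- normalize_label(label)
  i <- config$index[[section]][key]
  if (is.na(i)) {
    rlang::abort(
      paste0("no ", sub("s$", "", section), " binding for literal '", label, "'"),
      class = "ehr_unmapped_term",
      label = label, section = section
    )
  }
  config[[section]][[i]]
}

section_concept_ids <- function(config, section) {
  vapply(config[[section]], `[[`, character(1), "concept_id")
}

#' Coded value from a term binding
#'
#' @param binding A [term_binding()].
#' @return A [coded_value()] carrying the binding's concept id, scheme,
#'   display and code URI.
#' @export
binding_to_coded <- function(binding) {
  coded_value(binding$concept_id, binding$scheme_uri, binding$display,
              code_uri = binding$code_uri)
}
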