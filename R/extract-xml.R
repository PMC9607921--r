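# Wire format: bit-stable XML serialization of extracts, with a published
# strict XSD. Documents are canonicalized before writing and carry no
# write-time timestamps, so identical extracts always serialize to identical
# bytes — which is what makes content-hash dedupe at ingestion meaningful.

EXTRACT_NS <- "urn:ehr13606:extract:1"

#' Path of the published extract XSD
#'
#' @return File path under the installed package.
#' @export
extract_xsd_path <- function() {
  system.file("extdata", "schema", "ehr-extract.xsd",
              package = "ehr13606", mustWork = TRUE)
}

extract_schema <- function() xml2::read_xml(extract_xsd_path())

#' Serialize an extract to canonical XML
#'
#' UTF-8, LF line endings, deterministic attribute and element order (the
#' document is canonicalized first). Serialization is refused for a
#' structurally invalid extract (no entries, empty entry).
#'
#' @param extract An [extract_document()].
#' @param path Optional output file; when `NULL` the XML is returned as a
#'   single string.
#' @param registry Archetype registry used for canonical element order.
#' @return The XML string (invisibly when `path` is given).
#' @export
write_extract <- function(extract, path = NULL, registry = builtin_registry()) {
  stopifnot(inherits(extract, "ehr_extract"))
  if (length(extract$entries) == 0L) {
    stop("refusing to serialize extract with no entries", call. = FALSE)
  }
  for (e in extract$entries) {
    if (!inherits(e, "ehr_entry") || length(e$elements) == 0L) {
      stop("refusing to serialize structurally invalid entry", call. = FALSE)
    }
  }
  extract <- canonicalize(extract, registry)
  doc <- xml2::xml_new_root(
    "ehrExtract", xmlns = EXTRACT_NS,
    extractId = extract$extract_id,
    subjectId = extract$subject_id,
    timeCreated = extract$time_created
  )
  for (entry in extract$entries) {
    attrs <- c(archetypeId = entry$archetype_id)
    if (!is.null(entry$rc_id)) attrs <- c(attrs, rcId = entry$rc_id)
    e_node <- do.call(xml2::xml_add_child, c(list(doc, "entry"), as.list(attrs)))
    for (el in entry$elements) {
      el_node <- xml2::xml_add_child(e_node, "element",
                                     nodeId = el$node_id, name = el$name)
      v <- el$value
      v_attrs <- switch(value_kind(v),
        coded = list(kind = "coded", conceptId = v$concept_id,
                     schemeUri = v$scheme_uri, codeUri = v$code_uri),
        date = list(kind = "date"),
        quantity = list(kind = "quantity", unit = v$unit),
        text = list(kind = "text")
      )
      v_node <- do.call(xml2::xml_add_child, c(list(el_node, "value"), v_attrs))
      xml2::xml_text(v_node) <- switch(value_kind(v),
        coded = v$display,
        date = format(v$value, "%Y-%m-%d"),
        quantity = format_magnitude(v$magnitude),
        text = v$value
      )
    }
  }
  tf <- tempfile(fileext = ".xml")
  on.exit(unlink(tf), add = TRUE)
  xml2::write_xml(doc, tf, options = "format")
  txt <- readChar(tf, file.info(tf)$size, useBytes = TRUE)
  Encoding(txt) <- "UTF-8"
  txt <- gsub("\r\n", "\n", txt, fixed = TRUE)
  if (!endsWith(txt, "\n")) txt <- paste0(txt, "\n")
  if (!is.null(path)) {
    writeBin(charToRaw(enc2utf8(txt)), path)
    return(invisible(txt))
  }
  txt
}

#' Parse and schema-validate an extract XML document
#'
#' Rejects anything the published XSD does not allow (unknown elements,
#' missing attributes, bad node ids) and additionally enforces the
#' kind-conditional attribute rules and value formats the XSD cannot
#' express: coded values need conceptId/schemeUri/codeUri, quantities need a
#' unit and a non-negative decimal magnitude, dates must be valid ISO dates.
#'
#' @param x A file path, an XML string, or raw XML bytes.
#' @return The parsed [extract_document()] in canonical form.
#' @export
read_extract <- function(x) {
  doc <- tryCatch(
    xml2::read_xml(x),
    error = function(e) stop("XML parse error: ", conditionMessage(e), call. = FALSE)
  )
  ok <- xml2::xml_validate(doc, extract_schema())
  if (!isTRUE(ok)) {
    stop("extract fails schema validation:\n  ",
         paste(attr(ok, "errors"), collapse = "\n  "), call. = FALSE)
  }
  root <- xml2::xml_root(doc)
  entries <- lapply(xml2::xml_find_all(root, "./*[local-name()='entry']"), function(e_node) {
    elements <- lapply(xml2::xml_find_all(e_node, "./*[local-name()='element']"),
                       parse_element_node)
    rc_id <- xml2::xml_attr(e_node, "rcId")
    entry_node(
      archetype_id = xml2::xml_attr(e_node, "archetypeId"),
      elements = elements,
      rc_id = if (is.na(rc_id)) NULL else rc_id
    )
  })
  canonicalize(extract_document(
    extract_id = xml2::xml_attr(root, "extractId"),
    subject_id = xml2::xml_attr(root, "subjectId"),
    time_created = xml2::xml_attr(root, "timeCreated"),
    entries = entries
  ))
}

parse_element_node <- function(el_node) {
  v_node <- xml2::xml_find_first(el_node, "./*[local-name()='value']")
  kind <- xml2::xml_attr(v_node, "kind")
  txt <- xml2::xml_text(v_node)
  name <- xml2::xml_attr(el_node, "name")
  need <- function(attr) {
    a <- xml2::xml_attr(v_node, attr)
    if (is.na(a)) stop("element '", name, "': kind '", kind,
                       "' requires attribute '", attr, "'", call. = FALSE)
    a
  }
  forbid <- function(attrs) {
    for (a in attrs) {
      if (!is.na(xml2::xml_attr(v_node, a))) {
        stop("element '", name, "': attribute '", a,
             "' not allowed for kind '", kind, "'", call. = FALSE)
      }
    }
  }
  value <- switch(kind,
    coded = {
      forbid("unit")
      coded_value(need("conceptId"), need("schemeUri"), txt,
                  code_uri = need("codeUri"))
    },
    date = {
      forbid(c("conceptId", "schemeUri", "codeUri", "unit"))
      date_value(txt)
    },
    quantity = {
      forbid(c("conceptId", "schemeUri", "codeUri"))
      if (!grepl("^[0-9]+(\\.[0-9]+)?$", txt)) {
        stop("element '", name, "': quantity magnitude is not a non-negative decimal: '",
             txt, "'", call. = FALSE)
      }
      quantity_value(as.numeric(txt), need("unit"))
    },
    text = {
      forbid(c("conceptId", "schemeUri", "codeUri", "unit"))
      text_value(txt)
    },
    stop("unknown value kind '", kind, "'", call. = FALSE)
  )
  element_node(xml2::xml_attr(el_node, "nodeId"), name, value)
}

#' Write a set of extracts as one XML file each
#'
#' Files are named `<subject>_<archetype>_<date>.xml` from the first entry's
#' archetype and first date-valued element, matching the daily batch layout.
#'
#' @param extracts List of [extract_document()]s.
#' @param dir Output directory (created if missing).
#' @param registry Archetype registry.
#' @return Data frame manifest with columns `extract_id`, `file`.
#' @export
write_extract_set <- function(extracts, dir, registry = builtin_registry()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- data.frame(extract_id = character(0), file = character(0),
                         stringsAsFactors = FALSE)
  for (x in extracts) {
    entry <- x$entries[[1]]
    date <- ""
    for (el in entry$elements) {
      if (inherits(el$value, "ehr_date")) {
        date <- format(el$value$value, "%Y-%m-%d"); break
      }
    }
    file <- file.path(dir, paste0(x$subject_id, "_", entry$archetype_id,
                                  "_", date, ".xml"))
    write_extract(x, path = file, registry = registry)
    manifest <- rbind(manifest, data.frame(extract_id = x$extract_id,
                                           file = file, stringsAsFactors = FALSE))
  }
  manifest
}
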