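# Ontology-based clinical repository stand-in. Archetyped concepts are
# modeled as subclasses of an ISO 13606 ENTRY class; terminology-bound
# concepts (findings, severities) become classes that are *instances* of a
# SNOMED CT metaclass, carrying concept_id and code_uri annotations — the
# metaclass pattern represented with plain rdf:type links so no OWL-Full
# reasoning is ever needed. Patient data ingests as one instance per entry,
# keyed by a repository-wide monotonically increasing rc_id, with
# idempotency keyed on the extract's content-hash id.
#
# Triples are held as a data frame (s, p, o, o_kind) in prefixed-name form
# and persisted as Turtle. No R RDF library is involved: the emitter and
# reader cover exactly the small Turtle subset this repository produces
# (prefix declarations plus one triple per line).

RDF_PREFIXES <- c(
  rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  owl  = "http://www.w3.org/2002/07/owl#",
  xsd  = "http://www.w3.org/2001/XMLSchema#",
  iso  = "urn:ehr13606:iso13606#",
  onto = "urn:ehr13606:ontoclinic#",
  inst = "urn:ehr13606:instance#"
)

triple_frame <- function(s = character(0), p = character(0), o = character(0),
                         o_kind = character(0), dtype = character(0)) {
  data.frame(s = s, p = p, o = o, o_kind = o_kind, dtype = dtype,
             stringsAsFactors = FALSE)
}

tr <- function(s, p, o, o_kind = "iri", dtype = NA_character_) {
  triple_frame(s, p, o, o_kind, dtype)
}

lit <- function(s, p, o, dtype = NA_character_) {
  tr(s, p, as.character(o), o_kind = "literal", dtype = dtype)
}

class_local_name <- function(x) {
  nm <- gsub("[^A-Za-z0-9]+", "_", x)
  gsub("^_+|_+$", "", nm)
}

binding_class_iri <- function(binding) {
  paste0("onto:", class_local_name(binding$display))
}

#' Build the base ontology for a registry and mapping
#'
#' Produces the ISO 13606 layer (`iso:ENTRY`, `iso:ELEMENT`, the `iso:rc_id`
#' property), one concept class per archetype as a subclass of `iso:ENTRY`,
#' one property per element constraint, a SNOMED CT metaclass, and one
#' concept class per terminology binding typed as an instance of that
#' metaclass and annotated with its concept id and code URI.
#'
#' @param registry Archetype registry ([builtin_registry()]); may be empty.
#' @param mapping Terminology mapping ([load_mapping()]); may be empty.
#' @return Data frame of triples (columns `s`, `p`, `o`, `o_kind`, `dtype`)
#'   in prefixed-name form.
#' @export
build_base_ontology <- function(registry = builtin_registry(),
                                mapping = load_builtin_mapping()) {
  t <- rbind(
    tr("iso:ENTRY", "rdf:type", "owl:Class"),
    lit("iso:ENTRY", "rdfs:label", "EN/ISO 13606 ENTRY"),
    tr("iso:ELEMENT", "rdf:type", "owl:Class"),
    lit("iso:ELEMENT", "rdfs:label", "EN/ISO 13606 ELEMENT"),
    tr("iso:rc_id", "rdf:type", "owl:DatatypeProperty"),
    lit("iso:rc_id", "rdfs:label", "record identifier"),
    tr("onto:SNOMED_CT_Concept", "rdf:type", "owl:Class"),
    lit("onto:SNOMED_CT_Concept", "rdfs:label", "SNOMED CT metaclass"),
    tr("onto:concept_id", "rdf:type", "owl:AnnotationProperty"),
    tr("onto:code_uri", "rdf:type", "owl:AnnotationProperty"),
    tr("onto:subject", "rdf:type", "owl:DatatypeProperty"),
    tr("onto:source_extract", "rdf:type", "owl:DatatypeProperty"),
    tr("onto:time_created", "rdf:type", "owl:DatatypeProperty")
  )
  for (arch in registry) {
    cls <- paste0("onto:", arch$ontology_class)
    t <- rbind(t,
      tr(cls, "rdf:type", "owl:Class"),
      tr(cls, "rdfs:subClassOf", "iso:ENTRY"),
      lit(cls, "rdfs:label", arch$concept)
    )
    for (cst in arch$constraints) {
      prop <- paste0("onto:", cst$name)
      if (cst$value_kind == "coded") {
        t <- rbind(t,
          tr(prop, "rdf:type", "owl:ObjectProperty"),
          tr(prop, "rdfs:range", "onto:SNOMED_CT_Concept"))
      } else {
        rng <- switch(cst$value_kind, date = "xsd:date",
                      quantity = "xsd:decimal", text = "xsd:string")
        t <- rbind(t,
          tr(prop, "rdf:type", "owl:DatatypeProperty"),
          tr(prop, "rdfs:range", rng))
      }
      t <- rbind(t, lit(prop, "rdfs:label", cst$name))
    }
  }
  if (inherits(mapping, "ehr_mapping")) {
    for (sec in c("findings", "severities")) {
      for (b in mapping[[sec]]) {
        cls <- binding_class_iri(b)
        t <- rbind(t,
          tr(cls, "rdf:type", "owl:Class"),
          tr(cls, "rdf:type", "onto:SNOMED_CT_Concept"),
          lit(cls, "onto:concept_id", b$concept_id),
          tr(cls, "onto:code_uri", paste0("<", b$code_uri, ">")),
          lit(cls, "rdfs:label", b$display)
        )
      }
    }
  }
  unique(t)
}

#' Create an in-memory clinical repository
#'
#' Holds the base ontology plus ingested patient instances; mutable (an
#' environment), so [ingest_extract()] updates it in place.
#'
#' @param registry Archetype registry.
#' @param mapping Terminology mapping.
#' @return Object of class `ehr_repository`.
#' @export
new_repository <- function(registry = builtin_registry(),
                           mapping = load_builtin_mapping()) {
  repo <- new.env(parent = emptyenv())
  repo$registry <- registry
  repo$mapping <- mapping
  repo$triples <- build_base_ontology(registry, mapping)
  repo$next_rc <- 1L
  repo$extract_index <- list()
  # concept_id -> binding class IRI, for coded-value instantiation
  cid <- character(0)
  for (sec in c("findings", "severities")) {
    for (b in mapping[[sec]]) cid[b$concept_id] <- binding_class_iri(b)
  }
  repo$concept_class <- cid
  class(repo) <- "ehr_repository"
  repo
}

#' @export
print.ehr_repository <- function(x, ...) {
  n_inst <- length(unlist(lapply(x$extract_index, function(r) r$rc_id)))
  cat("<ehr_repository> ", nrow(x$triples), " triples, ",
      length(x$extract_index), " extracts, ", n_inst, " instances\n", sep = "")
  invisible(x)
}

instance_iri <- function(rc_id) paste0("inst:rec-", rc_id)

#' Ingest an extract into the repository
#'
#' Validates the extract against the archetypes and mapping, resolves the
#' pseudonymous app subject to its study id through the link table, and
#' inserts one instance per entry with a fresh sequential `rc_id`.
#' Ingestion is atomic (a failure leaves the repository unchanged) and
#' idempotent: re-ingesting an extract whose `extract_id` has been seen
#' returns the original insertion results without inserting anything.
#'
#' @param repo An [new_repository()] object.
#' @param extract An [extract_document()].
#' @param links Patient link table ([patient_links()]).
#' @return Data frame of insertion results with columns `rc_id` (integer)
#'   and `iri`.
#' @export
ingest_extract <- function(repo, extract, links) {
  stopifnot(inherits(repo, "ehr_repository"), inherits(extract, "ehr_extract"))
  cached <- repo$extract_index[[extract$extract_id]]
  if (!is.null(cached)) return(cached)
  report <- validate_extract(extract, repo$registry, repo$mapping)
  if (!report$valid) {
    msgs <- vapply(report_errors(report), function(i) paste0(i$path, ": ", i$message),
                   character(1))
    rlang::abort(paste0("extract ", extract$extract_id,
                        " rejected by validation:\n  ",
                        paste(msgs, collapse = "\n  ")),
                 class = "ehr_validation_failure", report = report)
  }
  study_id <- lookup_study_id(links, extract$subject_id) # may abort, repo untouched
  extract <- canonicalize(extract, repo$registry)

  new_triples <- triple_frame()
  results <- data.frame(rc_id = integer(0), iri = character(0),
                        stringsAsFactors = FALSE)
  rc <- repo$next_rc
  for (entry in extract$entries) {
    arch <- repo$registry[[entry$archetype_id]]
    iri <- instance_iri(rc)
    t <- rbind(
      tr(iri, "rdf:type", paste0("onto:", arch$ontology_class)),
      lit(iri, "iso:rc_id", rc, dtype = "xsd:integer"),
      lit(iri, "onto:subject", study_id),
      lit(iri, "onto:source_extract", extract$extract_id),
      lit(iri, "onto:time_created", extract$time_created)
    )
    for (el in entry$elements) {
      prop <- paste0("onto:", el$name)
      v <- el$value
      t <- rbind(t, switch(value_kind(v),
        coded = {
          cls <- repo$concept_class[v$concept_id]
          if (is.na(cls)) stop("no ontology class for concept_id ", v$concept_id,
                               call. = FALSE)
          tr(iri, prop, unname(cls))
        },
        date = lit(iri, prop, format(v$value, "%Y-%m-%d"), dtype = "xsd:date"),
        quantity = lit(iri, prop, format_magnitude(v$magnitude),
                       dtype = "xsd:decimal"),
        text = lit(iri, prop, v$value)
      ))
    }
    new_triples <- rbind(new_triples, t)
    results <- rbind(results, data.frame(rc_id = rc, iri = iri,
                                         stringsAsFactors = FALSE))
    rc <- rc + 1L
  }
  # commit
  repo$triples <- rbind(repo$triples, new_triples)
  repo$next_rc <- rc
  repo$extract_index[[extract$extract_id]] <- results
  results
}

#' Ingest a set of extracts, collecting failures
#'
#' @param repo Repository.
#' @param extracts List of extracts.
#' @param links Link table.
#' @return List with `results` (row-bound insertion results), `n_ingested`,
#'   `n_duplicates` (idempotent re-sends), and `failures` (data frame
#'   `extract_id`, `message`).
#' @export
ingest_batch <- function(repo, extracts, links) {
  results <- data.frame(rc_id = integer(0), iri = character(0),
                        stringsAsFactors = FALSE)
  failures <- data.frame(extract_id = character(0), message = character(0),
                         stringsAsFactors = FALSE)
  n_new <- 0L; n_dup <- 0L
  for (x in extracts) {
    seen <- !is.null(repo$extract_index[[x$extract_id]])
    res <- tryCatch(ingest_extract(repo, x, links), error = function(e) e)
    if (inherits(res, "error")) {
      failures <- rbind(failures, data.frame(
        extract_id = x$extract_id, message = conditionMessage(res),
        stringsAsFactors = FALSE))
    } else {
      if (seen) n_dup <- n_dup + 1L else n_new <- n_new + 1L
      results <- rbind(results, res)
    }
  }
  list(results = results, n_ingested = n_new, n_duplicates = n_dup,
       failures = failures)
}

#' Percentage, rounded half-up to one decimal
#'
#' Matches how the repository report prints shares (e.g. 234/1100 = 21.3).
#' Returns 0 when the denominator is 0.
#'
#' @param numerator,denominator Non-negative counts.
#' @return Percentage as a number with one decimal.
#' @export
#' @examples
#' pct(234, 1100) # 21.3
#' pct(12, 62)    # 19.4
pct <- function(numerator, denominator) {
  stopifnot(is.numeric(numerator), is.numeric(denominator))
  if (any(numerator < 0) || any(denominator < 0)) {
    stop("pct() requires non-negative inputs", call. = FALSE)
  }
  out <- floor(1000 * numerator / denominator + 0.5) / 10
  out[rep_len(denominator == 0, length(out))] <- 0
  out
}

repo_instances <- function(repo) {
  classes <- vapply(repo$registry, function(a) paste0("onto:", a$ontology_class),
                    character(1))
  t <- repo$triples
  typ <- t[t$p == "rdf:type" & t$o %in% classes, , drop = FALSE]
  if (nrow(typ) == 0L) {
    return(data.frame(iri = character(0), archetype_id = character(0),
                      subject = character(0), stringsAsFactors = FALSE))
  }
  arch_of_class <- stats::setNames(names(repo$registry), classes)
  subj <- t[t$p == "onto:subject", , drop = FALSE]
  data.frame(
    iri = typ$s,
    archetype_id = unname(arch_of_class[typ$o]),
    subject = subj$o[match(typ$s, subj$s)],
    stringsAsFactors = FALSE
  )
}

#' Repository count report
#'
#' Per archetype: number of ingested extracts (one entry per extract in this
#' pipeline, so instance counts), their share of all extracts, the number of
#' distinct patients with at least one extract of that type, and their share
#' of the app-user total. The user denominator is supplied by the caller
#' because never-users leave no trace in the repository.
#'
#' @param repo Repository.
#' @param total_users Denominator for the patient percentages (distinct
#'   linked app users in the study).
#' @return Object of class `ehr_repo_report`: a list with `table` (one row
#'   per archetype), `total_extracts` and `total_users`.
#' @export
count_report <- function(repo, total_users) {
  stopifnot(is.numeric(total_users), length(total_users) == 1L, total_users >= 0)
  inst <- repo_instances(repo)
  archs <- names(repo$registry)
  n_ext <- vapply(archs, function(a) sum(inst$archetype_id == a), integer(1))
  n_pat <- vapply(archs, function(a)
    length(unique(inst$subject[inst$archetype_id == a])), integer(1))
  total <- sum(n_ext)
  tab <- data.frame(
    archetype_id = archs,
    concept = vapply(repo$registry, `[[`, character(1), "concept"),
    n_extracts = unname(n_ext),
    pct_extracts = pct(unname(n_ext), total),
    n_patients = unname(n_pat),
    pct_patients = pct(unname(n_pat), total_users),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(table = tab, total_extracts = total,
                 total_users = as.integer(total_users)),
            class = "ehr_repo_report")
}

#' @export
print.ehr_repo_report <- function(x, ...) {
  cat("Number of extracts communicated\n")
  cat(sprintf("%-16s %-22s %-18s\n", "EHR archetype",
              sprintf("Extracts (N=%d), n (%%)", x$total_extracts),
              sprintf("Patients (N=%d), n (%%)", x$total_users)))
  for (i in seq_len(nrow(x$table))) {
    r <- x$table[i, ]
    cat(sprintf("%-16s %-22s %-18s\n", r$concept,
                sprintf("%d (%.1f)", r$n_extracts, r$pct_extracts),
                sprintf("%d (%.1f)", r$n_patients, r$pct_patients)))
  }
  invisible(x)
}

#' Serialize a count report to JSON
#'
#' @param report An `ehr_repo_report`.
#' @param path Optional output file.
#' @return JSON string (invisibly when `path` given).
#' @export
report_json <- function(report, path = NULL) {
  obj <- list(total_extracts = report$total_extracts,
              total_users = report$total_users,
              archetypes = report$table)
  txt <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                          pretty = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(as.character(txt)))
  }
  as.character(txt)
}

#' Export ingested instances back to extract documents
#'
#' Rebuilds one single-entry extract per instance from the stored triples
#' (coded values recovered through the ontology's concept-class
#' annotations, quantity units through the archetype). Used to show that
#' repository content still conforms to the originating archetypes.
#'
#' @param repo Repository.
#' @return List of [extract_document()]s; subjects carry the repository-side
#'   study id.
#' @export
export_extracts <- function(repo) {
  inst <- repo_instances(repo)
  t <- repo$triples
  lapply(seq_len(nrow(inst)), function(i) {
    iri <- inst$iri[[i]]
    arch <- repo$registry[[inst$archetype_id[[i]]]]
    mine <- t[t$s == iri, , drop = FALSE]
    get1 <- function(p) mine$o[match(p, mine$p)]
    values <- list()
    for (cst in arch$constraints) {
      row <- mine[mine$p == paste0("onto:", cst$name), , drop = FALSE]
      if (nrow(row) == 0L) next
      values[[cst$name]] <- switch(cst$value_kind,
        date = date_value(row$o[[1]]),
        quantity = quantity_value(as.numeric(row$o[[1]]), cst$unit),
        text = text_value(row$o[[1]]),
        coded = {
          cls <- row$o[[1]]
          ann <- t[t$s == cls, , drop = FALSE]
          code_uri <- ann$o[match("onto:code_uri", ann$p)]
          coded_value(
            concept_id = ann$o[match("onto:concept_id", ann$p)],
            scheme_uri = repo$mapping$scheme_uri,
            display = ann$o[match("rdfs:label", ann$p)],
            code_uri = gsub("^<|>$", "", code_uri)
          )
        }
      )
    }
    entry <- build_entry(arch$archetype_id, values, repo$registry)
    entry$rc_id <- sub("\\^\\^.*$", "", get1("iso:rc_id"))
    extract_document(
      extract_id = get1("onto:source_extract"),
      subject_id = get1("onto:subject"),
      time_created = get1("onto:time_created"),
      entries = list(entry)
    )
  })
}
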