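make_links <- function(n = 10) {
  patient_links(data.frame(
    app_patient_id = sprintf("XR-%03d", seq_len(n)),
    study_id = sprintf("ASC-%04d", 1000 + seq_len(n)),
    stringsAsFactors = FALSE))
}

test_that("the base ontology models concepts as ENTRY subclasses with SCT metaclass bindings", {
  t <- build_base_ontology(fixture_registry(), fixture_mapping())
  has <- function(s, p, o) any(t$s == s & t$p == p & t$o == o)
  expect_true(has("onto:Secondary_effect", "rdfs:subClassOf", "iso:ENTRY"))
  expect_true(has("onto:Daily_activity", "rdfs:subClassOf", "iso:ENTRY"))
  expect_true(has("iso:ENTRY", "rdf:type", "owl:Class"))
  expect_true(has("iso:rc_id", "rdf:type", "owl:DatatypeProperty"))
  # the Severe class is an instance of the SNOMED CT metaclass with its code
  expect_true(has("onto:Severe", "rdf:type", "onto:SNOMED_CT_Concept"))
  expect_true(any(t$s == "onto:Severe" & t$p == "onto:concept_id" &
                    t$o == "24484000"))
  expect_true(has("onto:Wakefulness", "rdf:type", "onto:SNOMED_CT_Concept"))
  # one property per element constraint
  for (p in c("onto:date", "onto:finding", "onto:value", "onto:severity",
              "onto:steps", "onto:calories", "onto:duration")) {
    expect_true(p %in% t$s)
  }
  # every binding class is typed as a metaclass instance
  metaclass_instances <- t$s[t$p == "rdf:type" & t$o == "onto:SNOMED_CT_Concept"]
  n_bindings <- length(fixture_mapping()$findings) +
    length(fixture_mapping()$severities)
  expect_length(unique(metaclass_instances), n_bindings)
})

test_that("an empty registry and mapping still yield the ISO 13606 layer", {
  t <- build_base_ontology(registry = list(),
                           mapping = structure(list(findings = list(),
                                                    severities = list()),
                                               class = "ehr_mapping"))
  expect_true(any(t$s == "iso:ENTRY"))
  expect_false(any(grepl("^onto:Secondary", t$s)))
})

test_that("ingestion instantiates properties and assigns sequential rc_ids", {
  m <- fixture_mapping()
  repo <- new_repository(fixture_registry(), m)
  links <- make_links()
  x <- convert_side_effect(
    side_effect_record("XR-001", "2021-03-01", "Vigilia", "Severo", "mal"), m)
  res <- ingest_extract(repo, x, links)
  expect_equal(res$rc_id, 1L)
  t <- repo$triples
  iri <- res$iri
  expect_true(any(t$s == iri & t$p == "rdf:type" & t$o == "onto:Secondary_effect"))
  for (p in c("onto:date", "onto:finding", "onto:value", "onto:severity",
              "iso:rc_id", "onto:subject")) {
    expect_true(any(t$s == iri & t$p == p), label = p)
  }
  expect_true(any(t$s == iri & t$p == "onto:finding" & t$o == "onto:Wakefulness"))
  expect_true(any(t$s == iri & t$p == "onto:subject" & t$o == "ASC-1001"))

  y <- convert_activity(activity_record("XR-002", "2021-03-02", 500, 20, 5))
  res2 <- ingest_extract(repo, y, links)
  expect_equal(res2$rc_id, 2L)
})

test_that("ingestion is idempotent and conserves instance counts", {
  m <- fixture_mapping()
  repo <- new_repository(fixture_registry(), m)
  links <- make_links()
  x <- convert_side_effect(
    side_effect_record("XR-001", "2021-03-01", "Vigilia", "Severo"), m)
  r1 <- ingest_extract(repo, x, links)
  n_triples <- nrow(repo$triples)
  r2 <- ingest_extract(repo, x, links)
  expect_identical(r1, r2)
  expect_equal(nrow(repo$triples), n_triples)
  expect_equal(count_report(repo, 10)$total_extracts, 1L)

  # batch re-send: all duplicates, nothing inserted
  res <- ingest_batch(repo, list(x, x), links)
  expect_equal(res$n_ingested, 0L)
  expect_equal(res$n_duplicates, 2L)
  expect_equal(nrow(repo$triples), n_triples)
})

test_that("unknown subjects and invalid extracts are rejected atomically", {
  m <- fixture_mapping()
  repo <- new_repository(fixture_registry(), m)
  links <- make_links(2)
  before <- nrow(repo$triples)
  x <- convert_side_effect(
    side_effect_record("XR-999", "2021-03-01", "Vigilia", "Leve"), m)
  expect_error(ingest_extract(repo, x, links), class = "ehr_unlinked_subject")
  expect_equal(nrow(repo$triples), before)
  expect_equal(repo$next_rc, 1L)

  bad <- extract_document("x-bad", "XR-001", "2021-06-01T12:00:00Z", list(
    entry_node("side_effect", list(
      element_node("at0001", "date", date_value("2021-01-01"))))))
  expect_error(ingest_extract(repo, bad, links), class = "ehr_validation_failure")
  expect_equal(nrow(repo$triples), before)
})

test_that("pct matches the study's printed rounding (half-up, one decimal)", {
  expect_equal(pct(234, 1100), 21.3)
  expect_equal(pct(866, 1100), 78.7)
  expect_equal(pct(34, 47), 72.3)
  expect_equal(pct(38, 47), 80.9)
  expect_equal(pct(12, 62), 19.4)
  expect_equal(pct(47, 62), 75.8)
  expect_equal(pct(3, 62), 4.8)
  expect_equal(pct(0, 47), 0)
  expect_equal(pct(5, 0), 0)
  expect_equal(pct(1, 16), 6.3) # 6.25 rounds up, not to even
  expect_error(pct(-1, 10), "non-negative")
})

test_that("count reports cover degenerate repositories", {
  repo <- new_repository(fixture_registry(), fixture_mapping())
  rep0 <- count_report(repo, 47)
  expect_equal(rep0$total_extracts, 0L)
  expect_equal(rep0$table$n_extracts, c(0L, 0L))
  expect_equal(rep0$table$pct_extracts, c(0, 0))

  links <- make_links(1)
  x <- convert_activity(activity_record("XR-001", "2021-01-01", 10, 1, 1))
  ingest_extract(repo, x, links)
  rep1 <- count_report(repo, 1)
  tab <- rep1$table
  expect_equal(tab$pct_extracts[tab$archetype_id == "daily_activity"], 100)
  expect_equal(tab$pct_extracts[tab$archetype_id == "side_effect"], 0)
})

test_that("per-report extract percentages sum to 100 within rounding slack", {
  m <- fixture_mapping()
  set.seed(77)
  for (trial in 1:5) {
    repo <- new_repository(fixture_registry(), m)
    links <- make_links(8)
    n_se <- sample.int(15, 1); n_act <- sample.int(15, 1)
    finding_labels <- vapply(m$findings, `[[`, character(1), "local_label")
    for (i in seq_len(n_se)) {
      ingest_extract(repo, convert_side_effect(side_effect_record(
        sprintf("XR-%03d", sample.int(8, 1)),
        as.Date("2021-01-01") + i, sample(finding_labels, 1), "Leve"), m), links)
    }
    for (i in seq_len(n_act)) {
      ingest_extract(repo, convert_activity(activity_record(
        sprintf("XR-%03d", sample.int(8, 1)),
        as.Date("2021-01-01") + i, i * 10, i, i)), links)
    }
    rep <- count_report(repo, 8)
    expect_lte(abs(sum(rep$table$pct_extracts) - 100), 0.1)
  }
})

test_that("repository instances export back to archetype-valid extracts", {
  m <- fixture_mapping(); reg <- fixture_registry()
  repo <- new_repository(reg, m)
  links <- make_links()
  x1 <- convert_side_effect(
    side_effect_record("XR-003", "2021-05-01", "Cefalea", "Moderado", "nota"), m)
  x2 <- convert_activity(activity_record("XR-004", "2021-05-02", 1234, 56, 18))
  ingest_extract(repo, x1, links)
  ingest_extract(repo, x2, links)
  exported <- export_extracts(repo)
  expect_length(exported, 2L)
  for (e in exported) {
    rep <- validate_extract(e, reg, m)
    expect_true(rep$valid)
    expect_false(is.null(e$entries[[1]]$rc_id))
  }
  # coded content survives the round trip through triples
  se <- exported[[which(vapply(exported, function(e)
    e$entries[[1]]$archetype_id, character(1)) == "side_effect")]]
  nms <- vapply(se$entries[[1]]$elements, `[[`, character(1), "name")
  finding <- se$entries[[1]]$elements[[match("finding", nms)]]$value
  expect_equal(finding$concept_id, "900000104")
})

test_that("rc_ids stay unique and stable under re-ingestion", {
  m <- fixture_mapping()
  repo <- new_repository(fixture_registry(), m)
  links <- make_links()
  xs <- lapply(1:6, function(i) convert_activity(activity_record(
    sprintf("XR-%03d", (i %% 3) + 1), as.Date("2021-01-01") + i,
    i * 100, i, i)))
  res1 <- ingest_batch(repo, xs, links)
  expect_equal(res1$results$rc_id, 1:6)
  res2 <- ingest_batch(repo, xs, links)
  expect_identical(res1$results, res2$results)
  expect_equal(repo$next_rc, 7L)
})

test_that("the Turtle file round-trips and is valid Turtle for an independent parser", {
  m <- fixture_mapping()
  repo <- new_repository(fixture_registry(), m)
  links <- make_links()
  ingest_extract(repo, convert_side_effect(side_effect_record(
    "XR-001", "2021-03-01", "Vigilia", "Severo", "texto con \"comillas\"\ny salto"), m),
    links)
  tf <- tempfile(fileext = ".ttl")
  write_ontology(repo, tf)
  back <- read_ontology(tf)
  expect_equal(nrow(back$triples), nrow(repo$triples))
  expect_equal(back$triples$s, repo$triples$s)
  expect_equal(back$triples$o, repo$triples$o)
  expect_equal(back$prefixes[["onto"]], "urn:ehr13606:ontoclinic#")

  # independent oracle: the Python rdflib parser must accept the file
  py <- Sys.which("python")
  if (nzchar(py)) {
    out <- suppressWarnings(system2(py, c("-c", shQuote(paste0(
      "import rdflib; g = rdflib.Graph(); g.parse('", tf,
      "', format='turtle'); print(len(g))"))), stdout = TRUE, stderr = TRUE))
    status <- attr(out, "status")
    if (is.null(status)) {
      expect_equal(as.integer(out[length(out)]), nrow(unique(repo$triples)))
    }
  }
})
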