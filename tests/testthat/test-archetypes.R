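test_that("the bundled registry holds exactly the two study archetypes", {
  reg <- fixture_registry()
  expect_length(reg, 2L)
  expect_setequal(names(reg), c("side_effect", "daily_activity"))
  se <- reg$side_effect
  expect_equal(vapply(se$constraints, `[[`, character(1), "name"),
               c("date", "finding", "value", "severity"))
  expect_equal(vapply(se$constraints, `[[`, character(1), "value_kind"),
               c("date", "coded", "text", "coded"))
  req <- vapply(se$constraints, `[[`, logical(1), "required")
  expect_equal(req, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(se$constraints[[2]]$binding, "findings")
  expect_equal(se$constraints[[4]]$binding, "severities")

  da <- reg$daily_activity
  expect_equal(vapply(da$constraints, `[[`, character(1), "name"),
               c("date", "steps", "calories", "duration"))
  expect_true(all(vapply(da$constraints, `[[`, logical(1), "required")))
  expect_equal(vapply(da$constraints[-1], `[[`, character(1), "unit"),
               c("steps", "kcal", "min"))
})

test_that("constraint invariants: unit iff quantity, binding only for coded", {
  expect_error(element_constraint("steps", "quantity"), "unit")
  expect_error(element_constraint("date", "date", unit = "d"), "unit only")
  expect_error(element_constraint("date", "date", binding = "findings"),
               "binding only")
})

test_that("a complete mapped side-effect entry validates cleanly", {
  m <- fixture_mapping(); reg <- fixture_registry()
  entry <- build_entry("side_effect", list(
    date = "2021-03-01",
    finding = binding_to_coded(resolve_term(m, "findings", "Vigilia")),
    value = text_value("poor sleep"),
    severity = binding_to_coded(resolve_term(m, "severities", "Leve"))
  ))
  rep <- validate_entry(entry, reg$side_effect, m)
  expect_true(rep$valid)
  expect_length(rep$issues, 0L)
})

test_that("validation flags each kind of archetype violation", {
  m <- fixture_mapping(); reg <- fixture_registry()
  # missing required finding
  no_finding <- build_entry("side_effect", list(
    date = "2021-03-01",
    severity = binding_to_coded(resolve_term(m, "severities", "Leve"))
  ))
  rep <- validate_entry(no_finding, reg$side_effect, m)
  expect_false(rep$valid)
  errs <- Filter(function(i) i$severity == "error", rep$issues)
  expect_length(errs, 1L)
  expect_match(errs[[1]]$path, "finding")

  # unexpected element from the other archetype (closed content)
  mixed <- build_entry("side_effect", list(
    date = "2021-03-01",
    finding = binding_to_coded(resolve_term(m, "findings", "Vigilia")),
    severity = binding_to_coded(resolve_term(m, "severities", "Leve")),
    steps = quantity_value(100, "steps")
  ))
  rep <- validate_entry(mixed, reg$side_effect, m)
  expect_false(rep$valid)
  expect_true(any(vapply(rep$issues, function(i)
    grepl("unexpected element", i$message), logical(1))))

  # kind mismatch: date carried as text
  wrong_kind <- build_entry("side_effect", list(
    date = text_value("yesterday"),
    finding = binding_to_coded(resolve_term(m, "findings", "Vigilia")),
    severity = binding_to_coded(resolve_term(m, "severities", "Leve"))
  ))
  expect_false(validate_entry(wrong_kind, reg$side_effect, m)$valid)

  # unit mismatch
  bad_unit <- build_entry("daily_activity", list(
    date = "2021-03-01", steps = quantity_value(10, "paces"),
    calories = quantity_value(1, "kcal"), duration = quantity_value(1, "min")
  ))
  rep <- validate_entry(bad_unit, reg$daily_activity, m)
  expect_false(rep$valid)
  expect_true(any(vapply(rep$issues, function(i)
    grepl("unit mismatch", i$message), logical(1))))

  # coded value outside the bound value set
  alien <- build_entry("side_effect", list(
    date = "2021-03-01",
    finding = coded_value("123456789", "http://snomed.info/sct", "Unknown"),
    severity = binding_to_coded(resolve_term(m, "severities", "Leve"))
  ))
  rep <- validate_entry(alien, reg$side_effect, m)
  expect_false(rep$valid)
  expect_true(any(vapply(rep$issues, function(i)
    grepl("not in bound value set", i$message), logical(1))))
})

test_that("archetype mismatch is a usage error, not a validation finding", {
  m <- fixture_mapping(); reg <- fixture_registry()
  entry <- random_activity_entry()
  expect_error(validate_entry(entry, reg$side_effect, m), "mismatch")
})

test_that("extract-level validation reports unknown archetypes and empty extracts", {
  m <- fixture_mapping(); reg <- fixture_registry()
  set.seed(5)
  good <- extract_document("x-1", "XR-001", "2021-06-01T12:00:00Z",
                           list(random_side_effect_entry(),
                                random_activity_entry()))
  expect_true(validate_extract(good, reg, m)$valid)

  foo <- entry_node("foo", list(element_node("at0001", "date",
                                             date_value("2021-01-01"))))
  bad <- extract_document("x-2", "XR-001", "2021-06-01T12:00:00Z", list(foo))
  rep <- validate_extract(bad, reg, m)
  expect_false(rep$valid)
  expect_match(rep$issues[[1]]$message, "unknown archetype")

  empty <- good
  empty$entries <- list()
  expect_false(validate_extract(empty, reg, m)$valid)
})

test_that("closed-content property: adding or removing elements breaks validity", {
  m <- fixture_mapping(); reg <- fixture_registry()
  set.seed(11)
  for (i in 1:10) {
    entry <- random_side_effect_entry()
    arch <- reg$side_effect
    expect_true(validate_entry(entry, arch, m)$valid)
    # add a fresh-name element
    plus <- entry
    plus$elements <- c(plus$elements,
                       list(element_node("at0099", "extra", text_value("x"))))
    plus <- entry_node(plus$archetype_id, plus$elements)
    expect_false(validate_entry(plus, arch, m)$valid)
    # drop each required element in turn
    req <- c("date", "finding", "severity")
    for (nm in req) {
      nms <- vapply(entry$elements, `[[`, character(1), "name")
      minus <- entry_node(entry$archetype_id, entry$elements[nms != nm])
      expect_false(validate_entry(minus, arch, m)$valid)
    }
  }
})

test_that("archetype definitions load from user-supplied files", {
  tf <- tempfile(fileext = ".json")
  writeLines('{
    "archetype_id": "qol_score",
    "concept": "Quality of life score",
    "constraints": [
      {"name": "date", "value_kind": "date", "required": true},
      {"name": "score", "value_kind": "quantity", "required": true, "unit": "points"}
    ]
  }', tf)
  reg <- builtin_registry(paths = tf)
  expect_length(reg, 3L)
  expect_equal(reg$qol_score$ontology_class, "Quality_of_life_score")
  entry <- build_entry("qol_score", list(
    date = "2021-05-05", score = quantity_value(70, "points")), reg)
  expect_true(validate_entry(entry, reg$qol_score, fixture_mapping())$valid)
})
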