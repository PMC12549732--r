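twin_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- fixture_dir()
      co <- read_cohort_csv(file.path(fx, "cohort.csv"))
      tr <- read_trial_csv(file.path(fx, "trials", "child-001.csv"),
                           file.path(fx, "trials", "child-001.json"))
      m <- extract_trial_metrics(tr, co[1, ])
      cache <<- list(child = co[1, ], metrics = m,
                     doc = build_twin(co[1, ], m, "T24", salt = "test-salt",
                                      created = "1970-01-01T00:00:00Z"))
    }
    cache
  }
})

test_that("pseudonymisation is deterministic, salted and format-stable", {
  expect_identical(pseudonymise("child-001", "s"), pseudonymise("child-001", "s"))
  expect_false(identical(pseudonymise("child-001", "s1"),
                         pseudonymise("child-001", "s2")))
  expect_false(identical(pseudonymise("child-001", "s"),
                         pseudonymise("child-002", "s")))
  expect_match(pseudonymise("x", "y"), "^[0-9a-f]{32}$")
  expect_error(pseudonymise("id", ""), class = "gaitwin_validation_error")
  expect_error(pseudonymise("", "salt"), class = "gaitwin_validation_error")
})

test_that("twin documents carry the full observation battery without raw identifiers", {
  fxt <- twin_fixture()
  doc <- fxt$doc
  expect_gte(length(doc$observations), 40)
  codes <- vapply(doc$observations, `[[`, "", "code")
  expect_true(all(c("GW-GA", "GW-BWT", "GW-RISK", "GW-IMG", "GW-NUTR",
                    "GW-M-strideT", "GW-M-RR_v") %in% codes))
  expect_false(any(duplicated(codes)))
  js <- to_fhir_json(doc)
  ttl <- to_rdf_turtle(doc)
  expect_false(grepl("child-001", js, fixed = TRUE))
  expect_false(grepl("child-001", ttl, fixed = TRUE))
  expect_error(build_twin(fxt$child, transform(fxt$metrics, child_id = "other")),
               class = "gaitwin_validation_error")
})

test_that("FHIR JSON round trip is lossless and counts resources", {
  fxt <- twin_fixture()
  js <- to_fhir_json(fxt$doc)
  back <- from_fhir_json(js)
  expect_equal(back, fxt$doc)
  bundle <- jsonlite::parse_json(js)
  expect_equal(length(bundle$entry), 1 + length(fxt$doc$observations))
  expect_error(from_fhir_json("{not json"), class = "gaitwin_parse_error")
  # a numeric observation without a unit is rejected, naming the code
  doc2 <- fxt$doc
  doc2$observations[[3]]$unit <- NULL
  doc2$observations[[3]]$value <- 1.5
  err <- tryCatch(to_fhir_json(doc2), error = function(e) e)
  expect_s3_class(err, "gaitwin_validation_error")
  expect_match(conditionMessage(err), doc2$observations[[3]]$code, fixed = TRUE)
})

test_that("Turtle output is canonical and parses back to the same bytes", {
  fxt <- twin_fixture()
  ttl <- to_rdf_turtle(fxt$doc)
  reparsed <- parse_turtle_subset(ttl)
  expect_identical(gaitwin:::serialize_triples(reparsed), ttl)
  pat_nodes <- unique(reparsed$subject[reparsed$object == "fhir:Patient"])
  obs_nodes <- unique(reparsed$subject[reparsed$object == "fhir:Observation"])
  expect_length(pat_nodes, 1)
  expect_equal(length(obs_nodes), length(fxt$doc$observations))
  ga <- reparsed[reparsed$predicate == "gw:unit" &
                 grepl("gw-ga$", reparsed$subject), "object"]
  expect_equal(ga, '"wk"')
})

test_that("knowledge-graph export links children, exams, metrics and risk factors", {
  fx <- fixture_dir()
  co <- read_cohort_csv(file.path(fx, "cohort.csv"))
  docs <- lapply(1:2, function(i) {
    tr <- read_trial_csv(file.path(fx, "trials", paste0(co$child_id[i], ".csv")),
                         file.path(fx, "trials", paste0(co$child_id[i], ".json")))
    build_twin(co[i, ], extract_trial_metrics(tr, co[i, ]), "T24",
               created = "1970-01-01T00:00:00Z")
  })
  kg <- export_knowledge_graph(docs)
  e <- kg$edges
  expect_equal(sum(e$rel == "instance_of" & e$to == "class:Child"), 2)
  expect_equal(sum(e$rel == "has_assessment"), 2)
  # acyclic over has_assessment: no exam is also a source of has_assessment
  ha <- e[e$rel == "has_assessment", ]
  expect_false(any(ha$to %in% ha$from))
  metric_nodes <- sub("^metric-", "", e$to[e$rel == "measured_by"])
  expect_true(all(metric_nodes %in% metric_schema()))
  expect_true(any(e$rel == "has_risk_factor"))
  reparsed <- parse_turtle_subset(kg$turtle)
  expect_identical(gaitwin:::serialize_triples(reparsed), kg$turtle)
  expect_error(export_knowledge_graph(list()),
               class = "gaitwin_validation_error")
})

test_that("two timepoints for one child coexist without code collisions", {
  fxt <- twin_fixture()
  doc_b <- build_twin(fxt$child, fxt$metrics, "T18", salt = "test-salt",
                      created = "1970-01-01T00:00:00Z")
  merged <- fxt$doc
  merged$observations <- c(merged$observations, doc_b$observations)
  expect_silent(validate_twin(merged))
  dup <- fxt$doc
  dup$observations <- c(dup$observations, dup$observations[1])
  expect_error(validate_twin(dup), class = "gaitwin_validation_error")
})
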