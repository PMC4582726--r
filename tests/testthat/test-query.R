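test_that("SELECT over the empty graph returns an empty table", {
  out <- runQuery(emptyGraph(), "SELECT ?x WHERE { ?x mcfe:part_of mcfe:embryo . }")
  expect_equal(nrow(out), 0L)
  expect_named(out, "x")
})

test_that("basic graph patterns bind subjects, and predicates can be variables", {
  g <- refGraph()
  out <- runQuery(g, "SELECT ?x WHERE { ?x mcfe:part_of mcfe:embryo . }")
  expect_true("mcfe:left_kidney" %in% out$x)
  # schema-level querying: a variable in predicate position
  outp <- runQuery(g, "SELECT ?p WHERE { mcfe:left_kidney ?p mcfe:embryo . }")
  expect_equal(outp$p, "mcfe:part_of")
})

test_that("joins across patterns and FILTER comparisons work", {
  g <- refGraph()
  out <- runQuery(g, paste(
    "SELECT ?i ?g ?t WHERE {",
    "  ?s mcfe:describes ?i .",
    "  ?s mcfe:has_geometrical_representation ?g .",
    "  ?s mcfe:at_stage ?t .",
    "}"))
  expect_true(all(c("i", "g", "t") %in% names(out)))
  expect_true(any(out$i == "mcfe:e00_left_kidney" & out$t == "mcfe:te14"))

  flt <- runQuery(g, paste(
    "SELECT ?st ?d WHERE {",
    "  ?st mcfe:from_gestation_day ?d .",
    "  FILTER(?d >= 77)",
    "}"))
  expect_equal(flt$st, "mcfe:gw12")
})

test_that("full IRIs and declared prefixes resolve to the same resources", {
  g <- refGraph()
  out <- runQuery(g, paste0(
    "PREFIX emb: <http://example.org/mycf-embryo#>\n",
    "SELECT ?x WHERE { ?x emb:part_of <http://example.org/mycf-embryo#embryo> . }"))
  expect_true("mcfe:left_kidney" %in% out$x)
})

test_that("query answers on the saturated graph are a superset", {
  q <- "SELECT ?x ?y WHERE { ?x mcfe:develops_from ?y . }"
  before <- runQuery(refGraph(), q)
  after <- runQuery(refSaturated(), q)
  expect_true(all(paste(before$x, before$y) %in% paste(after$x, after$y)))
  expect_gt(nrow(after), nrow(before))
})

test_that("descendant representations of the cloaca from te14 are found", {
  out <- representationsDevelopingFrom(refSaturated(), "mcfe:cloaca",
                                       "mcfe:te14", saturated = TRUE)
  expect_setequal(out$ee, c("mcfe:bladder", "mcfe:rectum"))
  expect_setequal(out$g, c("mcfe:bladder_ovoid_te15", "mcfe:rectum_ovoid_te15"))
  # matches a hand-rolled closure oracle over the asserted lineage
  direct <- subjectsOf(refGraph(), "mcfe:directly_develops_from", "mcfe:cloaca")
  expect_setequal(unique(out$ee), direct)
})

test_that("unknown ancestors and out-of-range stages yield empty tables", {
  expect_warning(
    out <- representationsDevelopingFrom(refSaturated(), "mcfe:no_such_organ",
                                         "mcfe:te14", saturated = TRUE),
    "unknown ancestor")
  expect_equal(nrow(out), 0L)
  late <- representationsDevelopingFrom(refSaturated(), "mcfe:cloaca",
                                        "mcfe:gw11", saturated = TRUE)
  expect_equal(nrow(late), 0L)
  noDesc <- representationsDevelopingFrom(refSaturated(), "mcfe:rectum",
                                          "mcfe:te14", saturated = TRUE)
  expect_equal(nrow(noDesc), 0L)
})

test_that("extractScene collects statics in the period and the growth process", {
  sc <- extractScene(refSaturated(), "mcfe:left_kidney",
                     c("mcfe:te14", "mcfe:te20"))
  rec <- sc@organs[["mcfe:e00_left_kidney"]]
  stages <- vapply(rec$statics, `[[`, character(1), "stage")
  expect_true(all(c("mcfe:te14", "mcfe:te15") %in% stages))
  expect_true(all(vapply(rec$statics, `[[`, character(1), "shape") == "ovoid"))
  kinds <- vapply(rec$processes, `[[`, character(1), "kind")
  expect_true("growth" %in% kinds)
  growth <- rec$processes[[which(kinds == "growth")[1]]]
  expect_equal(growth$from, "mcfe:te14")
  expect_equal(growth$to, "mcfe:te20")
  expect_equal(growth$parameters$growth_proportion, 10)
  # geometric property maps carry parsed 3-vectors
  te14 <- rec$statics[[which(stages == "mcfe:te14")[1]]]
  expect_equal(te14$properties$axis_size, c(0.04, 0.03, 0.06))
})

test_that("an empty organ list yields an empty scene description", {
  sc <- extractScene(refSaturated(), character(), c("mcfe:te14", "mcfe:te20"))
  expect_length(sc@organs, 0L)
})

test_that("the urogenital period query includes the cloaca division process", {
  sc <- extractScene(refSaturated(),
                     c("mcfe:cloaca", "mcfe:bladder", "mcfe:rectum"),
                     c("mcfe:te10", "mcfe:gw12"))
  rec <- sc@organs[["mcfe:e00_cloaca"]]
  kinds <- vapply(rec$processes, `[[`, character(1), "kind")
  expect_true("division" %in% kinds)
})

test_that("reversed periods and missing organs are handled as contracted", {
  expect_error(extractScene(refSaturated(), "mcfe:left_kidney",
                            c("mcfe:te20", "mcfe:te14")), "invalid period")
  expect_warning(extractScene(refSaturated(), "mcfe:no_such_organ",
                              c("mcfe:te14", "mcfe:te20")),
                 "no representation")
})
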