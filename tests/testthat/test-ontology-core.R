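test_that("graphs have set semantics: re-adding a triple is a no-op", {
  g <- addTriples(emptyGraph(), c("mcfe:left_kidney", "mcfe:part_of", "mcfe:embryo"))
  expect_equal(tripleCount(g), 1L)
  g2 <- addTriples(g, c("mcfe:left_kidney", "mcfe:part_of", "mcfe:embryo"))
  expect_equal(tripleCount(g2), 1L)
  # inferred duplicate of an asserted triple keeps asserted provenance
  g3 <- addTriples(g, c("mcfe:left_kidney", "mcfe:part_of", "mcfe:embryo"),
                   src = "R6")
  expect_equal(triples(g3)$src, "asserted")
})

test_that("literal terms encode scalars, strings and 3-vectors", {
  expect_true(isLit(lit(10)))
  expect_equal(litNum(lit(10)), 10)
  expect_equal(litVec(lit(c(0.25, 0, -0.55))), c(0.25, 0, -0.55))
  expect_false(isLit("mcfe:left_kidney"))
  expect_equal(litValue(lit("x")), "x")
})

test_that("turtle documents parse to the expected triple sets", {
  expect_equal(tripleCount(loadGraph("", format = "turtle")), 0L)
  g <- loadGraph(paste0("@prefix mcfe: <http://example.org/mycf-embryo#> .\n",
                        "mcfe:left_kidney mcfe:part_of mcfe:embryo ."),
                 format = "turtle")
  expect_equal(tripleCount(g), 1L)
  expect_true(hasTriple(g, "mcfe:left_kidney", "mcfe:part_of", "mcfe:embryo"))
  # semicolon/comma lists, a-keyword, numeric and quoted literals
  g2 <- loadGraph(paste0(
    "@prefix mcfe: <http://example.org/mycf-embryo#> .\n",
    "mcfe:k a mcfe:ovoid ;\n",
    "  mcfe:growth_proportion 10 ;\n",
    "  mcfe:barycenter_position \"0.25 0 -0.55\" ;\n",
    "  mcfe:part_of mcfe:embryo , mcfe:nephros .\n"), format = "turtle")
  expect_equal(tripleCount(g2), 5L)
  expect_true(hasTriple(g2, "mcfe:k", "rdf:type", "mcfe:ovoid"))
  expect_equal(litNum(objectsOf(g2, "mcfe:k", "mcfe:growth_proportion")), 10)
  expect_equal(length(objectsOf(g2, "mcfe:k", "mcfe:part_of")), 2L)
})

test_that("serialization round trip is the identity on triple sets", {
  g <- refGraph()
  for (fmt in c("turtle", "ntriples", "rdfxml")) {
    text <- saveGraph(g, fmt)
    expect_true(sameTriples(g, loadGraph(text, fmt)), label = fmt)
  }
  # file-based round trip with extension-guessed formats
  for (ext in c("ttl", "nt", "rdf")) {
    f <- file.path(withr::local_tempdir(), paste0("g.", ext))
    saveGraph(g, path = f)
    expect_true(sameTriples(g, loadGraph(f)), label = ext)
  }
})

test_that("unknown serialization names and malformed input are errors", {
  expect_error(saveGraph(emptyGraph(), "trig"), "unknown serialization")
  expect_error(loadGraph("mcfe:a mcfe:b", format = "turtle"))
  expect_error(loadGraph("<a> <b> .", format = "ntriples"), "line")
})

test_that("the schema vocabulary has the six fixed taxonomies and kinds", {
  voc <- schemaVocabulary()
  expect_length(voc$topClasses, 6L)
  expect_equal(anyDuplicated(voc$topClasses), 0L)
  expect_length(voc$geometricKinds, 6L)
  expect_length(voc$processKinds, 6L)
  # subproperty axioms hold as asserted triples in the schema graph
  sg <- schemaGraph()
  expect_true(hasTriple(sg, "mcfe:directly_develops_from",
                        "rdfs:subPropertyOf", "mcfe:develops_from"))
  expect_true(hasTriple(sg, "mcfe:migration_direction",
                        "rdfs:subPropertyOf", "mcfe:vector_coordinates"))
  expect_true(hasTriple(sg, "mcfe:x_axis_orientation",
                        "rdfs:subPropertyOf", "mcfe:vector_coordinates"))
  expect_true(hasTriple(sg, "mcfe:caudal_end_axis_size",
                        "rdfs:subPropertyOf", "mcfe:axis_size"))
  # and the shipped schema.ttl matches the in-code vocabulary
  shipped <- loadGraph(system.file("extdata", "schema.ttl",
                                   package = "embryofab"))
  expect_true(sameTriples(sg, shipped))
})

test_that("validateSchema flags the documented violation classes", {
  expect_true(isValid(validateSchema(refGraph())))

  bad <- addTriples(emptyGraph(), rbind(
    c("mcfe:teX", "mcfe:from_gestation_day", lit(34)),
    c("mcfe:teX", "mcfe:to_gestation_day", lit(32))))
  expect_equal(violations(validateSchema(bad))$code, "c")

  both <- addTriples(emptyGraph(), rbind(
    c("mcfe:strX", "mcfe:describes", "mcfe:e00_left_kidney"),
    c("mcfe:strX", "mcfe:at_stage", "mcfe:te14"),
    c("mcfe:strX", "mcfe:from_stage", "mcfe:te14")))
  expect_true("a" %in% violations(validateSchema(both))$code)

  orphan <- addTriples(emptyGraph(),
                       c("mcfe:strY", "mcfe:at_stage", "mcfe:te14"))
  expect_true("d" %in% violations(validateSchema(orphan))$code)

  noStages <- addTriples(emptyGraph(), rbind(
    c("mcfe:strZ", "mcfe:describes", "mcfe:x"),
    c("mcfe:strZ", "mcfe:has_process", "mcfe:p")))
  expect_true("b" %in% violations(validateSchema(noStages))$code)

  skewed <- addTriples(emptyGraph(), rbind(
    c("mcfe:strG", "mcfe:describes", "mcfe:x"),
    c("mcfe:strG", "mcfe:at_stage", "mcfe:te14"),
    c("mcfe:strG", "mcfe:has_geometrical_representation", "mcfe:gX"),
    c("mcfe:gX", "rdf:type", "mcfe:ovoid"),
    c("mcfe:gX", "mcfe:barycenter_position", lit(c(0, 0, 0))),
    c("mcfe:gX", "mcfe:axis_size", lit(c(1, 1, 1))),
    c("mcfe:gX", "mcfe:x_axis_orientation", lit(c(1, 0, 0))),
    c("mcfe:gX", "mcfe:y_axis_orientation", lit(c(1, 1, 0))),
    c("mcfe:gX", "mcfe:z_axis_orientation", lit(c(0, 0, 1)))))
  expect_true("f" %in% violations(validateSchema(skewed))$code)
  # dropping a required property is flagged too
  incomplete <- addTriples(emptyGraph(), rbind(
    c("mcfe:strH", "mcfe:describes", "mcfe:x"),
    c("mcfe:strH", "mcfe:has_geometrical_representation", "mcfe:gY"),
    c("mcfe:gY", "rdf:type", "mcfe:ovoid"),
    c("mcfe:gY", "mcfe:barycenter_position", lit(c(0, 0, 0)))))
  expect_true("e" %in% violations(validateSchema(incomplete))$code)
})

test_that("validateSchema is monotone: adding a violating triple never heals", {
  g <- addTriples(emptyGraph(), rbind(
    c("mcfe:teX", "mcfe:from_gestation_day", lit(34)),
    c("mcfe:teX", "mcfe:to_gestation_day", lit(32))))
  v1 <- violations(validateSchema(g))
  g2 <- addTriples(g, c("mcfe:strY", "mcfe:at_stage", "mcfe:te14"))
  v2 <- violations(validateSchema(g2))
  expect_true(all(paste(v1$subject, v1$code) %in% paste(v2$subject, v2$code)))
  expect_gt(nrow(v2), nrow(v1))
})
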