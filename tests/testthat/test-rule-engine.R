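test_that("the default ruleset has fifteen safe rules R1..R15", {
  rs <- defaultRuleset()
  expect_length(rs, 15L)
  expect_equal(vapply(rs, ruleId, character(1)), paste0("R", 1:15))
  expect_true(all(vapply(rs, ruleIsSafe, logical(1))))
})

test_that("unsafe rules are rejected at construction and application", {
  expect_error(rule("bad", list(c("?x", "mcfe:part_of", "?y")),
                    list(c("?x", "mcfe:part_of", "?z"))),
               "unsafe")
})

test_that("direct lineage entails develops_from (subproperty rule)", {
  g <- addTriples(emptyGraph(),
    c("mcfe:kidney", "mcfe:directly_develops_from", "mcfe:metanephric_blastema"))
  r1 <- defaultRuleset()[[1]]
  out <- applyRule(g, r1)
  expect_equal(nrow(out), 1L)
  expect_equal(unlist(out[1, ], use.names = FALSE),
               c("mcfe:kidney", "mcfe:develops_from", "mcfe:metanephric_blastema"))
})

test_that("lineage propagates through part_of of the precursor", {
  g <- addTriples(emptyGraph(), rbind(
    c("mcfe:metanephric_blastema", "mcfe:directly_develops_from", "mcfe:metanephros"),
    c("mcfe:metanephros", "mcfe:part_of", "mcfe:nephros")))
  r3 <- defaultRuleset()[[3]]
  out <- applyRule(g, r3)
  expect_equal(nrow(out), 1L)
  expect_equal(unlist(out[1, ], use.names = FALSE),
               c("mcfe:metanephric_blastema", "mcfe:develops_from", "mcfe:nephros"))
})

test_that("any rule applied to the empty graph yields the empty set", {
  for (r in defaultRuleset())
    expect_equal(nrow(applyRule(emptyGraph(), r)), 0L)
})

test_that("one pass of stage-order transitivity yields the distance-2 pairs", {
  st <- paste0("mcfe:te", 1:4)
  g <- addTriples(emptyGraph(),
                  cbind(st[-1], "mcfe:following_stage", st[-4]))
  r10 <- defaultRuleset()[[10]]
  out <- applyRule(g, r10)
  expect_equal(nrow(out), 2L)  # te3->te1, te4->te2 in one pass
  expect_setequal(paste(out$s, out$o),
                  c("mcfe:te3 mcfe:te1", "mcfe:te4 mcfe:te2"))
})

test_that("saturation derives the documented lineage and disease facts", {
  gs <- refSaturated()
  expect_true(hasTriple(gs, "mcfe:kidney", "mcfe:develops_from",
                        "mcfe:metanephros"))
  expect_true(hasTriple(gs, "mcfe:metanephric_blastema", "mcfe:develops_from",
                        "mcfe:nephros"))
  expect_true(hasTriple(gs, "mcfe:hypoplastic_kidney", "mcfe:impacts_processus",
                        "mcfe:ureter_kidney_interaction"))
  # R11: growth depends (transitively) on the fixation hard link
  expect_true(hasTriple(gs, "mcfe:kidney_growth", "mcfe:depends_on",
                        "mcfe:ureter_fixation"))
  # R13..R15: process-to-entity and process-to-interval links
  expect_true(hasTriple(gs, "mcfe:kidney_growth", "mcfe:impacts_entity",
                        "mcfe:e00_left_kidney"))
  expect_true(hasTriple(gs, "mcfe:kidney_growth", "mcfe:process_from_stage",
                        "mcfe:te14"))
  expect_true(hasTriple(gs, "mcfe:kidney_growth", "mcfe:process_to_stage",
                        "mcfe:te20"))
  # R8/R9: geometric model tied to instance and stage
  expect_true(hasTriple(gs, "mcfe:lk_ovoid_te14", "mcfe:represents",
                        "mcfe:e00_left_kidney"))
  expect_true(hasTriple(gs, "mcfe:lk_ovoid_te14", "mcfe:geometry_at_stage",
                        "mcfe:te14"))
})

test_that("every inferred triple carries the id of a producing rule", {
  inf <- inferredTriples(refSaturated())
  expect_gt(nrow(inf), 0L)
  expect_true(all(inf$src %in% paste0("R", 1:15)))
})

test_that("the 23-stage chain closes to 253 ordered pairs", {
  st <- paste0("mcfe:te", 1:23)
  g <- addTriples(emptyGraph(),
                  cbind(st[-1], "mcfe:following_stage", st[-23]))
  gs <- saturate(g)
  expect_equal(sum(triples(gs)$p == "mcfe:following_stage"), 253L)
  expect_setequal(saturatedPairs(gs, "mcfe:following_stage"),
                  igraphClosurePairs(g, "mcfe:following_stage"))
})

test_that("saturation is monotone and idempotent", {
  g <- refGraph()
  gs <- refSaturated()
  expect_true(all(tripleKeySet(g) %in% tripleKeySet(gs)))
  expect_true(sameTriples(saturate(gs), gs))
})

test_that("saturation is order-independent and matches naive evaluation", {
  g <- refGraph()
  gs <- refSaturated()
  set.seed(7)
  for (k in 1:3)
    expect_true(sameTriples(saturate(g, sample(defaultRuleset())), gs))
  expect_true(sameTriples(saturate(g, method = "naive"), gs))
})

test_that("saturation equals a graph-library closure oracle on random graphs", {
  set.seed(42)
  preds <- c("mcfe:develops_from", "mcfe:part_of", "mcfe:following_stage")
  for (rep_ in 1:100) {
    p <- sample(preds, 1)
    g <- randomEdgeGraph(nNodes = sample(5:14, 1), nEdges = sample(5:25, 1),
                         predicate = p)
    gs <- saturate(g)
    expect_setequal(saturatedPairs(gs, p), igraphClosurePairs(g, p))
    # monotone and idempotent on every instance
    expect_true(all(tripleKeySet(g) %in% tripleKeySet(gs)))
    expect_true(sameTriples(saturate(gs), gs))
    # naive evaluation agrees on a subsample
    if (rep_ %% 20 == 0)
      expect_true(sameTriples(saturate(g, method = "naive"), gs))
  }
})

test_that("subproperty entailment lifts rostral/caudal and orientation values", {
  gs <- refSaturated()
  # the duct's rostral radius is visible under the parent axis_size property
  expect_true(hasTriple(gs, "mcfe:lu_duct_te14", "mcfe:axis_size",
                        lit(rep(0.012, 3))))
  # orientation vectors are visible as generic vector_coordinates
  expect_true(hasTriple(gs, "mcfe:lk_ovoid_te14", "mcfe:vector_coordinates",
                        lit(c(1, 0, 0))))
})
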