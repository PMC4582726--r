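# Shared fixtures, built once per test run.

refGraph <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- buildReferenceEmbryo(withGeometry = TRUE)
    g
  }
})

refSaturated <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- saturate(refGraph())
    g
  }
})

# random edge graph over a fixed node set, one predicate
randomEdgeGraph <- function(nNodes, nEdges, predicate) {
  nodes <- paste0("mcfe:n", seq_len(nNodes))
  s <- sample(nodes, nEdges, replace = TRUE)
  o <- sample(nodes, nEdges, replace = TRUE)
  addTriples(emptyGraph(), data.frame(s = s, p = predicate, o = o))
}

# independent reachability oracle: pair (u,v) is in the transitive
# closure iff v is reachable from some out-neighbour of u
igraphClosurePairs <- function(graph, predicate) {
  tr <- triples(graph)
  edges <- tr[tr$p == predicate, c("s", "o")]
  nodes <- unique(c(edges$s, edges$o))
  ig <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                      vertices = nodes)
  D <- igraph::distances(ig, mode = "out")
  out <- character()
  for (u in nodes) {
    nb <- unique(edges$o[edges$s == u])
    reach <- nodes[apply(D[nb, nodes, drop = FALSE] < Inf, 2, any)]
    if (length(reach)) out <- c(out, paste(u, reach))
  }
  sort(unique(out))
}

saturatedPairs <- function(graph, predicate) {
  tr <- triples(graph)
  rows <- tr[tr$p == predicate, , drop = FALSE]
  sort(unique(paste(rows$s, rows$o)))
}

tripleKeySet <- function(g) {
  tr <- triples(g)
  paste(tr$s, tr$p, tr$o)
}
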