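# OntologyGraph construction and accessors.

emptyTripleFrame <- function() {
  data.frame(s = character(), p = character(), o = character(),
             src = character(), stringsAsFactors = FALSE)
}

tripleKey <- function(tr) paste(tr$s, tr$p, tr$o, sep = "\r")

#' Create an empty ontology graph
#'
#' @param namespaces named character vector of prefix -> IRI mappings;
#'   the project defaults ([defaultNamespaces()]) are always included.
#' @return an [OntologyGraph-class] with no triples.
#' @examples
#' g <- emptyGraph()
#' tripleCount(g)
#' @export
emptyGraph <- function(namespaces = character()) {
  ns <- defaultNamespaces()
  if (length(namespaces)) ns[names(namespaces)] <- namespaces
  new("OntologyGraph", triples = emptyTripleFrame(), namespaces = ns)
}

#' Default namespace table
#'
#' The project prefix `mcfe:` is minted for this package's vocabulary;
#' `rdf:`, `rdfs:` and `xsd:` carry their standard IRIs.
#' @return named character vector.
#' @export
defaultNamespaces <- function() {
  c(mcfe = "http://example.org/mycf-embryo#",
    rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    rdfs = "http://www.w3.org/2000/01/rdf-schema#",
    xsd  = "http://www.w3.org/2001/XMLSchema#")
}

asTripleFrame <- function(triples, src) {
  if (is.character(triples) && length(triples) == 3L)
    triples <- data.frame(s = triples[1], p = triples[2], o = triples[3],
                          stringsAsFactors = FALSE)
  if (is.matrix(triples))
    triples <- data.frame(s = triples[, 1], p = triples[, 2], o = triples[, 3],
                          stringsAsFactors = FALSE)
  stopifnot(is.data.frame(triples), all(c("s", "p", "o") %in% names(triples)))
  if (!"src" %in% names(triples)) triples$src <- src
  triples[c("s", "p", "o", "src")]
}

#' @rdname addTriples
setMethod("addTriples", "OntologyGraph", function(x, triples, src = "asserted") {
  add <- asTripleFrame(triples, src)
  if (!nrow(add)) return(x)
  add <- add[!duplicated(paste(add$s, add$p, add$o, sep = "\r")), , drop = FALSE]
  new <- !(paste(add$s, add$p, add$o, sep = "\r") %in% tripleKey(x@triples))
  if (any(new)) {
    x@triples <- rbind(x@triples, add[new, , drop = FALSE])
    rownames(x@triples) <- NULL
  }
  x
})

#' @rdname triples
setMethod("triples", "OntologyGraph", function(x) x@triples)

#' @rdname tripleCount
setMethod("tripleCount", "OntologyGraph", function(x) nrow(x@triples))

#' @rdname namespaces
setMethod("namespaces", "OntologyGraph", function(x) x@namespaces)

#' @rdname hasTriple
setMethod("hasTriple", "OntologyGraph", function(x, s, p, o) {
  any(x@triples$s == s & x@triples$p == p & x@triples$o == o)
})

#' @rdname objectsOf
setMethod("objectsOf", "OntologyGraph", function(x, s, p) {
  unique(x@triples$o[x@triples$s == s & x@triples$p == p])
})

#' @rdname subjectsOf
setMethod("subjectsOf", "OntologyGraph", function(x, p, o) {
  unique(x@triples$s[x@triples$p == p & x@triples$o == o])
})

setMethod("show", "OntologyGraph", function(object) {
  tr <- object@triples
  cat(sprintf("OntologyGraph with %d triples (%d asserted, %d inferred)\n",
              nrow(tr), sum(tr$src == "asserted"), sum(tr$src != "asserted")))
  cat(sprintf("namespaces: %s\n", paste(names(object@namespaces), collapse = " ")))
  if (nrow(tr)) {
    shown <- utils::head(tr, 6L)
    for (i in seq_len(nrow(shown)))
      cat(sprintf("  %s %s %s .\n", shown$s[i], shown$p[i], shown$o[i]))
    if (nrow(tr) > 6L) cat(sprintf("  ... and %d more\n", nrow(tr) - 6L))
  }
})

#' Provenance of the triples in a graph
#'
#' @param graph an [OntologyGraph-class].
#' @return data.frame of the inferred triples with the id of the rule
#'   that produced each one.
#' @export
inferredTriples <- function(graph) {
  tr <- triples(graph)
  tr[tr$src != "asserted", , drop = FALSE]
}

#' Set-equality of two graphs' triple sets
#' @param a,b [OntologyGraph-class] objects.
#' @export
sameTriples <- function(a, b) {
  setequal(tripleKey(triples(a)), tripleKey(triples(b)))
}

# ValidationReport accessors ------------------------------------------------

#' @rdname isValid
setMethod("isValid", "ValidationReport", function(x) nrow(x@violations) == 0L)

#' @rdname violations
setMethod("violations", "ValidationReport", function(x) x@violations)

setMethod("show", "ValidationReport", function(object) {
  if (isValid(object)) cat("ValidationReport: valid, 0 violations\n")
  else {
    cat(sprintf("ValidationReport: %d violation(s)\n", nrow(object@violations)))
    v <- object@violations
    for (i in seq_len(min(nrow(v), 10L)))
      cat(sprintf("  [%s] %s: %s\n", v$code[i], v$subject[i], v$message[i]))
  }
})

# Mesh accessors -------------------------------------------------------------

#' @rdname meshVertices
setMethod("meshVertices", "Mesh", function(x) x@vertices)

#' @rdname meshFaces
setMethod("meshFaces", "Mesh", function(x) x@faces)

setMethod("show", "Mesh", function(object) {
  cat(sprintf("Mesh: %d vertices, %d faces\n",
              nrow(object@vertices), nrow(object@faces)))
})

setMethod("show", "Rule", function(object) {
  pat <- function(x) sprintf("(%s %s %s)", x[1], x[2], x[3])
  cat(sprintf("%s: %s => %s\n", object@id,
              paste(vapply(object@conditions, pat, character(1)), collapse = " & "),
              paste(vapply(object@conclusions, pat, character(1)), collapse = " & ")))
})

#' @rdname ruleId
setMethod("ruleId", "Rule", function(x) x@id)

setMethod("show", "Timeline", function(object) {
  fr <- object@frames
  cat(sprintf("Timeline: %d day units", object@totalUnits))
  if (nrow(fr))
    cat(sprintf(" (day %d [%s] .. day %d [%s])",
                fr$day[1], fr$stage[1], fr$day[nrow(fr)], fr$stage[nrow(fr)]))
  cat("\n")
})

setMethod("show", "AnimatedScene", function(object) {
  cat(sprintf("AnimatedScene: %d organ(s), %d day units\n",
              length(object@organs), object@timeline@totalUnits))
  for (nm in names(object@organs))
    cat(sprintf("  %s: %d keyframes\n", nm, length(object@organs[[nm]]$keyframes)))
})

#' @rdname timeline
setMethod("timeline", "AnimatedScene", function(x) x@timeline)

#' @rdname keyframes
setMethod("keyframes", "AnimatedScene", function(x, organ) {
  if (!organ %in% names(x@organs))
    stop("no such organ in scene: ", organ)
  x@organs[[organ]]$keyframes
})

setMethod("show", "SceneDescription", function(object) {
  cat(sprintf("SceneDescription over (%s, %s): %d organ(s)\n",
              object@period[1], object@period[2], length(object@organs)))
  for (nm in names(object@organs)) {
    o <- object@organs[[nm]]
    cat(sprintf("  %s: %d static, %d process record(s)\n",
                nm, length(o$statics), length(o$processes)))
  }
})
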