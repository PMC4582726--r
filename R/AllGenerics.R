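#' Triples of a graph
#' @param x an [OntologyGraph-class].
#' @return data.frame with columns `s`, `p`, `o`, `src`.
#' @export
setGeneric("triples", function(x) standardGeneric("triples"))

#' Number of triples in a graph
#' @param x an [OntologyGraph-class].
#' @export
setGeneric("tripleCount", function(x) standardGeneric("tripleCount"))

#' Namespace table of a graph
#' @param x an [OntologyGraph-class].
#' @export
setGeneric("namespaces", function(x) standardGeneric("namespaces"))

#' Add triples to a graph (set semantics)
#'
#' Adding a triple that is already present is a no-op on the triple set;
#' in particular an inferred duplicate of an asserted triple keeps the
#' asserted provenance.
#'
#' @param x an [OntologyGraph-class].
#' @param triples data.frame with columns `s`, `p`, `o` (and optionally
#'   `src`), or a character vector of length 3.
#' @param src provenance tag for triples lacking one (default "asserted").
#' @return the updated graph.
#' @export
setGeneric("addTriples", function(x, triples, src = "asserted")
  standardGeneric("addTriples"))

#' Test for the presence of a triple
#' @param x an [OntologyGraph-class].
#' @param s,p,o subject, predicate, object terms.
#' @export
setGeneric("hasTriple", function(x, s, p, o) standardGeneric("hasTriple"))

#' Objects o such that (s, p, o) is in the graph
#' @param x an [OntologyGraph-class].
#' @param s,p subject and predicate (constants).
#' @export
setGeneric("objectsOf", function(x, s, p) standardGeneric("objectsOf"))

#' Subjects s such that (s, p, o) is in the graph
#' @param x an [OntologyGraph-class].
#' @param p,o predicate and object (constants).
#' @export
setGeneric("subjectsOf", function(x, p, o) standardGeneric("subjectsOf"))

#' Is a validation report free of violations?
#' @param x a [ValidationReport-class].
#' @export
setGeneric("isValid", function(x) standardGeneric("isValid"))

#' Violations recorded by a validation report
#' @param x a [ValidationReport-class].
#' @export
setGeneric("violations", function(x) standardGeneric("violations"))

#' Rule identifier
#' @param x a [Rule-class].
#' @export
setGeneric("ruleId", function(x) standardGeneric("ruleId"))

#' Vertices of a mesh
#' @param x a [Mesh-class].
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))

#' Faces of a mesh
#' @param x a [Mesh-class].
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))

#' Timeline of an animated scene
#' @param x an [AnimatedScene-class].
#' @export
setGeneric("timeline", function(x) standardGeneric("timeline"))

#' Keyframes of one organ in an animated scene
#' @param x an [AnimatedScene-class].
#' @param organ organ instance id.
#' @export
setGeneric("keyframes", function(x, organ) standardGeneric("keyframes"))
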