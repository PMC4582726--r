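#' @import methods
NULL

#' OntologyGraph: a set of RDF-style triples with provenance
#'
#' The central container of the package. A graph is a *set* of triples
#' (subject, predicate, object); objects may be resources or literals.
#' Every triple carries a provenance tag: `"asserted"` for triples loaded
#' or added explicitly, or the id of the inference rule that derived it.
#'
#' Resources are written as CURIEs (`mcfe:left_kidney`, `rdfs:subClassOf`)
#' resolved against the graph's namespace table. Literals are stored
#' internally wrapped in double quotes; use [lit()] / [litValue()] to
#' construct and inspect them. 3-vectors are single literals of three
#' space-separated decimal numbers.
#'
#' @slot triples data.frame with character columns `s`, `p`, `o`, `src`.
#' @slot namespaces named character vector mapping prefix to IRI.
#'
#' @seealso [emptyGraph()], [addTriples()], [loadGraph()], [saturate()]
#' @export
setClass("OntologyGraph",
  representation(triples = "data.frame", namespaces = "character"),
  prototype(
    triples = data.frame(s = character(), p = character(),
                         o = character(), src = character(),
                         stringsAsFactors = FALSE),
    namespaces = character()
  )
)

setValidity("OntologyGraph", function(object) {
  tr <- object@triples
  msgs <- character()
  if (!all(c("s", "p", "o", "src") %in% names(tr)))
    msgs <- c(msgs, "triples must have columns s, p, o, src")
  else {
    if (anyDuplicated(paste(tr$s, tr$p, tr$o, sep = "\r")))
      msgs <- c(msgs, "duplicate triples: the graph is a set")
    if (any(startsWith(tr$s, "\"")))
      msgs <- c(msgs, "subjects must be resources, not literals")
  }
  if (length(msgs)) msgs else TRUE
})

#' Rule: a safe condition-to-conclusion inference rule
#'
#' Conditions and conclusions are triple patterns: character vectors of
#' length three whose components are constants (CURIEs) or variables
#' (names starting with `?`). A rule is *safe* when every conclusion
#' variable also occurs in some condition, which guarantees that
#' saturation terminates on a finite graph.
#'
#' @slot id rule identifier, e.g. `"R2"`.
#' @slot conditions list of length-3 character vectors.
#' @slot conclusions list of length-3 character vectors.
#' @export
setClass("Rule",
  representation(id = "character", conditions = "list", conclusions = "list"))

setValidity("Rule", function(object) {
  ok3 <- function(x) is.character(x) && length(x) == 3L
  if (!all(vapply(object@conditions, ok3, logical(1))))
    return("every condition must be a character vector of length 3")
  if (!all(vapply(object@conclusions, ok3, logical(1))))
    return("every conclusion must be a character vector of length 3")
  if (!length(object@conclusions))
    return("rule needs at least one conclusion")
  if (!ruleIsSafe(object))
    return(sprintf("rule %s is unsafe: conclusion variable missing from conditions",
                   object@id))
  TRUE
})

#' ValidationReport: outcome of structural schema validation
#'
#' @slot violations data.frame with columns `subject`, `code`, `message`.
#' @seealso [validateSchema()], [isValid()]
#' @export
setClass("ValidationReport", representation(violations = "data.frame"))

#' GeometricPrimitive: parametric 3D shape description
#'
#' One of the six primitive kinds (`point`, `line`, `plane`, `ovoid`,
#' `cylinder`, `duct`) with a barycenter, per-axis half-sizes and an
#' orthonormal right-handed orientation frame. Ducts and lines carry two
#' end sub-records (`rostral`, `caudal`), each with an endpoint position,
#' a tangent vector and a local radius.
#'
#' @slot kind character, one of the six kinds.
#' @slot barycenter numeric(3).
#' @slot axisSize numeric(3) half-lengths along the local axes.
#' @slot orientation 3x3 matrix whose columns are the local x/y/z axes.
#' @slot ends list with elements `rostral` and `caudal` for duct/line,
#'   each `list(position, tangent, radius)`; empty otherwise.
#' @export
setClass("GeometricPrimitive",
  representation(kind = "character", barycenter = "numeric",
                 axisSize = "numeric", orientation = "matrix",
                 ends = "list"))

setValidity("GeometricPrimitive", function(object) {
  kinds <- c("point", "line", "plane", "ovoid", "cylinder", "duct")
  if (!(length(object@kind) == 1L && object@kind %in% kinds))
    return(sprintf("kind must be one of: %s", paste(kinds, collapse = ", ")))
  if (length(object@barycenter) != 3L || length(object@axisSize) != 3L)
    return("barycenter and axisSize must be numeric(3)")
  R <- object@orientation
  if (!all(dim(R) == c(3L, 3L)))
    return("orientation must be a 3x3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    return("orientation frame must be orthonormal (tolerance 1e-6)")
  if (det(R) < 0)
    return("orientation frame must be right-handed")
  if (object@kind %in% c("ovoid", "cylinder") && any(object@axisSize <= 0))
    return("axisSize components must be > 0 for ovoid/cylinder")
  if (object@kind %in% c("duct", "line")) {
    if (!all(c("rostral", "caudal") %in% names(object@ends)))
      return("duct/line needs rostral and caudal end records")
    for (e in object@ends[c("rostral", "caudal")]) {
      if (!all(c("position", "tangent", "radius") %in% names(e)))
        return("end record needs position, tangent and radius")
      if (object@kind == "duct" && e$radius <= 0)
        return("duct end radii must be > 0")
    }
  }
  TRUE
})

#' Mesh: indexed triangle mesh
#'
#' @slot vertices n x 3 numeric matrix.
#' @slot faces m x 3 integer matrix of 1-based vertex indices.
#' @export
setClass("Mesh", representation(vertices = "matrix", faces = "matrix"))

setValidity("Mesh", function(object) {
  v <- object@vertices; f <- object@faces
  if (ncol(v) != 3L && nrow(v) > 0L) return("vertices must have 3 columns")
  if (nrow(f)) {
    if (ncol(f) != 3L) return("faces must have 3 columns")
    if (min(f) < 1L || max(f) > nrow(v)) return("face index out of range")
    if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
      return("degenerate face with a repeated vertex index")
  }
  TRUE
})

#' ImplicitShape: sum of compact-support meta-ball fields
#'
#' Each skeleton is a point (numeric(3)) or a polyline (k x 3 matrix)
#' with a support radius `R` and a weight. The field contributed by a
#' skeleton at distance `d` is `weight * (1 - d^2/R^2)^3` for `d < R`
#' and exactly 0 beyond (compact support). The shape is the isosurface
#' `field = isovalue` of the summed fields.
#'
#' @slot skeletons list of `list(skeleton, R, weight)`.
#' @slot isovalue scalar in (0, sum of weights).
#' @export
setClass("ImplicitShape",
  representation(skeletons = "list", isovalue = "numeric"))

setValidity("ImplicitShape", function(object) {
  for (sk in object@skeletons) {
    if (!all(c("skeleton", "R", "weight") %in% names(sk)))
      return("skeleton record needs skeleton, R, weight")
    if (sk$R <= 0) return("support radius must be > 0")
  }
  if (length(object@isovalue) != 1L || object@isovalue <= 0)
    return("isovalue must be a single positive number")
  TRUE
})

#' Timeline: gestation-day frames for an animation period
#'
#' One frame per gestation day covered by the period, the gestation day
#' being the common time unit across stages of unequal duration.
#'
#' @slot frames data.frame with columns `stage` (character) and `day`
#'   (integer), strictly increasing in day.
#' @slot totalUnits integer, number of day units (sum of stage durations).
#' @export
setClass("Timeline",
  representation(frames = "data.frame", totalUnits = "integer"))

setValidity("Timeline", function(object) {
  fr <- object@frames
  if (!all(c("stage", "day") %in% names(fr)))
    return("frames must have columns stage and day")
  if (nrow(fr) && any(diff(fr$day) <= 0))
    return("frame days must be strictly increasing")
  if (object@totalUnits != nrow(fr))
    return("totalUnits must equal the number of day frames")
  TRUE
})

#' SceneDescription: per-organ records extracted from the graph
#'
#' Result of [extractScene()]: for each requested organ instance, the
#' static representations (one stage each) and process records (stage
#' interval each) found in the period, with full geometric property maps.
#'
#' @slot organs named list; each element has `instance`, `statics`
#'   (list of records), `processes` (list of records).
#' @slot period character(2) of stage ids.
#' @export
setClass("SceneDescription",
  representation(organs = "list", period = "character"))

#' AnimatedScene: per-day keyframed organ states
#'
#' @slot organs named list; each element carries the base
#'   [GeometricPrimitive-class] and an ordered list of per-day keyframes
#'   (day, axis sizes, rotation, barycenter, end positions, implicit
#'   shape state).
#' @slot timeline a [Timeline-class].
#' @export
setClass("AnimatedScene",
  representation(organs = "list", timeline = "Timeline"))
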