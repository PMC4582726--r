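# Structural validation of a graph against the schema conventions.

violation <- function(subject, code, message) {
  data.frame(subject = subject, code = code, message = message,
             stringsAsFactors = FALSE)
}

# properties required on a geometric instance, per primitive kind
requiredGeomProps <- function(kind) {
  switch(kind,
    ovoid = ,
    cylinder = c("mcfe:barycenter_position", "mcfe:axis_size",
                 "mcfe:x_axis_orientation", "mcfe:y_axis_orientation",
                 "mcfe:z_axis_orientation"),
    duct = ,
    line = c("mcfe:rostral_end_barycenter_position",
             "mcfe:caudal_end_barycenter_position",
             "mcfe:rostral_end_vector_coordinates",
             "mcfe:caudal_end_vector_coordinates",
             "mcfe:rostral_end_axis_size", "mcfe:caudal_end_axis_size"),
    point = "mcfe:barycenter_position",
    plane = c("mcfe:barycenter_position", "mcfe:axis_size",
              "mcfe:x_axis_orientation", "mcfe:y_axis_orientation",
              "mcfe:z_axis_orientation"),
    character())
}

#' Validate a graph against the schema's structural constraints
#'
#' Flags, without erroring:
#' \itemize{
#' \item (a) a spatio-temporal representation carrying both `at_stage`
#'   and `from_stage`/`to_stage` (a record is static *or* a process span);
#' \item (b) a representation with `has_process` but no complete
#'   `from_stage`/`to_stage` pair;
#' \item (c) a stage whose `from_gestation_day` exceeds its
#'   `to_gestation_day`;
#' \item (d) a representation lacking a `describes` link;
#' \item (e) a geometric instance missing a property its primitive kind
#'   requires (barycenter/axis sizes/orientations, or the rostral/caudal
#'   end records of a duct or line);
#' \item (f) orientation vectors that are not unit length and pairwise
#'   orthogonal within 1e-6.
#' }
#'
#' @param graph an [OntologyGraph-class].
#' @return a [ValidationReport-class].
#' @export
validateSchema <- function(graph) {
  stopifnot(is(graph, "OntologyGraph"))
  tr <- triples(graph)
  v <- list()
  note <- function(...) v[[length(v) + 1L]] <<- violation(...)

  strs <- unique(tr$s[tr$p %in% c("mcfe:describes", "mcfe:at_stage",
                                  "mcfe:from_stage", "mcfe:to_stage",
                                  "mcfe:has_geometrical_representation",
                                  "mcfe:has_process")])
  for (s in strs) {
    props <- tr$p[tr$s == s]
    hasAt <- "mcfe:at_stage" %in% props
    hasFrom <- "mcfe:from_stage" %in% props
    hasTo <- "mcfe:to_stage" %in% props
    if (hasAt && (hasFrom || hasTo))
      note(s, "a", "representation carries both at_stage and from_stage/to_stage")
    if ("mcfe:has_process" %in% props && !(hasFrom && hasTo))
      note(s, "b", "representation has a process but no from_stage/to_stage pair")
    if (!"mcfe:describes" %in% props)
      note(s, "d", "representation lacks a describes link")
  }

  stages <- unique(tr$s[tr$p == "mcfe:from_gestation_day"])
  for (st in stages) {
    fromD <- objectsOf(graph, st, "mcfe:from_gestation_day")
    toD <- objectsOf(graph, st, "mcfe:to_gestation_day")
    if (length(fromD) && length(toD) && litNum(fromD[1]) > litNum(toD[1]))
      note(st, "c", sprintf("stage interval inverted: from day %s to day %s",
                            litValue(fromD[1]), litValue(toD[1])))
  }

  geoms <- unique(tr$o[tr$p == "mcfe:has_geometrical_representation"])
  kinds <- schemaVocabulary()$geometricKinds
  for (gm in geoms) {
    types <- objectsOf(graph, gm, "rdf:type")
    kind <- kinds[paste0("mcfe:", kinds) %in% types]
    if (!length(kind)) next
    kind <- kind[1]
    props <- tr$p[tr$s == gm]
    missing <- setdiff(requiredGeomProps(kind), props)
    for (m in missing)
      note(gm, "e", sprintf("%s is missing required property %s", kind, m))
    axes <- c("mcfe:x_axis_orientation", "mcfe:y_axis_orientation",
              "mcfe:z_axis_orientation")
    if (all(axes %in% props)) {
      M <- vapply(axes, function(a) litVec(objectsOf(graph, gm, a)[1]),
                  numeric(3))
      if (max(abs(crossprod(M) - diag(3))) > 1e-6)
        note(gm, "f", "orientation vectors not unit-length and pairwise orthogonal")
    }
  }

  viols <- if (length(v)) do.call(rbind, v)
  else violation(character(), character(), character())
  new("ValidationReport", violations = viols)
}
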