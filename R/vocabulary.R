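# Schema vocabulary: the six top taxonomies, the property set, and the
# schema-level triples (subproperty links) shipped with every graph.

#' Schema vocabulary of the embryo development ontology
#'
#' Returns the fixed vocabulary: the six top taxonomy classes
#' (embryological entity, temporal entity, geometrical entity, process,
#' spatio-temporal representation, disease), the six geometric primitive
#' kinds, the six process kinds, and the full property list.
#'
#' @return list with elements `topClasses`, `geometricKinds`,
#'   `processKinds`, `properties` (all character vectors of CURIEs or
#'   bare kind names).
#' @examples
#' length(schemaVocabulary()$topClasses)
#' @export
schemaVocabulary <- function() {
  list(
    topClasses = c("mcfe:embryological_entity", "mcfe:temporal_entity",
                   "mcfe:geometrical_entity", "mcfe:process",
                   "mcfe:spatio_temporal_representation", "mcfe:disease"),
    geometricKinds = c("point", "line", "plane", "ovoid", "cylinder", "duct"),
    processKinds = c("growth", "migration", "rotation", "interaction",
                     "division", "fixation"),
    properties = c(
      "rdfs:subClassOf", "rdf:type", "rdfs:subPropertyOf",
      "mcfe:part_of", "mcfe:has_part",
      "mcfe:directly_develops_from", "mcfe:develops_from",
      "mcfe:starts_at", "mcfe:ends_at",
      "mcfe:from_gestation_day", "mcfe:to_gestation_day",
      "mcfe:following_stage",
      "mcfe:describes", "mcfe:at_stage", "mcfe:from_stage", "mcfe:to_stage",
      "mcfe:has_geometrical_representation", "mcfe:has_process",
      "mcfe:depends_on", "mcfe:impacts_processus", "mcfe:impacts_entity",
      "mcfe:axis_size", "mcfe:barycenter_position",
      "mcfe:x_axis_orientation", "mcfe:y_axis_orientation",
      "mcfe:z_axis_orientation", "mcfe:vector_coordinates",
      "mcfe:caudal_end_axis_size", "mcfe:rostral_end_axis_size",
      "mcfe:caudal_end_barycenter_position",
      "mcfe:rostral_end_barycenter_position",
      "mcfe:caudal_end_vector_coordinates",
      "mcfe:rostral_end_vector_coordinates",
      "mcfe:migration_direction", "mcfe:rotation_degree", "mcfe:rotation_axis",
      "mcfe:growth_proportion", "mcfe:rostral_end_growth_proportion",
      "mcfe:caudal_end_growth_proportion",
      "mcfe:fixed_to", "mcfe:rostral_end_fixed_to", "mcfe:caudal_end_fixed_to",
      "mcfe:represents", "mcfe:geometry_at_stage",
      "mcfe:process_from_stage", "mcfe:process_to_stage",
      "mcfe:has_mesh_file")
  )
}

# Subproperty axioms shipped as asserted triples in the schema graph.
schemaSubPropertyTable <- function() {
  rbind(
    c("mcfe:directly_develops_from", "mcfe:develops_from"),
    c("mcfe:migration_direction", "mcfe:vector_coordinates"),
    c("mcfe:x_axis_orientation", "mcfe:vector_coordinates"),
    c("mcfe:y_axis_orientation", "mcfe:vector_coordinates"),
    c("mcfe:z_axis_orientation", "mcfe:vector_coordinates"),
    c("mcfe:caudal_end_axis_size", "mcfe:axis_size"),
    c("mcfe:rostral_end_axis_size", "mcfe:axis_size"),
    c("mcfe:caudal_end_barycenter_position", "mcfe:barycenter_position"),
    c("mcfe:rostral_end_barycenter_position", "mcfe:barycenter_position"),
    c("mcfe:caudal_end_vector_coordinates", "mcfe:vector_coordinates"),
    c("mcfe:rostral_end_vector_coordinates", "mcfe:vector_coordinates"),
    c("mcfe:rostral_end_growth_proportion", "mcfe:growth_proportion"),
    c("mcfe:caudal_end_growth_proportion", "mcfe:growth_proportion"),
    c("mcfe:rostral_end_fixed_to", "mcfe:fixed_to"),
    c("mcfe:caudal_end_fixed_to", "mcfe:fixed_to"))
}

#' Schema graph of the ontology vocabulary
#'
#' Builds the graph of schema-level triples: the six top classes typed as
#' `rdfs:Class`, the geometric primitive classes and process kind classes
#' under their taxonomies, and the subproperty axioms
#' (e.g. `directly_develops_from rdfs:subPropertyOf develops_from`,
#' the x/y/z orientation properties under `vector_coordinates`, and the
#' rostral/caudal variants under their parent properties).
#'
#' @return an [OntologyGraph-class] of asserted schema triples.
#' @export
schemaGraph <- function() {
  voc <- schemaVocabulary()
  g <- emptyGraph()
  tr <- list()
  for (cl in voc$topClasses) tr[[length(tr) + 1L]] <- c(cl, "rdf:type", "rdfs:Class")
  for (k in voc$geometricKinds)
    tr[[length(tr) + 1L]] <- c(paste0("mcfe:", k), "rdfs:subClassOf",
                               "mcfe:geometrical_entity")
  for (k in voc$processKinds)
    tr[[length(tr) + 1L]] <- c(paste0("mcfe:", k), "rdfs:subClassOf",
                               "mcfe:process")
  sp <- schemaSubPropertyTable()
  for (i in seq_len(nrow(sp)))
    tr[[length(tr) + 1L]] <- c(sp[i, 1], "rdfs:subPropertyOf", sp[i, 2])
  addTriples(g, do.call(rbind, tr))
}
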