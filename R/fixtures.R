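# Programmatic regeneration of the reference embryo (embryo 00,
# urogenital system) and the staging timetable, so every module is
# testable without external downloads.

#' Reference staging table: te1..te23 and gw9..gw12
#'
#' The 23 Carnegie stages cover the first eight gestation weeks; the
#' remaining gestation weeks 9 to 12 are single classes. Day intervals
#' are half-open \[from_day, to_day), so a stage's duration in day units
#' is `to_day - from_day`. The documented anchors are te11 (1 day), te14
#' (days 32-34, 2 days) and te17 (days 39-42, 3 days); the remaining
#' stage bounds are standard embryology staging defaults embedded as
#' data, externally sourced and overridable by asserting different
#' gestation-day triples in a graph.
#'
#' @return data.frame with columns `stage`, `from_day`, `to_day`,
#'   `successor`, forming a single 27-stage chain.
#' @examples
#' tab <- referenceStageTable()
#' subset(tab, stage == "mcfe:te14")
#' @export
referenceStageTable <- function() {
  fromD <- c(1, 2, 4, 6, 8, 12, 14, 16, 18, 20, 22, 23, 26,
             32, 34, 36, 39, 42, 44, 46, 49, 51, 53, 56, 63, 70, 77)
  toD <- c(fromD[-1], 84)
  stage <- c(paste0("mcfe:te", 1:23), paste0("mcfe:gw", 9:12))
  data.frame(stage = stage, from_day = as.integer(fromD),
             to_day = as.integer(toD),
             successor = c(stage[-1], NA_character_),
             stringsAsFactors = FALSE)
}

# triple-list helpers used by the builder
tl <- function() new.env(parent = emptyenv())
push <- function(env, s, p, o) {
  env$rows <- c(env$rows, list(c(s, p, o)))
  invisible(env)
}
pushOvoid <- function(env, id, spec, orientation = diag(3)) {
  push(env, id, "rdf:type", "mcfe:ovoid")
  push(env, id, "mcfe:barycenter_position", lit(spec$barycenter))
  push(env, id, "mcfe:axis_size", lit(spec$axisSize))
  push(env, id, "mcfe:x_axis_orientation", lit(orientation[, 1]))
  push(env, id, "mcfe:y_axis_orientation", lit(orientation[, 2]))
  push(env, id, "mcfe:z_axis_orientation", lit(orientation[, 3]))
}
pushDuct <- function(env, id, spec) {
  push(env, id, "rdf:type", "mcfe:duct")
  push(env, id, "mcfe:rostral_end_barycenter_position", lit(spec$rostral))
  push(env, id, "mcfe:caudal_end_barycenter_position", lit(spec$caudal))
  push(env, id, "mcfe:rostral_end_vector_coordinates", lit(spec$rostralTangent))
  push(env, id, "mcfe:caudal_end_vector_coordinates", lit(spec$caudalTangent))
  push(env, id, "mcfe:rostral_end_axis_size",
       lit(rep(spec$rostralRadius, 3)))
  push(env, id, "mcfe:caudal_end_axis_size",
       lit(rep(spec$caudalRadius, 3)))
}
pushStatic <- function(env, strId, instance, stage, geomId) {
  push(env, strId, "rdf:type", "mcfe:spatio_temporal_representation")
  push(env, strId, "mcfe:describes", instance)
  push(env, strId, "mcfe:at_stage", stage)
  push(env, strId, "mcfe:has_geometrical_representation", geomId)
}
pushProcess <- function(env, strId, instance, procId, kind, from, to) {
  push(env, strId, "rdf:type", "mcfe:spatio_temporal_representation")
  push(env, strId, "mcfe:describes", instance)
  push(env, strId, "mcfe:has_process", procId)
  push(env, strId, "mcfe:from_stage", from)
  push(env, strId, "mcfe:to_stage", to)
  push(env, procId, "rdf:type", paste0("mcfe:", kind))
}

#' Build the reference embryo graph (embryo 00, urogenital system)
#'
#' Regenerates the worked-example knowledge base: the anatomical
#' taxonomy (left kidney under kidney, part of the embryo), the lineage
#' facts (kidney from metanephric blastema from metanephros, the
#' metanephros part of the nephros; bladder and rectum from the cloaca),
#' the staging timetable with `following_stage` links, the organ
#' instances of embryo 00 with their spatio-temporal representations,
#' the six process kinds over their stage intervals (the left-kidney
#' growth of proportion 10 per axis from te14 to te20, the 90 degree
#' rotation about two reference axes, migrations, the ureter fixation at
#' the uretero-vesicular junction, the ureter-kidney interaction, the
#' cloaca division), and the hypoplastic-kidney disease that inhibits
#' kidney growth.
#'
#' @param withGeometry attach geometric primitives with fixed placeholder
#'   coordinates (see the package's non-canonical fixture constants);
#'   geometry is required for scene building.
#' @return an asserted [OntologyGraph-class]; saturate with [saturate()]
#'   for the inferred closure.
#' @examples
#' g <- saturate(buildReferenceEmbryo())
#' hasTriple(g, "mcfe:kidney", "mcfe:develops_from", "mcfe:metanephros")
#' @export
buildReferenceEmbryo <- function(withGeometry = TRUE) {
  e <- tl()
  G <- FIXTURE_GEOMETRY

  # -- taxonomy and lineage (the documented anatomical facts) --------------
  ent <- function(x) push(e, x, "rdfs:subClassOf", "mcfe:embryological_entity")
  for (cls in c("mcfe:embryo", "mcfe:kidney", "mcfe:ureter", "mcfe:gonad",
                "mcfe:cloaca", "mcfe:bladder", "mcfe:rectum",
                "mcfe:metanephric_blastema", "mcfe:metanephros", "mcfe:nephros",
                "mcfe:ureteric_bud", "mcfe:uretero_vesicular_junction"))
    ent(cls)
  push(e, "mcfe:left_kidney", "rdfs:subClassOf", "mcfe:kidney")
  push(e, "mcfe:right_kidney", "rdfs:subClassOf", "mcfe:kidney")
  push(e, "mcfe:left_ureter", "rdfs:subClassOf", "mcfe:ureter")
  push(e, "mcfe:right_ureter", "rdfs:subClassOf", "mcfe:ureter")
  push(e, "mcfe:left_gonad", "rdfs:subClassOf", "mcfe:gonad")
  push(e, "mcfe:right_gonad", "rdfs:subClassOf", "mcfe:gonad")
  push(e, "mcfe:left_kidney", "mcfe:part_of", "mcfe:embryo")
  push(e, "mcfe:right_kidney", "mcfe:part_of", "mcfe:embryo")
  push(e, "mcfe:metanephros", "mcfe:part_of", "mcfe:nephros")
  push(e, "mcfe:kidney", "mcfe:directly_develops_from", "mcfe:metanephric_blastema")
  push(e, "mcfe:metanephric_blastema", "mcfe:directly_develops_from",
       "mcfe:metanephros")
  push(e, "mcfe:bladder", "mcfe:directly_develops_from", "mcfe:cloaca")
  push(e, "mcfe:rectum", "mcfe:directly_develops_from", "mcfe:cloaca")
  push(e, "mcfe:ureter", "mcfe:directly_develops_from", "mcfe:ureteric_bud")

  # existence windows
  push(e, "mcfe:cloaca", "mcfe:starts_at", "mcfe:te11")
  push(e, "mcfe:cloaca", "mcfe:ends_at", "mcfe:te14")
  for (cls in c("mcfe:bladder", "mcfe:rectum")) {
    push(e, cls, "mcfe:starts_at", "mcfe:te15")
    push(e, cls, "mcfe:ends_at", "mcfe:gw12")
  }
  for (cls in c("mcfe:left_kidney", "mcfe:right_kidney", "mcfe:left_ureter",
                "mcfe:right_ureter", "mcfe:left_gonad", "mcfe:right_gonad")) {
    push(e, cls, "mcfe:starts_at", "mcfe:te13")
    push(e, cls, "mcfe:ends_at", "mcfe:gw12")
  }

  # -- staging timetable ---------------------------------------------------
  tab <- referenceStageTable()
  for (i in seq_len(nrow(tab))) {
    push(e, tab$stage[i], "rdf:type", "mcfe:temporal_entity")
    push(e, tab$stage[i], "mcfe:from_gestation_day", lit(tab$from_day[i]))
    push(e, tab$stage[i], "mcfe:to_gestation_day", lit(tab$to_day[i]))
    if (i > 1L) push(e, tab$stage[i], "mcfe:following_stage", tab$stage[i - 1L])
  }

  # -- embryo 00 instances -------------------------------------------------
  push(e, "mcfe:e00", "rdf:type", "mcfe:embryo")
  inst <- c(left_kidney = "mcfe:e00_left_kidney",
            right_kidney = "mcfe:e00_right_kidney",
            left_ureter = "mcfe:e00_left_ureter",
            right_ureter = "mcfe:e00_right_ureter",
            left_gonad = "mcfe:e00_left_gonad",
            right_gonad = "mcfe:e00_right_gonad",
            cloaca = "mcfe:e00_cloaca",
            bladder = "mcfe:e00_bladder",
            rectum = "mcfe:e00_rectum")
  for (nm in names(inst))
    push(e, inst[[nm]], "rdf:type", paste0("mcfe:", nm))
  push(e, "mcfe:e00_left_uvj", "rdf:type", "mcfe:uretero_vesicular_junction")
  push(e, "mcfe:e00_right_uvj", "rdf:type", "mcfe:uretero_vesicular_junction")

  # -- processes (all six kinds) -------------------------------------------
  pushProcess(e, "mcfe:str_lk_growth_te14_te20", "mcfe:e00_left_kidney",
              "mcfe:kidney_growth", "growth", "mcfe:te14", "mcfe:te20")
  push(e, "mcfe:kidney_growth", "mcfe:growth_proportion", lit(10))
  pushProcess(e, "mcfe:str_lk_rotation_te14_te20", "mcfe:e00_left_kidney",
              "mcfe:kidney_rotation", "rotation", "mcfe:te14", "mcfe:te20")
  push(e, "mcfe:kidney_rotation", "mcfe:rotation_degree", lit(90))
  push(e, "mcfe:kidney_rotation", "mcfe:rotation_axis", lit("x"))
  push(e, "mcfe:kidney_rotation", "mcfe:rotation_axis", lit("y"))
  pushProcess(e, "mcfe:str_lk_migration_te14_te20", "mcfe:e00_left_kidney",
              "mcfe:kidney_migration", "migration", "mcfe:te14", "mcfe:te20")
  push(e, "mcfe:kidney_migration", "mcfe:migration_direction",
       lit(G$kidney_migration_direction))
  pushProcess(e, "mcfe:str_lg_migration_te14_te20", "mcfe:e00_left_gonad",
              "mcfe:gonad_migration", "migration", "mcfe:te14", "mcfe:te20")
  push(e, "mcfe:gonad_migration", "mcfe:migration_direction",
       lit(G$gonad_migration_direction))
  pushProcess(e, "mcfe:str_lu_fixation_te14_te20", "mcfe:e00_left_ureter",
              "mcfe:ureter_fixation", "fixation", "mcfe:te14", "mcfe:te20")
  push(e, "mcfe:ureter_fixation", "mcfe:caudal_end_fixed_to", "mcfe:e00_left_uvj")
  pushProcess(e, "mcfe:str_uk_interaction_te14_te20", "mcfe:e00_left_ureter",
              "mcfe:ureter_kidney_interaction", "interaction",
              "mcfe:te14", "mcfe:te20")
  pushProcess(e, "mcfe:str_cl_division_te11_te14", "mcfe:e00_cloaca",
              "mcfe:cloaca_division", "division", "mcfe:te11", "mcfe:te14")

  # dependency chain: growth needs the ureter-kidney interaction, which
  # needs the hard fixation link
  push(e, "mcfe:kidney_growth", "mcfe:depends_on", "mcfe:ureter_kidney_interaction")
  push(e, "mcfe:ureter_kidney_interaction", "mcfe:depends_on", "mcfe:ureter_fixation")

  # -- disease -------------------------------------------------------------
  push(e, "mcfe:hypoplastic_kidney", "rdf:type", "mcfe:disease")
  push(e, "mcfe:hypoplastic_kidney", "mcfe:impacts_processus", "mcfe:kidney_growth")

  # -- geometry ------------------------------------------------------------
  if (withGeometry) {
    pushOvoid(e, "mcfe:embryo_boundary_ovoid", G$embryo)
    pushStatic(e, "mcfe:str_embryo_te11", "mcfe:e00", "mcfe:te11",
               "mcfe:embryo_boundary_ovoid")
    addOvoidStage <- function(organKey, instId, stage, geomId) {
      pushOvoid(e, geomId, G[[organKey]][[sub("mcfe:", "", stage)]])
      pushStatic(e, paste0("mcfe:str_", gsub("mcfe:e00_", "", instId), "_",
                           sub("mcfe:", "", stage)), instId, stage, geomId)
    }
    addOvoidStage("left_kidney", "mcfe:e00_left_kidney", "mcfe:te14",
                  "mcfe:lk_ovoid_te14")
    addOvoidStage("left_kidney", "mcfe:e00_left_kidney", "mcfe:te15",
                  "mcfe:lk_ovoid_te15")
    addOvoidStage("left_kidney", "mcfe:e00_left_kidney", "mcfe:te20",
                  "mcfe:lk_ovoid_te20")
    addOvoidStage("right_kidney", "mcfe:e00_right_kidney", "mcfe:te14",
                  "mcfe:rk_ovoid_te14")
    addOvoidStage("left_gonad", "mcfe:e00_left_gonad", "mcfe:te14",
                  "mcfe:lg_ovoid_te14")
    addOvoidStage("right_gonad", "mcfe:e00_right_gonad", "mcfe:te14",
                  "mcfe:rg_ovoid_te14")
    addOvoidStage("cloaca", "mcfe:e00_cloaca", "mcfe:te11",
                  "mcfe:cloaca_ovoid_te11")
    addOvoidStage("bladder", "mcfe:e00_bladder", "mcfe:te15",
                  "mcfe:bladder_ovoid_te15")
    addOvoidStage("rectum", "mcfe:e00_rectum", "mcfe:te15",
                  "mcfe:rectum_ovoid_te15")
    pushDuct(e, "mcfe:lu_duct_te14", G$left_ureter$te14)
    pushStatic(e, "mcfe:str_left_ureter_te14", "mcfe:e00_left_ureter",
               "mcfe:te14", "mcfe:lu_duct_te14")
    pushDuct(e, "mcfe:ru_duct_te14", G$right_ureter$te14)
    pushStatic(e, "mcfe:str_right_ureter_te14", "mcfe:e00_right_ureter",
               "mcfe:te14", "mcfe:ru_duct_te14")
    # junction points (immaterial contact entities)
    push(e, "mcfe:lk_uvj_point_te14", "rdf:type", "mcfe:point")
    push(e, "mcfe:lk_uvj_point_te14", "mcfe:barycenter_position",
         lit(G$left_uvj$point))
    pushStatic(e, "mcfe:str_left_uvj_te14", "mcfe:e00_left_uvj", "mcfe:te14",
               "mcfe:lk_uvj_point_te14")
    push(e, "mcfe:rk_uvj_point_te14", "rdf:type", "mcfe:point")
    push(e, "mcfe:rk_uvj_point_te14", "mcfe:barycenter_position",
         lit(G$right_uvj$point))
    pushStatic(e, "mcfe:str_right_uvj_te14", "mcfe:e00_right_uvj", "mcfe:te14",
               "mcfe:rk_uvj_point_te14")
  }

  addTriples(schemaGraph(), do.call(rbind, e$rows))
}
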