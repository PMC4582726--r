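# ---------------------------------------------------------------------------
# NON-CANONICAL geometry placeholders for the reference embryo fixture.
#
# The published description of the worked example prints no coordinates,
# sizes or orientations for the organs; the constants below are invented
# placeholders with plausible embryo-local magnitudes, fixed here so the
# fixture is deterministic. They are NOT anatomical measurements. The
# facts that ARE documented (growth proportion 10, the 90 degree
# two-axis kidney rotation, cloaca existence te11..te14, the te14/te17
# stage day bounds) live in buildReferenceEmbryo()/referenceStageTable()
# and are the only values acceptance-grade tests rely on.
# ---------------------------------------------------------------------------

FIXTURE_GEOMETRY <- list(
  embryo = list(barycenter = c(0, 0, 0), axisSize = c(1.0, 0.6, 1.6)),
  left_kidney = list(
    te14 = list(barycenter = c(0.25, 0, -0.55), axisSize = c(0.04, 0.03, 0.06)),
    te15 = list(barycenter = c(0.25, 0, -0.45), axisSize = c(0.06, 0.045, 0.09)),
    te20 = list(barycenter = c(0.25, 0, 0.05), axisSize = c(0.4, 0.3, 0.6))),
  right_kidney = list(
    te14 = list(barycenter = c(-0.25, 0, -0.55), axisSize = c(0.04, 0.03, 0.06))),
  left_gonad = list(
    te14 = list(barycenter = c(0.18, 0.05, -0.35), axisSize = c(0.03, 0.02, 0.05))),
  right_gonad = list(
    te14 = list(barycenter = c(-0.18, 0.05, -0.35), axisSize = c(0.03, 0.02, 0.05))),
  left_ureter = list(
    te14 = list(rostral = c(0.25, 0, -0.61), rostralTangent = c(0, 0, -0.3),
                caudal = c(0.08, 0, -0.72), caudalTangent = c(-0.3, 0, -0.1),
                rostralRadius = 0.012, caudalRadius = 0.01)),
  right_ureter = list(
    te14 = list(rostral = c(-0.25, 0, -0.61), rostralTangent = c(0, 0, -0.3),
                caudal = c(-0.08, 0, -0.72), caudalTangent = c(0.3, 0, -0.1),
                rostralRadius = 0.012, caudalRadius = 0.01)),
  cloaca = list(
    te11 = list(barycenter = c(0, 0, -0.75), axisSize = c(0.08, 0.06, 0.07))),
  bladder = list(
    te15 = list(barycenter = c(0, 0.05, -0.72), axisSize = c(0.06, 0.05, 0.05))),
  rectum = list(
    te15 = list(barycenter = c(0, -0.05, -0.78), axisSize = c(0.04, 0.04, 0.06))),
  left_uvj = list(point = c(0.08, 0, -0.72)),
  right_uvj = list(point = c(-0.08, 0, -0.72)),
  kidney_migration_direction = c(0, 0, 0.6),
  gonad_migration_direction = c(0, 0, -0.2)
)
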