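test_that("stage durations follow the half-open gestation-day convention", {
  tab <- referenceStageTable()
  tl14 <- buildTimeline(c("mcfe:te14", "mcfe:te14"), tab)
  expect_equal(tl14@totalUnits, 2L)
  expect_equal(tl14@frames$day, c(32L, 33L))
  expect_equal(buildTimeline(c("mcfe:te17", "mcfe:te17"), tab)@totalUnits, 3L)
  expect_equal(buildTimeline(c("mcfe:te11", "mcfe:te11"), tab)@totalUnits, 1L)
  # a longer period sums the per-stage durations
  tlLong <- buildTimeline(c("mcfe:te14", "mcfe:te17"), tab)
  i <- match(c("mcfe:te14", "mcfe:te17"), tab$stage)
  expect_equal(tlLong@totalUnits,
               sum(tab$to_day[i[1]:i[2]] - tab$from_day[i[1]:i[2]]))
})

test_that("timeline totals are conserved under splitting a period", {
  tab <- referenceStageTable()
  whole <- buildTimeline(c("mcfe:te10", "mcfe:gw12"), tab)
  left <- buildTimeline(c("mcfe:te10", "mcfe:te16"), tab)
  right <- buildTimeline(c("mcfe:te17", "mcfe:gw12"), tab)
  expect_equal(whole@totalUnits, left@totalUnits + right@totalUnits)
})

test_that("invalid timeline periods raise usage errors", {
  tab <- referenceStageTable()
  expect_error(buildTimeline(c("mcfe:te99", "mcfe:te14"), tab), "unknown stage")
  expect_error(buildTimeline(c("mcfe:te17", "mcfe:te14"), tab), "reversed")
})

test_that("growth tracks interpolate the scale factor linearly", {
  tr <- growthTrack(10, 16)
  expect_equal(tr[1], 1)
  expect_equal(tr[17], 10)
  expect_equal(tr[9], 5.5)  # midpoint of an even interval: (1 + 10) / 2
  expect_equal(growthTrack(1, 5), rep(1, 6))
  expect_error(growthTrack(0, 4), "> 0")
  paired <- growthTrack(c(2, 4), 10)
  expect_equal(paired[11, ], c(rostral = 2, caudal = 4))
})

test_that("rotation tracks accumulate the declared angle about each axis", {
  tr <- rotationTrack(90, c("x", "y"), 12)
  expect_equal(tr$angles[13], 90)
  expect_equal(tr$angles[1], 0)
  final <- tr$rotations[[13]]
  expect_equal(recoverRotationAngles(diag(3), final, c("x", "y")),
               c(x = 90, y = 90), tolerance = 1e-5)
  # no rotation is the identity at every frame
  none <- rotationTrack(0, "z", 5)
  for (R in none$rotations) expect_equal(R, diag(3))
  # a single 90-degree z rotation maps local x onto local y
  single <- rotationTrack(90, "z", 4)$rotations[[5]]
  expect_equal(drop(single %*% c(1, 0, 0)), c(0, 1, 0), tolerance = 1e-12)
  expect_error(rotationTrack(90, character(), 4), "axis")
})

test_that("migration tracks land exactly on their target", {
  still <- migrationTrack(c(1, 2, 3), list(), endPosition = c(1, 2, 3),
                          intervalFrames = 5)
  expect_equal(still, matrix(rep(c(1, 2, 3), each = 6), ncol = 3))
  proc <- list(process = "mcfe:p", parameters = list(migration_direction = c(0, 0, 6)))
  track <- migrationTrack(c(0, 0, 0), proc, intervalFrames = 6)
  expect_equal(track[, 3], 0:6)
  expect_error(migrationTrack(c(0, 0, 0), list(process = "mcfe:p",
                                               parameters = list()),
                              intervalFrames = 3),
               "migration_direction")
})

test_that("fixation pins the selected duct end and only that end", {
  kf <- list(kind = "duct", ends = list(
    rostral = list(position = c(0, 0, 0), radius = 1),
    caudal = list(position = c(1, 0, 0), radius = 1)))
  same <- applyFixation(kf, list(end = "caudal", target = c(1, 0, 0)))
  expect_equal(same, kf)
  moved <- applyFixation(kf, list(end = "caudal", target = c(2, 0, 0)))
  expect_equal(moved$ends$caudal$position, c(2, 0, 0))
  expect_equal(moved$ends$rostral$position, c(0, 0, 0))
  expect_error(applyFixation(list(kind = "ovoid", ends = NULL),
                             list(end = "caudal", target = c(0, 0, 0))),
               "duct or line")
})

test_that("diseases inactivate exactly the closure of their impacted processes", {
  gs <- refSaturated()
  all_ <- resolveActiveProcesses(gs, character(), saturated = TRUE)
  expect_true(all(all_))
  withDisease <- resolveActiveProcesses(gs, "mcfe:hypoplastic_kidney",
                                        saturated = TRUE)
  expect_false(withDisease[["mcfe:kidney_growth"]])
  expect_false(withDisease[["mcfe:ureter_kidney_interaction"]])  # via closure
  expect_false(withDisease[["mcfe:ureter_fixation"]])            # depth 2
  expect_true(withDisease[["mcfe:kidney_rotation"]])
  expect_true(withDisease[["mcfe:kidney_migration"]])
  # adding a disease never activates anything
  expect_true(all(names(which(!all_)) %in% names(which(!withDisease))))
  expect_error(resolveActiveProcesses(gs, "mcfe:no_such_disease",
                                      saturated = TRUE), "unknown disease")
})

test_that("the animated left kidney grows tenfold and rotates 90 about two axes", {
  scene <- buildAnimatedScene(refSaturated(), "mcfe:left_kidney",
                              c("mcfe:te14", "mcfe:te20"), saturated = TRUE)
  kf <- keyframes(scene, "mcfe:e00_left_kidney")
  expect_length(kf, 18L)  # days 32..49 inclusive
  k0 <- kf[[1]]; k1 <- kf[[length(kf)]]
  expect_equal(k1$axisSize / k0$axisSize, rep(10, 3), tolerance = 1e-9)
  ang <- recoverRotationAngles(k0$orientation, k1$orientation, c("x", "y"))
  expect_equal(unname(ang), c(90, 90), tolerance = 1e-5)
  # migration endpoint matches the te20 static pose
  expect_equal(k1$barycenter, c(0.25, 0, 0.05), tolerance = 1e-9)
})

test_that("an inactivated growth process leaves the kidney at its initial size", {
  scene <- buildAnimatedScene(refSaturated(), "mcfe:left_kidney",
                              c("mcfe:te14", "mcfe:te20"),
                              diseases = "mcfe:hypoplastic_kidney",
                              saturated = TRUE)
  kf <- keyframes(scene, "mcfe:e00_left_kidney")
  k0 <- kf[[1]]; k1 <- kf[[length(kf)]]
  expect_equal(k1$axisSize / k0$axisSize, rep(1, 3), tolerance = 1e-12)
  # rotation and migration are not impacted by the disease
  ang <- recoverRotationAngles(k0$orientation, k1$orientation, c("x", "y"))
  expect_equal(unname(ang), c(90, 90), tolerance = 1e-5)
})

test_that("the fixed ureter end coincides with the junction point at every frame", {
  scene <- buildAnimatedScene(refSaturated(),
                              c("mcfe:left_ureter", "mcfe:left_kidney"),
                              c("mcfe:te14", "mcfe:te20"), saturated = TRUE)
  target <- c(0.08, 0, -0.72)  # junction point of the fixture
  for (kf in keyframes(scene, "mcfe:e00_left_ureter"))
    expect_equal(kf$ends$caudal$position, target, tolerance = 1e-9)
})

test_that("the cloaca morph splits and its products exist only after te14", {
  scene <- buildAnimatedScene(refSaturated(),
                              c("mcfe:cloaca", "mcfe:bladder", "mcfe:rectum"),
                              c("mcfe:te10", "mcfe:te16"), saturated = TRUE)
  ck <- keyframes(scene, "mcfe:e00_cloaca")
  days <- vapply(ck, `[[`, numeric(1), "day")
  expect_equal(range(days), c(22, 33))  # existence te11..te14, half-open
  seps <- vapply(ck, function(k) k$division$separation, numeric(1))
  expect_true(all(diff(seps) >= 0))
  comps <- vapply(ck[c(1, length(ck))], function(k)
    meshComponentCount(keyframeMesh(k, gridResolution = 30L)), integer(1))
  expect_equal(comps[1], 1L)
  expect_equal(comps[2], 2L)
  bl <- vapply(keyframes(scene, "mcfe:e00_bladder"), `[[`, numeric(1), "day")
  expect_equal(min(bl), 34)  # first day after the cloaca's ends_at stage
  rc <- vapply(keyframes(scene, "mcfe:e00_rectum"), `[[`, numeric(1), "day")
  expect_equal(min(rc), 34)
})

test_that("exported OBJ sequences have one frame per day boundary and reload", {
  scene <- buildAnimatedScene(refSaturated(), "mcfe:left_kidney",
                              c("mcfe:te14", "mcfe:te20"), saturated = TRUE)
  dir <- withr::local_tempdir()
  files <- exportScene(scene, "obj", dir, resolution = 8L)
  expect_length(files, timeline(scene)@totalUnits + 1L)
  expect_true(all(file.exists(files)))
  back <- readOBJ(files[1])
  kf <- keyframes(scene, "mcfe:e00_left_kidney")[[1]]
  expect_equal(meshVertices(back), meshVertices(keyframeMesh(kf, 8L)),
               tolerance = 1e-6)
  expect_error(exportScene(scene, "gltf", dir), "unknown export format")
})

test_that("identical graph and config produce byte-identical exports", {
  build <- function(dir) {
    scene <- buildAnimatedScene(refSaturated(), "mcfe:left_kidney",
                                c("mcfe:te14", "mcfe:te15"), saturated = TRUE)
    exportScene(scene, "obj", dir, resolution = 8L)
  }
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- build(d1); f2 <- build(d2)
  expect_equal(length(f1), length(f2))
  for (k in seq_along(f1))
    expect_identical(readLines(f1[k]), readLines(f2[k]))
})
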