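# Day-based animation: timelines, per-process tracks, disease
# inactivation, scene assembly and export.
#
# The gestation day is the common unit of time across stages of unequal
# duration. Interpolation laws are linear (in scale factor, angle and
# position): the ontology specifies endpoints, never easing. Per frame,
# transforms compose growth -> rotation -> migration -> fixation, so an
# organ scales and rotates in its local frame before being placed, and
# the hard fixation link wins last.

#' Stage table of a graph
#'
#' Collects every stage resource carrying gestation-day bounds, ordered
#' chronologically, with the successor chain (contiguity by day).
#'
#' @param graph an [OntologyGraph-class].
#' @return data.frame with columns `stage`, `from_day`, `to_day`,
#'   `successor` (NA for the last stage).
#' @export
stageTableFromGraph <- function(graph) {
  tr <- triples(graph)
  stages <- unique(tr$s[tr$p == "mcfe:from_gestation_day"])
  if (!length(stages))
    stop("graph declares no stages (no from_gestation_day triples)")
  fromD <- vapply(stages, function(s)
    litNum(objectsOf(graph, s, "mcfe:from_gestation_day")[1]), numeric(1))
  toD <- vapply(stages, function(s)
    litNum(objectsOf(graph, s, "mcfe:to_gestation_day")[1]), numeric(1))
  ord <- order(fromD)
  out <- data.frame(stage = stages[ord], from_day = as.integer(fromD[ord]),
                    to_day = as.integer(toD[ord]),
                    successor = NA_character_, stringsAsFactors = FALSE)
  n <- nrow(out)
  if (n > 1L)
    out$successor[-n] <- ifelse(out$from_day[-1] == out$to_day[-n],
                                out$stage[-1], NA_character_)
  rownames(out) <- NULL
  out
}

#' Build the day timeline of an animation period
#'
#' One frame per gestation day covered by the period, using the
#' half-open day convention: a stage spanning days \[from, to) lasts
#' `to - from` units, so a 2-day stage contributes 2 frames and a 3-day
#' stage 3.
#'
#' @param period character(2) of stage ids, start before end.
#' @param stageTable data.frame as returned by [stageTableFromGraph()]
#'   or [referenceStageTable()].
#' @return a [Timeline-class].
#' @examples
#' tl <- buildTimeline(c("mcfe:te14", "mcfe:te14"), referenceStageTable())
#' tl@totalUnits
#' @export
buildTimeline <- function(period, stageTable) {
  stopifnot(length(period) == 2L)
  i0 <- match(period[1], stageTable$stage)
  i1 <- match(period[2], stageTable$stage)
  if (is.na(i0) || is.na(i1))
    stop("unknown stage in period: ",
         paste(period[is.na(c(i0, i1))], collapse = ", "))
  if (i0 > i1) stop("reversed period: ", period[1], " is after ", period[2])
  days <- seq(stageTable$from_day[i0], stageTable$to_day[i1] - 1L)
  stageOf <- vapply(days, function(d) {
    row <- which(stageTable$from_day <= d & d < stageTable$to_day)
    stageTable$stage[row[1]]
  }, character(1))
  new("Timeline",
      frames = data.frame(stage = stageOf, day = as.integer(days),
                          stringsAsFactors = FALSE),
      totalUnits = length(days))
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Per-frame scale factors of a growth process
#'
#' The factor rises linearly from 1 at the interval start to
#' `proportion` at the interval end. A (rostral, caudal) pair scales the
#' two end radii of a duct or line independently.
#'
#' @param proportion positive scalar, or numeric(2) `(rostral, caudal)`.
#' @param intervalFrames number of day units in the process interval
#'   (>= 1); factors are returned at the `intervalFrames + 1` inclusive
#'   frame boundaries.
#' @return numeric vector of factors, or a 2-column matrix
#'   (`rostral`, `caudal`) for the paired form.
#' @examples
#' growthTrack(10, 16)[17]
#' @export
growthTrack <- function(proportion, intervalFrames) {
  if (any(proportion <= 0)) stop("growth proportion must be > 0")
  stopifnot(intervalFrames >= 1L)
  u <- seq(0, 1, length.out = intervalFrames + 1L)
  if (length(proportion) == 2L) {
    out <- cbind(rostral = 1 + (proportion[1] - 1) * u,
                 caudal = 1 + (proportion[2] - 1) * u)
    return(out)
  }
  1 + (proportion - 1) * u
}

#' Per-frame rotations of a rotation process
#'
#' The angle about each selected local axis interpolates linearly from 0
#' to `degrees`; the per-frame rotation composes the selected-axis
#' rotations in declared order about the primitive's local frame.
#'
#' @param degrees total rotation angle in degrees.
#' @param axes character vector of axis selectors among `"x"`, `"y"`,
#'   `"z"` (at least one).
#' @param intervalFrames number of day units in the interval (>= 1).
#' @return list with `angles` (numeric, per-frame accumulated angle)
#'   and `rotations` (list of 3x3 local rotation matrices).
#' @export
rotationTrack <- function(degrees, axes, intervalFrames) {
  if (!length(axes)) stop("rotation process needs at least one axis selector")
  stopifnot(all(axes %in% c("x", "y", "z")), intervalFrames >= 1L)
  angles <- degrees * seq(0, 1, length.out = intervalFrames + 1L)
  rotations <- lapply(angles, function(a) {
    R <- diag(3)
    for (ax in axes) R <- R %*% rotationMatrix(ax, a)
    R
  })
  list(angles = angles, rotations = rotations)
}

#' Per-frame barycenter of a migration process
#'
#' If the organ has a later static pose, the barycenter interpolates
#' linearly from the start to that end position (end-stage pose takes
#' priority); otherwise the declared `migration_direction` vector is the
#' total displacement, applied linearly. The final frame lands exactly
#' on the target.
#'
#' @param startPosition numeric(3).
#' @param process process record (as in a [SceneDescription-class]),
#'   consulted for `migration_direction`.
#' @param endPosition optional numeric(3) target.
#' @param intervalFrames number of day units (>= 1).
#' @return (intervalFrames + 1) x 3 matrix of positions.
#' @export
migrationTrack <- function(startPosition, process, endPosition = NULL,
                           intervalFrames = 1L) {
  stopifnot(intervalFrames >= 1L)
  if (is.null(endPosition)) {
    dir <- process$parameters$migration_direction
    if (is.null(dir))
      stop("migration process ", process$process,
           " has neither an end-stage pose nor a migration_direction")
    endPosition <- startPosition + dir
  }
  u <- seq(0, 1, length.out = intervalFrames + 1L)
  outer(1 - u, startPosition) + outer(u, endPosition)
}

#' Apply a fixation constraint to a keyframe
#'
#' After all other transforms, the selected end of a duct/line is set
#' exactly to the target point's current position; the opposite end is
#' unchanged. The contact between the two organs is a unique point
#' belonging to both.
#'
#' @param organState a keyframe list with an `ends` element (duct/line).
#' @param constraint `list(end = "rostral"|"caudal", target = numeric(3))`.
#' @return the adjusted keyframe.
#' @export
applyFixation <- function(organState, constraint) {
  if (is.null(organState$ends))
    stop("fixation end-selector needs a duct or line primitive, not an ",
         organState$kind %||% "ovoid")
  end <- match.arg(constraint$end, c("rostral", "caudal"))
  organState$ends[[end]]$position <- constraint$target
  organState
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve which processes are inactivated by selected diseases
#'
#' A process is inactive iff some selected disease `impacts_processus`
#' it in the saturated graph, i.e. directly or through the closure of
#' `depends_on` chains; every other process is active.
#'
#' @param graph an [OntologyGraph-class].
#' @param diseases character vector of disease ids (may be empty).
#' @param saturated set TRUE to skip re-saturation.
#' @return named logical vector: process id -> active flag.
#' @export
resolveActiveProcesses <- function(graph, diseases = character(),
                                   saturated = FALSE) {
  if (!saturated) graph <- saturate(graph)
  tr <- triples(graph)
  procs <- unique(tr$o[tr$p == "mcfe:has_process"])
  active <- rep(TRUE, length(procs)); names(active) <- procs
  for (d in diseases) {
    if (!d %in% c(tr$s, tr$o))
      stop("unknown disease id: ", d)
    hit <- objectsOf(graph, d, "mcfe:impacts_processus")
    active[names(active) %in% hit] <- FALSE
  }
  active
}

# -- scene assembly ---------------------------------------------------------

orientationFromProps <- function(props) {
  if (is.null(props$x_axis_orientation)) return(diag(3))
  cbind(props$x_axis_orientation, props$y_axis_orientation,
        props$z_axis_orientation)
}

primitiveFromStatic <- function(static) {
  props <- static$properties
  kind <- static$shape
  if (kind %in% c("duct", "line")) {
    ends <- list(
      rostral = list(position = props$rostral_end_barycenter_position,
                     tangent = props$rostral_end_vector_coordinates,
                     radius = props$rostral_end_axis_size[1]),
      caudal = list(position = props$caudal_end_barycenter_position,
                    tangent = props$caudal_end_vector_coordinates,
                    radius = props$caudal_end_axis_size[1]))
    bary <- (ends$rostral$position + ends$caudal$position) / 2
    return(geometricPrimitive(kind, bary, rep(max(
      ends$rostral$radius, ends$caudal$radius), 3), diag(3), ends))
  }
  geometricPrimitive(kind,
    barycenter = props$barycenter_position %||% c(0, 0, 0),
    axisSize = props$axis_size %||% rep(0.02, 3),
    orientation = orientationFromProps(props))
}

stageDayLookup <- function(stageTable) {
  function(stage, which = c("from", "to")) {
    which <- match.arg(which)
    i <- match(stage, stageTable$stage)
    if (is.na(i)) stop("unknown stage: ", stage)
    if (which == "from") stageTable$from_day[i] else stageTable$to_day[i]
  }
}

# geometric center of a fixation target: a point entity, its geometric
# instance, or an organ animated in the scene
resolveTargetPosition <- function(graph, target, organsState, day) {
  for (nm in names(organsState)) {
    org <- organsState[[nm]]
    if (identical(nm, target) || identical(org$geometry, target)) {
      kf <- Filter(function(k) k$day == day, org$keyframes)
      if (length(kf)) return(kf[[1]]$barycenter)
    }
  }
  bp <- objectsOf(graph, target, "mcfe:barycenter_position")
  if (length(bp)) return(litVec(bp[1]))
  strs <- subjectsOf(graph, "mcfe:describes", target)
  for (s in strs) for (g in objectsOf(graph, s, "mcfe:has_geometrical_representation")) {
    bp <- objectsOf(graph, g, "mcfe:barycenter_position")
    if (length(bp)) return(litVec(bp[1]))
  }
  stop("cannot resolve fixation target position for ", target)
}

divisionParamsFor <- function(prim) {
  # support radius chosen so the undivided blob circumscribes the source
  # primitive: a single unit-weight ball has iso-radius
  # R * sqrt(1 - iso^(1/3)) at isovalue 0.3
  iso <- 0.3
  a <- max(prim@axisSize)
  R <- a / sqrt(1 - iso^(1 / 3))
  list(R = R, weight = 1, isovalue = iso, maxOffset = 1.5 * R,
       axis = prim@orientation[, 1])
}

#' Build an animated scene from a (saturated) graph
#'
#' Static representations seed each organ's primitive at its stages;
#' every active process track then deforms the organ over its interval
#' (growth scales the axis sizes, rotation turns the local frame,
#' migration moves the barycenter, fixation pins a duct end to its
#' target point after everything else). Organs outside their
#' `starts_at`/`ends_at` existence window produce no keyframes; a
#' division process swaps the source organ's mesh for the two-blob
#' implicit morph over its interval, and the products start on the first
#' day after the source's `ends_at` stage.
#'
#' @param graph an [OntologyGraph-class].
#' @param organs character vector of organ class or instance ids.
#' @param period character(2) of stage ids.
#' @param diseases character vector of disease ids; processes they
#'   impact (directly or via the saturated `depends_on` closure) are
#'   inactivated.
#' @param saturated set TRUE if `graph` is already saturated.
#' @return an [AnimatedScene-class].
#' @export
buildAnimatedScene <- function(graph, organs, period, diseases = character(),
                               saturated = FALSE) {
  if (!saturated) graph <- saturate(graph)
  stageTable <- stageTableFromGraph(graph)
  tl <- buildTimeline(period, stageTable)
  dayOf <- stageDayLookup(stageTable)
  sceneDays <- seq(dayOf(period[1], "from"), dayOf(period[2], "to"))
  scene <- extractScene(graph, organs, period)
  active <- resolveActiveProcesses(graph, diseases, saturated = TRUE)

  organsState <- list()
  for (nm in names(scene@organs)) {
    rec <- scene@organs[[nm]]
    if (!length(rec$statics)) next
    stageFrom <- vapply(rec$statics, function(s) dayOf(s$stage, "from"),
                        numeric(1))
    ord <- order(stageFrom)
    statics <- rec$statics[ord]
    base <- primitiveFromStatic(statics[[1]])

    # per-stage conflicting statics are an error
    if (anyDuplicated(vapply(statics, `[[`, character(1), "stage")))
      stop("conflicting static representations for ", nm, " at one stage")

    # existence window of the organ class, half-open in days
    cls <- rec$organ
    startsAt <- objectsOf(graph, cls, "mcfe:starts_at")
    endsAt <- objectsOf(graph, cls, "mcfe:ends_at")
    exFrom <- if (length(startsAt)) dayOf(startsAt[1], "from") else min(sceneDays)
    exTo <- if (length(endsAt)) dayOf(endsAt[1], "to") else max(sceneDays) + 1L

    procs <- rec$processes
    for (i in seq_along(procs))
      procs[[i]]$active <- isTRUE(active[[procs[[i]]$process]] %||% TRUE)

    organsState[[nm]] <- list(
      instance = nm, organ = cls, primitive = base,
      geometry = statics[[1]]$geometry, statics = statics,
      processes = procs, existence = c(exFrom, exTo), keyframes = list())
  }

  # first pass: keyframes without fixation (so targets resolve), then pin
  for (pass in 1:2) for (nm in names(organsState)) {
    org <- organsState[[nm]]
    base <- org$primitive
    days <- sceneDays[sceneDays >= org$existence[1] & sceneDays < org$existence[2]]
    # division products appear on the first day after the source ends
    kfs <- list()
    for (d in days) {
      axisSize <- base@axisSize
      orientation <- base@orientation
      barycenter <- base@barycenter
      ends <- if (base@kind %in% c("duct", "line")) base@ends else NULL
      division <- NULL
      for (pr in org$processes) {
        d0 <- stageDayLookup(stageTable)(pr$from, "from")
        d1 <- stageDayLookup(stageTable)(pr$to, "to")
        u <- clamp01((d - d0) / (d1 - d0))
        if (!pr$active) next
        if (identical(pr$kind, "growth")) {
          prop <- pr$parameters$growth_proportion
          rprop <- pr$parameters$rostral_end_growth_proportion
          cprop <- pr$parameters$caudal_end_growth_proportion
          if (!is.null(prop)) {
            if (prop <= 0) stop("growth proportion must be > 0 on ", pr$process)
            fac <- 1 + (prop - 1) * u
            axisSize <- axisSize * fac
            if (!is.null(ends)) {
              ends$rostral$radius <- ends$rostral$radius * fac
              ends$caudal$radius <- ends$caudal$radius * fac
            }
          }
          if (!is.null(ends) && !is.null(rprop))
            ends$rostral$radius <- ends$rostral$radius * (1 + (rprop - 1) * u)
          if (!is.null(ends) && !is.null(cprop))
            ends$caudal$radius <- ends$caudal$radius * (1 + (cprop - 1) * u)
        } else if (identical(pr$kind, "rotation")) {
          degrees <- pr$parameters$rotation_degree
          axes <- pr$parameters$rotation_axis %||% c("x", "y")
          Rloc <- diag(3)
          for (ax in axes) Rloc <- Rloc %*% rotationMatrix(ax, degrees * u)
          orientation <- orientation %*% Rloc
        } else if (identical(pr$kind, "migration")) {
          endPos <- NULL
          atEnd <- Filter(function(s) identical(s$stage, pr$to) &&
                            !is.null(s$properties$barycenter_position),
                          org$statics)
          if (length(atEnd))
            endPos <- atEnd[[1]]$properties$barycenter_position
          disp <- if (!is.null(endPos)) endPos - base@barycenter
          else if (!is.null(pr$parameters$migration_direction))
            pr$parameters$migration_direction
          else stop("migration process ", pr$process,
                    " has neither an end-stage pose nor a migration_direction")
          barycenter <- barycenter + disp * u
          if (!is.null(ends)) {
            ends$rostral$position <- ends$rostral$position + disp * u
            ends$caudal$position <- ends$caudal$position + disp * u
          }
        } else if (identical(pr$kind, "division")) {
          params <- divisionParamsFor(base)
          division <- list(separation = u,
                           shape = divisionShape(barycenter, u, params),
                           params = params)
        }
        # interaction processes are geometrically inert: they exist as
        # depends_on nodes that diseases can sever
      }
      kf <- list(day = d, kind = base@kind, axisSize = axisSize,
                 orientation = orientation, barycenter = barycenter,
                 ends = ends, division = division)
      if (pass == 2L) for (pr in org$processes) {
        if (!identical(pr$kind, "fixation") || !pr$active) next
        for (endName in c("rostral", "caudal")) {
          tgt <- pr$fixedTo[[endName]]
          if (!length(tgt)) next
          pos <- resolveTargetPosition(graph, tgt[1], organsState, d)
          kf <- applyFixation(kf, list(end = endName, target = pos))
        }
      }
      kfs[[length(kfs) + 1L]] <- kf
    }
    organsState[[nm]]$keyframes <- kfs
  }

  new("AnimatedScene", organs = organsState, timeline = tl)
}

#' Export an animated scene as a per-frame OBJ sequence
#'
#' Writes `frame_0001.obj`, `frame_0002.obj`, ... into `path`, one file
#' per day keyframe (inclusive endpoints: `totalUnits + 1` frames for a
#' full-period organ set), each containing the meshes of every organ
#' that exists on that day, as named groups.
#'
#' @param scene an [AnimatedScene-class].
#' @param format only `"obj"` is supported.
#' @param path output directory (created if needed).
#' @param resolution mesh tessellation resolution.
#' @param gridResolution marching grid resolution for division morphs.
#' @return invisibly, the vector of files written.
#' @export
exportScene <- function(scene, format = "obj", path = ".",
                        resolution = 16L, gridResolution = 32L) {
  if (!identical(tolower(format), "obj"))
    stop("unknown export format: ", format, " (supported: obj)")
  if (!length(scene@organs)) stop("cannot export an empty scene")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  fr <- scene@timeline@frames
  days <- c(fr$day, fr$day[nrow(fr)] + 1L)
  files <- character()
  for (k in seq_along(days)) {
    d <- days[k]
    meshes <- list()
    for (nm in names(scene@organs)) {
      kf <- Filter(function(x) x$day == d, scene@organs[[nm]]$keyframes)
      if (!length(kf)) next
      meshes[[gsub("[^A-Za-z0-9_]", "_", nm)]] <-
        keyframeMesh(kf[[1]], resolution, gridResolution)
    }
    f <- file.path(path, sprintf("frame_%04d.obj", k))
    writeOBJ(meshes, f)
    files <- c(files, f)
  }
  invisible(files)
}

#' Mesh of a single keyframe state
#'
#' @param kf a keyframe (see [keyframes()]).
#' @param resolution mesh tessellation resolution.
#' @param gridResolution marching grid resolution for division morphs.
#' @return a [Mesh-class].
#' @export
keyframeMesh <- function(kf, resolution = 16L, gridResolution = 32L) {
  if (!is.null(kf$division))
    return(isosurfaceMesh(kf$division$shape, gridResolution = gridResolution))
  prim <- if (kf$kind %in% c("duct", "line"))
    geometricPrimitive(kf$kind, kf$barycenter, kf$axisSize, diag(3), kf$ends)
  else
    geometricPrimitive(kf$kind, kf$barycenter, kf$axisSize, kf$orientation)
  primitiveMesh(prim, resolution)
}

#' Recover per-axis rotation angles between two frames
#'
#' Given initial and final local frames, decomposes the relative
#' rotation `t(R0) %*% R1` as a composition of rotations about the
#' selected local axes in declared order, and returns the accumulated
#' angle about each (degrees). Solved numerically (coarse scan plus
#' refinement), so it works for any ordered pair of principal axes.
#'
#' @param R0,R1 3x3 orientation matrices (columns = local axes).
#' @param axes character vector of 1 or 2 axis selectors.
#' @return named numeric vector of angles in degrees.
#' @export
recoverRotationAngles <- function(R0, R1, axes) {
  Rrel <- t(R0) %*% R1
  build <- function(angles) {
    R <- diag(3)
    for (i in seq_along(axes)) R <- R %*% rotationMatrix(axes[i], angles[i])
    R
  }
  objective <- function(angles) sum((build(angles) - Rrel)^2)
  if (length(axes) == 1L) {
    grid <- seq(-180, 180, by = 1)
    best <- grid[which.min(vapply(grid, function(a) objective(a), numeric(1)))]
    opt <- stats::optimize(function(a) objective(a), c(best - 2, best + 2))
    out <- opt$minimum
  } else if (length(axes) == 2L) {
    grid <- seq(-180, 175, by = 5)
    gg <- expand.grid(a = grid, b = grid)
    vals <- mapply(function(a, b) objective(c(a, b)), gg$a, gg$b)
    start <- as.numeric(gg[which.min(vals), ])
    opt <- stats::optim(start, objective, method = "BFGS")
    out <- opt$par
  } else stop("recoverRotationAngles supports 1 or 2 axes")
  names(out) <- axes
  out
}
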