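# Procedural triangle meshes for the six geometric primitive kinds.

#' Construct a geometric primitive
#'
#' @param kind one of `point`, `line`, `plane`, `ovoid`, `cylinder`,
#'   `duct`.
#' @param barycenter numeric(3), embryo-local units.
#' @param axisSize numeric(3) half-lengths along the local axes.
#' @param orientation 3x3 matrix, columns = local x/y/z axes
#'   (orthonormal, right-handed); identity by default.
#' @param ends for duct/line: `list(rostral = list(position, tangent,
#'   radius), caudal = ...)`.
#' @return a validated [GeometricPrimitive-class].
#' @export
geometricPrimitive <- function(kind, barycenter = c(0, 0, 0),
                               axisSize = c(1, 1, 1), orientation = diag(3),
                               ends = list()) {
  new("GeometricPrimitive", kind = kind, barycenter = as.numeric(barycenter),
      axisSize = as.numeric(axisSize), orientation = orientation, ends = ends)
}

#' Rotation matrix about a principal or arbitrary axis
#'
#' @param axis `"x"`, `"y"`, `"z"` or a numeric(3) direction.
#' @param degrees rotation angle in degrees (right-hand rule).
#' @return 3x3 rotation matrix.
#' @export
rotationMatrix <- function(axis, degrees) {
  a <- degrees * pi / 180
  ca <- cos(a); sa <- sin(a)
  if (is.character(axis)) {
    switch(axis,
      x = matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3),
      y = matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3),
      z = matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3),
      stop("axis must be x, y or z"))
  } else {
    u <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
    diag(3) + sa * K + (1 - ca) * (K %*% K)
  }
}

applyFrame <- function(V, prim) {
  sweep(V %*% t(prim@orientation), 2, prim@barycenter, "+")
}

mesh <- function(vertices, faces) {
  new("Mesh", vertices = vertices,
      faces = matrix(as.integer(faces), ncol = 3))
}

#' Tessellate an ovoid (ellipsoid) primitive
#'
#' UV-sphere tessellation with `resolution` meridians and
#' `resolution - 1` parallels, scaled by the per-axis half-sizes,
#' rotated by the orientation frame and translated to the barycenter.
#' Vertex count is `resolution * (resolution - 1) + 2` (two poles).
#'
#' @param primitive an ovoid [GeometricPrimitive-class].
#' @param resolution integer >= 3.
#' @return a watertight [Mesh-class].
#' @export
ovoidMesh <- function(primitive, resolution = 16L) {
  stopifnot(is(primitive, "GeometricPrimitive"), primitive@kind == "ovoid",
            resolution >= 3L)
  n <- as.integer(resolution)
  theta <- pi * seq_len(n - 1L) / n
  phi <- 2 * pi * (seq_len(n) - 1L) / n
  rings <- do.call(rbind, lapply(theta, function(th)
    cbind(sin(th) * cos(phi), sin(th) * sin(phi), rep(cos(th), n))))
  V <- rbind(c(0, 0, 1), rings, c(0, 0, -1))
  V <- sweep(V, 2, primitive@axisSize, "*")
  V <- applyFrame(V, primitive)

  idx <- function(i, j) 1L + (i - 1L) * n + ((j - 1L) %% n) + 1L  # ring i, slot j
  F <- list()
  for (j in seq_len(n)) F[[length(F) + 1L]] <- c(1L, idx(1L, j), idx(1L, j + 1L))
  for (i in seq_len(n - 2L)) for (j in seq_len(n)) {
    F[[length(F) + 1L]] <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
    F[[length(F) + 1L]] <- c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  }
  south <- nrow(V)
  for (j in seq_len(n))
    F[[length(F) + 1L]] <- c(south, idx(n - 1L, j + 1L), idx(n - 1L, j))
  mesh(V, do.call(rbind, F))
}

#' Tessellate a capped cylinder primitive
#'
#' Right circular cylinder of radius `axisSize[1]` and half-height
#' `axisSize[3]` along the local z axis, with both caps.
#'
#' @param primitive a cylinder [GeometricPrimitive-class].
#' @param resolution integer >= 3, points around the circumference.
#' @return a watertight [Mesh-class].
#' @export
cylinderMesh <- function(primitive, resolution = 16L) {
  stopifnot(is(primitive, "GeometricPrimitive"), primitive@kind == "cylinder",
            resolution >= 3L)
  n <- as.integer(resolution)
  r <- primitive@axisSize[1]; h <- primitive@axisSize[3]
  phi <- 2 * pi * (seq_len(n) - 1L) / n
  top <- cbind(r * cos(phi), r * sin(phi), rep(h, n))
  bot <- cbind(r * cos(phi), r * sin(phi), rep(-h, n))
  V <- rbind(c(0, 0, h), top, bot, c(0, 0, -h))
  V <- applyFrame(V, primitive)
  ti <- function(j) 1L + ((j - 1L) %% n) + 1L
  bi <- function(j) 1L + n + ((j - 1L) %% n) + 1L
  F <- list()
  for (j in seq_len(n)) F[[length(F) + 1L]] <- c(1L, ti(j), ti(j + 1L))
  for (j in seq_len(n)) {
    F[[length(F) + 1L]] <- c(ti(j), bi(j), bi(j + 1L))
    F[[length(F) + 1L]] <- c(ti(j), bi(j + 1L), ti(j + 1L))
  }
  south <- nrow(V)
  for (j in seq_len(n)) F[[length(F) + 1L]] <- c(south, bi(j + 1L), bi(j))
  mesh(V, do.call(rbind, F))
}

#' Evaluate a cubic Bezier curve given endpoints and tangents
#'
#' Hermite-equivalent cubic Bezier with control points `p0`,
#' `p0 + m0/3`, `p1 - m1/3`, `p1`, so the curve leaves `p0` along
#' tangent `m0` and arrives at `p1` along `m1`.
#'
#' @param p0,p1 numeric(3) endpoints.
#' @param m0,m1 numeric(3) endpoint tangents.
#' @param t parameter(s) in \[0, 1\].
#' @return numeric(3) for scalar `t`, else a length(t) x 3 matrix.
#' @examples
#' bezierPoint(c(0, 0, 0), c(3, 0, 0), c(3, 0, 0), c(3, 0, 0), 0.5)
#' @export
bezierPoint <- function(p0, m0, p1, m1, t) {
  if (any(t < 0 | t > 1)) stop("Bezier parameter t must lie in [0, 1]")
  P <- rbind(p0, p0 + m0 / 3, p1 - m1 / 3, p1)
  B <- cbind((1 - t)^3, 3 * t * (1 - t)^2, 3 * t^2 * (1 - t), t^3)
  out <- B %*% P
  if (length(t) == 1L) drop(out) else out
}

bezierTangent <- function(p0, m0, p1, m1, t) {
  P <- rbind(p0, p0 + m0 / 3, p1 - m1 / 3, p1)
  D <- 3 * (P[-1, , drop = FALSE] - P[-4, , drop = FALSE])
  B <- cbind((1 - t)^2, 2 * t * (1 - t), t^2)
  out <- B %*% D
  if (length(t) == 1L) drop(out) else out
}

normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

# rotation taking unit vector a onto unit vector b (identity if parallel)
rotationBetween <- function(a, b) {
  c_ <- sum(a * b)
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # opposite: rotate 180 about any perpendicular axis
    perp <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- normalize(perp - sum(perp * a) * a)
    return(rotationMatrix(axis, 180))
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - c_) / s^2)
}

#' Sweep a duct primitive into a closed tube mesh
#'
#' Samples the Bezier skeleton (endpoints and tangents from the rostral
#' and caudal end records) at `segments + 1` stations, sweeps circular
#' cross-sections whose radius interpolates linearly between the two end
#' radii, and closes the tube with two end caps. Ring frames are
#' parallel-transported (rotation-minimizing) along the skeleton to
#' avoid twist.
#'
#' @param primitive a duct [GeometricPrimitive-class] with both end
#'   records.
#' @param segments integer >= 1.
#' @param radialResolution integer >= 3.
#' @return a watertight [Mesh-class].
#' @export
ductMesh <- function(primitive, segments = 16L, radialResolution = 12L) {
  stopifnot(is(primitive, "GeometricPrimitive"), primitive@kind == "duct",
            segments >= 1L, radialResolution >= 3L)
  for (endName in c("rostral", "caudal"))
    if (is.null(primitive@ends[[endName]]))
      stop("duct is missing the ", endName, " end record (",
           endName, "_end_barycenter_position and friends)")
  ro <- primitive@ends$rostral; ca <- primitive@ends$caudal
  m <- as.integer(segments); n <- as.integer(radialResolution)
  ts <- seq(0, 1, length.out = m + 1L)
  P <- bezierPoint(ro$position, ro$tangent, ca$position, ca$tangent, ts)
  if (is.null(dim(P))) P <- matrix(P, nrow = 1)
  Tg <- bezierTangent(ro$position, ro$tangent, ca$position, ca$tangent, ts)
  Tg <- t(apply(Tg, 1, normalize))
  radii <- ro$radius + (ca$radius - ro$radius) * ts

  # parallel transport of the ring normal along the samples
  seed <- if (abs(Tg[1, 1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  N <- matrix(0, m + 1L, 3)
  N[1, ] <- normalize(seed - sum(seed * Tg[1, ]) * Tg[1, ])
  for (k in seq_len(m)) {
    R <- rotationBetween(Tg[k, ], Tg[k + 1L, ])
    nk <- drop(R %*% N[k, ])
    nk <- normalize(nk - sum(nk * Tg[k + 1L, ]) * Tg[k + 1L, ])
    N[k + 1L, ] <- nk
  }

  phi <- 2 * pi * (seq_len(n) - 1L) / n
  V <- matrix(0, (m + 1L) * n + 2L, 3)
  for (k in 0:m) {
    B <- c(Tg[k + 1L, 2] * N[k + 1L, 3] - Tg[k + 1L, 3] * N[k + 1L, 2],
           Tg[k + 1L, 3] * N[k + 1L, 1] - Tg[k + 1L, 1] * N[k + 1L, 3],
           Tg[k + 1L, 1] * N[k + 1L, 2] - Tg[k + 1L, 2] * N[k + 1L, 1])
    ring <- outer(cos(phi), N[k + 1L, ]) + outer(sin(phi), B)
    V[k * n + seq_len(n), ] <- sweep(radii[k + 1L] * ring, 2, P[k + 1L, ], "+")
  }
  c0 <- (m + 1L) * n + 1L; c1 <- c0 + 1L
  V[c0, ] <- P[1, ]; V[c1, ] <- P[m + 1L, ]

  ri <- function(k, j) k * n + ((j - 1L) %% n) + 1L
  F <- list()
  for (j in seq_len(n)) F[[length(F) + 1L]] <- c(c0, ri(0L, j + 1L), ri(0L, j))
  for (k in 0:(m - 1L)) for (j in seq_len(n)) {
    F[[length(F) + 1L]] <- c(ri(k, j), ri(k, j + 1L), ri(k + 1L, j + 1L))
    F[[length(F) + 1L]] <- c(ri(k, j), ri(k + 1L, j + 1L), ri(k + 1L, j))
  }
  for (j in seq_len(n)) F[[length(F) + 1L]] <- c(c1, ri(m, j), ri(m, j + 1L))
  mesh(V, do.call(rbind, F))
}

#' Marker meshes for point, line and plane primitives
#'
#' Immaterial entities are rendered as visualization stand-ins: a point
#' as a small octahedron-subdivision sphere marker, a line as a thin
#' tube of epsilon radius, a plane as a thin quad slab.
#'
#' @param primitive point/line/plane [GeometricPrimitive-class].
#' @param epsilon marker radius / slab half-thickness.
#' @param resolution tessellation resolution.
#' @return a [Mesh-class].
#' @export
markerMesh <- function(primitive, epsilon = 0.02, resolution = 8L) {
  kind <- primitive@kind
  if (kind == "point") {
    p <- geometricPrimitive("ovoid", primitive@barycenter,
                            rep(epsilon, 3), primitive@orientation)
    return(ovoidMesh(p, resolution))
  }
  if (kind == "line") {
    ends <- primitive@ends
    d <- geometricPrimitive("duct", primitive@barycenter, primitive@axisSize,
                            primitive@orientation,
                            ends = list(
      rostral = list(position = ends$rostral$position,
                     tangent = ends$rostral$tangent, radius = epsilon),
      caudal = list(position = ends$caudal$position,
                    tangent = ends$caudal$tangent, radius = epsilon)))
    return(ductMesh(d, segments = max(resolution, 1L), radialResolution = 6L))
  }
  if (kind == "plane") {
    p <- geometricPrimitive("cylinder", primitive@barycenter,
                            c(primitive@axisSize[1], primitive@axisSize[2],
                              epsilon),
                            primitive@orientation)
    return(cylinderMesh(p, max(resolution, 4L)))
  }
  stop("markerMesh handles point, line and plane primitives")
}

#' Mesh a primitive according to its kind
#'
#' Dispatch helper used by the scene builder: ovoid and cylinder go to
#' their parametric tessellations, ducts are swept along their Bezier
#' skeleton, point/line/plane become markers.
#'
#' @param primitive a [GeometricPrimitive-class].
#' @param resolution tessellation resolution.
#' @return a [Mesh-class].
#' @export
primitiveMesh <- function(primitive, resolution = 16L) {
  switch(primitive@kind,
         ovoid = ovoidMesh(primitive, resolution),
         cylinder = cylinderMesh(primitive, resolution),
         duct = ductMesh(primitive, segments = resolution,
                         radialResolution = max(3L, resolution %/% 2L)),
         markerMesh(primitive, resolution = resolution))
}

# -- mesh utilities ---------------------------------------------------------

meshEdges <- function(m) {
  f <- meshFaces(m)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Is a mesh watertight (edge-manifold and closed)?
#'
#' Every undirected edge must border exactly two faces.
#'
#' @param m a [Mesh-class].
#' @export
meshIsWatertight <- function(m) {
  if (!nrow(meshFaces(m))) return(FALSE)
  e <- meshEdges(m)
  counts <- table(paste(e[, 1], e[, 2]))
  all(counts == 2L)
}

#' Number of connected components of a mesh
#'
#' Components of the vertex graph induced by the faces (isolated,
#' unreferenced vertices are ignored).
#'
#' @param m a [Mesh-class].
#' @export
meshComponentCount <- function(m) {
  f <- meshFaces(m)
  if (!nrow(f)) return(0L)
  used <- sort(unique(as.vector(f)))
  parent <- seq_along(used)
  idx <- integer(max(used)); idx[used] <- seq_along(used)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]
                                                 i <- parent[i] }; i }
  e <- meshEdges(m)
  for (k in seq_len(nrow(e))) {
    a <- find(idx[e[k, 1]]); b <- find(idx[e[k, 2]])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_along(used), find, integer(1))))
}

#' Write a mesh to a Wavefront OBJ file
#' @param m a [Mesh-class] (or a named list of meshes, written as
#'   named groups).
#' @param path output file.
#' @export
writeOBJ <- function(m, path) {
  lines <- character()
  writeOne <- function(m, name, offset) {
    v <- meshVertices(m); f <- meshFaces(m)
    c(if (!is.null(name)) paste("g", name),
      sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
      sprintf("f %d %d %d", f[, 1] + offset, f[, 2] + offset, f[, 3] + offset))
  }
  if (is(m, "Mesh")) lines <- writeOne(m, NULL, 0L)
  else {
    offset <- 0L
    for (nm in names(m)) {
      lines <- c(lines, writeOne(m[[nm]], nm, offset))
      offset <- offset + nrow(meshVertices(m[[nm]]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a Wavefront OBJ file into a single mesh
#' @param path OBJ file (v/f records; polygonal faces are fanned into
#'   triangles).
#' @return a [Mesh-class].
#' @export
readOBJ <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  V <- do.call(rbind, lapply(strsplit(vl, "[[:space:]]+"), function(x)
    as.numeric(x[2:4])))
  F <- list()
  for (ln in strsplit(fl, "[[:space:]]+")) {
    ids <- as.integer(sub("/.*$", "", ln[-1]))
    for (k in seq_len(length(ids) - 2L))
      F[[length(F) + 1L]] <- c(ids[1], ids[k + 1L], ids[k + 2L])
  }
  mesh(V, do.call(rbind, F))
}
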