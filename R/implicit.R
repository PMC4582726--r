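# Meta-ball implicit surfaces: compact-support fields, isosurface
# extraction on a regular grid, and the two-blob division shape.

#' Construct an implicit meta-ball shape
#'
#' @param skeletons list of `list(skeleton, R, weight)`; `skeleton` is a
#'   point (numeric(3)) or a polyline (k x 3 matrix).
#' @param isovalue the field level defining the surface.
#' @return an [ImplicitShape-class].
#' @export
implicitShape <- function(skeletons, isovalue = 0.3) {
  skeletons <- lapply(skeletons, function(sk) {
    if (is.null(sk$weight)) sk$weight <- 1
    sk
  })
  new("ImplicitShape", skeletons = skeletons, isovalue = isovalue)
}

# squared distances from point rows P to a segment a-b
distToSegment <- function(P, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 < 1e-24) return(sqrt(rowSums(sweep(P, 2, a)^2)))
  t <- pmin(1, pmax(0, (sweep(P, 2, a) %*% ab) / len2))
  proj <- outer(drop(t), ab) + matrix(a, nrow(P), 3, byrow = TRUE)
  sqrt(rowSums((P - proj)^2))
}

skeletonDistance <- function(P, skeleton) {
  if (is.null(dim(skeleton)))
    return(sqrt(rowSums(sweep(P, 2, skeleton)^2)))
  if (nrow(skeleton) == 1L)
    return(sqrt(rowSums(sweep(P, 2, skeleton[1, ])^2)))
  d <- rep(Inf, nrow(P))
  for (k in seq_len(nrow(skeleton) - 1L))
    d <- pmin(d, distToSegment(P, skeleton[k, ], skeleton[k + 1L, ]))
  d
}

#' Evaluate the meta-ball field of an implicit shape
#'
#' Sum over skeletons of `weight * (1 - d^2/R^2)^3` for `d < R` and
#' exactly 0 at `d >= R` (compact support), where `d` is the distance
#' from the query point to the skeleton (point distance, or minimum
#' distance to the polyline).
#'
#' @param p numeric(3) or an n x 3 matrix of query points.
#' @param shape an [ImplicitShape-class].
#' @return numeric field value(s).
#' @examples
#' sh <- implicitShape(list(list(skeleton = c(0, 0, 0), R = 1, weight = 1)))
#' fieldValue(c(0, 0, 0), sh)
#' @export
fieldValue <- function(p, shape) {
  P <- if (is.null(dim(p))) matrix(p, 1, 3) else p
  f <- numeric(nrow(P))
  for (sk in shape@skeletons) {
    d <- skeletonDistance(P, sk$skeleton)
    u <- 1 - (d / sk$R)^2
    f <- f + sk$weight * ifelse(d < sk$R, u^3, 0)
  }
  if (is.null(dim(p))) f[1] else f
}

supportBounds <- function(shape, pad = 0.05) {
  pts <- do.call(rbind, lapply(shape@skeletons, function(sk) {
    S <- if (is.null(dim(sk$skeleton))) matrix(sk$skeleton, 1, 3) else sk$skeleton
    rbind(sweep(S, 2, rep(sk$R, 3), "-"), sweep(S, 2, rep(sk$R, 3), "+"))
  }))
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  margin <- pad * max(hi - lo)
  list(min = lo - margin, max = hi + margin)
}

# marching-tetrahedra case table: for each corner-sign case (1..14) the
# triangles as triples of tet edges, an edge being a pair of local
# corner slots (1..4)
tetCaseTable <- function() {
  lapply(1:14, function(case) {
    b <- as.logical(bitwAnd(case, c(1L, 2L, 4L, 8L)))
    ins <- which(b); out <- which(!b)
    if (length(ins) == 1L) {
      v <- ins
      list(rbind(c(v, out[1]), c(v, out[2]), c(v, out[3])))
    } else if (length(ins) == 3L) {
      v <- out
      list(rbind(c(v, ins[1]), c(v, ins[2]), c(v, ins[3])))
    } else {
      a <- ins[1]; b2 <- ins[2]; c_ <- out[1]; d <- out[2]
      quad <- rbind(c(a, c_), c(a, d), c(b2, d), c(b2, c_))
      list(quad[c(1, 2, 3), , drop = FALSE], quad[c(1, 3, 4), , drop = FALSE])
    }
  })
}

#' Extract the isosurface of an implicit shape as a triangle mesh
#'
#' Samples the field on a regular grid and triangulates the level set
#' `field = isovalue` by marching tetrahedra over the Freudenthal
#' 6-tetrahedra decomposition of each grid cell (consistent across
#' cells, so shared faces match up). Surface vertices are placed by
#' linear interpolation along crossing edges and deduplicated per grid
#' edge.
#'
#' @param shape an [ImplicitShape-class].
#' @param gridBounds `list(min = numeric(3), max = numeric(3))`; default
#'   is the padded bounding box of the skeletons' support.
#' @param gridResolution grid vertices per axis (default 64).
#' @return a [Mesh-class]; empty (0 faces) when the isovalue is outside
#'   the field range on the grid, with a warning.
#' @export
isosurfaceMesh <- function(shape, gridBounds = NULL, gridResolution = 64L) {
  stopifnot(is(shape, "ImplicitShape"), gridResolution >= 2L)
  if (is.null(gridBounds)) gridBounds <- supportBounds(shape)
  res <- as.integer(gridResolution)
  xs <- seq(gridBounds$min[1], gridBounds$max[1], length.out = res)
  ys <- seq(gridBounds$min[2], gridBounds$max[2], length.out = res)
  zs <- seq(gridBounds$min[3], gridBounds$max[3], length.out = res)
  G <- as.matrix(expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE))
  F <- fieldValue(G, shape)
  iso <- shape@isovalue
  inside <- F > iso
  if (!any(inside) || all(inside)) {
    warning("isovalue outside the field range on the grid; empty mesh")
    return(mesh(matrix(numeric(), 0, 3), matrix(integer(), 0, 3)))
  }
  s <- c(1L, res, res * res)
  # cube origins with at least one corner on each side of the isovalue
  oi <- seq_len(res - 1L)
  origins <- as.vector(outer(outer(oi, (oi - 1L) * s[2], "+"),
                             (oi - 1L) * s[3], "+"))
  off <- c(0L, s[1], s[2], s[1] + s[2], s[3], s[1] + s[3], s[2] + s[3],
           s[1] + s[2] + s[3])
  cnt <- rowSums(vapply(off, function(o) inside[origins + o], logical(length(origins))))
  origins <- origins[cnt > 0L & cnt < 8L]
  if (!length(origins)) {
    warning("no surface-crossing cell on the grid; empty mesh")
    return(mesh(matrix(numeric(), 0, 3), matrix(integer(), 0, 3)))
  }
  # Freudenthal: 6 tets per cube, one per axis permutation
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  Tlist <- lapply(perms, function(pm) {
    o1 <- s[pm[1]]; o2 <- o1 + s[pm[2]]; o3 <- o2 + s[pm[3]]
    cbind(origins, origins + o1, origins + o2, origins + o3)
  })
  T <- do.call(rbind, Tlist)
  B <- matrix(inside[T], nrow(T), 4L)
  caseId <- B %*% c(1L, 2L, 4L, 8L)
  keep <- caseId > 0L & caseId < 15L
  T <- T[keep, , drop = FALSE]; caseId <- caseId[keep]

  table_ <- tetCaseTable()
  cornersA <- list(); cornersB <- list()
  for (cs in unique(caseId)) {
    rows <- which(caseId == cs)
    for (tri in table_[[cs]]) {
      cornersA[[length(cornersA) + 1L]] <-
        cbind(T[rows, tri[1, 1]], T[rows, tri[2, 1]], T[rows, tri[3, 1]])
      cornersB[[length(cornersB) + 1L]] <-
        cbind(T[rows, tri[1, 2]], T[rows, tri[2, 2]], T[rows, tri[3, 2]])
    }
  }
  A <- do.call(rbind, cornersA); Bm <- do.call(rbind, cornersB)
  lo <- pmin(A, Bm); hi <- pmax(A, Bm)
  keyM <- matrix(paste(lo, hi), nrow(lo), 3L)
  ukeys <- unique(as.vector(keyM))
  fidx <- matrix(match(keyM, ukeys), nrow(keyM), 3L)
  # drop degenerate faces (an edge used twice can occur when a corner
  # value equals the isovalue exactly); keep the well-formed ones
  good <- fidx[, 1] != fidx[, 2] & fidx[, 2] != fidx[, 3] & fidx[, 1] != fidx[, 3]
  fidx <- fidx[good, , drop = FALSE]

  parts <- strsplit(ukeys, " ", fixed = TRUE)
  g1 <- as.integer(vapply(parts, `[`, character(1), 1L))
  g2 <- as.integer(vapply(parts, `[`, character(1), 2L))
  t <- (iso - F[g1]) / (F[g2] - F[g1])
  t[!is.finite(t)] <- 0.5
  V <- G[g1, , drop = FALSE] + t * (G[g2, , drop = FALSE] - G[g1, , drop = FALSE])
  mesh(V, fidx)
}

#' Two-blob implicit shape for a division process
#'
#' Two point meta-balls start coincident at `center` and move apart
#' along `axis` as `separation` grows from 0 to 1, the extracted
#' isosurface transitioning from a single blended blob to two separate
#' components once the midpoint field drops below the isovalue.
#'
#' @param center numeric(3).
#' @param separation scalar in \[0, 1\].
#' @param params list with `R` (support radius), `weight`, `isovalue`,
#'   `maxOffset` (offset of each blob at separation 1) and optional
#'   `axis` (default local x).
#' @return an [ImplicitShape-class].
#' @export
divisionShape <- function(center, separation,
                          params = list(R = 1, weight = 1, isovalue = 0.3,
                                        maxOffset = 1)) {
  stopifnot(separation >= 0, separation <= 1)
  axis <- if (is.null(params$axis)) c(1, 0, 0) else normalize(params$axis)
  d <- separation * params$maxOffset
  implicitShape(list(
    list(skeleton = center + d * axis, R = params$R, weight = params$weight),
    list(skeleton = center - d * axis, R = params$R, weight = params$weight)),
    isovalue = params$isovalue)
}

#' Analytic separation threshold of a division shape
#'
#' The separation at which the field at the midpoint between the two
#' blobs equals the isovalue, i.e. where the extracted surface splits
#' into two components: solving `2 w (1 - (s m / R)^2)^3 = isovalue`
#' for s (m = maxOffset).
#'
#' @param params as in [divisionShape()].
#' @return separation in \[0, 1\] (possibly > 1 if the blobs never
#'   separate within the parameter range).
#' @export
divisionSplitThreshold <- function(params = list(R = 1, weight = 1,
                                                 isovalue = 0.3, maxOffset = 1)) {
  ratio <- params$isovalue / (2 * params$weight)
  stopifnot(ratio > 0, ratio < 1)
  (params$R / params$maxOffset) * sqrt(1 - ratio^(1 / 3))
}
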