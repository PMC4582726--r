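test_that("the unit ovoid tessellates to a sphere with the stated vertex count", {
  for (res in c(3L, 8L, 16L)) {
    m <- ovoidMesh(geometricPrimitive("ovoid"), res)
    expect_equal(nrow(meshVertices(m)), res * (res - 1L) + 2L)
    expect_lt(max(abs(sqrt(rowSums(meshVertices(m)^2)) - 1)), 1e-12)
    expect_true(meshIsWatertight(m))
  }
})

test_that("ellipsoid bounding box and barycenter follow the axis sizes", {
  prim <- geometricPrimitive("ovoid", barycenter = c(0.25, 0, -0.55),
                             axisSize = c(1, 2, 3))
  m <- ovoidMesh(prim, 24)
  V <- sweep(meshVertices(m), 2, prim@barycenter)
  expect_equal(apply(V, 2, function(v) diff(range(v))), c(2, 4, 6),
               tolerance = 1e-9)
  expect_equal(colMeans(meshVertices(m)), prim@barycenter, tolerance = 1e-9)
})

test_that("cylinders are watertight at several resolutions and rotate correctly", {
  prim <- geometricPrimitive("cylinder")
  for (res in c(3L, 8L, 32L)) {
    m <- cylinderMesh(prim, res)
    expect_true(meshIsWatertight(m))
    side <- meshVertices(m)[2:(res + 1L), ]
    expect_lt(max(abs(sqrt(side[, 1]^2 + side[, 2]^2) - 1)), 1e-12)
  }
  # rotating the frame by 90 degrees about x maps local z onto -y
  R <- rotationMatrix("x", 90)
  expect_equal(drop(R %*% c(0, 0, 1)), c(0, -1, 0), tolerance = 1e-12)
  rot <- geometricPrimitive("cylinder", orientation = R)
  m <- cylinderMesh(rot, 8)
  expect_equal(meshVertices(m)[1, ], c(0, -1, 0), tolerance = 1e-12)
})

test_that("Bezier evaluation interpolates endpoints and the straight case", {
  p0 <- c(0, 0, 0); p1 <- c(3, 0, 0); m <- c(3, 0, 0)
  expect_equal(bezierPoint(p0, m, p1, m, 0), p0)
  expect_equal(bezierPoint(p0, m, p1, m, 1), p1)
  expect_equal(bezierPoint(p0, m, p1, m, 0.5), c(1.5, 0, 0))
  expect_error(bezierPoint(p0, m, p1, m, 1.2), "\\[0, 1\\]")
  # curved case: endpoint tangency
  pA <- c(0, 0, 0); mA <- c(0, 3, 0); pB <- c(2, 0, 0); mB <- c(0, -3, 0)
  expect_equal(bezierPoint(pA, mA, pB, mB, 0), pA)
  expect_equal(bezierPoint(pA, mA, pB, mB, 1), pB)
})

test_that("straight ducts have exact arc length and interpolated radii", {
  du <- geometricPrimitive("duct", ends = list(
    rostral = list(position = c(0, 0, 0), tangent = c(3, 0, 0), radius = 1),
    caudal = list(position = c(3, 0, 0), tangent = c(3, 0, 0), radius = 2)))
  ts <- seq(0, 1, length.out = 17)
  P <- bezierPoint(c(0, 0, 0), c(3, 0, 0), c(3, 0, 0), c(3, 0, 0), ts)
  arc <- sum(sqrt(rowSums(diff(P)^2)))
  expect_equal(arc, 3, tolerance = 1e-6)

  m <- ductMesh(du, segments = 16, radialResolution = 12)
  expect_true(meshIsWatertight(m))
  V <- meshVertices(m)
  firstRing <- V[1:12, ]
  lastRing <- V[(16 * 12 + 1):(17 * 12), ]
  expect_equal(sqrt(rowSums(sweep(firstRing, 2, c(0, 0, 0))^2)),
               rep(1, 12), tolerance = 1e-9)
  expect_equal(sqrt(rowSums(sweep(lastRing, 2, c(3, 0, 0))^2)),
               rep(2, 12), tolerance = 1e-9)
})

test_that("the fixture ureter duct meshes watertight with two caps", {
  sc <- extractScene(refSaturated(), "mcfe:left_ureter",
                     c("mcfe:te14", "mcfe:te20"))
  rec <- sc@organs[["mcfe:e00_left_ureter"]]
  static <- rec$statics[[1]]
  expect_equal(static$shape, "duct")
  prim <- embryofab:::primitiveFromStatic(static)
  m <- ductMesh(prim, segments = 12, radialResolution = 10)
  expect_true(meshIsWatertight(m))
  expect_equal(meshComponentCount(m), 1L)
})

test_that("missing duct end records produce a named geometry error", {
  du <- geometricPrimitive("duct", ends = list(
    rostral = list(position = c(0, 0, 0), tangent = c(1, 0, 0), radius = 1),
    caudal = list(position = c(1, 0, 0), tangent = c(1, 0, 0), radius = 1)))
  du@ends$caudal <- NULL
  expect_error(ductMesh(du, 4, 6), "caudal")
})

test_that("meshes are equivariant under rigid motions and deterministic", {
  base <- geometricPrimitive("ovoid", axisSize = c(1, 2, 3))
  m0 <- ovoidMesh(base, 12)
  R <- rotationMatrix(c(1, 1, 0), 35)
  t <- c(0.3, -0.2, 1.1)
  moved <- geometricPrimitive("ovoid", barycenter = t, axisSize = c(1, 2, 3),
                              orientation = R)
  m1 <- ovoidMesh(moved, 12)
  expect_equal(meshVertices(m1),
               sweep(meshVertices(m0) %*% t(R), 2, t, "+"),
               tolerance = 1e-9)
  expect_identical(meshVertices(ovoidMesh(base, 12)), meshVertices(m0))
})

test_that("non-orthonormal frames are rejected when building primitives", {
  skewed <- matrix(c(1, 0, 0, 1, 1, 0, 0, 0, 1), 3, 3)
  expect_error(geometricPrimitive("ovoid", orientation = skewed),
               "orthonormal")
})

test_that("point, line and plane primitives render as marker meshes", {
  pt <- geometricPrimitive("point", barycenter = c(0.08, 0, -0.72))
  mp <- markerMesh(pt, epsilon = 0.02)
  expect_true(meshIsWatertight(mp))
  expect_equal(colMeans(meshVertices(mp)), c(0.08, 0, -0.72), tolerance = 1e-9)
  pl <- geometricPrimitive("plane", axisSize = c(1, 1, 1))
  expect_true(meshIsWatertight(markerMesh(pl)))
  ln <- geometricPrimitive("line", ends = list(
    rostral = list(position = c(0, 0, 0), tangent = c(1, 0, 0), radius = 1),
    caudal = list(position = c(1, 0, 0), tangent = c(1, 0, 0), radius = 1)))
  expect_true(meshIsWatertight(markerMesh(ln)))
})

test_that("OBJ files round-trip vertex positions and faces", {
  m <- ovoidMesh(geometricPrimitive("ovoid", axisSize = c(1, 2, 3)), 8)
  f <- file.path(withr::local_tempdir(), "m.obj")
  writeOBJ(m, f)
  back <- readOBJ(f)
  expect_equal(meshVertices(back), meshVertices(m), tolerance = 1e-7)
  expect_equal(meshFaces(back), meshFaces(m))
})
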