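test_that("vertex generation emits 36 symmetric vertices around the input", {
  set.seed(7)
  for (i in 1:5) {
    x <- rnorm(18) * sample(c(0.01, 1, 10), 18, replace = TRUE)
    v <- generateVertices(x, alpha = 1, epsilon = 0.05)
    expect_equal(dim(v), c(36, 18))
    expect_equal(unname(colMeans(v)), unname(x))
    d <- attr(v, "deltas")
    expect_equal(d, pmax(abs(x), 0.05))
  }
  # the epsilon safeguard dominates at the origin
  v0 <- generateVertices(rep(0, 18), epsilon = 0.05)
  expect_setequal(unique(abs(v0[v0 != 0])), 0.05)
})

test_that("the closed-form cross-polytope volume matches known values", {
  expect_equal(crossPolytopeVolume(c(1, 1, 1)), 4 / 3)
  expect_equal(crossPolytopeVolume(c(1, 1)), 2)
  expect_equal(crossPolytopeVolume(rep(1, 18)), 2^18 / factorial(18))
  expect_equal(crossPolytopeVolume(c(2, 3, 4)), 4 / 3 * 24)  # scaling law
  expect_error(crossPolytopeVolume(c(1, 0)), "domain error")
})

test_that("the 3-D hull reproduces octahedron and cube geometry", {
  oct <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  h <- convexHull3d(oct)
  expect_equal(h$volume, crossPolytopeVolume(c(1, 1, 1)), tolerance = 1e-12)
  expect_equal(h$nHullVertices, 6)
  expect_equal(nrow(h$facets), 8)
  expect_equal(h$area, 8 * sqrt(3) / 2, tolerance = 1e-12)

  cube <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))
  hc <- convexHull3d(cube)
  expect_equal(hc$volume, 1, tolerance = 1e-12)
  expect_equal(hc$area, 6, tolerance = 1e-12)

  # interior points do not change the hull
  withPt <- rbind(oct, c(0.1, 0.1, 0.1))
  expect_equal(convexHull3d(withPt)$volume, h$volume, tolerance = 1e-12)
})

test_that("hull volume is monotone under point deletion", {
  set.seed(11)
  pts <- matrix(rnorm(36 * 3), ncol = 3)
  full <- convexHull3d(pts)$volume
  for (k in 1:5) {
    sub <- pts[sample(36, 20), ]
    expect_lte(convexHull3d(sub)$volume, full + 1e-12)
  }
})

test_that("hull volumes agree with Monte-Carlo estimates within 3 SE", {
  set.seed(23)
  for (i in 1:20) {
    pts <- matrix(rnorm(36 * 3, sd = runif(1, 0.5, 2)), ncol = 3)
    h <- convexHull3d(pts)
    mc <- mcHullVolume(pts, h$facets)
    expect_lt(abs(h$volume - mc$volume), 3 * mc$se + 1e-9)
  }
})

test_that("degenerate clouds raise a typed error carrying the rank", {
  flat <- cbind(matrix(rnorm(20), ncol = 2), 0)
  err <- tryCatch(convexHull3d(flat), degenerateGeometryError = identity)
  expect_s3_class(err, "degenerateGeometryError")
  expect_match(conditionMessage(err), "rank 2")
})

test_that("full-dimensional cross-polytope volume matches the hull in 3-D", {
  # the projected-vertex construction IS an axis-aligned cross-polytope when
  # the projection is the identity on 3 of the axes
  x <- c(1.5, -2, 0.5)
  d <- pmax(abs(x), 0.05)
  verts <- t(x + t(rbind(diag(d), -diag(d))))
  expect_equal(convexHull3d(verts)$volume, crossPolytopeVolume(d),
               tolerance = 1e-6)
})

test_that("barycenter and barycenter distance satisfy their contracts", {
  expect_equal(barycenterDistance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(barycenterDistance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(barycenterDistance(c(1, 2), c(1, 2, 3)), "shape error")
  pts <- matrix(rnorm(30), ncol = 3)
  expect_equal(polytopeBarycenter(pts), colMeans(pts))
  expect_equal(polytopeBarycenter(matrix(c(1, 2, 3), 1)), c(1, 2, 3))
  # joint rotation invariance
  set.seed(5)
  for (i in 1:5) {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    a <- rnorm(3); b <- rnorm(3)
    expect_equal(barycenterDistance(as.vector(q %*% a), as.vector(q %*% b)),
                 barycenterDistance(a, b), tolerance = 1e-10)
  }
})

test_that("volume asymmetry and its symmetrized form behave", {
  expect_equal(volumeAsymmetry(8, 2), 4)
  expect_equal(volumeAsymmetry(2, 8), 0.25)
  expect_equal(volumeAsymmetry(2, 8, symmetrized = TRUE), 4)
  expect_equal(volumeAsymmetry(3, 3, symmetrized = TRUE), 1)
  err <- tryCatch(volumeAsymmetry(0, 1), degenerateGeometryError = identity)
  expect_s3_class(err, "degenerateGeometryError")
})

test_that("anisotropy measures directional dominance and is rotation invariant", {
  set.seed(31)
  iso <- matrix(rnorm(3000 * 3), ncol = 3)
  expect_lt(cloudAnisotropy(iso), 1.15)
  stretched <- iso %*% diag(c(10, 1, 1))
  a <- cloudAnisotropy(stretched)
  expect_gt(a, 8); expect_lt(a, 12)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  expect_equal(cloudAnisotropy(stretched %*% q), a, tolerance = 1e-8)
})

test_that("dual polytopes compose projection, hulls, and descriptors", {
  tab <- makeMixedTable()
  x <- buildLatentTensor(tab)
  model <- fitEmbedding(standardizeTensor(x))
  # identical sides: dbary 0, asymmetry 1
  dp1 <- buildDualPolytope(tab, "CIRC-001", model)
  expect_equal(dp1@dbary, 0, tolerance = 1e-12)
  expect_equal(dp1@asymRatio, 1, tolerance = 1e-9)
  expect_equal(nrow(dp1@projSig), 36)
  expect_gte(length(unique(as.vector(dp1@facetsSig))), 4)
  # fully opposed sides: far beyond the extreme-discordance threshold
  dp3 <- buildDualPolytope(tab, "CIRC-003", model)
  expect_gt(dp3@dbary, 2.5)
  # barycenter/projection commutation: dbary equals the direct distance
  # between the projected latent points
  n <- nCircuitries(tab)
  p3 <- projectLatent(model, x, 3)
  direct <- sqrt(sum((p3[3, ] - p3[n + 3, ])^2))
  expect_equal(dp3@dbary, direct, tolerance = 1e-10)
})

test_that("hull volumes scale cubically with the perturbation constant", {
  tab <- makeMixedTable()
  x <- buildLatentTensor(tab)
  model <- fitEmbedding(standardizeTensor(x))
  p1 <- SigPolytopeParam(alpha = 1, epsilon = 0.05)
  p2 <- SigPolytopeParam(alpha = 3, epsilon = 0.15)  # all deltas tripled
  a <- buildDualPolytope(tab, "CIRC-002", model, p1)
  b <- buildDualPolytope(tab, "CIRC-002", model, p2)
  expect_equal(b@volSig / a@volSig, 27, tolerance = 1e-6)
  expect_equal(b@dbary, a@dbary, tolerance = 1e-12)  # dbary unaffected
})

test_that("the optional full-dimensional volume mode uses the closed form", {
  tab <- makeMixedTable()
  x <- buildLatentTensor(tab)
  model <- fitEmbedding(standardizeTensor(x))
  param <- SigPolytopeParam(volumeSpace = "latent18")
  dp <- buildDualPolytope(tab, "CIRC-002", model, param)
  xsig <- buildLatentVector(tab, "CIRC-002", "sig")
  deltas <- pmax(abs(xsig), param@epsilon)
  expect_equal(dp@volSig, crossPolytopeVolume(deltas / model@scales),
               tolerance = 1e-6)
})
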