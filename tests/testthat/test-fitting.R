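test_that("closest-point projection recovers on-surface and offset points", {
  m <- templateLungMesh()
  known <- data.frame(element = c(3L, 20L, 55L), xi1 = c(0.3, 0.62, 0.5),
                      xi2 = c(0.7, 0.18, 0.44))
  pts <- evaluateSurface(m, known$element, known$xi1, known$xi2)
  pr <- projectPoints(m, pts, labels = meshSurface(m)[known$element])
  expect_equal(pr$element, known$element)
  expect_lt(max(abs(pr$xi1 - known$xi1)), 1e-4)
  expect_lt(max(abs(pr$xi2 - known$xi2)), 1e-4)
  expect_lt(max(pr$distance), 1e-8)

  # offset along the local unit normal; dense-grid brute force as oracle
  e <- 20L; x1 <- 0.62; x2 <- 0.18; d <- 2.5
  d1 <- evaluateSurface(m, e, x1, x2, "d1")
  d2 <- evaluateSurface(m, e, x1, x2, "d2")
  nr <- c(d1[2] * d2[3] - d1[3] * d2[2],
          d1[3] * d2[1] - d1[1] * d2[3],
          d1[1] * d2[2] - d1[2] * d2[1])
  nr <- nr / sqrt(sum(nr^2))
  p <- evaluateSurface(m, e, x1, x2) + d * nr
  pr <- projectPoints(m, p, labels = meshSurface(m)[e])
  g <- seq(0, 1, length.out = 60)
  loc <- expand.grid(x1 = g, x2 = g)
  brute <- min(vapply(which(meshSurface(m) == meshSurface(m)[e]),
                      function(el) {
                        q <- evaluateSurface(m, el, loc$x1, loc$x2)
                        min(sqrt(rowSums(sweep(q, 2, as.vector(p))^2)))
                      }, numeric(1)))
  expect_equal(pr$distance, d, tolerance = 1e-4)
  expect_lte(pr$distance, brute + 1e-9)
})

test_that("exact projection ties resolve to the lowest element id", {
  # two elements over the same 4 nodes: identical patches, exact tie
  sp <- singlePatchMesh()
  m <- HermiteMesh(meshNodes(sp), rbind(1:4, 1:4),
                   c("left_lung", "left_lung"))
  pr <- projectPoints(m, rbind(c(0.4, 0.4, 3)))
  expect_equal(pr$element, 1L)
})

test_that("smoothness matrix is a PSD quadratic form with exact zeros", {
  m <- singlePatchMesh()
  expect_equal(smoothnessMatrix(m, c(0, 0, 0)), matrix(0, 16, 16))
  G <- smoothnessMatrix(m, c(0.3, 0.7, 0.5))
  expect_equal(G, t(G))
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-12)
  # constant patch: zero deformation => zero penalty
  u0 <- meshNodes(constantPatchMesh(c(2, 2, 2)))
  en <- function(nodes, G) {
    tot <- 0
    for (c in 1:3) {
      u <- as.vector(t(nodes[, c + c(0, 3, 6, 9)]))
      tot <- tot + drop(crossprod(u, G %*% u))
    }
    tot
  }
  expect_equal(en(u0, smoothnessMatrix(constantPatchMesh(), c(1, 1, 1))), 0)
})

test_that("penalty scales quadratically and matches brute-force quadrature", {
  m <- singlePatchMesh()
  w <- c(0.2, 0.9, 0.4)
  G <- smoothnessMatrix(m, w)
  en <- function(nodes) {
    tot <- 0
    for (c in 1:3) {
      u <- as.vector(t(nodes[, c + c(0, 3, 6, 9)]))
      tot <- tot + drop(crossprod(u, G %*% u))
    }
    tot
  }
  base <- meshNodes(m)
  pert <- base
  pert[2, 6] <- pert[2, 6] + 1   # one derivative DoF set to v = 1
  e1 <- en(pert) - en(base) -
    2 * sum(vapply(1:3, function(c) {
      u <- as.vector(t(base[, c + c(0, 3, 6, 9)]))
      du <- as.vector(t((pert - base)[, c + c(0, 3, 6, 9)]))
      drop(crossprod(du, G %*% u))
    }, numeric(1)))
  pert3 <- base
  pert3[2, 6] <- pert3[2, 6] + 3
  e3 <- en(pert3) - en(base) -
    2 * sum(vapply(1:3, function(c) {
      u <- as.vector(t(base[, c + c(0, 3, 6, 9)]))
      du <- as.vector(t((pert3 - base)[, c + c(0, 3, 6, 9)]))
      drop(crossprod(du, G %*% u))
    }, numeric(1)))
  expect_equal(e3 / e1, 9, tolerance = 1e-10)  # quadratic form in v

  # brute-force fine-quadrature oracle for the full energy of a patch
  mp <- HermiteMesh(pert, meshElements(m), meshSurface(m))
  gq <- 300L
  g <- (seq_len(gq) - 0.5) / gq
  loc <- expand.grid(x1 = g, x2 = g)
  sq <- function(order) {
    d <- evaluateSurface(mp, 1, loc$x1, loc$x2, order)
    sum(rowSums(d^2)) / gq^2
  }
  oracle <- w[1] * (sq("d1") + sq("d2")) + w[2] * (sq("d11") + sq("d22")) +
    w[3] * sq("d12")
  expect_equal(en(pert), oracle, tolerance = 1e-4)
})

test_that("noise-free self-fit recovers the generating mesh", {
  m <- templateLungMesh()
  s <- sampleSurface(m, 5)
  cl <- DataPointSet(as.matrix(s[, c("x", "y", "z")]), labels = s$surface)
  f <- fitMesh(m, cl, fitConfig(smoothing = c(1e-8, 1e-8, 1e-8),
                               tol = 1e-9, maxOuterIterations = 40L))
  expect_lt(fitRMSE(f), 1e-6)
  expect_lt(max(abs(meshNodes(fittedMesh(f))[, 1:3] -
                    meshNodes(m)[, 1:3])), 1e-4)
})

test_that("fit residuals under Gaussian noise carry the noise scale", {
  set.seed(42)
  m <- templateLungMesh()
  truth <- deformSubject(m, list(age = 70, sex = "M", bmi = 25,
                                 volume_L = 6.0),
                         generatorConfig(), seed = 3)$mesh
  cl <- sampleCloud(truth, density = 7, noiseSD = 1.0, seed = 4)
  f <- fitMesh(m, cl, fitConfig())
  expect_gte(fitRMSE(f), 0.8)
  expect_lte(fitRMSE(f), 1.2)
  # stronger smoothing trades misfit for smoothness
  f10 <- fitMesh(m, cl, fitConfig(smoothing = 10 * fitConfig()$smoothing))
  expect_lte(fitRMSE(f), f10@rmse + 1e-9)
})

test_that("fitting energy is non-increasing over outer iterations", {
  set.seed(7)
  m <- templateLungMesh()
  truth <- deformSubject(m, list(age = 40, sex = "F", bmi = 23,
                                 volume_L = 4.8),
                         generatorConfig(), seed = 8)$mesh
  cl <- sampleCloud(truth, density = 6, noiseSD = 0.5, seed = 9)
  f <- fitMesh(m, cl, fitConfig(projectionGrid = 7L))
  tr <- attr(f, "energyTrace")
  expect_gt(length(tr), 2L)
  expect_true(all(diff(tr) <= 1e-10 * max(tr)))
})

test_that("fitting is equivariant under rigid motion of data and template", {
  set.seed(11)
  m <- templateLungMesh()
  truth <- deformSubject(m, list(age = 60, sex = "F", bmi = 26,
                                 volume_L = 5.1),
                         generatorConfig(), seed = 12)$mesh
  cl <- sampleCloud(truth, density = 5, noiseSD = 1.0, seed = 13)
  f0 <- fitMesh(m, cl, fitConfig())
  tf <- rigidTransform()
  mR <- meshFromShapeVector(m, applyToShapeVector(shapeVector(m), tf))
  ptsR <- t(tf$alpha * tf$R %*% t(cloudPoints(cl)) + tf$T)
  clR <- DataPointSet(ptsR, labels = cloudLabels(cl))
  fR <- fitMesh(mR, clR, fitConfig())
  expect_equal(fitRMSE(fR), fitRMSE(f0), tolerance = 1e-8)
})

test_that("rank-deficient systems without smoothing raise a useful error", {
  m <- templateLungMesh()
  few <- sampleSurface(m, 2)[1:10, ]
  cl <- DataPointSet(as.matrix(few[, c("x", "y", "z")]),
                     labels = few$surface)
  expect_error(fitMesh(m, cl, fitConfig(smoothing = c(0, 0, 0))),
               "smoothing > 0")
})

test_that("C++ normal equations agree with the dense design-matrix route", {
  m <- templateLungMesh()
  set.seed(21)
  s <- sampleSurface(m, 3)
  keep <- sample(nrow(s), 150L)
  pts <- as.matrix(s[keep, c("x", "y", "z")]) + rnorm(450, sd = 0.5)
  pr <- projectPoints(m, pts, labels = s$surface[keep])
  gam <- runif(150, 0.5, 2)
  ne <- LungSSM:::.cpp_normal_eqs(meshElements(m), pr$element, pr$xi1,
                                  pr$xi2, gam, pts, nodeCount(m))
  W <- LungSSM:::.designMatrix(m, pr)
  expect_equal(ne$A, crossprod(W * gam, W), tolerance = 1e-12)
  expect_equal(ne$B, crossprod(W * gam, pts), tolerance = 1e-12,
               ignore_attr = TRUE)
})
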