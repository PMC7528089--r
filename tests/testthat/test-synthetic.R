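test_that("the template is deterministic with full surface coverage", {
  m1 <- templateLungMesh()
  m2 <- templateLungMesh()
  expect_identical(meshNodes(m1), meshNodes(m2))
  expect_identical(meshElements(m1), meshElements(m2))
  expect_setequal(unique(meshSurface(m1)), surfaceLabels())
  expect_true(all(meshElements(m1) >= 1 &
                    meshElements(m1) <= nodeCount(m1)))
  expect_true(any(meshLandmarks(m1) == "anatomical"))
  expect_true(any(meshLandmarks(m1) == "pseudo"))
  # resolution is configurable
  big <- templateLungMesh(c(9L, 8L), c(9L, 3L))
  expect_equal(nodeCount(big), 225L)
})

test_that("the template self-fits its own dense samples", {
  m <- templateLungMesh()
  s <- sampleSurface(m, 5)
  cl <- DataPointSet(as.matrix(s[, c("x", "y", "z")]), labels = s$surface)
  f <- fitMesh(m, cl, fitConfig(smoothing = c(1e-8, 1e-8, 1e-8),
                               tol = 1e-9, maxOuterIterations = 40L))
  expect_lt(fitRMSE(f), 1e-6)
})

test_that("subject deformation plants the advertised covariate effects", {
  tpl <- templateLungMesh()
  cfg <- generatorConfig()
  # zero effects, zero residual noise -> pure isotropic scaling
  cfg0 <- generatorConfig(taperPerAgeYear = 0, fissureShiftPerAgeYear = 0,
                          obliqueRotPerAgeYear = 0, apChangePerBmi = 0,
                          residualSD = 0)
  d0 <- deformSubject(tpl, list(age = 53, sex = "F", bmi = 24.7,
                                volume_L = 5), cfg0, seed = 1)
  alpha <- d0$loadings["size"]
  expect_equal(meshNodes(d0$mesh), alpha * meshNodes(tpl),
               tolerance = 1e-12, ignore_attr = TRUE)

  # same seed -> identical mesh; different seed -> different
  cv <- list(age = 70, sex = "M", bmi = 26, volume_L = 6.2)
  dA <- deformSubject(tpl, cv, cfg, seed = 5)
  dB <- deformSubject(tpl, cv, cfg, seed = 5)
  dC <- deformSubject(tpl, cv, cfg, seed = 6)
  expect_identical(meshNodes(dA$mesh), meshNodes(dB$mesh))
  expect_false(identical(meshNodes(dA$mesh), meshNodes(dC$mesh)))

  # age 90 vs age 20, same seed and other covariates: apical AP extent
  # shrinks and the horizontal fissure moves toward the base
  cfgD <- generatorConfig(residualSD = 0)
  cfgD$ageLoadingNoiseSD <- 0   # isolate the deterministic age pathway
  old <- deformSubject(tpl, list(age = 90, sex = "M", bmi = 25,
                                 volume_L = 6), cfgD, seed = 2)$mesh
  young <- deformSubject(tpl, list(age = 20, sex = "M", bmi = 25,
                                   volume_L = 6), cfgD, seed = 2)$mesh
  apExtent <- function(mesh) {
    s <- sampleSurface(mesh, 4)
    top <- s[s$z > quantile(s$z, 0.8) &
               s$surface %in% c("left_lung", "right_lung"), ]
    diff(range(top$y))
  }
  expect_lt(apExtent(old), apExtent(young))
  fissZ <- function(mesh) {
    s <- sampleSurface(mesh, 4)
    mean(s$z[s$surface == "horizontal_fissure"])
  }
  expect_lt(fissZ(old), fissZ(young))
})

test_that("derivative DoFs are transported exactly through affine maps", {
  tpl <- templateLungMesh()
  R <- rigidTransform()$R
  a <- 1.7
  map <- list(f = function(x) a * as.vector(R %*% x) + c(1, 2, 3),
              J = function(x) a * R, H = NULL)
  nodes <- LungSSM:::.applyMap(meshNodes(tpl), map)
  v <- applyToShapeVector(shapeVector(tpl),
                          rigidTransform(R = R, T = c(1, 2, 3), alpha = a))
  expect_equal(as.vector(t(nodes)), v, tolerance = 1e-12)
})

test_that("sampled clouds sit on the surface and scale with the noise", {
  mesh <- templateLungMesh()
  c0 <- sampleCloud(mesh, density = 3, noiseSD = 0, seed = 3)
  pr <- projectPoints(mesh, c0)
  expect_lt(max(pr$distance), 1e-9)
  expect_equal(nrow(cloudPoints(c0)), elementCount(mesh) * 9L)
  expect_setequal(unique(cloudLabels(c0)), surfaceLabels())

  cA <- sampleCloud(mesh, density = 3, noiseSD = 1, seed = 4)
  cB <- sampleCloud(mesh, density = 3, noiseSD = 1, seed = 4)
  expect_identical(cloudPoints(cA), cloudPoints(cB))

  # mean point-to-surface distance of isotropic noise ~ the folded-normal
  # mean of the normal component, sigma * sqrt(2/pi) (projection-distance
  # statistics oracle; curvature inflates it slightly)
  sigma <- 1.5
  cn <- sampleCloud(mesh, density = 4, noiseSD = sigma, seed = 5)
  prn <- projectPoints(mesh, cn)
  expected <- sigma * sqrt(2 / pi)
  expect_gt(mean(prn$distance), 0.9 * expected)
  expect_lt(mean(prn$distance), 1.35 * expected)
})

test_that("generated cohorts reproduce the target covariate distributions", {
  cfg <- generatorConfig(nSubjects = 83, seed = 19)
  coh <- generateCohort(cfg)
  cov <- coh$covariates
  expect_equal(nrow(cov), 83L)
  expect_true(all(cov$age >= 20 & cov$age <= 93))
  expect_true(all(cov$bmi < 30))
  expect_true(all(cov$volume_L > 0))
  # moments near the cohort's anthropometrics (wide Monte-Carlo tolerances)
  expect_equal(mean(cov$age), 53, tolerance = 0.12)
  expect_equal(sd(cov$age), 22, tolerance = 0.15)
  expect_equal(mean(cov$bmi), 24.7, tolerance = 0.05)
  expect_gt(mean(cov$sex == "F"), 0.40)
  expect_lt(mean(cov$sex == "F"), 0.78)
  expect_gt(mean(cov$volume_L[cov$sex == "M"]),
            mean(cov$volume_L[cov$sex == "F"]))
  # planted loadings present and finite
  expect_true(all(is.finite(coh$loadings)))
  # the age loading is oriented against age (negative correlation)
  expect_lt(cor(cov$age, coh$loadings[, "age"]), -0.5)
})

test_that("the same seed reproduces the covariates file byte for byte", {
  tmp1 <- tempfile(fileext = ".csv"); tmp2 <- tempfile(fileext = ".csv")
  cfg <- generatorConfig(nSubjects = 10, seed = 77, cloudDensity = 2)
  generateCohort(cfg, covariatesCsv = tmp1)
  generateCohort(cfg, covariatesCsv = tmp2)
  expect_identical(readLines(tmp1), readLines(tmp2))
})
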