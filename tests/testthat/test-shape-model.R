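# build a centred training matrix with prescribed mode variances
controlledMatrix <- function(P, variances, seed = 1) {
  set.seed(seed)
  N <- length(variances) + 1L
  U <- qr.Q(qr(matrix(rnorm(P * length(variances)), P)))
  # right factors orthogonal to the constant vector so columns stay centred
  B <- cbind(rep(1, N) / sqrt(N),
             matrix(rnorm(N * length(variances)), N))
  V <- qr.Q(qr(B))[, -1L, drop = FALSE]
  S <- diag(sqrt(variances * (N - 1)), length(variances))
  U %*% S %*% t(V) + 10   # constant offset becomes the mean
}

test_that("assembled training matrices preserve input order and length", {
  v1 <- 1:24 + 0.5; v2 <- 24:1 - 0.25
  tm <- assembleShapes(list(a = v1, b = v2))
  expect_equal(dim(tm$data), c(24L, 2L))
  expect_equal(tm$data[, 1], v1, ignore_attr = TRUE)
  expect_equal(tm$data[, 2], v2, ignore_attr = TRUE)
  expect_equal(tm$subjectIds, c("a", "b"))
  expect_error(assembleShapes(list(a = v1, b = v2[-1])), "mismatch.*b")
})

test_that("SVD model matches the dense covariance eigendecomposition", {
  set.seed(41)
  X <- matrix(rnorm(6 * 4), 6, 4) * 3
  mdl <- buildSSM(X)
  Xc <- X - rowMeans(X)
  ev <- eigen(tcrossprod(Xc) / (ncol(X) - 1), symmetric = TRUE)
  lam <- modelSingularValues(mdl)^2 / (ncol(X) - 1)
  expect_equal(lam, ev$values[seq_along(lam)], tolerance = 1e-10)
  for (l in seq_len(mdl@L)) {
    if (lam[l] < 1e-10) next
    expect_equal(abs(sum(modelModes(mdl)[, l] * ev$vectors[, l])), 1,
                 tolerance = 1e-8)
  }
  expect_equal(crossprod(modelModes(mdl)), diag(mdl@L), tolerance = 1e-10)
  # sign convention: largest-magnitude loading positive
  for (l in seq_len(mdl@L)) {
    u <- modelModes(mdl)[, l]
    expect_gt(u[which.max(abs(u))], 0)
  }
})

test_that("identical shapes give a zero-variance model", {
  v <- rnorm(30)
  expect_message(mdl <- buildSSM(cbind(v, v, v)), "zero variance")
  expect_equal(modelMean(mdl), v, ignore_attr = TRUE)
  expect_equal(modelSingularValues(mdl), rep(0, mdl@L), tolerance = 1e-10)
})

test_that("variance explained follows the cumulative-percentage rule", {
  X <- controlledMatrix(12, c(3, 1), seed = 2)
  mdl <- buildSSM(X)
  expect_equal(varianceExplained(mdl, 1), 75, tolerance = 1e-8)
  expect_equal(varianceExplained(mdl, mdl@L), 100, tolerance = 1e-10)
  vm <- vapply(seq_len(mdl@L), varianceExplained, numeric(1), model = mdl)
  expect_true(all(diff(vm) >= -1e-12))
  expect_error(varianceExplained(mdl, 0), "1..L")
  expect_error(varianceExplained(mdl, mdl@L + 1L), "1..L")

  # cutoff selection on prescribed fractions 50/30/15/5
  m2 <- buildSSM(controlledMatrix(16, c(50, 30, 15, 5), seed = 3))
  expect_equal(selectModes(m2, 80), 2L)
  expect_equal(selectModes(m2, 81), 3L)
  expect_equal(selectModes(m2, 100), 4L)
  expect_equal(selectModes(m2, 10), 1L)
})

test_that("mode shapes, projection and reconstruction are mutually inverse", {
  set.seed(44)
  shapes <- truthShapes(10, seed = 9)$shapes
  al <- gpa(shapes)
  mdl <- buildSSM(assembleShapes(al$aligned))
  mu <- modelMean(mdl)

  expect_equal(modeShape(mdl, 1, 0), mu)
  expect_equal(modeShape(mdl, 2, 1) - mu, -(modeShape(mdl, 2, -1) - mu))
  # +2.5 SD along mode 1 projects to scores (2.5, 0, ..., 0)
  sc <- projectShapes(mdl, modeShape(mdl, 1, 2.5))
  expect_equal(unname(sc[1]), 2.5, tolerance = 1e-8)
  expect_lt(max(abs(sc[-1]), na.rm = TRUE), 1e-8)

  expect_lt(max(abs(projectShapes(mdl, mu))), 1e-8)
  # SD-unit convention: training scores have sample SD 1 per mode
  tr <- projectShapes(mdl, al$aligned)
  sds <- apply(tr, 2, sd)
  expect_equal(sds[modelSingularValues(mdl) > 1e-8],
               rep(1, sum(modelSingularValues(mdl) > 1e-8)),
               tolerance = 1e-6, ignore_attr = TRUE)
  # completeness round trip for every training subject
  for (i in seq_len(ncol(al$aligned))) {
    rec <- reconstructShape(mdl, tr[i, ])
    expect_lt(max(abs(rec - al$aligned[, i])), 1e-8)
  }
  # reconstruction error is non-increasing in the number of modes
  errs <- vapply(seq_len(mdl@L), function(k)
    sqrt(sum((reconstructShape(mdl, tr[3, ], k) - al$aligned[, 3])^2)),
    numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
  expect_error(projectShapes(mdl, mu[-1]), "length")
})

test_that("variance is conserved across the decomposition", {
  set.seed(45)
  shapes <- truthShapes(8, seed = 10)$shapes
  al <- gpa(shapes, withScale = TRUE)
  mdl <- buildSSM(assembleShapes(al$aligned))
  Xc <- al$aligned - rowMeans(al$aligned)
  total <- sum(Xc^2) / (ncol(Xc) - 1)
  expect_equal(sum(modelSingularValues(mdl)^2) / (mdl@N - 1), total,
               tolerance = 1e-8)
  expect_equal(varianceExplained(mdl, mdl@L), 100, tolerance = 1e-8)
})

test_that("leave-one-out refits keep the dominant planted mode stable", {
  # near-identical shapes plus one strong planted direction of variation
  set.seed(46)
  base <- truthShapes(2, seed = 11)$shapes[, 1]
  d <- rnorm(length(base)); d <- d / sqrt(sum(d^2))
  shapes <- sapply(seq_len(8), function(i)
    base + rnorm(1, sd = 8) * d + rnorm(length(base), sd = 0.05))
  st <- looStability(shapes, withScale = TRUE, nModes = 2L)
  expect_false(attr(st, "degenerate"))
  m1 <- st[st$mode == 1L, ]
  expect_equal(nrow(m1), 8L)
  expect_true(all(m1$absCos > 0.99))
  # variance fractions re-sum to 100% in every fold (delta bounded by 1)
  expect_true(all(is.finite(m1$delta)))

  v <- rnorm(120)
  same <- cbind(v, v, v, v)
  expect_message(stD <- looStability(same, nModes = 1L), "zero variance")
  expect_true(attr(stD, "degenerate"))
  expect_true(all(is.na(stD$absCos)))
})
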