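# Small deterministic fixtures shared across the suite.

# one flat unit-square patch in the z = 0 plane with edge-matched first
# derivatives and zero cross terms
singlePatchMesh <- function(label = "left_lung") {
  nodes <- rbind(
    c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 0),
    c(1, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 0),
    c(0, 1, 0, 1, 0, 0, 0, 1, 0, 0, 0, 0),
    c(1, 1, 0, 1, 0, 0, 0, 1, 0, 0, 0, 0))
  HermiteMesh(nodes, rbind(1:4), label)
}

# all four nodes coincident, all derivatives zero
constantPatchMesh <- function(P = c(1, 2, 3)) {
  nodes <- matrix(rep(c(P, rep(0, 9)), 4), nrow = 4, byrow = TRUE)
  HermiteMesh(nodes, rbind(1:4), "left_lung")
}

# rigid-transform helper for equivariance checks
randomRotation <- function() {
  M <- matrix(rnorm(9), 3)
  qr_ <- qr(M)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

rigidTransform <- function(R = randomRotation(), T = rnorm(3, sd = 20),
                           alpha = 1) {
  structure(list(alpha = alpha, R = R, T = T), class = "SimilarityTransform")
}

# small cohort of ground-truth shape vectors (no mesh fitting), cheap
truthShapes <- function(n, seed, ...) {
  cfg <- generatorConfig(nSubjects = n, seed = seed, cloudDensity = 2, ...)
  coh <- generateCohort(cfg)
  shapes <- vapply(coh$subjects, function(s) shapeVector(s$truthMesh),
                   numeric(12L * nodeCount(coh$template)))
  colnames(shapes) <- coh$covariates$subject_id
  list(shapes = shapes, cohort = coh)
}
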