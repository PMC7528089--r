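#' Mesh fitting configuration
#'
#' @param smoothing non-negative penalty weights for the first-, second- and
#'   cross-derivative terms of the Sobolev-type smoothness norm (mm^2 units).
#' @param maxOuterIterations maximum number of outer project/solve loops.
#' @param tol convergence tolerance on the RMSE change between outer
#'   iterations (mm).
#' @param projectionGrid coarse grid resolution per parametric direction used
#'   to seed closest-point projection.
#' @return A list of class \code{"FitConfig"}.
#' @export
fitConfig <- function(smoothing = c(first = 1e-3, second = 0.3, cross = 0.3),
                      maxOuterIterations = 10L, tol = 1e-3,
                      projectionGrid = 5L, initialise = TRUE) {
  smoothing <- rep_len(as.numeric(smoothing), 3L)
  if (any(!is.finite(smoothing)) || any(smoothing < 0))
    stop("smoothing weights must be finite and >= 0")
  if (tol <= 0) stop("tol must be > 0")
  structure(list(smoothing = smoothing,
                 maxOuterIterations = as.integer(maxOuterIterations),
                 tol = as.numeric(tol),
                 projectionGrid = as.integer(projectionGrid),
                 initialise = isTRUE(initialise)),
            class = "FitConfig")
}

# integer surface codes aligned with surfaceLabels(); 0 = any
.surfaceCodes <- function(labels) {
  codes <- match(labels, surfaceLabels())
  codes[is.na(labels)] <- 0L
  if (any(is.na(codes)))
    stop("unknown surface label(s): ",
         paste(unique(labels[is.na(codes) & !is.na(labels)]), collapse = ", "))
  as.integer(codes)
}

#' Project points onto the closest mesh surface location
#'
#' Closest-point projection by coarse regular-grid search over candidate
#' elements (restricted to elements whose surface label matches the point's
#' label) refined by damped Newton iteration on the squared distance. Exact
#' grid ties resolve to the lowest element id; Newton divergence falls back to
#' the best grid point (counted and reported via a message, not an error).
#'
#' @param mesh a \linkS4class{HermiteMesh}.
#' @param points m x 3 matrix or a \linkS4class{DataPointSet}.
#' @param labels optional per-point surface labels (ignored when
#'   \code{points} is a \linkS4class{DataPointSet}).
#' @param grid coarse search resolution (>= 2).
#' @return A data.frame with columns \code{element, xi1, xi2, distance}.
#' @export
projectPoints <- function(mesh, points, labels = NULL, grid = 5L) {
  stopifnot(is(mesh, "HermiteMesh"))
  if (is(points, "DataPointSet")) {
    labels <- points@labels
    points <- points@points
  }
  points <- as.matrix(points)
  if (is.null(labels)) labels <- rep(NA_character_, nrow(points))
  ptCodes <- .surfaceCodes(labels)
  elCodes <- .surfaceCodes(mesh@surface)
  res <- .cpp_project(mesh@nodes, mesh@elements, elCodes, points,
                      ptCodes, as.integer(grid), 30L)
  nFail <- sum(res[, 5] == 0)
  if (nFail > 0)
    message(nFail, " point(s) used the grid fallback after Newton divergence")
  data.frame(element = as.integer(res[, 1]), xi1 = res[, 2], xi2 = res[, 3],
             distance = res[, 4])
}

# Gauss-Legendre rule on [0, 1]
.gauss01 <- function(n = 4L) {
  if (n == 4L) {
    x <- c(-0.861136311594053, -0.339981043584856,
           0.339981043584856, 0.861136311594053)
    w <- c(0.347854845137454, 0.652145154862546,
           0.652145154862546, 0.347854845137454)
  } else {
    # Golub-Welsch for other orders
    i <- seq_len(n - 1)
    b <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- b
    J[cbind(i + 1, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    x <- e$values
    w <- 2 * e$vectors[1, ]^2
    o <- order(x)
    x <- x[o]; w <- w[o]
  }
  list(x = (x + 1) / 2, w = w / 2)
}

#' Smoothness penalty matrix
#'
#' Assembles the symmetric positive semi-definite quadratic form over all
#' nodal DoFs of one spatial coordinate that measures surface deformation:
#' the weighted integral (4 x 4 Gauss-Legendre quadrature per element) of the
#' squared first parametric derivatives, squared second parametric
#' derivatives and squared mixed derivative. The same form applies to each of
#' x, y and z, so the matrix has dimension \code{4 * nodeCount(mesh)}.
#'
#' @param mesh a \linkS4class{HermiteMesh} (only the topology is used).
#' @param smoothing weights \code{c(first, second, cross)}, all >= 0.
#' @return A \code{4n x 4n} symmetric PSD matrix (zero when all weights are
#'   zero).
#' @export
smoothnessMatrix <- function(mesh, smoothing = c(1e-3, 0.3, 0.3)) {
  stopifnot(is(mesh, "HermiteMesh"))
  smoothing <- rep_len(as.numeric(smoothing), 3L)
  if (any(smoothing < 0)) stop("smoothing weights must be >= 0")
  n <- nodeCount(mesh)
  G <- matrix(0, 4L * n, 4L * n)
  if (all(smoothing == 0)) return(G)
  q <- .gauss01(4L)
  qp <- expand.grid(a = seq_len(4L), b = seq_len(4L))
  el <- mesh@elements
  for (e in seq_len(nrow(el))) {
    idx <- as.vector(t(outer((el[e, ] - 1L) * 4L, 1:4, "+")))
    Gl <- matrix(0, 16L, 16L)
    for (r in seq_len(nrow(qp))) {
      x1 <- q$x[qp$a[r]]; x2 <- q$x[qp$b[r]]
      ww <- q$w[qp$a[r]] * q$w[qp$b[r]]
      v1 <- .elementWeights(x1, x2, 1L, 0L)[1, ]
      v2 <- .elementWeights(x1, x2, 0L, 1L)[1, ]
      v11 <- .elementWeights(x1, x2, 2L, 0L)[1, ]
      v22 <- .elementWeights(x1, x2, 0L, 2L)[1, ]
      v12 <- .elementWeights(x1, x2, 1L, 1L)[1, ]
      Gl <- Gl + ww * (smoothing[1] * (tcrossprod(v1) + tcrossprod(v2)) +
                       smoothing[2] * (tcrossprod(v11) + tcrossprod(v22)) +
                       smoothing[3] * tcrossprod(v12))
    }
    G[idx, idx] <- G[idx, idx] + Gl
  }
  G
}

# design matrix rows: m x 4n per-coordinate weights for fixed projections
.designMatrix <- function(mesh, proj) {
  n <- nodeCount(mesh)
  m <- nrow(proj)
  w <- .elementWeights(proj$xi1, proj$xi2, 0L, 0L)
  el <- mesh@elements
  W <- matrix(0, m, 4L * n)
  for (k in 1:4) {
    nd <- el[proj$element, k]
    cols0 <- (nd - 1L) * 4L
    for (g in 1:4) {
      W[cbind(seq_len(m), cols0 + g)] <-
        W[cbind(seq_len(m), cols0 + g)] + w[, (k - 1L) * 4L + g]
    }
  }
  W
}

#' Fit a template mesh to a segmented surface point cloud
#'
#' Minimises the fitting energy: the gamma-weighted sum of squared distances
#' between each data point and its projection onto the surface, plus the
#' smoothness penalty evaluated on the deformation of the surface away from
#' the placed template (so the template's own curvature is not penalised and
#' rigid offsets of whole surfaces remain cheap, while wrinkling and
#' tangential node sliding are damped). Since projections
#' depend on the current geometry, the solver alternates (a) closest-point
#' projection of all points at the current geometry with (b) an exact linear
#' least-squares solve for all nodal DoFs with projections held fixed, until
#' the RMSE change falls below \code{tol} or \code{maxOuterIterations} is
#' reached. The three coordinates share one normal matrix, which is factorised
#' once per iteration.
#'
#' @param template a \linkS4class{HermiteMesh} supplying topology and starting
#'   geometry.
#' @param data a \linkS4class{DataPointSet}.
#' @param config a \code{\link{fitConfig}}.
#' @param smoothnessG optional precomputed \code{\link{smoothnessMatrix}} for
#'   this topology and \code{config$smoothing} (an optimisation for cohort
#'   fitting; recomputed when \code{NULL}).
#' @return A \linkS4class{FitResult}.
#' @export
fitMesh <- function(template, data, config = fitConfig(),
                    smoothnessG = NULL) {
  stopifnot(is(template, "HermiteMesh"), is(data, "DataPointSet"))
  n <- nodeCount(template)
  pts <- data@points
  gam <- data@weights
  if (is.null(smoothnessG))
    smoothnessG <- smoothnessMatrix(template, config$smoothing)
  mesh <- template
  if (isTRUE(config$initialise)) {
    # initial placement: match the template surface's centroid and RMS size
    # to the data cloud so the projection-based fit starts near the target.
    # Skipped when already nearly the identity (re-fitting in place would
    # otherwise re-converge slowly through tangential sliding).
    tp <- as.matrix(sampleSurface(mesh, 3L)[, c("x", "y", "z")])
    tc <- colMeans(tp)
    dc <- colMeans(pts)
    ts <- sqrt(sum(sweep(tp, 2L, tc)^2) / nrow(tp))
    ds <- sqrt(sum(sweep(pts, 2L, dc)^2) / nrow(pts))
    a0 <- if (ts > 0) ds / ts else 1
    Tv <- dc - a0 * tc
    if (abs(a0 - 1) > 0.02 || sqrt(sum(Tv^2)) > 0.02 * ds) {
      tf <- structure(list(alpha = a0, R = diag(3), T = Tv),
                      class = "SimilarityTransform")
      mesh@nodes <- matrix(applyToShapeVector(shapeVector(mesh), tf),
                           ncol = 12L, byrow = TRUE)
    }
  }
  # reference DoFs for the deformation penalty (the placed template)
  refU <- .coordDoFs(mesh@nodes)
  ptCodes <- .surfaceCodes(data@labels)
  elCodes <- .surfaceCodes(mesh@surface)
  rmsePrev <- Inf
  proj <- NULL
  iters <- 0L
  energyTrace <- numeric()
  for (it in seq_len(config$maxOuterIterations)) {
    res <- .cpp_project(mesh@nodes, mesh@elements, elCodes, pts, ptCodes,
                        config$projectionGrid, 30L)
    proj <- data.frame(element = as.integer(res[, 1]), xi1 = res[, 2],
                       xi2 = res[, 3], distance = res[, 4])
    rmse <- sqrt(sum(gam * proj$distance^2) / sum(gam))
    energyTrace <- c(energyTrace,
                     sum(gam * proj$distance^2) +
                       .deformationEnergy(mesh, smoothnessG, refU))
    if (abs(rmsePrev - rmse) < config$tol) break
    rmsePrev <- rmse
    iters <- it
    ne <- .cpp_normal_eqs(mesh@elements, proj$element, proj$xi1, proj$xi2,
                          gam, pts, n)
    A <- ne$A + smoothnessG
    B <- ne$B + smoothnessG %*% refU
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) {
      if (all(config$smoothing == 0))
        stop("fitting system is rank-deficient with zero smoothing; ",
             "set smoothing > 0 to regularise")
      stop("fitting system could not be factorised")
    }
    U <- backsolve(ch, forwardsolve(t(ch), B))
    nodes <- matrix(0, n, 12L)
    for (g in 1:4) {
      nodes[, (g - 1L) * 3L + (1:3)] <- U[seq(g, 4L * n, by = 4L), ,
                                          drop = FALSE]
    }
    mesh@nodes <- nodes
  }
  # residuals of the final geometry
  res <- .cpp_project(mesh@nodes, mesh@elements, elCodes, pts, ptCodes,
                      config$projectionGrid, 30L)
  residuals <- res[, 4]
  rmse <- sqrt(sum(gam * residuals^2) / sum(gam))
  energy <- sum(gam * residuals^2) +
    .deformationEnergy(mesh, smoothnessG, refU)
  out <- new("FitResult", mesh = mesh, residuals = residuals, rmse = rmse,
             iterations = iters, energy = energy)
  attr(out, "energyTrace") <- c(energyTrace, energy)
  out
}

# per-coordinate DoF columns (4n x 3) of a nodes matrix
.coordDoFs <- function(nodes) {
  vapply(1:3, function(c)
    as.vector(t(nodes[, c + c(0L, 3L, 6L, 9L), drop = FALSE])),
    numeric(4L * nrow(nodes)))
}

# (u - u0)' G (u - u0) summed over the three coordinates
.deformationEnergy <- function(mesh, G, refU) {
  D <- .coordDoFs(mesh@nodes) - refU
  sum(vapply(1:3, function(c) drop(crossprod(D[, c], G %*% D[, c])),
             numeric(1L)))
}

#' Fitting energy of a mesh against a point cloud
#'
#' The objective the fitting loop minimises: gamma-weighted squared projection
#' distances plus the smoothness penalty on the deformation from
#' \code{reference}.
#'
#' @inheritParams fitMesh
#' @param mesh geometry to evaluate.
#' @param reference mesh supplying the undeformed DoFs (defaults to
#'   \code{mesh} itself, i.e. zero penalty).
#' @return Scalar energy value.
#' @export
fitEnergy <- function(mesh, data, config = fitConfig(), smoothnessG = NULL,
                      reference = mesh) {
  if (is.null(smoothnessG))
    smoothnessG <- smoothnessMatrix(mesh, config$smoothing)
  proj <- suppressMessages(
    projectPoints(mesh, data, grid = config$projectionGrid))
  sum(data@weights * proj$distance^2) +
    .deformationEnergy(mesh, smoothnessG, .coordDoFs(reference@nodes))
}
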