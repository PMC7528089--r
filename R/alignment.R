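#' Optimal similarity transform between corresponding point sets
#'
#' Least-squares rigid (or similarity) superimposition of \code{source} onto
#' \code{target}: rotation via SVD of the cross-covariance matrix with a
#' reflection guard (Kabsch), translation from the centroids, and, when
#' \code{withScale}, scale as the centroid-size ratio.
#'
#' @param source,target n x 3 matrices of corresponding points (n >= 3,
#'   non-collinear).
#' @param withScale estimate a scale factor (default \code{FALSE}, i.e.
#'   \code{alpha = 1}).
#' @return A list of class \code{"SimilarityTransform"} with elements
#'   \code{alpha} (positive scalar), \code{R} (3 x 3 proper rotation) and
#'   \code{T} (translation, mm), mapping \code{x} to
#'   \code{alpha * R \%*\% x + T}.
#' @export
optimalSimilarity <- function(source, target, withScale = FALSE) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (nrow(source) < 3L || !identical(dim(source), dim(target)))
    stop("need >= 3 corresponding 3-D points")
  ms <- colMeans(source); mt <- colMeans(target)
  Xs <- sweep(source, 2L, ms); Xt <- sweep(target, 2L, mt)
  ss <- sqrt(sum(Xs^2)); st <- sqrt(sum(Xt^2))
  if (ss < 1e-12 || st < 1e-12)
    stop("degenerate configuration: zero centroid size")
  H <- crossprod(Xs, Xt)
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-300))
    stop("degenerate configuration: points are collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  alpha <- if (withScale) st / ss else 1
  Tv <- mt - alpha * as.vector(R %*% ms)
  structure(list(alpha = alpha, R = R, T = Tv),
            class = "SimilarityTransform")
}

#' Apply a similarity transform to a shape vector
#'
#' Position DoFs map by \code{alpha * R x + T}; all derivative DoFs are
#' direction vectors and map by \code{alpha * R} only (a constant shift has
#' zero derivative).
#'
#' @param shape a shape vector (length divisible by 12).
#' @param transform a \code{"SimilarityTransform"} from
#'   \code{\link{optimalSimilarity}}.
#' @return The transformed shape vector.
#' @export
applyToShapeVector <- function(shape, transform) {
  stopifnot(inherits(transform, "SimilarityTransform"))
  M <- matrix(shape, ncol = 12L, byrow = TRUE)
  aRt <- transform$alpha * t(transform$R)
  for (g in 1:4) {
    cols <- (g - 1L) * 3L + (1:3)
    M[, cols] <- M[, cols, drop = FALSE] %*% aRt
    if (g == 1L) M[, cols] <- sweep(M[, cols, drop = FALSE], 2L,
                                    transform$T, "+")
  }
  as.vector(t(M))
}

#' Generalised Procrustes alignment of a shape cohort
#'
#' Iteratively aligns every shape to the evolving consensus mean, removing
#' translation and rotation differences and, when \code{withScale}, scale
#' differences (the size-exclusive model). Only the nodal positions drive the
#' transform estimation; the resulting similarity is applied to the full
#' 12-DoF vectors. The first shape initialises the reference mean. The
#' consensus is centred at the origin and, when \code{withScale}, normalised
#' to unit centroid size.
#'
#' @param shapes a P x N matrix (columns are subjects) or a list of
#'   equal-length shape vectors.
#' @param withScale remove scale differences (size-exclusive model).
#' @param tol convergence tolerance on the relative consensus change.
#' @param maxIter maximum number of iterations.
#' @return A list with \code{aligned} (P x N matrix), \code{mean} (consensus
#'   shape vector, the arithmetic average of the aligned vectors),
#'   \code{transforms} (per-subject similarity transforms from the input
#'   shapes to the aligned shapes), \code{iterations} and \code{withScale}.
#' @export
gpa <- function(shapes, withScale = FALSE, tol = 1e-6, maxIter = 100L) {
  if (is.list(shapes)) shapes <- do.call(cbind, shapes)
  shapes <- as.matrix(shapes)
  N <- ncol(shapes)
  if (N < 2L) stop("need at least 2 shapes")
  if (nrow(shapes) %% 12L != 0L)
    stop("shape vector length must be divisible by 12")
  posOf <- function(v) .shapePositions(v)
  normalise <- function(m) {
    p <- posOf(m)
    ctr <- colMeans(p)
    id <- structure(list(alpha = 1, R = diag(3), T = -ctr),
                    class = "SimilarityTransform")
    m <- applyToShapeVector(m, id)
    if (withScale) {
      cs <- centroidSize(m)
      if (cs < 1e-12) stop("degenerate consensus: zero centroid size")
      m <- m / cs
    }
    m
  }
  consensus <- normalise(shapes[, 1L])
  transforms <- vector("list", N)
  aligned <- shapes
  iterations <- 0L
  change <- Inf
  for (it in seq_len(maxIter)) {
    tgt <- posOf(consensus)
    for (i in seq_len(N)) {
      tf <- optimalSimilarity(posOf(shapes[, i]), tgt, withScale = withScale)
      transforms[[i]] <- tf
      aligned[, i] <- applyToShapeVector(shapes[, i], tf)
    }
    newMean <- normalise(rowMeans(aligned))
    change <- sqrt(sum((newMean - consensus)^2)) /
      max(sqrt(sum(consensus^2)), 1e-12)
    consensus <- newMean
    iterations <- it
    if (change < tol) break
  }
  if (change >= tol)
    stop(sprintf("GPA did not converge in %d iterations (last change %.3g)",
                 maxIter, change))
  list(aligned = aligned, mean = rowMeans(aligned), transforms = transforms,
       iterations = iterations, withScale = withScale)
}
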