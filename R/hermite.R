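#' One-dimensional cubic Hermite basis
#'
#' Evaluates the four cubic Hermite polynomials that interpolate value and
#' derivative at the two ends of the unit interval. Tensor products of two
#' calls give the 16 bicubic patch basis values that weight the 12 nodal DoFs
#' of a surface element.
#'
#' @param xi evaluation points in \code{[0, 1]}.
#' @param deriv derivative order 0, 1 or 2.
#' @return A \code{length(xi) x 4} matrix with columns
#'   \code{(value0, deriv0, value1, deriv1)}.
#' @examples
#' hermiteBasis(0)    # (1, 0, 0, 0)
#' hermiteBasis(0.5)  # (0.5, 0.125, 0.5, -0.125)
#' @export
hermiteBasis <- function(xi, deriv = 0L) {
  if (any(!is.finite(xi)) || any(xi < 0) || any(xi > 1))
    stop("xi must lie in [0, 1]")
  t <- xi
  out <- switch(as.character(deriv),
    "0" = cbind(2 * t^3 - 3 * t^2 + 1, t^3 - 2 * t^2 + t,
                -2 * t^3 + 3 * t^2, t^3 - t^2),
    "1" = cbind(6 * t^2 - 6 * t, 3 * t^2 - 4 * t + 1,
                -6 * t^2 + 6 * t, 3 * t^2 - 2 * t),
    "2" = cbind(12 * t - 6, 6 * t - 4, -12 * t + 6, 6 * t - 2),
    stop("deriv must be 0, 1 or 2"))
  colnames(out) <- c("value0", "deriv0", "value1", "deriv1")
  out
}

# 16 tensor-product basis weights at (xi1, xi2) for one element, ordered as
# (corner (0,0),(1,0),(0,1),(1,1)) x (pos, d1, d2, d12). d1/d2 pick the
# derivative order of the basis in each direction.
.elementWeights <- function(xi1, xi2, d1 = 0L, d2 = 0L) {
  h1 <- hermiteBasis(xi1, d1)
  h2 <- hermiteBasis(xi2, d2)
  ca <- c(0L, 1L, 0L, 1L)
  cb <- c(0L, 0L, 1L, 1L)
  m <- length(xi1)
  w <- matrix(0, m, 16L)
  for (k in 1:4) {
    a <- ca[k]; b <- cb[k]
    w[, (k - 1L) * 4L + 1L] <- h1[, 2L * a + 1L] * h2[, 2L * b + 1L]
    w[, (k - 1L) * 4L + 2L] <- h1[, 2L * a + 2L] * h2[, 2L * b + 1L]
    w[, (k - 1L) * 4L + 3L] <- h1[, 2L * a + 1L] * h2[, 2L * b + 2L]
    w[, (k - 1L) * 4L + 4L] <- h1[, 2L * a + 2L] * h2[, 2L * b + 2L]
  }
  w
}

.orderSpec <- function(order) {
  switch(order,
    value = c(0L, 0L), d1 = c(1L, 0L), d2 = c(0L, 1L),
    d11 = c(2L, 0L), d22 = c(0L, 2L), d12 = c(1L, 1L),
    stop("order must be one of value, d1, d2, d11, d22, d12"))
}

#' Evaluate a mesh surface element
#'
#' Bicubic Hermite tensor-product interpolation of an element's four nodes'
#' 12-DoF data at local coordinates \code{(xi1, xi2)}. \code{order} selects
#' the position (\code{"value"}), the first parametric derivatives
#' (\code{"d1"}, \code{"d2"}) or the second parametric derivatives
#' (\code{"d11"}, \code{"d22"}, \code{"d12"}).
#'
#' @param mesh a \linkS4class{HermiteMesh}.
#' @param element element index (scalar or vector, recycled against xi).
#' @param xi1,xi2 local coordinates in \code{[0, 1]}.
#' @param order which quantity to evaluate.
#' @return An m x 3 matrix of positions (mm) or derivative vectors.
#' @export
evaluateSurface <- function(mesh, element, xi1, xi2, order = "value") {
  stopifnot(is(mesh, "HermiteMesh"))
  spec <- .orderSpec(match.arg(order, c("value", "d1", "d2",
                                        "d11", "d22", "d12")))
  m <- max(length(element), length(xi1), length(xi2))
  element <- rep_len(as.integer(element), m)
  xi1 <- rep_len(as.numeric(xi1), m)
  xi2 <- rep_len(as.numeric(xi2), m)
  if (any(element < 1L | element > elementCount(mesh)))
    stop("unknown element id")
  if (any(xi1 < 0 | xi1 > 1 | xi2 < 0 | xi2 > 1))
    stop("xi must lie in [0, 1]")
  w <- .elementWeights(xi1, xi2, spec[1L], spec[2L])
  nodes <- mesh@nodes
  el <- mesh@elements
  out <- matrix(0, m, 3L)
  for (k in 1:4) {
    nd <- el[element, k]
    for (g in 1:4) {
      wk <- w[, (k - 1L) * 4L + g]
      out <- out + wk * nodes[nd, (g - 1L) * 3L + (1:3), drop = FALSE]
    }
  }
  colnames(out) <- c("x", "y", "z")
  out
}

#' Sample a regular grid of surface points on every element
#'
#' @param mesh a \linkS4class{HermiteMesh}.
#' @param grid points per parametric direction per element (>= 2).
#' @return A data.frame with columns \code{element, xi1, xi2, x, y, z,
#'   surface}; \code{elements x grid^2} rows.
#' @export
sampleSurface <- function(mesh, grid = 4L) {
  stopifnot(is(mesh, "HermiteMesh"))
  grid <- as.integer(grid)
  if (grid < 2L) stop("grid must be >= 2")
  g <- seq(0, 1, length.out = grid)
  loc <- expand.grid(xi1 = g, xi2 = g)
  ne <- elementCount(mesh)
  element <- rep(seq_len(ne), each = nrow(loc))
  xi1 <- rep(loc$xi1, ne)
  xi2 <- rep(loc$xi2, ne)
  p <- evaluateSurface(mesh, element, xi1, xi2, "value")
  data.frame(element = element, xi1 = xi1, xi2 = xi2,
             x = p[, 1], y = p[, 2], z = p[, 3],
             surface = mesh@surface[element],
             stringsAsFactors = FALSE)
}

#' Flatten a mesh into its shape vector
#'
#' Concatenates all nodal DoFs in fixed node order (12 per node), the unit of
#' statistical analysis: with a shared topology this provides point-to-point
#' correspondence across subjects.
#'
#' @param mesh a \linkS4class{HermiteMesh}.
#' @return Numeric vector of length \code{12 * nodeCount(mesh)}.
#' @export
shapeVector <- function(mesh) as.vector(t(mesh@nodes))

#' Rebuild a mesh from a shape vector
#'
#' @param template a \linkS4class{HermiteMesh} supplying the topology.
#' @param v shape vector of length \code{12 * nodeCount(template)}.
#' @return A \linkS4class{HermiteMesh} with the template's topology and the
#'   vector's DoFs.
#' @export
meshFromShapeVector <- function(template, v) {
  n <- nodeCount(template)
  if (length(v) != 12L * n)
    stop("shape vector length must be 12 * nodeCount(template)")
  HermiteMesh(matrix(v, nrow = n, byrow = TRUE), template@elements,
              template@surface, template@landmarks)
}

# position block (n x 3) of a shape vector
.shapePositions <- function(v) {
  matrix(v, ncol = 12L, byrow = TRUE)[, 1:3, drop = FALSE]
}

#' Centroid size of a shape vector
#'
#' Root sum of squared distances of the nodal positions from their centroid;
#' the standard geometric-morphometrics size measure removed by scaling GPA.
#'
#' @param v a shape vector (length divisible by 12).
#' @return Positive scalar (mm).
#' @export
centroidSize <- function(v) {
  p <- .shapePositions(v)
  sqrt(sum(scale(p, scale = FALSE)^2))
}
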