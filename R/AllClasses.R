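#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib LungSSM, .registration = TRUE
NULL

#' Recognised anatomical surface labels
#'
#' The five surfaces carried by a bi-lung shape description: the two lung
#' external surfaces and the three lobar fissure sheets (the left lung has an
#' oblique fissure only; the right lung has an oblique and a horizontal
#' fissure).
#'
#' @export
surfaceLabels <- function() {
  c("left_lung", "right_lung", "left_oblique_fissure",
    "right_oblique_fissure", "horizontal_fissure")
}

.landmarkLevels <- c("anatomical", "pseudo", "none")

#' HermiteMesh: a bicubic Hermite finite-element surface mesh
#'
#' Nodes carry 12 degrees of freedom each (four per spatial direction):
#' position, the two first parametric derivatives and the mixed second
#' derivative, stored as rows of an \code{n x 12} matrix in column order
#' \code{x,y,z, d1x,d1y,d1z, d2x,d2y,d2z, d12x,d12y,d12z}. Units are mm for
#' positions and mm per unit local coordinate for derivatives. Elements are
#' quadrilateral patches referencing 4 nodes in local corner order
#' (0,0),(1,0),(0,1),(1,1) of the \code{(xi1, xi2)} unit square, each tagged
#' with one of the five anatomical surface labels. The node ordering is fixed
#' and shared across subjects, which is what provides shape correspondence.
#'
#' @slot nodes numeric matrix, n x 12 nodal degrees of freedom.
#' @slot elements integer matrix, e x 4 node indices (1-based).
#' @slot surface character vector of per-element surface labels.
#' @slot landmarks character vector of per-node landmark flags
#'   (\code{"anatomical"}, \code{"pseudo"} or \code{"none"}).
#' @export
setClass("HermiteMesh", representation(
  nodes = "matrix",
  elements = "matrix",
  surface = "character",
  landmarks = "character"
))

setValidity("HermiteMesh", function(object) {
  msgs <- character()
  if (ncol(object@nodes) != 12L)
    msgs <- c(msgs, "nodes must have 12 columns (12 DoF per node)")
  if (!all(is.finite(object@nodes)))
    msgs <- c(msgs, "all nodal DoFs must be finite")
  if (ncol(object@elements) != 4L)
    msgs <- c(msgs, "elements must have 4 node references each")
  n <- nrow(object@nodes)
  el <- object@elements
  if (nrow(el) > 0) {
    if (any(el < 1L | el > n))
      msgs <- c(msgs, "element references a non-existent node")
    if (any(apply(el, 1L, anyDuplicated) > 0))
      msgs <- c(msgs, "element node ids must be distinct")
  }
  if (length(object@surface) != nrow(el))
    msgs <- c(msgs, "one surface label per element required")
  bad <- setdiff(unique(object@surface), surfaceLabels())
  if (length(bad))
    msgs <- c(msgs, sprintf("unknown surface label(s): %s (allowed: %s)",
                            paste(bad, collapse = ", "),
                            paste(surfaceLabels(), collapse = ", ")))
  if (length(object@landmarks) != n)
    msgs <- c(msgs, "one landmark flag per node required")
  if (!all(object@landmarks %in% .landmarkLevels))
    msgs <- c(msgs, "landmark flags must be anatomical/pseudo/none")
  if (length(msgs)) msgs else TRUE
})

#' Construct a HermiteMesh
#'
#' @param nodes n x 12 numeric matrix of nodal DoFs.
#' @param elements e x 4 integer matrix of node indices.
#' @param surface character vector of per-element surface labels.
#' @param landmarks optional per-node landmark flags (default all
#'   \code{"none"}).
#' @return A validated \linkS4class{HermiteMesh}.
#' @export
HermiteMesh <- function(nodes, elements, surface,
                        landmarks = rep("none", nrow(nodes))) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  new("HermiteMesh", nodes = nodes, elements = elements,
      surface = as.character(surface), landmarks = as.character(landmarks))
}

#' @describeIn HermiteMesh-class number of nodes
#' @param mesh a \linkS4class{HermiteMesh}
#' @export
nodeCount <- function(mesh) nrow(mesh@nodes)

#' @describeIn HermiteMesh-class number of elements
#' @export
elementCount <- function(mesh) nrow(mesh@elements)

#' @describeIn HermiteMesh-class the n x 12 nodal DoF matrix
#' @export
meshNodes <- function(mesh) mesh@nodes

#' @describeIn HermiteMesh-class the e x 4 element connectivity matrix
#' @export
meshElements <- function(mesh) mesh@elements

#' @describeIn HermiteMesh-class per-element surface labels
#' @export
meshSurface <- function(mesh) mesh@surface

#' @describeIn HermiteMesh-class per-node landmark flags
#' @export
meshLandmarks <- function(mesh) mesh@landmarks

setMethod("show", "HermiteMesh", function(object) {
  cat("HermiteMesh:", nodeCount(object), "nodes,",
      elementCount(object), "elements,",
      12L * nodeCount(object), "shape parameters\n")
  tab <- table(object@surface)
  for (s in names(tab)) cat("  ", s, ": ", tab[[s]], " elements\n", sep = "")
})

#' DataPointSet: a labelled surface point cloud
#'
#' Segmented surface sample points in mm, with a per-point fitting weight
#' (gamma, default 1) and an anatomical surface label restricting which
#' elements the point may be fitted to.
#'
#' @slot points numeric matrix, m x 3 (mm).
#' @slot weights numeric vector of non-negative per-point weights.
#' @slot labels character vector of per-point surface labels (may be
#'   \code{NA} meaning "any surface").
#' @export
setClass("DataPointSet", representation(
  points = "matrix",
  weights = "numeric",
  labels = "character"
))

setValidity("DataPointSet", function(object) {
  msgs <- character()
  if (nrow(object@points) == 0L) msgs <- c(msgs, "point set must be non-empty")
  if (ncol(object@points) != 3L) msgs <- c(msgs, "points must be m x 3")
  if (!all(is.finite(object@points))) msgs <- c(msgs, "points must be finite")
  if (length(object@weights) != nrow(object@points))
    msgs <- c(msgs, "one weight per point required")
  if (!all(is.finite(object@weights)) || any(object@weights < 0))
    msgs <- c(msgs, "weights must be finite and non-negative")
  if (length(object@labels) != nrow(object@points))
    msgs <- c(msgs, "one label per point required")
  bad <- setdiff(unique(object@labels[!is.na(object@labels)]), surfaceLabels())
  if (length(bad))
    msgs <- c(msgs, sprintf("unknown point label(s): %s",
                            paste(bad, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct a DataPointSet
#'
#' @param points m x 3 numeric matrix (mm).
#' @param weights per-point non-negative weights, recycled if scalar.
#' @param labels per-point surface labels (or \code{NA} for unlabelled).
#' @return A validated \linkS4class{DataPointSet}.
#' @export
DataPointSet <- function(points, weights = 1, labels = NA_character_) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  m <- nrow(points)
  new("DataPointSet", points = points,
      weights = rep_len(as.numeric(weights), m),
      labels = rep_len(as.character(labels), m))
}

#' @describeIn DataPointSet-class the m x 3 coordinate matrix
#' @param x a \linkS4class{DataPointSet}
#' @export
cloudPoints <- function(x) x@points

#' @describeIn DataPointSet-class per-point surface labels
#' @export
cloudLabels <- function(x) x@labels

#' @describeIn DataPointSet-class per-point weights
#' @export
cloudWeights <- function(x) x@weights

setMethod("show", "DataPointSet", function(object) {
  cat("DataPointSet:", nrow(object@points), "points\n")
  lb <- object@labels
  if (all(is.na(lb))) {
    cat("  unlabelled\n")
  } else {
    tab <- table(lb, useNA = "ifany")
    for (s in names(tab)) cat("  ", s, ": ", tab[[s]], "\n", sep = "")
  }
})

#' FitResult: outcome of fitting a template mesh to a point cloud
#'
#' @slot mesh the fitted \linkS4class{HermiteMesh}.
#' @slot residuals per-point closest distances to the fitted surface (mm).
#' @slot rmse root mean squared residual (mm).
#' @slot iterations number of outer projection/solve iterations used.
#' @slot energy final value of the fitting energy (data misfit plus
#'   smoothness penalty).
#' @export
setClass("FitResult", representation(
  mesh = "HermiteMesh",
  residuals = "numeric",
  rmse = "numeric",
  iterations = "integer",
  energy = "numeric"
))

setValidity("FitResult", function(object) {
  msgs <- character()
  if (any(object@residuals < 0)) msgs <- c(msgs, "residuals must be >= 0")
  if (length(object@rmse) == 1L && length(object@residuals) > 0L) {
    if (abs(object@rmse - sqrt(mean(object@residuals^2))) >
        1e-8 * (1 + object@rmse))
      msgs <- c(msgs, "rmse must equal the root mean squared residual")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn FitResult-class the fitted mesh
#' @param fit a \linkS4class{FitResult}
#' @export
fittedMesh <- function(fit) fit@mesh

#' @describeIn FitResult-class root mean squared residual in mm
#' @export
fitRMSE <- function(fit) fit@rmse

#' @describeIn FitResult-class per-point residual distances in mm
#' @export
fitResiduals <- function(fit) fit@residuals

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: RMSE %.4g mm over %d points (%d outer iterations)\n",
              object@rmse, length(object@residuals), object@iterations))
})

#' ShapeModel: a PCA statistical shape model
#'
#' Holds the mean shape vector, orthonormal shape modes (left singular vectors
#' of the centred training matrix), singular values, per-mode standard
#' deviations (sigma / sqrt(N - 1), the sample SD of training scores in
#' original units) and variance fractions.
#'
#' @slot meanVector numeric, the cohort mean shape vector.
#' @slot modes P x L matrix of orthonormal mode vectors.
#' @slot singularValues non-increasing, non-negative singular values.
#' @slot modeSD per-mode score SD in original units.
#' @slot varianceFractions per-mode fraction of total variance (sums to 1).
#' @slot N number of training subjects.
#' @slot L number of retained modes.
#' @export
setClass("ShapeModel", representation(
  meanVector = "numeric",
  modes = "matrix",
  singularValues = "numeric",
  modeSD = "numeric",
  varianceFractions = "numeric",
  N = "integer",
  L = "integer"
))

setValidity("ShapeModel", function(object) {
  msgs <- character()
  L <- object@L
  if (ncol(object@modes) != L) msgs <- c(msgs, "modes must have L columns")
  if (length(object@singularValues) != L ||
      any(object@singularValues < -1e-12))
    msgs <- c(msgs, "need L non-negative singular values")
  if (is.unsorted(rev(object@singularValues), strictly = FALSE) &&
      any(diff(object@singularValues) > 1e-8 * max(object@singularValues, 1)))
    msgs <- c(msgs, "singular values must be non-increasing")
  if (L > 0) {
    g <- crossprod(object@modes)
    if (max(abs(g - diag(L))) > 1e-8)
      msgs <- c(msgs, "mode vectors must be orthonormal")
  }
  tv <- sum(object@varianceFractions)
  if (L > 0 && sum(object@singularValues) > 0 && abs(tv - 1) > 1e-8)
    msgs <- c(msgs, "variance fractions must sum to 1")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ShapeModel-class the mean shape vector
#' @param model a \linkS4class{ShapeModel}
#' @export
modelMean <- function(model) model@meanVector

#' @describeIn ShapeModel-class the P x L orthonormal mode matrix
#' @export
modelModes <- function(model) model@modes

#' @describeIn ShapeModel-class singular values of the centred training matrix
#' @export
modelSingularValues <- function(model) model@singularValues

#' @describeIn ShapeModel-class per-mode training-score SD in original units
#' @export
modelModeSD <- function(model) model@modeSD

#' @describeIn ShapeModel-class per-mode variance fractions
#' @export
modelVarianceFractions <- function(model) model@varianceFractions

#' @describeIn ShapeModel-class number of retained modes
#' @export
modeCount <- function(model) model@L

setMethod("show", "ShapeModel", function(object) {
  cat("ShapeModel:", length(object@meanVector), "parameters,",
      object@N, "training subjects,", object@L, "modes\n")
  k <- min(4L, object@L)
  if (k > 0) {
    pct <- 100 * object@varianceFractions[seq_len(k)]
    cat("  variance explained by first", k, "modes:",
        paste(sprintf("%.1f%%", pct), collapse = ", "), "\n")
  }
})
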