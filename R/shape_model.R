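#' Assemble aligned shape vectors into a training matrix
#'
#' Column-stacks equal-length aligned shape vectors (one column per subject).
#'
#' @param shapes a list of shape vectors or a P x N matrix.
#' @param subjectIds optional subject identifiers (defaults to list/column
#'   names or \code{subj1..subjN}).
#' @return A list of class \code{"ShapeTrainingMatrix"} with elements
#'   \code{data} (P x N), \code{subjectIds} and \code{centered = FALSE}.
#' @export
assembleShapes <- function(shapes, subjectIds = NULL) {
  if (is.list(shapes)) {
    lens <- lengths(shapes)
    if (length(unique(lens)) != 1L) {
      bad <- names(shapes)[which(lens != lens[1L])[1L]]
      if (is.null(bad) || is.na(bad) || !nzchar(bad))
        bad <- paste0("subject ", which(lens != lens[1L])[1L])
      stop("shape vector length mismatch for ", bad)
    }
    if (is.null(subjectIds)) subjectIds <- names(shapes)
    shapes <- do.call(cbind, shapes)
  }
  shapes <- as.matrix(shapes)
  if (is.null(subjectIds)) subjectIds <- colnames(shapes)
  if (is.null(subjectIds)) subjectIds <- paste0("subj", seq_len(ncol(shapes)))
  if (ncol(shapes) < 2L) stop("need at least 2 subjects")
  colnames(shapes) <- subjectIds
  structure(list(data = shapes, subjectIds = subjectIds, centered = FALSE),
            class = "ShapeTrainingMatrix")
}

# deterministic sign convention: largest-magnitude loading positive
.fixModeSigns <- function(modes) {
  for (l in seq_len(ncol(modes))) {
    i <- which.max(abs(modes[, l]))
    if (modes[i, l] < 0) modes[, l] <- -modes[, l]
  }
  modes
}

#' Build a PCA statistical shape model
#'
#' Centres the training columns about the mean shape and factorises the
#' centred matrix by thin SVD. The left singular vectors are the shape modes;
#' mode variances are \code{sigma^2 / (N - 1)} (the eigenvalues of the sample
#' covariance matrix) and variance fractions their share of the total. Each
#' mode's sign is fixed so its largest-magnitude loading is positive. A cohort
#' of identical shapes yields a valid model with all singular values zero
#' (reported via a message).
#'
#' @param x a \code{"ShapeTrainingMatrix"} from \code{\link{assembleShapes}},
#'   or anything it accepts.
#' @return A \linkS4class{ShapeModel}.
#' @export
buildSSM <- function(x) {
  if (!inherits(x, "ShapeTrainingMatrix")) x <- assembleShapes(x)
  S0 <- x$data
  N <- ncol(S0)
  mu <- rowMeans(S0)
  S <- S0 - mu
  L <- min(N - 1L, nrow(S))
  sv <- svd(S, nu = L, nv = 0L)
  sig <- sv$d[seq_len(L)]
  sig[sig < 0] <- 0
  if (all(sig < 1e-12 * max(1, sqrt(sum(mu^2)))))
    message("all shapes identical: model has zero variance")
  modes <- .fixModeSigns(sv$u)
  lam <- sig^2 / (N - 1L)
  tot <- sum(lam)
  vf <- if (tot > 0) lam / tot else rep(0, L)
  new("ShapeModel", meanVector = mu, modes = modes, singularValues = sig,
      modeSD = sig / sqrt(N - 1), varianceFractions = vf,
      N = as.integer(N), L = as.integer(L))
}

#' Cumulative percentage of variance explained
#'
#' @param model a \linkS4class{ShapeModel}.
#' @param m number of leading modes (1 <= m <= L).
#' @return Percent of total shape variance captured by the first m modes.
#' @export
varianceExplained <- function(model, m) {
  m <- as.integer(m)
  if (m < 1L || m > model@L) stop("m must be in 1..L")
  100 * sum(model@varianceFractions[seq_len(m)])
}

#' Smallest number of modes exceeding a cumulative variance cutoff
#'
#' @param model a \linkS4class{ShapeModel}.
#' @param cutoffPercent cumulative-variance cutoff in (0, 100].
#' @return The smallest m with \code{varianceExplained(model, m) >=
#'   cutoffPercent}.
#' @export
selectModes <- function(model, cutoffPercent) {
  if (cutoffPercent <= 0 || cutoffPercent > 100)
    stop("cutoffPercent must be in (0, 100]")
  cum <- 100 * cumsum(model@varianceFractions)
  m <- which(cum >= cutoffPercent - 1e-9)[1L]
  if (is.na(m)) m <- sum(model@singularValues > 0)
  as.integer(m)
}

#' Shape at a signed number of SDs along one mode
#'
#' Perturbs the mean along mode l by w standard deviations of the training
#' scores, the protocol used to visualise modes at e.g. +/- 2.5 SD.
#'
#' @param model a \linkS4class{ShapeModel}.
#' @param l mode index.
#' @param w weight in SD units.
#' @return A shape vector.
#' @export
modeShape <- function(model, l, w) {
  l <- as.integer(l)
  if (l < 1L || l > model@L) stop("l must be in 1..L")
  model@meanVector + w * model@modeSD[l] * model@modes[, l]
}

#' Project shapes onto the model's modes (SD-unit scores)
#'
#' Centred dot products with each mode, divided by the per-mode training SD,
#' so training-cohort scores have sample SD 1 per mode.
#'
#' @param model a \linkS4class{ShapeModel}.
#' @param shapes a shape vector, list of shape vectors, or P x N matrix
#'   (aligned into the model's GPA frame).
#' @return An N x L score matrix in SD units (a single vector input returns a
#'   length-L vector). Zero-variance modes yield \code{NA} scores.
#' @export
projectShapes <- function(model, shapes) {
  single <- is.numeric(shapes) && is.null(dim(shapes))
  if (single) shapes <- matrix(shapes, ncol = 1L)
  if (is.list(shapes)) shapes <- do.call(cbind, shapes)
  shapes <- as.matrix(shapes)
  if (nrow(shapes) != length(model@meanVector))
    stop("shape vector length does not match the model")
  X <- shapes - model@meanVector
  raw <- crossprod(X, model@modes)           # N x L, original units
  sd <- model@modeSD
  sdz <- ifelse(sd > 0, sd, NA_real_)
  scores <- sweep(raw, 2L, sdz, "/")
  colnames(scores) <- paste0("mode", seq_len(model@L))
  if (!is.null(colnames(shapes))) rownames(scores) <- colnames(shapes)
  attr(scores, "rawScores") <- raw
  if (single) scores[1L, ] else scores
}

#' Reconstruct a shape from SD-unit mode scores
#'
#' @param model a \linkS4class{ShapeModel}.
#' @param scores length-L (or shorter) vector of SD-unit scores.
#' @param kModes number of leading modes to use (default all provided).
#' @return A shape vector: mean + sum over the first k modes of
#'   \code{score_l * SD_l * mode_l}.
#' @export
reconstructShape <- function(model, scores, kModes = length(scores)) {
  kModes <- as.integer(kModes)
  if (kModes > model@L) stop("kModes must be <= L")
  v <- model@meanVector
  if (kModes == 0L) return(v)
  k <- seq_len(kModes)
  w <- scores[k] * model@modeSD[k]
  w[is.na(w)] <- 0
  v + as.vector(model@modes[, k, drop = FALSE] %*% w)
}

#' Leave-one-out stability of the shape modes
#'
#' Refits the whole GPA + PCA pipeline N times, each omitting one subject,
#' and reports per retained mode the absolute cosine between the fold's mode
#' vector and the full model's (sign-aligned) and the difference in variance
#' fraction. All folds share the full cohort's GPA convention (same reference
#' initialisation), so mode vectors are comparable across folds.
#'
#' @param shapes P x N matrix or list of unaligned shape vectors.
#' @param withScale passed to \code{\link{gpa}}.
#' @param nModes number of leading modes to track (default 4).
#' @return A data.frame with columns \code{fold, mode, absCos,
#'   varianceFractionFull, varianceFractionFold, delta}; attribute
#'   \code{"degenerate"} flags an all-zero-variance cohort, in which case the
#'   stability values are \code{NA}.
#' @export
looStability <- function(shapes, withScale = FALSE, nModes = 4L) {
  if (is.list(shapes)) shapes <- do.call(cbind, shapes)
  shapes <- as.matrix(shapes)
  N <- ncol(shapes)
  if (N < 3L) stop("need at least 3 subjects")
  full <- buildSSM(gpa(shapes, withScale = withScale)$aligned)
  degenerate <- all(full@singularValues < 1e-12)
  nModes <- min(as.integer(nModes), full@L, N - 2L)
  rows <- list()
  for (i in seq_len(N)) {
    fold <- buildSSM(gpa(shapes[, -i, drop = FALSE],
                         withScale = withScale)$aligned)
    for (l in seq_len(min(nModes, fold@L))) {
      ac <- if (degenerate || fold@singularValues[l] < 1e-12) NA_real_ else
        abs(sum(full@modes[, l] * fold@modes[, l]))
      rows[[length(rows) + 1L]] <- data.frame(
        fold = i, mode = l, absCos = ac,
        varianceFractionFull = full@varianceFractions[l],
        varianceFractionFold = fold@varianceFractions[l],
        delta = if (degenerate) NA_real_ else
          fold@varianceFractions[l] - full@varianceFractions[l])
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "degenerate") <- degenerate
  out
}
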