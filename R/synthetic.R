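## Synthetic bi-lung cohort generator: idealised superellipsoid-like lung
## surfaces carrying fissure sheets, deformed by covariate-linked effects
## (size~sex via volume, apical taper + basal fissure shift~age, AP change~BMI)
## plus a smooth random residual field, then sampled into noisy point clouds.

# fixed idealised geometry (mm). Frame: +x toward the subject's left,
# +y posterior -> anterior, +z caudal -> cranial.
.lungGeometry <- function() {
  list(
    left = list(cx = 75, a = 50, b = 80, c = 115, dome = 45),
    right = list(cx = -75, a = 55, b = 85, c = 120, dome = 45),
    theta = c(0.10, 0.92) * pi
  )
}

# lung external surface parameterisation with analytic derivatives.
# u in [0,1) wraps around the azimuth, v in [0,1] runs apex -> base.
.lungSurface <- function(g, thetaRange) {
  th0 <- thetaRange[1L]; dth <- diff(thetaRange)
  function(u, v) {
    th <- th0 + v * dth
    ph <- 2 * pi * u
    st <- sin(th); ct <- cos(th)
    sp <- sin(ph); cp <- cos(ph)
    dome <- g$dome * ((1 - ct) / 2)^4
    domeD <- g$dome * 2 * st * ((1 - ct) / 2)^3   # d(dome)/d(theta)
    list(
      pos = cbind(g$cx + g$a * st * cp, g$b * st * sp, g$c * ct + dome),
      du = 2 * pi * cbind(-g$a * st * sp, g$b * st * cp, 0),
      dv = dth * cbind(g$a * ct * cp, g$b * ct * sp, -g$c * st + domeD),
      duv = 2 * pi * dth * cbind(-g$a * ct * sp, g$b * ct * cp, 0)
    )
  }
}

# fissure sheet parameterisations: s in [0,1] medio-lateral, t in [0,1]
# along the fissure. Oblique runs posterior-superior -> anterior-inferior.
.obliqueSurface <- function(g) {
  function(s, t) {
    q <- 2 * t - 1
    rho <- 0.8 * sqrt(1 - 0.64 * q^2)
    drho <- -2 * 0.8 * 0.64 * q / sqrt(1 - 0.64 * q^2)
    w <- 1.7 * g$a
    list(
      pos = cbind(g$cx + (s - 0.5) * w * rho,
                  g$b * (-0.55 + 1.0 * t),
                  g$c * (0.45 - 1.0 * t) + 0.06 * g$c * sin(pi * t)),
      du = cbind(w * rho, 0, 0),
      dv = cbind((s - 0.5) * w * drho, g$b * 1.0,
                 -g$c + 0.06 * g$c * pi * cos(pi * t)),
      duv = cbind(w * drho, 0, 0)
    )
  }
}

# the right horizontal fissure: a nearly horizontal anterior sheet
.horizontalSurface <- function(g) {
  function(s, t) {
    q <- 2 * t - 1
    rho <- 0.9 * sqrt(1 - 0.5 * q^2)
    drho <- -2 * 0.9 * 0.5 * q / sqrt(1 - 0.5 * q^2)
    w <- 1.5 * g$a
    list(
      pos = cbind(g$cx + (s - 0.5) * w * rho,
                  g$b * (0.05 + 0.55 * t),
                  0.05 * g$c + 8 * (t - 0.5) + 5 * sin(pi * s)),
      du = cbind(w * rho, 0, 5 * pi * cos(pi * s)),
      dv = cbind((s - 0.5) * w * drho, g$b * 0.55, 8),
      duv = cbind(w * drho, 0, 0)
    )
  }
}

# tabulate a parametric surface into Hermite nodes/elements.
# wrap: close the u direction (azimuthal surfaces).
.gridSurface <- function(fn, nu, nv, wrap, label, landmark = "pseudo") {
  du <- if (wrap) 1 / nu else 1 / (nu - 1)
  dv <- 1 / (nv - 1)
  us <- (seq_len(nu) - 1L) * du
  vs <- (seq_len(nv) - 1L) * dv
  uu <- rep(us, times = nv)
  vv <- rep(vs, each = nu)
  sf <- fn(uu, vv)
  nodes <- cbind(sf$pos, sf$du * du, sf$dv * dv, sf$duv * du * dv)
  idx <- function(i, j) {
    i <- if (wrap) ((i - 1L) %% nu) + 1L else i
    (j - 1L) * nu + i
  }
  els <- list()
  for (j in seq_len(nv - 1L)) {
    for (i in seq_len(if (wrap) nu else nu - 1L)) {
      els[[length(els) + 1L]] <- c(idx(i, j), idx(i + 1L, j),
                                   idx(i, j + 1L), idx(i + 1L, j + 1L))
    }
  }
  elements <- do.call(rbind, els)
  lm <- rep(landmark, nrow(nodes))
  list(nodes = nodes, elements = elements,
       surface = rep(label, nrow(elements)), landmarks = lm)
}

#' Idealised two-lung template mesh
#'
#' A fixed, deterministic template: each lung is a smooth closed
#' ellipsoid-like Hermite surface with a basal diaphragm dome (small apical
#' and basal openings keep every patch non-degenerate); the left lung carries
#' an oblique fissure sheet, the right lung an oblique and a horizontal sheet.
#' Node and element counts follow the grids and are configurable; the default
#' resolution is comparable to a clinical bi-lung fit (tens of nodes per
#' lung). Apex- and base-ring lung nodes are flagged as anatomical landmarks,
#' all other nodes as pseudo-landmarks.
#'
#' @param lungGrid \code{c(nAzimuth, nApexToBase)} nodes per lung surface.
#' @param fissureGrid \code{c(nMedioLateral, nAlong)} nodes per fissure sheet.
#' @return A \linkS4class{HermiteMesh} with all five surface labels.
#' @export
templateLungMesh <- function(lungGrid = c(6L, 5L), fissureGrid = c(4L, 3L)) {
  geom <- .lungGeometry()
  parts <- list(
    .gridSurface(.lungSurface(geom$left, geom$theta), lungGrid[1L],
                 lungGrid[2L], wrap = TRUE, label = "left_lung"),
    .gridSurface(.lungSurface(geom$right, geom$theta), lungGrid[1L],
                 lungGrid[2L], wrap = TRUE, label = "right_lung"),
    .gridSurface(.obliqueSurface(geom$left), fissureGrid[1L], fissureGrid[2L],
                 wrap = FALSE, label = "left_oblique_fissure"),
    .gridSurface(.obliqueSurface(geom$right), fissureGrid[1L],
                 fissureGrid[2L], wrap = FALSE,
                 label = "right_oblique_fissure"),
    .gridSurface(.horizontalSurface(geom$right), fissureGrid[1L],
                 fissureGrid[2L], wrap = FALSE, label = "horizontal_fissure")
  )
  offset <- 0L
  nodes <- NULL; elements <- NULL; surface <- character(); lms <- character()
  for (k in seq_along(parts)) {
    p <- parts[[k]]
    nodes <- rbind(nodes, p$nodes)
    elements <- rbind(elements, p$elements + offset)
    surface <- c(surface, p$surface)
    lm <- p$landmarks
    if (k <= 2L) {  # lungs: apex and base rings are anatomical landmarks
      nu <- lungGrid[1L]; nv <- lungGrid[2L]
      lm[seq_len(nu)] <- "anatomical"
      lm[(nv - 1L) * nu + seq_len(nu)] <- "anatomical"
    }
    lms <- c(lms, lm)
    offset <- offset + nrow(p$nodes)
  }
  HermiteMesh(nodes, elements, surface, lms)
}

# nominal enclosed volume of the undeformed template (mm^3): ellipsoid
# volumes with a cap-trim factor. Reference for the volume -> scale mapping.
.templateVolume <- function() {
  g <- .lungGeometry()
  0.9 * 4 / 3 * pi * (g$left$a * g$left$b * g$left$c +
                      g$right$a * g$right$b * g$right$c)
}

#' Synthetic cohort generator configuration
#'
#' Defaults reproduce the study conditions of a never-smoking adult cohort:
#' n = 83 with 49 F / 34 M expected, age drawn from the two-centre mixture
#' (47/83 weight on 71.2 +/- 10.9 years clipped to 50-93; 36/83 weight on
#' 32.0 +/- 12 years clipped to 20-49; cohort moments approx 53 +/- 22), BMI
#' 24.7 +/- 2.7 clipped below 30, and imaged lung volume 6.81 +/- 1.16 L for
#' males, 4.84 +/- 0.85 L for females. The latent age-severity noise SD is
#' calibrated so the population correlation between age and the planted
#' taper/fissure loading is \code{-ageCorTarget}.
#'
#' @param nSubjects cohort size.
#' @param seed base RNG seed; all randomness derives from it.
#' @param ageMean,ageSD nominal cohort age moments (years), used for the
#'   correlation calibration.
#' @param ageRange hard clip for ages (years).
#' @param ageMix two-centre recruitment mixture: \code{weight1, mean1, sd1,
#'   range1} and \code{mean2, sd2, range2}.
#' @param bmiMean,bmiSD,bmiMax BMI distribution (kg/m^2), clipped below
#'   \code{bmiMax} (the exclusion criterion).
#' @param sexPropF proportion of females.
#' @param volumeF,volumeM \code{c(mean, sd)} imaged lung volume by sex (L).
#' @param ageCorTarget target |correlation| between age and the planted age
#'   loading (the calibration the cohort emulates).
#' @param taperPerAgeYear apical antero-posterior taper per effective age
#'   year (fractional AP change at the apex).
#' @param fissureShiftPerAgeYear basal displacement of the horizontal fissure
#'   (mm per effective age year).
#' @param obliqueRotPerAgeYear posterior rotation of the oblique fissures
#'   (radians per effective age year).
#' @param apChangePerBmi fractional antero-posterior change per BMI unit.
#' @param bmiCorTarget target |correlation| between BMI and its loading.
#' @param residualSD per-field amplitude SD of the smooth random residual
#'   deformation (mm).
#' @param residualFields number of smooth random fields.
#' @param cloudDensity point-cloud samples per parametric direction per
#'   element.
#' @param cloudNoiseSD isotropic Gaussian noise added to cloud points (mm).
#' @param lungGrid,fissureGrid template resolution, see
#'   \code{\link{templateLungMesh}}.
#' @return A list of class \code{"GeneratorConfig"}.
#' @export
generatorConfig <- function(nSubjects = 83L, seed = 1L,
                            ageMean = 53, ageSD = 22,
                            ageRange = c(20, 93),
                            ageMix = list(w1 = 47 / 83, mean1 = 71.2,
                                          sd1 = 10.9, range1 = c(50, 93),
                                          mean2 = 32.0, sd2 = 12,
                                          range2 = c(20, 49)),
                            bmiMean = 24.7, bmiSD = 2.7, bmiMax = 30,
                            sexPropF = 49 / 83,
                            volumeF = c(4.84, 0.85), volumeM = c(6.81, 1.16),
                            ageCorTarget = 0.75,
                            taperPerAgeYear = 0.002,
                            fissureShiftPerAgeYear = 0.3,
                            obliqueRotPerAgeYear = 0.0015,
                            apChangePerBmi = 0.004,
                            bmiCorTarget = 0.6,
                            residualSD = 1.0, residualFields = 6L,
                            cloudDensity = 6L, cloudNoiseSD = 1.0,
                            lungGrid = c(6L, 5L), fissureGrid = c(4L, 3L)) {
  stopifnot(nSubjects >= 2L, ageSD >= 0, bmiSD >= 0,
            sexPropF >= 0, sexPropF <= 1, residualSD >= 0,
            cloudNoiseSD >= 0, cloudDensity >= 2L)
  structure(list(
    nSubjects = as.integer(nSubjects), seed = as.integer(seed),
    ageMean = ageMean, ageSD = ageSD, ageRange = ageRange, ageMix = ageMix,
    bmiMean = bmiMean, bmiSD = bmiSD, bmiMax = bmiMax, sexPropF = sexPropF,
    volumeF = volumeF, volumeM = volumeM,
    ageCorTarget = ageCorTarget,
    # calibrated against the exact population SD of the truncated age
    # mixture so cor(age, loading) hits the target in population
    ageLoadingNoiseSD = .ageMixtureSD(ageMix) *
      sqrt(1 / ageCorTarget^2 - 1),
    taperPerAgeYear = taperPerAgeYear,
    fissureShiftPerAgeYear = fissureShiftPerAgeYear,
    obliqueRotPerAgeYear = obliqueRotPerAgeYear,
    apChangePerBmi = apChangePerBmi,
    bmiCorTarget = bmiCorTarget,
    bmiLoadingNoiseSD = bmiSD * sqrt(1 / bmiCorTarget^2 - 1),
    residualSD = residualSD, residualFields = as.integer(residualFields),
    cloudDensity = as.integer(cloudDensity), cloudNoiseSD = cloudNoiseSD,
    lungGrid = lungGrid, fissureGrid = fissureGrid
  ), class = "GeneratorConfig")
}

# exact truncated-normal moments
.truncMoments <- function(mu, s, a, b) {
  al <- (a - mu) / s; be <- (b - mu) / s
  Z <- stats::pnorm(be) - stats::pnorm(al)
  m <- mu + s * (stats::dnorm(al) - stats::dnorm(be)) / Z
  v <- s^2 * (1 + (al * stats::dnorm(al) - be * stats::dnorm(be)) / Z -
                ((stats::dnorm(al) - stats::dnorm(be)) / Z)^2)
  c(mean = m, var = v)
}

# population SD of the two-centre truncated age mixture
.ageMixtureSD <- function(mx) {
  c1 <- .truncMoments(mx$mean1, mx$sd1, mx$range1[1], mx$range1[2])
  c2 <- .truncMoments(mx$mean2, mx$sd2, mx$range2[1], mx$range2[2])
  E <- mx$w1 * c1["mean"] + (1 - mx$w1) * c2["mean"]
  EX2 <- mx$w1 * (c1["var"] + c1["mean"]^2) +
    (1 - mx$w1) * (c2["var"] + c2["mean"]^2)
  unname(sqrt(EX2 - E^2))
}

.truncNorm <- function(n, mean, sd, range) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  out[seq_len(n)]
}

# map node index -> owning surface label (nodes are not shared across
# surfaces in the template construction)
.nodeSurfaces <- function(mesh) {
  out <- rep(NA_character_, nodeCount(mesh))
  el <- mesh@elements
  for (e in seq_len(nrow(el))) {
    out[el[e, ]] <- mesh@surface[e]
  }
  out
}

# push nodal DoFs through a differentiable map given as
# list(f(x) -> pos, J(x) -> 3x3, H(x, d1, d2) -> 3-vector or NULL)
.applyMap <- function(nodes, map, subset = seq_len(nrow(nodes))) {
  for (i in subset) {
    p <- nodes[i, 1:3]
    d1 <- nodes[i, 4:6]; d2 <- nodes[i, 7:9]; d12 <- nodes[i, 10:12]
    J <- map$J(p)
    nodes[i, 1:3] <- map$f(p)
    nodes[i, 4:6] <- as.vector(J %*% d1)
    nodes[i, 7:9] <- as.vector(J %*% d2)
    h <- if (is.null(map$H)) c(0, 0, 0) else map$H(p, d1, d2)
    nodes[i, 10:12] <- as.vector(J %*% d12) + h
  }
  nodes
}

#' Deform the template into one subject's ground-truth mesh
#'
#' Applies, in a fixed order: (1) an isotropic scale matching the subject's
#' imaged lung volume; (2) an age-proportional apical antero-posterior taper
#' (older lungs become more pyramidal); (3) a BMI-proportional
#' antero-posterior change; (4) age-proportional fissure displacement (the
#' horizontal fissure translates toward the base, the oblique fissures rotate
#' posteriorly); and (5) a smooth random residual deformation. Derivative
#' DoFs are transported exactly through each map's Jacobian (plus the Hessian
#' contraction for the mixed derivative).
#'
#' @param template a \linkS4class{HermiteMesh}.
#' @param covariates list or one-row data.frame with \code{age} (years),
#'   \code{sex} ("F"/"M"), \code{bmi} (kg/m^2), \code{volume_L} (L).
#' @param config a \code{\link{generatorConfig}}.
#' @param seed optional seed making the subject fully reproducible; when
#'   \code{NULL} the current RNG stream is used.
#' @return A list with \code{mesh} (the truth \linkS4class{HermiteMesh}) and
#'   \code{loadings}: the planted effect scalars \code{size} (linear scale
#'   factor), \code{age} (oriented so its population correlation with age is
#'   \code{-ageCorTarget}) and \code{bmi}.
#' @export
deformSubject <- function(template, covariates, config = generatorConfig(),
                          seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  cv <- as.list(covariates)
  if (is.null(cv$volume_L)) cv$volume_L <- cv$volume
  nodes <- template@nodes
  nodeSurf <- .nodeSurfaces(template)

  # latent loadings
  epsA <- stats::rnorm(1L, 0, config$ageLoadingNoiseSD)
  epsB <- stats::rnorm(1L, 0, config$bmiLoadingNoiseSD)
  a <- (cv$age - config$ageMean) + epsA      # effective age severity (years)
  bLoad <- (cv$bmi - config$bmiMean) + epsB

  # 1. isotropic scale from imaged volume
  alpha <- (cv$volume_L * 1e6 / .templateVolume())^(1 / 3)
  nodes <- .applyMap(nodes, list(
    f = function(x) alpha * x,
    J = function(x) alpha * diag(3),
    H = NULL))

  # 2. apical AP taper: y * (1 + t * zhat), t = -taper * a
  zr <- range(nodes[, 3])
  dz <- diff(zr)
  tl <- -config$taperPerAgeYear * a
  nodes <- .applyMap(nodes, list(
    f = function(x) {
      zh <- (x[3] - zr[1]) / dz
      c(x[1], x[2] * (1 + tl * zh), x[3])
    },
    J = function(x) {
      zh <- (x[3] - zr[1]) / dz
      matrix(c(1, 0, 0,
               0, 1 + tl * zh, x[2] * tl / dz,
               0, 0, 1), 3, 3, byrow = TRUE)
    },
    H = function(x, d1, d2) {
      c(0, (tl / dz) * (d1[2] * d2[3] + d1[3] * d2[2]), 0)
    }))

  # 3. BMI AP change: uniform y scaling
  bs <- 1 + config$apChangePerBmi * bLoad
  nodes <- .applyMap(nodes, list(
    f = function(x) c(x[1], bs * x[2], x[3]),
    J = function(x) diag(c(1, bs, 1)),
    H = NULL))

  # 4. fissure displacement with age
  horiz <- which(nodeSurf == "horizontal_fissure")
  shift <- config$fissureShiftPerAgeYear * a
  nodes <- .applyMap(nodes, list(
    f = function(x) c(x[1], x[2], x[3] - shift),
    J = function(x) diag(3),
    H = NULL), subset = horiz)
  ang <- config$obliqueRotPerAgeYear * a
  Rx <- matrix(c(1, 0, 0,
                 0, cos(ang), -sin(ang),
                 0, sin(ang), cos(ang)), 3, 3, byrow = TRUE)
  for (lbl in c("left_oblique_fissure", "right_oblique_fissure")) {
    sub <- which(nodeSurf == lbl)
    ctr <- colMeans(nodes[sub, 1:3, drop = FALSE])
    nodes <- .applyMap(nodes, list(
      f = function(x) ctr + as.vector(Rx %*% (x - ctr)),
      J = function(x) Rx,
      H = NULL), subset = sub)
  }

  # 5. smooth random residual deformation
  if (config$residualFields > 0L && config$residualSD > 0) {
    ctr <- colMeans(nodes[, 1:3])
    scl <- pmax(apply(abs(sweep(nodes[, 1:3], 2L, ctr)), 2L, max), 1)
    J <- config$residualFields
    dirs <- matrix(stats::rnorm(3L * J), J, 3L)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    freq <- matrix(stats::runif(3L * J, -1.5, 1.5), J, 3L)
    phase <- stats::runif(J, 0, 2 * pi)
    amp <- stats::rnorm(J, 0, config$residualSD)
    khat <- sweep(freq, 2L, scl, "/")
    nodes <- .applyMap(nodes, list(
      f = function(x) {
        arg <- as.vector(freq %*% ((x - ctr) / scl)) + phase
        x + as.vector(t(dirs) %*% (amp * sin(arg)))
      },
      J = function(x) {
        arg <- as.vector(freq %*% ((x - ctr) / scl)) + phase
        diag(3) + t(dirs * (amp * cos(arg))) %*% khat
      },
      H = function(x, d1, d2) {
        arg <- as.vector(freq %*% ((x - ctr) / scl)) + phase
        k1 <- as.vector(khat %*% d1)
        k2 <- as.vector(khat %*% d2)
        as.vector(t(dirs) %*% (-amp * sin(arg) * k1 * k2))
      }))
  }

  mesh <- HermiteMesh(nodes, template@elements, template@surface,
                      template@landmarks)
  list(mesh = mesh,
       loadings = c(size = alpha, age = -a, bmi = bLoad))
}

#' Sample a noisy surface point cloud from a mesh
#'
#' Uniform random local-coordinate samples on every element (density^2 per
#' element) perturbed by isotropic Gaussian noise; labels are inherited from
#' the surface of origin.
#'
#' @param mesh a \linkS4class{HermiteMesh}.
#' @param density samples per parametric direction per element (>= 2).
#' @param noiseSD isotropic Gaussian noise SD (mm).
#' @param seed optional seed for reproducibility.
#' @return A \linkS4class{DataPointSet}.
#' @export
sampleCloud <- function(mesh, density = 4L, noiseSD = 1.0, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  density <- as.integer(density)
  if (density < 2L) stop("density must be >= 2")
  ne <- elementCount(mesh)
  perEl <- density^2
  element <- rep(seq_len(ne), each = perEl)
  m <- length(element)
  xi1 <- stats::runif(m)
  xi2 <- stats::runif(m)
  p <- evaluateSurface(mesh, element, xi1, xi2, "value")
  if (noiseSD > 0) p <- p + matrix(stats::rnorm(3L * m, 0, noiseSD), m, 3L)
  DataPointSet(p, weights = 1, labels = mesh@surface[element])
}

#' Generate a full synthetic cohort
#'
#' Draws covariates (age from the two-centre mixture; sex Bernoulli; BMI
#' normal clipped below the exclusion threshold; volume by sex), then deforms
#' the template and samples a noisy cloud per subject. Fully reproducible
#' from \code{config$seed}.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @param covariatesCsv optional path: write the covariate table as CSV.
#' @return A list of class \code{"SyntheticCohort"}: \code{subjects} (each
#'   with \code{subjectId, covariates, truthMesh, cloud, plantedLoadings}),
#'   \code{covariates} (data.frame), \code{loadings} (n x 3 matrix),
#'   \code{template} and \code{config}.
#' @export
generateCohort <- function(config = generatorConfig(), covariatesCsv = NULL) {
  set.seed(config$seed)
  n <- config$nSubjects
  mx <- config$ageMix
  fromOld <- stats::runif(n) < mx$w1
  age <- numeric(n)
  age[fromOld] <- .truncNorm(sum(fromOld), mx$mean1, mx$sd1, mx$range1)
  age[!fromOld] <- .truncNorm(sum(!fromOld), mx$mean2, mx$sd2, mx$range2)
  sex <- ifelse(stats::runif(n) < config$sexPropF, "F", "M")
  bmi <- .truncNorm(n, config$bmiMean, config$bmiSD, c(15, config$bmiMax))
  vol <- numeric(n)
  vol[sex == "F"] <- .truncNorm(sum(sex == "F"), config$volumeF[1],
                                config$volumeF[2], c(2, 12))
  vol[sex == "M"] <- .truncNorm(sum(sex == "M"), config$volumeM[1],
                                config$volumeM[2], c(2, 12))
  covariates <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    age = round(age, 1), sex = sex, bmi = round(bmi, 1),
    volume_L = round(vol, 2), stringsAsFactors = FALSE)
  template <- templateLungMesh(config$lungGrid, config$fissureGrid)
  subjects <- vector("list", n)
  loadings <- matrix(0, n, 3L,
                     dimnames = list(covariates$subject_id,
                                     c("size", "age", "bmi")))
  for (i in seq_len(n)) {
    cv <- covariates[i, ]
    dm <- deformSubject(template, cv, config, seed = config$seed + i)
    cloud <- sampleCloud(dm$mesh, config$cloudDensity, config$cloudNoiseSD,
                         seed = config$seed + 500000L + i)
    loadings[i, ] <- dm$loadings
    subjects[[i]] <- list(subjectId = cv$subject_id,
                          covariates = as.list(cv),
                          truthMesh = dm$mesh, cloud = cloud,
                          plantedLoadings = dm$loadings)
  }
  if (!is.null(covariatesCsv))
    utils::write.csv(covariates, covariatesCsv, row.names = FALSE)
  structure(list(subjects = subjects, covariates = covariates,
                 loadings = loadings, template = template, config = config),
            class = "SyntheticCohort")
}
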