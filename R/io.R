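.MESH_SCHEMA <- "lungssm-mesh/1"
.MODEL_SCHEMA <- "lungssm-model/1"

.cloudFormat <- function(path, format = NULL) {
  if (!is.null(format)) return(match.arg(format, c("ply", "obj", "xyz")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("ply", "obj", "xyz")) return(ext)
  if (ext %in% c("txt", "dat")) return("xyz")
  stop("unknown point-cloud extension: .", ext,
       " (expected .ply, .obj or .xyz)")
}

#' Read a surface point cloud
#'
#' Supports ascii PLY, OBJ (vertex records) and whitespace-separated XYZ
#' (optionally with a fourth surface-label column). Coordinates are taken to
#' be in mm. The format is auto-detected from the extension unless given.
#'
#' @param path input file.
#' @param format \code{"ply"}, \code{"obj"} or \code{"xyz"} (optional).
#' @return A \linkS4class{DataPointSet}.
#' @export
readPointCloud <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  format <- .cloudFormat(path, format)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(trimws(lines))))
    stop("empty point-cloud file: ", path)
  parseRow <- function(ln, i, minCols) {
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(f) < minCols)
      stop(sprintf("malformed record at line %d of %s: expected >= %d fields",
                   i, path, minCols))
    f
  }
  if (format == "xyz") {
    keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
    rows <- lapply(keep, function(i) parseRow(lines[i], i, 3L))
    pts <- t(vapply(rows, function(f) {
      v <- suppressWarnings(as.numeric(f[1:3]))
      if (anyNA(v)) stop("malformed coordinates in ", path)
      v
    }, numeric(3L)))
    labels <- vapply(rows, function(f)
      if (length(f) >= 4L) f[4L] else NA_character_, character(1L))
    return(DataPointSet(pts, labels = labels))
  }
  if (format == "obj") {
    vl <- grep("^v\\s", lines)
    if (length(vl) == 0L) stop("no vertex records in OBJ file: ", path)
    pts <- t(vapply(vl, function(i) {
      f <- parseRow(lines[i], i, 4L)
      v <- suppressWarnings(as.numeric(f[2:4]))
      if (anyNA(v)) stop(sprintf("malformed vertex at line %d of %s", i, path))
      v
    }, numeric(3L)))
    return(DataPointSet(pts))
  }
  # ascii PLY
  if (trimws(lines[1L]) != "ply") stop("not a PLY file: ", path)
  endHdr <- which(trimws(lines) == "end_header")[1L]
  if (is.na(endHdr)) stop("PLY header not terminated in ", path)
  hdr <- lines[seq_len(endHdr)]
  if (!any(grepl("^format\\s+ascii", trimws(hdr))))
    stop("only ascii PLY is supported: ", path)
  vline <- grep("^element\\s+vertex\\s+\\d+", trimws(hdr), value = TRUE)
  if (length(vline) != 1L) stop("PLY vertex element not found in ", path)
  nv <- as.integer(sub("^element\\s+vertex\\s+(\\d+).*", "\\1",
                       trimws(vline)))
  props <- sub("^property\\s+\\S+\\s+(\\S+)$", "\\1",
               grep("^property\\s", trimws(hdr), value = TRUE))
  need <- match(c("x", "y", "z"), props)
  if (anyNA(need)) stop("PLY file lacks x/y/z vertex properties: ", path)
  labCol <- match("label", props)
  body <- lines[endHdr + seq_len(nv)]
  if (length(body) < nv || anyNA(body))
    stop("PLY file truncated: expected ", nv, " vertices in ", path)
  rows <- lapply(seq_along(body), function(i)
    parseRow(body[i], endHdr + i, length(props)))
  pts <- t(vapply(rows, function(f) {
    v <- suppressWarnings(as.numeric(f[need]))
    if (anyNA(v)) stop("malformed vertex coordinates in ", path)
    v
  }, numeric(3L)))
  labels <- if (is.na(labCol)) NA_character_ else
    surfaceLabels()[as.integer(vapply(rows, `[`, character(1L), labCol))]
  DataPointSet(pts, labels = labels)
}

#' Write a surface point cloud
#'
#' @param x a \linkS4class{DataPointSet} or m x 3 matrix.
#' @param path output file.
#' @param format \code{"ply"}, \code{"obj"} or \code{"xyz"} (default from
#'   the extension). PLY output is ascii; labels are written as an integer
#'   vertex property (index into \code{\link{surfaceLabels}}) when present.
#' @return \code{path}, invisibly.
#' @export
writePointCloud <- function(x, path, format = NULL) {
  if (!is(x, "DataPointSet")) x <- DataPointSet(as.matrix(x))
  format <- .cloudFormat(path, format)
  p <- x@points
  lb <- x@labels
  hasLab <- !all(is.na(lb))
  fmtNum <- function(v) formatC(v, format = "g", digits = 17)
  if (format == "xyz") {
    rows <- paste(fmtNum(p[, 1]), fmtNum(p[, 2]), fmtNum(p[, 3]))
    if (hasLab) rows <- paste(rows, lb)
    writeLines(rows, path)
  } else if (format == "obj") {
    writeLines(paste("v", fmtNum(p[, 1]), fmtNum(p[, 2]), fmtNum(p[, 3])),
               path)
  } else {
    hdr <- c("ply", "format ascii 1.0",
             paste("element vertex", nrow(p)),
             "property double x", "property double y", "property double z",
             if (hasLab) "property int label",
             "end_header")
    rows <- paste(fmtNum(p[, 1]), fmtNum(p[, 2]), fmtNum(p[, 3]))
    if (hasLab) rows <- paste(rows, match(lb, surfaceLabels()))
    writeLines(c(hdr, rows), path)
  }
  invisible(path)
}

#' Write a mesh to its JSON schema
#'
#' @param mesh a \linkS4class{HermiteMesh}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMeshJSON <- function(mesh, path) {
  stopifnot(is(mesh, "HermiteMesh"))
  obj <- list(
    schema = .MESH_SCHEMA,
    nodes = lapply(seq_len(nodeCount(mesh)), function(i) list(
      id = i, x12dof = mesh@nodes[i, ], landmark = mesh@landmarks[i])),
    elements = lapply(seq_len(elementCount(mesh)), function(e) list(
      id = e, nodes = mesh@elements[e, ], surface = mesh@surface[e]))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a mesh from its JSON schema
#'
#' Lossless round trip of all 12 DoFs, surface labels and landmark flags.
#' Validates the schema version, node references and surface labels.
#'
#' @param path path to a mesh JSON file.
#' @return A \linkS4class{HermiteMesh}.
#' @export
readMeshJSON <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$schema, .MESH_SCHEMA))
    stop("mesh schema mismatch: found ",
         if (is.null(obj$schema)) "<none>" else obj$schema,
         ", expected ", .MESH_SCHEMA)
  ids <- vapply(obj$nodes, function(n) as.integer(n$id), integer(1L))
  o <- order(ids)
  nodes <- t(vapply(obj$nodes[o], function(n) as.numeric(unlist(n$x12dof)),
                    numeric(12L)))
  landmarks <- vapply(obj$nodes[o], function(n)
    if (is.null(n$landmark)) "none" else n$landmark, character(1L))
  elements <- t(vapply(obj$elements, function(e)
    as.integer(unlist(e$nodes)), integer(4L)))
  surface <- vapply(obj$elements, function(e) e$surface, character(1L))
  dangling <- setdiff(as.vector(elements), ids)
  if (length(dangling))
    stop("element references missing node(s): ",
         paste(utils::head(dangling, 5L), collapse = ", "))
  elements <- matrix(match(as.vector(elements), ids[o]),
                     ncol = 4L)
  HermiteMesh(nodes, elements, surface, landmarks)
}

#' Write a shape model archive
#'
#' A directory with \code{manifest.json} (schema, N, L, P, GPA mode,
#' package version), \code{mean.csv}, \code{modes.csv} (dense P x L),
#' \code{singular_values.csv} (with per-mode SD and variance fractions).
#'
#' @param model a \linkS4class{ShapeModel}.
#' @param dir output directory (created if needed).
#' @param gpaMode \code{"size-inclusive"} or \code{"size-exclusive"}, recorded
#'   in the manifest.
#' @return \code{dir}, invisibly.
#' @export
writeShapeModel <- function(model, dir, gpaMode = "size-inclusive") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(
    schema = .MODEL_SCHEMA, N = model@N, L = model@L,
    P = length(model@meanVector), gpa_mode = gpaMode,
    package_version = as.character(utils::packageVersion("LungSSM"))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  utils::write.csv(data.frame(mean = model@meanVector),
                   file.path(dir, "mean.csv"), row.names = FALSE)
  md <- as.data.frame(model@modes)
  names(md) <- paste0("mode", seq_len(model@L))
  utils::write.csv(md, file.path(dir, "modes.csv"), row.names = FALSE)
  utils::write.csv(data.frame(
    mode = seq_len(model@L), singular_value = model@singularValues,
    sd = model@modeSD, variance_fraction = model@varianceFractions),
    file.path(dir, "singular_values.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a shape model archive
#'
#' @param dir a directory written by \code{\link{writeShapeModel}}.
#' @return A \linkS4class{ShapeModel}; the GPA mode is attached as attribute
#'   \code{"gpaMode"}.
#' @export
readShapeModel <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  if (!identical(mf$schema, .MODEL_SCHEMA))
    stop("model schema mismatch: found ", mf$schema,
         ", expected ", .MODEL_SCHEMA)
  mean <- utils::read.csv(file.path(dir, "mean.csv"))$mean
  modes <- as.matrix(utils::read.csv(file.path(dir, "modes.csv")))
  sv <- utils::read.csv(file.path(dir, "singular_values.csv"))
  model <- new("ShapeModel", meanVector = mean, modes = unname(modes),
               singularValues = sv$singular_value, modeSD = sv$sd,
               varianceFractions = sv$variance_fraction,
               N = as.integer(mf$N), L = as.integer(mf$L))
  attr(model, "gpaMode") <- mf$gpa_mode
  model
}
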