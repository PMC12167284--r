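#' @include AllClasses.R
NULL

#' Read a surface mesh (PLY, OBJ or STL)
#'
#' Text formats only: ASCII PLY (vertex x/y/z properties and triangular
#' faces), Wavefront OBJ (v/f records, polygonal faces fan-triangulated) and
#' ASCII STL. The format is chosen by file extension. Coordinates are taken
#' to be millimetres.
#'
#' @param path file path.
#' @param frame frame label to attach (default "S").
#' @return A [SurfaceMesh-class].
#' @export
readMesh <- function(path, frame = "S") {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    ply = readMeshPLY(path, frame),
    obj = readMeshOBJ(path, frame),
    stl = readMeshSTL(path, frame),
    stop("unsupported mesh format '.", ext, "' (expected .ply, .obj or .stl)"))
}

readMeshPLY <- function(path, frame) {
  lines <- readLines(path, warn = FALSE)
  if (!startsWith(lines[1], "ply")) stop("not a PLY file: ", path)
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) stop("malformed PLY: no end_header")
  header <- lines[seq_len(endh)]
  if (!any(grepl("^format ascii", header)))
    stop("only ASCII PLY is supported")
  nv <- as.integer(sub("^element vertex\\s+", "",
                       grep("^element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub("^element face\\s+", "",
                       grep("^element face", header, value = TRUE)[1]))
  if (is.na(nv)) stop("malformed PLY: missing vertex element")
  if (is.na(nf)) nf <- 0L
  body <- lines[(endh + 1):length(lines)]
  vl <- body[seq_len(nv)]
  V <- matrix(scan(text = vl, quiet = TRUE), nrow = nv, byrow = TRUE)[, 1:3,
                                                                     drop = FALSE]
  F <- matrix(integer(), 0, 3)
  if (nf > 0) {
    fl <- body[nv + seq_len(nf)]
    toks <- strsplit(trimws(fl), "\\s+")
    F <- do.call(rbind, lapply(seq_along(toks), function(i) {
      tk <- as.integer(toks[[i]])
      if (tk[1] != 3)
        stop("non-triangular face at face line ", i, " (", tk[1], " vertices)")
      tk[2:4] + 1L
    }))
  }
  surfaceMesh(V, F, frame = frame)
}

readMeshOBJ <- function(path, frame) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (!length(vl)) stop("malformed OBJ: no vertices in ", path)
  V <- matrix(scan(text = sub("^v\\s+", "", vl), quiet = TRUE),
              nrow = length(vl), byrow = TRUE)[, 1:3, drop = FALSE]
  F <- list()
  for (ln in fl) {
    idx <- as.integer(sub("/.*$", "", strsplit(trimws(sub("^f\\s+", "", ln)),
                                               "\\s+")[[1]]))
    idx[idx < 0] <- nrow(V) + idx[idx < 0] + 1L   # negative = relative
    for (k in seq_len(length(idx) - 2))           # fan triangulation
      F[[length(F) + 1L]] <- c(idx[1], idx[k + 1], idx[k + 2])
  }
  surfaceMesh(V, if (length(F)) do.call(rbind, F) else matrix(integer(), 0, 3),
              frame = frame)
}

readMeshSTL <- function(path, frame) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^\\s*solid", lines[1]))
    stop("only ASCII STL is supported (file does not start with 'solid')")
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) %% 3 != 0) stop("malformed STL: vertex count not divisible by 3")
  V <- matrix(scan(text = sub("^\\s*vertex\\s+", "", vl), quiet = TRUE),
              nrow = length(vl), byrow = TRUE)
  # deduplicate vertices
  key <- apply(V, 1, paste, collapse = " ")
  uk <- !duplicated(key)
  map <- match(key, key[uk])
  F <- matrix(map, ncol = 3, byrow = TRUE)
  surfaceMesh(V[uk, , drop = FALSE], F, frame = frame)
}

#' Write a surface mesh as ASCII PLY
#'
#' @param mesh a [SurfaceMesh-class].
#' @param path output file path.
#' @param digits coordinate precision (default 8 significant digits).
#' @return \code{path}, invisibly.
#' @export
writeMeshPLY <- function(mesh, path, digits = 8) {
  V <- mesh@vertices; F <- mesh@faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("comment frame", mesh@frame),
               paste("element vertex", nrow(V)),
               "property double x", "property double y", "property double z",
               paste("element face", nrow(F)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(paste(format(V[, 1], digits = digits, trim = TRUE,
                          scientific = FALSE),
                   format(V[, 2], digits = digits, trim = TRUE,
                          scientific = FALSE),
                   format(V[, 3], digits = digits, trim = TRUE,
                          scientific = FALSE)), con)
  if (nrow(F))
    writeLines(paste(3, F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L), con)
  invisible(path)
}

#' Read labelled approximate marker centres
#'
#' Plain-text initialization file for [localizeMarkers()]: whitespace- or
#' tab-delimited columns \code{label x y z} (mm), comment lines starting
#' with \code{#}.
#'
#' @param path file path.
#' @return k x 3 numeric matrix with labels as row names.
#' @export
readMarkerInits <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path, warn = FALSE),
                value = TRUE, invert = TRUE)
  if (!length(lines)) stop("no marker initializations in ", path)
  toks <- strsplit(trimws(lines), "[[:space:],]+")
  bad <- which(lengths(toks) != 4)
  if (length(bad))
    stop("malformed marker init at line ", bad[1], ": expected 'label x y z'")
  M <- do.call(rbind, lapply(toks, function(tk) as.numeric(tk[2:4])))
  if (anyNA(M)) stop("non-numeric coordinates in marker init file")
  rownames(M) <- vapply(toks, `[[`, "", 1)
  M
}

#' Write marker centres (or inits) as delimited text
#' @param markers list of [SphereMarker-class] or a labelled n x 3 matrix.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeMarkerCenters <- function(markers, path) {
  if (is.list(markers)) {
    M <- do.call(rbind, lapply(markers, function(m) m@center))
    rownames(M) <- vapply(markers, function(m) m@label, "")
  } else M <- markers
  writeLines(c("# label x y z",
               paste(rownames(M),
                     format(M[, 1], digits = 10, trim = TRUE),
                     format(M[, 2], digits = 10, trim = TRUE),
                     format(M[, 3], digits = 10, trim = TRUE))), path)
  invisible(path)
}
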