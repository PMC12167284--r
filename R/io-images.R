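#' @include AllClasses.R
NULL

#' Read an image as a grayscale intensity matrix
#'
#' PNG and TIFF (8/16-bit) are supported; multi-channel images are converted
#' to grayscale by the Rec. 601 luma weights. The returned matrix is indexed
#' \code{\[y + 1, x + 1\]} for pixel (x, y).
#'
#' @param path file path (.png, .tif/.tiff).
#' @return numeric matrix in \[0, 1\].
#' @export
readImageGray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "' (expected .png or .tiff)"))
  if (length(dim(a)) == 3) {
    nc <- dim(a)[3]
    if (nc >= 3) a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    else a <- a[, , 1]
  }
  a
}

#' Write a grayscale image to disk
#'
#' PNG output is 8-bit (the depth the png writer supports); for full 16-bit
#' precision use a \code{.tiff} path, written with
#' \code{tiff::writeTIFF(..., bits.per.sample = 16)}.
#'
#' @param image numeric matrix in \[0, 1\], indexed \code{\[y + 1, x + 1\]}.
#' @param path output path (.png or .tif/.tiff).
#' @return \code{path}, invisibly.
#' @export
writeImageGray <- function(image, path) {
  img <- pmin(pmax(image, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 16L),
    stop("unsupported image format '.", ext, "'"))
  invisible(path)
}

#' @rdname writeImageGray
#' @export
writeImagePNG <- function(image, path) writeImageGray(image, path)

#' Write detections of one image as delimited text
#'
#' One row per outline point: \code{detection_id marker_label support x y};
#' unmatched detections carry label \code{.}.
#'
#' @param detections list of [EllipseDetection-class] for one image.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDetections <- function(detections, path) {
  lines <- "# detection_id marker_label support x y"
  for (i in seq_along(detections)) {
    d <- detections[[i]]
    lb <- if (nzchar(d@markerLabel)) d@markerLabel else "."
    pts <- d@outlinePoints
    lines <- c(lines, paste(i, lb, d@supportPixelCount,
                            format(pts[, 1], digits = 12, trim = TRUE),
                            format(pts[, 2], digits = 12, trim = TRUE)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read detections written by [writeDetections()]
#'
#' Conics are re-fitted to the stored outline points by
#' [fitEllipseDLS()].
#'
#' @param path file path.
#' @param imageId image identifier to attach.
#' @return list of [EllipseDetection-class].
#' @export
readDetections <- function(path, imageId = basename(path)) {
  lines <- grep("^\\s*(#|$)", readLines(path, warn = FALSE),
                value = TRUE, invert = TRUE)
  if (!length(lines)) return(list())
  toks <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(toks) != 5)
  if (length(bad)) stop("malformed detection row ", bad[1], " in ", path)
  df <- data.frame(id = vapply(toks, `[[`, "", 1),
                   label = vapply(toks, `[[`, "", 2),
                   support = as.integer(vapply(toks, `[[`, "", 3)),
                   x = as.numeric(vapply(toks, `[[`, "", 4)),
                   y = as.numeric(vapply(toks, `[[`, "", 5)))
  lapply(split(df, df$id), function(g) {
    pts <- cbind(g$x, g$y)
    new("EllipseDetection", conic = fitEllipseDLS(pts), outlinePoints = pts,
        supportPixelCount = g$support[1], imageId = imageId,
        markerLabel = if (g$label[1] == ".") "" else g$label[1])
  })
}

#' Write a registration result as a structured text report
#'
#' Emits \code{transform.json} (4x4 homogeneous matrix, scale, costs,
#' per-image RMS residuals, convergence diagnostics) into \code{dir}.
#'
#' @param result a [RegistrationResult-class].
#' @param dir output directory.
#' @return path to the JSON file, invisibly.
#' @export
writeRegistrationReport <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(
    frame_from = result@transform@frameFrom,
    frame_to = result@transform@frameTo,
    matrix = asMatrix(result@transform),
    scale = result@scale,
    initial_cost = result@initialCost,
    final_cost = result@finalCost,
    n_iterations = result@nIterations,
    converged = result@converged,
    per_image_rms = as.list(result@perImageRms))
  path <- file.path(dir, "transform.json")
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a registration transform written by [writeRegistrationReport()]
#' @param path path to \code{transform.json}.
#' @return A [RigidTransform-class].
#' @export
readRegistrationTransform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  transformFromMatrix(matrix(unlist(x$matrix), 4, 4, byrow = FALSE),
                      frameFrom = x$frame_from, frameTo = x$frame_to)
}

#' Write a radial-error report as delimited text
#' @param report a [RadialErrorReport-class].
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeRadialErrorReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report@perPoint, file.path(dir, "radial_per_point.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report@perMarker, file.path(dir, "radial_per_marker.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report@perImage, file.path(dir, "radial_per_image.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  q <- stats::quantile(report@perPoint$error_mm, c(0.5, 0.9, 0.95, 0.99))
  writeLines(c(sprintf("mean_mm\t%.9g", report@meanMm),
               sprintf("median_mm\t%.9g", report@medianMm),
               sprintf("p90_mm\t%.9g", q[2]),
               sprintf("p95_mm\t%.9g", q[3]),
               sprintf("p99_mm\t%.9g", q[4])),
             file.path(dir, "radial_summary.tsv"))
  invisible(dir)
}
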