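#' @include AllClasses.R registration-init.R registration-refine.R ellipse-fit.R
NULL

#' Convert an ObservationSet to unlabelled per-image detections
#'
#' Re-fits a conic to each (image, marker) outline-point group and packages
#' it as an [EllipseDetection-class], dropping marker labels. Useful for
#' exercising the full pipeline (correspondence search included) on
#' simulated observations.
#'
#' @param obs an [ObservationSet-class].
#' @return named list (by image id) of lists of [EllipseDetection-class].
#' @export
detectionsFromObservations <- function(obs) {
  e <- obs@entries
  out <- lapply(names(obs@cameras), function(img) {
    ei <- e[e$image == img, , drop = FALSE]
    dets <- lapply(split(seq_len(nrow(ei)), ei$marker), function(ix) {
      pts <- cbind(ei$x[ix], ei$y[ix])
      new("EllipseDetection", conic = fitEllipseDLS(pts),
          outlinePoints = pts, supportPixelCount = length(ix),
          imageId = img, markerLabel = "")
    })
    unname(dets)
  })
  names(out) <- names(obs@cameras)
  out
}

#' Match detections to markers across images
#'
#' Given an initial registration, each detection is assigned to the marker
#' whose projected centre is nearest within a gating radius; at most one
#' detection per (image, marker), conflicts keep the nearer detection, and
#' unassigned detections are dropped (with a message).
#'
#' @param detections named list (by image id) of [EllipseDetection-class]
#'   lists.
#' @param cameras named list of [Camera-class].
#' @param markers named list of [SphereMarker-class] (frame S).
#' @param Tinit initial S-to-W [RigidTransform-class].
#' @param gatePx gating radius (px); default [defaultGatePx()] of the first
#'   camera.
#' @param maxPointsPerDetection cap on outline points carried per detection
#'   (evenly subsampled); default Inf.
#' @param quiet suppress drop/conflict messages (default TRUE).
#' @return An [ObservationSet-class].
#' @export
matchDetections <- function(detections, cameras, markers, Tinit,
                            gatePx = defaultGatePx(cameras[[1]]),
                            maxPointsPerDetection = Inf, quiet = TRUE) {
  centersS <- do.call(rbind, lapply(markers, function(m) m@center))
  centersW <- applyTransform(Tinit, centersS)
  labels <- names(markers)
  rows <- list()
  for (img in names(detections)) {
    dets <- detections[[img]]
    if (length(dets) == 0) next
    cam <- cameras[[img]]
    Xc <- applyTransform(cam@pose, centersW)
    vis <- Xc[, 3] > 0
    proj <- cbind(cam@fx * Xc[, 1] / Xc[, 3] + cam@cx,
                  cam@fy * Xc[, 2] / Xc[, 3] + cam@cy)
    dctr <- t(vapply(dets, function(d) conicParams(d@conic)$center,
                     numeric(2)))
    dist <- sqrt(outer(dctr[, 1], proj[, 1], "-")^2 +
                 outer(dctr[, 2], proj[, 2], "-")^2)
    dist[, !vis] <- Inf
    assigned <- rep(NA_integer_, length(dets))   # detection -> marker
    taken <- rep(NA_integer_, length(markers))   # marker -> detection
    ord <- order(apply(dist, 1, min))
    for (di in ord) {
      j <- which.min(dist[di, ])
      if (!is.finite(dist[di, j]) || dist[di, j] > gatePx) {
        if (!quiet) message("image ", img, ": detection ", di,
                            " unassigned (outside gate), dropped")
        next
      }
      if (!is.na(taken[j])) {
        if (!quiet) message("image ", img, ": detections ", taken[j], " and ",
                            di, " compete for marker ", labels[j],
                            "; keeping the nearer")
        next  # earlier di in ord is nearer by construction
      }
      assigned[di] <- j
      taken[j] <- di
    }
    for (di in which(!is.na(assigned))) {
      pts <- dets[[di]]@outlinePoints
      if (nrow(pts) > maxPointsPerDetection) {
        keep <- round(seq(1, nrow(pts), length.out = maxPointsPerDetection))
        pts <- pts[keep, , drop = FALSE]
      }
      rows[[length(rows) + 1L]] <-
        data.frame(image = img, marker = labels[assigned[di]],
                   x = pts[, 1], y = pts[, 2])
    }
  }
  if (length(rows) == 0)
    stop("no detections could be matched to markers within the gate")
  observationSet(cameras, markers, do.call(rbind, rows))
}

#' End-to-end scene registration
#'
#' Pipeline: exhaustive PnP correspondence search on the image with the most
#' detections, detection-to-marker matching across all images under the
#' initial transform, then conic-residual refinement. In similarity mode the
#' initial scale is estimated from the camera-centre baseline between the
#' two best images (each solved independently by PnP in metric marker
#' units) relative to the same baseline in the camera world.
#'
#' @param markers named list of [SphereMarker-class] with centres in frame S
#'   (e.g. from [localizeMarkers()]).
#' @param detections named list (by image id) of [EllipseDetection-class]
#'   lists, e.g. from [detectEllipses()] or [detectionsFromObservations()].
#' @param cameras named list of [Camera-class].
#' @param mode "rigid" or "similarity".
#' @param gatePx gating radius (px) for init and matching.
#' @param imageWhitelist optional character vector of image ids to use.
#' @param quiet suppress progress messages (default TRUE).
#' @return A [RegistrationResult-class].
#' @export
registerScene <- function(markers, detections, cameras,
                          mode = c("rigid", "similarity"),
                          gatePx = defaultGatePx(cameras[[1]]),
                          imageWhitelist = NULL, quiet = TRUE) {
  mode <- match.arg(mode)
  if (!is.null(imageWhitelist)) {
    detections <- detections[intersect(names(detections), imageWhitelist)]
    cameras <- cameras[intersect(names(cameras), imageWhitelist)]
  }
  counts <- vapply(detections, length, 0L)
  if (!length(counts) || max(counts) < 4)
    stop("initialization failed: no image with at least 4 detections")
  ordImg <- names(sort(counts, decreasing = TRUE))

  detCenters <- function(img) {
    dets <- detections[[img]]
    ord <- order(vapply(dets, function(d) d@supportPixelCount, 0L),
                 decreasing = TRUE)
    t(vapply(dets[ord], function(d) conicParams(d@conic)$center, numeric(2)))
  }
  img1 <- ordImg[1]
  s1 <- tryCatch(
    pnpCorrespondenceSearch(detCenters(img1), cameras[[img1]], markers,
                            gatePx),
    error = function(e) stop("initialization stage: ", conditionMessage(e)))
  Tinit <- s1$transform
  if (mode == "similarity") {
    if (length(ordImg) < 2)
      stop("similarity mode needs at least two images for scale initialization")
    img2 <- ordImg[2]
    s2 <- tryCatch(
      pnpCorrespondenceSearch(detCenters(img2), cameras[[img2]], markers,
                              gatePx),
      error = function(e) stop("initialization stage: ", conditionMessage(e)))
    # camera centres in frame S (metric) vs in the camera world (arbitrary
    # units): their baseline ratio is the world scale
    cS1 <- applyTransform(invertTransform(s1$camFromS), c(0, 0, 0))
    cS2 <- applyTransform(invertTransform(s2$camFromS), c(0, 0, 0))
    baseS <- sqrt(sum((cS1 - cS2)^2))
    baseW <- sqrt(sum((cameraCenter(cameras[[img1]]) -
                       cameraCenter(cameras[[img2]]))^2))
    if (baseS < 1e-9 || baseW < 1e-9)
      stop("initialization stage: degenerate baseline for scale estimation")
    sHat <- baseW / baseS
    TsC <- rigidTransform(s1$camFromS@rotation,
                          sHat * s1$camFromS@translation, scale = sHat,
                          frameFrom = "S", frameTo = "C")
    Tinit <- compose(invertTransform(cameras[[img1]]@pose), TsC)
    if (!quiet) message("initial scale estimate: ", format(sHat))
  }
  obs <- tryCatch(
    matchDetections(detections, cameras, markers, Tinit, gatePx,
                    quiet = quiet),
    error = function(e) stop("matching stage: ", conditionMessage(e)))
  nPairs <- nrow(unique(obs@entries[c("image", "marker")]))
  nDet <- sum(vapply(detections, length, 0L))
  if (nPairs < nDet / 2)
    warning("only ", nPairs, " of ", nDet, " detections matched a marker; ",
            "the ", mode, " model may not explain these poses ",
            "(wrong mode or bad initialization)")
  tryCatch(refineRegistration(obs, Tinit, mode),
           error = function(e) stop("refinement stage: ",
                                    conditionMessage(e)))
}
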