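#' @include AllClasses.R ellipse-fit.R conics.R
NULL

## Otsu threshold on a 256-bin histogram of the intensity range
otsuThreshold <- function(im) {
  r <- range(im)
  if (r[1] == r[2]) return(r[1])
  h <- tabulate(pmin(255L, as.integer((im - r[1]) / (r[2] - r[1]) * 256)) + 1L,
                256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(256))
  muT <- mu[256]
  sigma <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigma[!is.finite(sigma)] <- 0
  k <- which.max(sigma)
  r[1] + (k - 0.5) / 256 * (r[2] - r[1])
}

#' Ellipse detection configuration
#'
#' @param polarity "bright" (default): markers brighter than background, or
#'   "dark".
#' @param threshold "otsu" (adaptive, invariant to affine gain/offset) or a
#'   numeric intensity level.
#' @param minAxisPx minimum semi-minor axis (default 10 px); smaller
#'   detections (noise specks) are rejected.
#' @param maxAxisPx maximum semi-major axis; default a quarter of the image
#'   diagonal (set at detection time when NULL).
#' @param maxResidualPx maximum mean geometric residual of edge points to
#'   the fitted ellipse (default 0.4 px); merged or non-elliptical blobs
#'   fail this gate.
#' @param minSupportPx minimum connected-component pixel count (default 50).
#' @return config list.
#' @export
detectionConfig <- function(polarity = "bright", threshold = "otsu",
                            minAxisPx = 10, maxAxisPx = NULL,
                            maxResidualPx = 0.4, minSupportPx = 50L) {
  list(polarity = match.arg(polarity, c("bright", "dark")),
       threshold = threshold, minAxisPx = minAxisPx, maxAxisPx = maxAxisPx,
       maxResidualPx = maxResidualPx, minSupportPx = as.integer(minSupportPx))
}

## sub-pixel threshold crossings between component pixels and their
## 4-neighbours outside the component, by linear interpolation of intensity
subpixelBoundary <- function(im, mask, thr) {
  h <- nrow(im); w <- ncol(im)
  pts <- list()
  shifts <- list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))   # (dy, dx)
  for (s in shifts) {
    dy <- s[1]; dx <- s[2]
    ys <- max(1, 1 - dy):min(h, h - dy)
    xs <- max(1, 1 - dx):min(w, w - dx)
    inM <- mask[ys, xs, drop = FALSE]
    outM <- mask[ys + dy, xs + dx, drop = FALSE]
    Iin <- im[ys, xs, drop = FALSE]
    Iout <- im[ys + dy, xs + dx, drop = FALSE]
    sel <- which(inM & !outM & (Iin >= thr) & (Iout < thr))
    if (!length(sel)) next
    fy <- ((sel - 1) %% nrow(inM)) + ys[1]       # row index in im
    fx <- ((sel - 1) %/% nrow(inM)) + xs[1]      # col index in im
    frac <- (Iin[sel] - thr) / (Iin[sel] - Iout[sel])
    # pixel (x, y) = (col - 1, row - 1); crossing along the neighbour offset
    pts[[length(pts) + 1L]] <- cbind((fx - 1) + frac * dx,
                                     (fy - 1) + frac * dy)
  }
  if (!length(pts)) return(matrix(numeric(), 0, 2))
  do.call(rbind, pts)
}

#' Detect elliptical marker projections in an image
#'
#' Pipeline: adaptive (Otsu) or fixed intensity threshold, connected
#' components, sub-pixel boundary extraction by linear interpolation of the
#' threshold crossing, direct least-squares ellipse-constrained conic fit,
#' and residual gating. Detections are returned sorted by descending
#' support. Components whose boundary does not fit an ellipse within the
#' residual gate (e.g. two merged silhouettes) are rejected.
#'
#' @param image 2D numeric matrix; element \[y + 1, x + 1\] is the intensity
#'   of pixel (x, y) (0-based, x right, y down).
#' @param params a [detectionConfig()].
#' @param imageId identifier stored in the detections.
#' @return list of [EllipseDetection-class] (possibly empty).
#' @export
detectEllipses <- function(image, params = detectionConfig(),
                           imageId = "img") {
  if (length(dim(image)) != 2)
    stop("image must be a 2D single-channel matrix")
  im <- if (params$polarity == "dark") max(image) - image else image
  thr <- if (identical(params$threshold, "otsu")) otsuThreshold(im)
         else as.numeric(params$threshold)
  maxAx <- params$maxAxisPx
  if (is.null(maxAx)) maxAx <- sqrt(nrow(im)^2 + ncol(im)^2) / 4
  bw <- im >= thr
  lab <- EBImage::bwlabel(bw)
  nlab <- max(lab)
  if (nlab == 0) return(list())
  counts <- tabulate(lab[lab > 0], nlab)
  dets <- list()
  for (k in which(counts >= params$minSupportPx)) {
    mask <- lab == k
    bnd <- subpixelBoundary(im, mask, thr)
    if (nrow(bnd) < 8) next
    co <- tryCatch(fitEllipseDLS(bnd), error = function(e) NULL)
    if (is.null(co) || !isEllipse(co)) next
    p <- conicParams(co)
    if (p$semiAxes[2] < params$minAxisPx || p$semiAxes[1] > maxAx) next
    resid <- mean(pointEllipseDistance(p, bnd))
    if (resid > params$maxResidualPx) {
      message("detection rejected (residual ", format(resid, digits = 3),
              " px > ", params$maxResidualPx, " px): non-elliptical boundary")
      next
    }
    dets[[length(dets) + 1L]] <-
      new("EllipseDetection", conic = co, outlinePoints = bnd,
          supportPixelCount = counts[k], imageId = imageId,
          markerLabel = "")
  }
  ord <- order(vapply(dets, function(d) d@supportPixelCount, 0L),
               decreasing = TRUE)
  dets[ord]
}

setMethod("show", "EllipseDetection", function(object) {
  p <- conicParams(object@conic)
  cat(sprintf(
    "EllipseDetection [%s%s]: centre (%.2f, %.2f), axes (%.2f, %.2f), %d px support\n",
    object@imageId,
    if (nzchar(object@markerLabel)) paste0(" -> ", object@markerLabel) else "",
    p$center[1], p$center[2], p$semiAxes[1], p$semiAxes[2],
    object@supportPixelCount))
})
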