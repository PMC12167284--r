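#' @include AllClasses.R conics.R
NULL

#' Render synthetic images of spherical markers
#'
#' Anti-aliased grayscale rendering of bright spheres on a textured dark
#' background, for exercising the ellipse detector. Edge anti-aliasing uses
#' the first-order approximation of the Euclidean distance to the silhouette
#' conic (algebraic value over gradient magnitude). A ground-truth conic
#' sidecar is returned alongside each image.
#'
#' @param markers list of [SphereMarker-class] with centres in the cameras'
#'   world frame.
#' @param cameras named list of [Camera-class]; image size is taken from each
#'   camera (capped at 4096 x 4096).
#' @param brightness sphere intensity (default 0.92).
#' @param background mean background level (default 0.10).
#' @param textureSd standard deviation of the background texture noise
#'   (default 0.03).
#' @param seed integer seed for the background texture.
#' @return named list (by image id) of lists with \code{image} (height x
#'   width matrix in \[0, 1\]; element \[y + 1, x + 1\] is pixel (x, y)) and
#'   \code{conics} (list of ground-truth [Conic-class], one per visible
#'   marker, named by marker label).
#' @export
renderImages <- function(markers, cameras, brightness = 0.92,
                         background = 0.10, textureSd = 0.03, seed = 1L) {
  set.seed(seed)
  out <- lapply(cameras, function(cam) {
    w <- cam@width; h <- cam@height
    if (w > 4096 || h > 4096)
      stop("render size capped at 4096 x 4096 (got ", w, " x ", h, ")")
    img <- matrix(background + stats::rnorm(w * h, sd = textureSd), h, w)
    conics <- list()
    for (m in markers) {
      co <- tryCatch(projectSphere(m, cam), error = function(e) NULL)
      if (is.null(co)) next
      conics[[m@label]] <- co
      p <- conicParams(co)
      a <- p$semiAxes[1]
      x0 <- max(0, floor(p$center[1] - a - 2))
      x1 <- min(w - 1, ceiling(p$center[1] + a + 2))
      y0 <- max(0, floor(p$center[2] - a - 2))
      y1 <- min(h - 1, ceiling(p$center[2] + a + 2))
      if (x1 < x0 || y1 < y0) next
      xs <- x0:x1; ys <- y0:y1
      E <- co@matrix
      X <- rep(xs, each = length(ys)); Y <- rep(ys, length(xs))
      q <- E[1, 1] * X^2 + 2 * E[1, 2] * X * Y + E[2, 2] * Y^2 +
        2 * E[1, 3] * X + 2 * E[2, 3] * Y + E[3, 3]
      gx <- 2 * (E[1, 1] * X + E[1, 2] * Y + E[1, 3])
      gy <- 2 * (E[1, 2] * X + E[2, 2] * Y + E[2, 3])
      d <- q / pmax(sqrt(gx^2 + gy^2), 1e-300)   # signed distance, <0 inside
      cov <- pmin(pmax(0.5 - d, 0), 1)
      blk <- img[ys + 1, xs + 1, drop = FALSE]
      img[ys + 1, xs + 1] <- cov * brightness + (1 - cov) * blk
    }
    list(image = pmin(pmax(img, 0), 1), conics = conics)
  })
  names(out) <- names(cameras)
  out
}
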