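#' @include AllClasses.R AllGenerics.R
NULL

#' Intrinsic matrix of a camera
#' @param cam a [Camera-class].
#' @return 3x3 upper-triangular intrinsic matrix K.
#' @export
intrinsicMatrix <- function(cam) {
  matrix(c(cam@fx, 0, 0,
           0, cam@fy, 0,
           cam@cx, cam@cy, 1), 3, 3)
}

#' @describeIn projectionMatrix \code{K [R | t]} from intrinsics and pose
#' @export
setMethod("projectionMatrix", "Camera", function(x) {
  K <- intrinsicMatrix(x)
  P <- K %*% cbind(x@pose@rotation, x@pose@translation)
  if (qr(P)$rank < 3) stop("projection matrix is rank-deficient")
  P
})

#' Camera centre in the world frame
#' @param cam a [Camera-class].
#' @return length-3 world coordinates of the optical centre.
#' @export
cameraCenter <- function(cam) {
  -as.numeric(crossprod(cam@pose@rotation, cam@pose@translation))
}

#' Project world points to pixel coordinates
#'
#' @param cam a [Camera-class].
#' @param points n x 3 matrix (or length-3 vector) of world points.
#' @return n x 2 matrix of pixel coordinates.
#' @export
projectPoints <- function(cam, points) {
  if (is.null(dim(points))) points <- matrix(points, 1, 3)
  Xc <- applyTransform(cam@pose, points)
  if (any(Xc[, 3] <= 0))
    stop("point behind camera (non-positive depth)")
  cbind(cam@fx * Xc[, 1] / Xc[, 3] + cam@cx,
        cam@fy * Xc[, 2] / Xc[, 3] + cam@cy)
}

#' Back-project a pixel to a world ray
#'
#' @param cam a [Camera-class].
#' @param px length-2 pixel coordinates.
#' @return list with \code{origin} (camera centre, world) and unit
#'   \code{direction} (world).
#' @export
backprojectRay <- function(cam, px) {
  d_cam <- c((px[1] - cam@cx) / cam@fx, (px[2] - cam@cy) / cam@fy, 1)
  d <- as.numeric(crossprod(cam@pose@rotation, d_cam))
  list(origin = cameraCenter(cam), direction = d / sqrt(sum(d^2)))
}

setMethod("show", "Camera", function(object) {
  cat(sprintf("Camera '%s': %dx%d px, f = (%.1f, %.1f), c = (%.1f, %.1f)\n",
              object@id, object@width, object@height, object@fx, object@fy,
              object@cx, object@cy))
  cc <- cameraCenter(object)
  cat(sprintf("  centre (world): (%.2f, %.2f, %.2f)\n", cc[1], cc[2], cc[3]))
})
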