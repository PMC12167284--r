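#' @include AllGenerics.R
NULL

#' @describeIn compose rigid/similarity composition with frame checking
#' @export
setMethod("compose", signature("RigidTransform", "RigidTransform"),
  function(a, b) {
    if (b@frameTo != a@frameFrom)
      stop("frame mismatch in compose(): inner transform maps to '",
           b@frameTo, "' but outer transform maps from '", a@frameFrom, "'")
    rigidTransform(
      rotation = a@rotation %*% b@rotation,
      translation = a@scale * as.numeric(a@rotation %*% b@translation) +
        a@translation,
      scale = a@scale * b@scale,
      frameFrom = b@frameFrom, frameTo = a@frameTo)
  })

#' @describeIn invertTransform closed-form inverse; swaps frame labels
#' @export
setMethod("invertTransform", "RigidTransform", function(x) {
  Rt <- t(x@rotation)
  rigidTransform(rotation = Rt,
                 translation = -as.numeric(Rt %*% x@translation) / x@scale,
                 scale = 1 / x@scale,
                 frameFrom = x@frameTo, frameTo = x@frameFrom)
})

#' @describeIn applyTransform maps points as \code{s R x + t}
#' @export
setMethod("applyTransform", "RigidTransform", function(x, points) {
  if (is.null(dim(points))) {
    stopifnot(length(points) == 3)
    return(x@scale * as.numeric(x@rotation %*% points) + x@translation)
  }
  stopifnot(ncol(points) == 3)
  sweep(x@scale * points %*% t(x@rotation), 2, x@translation, "+")
})

#' @describeIn asMatrix homogeneous matrix of a rigid/similarity transform
#' @export
setMethod("asMatrix", "RigidTransform", function(x) {
  H <- diag(4)
  H[1:3, 1:3] <- x@scale * x@rotation
  H[1:3, 4] <- x@translation
  H
})

#' Build a RigidTransform from a homogeneous 4x4 matrix
#'
#' The upper-left block is factored as \code{s R} with \code{s} the common
#' column norm; fails if the block is not a scaled rotation.
#'
#' @param H 4x4 homogeneous matrix.
#' @param frameFrom,frameTo frame labels.
#' @return A [RigidTransform-class].
#' @export
transformFromMatrix <- function(H, frameFrom = "A", frameTo = "B") {
  stopifnot(all(dim(H) == c(4, 4)))
  A <- H[1:3, 1:3]
  s <- det(A)
  if (s <= 0) stop("upper-left block has non-positive determinant")
  s <- s^(1 / 3)
  rigidTransform(rotation = A / s, translation = H[1:3, 4], scale = s,
                 frameFrom = frameFrom, frameTo = frameTo)
}

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf("RigidTransform %s -> %s (scale %.6g)\n",
              object@frameFrom, object@frameTo, object@scale))
  aa <- axisAngleFromRotation(object@rotation)
  cat(sprintf("  rotation: %.4f rad about (%.3f, %.3f, %.3f)\n",
              sqrt(sum(aa^2)),
              if (sqrt(sum(aa^2)) > 0) aa[1] / sqrt(sum(aa^2)) else 0,
              if (sqrt(sum(aa^2)) > 0) aa[2] / sqrt(sum(aa^2)) else 0,
              if (sqrt(sum(aa^2)) > 0) aa[3] / sqrt(sum(aa^2)) else 1))
  cat(sprintf("  translation: (%.4f, %.4f, %.4f)\n",
              object@translation[1], object@translation[2],
              object@translation[3]))
})
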