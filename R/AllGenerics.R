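#' @include AllClasses.R
NULL

#' Compose two transforms
#'
#' \code{compose(a, b)} returns the transform that first applies \code{b} and
#' then \code{a}; as homogeneous 4x4 matrices the result is \code{A %*% B}.
#' Frame labels must chain: \code{b@frameTo == a@frameFrom}.
#'
#' @param a,b [RigidTransform-class] objects.
#' @return A [RigidTransform-class] from \code{b@frameFrom} to \code{a@frameTo}.
#' @export
setGeneric("compose", function(a, b) standardGeneric("compose"))

#' Invert a transform
#' @param x a [RigidTransform-class].
#' @return The inverse transform, with frame labels swapped.
#' @export
setGeneric("invertTransform", function(x) standardGeneric("invertTransform"))

#' Apply a transform to 3D points
#' @param x a [RigidTransform-class].
#' @param points n x 3 matrix or length-3 vector.
#' @return Transformed points, same shape as input.
#' @export
setGeneric("applyTransform",
           function(x, points) standardGeneric("applyTransform"))

#' Homogeneous 4x4 matrix of a transform
#' @param x a [RigidTransform-class].
#' @return 4x4 matrix \code{[[s R, t], \[0, 1\]]}.
#' @export
setGeneric("asMatrix", function(x) standardGeneric("asMatrix"))

#' 3x4 projection matrix of a camera
#' @param x a [Camera-class].
#' @return 3x4 matrix \code{K [R | t]}.
#' @export
setGeneric("projectionMatrix",
           function(x) standardGeneric("projectionMatrix"))

#' Sphere quadric matrix
#'
#' The 4x4 symmetric quadric \code{Q = [[I, -c], [-c', c'c - r^2]]} whose
#' zero set in homogeneous coordinates is the sphere surface.
#'
#' @param m a [SphereMarker-class].
#' @return 4x4 symmetric matrix.
#' @export
setGeneric("sphereQuadric", function(m) standardGeneric("sphereQuadric"))
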