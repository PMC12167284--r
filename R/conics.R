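#' @include AllClasses.R AllGenerics.R camera.R
NULL

## adjugate of a 3x3 matrix (transpose of the cofactor matrix)
adjugate3 <- function(B) {
  matrix(c(
    B[2, 2] * B[3, 3] - B[2, 3] * B[3, 2],
    B[2, 3] * B[3, 1] - B[2, 1] * B[3, 3],
    B[2, 1] * B[3, 2] - B[2, 2] * B[3, 1],
    B[1, 3] * B[3, 2] - B[1, 2] * B[3, 3],
    B[1, 1] * B[3, 3] - B[1, 3] * B[3, 1],
    B[1, 2] * B[3, 1] - B[1, 1] * B[3, 2],
    B[1, 2] * B[2, 3] - B[1, 3] * B[2, 2],
    B[1, 3] * B[2, 1] - B[1, 1] * B[2, 3],
    B[1, 1] * B[2, 2] - B[1, 2] * B[2, 1]), 3, 3)
}

#' @describeIn sphereQuadric canonical quadric of a sphere marker
#' @export
setMethod("sphereQuadric", "SphereMarker", function(m) {
  c <- m@center; r <- m@radius
  rbind(cbind(diag(3), -c), c(-c, sum(c^2) - r^2))
})

## dual quadric of a sphere, proportional to adj(Q): acts on tangent planes.
## D = [[c c' - r^2 I, c], [c', 1]]
sphereDualQuadric <- function(center, radius) {
  rbind(cbind(tcrossprod(center) - radius^2 * diag(3), center),
        c(center, 1))
}

#' Project a sphere to its image conic
#'
#' The silhouette of a sphere under a pinhole camera is the conic
#' \eqn{E} with \eqn{E^{-1} = P Q^{-1} P^T} (dual-quadric projection). The
#' implementation uses the closed-form dual quadric of the sphere and the
#' adjugate of the projected 3x3 dual conic, which is numerically stable and
#' avoids explicit inversion.
#'
#' @param m a [SphereMarker-class] with centre in the camera's world frame.
#' @param cam a [Camera-class].
#' @return A normalized [Conic-class]; an ellipse whenever the sphere is
#'   fully in front of the principal plane.
#' @examples
#' cam <- camera(1000, 1000, 500, 500, 1000, 1000)
#' m <- sphereMarker(c(0, 0, 1000), 100, frame = "W")
#' conicParams(projectSphere(m, cam))
#' @export
projectSphere <- function(m, cam) {
  cc <- applyTransform(cam@pose, m@center)
  if (cc[3] <= 0 || sqrt(sum(cc^2)) <= m@radius)
    stop("degenerate silhouette: sphere behind camera or enclosing the ",
         "camera centre")
  P <- projectionMatrix(cam)
  B <- P %*% sphereDualQuadric(m@center, m@radius) %*% t(P)
  conic(adjugate3(B))
}

#' Evaluate the bilinear conic form at image points
#'
#' Returns \eqn{x^T E x} for each point, with \eqn{x} in homogeneous pixel
#' coordinates and \eqn{E} the normalized conic matrix. Points on the conic
#' give zero.
#'
#' @param c a [Conic-class].
#' @param points n x 2 matrix or length-2 vector of pixel coordinates.
#' @return numeric vector of residuals.
#' @export
conicResidual <- function(c, points) {
  if (is.null(dim(points))) points <- matrix(points, 1, 2)
  E <- c@matrix
  X <- cbind(points, 1)
  rowSums((X %*% E) * X)
}

#' Geometric parameters of an ellipse conic
#'
#' @param c a [Conic-class] representing a real ellipse.
#' @return list with \code{center} (px), \code{semiAxes} (a >= b, px) and
#'   \code{angle} (radians in (-pi/2, pi/2], the direction of the semi-major
#'   axis; 0 by convention for circles).
#' @export
conicParams <- function(c) {
  E <- c@matrix
  A33 <- E[1:2, 1:2]
  b <- E[1:2, 3]
  dA <- det(A33)
  if (dA <= 0) stop("conic is not an ellipse (non-elliptic quadratic part)")
  ctr <- -solve(A33, b)
  k <- E[3, 3] + sum(b * ctr)      # constant term after centring
  eg <- eigen(A33, symmetric = TRUE)
  ax2 <- -k / eg$values            # semi-axis^2 along each eigenvector
  if (any(ax2 <= 0)) stop("degenerate conic: empty or imaginary ellipse")
  # order semi-major first
  ord <- order(ax2, decreasing = TRUE)
  ax <- sqrt(ax2[ord])
  if (abs(ax[1] - ax[2]) < 1e-12 * ax[1]) {
    ang <- 0
  } else {
    v <- eg$vectors[, ord[1]]
    ang <- atan2(v[2], v[1])
    if (ang <= -pi / 2) ang <- ang + pi
    if (ang > pi / 2) ang <- ang - pi
    if (abs(ang + pi / 2) < 1e-12) ang <- pi / 2
  }
  list(center = as.numeric(ctr), semiAxes = ax, angle = ang)
}

#' Build an ellipse conic from geometric parameters
#'
#' Inverse of [conicParams()].
#'
#' @param center length-2 centre (px).
#' @param semiAxes length-2 semi-axes, major first (px).
#' @param angle rotation of the major axis (radians).
#' @return A normalized [Conic-class].
#' @export
paramsToConic <- function(center, semiAxes, angle = 0) {
  stopifnot(all(semiAxes > 0))
  a <- semiAxes[1]; b <- semiAxes[2]
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  A33 <- R %*% diag(1 / c(a^2, b^2)) %*% t(R)
  bb <- -A33 %*% center
  k <- as.numeric(t(center) %*% A33 %*% center) - 1
  conic(rbind(cbind(A33, bb), c(bb, k)))
}

#' Whether a conic is a real ellipse
#' @param c a [Conic-class].
#' @return logical.
#' @export
isEllipse <- function(c) {
  ok <- tryCatch({ conicParams(c); TRUE }, error = function(e) FALSE)
  ok
}

#' Sample points on an ellipse outline
#'
#' Returns \code{L} points uniformly spaced in the parametric angle of the
#' ellipse, starting at the semi-major vertex. Every returned point satisfies
#' the conic identity \eqn{x^T E x = 0} to numerical precision.
#'
#' @param c a [Conic-class] representing a real ellipse.
#' @param L number of points, at least 4 (default 20).
#' @return L x 2 matrix of pixel coordinates.
#' @export
sampleOutline <- function(c, L = 20L) {
  if (L < 4) stop("L must be at least 4 (got ", L, ")")
  p <- conicParams(c)
  th <- 2 * pi * (seq_len(L) - 1) / L
  a <- p$semiAxes[1]; b <- p$semiAxes[2]
  ca <- cos(p$angle); sa <- sin(p$angle)
  x <- a * cos(th); y <- b * sin(th)
  cbind(p$center[1] + ca * x - sa * y,
        p$center[2] + sa * x + ca * y)
}

setMethod("show", "Conic", function(object) {
  if (isEllipse(object)) {
    p <- conicParams(object)
    cat(sprintf(
      "Conic (ellipse): centre (%.3f, %.3f), semi-axes (%.3f, %.3f), angle %.4f rad\n",
      p$center[1], p$center[2], p$semiAxes[1], p$semiAxes[2], p$angle))
  } else {
    cat("Conic (non-elliptic)\n")
    print(object@matrix)
  }
})

setMethod("show", "SphereMarker", function(object) {
  cat(sprintf("SphereMarker '%s' [%s]: centre (%.3f, %.3f, %.3f), r = %.3f mm\n",
              object@label, object@frame, object@center[1], object@center[2],
              object@center[3], object@radius))
})

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh [%s]: %d vertices, %d faces\n", object@frame,
              nrow(object@vertices), nrow(object@faces)))
})

setMethod("show", "ObservationSet", function(object) {
  e <- object@entries
  cat(sprintf(
    "ObservationSet: %d cameras, %d markers, %d (image, marker) pairs, %d points\n",
    length(object@cameras), length(object@markers),
    nrow(unique(e[c("image", "marker")])), nrow(e)))
})
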