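#' @useDynLib sphereg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

## Rotation helpers shared by the transform, pose-IO and optimisation code.
## Conventions: rotations are 3x3 orthonormal matrices with det +1;
## quaternions are (w, x, y, z), unit norm; axis-angle vectors are in radians.

skew3 <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

#' Axis-angle to rotation matrix
#'
#' Rodrigues' formula. The zero vector maps to the identity.
#'
#' @param omega numeric length-3 axis-angle vector (radians).
#' @return 3x3 rotation matrix.
#' @export
rotationFromAxisAngle <- function(omega) {
  stopifnot(is.numeric(omega), length(omega) == 3)
  th <- sqrt(sum(omega^2))
  if (th < 1e-12) {
    K <- skew3(omega)
    return(diag(3) + K + 0.5 * K %*% K)
  }
  K <- skew3(omega / th)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation matrix to axis-angle
#'
#' @param R 3x3 rotation matrix.
#' @return numeric length-3 axis-angle vector (radians), angle in \[0, pi\].
#' @export
axisAngleFromRotation <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- max(-1, min(1, ct))
  th <- acos(ct)
  if (th < 1e-9) {
    return(c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2)
  }
  if (th > pi - 1e-6) {
    # near pi: extract axis from R + I
    A <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(A), 0))
    # fix signs using the largest component
    i <- which.max(ax)
    s <- sign(c(A[1, i], A[2, i], A[3, i]))
    s[s == 0] <- 1
    ax <- ax * s / sign(ax[i])
    return(th * ax / sqrt(sum(ax^2)))
  }
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  th * v / (2 * sin(th))
}

## Right Jacobian of SO(3): exp((omega + d)x) ~ exp(omega x) exp((Jr(omega) d)x)
so3RightJacobian <- function(omega) {
  th <- sqrt(sum(omega^2))
  K <- skew3(omega)
  if (th < 1e-6) {
    return(diag(3) - 0.5 * K + (1 / 6) * (K %*% K))
  }
  diag(3) - ((1 - cos(th)) / th^2) * K + ((th - sin(th)) / th^3) * (K %*% K)
}

#' Quaternion (w, x, y, z) to rotation matrix
#' @param q numeric length-4 unit quaternion, scalar part first.
#' @return 3x3 rotation matrix.
#' @export
rotationFromQuaternion <- function(q) {
  stopifnot(length(q) == 4)
  n <- sqrt(sum(q^2))
  if (abs(n - 1) > 1e-6) stop("quaternion is not unit norm: |q| = ", format(n))
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' Rotation matrix to quaternion (w, x, y, z)
#' @param R 3x3 rotation matrix.
#' @return numeric length-4 unit quaternion with non-negative scalar part.
#' @export
quaternionFromRotation <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, s / 4, (R[1, 2] + R[2, 1]) / s,
             (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, s / 4,
             (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, s / 4)
    }
  }
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q^2))
}

## Uniformly distributed random rotation (subgroup algorithm via quaternions).
randomRotation <- function() {
  q <- stats::rnorm(4)
  rotationFromQuaternion(q / sqrt(sum(q^2)))
}

## angle (radians) between two rotations
rotationAngleBetween <- function(R1, R2) {
  ct <- (sum(diag(crossprod(R1, R2))) - 1) / 2
  acos(max(-1, min(1, ct)))
}
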