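#' @include AllClasses.R conics.R
NULL

#' Direct least-squares ellipse fit
#'
#' Fits a conic constrained to be an ellipse to 2D points by the
#' numerically stable partitioned eigen formulation of the direct
#' least-squares method (quadratic constraint \eqn{4AC - B^2 = 1}).
#' Points are centred and scaled internally for conditioning.
#'
#' @param pts n x 2 matrix of points, n >= 5.
#' @return A normalized [Conic-class] ellipse.
#' @export
fitEllipseDLS <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 5) stop("at least 5 points are required to fit an ellipse")
  ctr <- colMeans(pts)
  sc <- mean(sqrt(rowSums(sweep(pts, 2, ctr)^2)))
  if (sc == 0) stop("degenerate point set")
  x <- (pts[, 1] - ctr[1]) / sc
  y <- (pts[, 2] - ctr[2]) / sc
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  Mm <- S1 + S2 %*% Tm
  Mm <- rbind(Mm[3, ] / 2, -Mm[2, ], Mm[1, ] / 2)
  eg <- eigen(Mm)
  # pick the eigenvector satisfying the ellipse constraint 4ac - b^2 > 0
  ok <- which(abs(Im(eg$values)) < 1e-8 &
              Re(4 * eg$vectors[1, ] * eg$vectors[3, ] -
                 eg$vectors[2, ]^2) > 0)
  if (length(ok) == 0) stop("no elliptical solution for these points")
  a1 <- Re(eg$vectors[, ok[1]])
  a2 <- as.numeric(Tm %*% a1)
  A <- a1[1]; B <- a1[2]; C <- a1[3]; D <- a2[1]; E <- a2[2]; Fc <- a2[3]
  En <- matrix(c(A, B / 2, D / 2,
                 B / 2, C, E / 2,
                 D / 2, E / 2, Fc), 3, 3)
  # undo the normalization x -> (x - ctr)/sc
  S <- matrix(c(1 / sc, 0, 0, 0, 1 / sc, 0,
                -ctr[1] / sc, -ctr[2] / sc, 1), 3, 3)
  conic(t(S) %*% En %*% S)
}
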