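#' @include AllClasses.R camera.R conics.R
NULL

#' Radial error of a back-projected outline ray
#'
#' The pixel is back-projected to a ray from the camera centre; the radial
#' error is the deviation of that ray from tangency to the sphere,
#' \eqn{| d(ray, centre) - r |} with \eqn{d} the perpendicular point-to-line
#' distance. A ray through the centre therefore scores \eqn{r}, and an exact
#' tangent ray scores 0. (Distance to the sphere surface as a point set
#' would be 0 for every secant ray and could not measure tangency.)
#'
#' @param outlinePoint length-2 pixel coordinates of an ellipse-outline point.
#' @param cam a [Camera-class].
#' @param marker a [SphereMarker-class] with centre in the world frame.
#' @return radial error in the units of the world frame (mm when metric).
#' @export
radialError <- function(outlinePoint, cam, marker) {
  cc <- applyTransform(cam@pose, marker@center)
  if (cc[3] <= 0) stop("marker behind camera")
  ray <- backprojectRay(cam, outlinePoint)
  v <- marker@center - ray$origin
  perp <- v - sum(v * ray$direction) * ray$direction
  abs(sqrt(sum(perp^2)) - marker@radius)
}

## distance from points (n x 2) to an ellipse given by conicParams-style list;
## foot-point (orthogonal) distance via robust bisection (Eberly).
pointEllipseDistance <- function(par, pts) {
  a <- par$semiAxes[1]; b <- par$semiAxes[2]
  ca <- cos(par$angle); sa <- sin(par$angle)
  d <- sweep(pts, 2, par$center)
  u0 <- abs(ca * d[, 1] + sa * d[, 2])
  v0 <- abs(-sa * d[, 1] + ca * d[, 2])
  n <- length(u0)
  out <- numeric(n)
  for (i in seq_len(n)) {
    u <- u0[i]; v <- v0[i]
    if (v > 1e-14 * b) {
      if (u > 1e-14 * a) {
        t0 <- -b^2 + b * v
        t1 <- -b^2 + sqrt(a^2 * u^2 + b^2 * v^2)
        for (k in 1:100) {
          t <- (t0 + t1) / 2
          Fv <- (a * u / (t + a^2))^2 + (b * v / (t + b^2))^2 - 1
          if (Fv > 0) t0 <- t else t1 <- t
          if (t1 - t0 < 1e-14 * (b^2 + t1)) break
        }
        t <- (t0 + t1) / 2
        x <- a^2 * u / (t + a^2); y <- b^2 * v / (t + b^2)
        out[i] <- sqrt((x - u)^2 + (y - v)^2)
      } else {
        out[i] <- abs(v - b)
      }
    } else {
      num <- a * u; den <- a^2 - b^2
      if (num < den) {
        z <- num / den
        out[i] <- sqrt((a * z - u)^2 + b^2 * (1 - z^2))
      } else {
        out[i] <- abs(u - a)
      }
    }
  }
  out
}

#' Geometric reprojection error between two ellipses
#'
#' Symmetric mean foot-point distance: \code{nSamples} points are sampled on
#' each ellipse, each point's orthogonal distance to the other ellipse is
#' computed, and the two directional means are averaged. Geometric (not
#' algebraic) distance is used so the result is in pixels.
#'
#' @param projected,detected [Conic-class] ellipses (e.g. the model
#'   projection under an estimated registration, and the detected ellipse).
#' @param nSamples points sampled per ellipse (default 200).
#' @return mean symmetric distance in pixels.
#' @export
reprojectionError <- function(projected, detected, nSamples = 200L) {
  pa <- conicParams(projected)
  pd <- conicParams(detected)
  d1 <- pointEllipseDistance(pd, sampleOutline(projected, nSamples))
  d2 <- pointEllipseDistance(pa, sampleOutline(detected, nSamples))
  (mean(d1) + mean(d2)) / 2
}

#' Area-uniform random samples on a mesh surface
#'
#' Triangles are drawn with probability proportional to area; points are
#' placed uniformly within each triangle.
#'
#' @param mesh a [SurfaceMesh-class] with at least one face.
#' @param n number of samples.
#' @return n x 3 matrix of surface points.
#' @export
sampleMeshPoints <- function(mesh, n) {
  F <- mesh@faces
  if (nrow(F) == 0) stop("mesh has no faces")
  V <- mesh@vertices
  A <- V[F[, 1], , drop = FALSE]
  e1 <- V[F[, 2], , drop = FALSE] - A
  e2 <- V[F[, 3], , drop = FALSE] - A
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- 0.5 * sqrt(rowSums(cr^2))
  f <- sample.int(nrow(F), n, replace = TRUE, prob = area)
  r1 <- sqrt(stats::runif(n)); r2 <- stats::runif(n)
  w1 <- 1 - r1; w2 <- r1 * (1 - r2); w3 <- r1 * r2
  A[f, , drop = FALSE] * w1 + (A + e1)[f, , drop = FALSE] * w2 +
    (A + e2)[f, , drop = FALSE] * w3
}

#' Chamfer distance between two surface meshes
#'
#' Samples \code{nSamples} points area-uniformly on each mesh and computes
#' the exact point-to-triangle nearest distance to the other mesh. Default
#' aggregation is the symmetric mean; median and RMS aggregation and
#' one-sided variants are available so other conventions can be matched.
#'
#' @param a,b [SurfaceMesh-class] objects in the same frame.
#' @param nSamples samples per mesh (default 1e5).
#' @param aggregate "mean" (default), "median" or "rms".
#' @param symmetric average both directions (default TRUE); otherwise only
#'   a-to-b.
#' @return distance in mm.
#' @export
chamferDistance <- function(a, b, nSamples = 1e5, aggregate = "mean",
                            symmetric = TRUE) {
  if (nrow(a@vertices) == 0 || nrow(b@vertices) == 0 ||
      nrow(a@faces) == 0 || nrow(b@faces) == 0)
    stop("chamferDistance requires non-empty triangulated meshes")
  if (a@frame != b@frame)
    stop("meshes are in different frames ('", a@frame, "' vs '", b@frame, "')")
  aggregate <- match.arg(aggregate, c("mean", "median", "rms"))
  agg <- switch(aggregate, mean = mean, median = stats::median,
                rms = function(v) sqrt(mean(v^2)))
  dab <- cpp_points_to_mesh_dist(sampleMeshPoints(a, nSamples),
                                 b@vertices, b@faces)
  if (!symmetric) return(agg(dab))
  dba <- cpp_points_to_mesh_dist(sampleMeshPoints(b, nSamples),
                                 a@vertices, a@faces)
  (agg(dab) + agg(dba)) / 2
}

#' Evaluate a registration with control markers
#'
#' Applies the estimated transform to the control-marker centres (markers
#' excluded from the registration itself) and computes the radial error of
#' every sampled outline ray in the control observations. In similarity
#' mode, errors are divided by the estimated scale so they are reported in
#' millimetres of the metric scan frame.
#'
#' @param result a [RegistrationResult-class].
#' @param controlObs an [ObservationSet-class] whose markers are the control
#'   markers, with centres in frame S.
#' @return A [RadialErrorReport-class]. The overall mean is the mean over
#'   points (equivalently the count-weighted mean of per-marker means);
#'   per-marker and per-image aggregations are also reported.
#' @export
evaluateRegistration <- function(result, controlObs) {
  if (length(controlObs@markers) == 0 || nrow(controlObs@entries) == 0)
    stop("empty control observation set")
  s <- result@scale
  markersW <- lapply(controlObs@markers, function(m)
    sphereMarker(applyTransform(result@transform, m@center), s * m@radius,
                 frame = result@transform@frameTo, label = m@label))
  e <- controlObs@entries
  err <- numeric(nrow(e))
  for (i in seq_len(nrow(e))) {
    err[i] <- radialError(c(e$x[i], e$y[i]), controlObs@cameras[[e$image[i]]],
                          markersW[[e$marker[i]]]) / s
  }
  perPoint <- data.frame(image = e$image, marker = e$marker, error_mm = err)
  aggBy <- function(key) {
    sp <- split(err, e[[key]])
    data.frame(key = names(sp), n = lengths(sp),
               mean_mm = vapply(sp, mean, 0),
               median_mm = vapply(sp, stats::median, 0), row.names = NULL)
  }
  pm <- aggBy("marker"); names(pm)[1] <- "marker"
  pi_ <- aggBy("image"); names(pi_)[1] <- "image"
  new("RadialErrorReport", perPoint = perPoint, perMarker = pm,
      perImage = pi_, meanMm = mean(err), medianMm = stats::median(err))
}

setMethod("show", "RadialErrorReport", function(object) {
  cat(sprintf(
    "RadialErrorReport: %d rays, %d markers, %d images\n",
    nrow(object@perPoint), nrow(object@perMarker), nrow(object@perImage)))
  cat(sprintf("  mean %.6g mm, median %.6g mm\n", object@meanMm,
              object@medianMm))
})
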