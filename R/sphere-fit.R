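#' @include AllClasses.R
NULL

#' Fit a fixed-radius sphere to mesh vertices
#'
#' Localizes one spherical marker in a scanned surface mesh. The radius is
#' known by construction (the markers are 3D printed), so only the centre is
#' estimated. Starting from a manual initialization, the fit alternates
#' (i) support selection -- vertices whose spherical distance residual
#' \eqn{| \|v - c\| - r |} is within \code{bandMm} -- with one pass of
#' 3-MAD trimming to reject fringe vertices at the sphere-mount junction,
#' and (ii) a Gauss-Newton update of the centre minimizing
#' \eqn{\sum (\|v - c\| - r)^2}. Iteration stops when the centre moves less
#' than 1e-6 mm, or after 100 iterations.
#'
#' @param mesh a [SurfaceMesh-class]; only its vertices are used.
#' @param radius known sphere radius (mm).
#' @param initCenter length-3 approximate centre (mm), expected within two
#'   radii of the true marker surface patch.
#' @param bandMm half-width of the support band around the sphere surface
#'   (mm); default 1.5 (10% of a 15 mm radius).
#' @return A [SphereFitResult-class].
#' @export
fitSphere <- function(mesh, radius, initCenter, bandMm = 1.5) {
  stopifnot(radius > 0, bandMm > 0, length(initCenter) == 3)
  V <- mesh@vertices
  c0 <- as.numeric(initCenter)
  niter <- 0L
  converged <- FALSE
  support <- integer()
  rmsHistory <- NULL
  for (it in seq_len(100L)) {
    niter <- it
    d <- sqrt(rowSums(sweep(V, 2, c0)^2))
    res <- d - radius
    support <- which(abs(res) <= bandMm)
    if (length(support) >= 20) {
      # one trimming pass: drop outliers beyond 3 * MAD of the band residuals
      m <- stats::median(res[support])
      s <- stats::mad(res[support])
      if (s > 0) support <- support[abs(res[support] - m) <= 3 * s]
    }
    if (length(support) < 10)
      stop("insufficient support: only ", length(support),
           " vertices within ", bandMm, " mm of the sphere surface")
    Vb <- V[support, , drop = FALSE]
    db <- d[support]
    rb <- res[support]
    # Gauss-Newton: residual f = |v - c| - r, df/dc = -(v - c)/|v - c|
    U <- sweep(Vb, 2, c0) / db          # unit vectors, J = -U
    JtJ <- crossprod(U)
    Jtf <- -as.numeric(crossprod(U, rb))
    step <- tryCatch(solve(JtJ, -Jtf), error = function(e)
      stop("degenerate support geometry in sphere fit"))
    c0 <- c0 + step
    dnew <- sqrt(rowSums(sweep(Vb, 2, c0)^2))
    rmsHistory <- rbind(rmsHistory,
                        c(before = sqrt(mean(rb^2)),
                          after = sqrt(mean((dnew - radius)^2))))
    if (sqrt(sum(step^2)) < 1e-6) { converged <- TRUE; break }
  }
  if (is.null(rmsHistory))
    rmsHistory <- matrix(numeric(), 0, 2,
                         dimnames = list(NULL, c("before", "after")))
  d <- sqrt(rowSums(sweep(V[support, , drop = FALSE], 2, c0)^2))
  new("SphereFitResult",
      marker = sphereMarker(c0, radius, frame = mesh@frame),
      rmsResidualMm = sqrt(mean((d - radius)^2)),
      nSupportVertices = length(support),
      converged = converged, nIterations = niter, rmsHistory = rmsHistory)
}

#' Localize all spherical markers in a mesh
#'
#' Runs [fitSphere()] once per approximate centre. Initial centres must be
#' pairwise separated by more than one marker diameter, so that no two
#' initializations can capture the same sphere.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param radius common marker radius (mm).
#' @param initCenters k x 3 matrix (or list of 3-vectors) of approximate
#'   centres; row names (or list names) become marker labels.
#' @param bandMm support band half-width, see [fitSphere()].
#' @return list with \code{markers} (list of [SphereMarker-class], ordered as
#'   the inits; failed fits are NULL), \code{fits} (list of
#'   [SphereFitResult-class] or condition objects) and \code{failures}
#'   (character labels of failed fits).
#' @export
localizeMarkers <- function(mesh, radius, initCenters, bandMm = 1.5) {
  if (is.list(initCenters) && !is.data.frame(initCenters))
    initCenters <- do.call(rbind, initCenters)
  initCenters <- as.matrix(initCenters)
  if (nrow(initCenters) == 0)
    return(list(markers = list(), fits = list(), failures = character()))
  stopifnot(ncol(initCenters) == 3)
  labels <- rownames(initCenters)
  if (is.null(labels)) labels <- sprintf("m%02d", seq_len(nrow(initCenters)))
  if (nrow(initCenters) > 1) {
    dd <- as.matrix(stats::dist(initCenters))
    diag(dd) <- Inf
    if (min(dd) <= 2 * radius)
      stop("initial centres must be pairwise separated by more than one ",
           "marker diameter (min separation ", format(min(dd)), " mm)")
  }
  markers <- vector("list", nrow(initCenters))
  fits <- vector("list", nrow(initCenters))
  failures <- character()
  for (i in seq_len(nrow(initCenters))) {
    fit <- tryCatch(
      fitSphere(mesh, radius, initCenters[i, ], bandMm = bandMm),
      error = function(e) e)
    fits[[i]] <- fit
    if (inherits(fit, "error")) {
      failures <- c(failures, labels[i])
      markers[i] <- list(NULL)
    } else {
      m <- fit@marker
      m@label <- labels[i]
      markers[[i]] <- m
    }
  }
  names(markers) <- labels
  names(fits) <- labels
  list(markers = markers, fits = fits, failures = failures)
}

setMethod("show", "SphereFitResult", function(object) {
  cat(sprintf(
    "SphereFitResult: centre (%.4f, %.4f, %.4f) mm, r = %.2f mm\n",
    object@marker@center[1], object@marker@center[2],
    object@marker@center[3], object@marker@radius))
  cat(sprintf("  rms residual %.5f mm over %d support vertices (%s, %d iter)\n",
              object@rmsResidualMm, object@nSupportVertices,
              if (object@converged) "converged" else "not converged",
              object@nIterations))
})
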