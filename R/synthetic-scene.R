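#' @include AllClasses.R conics.R
NULL

#' Triangulated UV-sphere mesh
#'
#' @param center length-3 centre (mm).
#' @param radius radius (mm).
#' @param nRings latitude rings between the poles (default 24).
#' @param nSegments longitude segments (default 48).
#' @param frame frame label.
#' @return A [SurfaceMesh-class] closed sphere mesh.
#' @export
sphereMesh <- function(center, radius, nRings = 24, nSegments = 48,
                       frame = "S") {
  th <- pi * seq_len(nRings) / (nRings + 1)       # polar angle, poles excluded
  ph <- 2 * pi * (seq_len(nSegments) - 1) / nSegments
  grid <- expand.grid(seg = seq_len(nSegments), ring = seq_len(nRings))
  st <- sin(th[grid$ring]); ct <- cos(th[grid$ring])
  V <- cbind(st * cos(ph[grid$seg]), st * sin(ph[grid$seg]), ct)
  V <- rbind(V, c(0, 0, 1), c(0, 0, -1))
  npole <- nrow(V) - 1L; spole <- nrow(V)
  idx <- function(ring, seg) (ring - 1L) * nSegments + ((seg - 1L) %% nSegments) + 1L
  F <- list()
  segs <- seq_len(nSegments)
  # pole caps
  F[[1]] <- cbind(npole, idx(1L, segs), idx(1L, segs + 1L))
  F[[2]] <- cbind(spole, idx(nRings, segs + 1L), idx(nRings, segs))
  # quads between rings
  for (r in seq_len(nRings - 1L)) {
    a <- idx(r, segs); b <- idx(r, segs + 1L)
    c2 <- idx(r + 1L, segs); d <- idx(r + 1L, segs + 1L)
    F[[length(F) + 1L]] <- cbind(a, c2, d)
    F[[length(F) + 1L]] <- cbind(a, d, b)
  }
  F <- do.call(rbind, F)
  surfaceMesh(sweep(V * radius, 2, center, "+"), F, frame = frame)
}

## ellipsoid by anisotropic scaling of a unit UV sphere
ellipsoidMesh <- function(center, semiAxes, nRings = 16, nSegments = 32,
                          frame = "S") {
  m <- sphereMesh(c(0, 0, 0), 1, nRings, nSegments, frame)
  surfaceMesh(sweep(m@vertices %*% diag(semiAxes), 2, center, "+"),
              m@faces, frame = frame)
}

## concatenate meshes (same frame)
mergeMeshes <- function(meshes) {
  off <- 0L
  V <- list(); F <- list()
  for (m in meshes) {
    V[[length(V) + 1L]] <- m@vertices
    if (nrow(m@faces)) F[[length(F) + 1L]] <- m@faces + off
    off <- off + nrow(m@vertices)
  }
  surfaceMesh(do.call(rbind, V),
              if (length(F)) do.call(rbind, F) else matrix(integer(), 0, 3),
              frame = meshes[[1]]@frame)
}

#' Area-uniform random samples on a sphere surface
#'
#' Stand-in for optical-scan point samples of a marker: uniform directions,
#' optionally restricted to the upper (+z) hemisphere as seen by a one-sided
#' scanner, with isotropic Gaussian radial noise on each coordinate.
#'
#' @param center length-3 centre (mm).
#' @param radius radius (mm).
#' @param n number of samples.
#' @param sigmaMm per-coordinate Gaussian noise (mm), default 0.
#' @param hemisphere keep only the +z hemisphere (default FALSE).
#' @return n x 3 matrix of points (mm).
#' @export
sampleSphereSurface <- function(center, radius, n, sigmaMm = 0,
                                hemisphere = FALSE) {
  U <- matrix(stats::rnorm(3 * n), n, 3)
  if (hemisphere) U[, 3] <- abs(U[, 3])
  U <- U / sqrt(rowSums(U^2))
  P <- sweep(U * radius, 2, center, "+")
  if (sigmaMm > 0) P <- P + matrix(stats::rnorm(3 * n, sd = sigmaMm), n, 3)
  P
}

#' Synthetic-scene configuration
#'
#' Defines a fully specified virtual scene: M spherical registration markers
#' of known radius placed in the scan frame S, optional control markers near
#' the scene centre, N calibrated viewpoints in the world frame W, and the
#' noise levels of the simulated measurements. The defaults reproduce the
#' evaluation conditions of the physical rig the simulator emulates:
#' M = 10 registration markers of 30 mm diameter on a ring around the
#' specimen, N = 16 viewpoints at roughly 1 m, and a full-resolution
#' 9504 x 6336 px sensor whose focal length (7000 px) makes a 30 mm marker
#' at 1 m span about 200 px.
#'
#' @param M registration marker count (default 10).
#' @param markerRadius marker radius in mm (default 15, i.e. 30 mm diameter).
#' @param markerLayout "ring" (default) or "board" (grid on a plate).
#' @param layoutExtent ring radius or board half-width (mm, default 250).
#' @param nControl control markers near the scene centre (default 3),
#'   excluded from registration and used only for evaluation.
#' @param N camera count (default 16).
#' @param cameraDistance camera distance from the scene centre (mm,
#'   default 1000).
#' @param intrinsics "fullres" (9504 x 6336 px, f = 7000 px, default) or
#'   "desk" (1920 x 1080 px, f = 1400 px) or a named list with fx, fy, cx,
#'   cy, width, height.
#' @param L outline samples per ellipse (default 20).
#' @param outlineNoisePx isotropic Gaussian pixel noise on outline points
#'   (default 0).
#' @param meshNoiseMm Gaussian vertex noise of the simulated scan (default
#'   0.05, the point accuracy of a handheld structured-light scanner).
#' @param meshCoverage "full" or "hemisphere" (scanner sees one side).
#' @param trueTransform ground-truth S-to-W [RigidTransform-class], or NULL
#'   to draw one (uniform random rotation, translation within +/- 100 mm).
#' @param trueScale ground-truth scale of the S-to-W map (default 1; values
#'   other than 1 emulate structure-from-motion worlds that are metric only
#'   up to scale).
#' @param seed integer seed driving every random draw.
#' @return A validated config list of class \code{"SceneConfig"}.
#' @export
sceneConfig <- function(M = 10, markerRadius = 15, markerLayout = "ring",
                        layoutExtent = 250, nControl = 3, N = 16,
                        cameraDistance = 1000, intrinsics = "fullres",
                        L = 20, outlineNoisePx = 0, meshNoiseMm = 0.05,
                        meshCoverage = "full", trueTransform = NULL,
                        trueScale = 1, seed = 1L) {
  if (is.character(intrinsics)) {
    intrinsics <- switch(match.arg(intrinsics, c("fullres", "desk")),
      fullres = list(fx = 7000, fy = 7000, cx = 4752, cy = 3168,
                     width = 9504, height = 6336),
      desk = list(fx = 1400, fy = 1400, cx = 960, cy = 540,
                  width = 1920, height = 1080))
  }
  cfg <- list(M = as.integer(M), markerRadius = markerRadius,
              markerLayout = match.arg(markerLayout, c("ring", "board")),
              layoutExtent = layoutExtent, nControl = as.integer(nControl),
              N = as.integer(N), cameraDistance = cameraDistance,
              intrinsics = intrinsics, L = as.integer(L),
              outlineNoisePx = outlineNoisePx, meshNoiseMm = meshNoiseMm,
              meshCoverage = match.arg(meshCoverage, c("full", "hemisphere")),
              trueTransform = trueTransform, trueScale = trueScale,
              seed = as.integer(seed))
  stopifnot(cfg$M >= 1, cfg$N >= 1, cfg$markerRadius > 0, cfg$L >= 4,
            cfg$outlineNoisePx >= 0, cfg$meshNoiseMm >= 0, cfg$trueScale > 0)
  class(cfg) <- "SceneConfig"
  cfg
}

## Marker centres in frame S per layout. Placement is jittered (seeded by the
## caller): physical markers are affixed by hand, and an exactly regular
## arrangement would be rotationally symmetric, making the correspondence
## between indistinguishable markers genuinely ambiguous.
markerLayoutCenters <- function(cfg) {
  M <- cfg$M
  if (cfg$markerLayout == "ring") {
    ang <- 2 * pi * (seq_len(M) - 1) / M +
      stats::runif(M, -0.3, 0.3) * 2 * pi / M
    rad <- cfg$layoutExtent * stats::runif(M, 0.85, 1.15)
    cbind(rad * cos(ang), rad * sin(ang), stats::runif(M, -15, 15))
  } else {
    k <- ceiling(sqrt(M))
    g <- expand.grid(x = seq_len(k), y = seq_len(k))[seq_len(M), ]
    s <- if (k > 1) 2 * cfg$layoutExtent / (k - 1) else 0
    jit <- if (k > 1) s * 0.15 else 10
    cbind(-cfg$layoutExtent + (g$x - 1) * s + stats::runif(M, -jit, jit),
          -cfg$layoutExtent + (g$y - 1) * s + stats::runif(M, -jit, jit),
          stats::runif(M, -15, 15))
  }
}

## world-to-camera pose for a camera at p looking at target
lookAtPose <- function(p, target, id = "cam") {
  z <- target - p; z <- z / sqrt(sum(z^2))
  up <- c(0, 0, 1)
  if (abs(sum(z * up)) > 0.99) up <- c(0, 1, 0)
  x <- c(z[2] * up[3] - z[3] * up[2], z[3] * up[1] - z[1] * up[3],
         z[1] * up[2] - z[2] * up[1])
  x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  R <- rbind(x, y, z); dimnames(R) <- NULL
  rigidTransform(R, -as.numeric(R %*% p), frameFrom = "W", frameTo = "C")
}

## exact observation entries for a set of markers seen by a set of cameras;
## also verifies that every silhouette lies fully inside every image
observeMarkers <- function(markersW, cameras, L) {
  rows <- vector("list", length(cameras) * length(markersW))
  k <- 0L
  for (cam in cameras) {
    for (m in markersW) {
      pts <- sampleOutline(projectSphere(m, cam), L)
      if (any(pts[, 1] < 0 | pts[, 1] > cam@width - 1 |
              pts[, 2] < 0 | pts[, 2] > cam@height - 1))
        stop("layout error: marker ", m@label, " not fully visible in image ",
             cam@id)
      k <- k + 1L
      rows[[k]] <- list(image = cam@id, marker = m@label, pts = pts)
    }
  }
  data.frame(
    image = rep(vapply(rows, `[[`, "", "image"), each = L),
    marker = rep(vapply(rows, `[[`, "", "marker"), each = L),
    x = unlist(lapply(rows, function(r) r$pts[, 1]), use.names = FALSE),
    y = unlist(lapply(rows, function(r) r$pts[, 2]), use.names = FALSE))
}

## add isotropic Gaussian pixel noise to observation entries
perturbEntries <- function(entries, noisePx) {
  if (noisePx > 0) {
    n <- nrow(entries)
    entries$x <- entries$x + stats::rnorm(n, sd = noisePx)
    entries$y <- entries$y + stats::rnorm(n, sd = noisePx)
  }
  entries
}

#' Generate a fully specified synthetic scene
#'
#' Builds markers, cameras, exact and noisy observation sets, a simulated
#' scan mesh, and the ground-truth transform, so that every stage of the
#' registration pipeline can be validated against known truth. All
#' randomness is driven by \code{cfg$seed}: the same config yields identical
#' output.
#'
#' @param cfg a [sceneConfig()] object.
#' @return list with elements \code{markersS} (registration markers, frame
#'   S), \code{controlMarkersS}, \code{cameras}, \code{exactObs} /
#'   \code{noisyObs} ([ObservationSet-class] of registration markers),
#'   \code{exactControlObs} / \code{noisyControlObs}, \code{mesh}
#'   (simulated scan, frame S), \code{truth} (list: \code{transform},
#'   \code{scale}) and \code{config}.
#' @export
generateScene <- function(cfg) {
  stopifnot(inherits(cfg, "SceneConfig"))
  set.seed(cfg$seed)
  intr <- cfg$intrinsics

  centersS <- markerLayoutCenters(cfg)
  markersS <- lapply(seq_len(cfg$M), function(i)
    sphereMarker(centersS[i, ], cfg$markerRadius, frame = "S",
                 label = sprintf("m%02d", i)))
  names(markersS) <- vapply(markersS, function(m) m@label, "")
  ctrlS <- list()
  if (cfg$nControl > 0) {
    ang <- 2 * pi * (seq_len(cfg$nControl) - 1) / cfg$nControl + 0.35
    rad <- cfg$layoutExtent * 0.35
    ctrlS <- lapply(seq_len(cfg$nControl), function(i)
      sphereMarker(c(rad * cos(ang[i]), rad * sin(ang[i]),
                     25 + 10 * (i %% 2)), cfg$markerRadius, frame = "S",
                   label = sprintf("c%02d", i)))
    names(ctrlS) <- vapply(ctrlS, function(m) m@label, "")
  }

  Tsw <- cfg$trueTransform
  if (is.null(Tsw)) {
    Tsw <- rigidTransform(randomRotation(), stats::runif(3, -100, 100),
                          frameFrom = "S", frameTo = "W")
  }
  truth <- rigidTransform(Tsw@rotation, Tsw@translation, scale = cfg$trueScale,
                          frameFrom = "S", frameTo = "W")

  toW <- function(m) sphereMarker(applyTransform(truth, m@center),
                                  cfg$trueScale * m@radius, frame = "W",
                                  label = m@label)
  markersW <- lapply(markersS, toW)
  ctrlW <- lapply(ctrlS, toW)

  sceneCenterW <- applyTransform(truth, c(0, 0, 0))
  d <- cfg$cameraDistance * cfg$trueScale
  # two arcs on opposite sides, alternating elevation: emulates capture from
  # two robot positions across the table
  az <- rep(c(0, pi), length.out = cfg$N) +
    (seq_len(cfg$N) - 1) %/% 2 * (2 * pi / cfg$N) - pi / 3
  el <- rep(c(0.7, 0.95), length.out = cfg$N)
  cameras <- lapply(seq_len(cfg$N), function(i) {
    p <- sceneCenterW + d * c(cos(el[i]) * cos(az[i]),
                              cos(el[i]) * sin(az[i]), sin(el[i]))
    camera(intr$fx, intr$fy, intr$cx, intr$cy, intr$width, intr$height,
           pose = lookAtPose(p, sceneCenterW), id = sprintf("img%03d", i))
  })
  names(cameras) <- vapply(cameras, function(c) c@id, "")

  exactEntries <- observeMarkers(markersW, cameras, cfg$L)
  exactObs <- observationSet(cameras, markersS, exactEntries)
  noisyObs <- observationSet(cameras, markersS,
                             perturbEntries(exactEntries, cfg$outlineNoisePx))
  exactCtrl <- NULL; noisyCtrl <- NULL
  if (cfg$nControl >= 3) {
    ctrlEntries <- observeMarkers(ctrlW, cameras, cfg$L)
    exactCtrl <- observationSet(cameras, ctrlS, ctrlEntries)
    noisyCtrl <- observationSet(cameras, ctrlS,
                                perturbEntries(ctrlEntries,
                                               cfg$outlineNoisePx))
  }

  # simulated scan mesh in frame S: marker spheres + an ellipsoidal anatomy
  # blob, with vertex noise; hemisphere coverage keeps the upper (+z) half
  parts <- lapply(c(markersS, ctrlS), function(m)
    sphereMesh(m@center, m@radius, frame = "S"))
  parts[[length(parts) + 1L]] <-
    ellipsoidMesh(c(0, 0, 0), c(cfg$layoutExtent * 0.55,
                                cfg$layoutExtent * 0.3, 35), frame = "S")
  mesh <- mergeMeshes(parts)
  if (cfg$meshCoverage == "hemisphere") {
    keep <- which(mesh@vertices[, 3] >= -1e-9)
    remap <- integer(nrow(mesh@vertices)); remap[keep] <- seq_along(keep)
    F <- mesh@faces
    ok <- rowSums(matrix(F %in% keep, nrow(F), 3)) == 3
    mesh <- surfaceMesh(mesh@vertices[keep, , drop = FALSE],
                        matrix(remap[F[ok, ]], ncol = 3), frame = "S")
  }
  if (cfg$meshNoiseMm > 0)
    mesh@vertices <- mesh@vertices +
      matrix(stats::rnorm(length(mesh@vertices), sd = cfg$meshNoiseMm),
             nrow(mesh@vertices), 3)

  list(markersS = markersS, controlMarkersS = ctrlS, cameras = cameras,
       exactObs = exactObs, noisyObs = noisyObs,
       exactControlObs = exactCtrl, noisyControlObs = noisyCtrl,
       mesh = mesh, truth = list(transform = truth, scale = cfg$trueScale),
       config = cfg)
}
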