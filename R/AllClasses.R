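#' RigidTransform: a rigid or similarity map between coordinate frames
#'
#' Represents the map \eqn{x' = s R x + t} taking points in frame
#' \code{frameFrom} to frame \code{frameTo}. Scale is 1 for a strictly rigid
#' (Euclidean) transform; similarity transforms (scale jointly estimated, as
#' when camera poses come from structure-from-motion and are metric only up to
#' scale) carry \code{scale != 1}. Translations are in millimetres whenever
#' the frame is metric.
#'
#' @slot rotation 3x3 orthonormal matrix, det +1.
#' @slot translation numeric length-3, millimetres in metric frames.
#' @slot scale positive scalar, 1 for rigid transforms.
#' @slot frameFrom,frameTo frame labels (e.g. "S" scan-local, "W" world,
#'   "C" camera, "B" robot base, "EE" end-effector).
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric",
                 scale = "numeric", frameFrom = "character",
                 frameTo = "character"),
  validity = function(object) {
    msg <- character()
    R <- object@rotation
    if (!all(dim(R) == c(3, 3))) msg <- c(msg, "rotation must be 3x3")
    else {
      if (max(abs(crossprod(R) - diag(3))) > 1e-9)
        msg <- c(msg, "rotation is not orthonormal (|R'R - I| > 1e-9)")
      if (abs(det(R) - 1) > 1e-9)
        msg <- c(msg, "rotation must have determinant +1")
    }
    if (length(object@translation) != 3 || anyNA(object@translation))
      msg <- c(msg, "translation must be a finite 3-vector")
    if (length(object@scale) != 1 || !is.finite(object@scale) ||
        object@scale <= 0)
      msg <- c(msg, "scale must be a positive scalar")
    if (length(msg)) msg else TRUE
  })

#' Construct a RigidTransform
#'
#' @param rotation 3x3 rotation matrix (default identity).
#' @param translation length-3 translation vector (default zero).
#' @param scale positive scalar (default 1, i.e. rigid).
#' @param frameFrom,frameTo frame labels.
#' @return A [RigidTransform-class] object.
#' @examples
#' Tsw <- rigidTransform(rotationFromAxisAngle(c(0, 0, pi / 2)),
#'                       c(100, 0, 0), frameFrom = "S", frameTo = "W")
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0),
                           scale = 1, frameFrom = "A", frameTo = "B") {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation), scale = as.numeric(scale),
      frameFrom = frameFrom, frameTo = frameTo)
}

#' Camera: pinhole intrinsics plus a world-to-camera pose
#'
#' The model is an undistorted pinhole: a world point \eqn{X_W} maps to the
#' camera frame by the pose (world-to-camera) and then through
#' \eqn{K = [[fx, 0, cx], [0, fy, cy], [0, 0, 1]]}. Pixel coordinates are
#' 0-based, x right / y down, origin at the centre of the top-left pixel.
#' Lens distortion is assumed removed upstream.
#'
#' @slot fx,fy focal lengths in pixels.
#' @slot cx,cy principal point in pixels.
#' @slot width,height image size in pixels.
#' @slot pose [RigidTransform-class] mapping world frame to camera frame.
#' @slot id image/camera identifier.
#' @export
setClass("Camera",
  representation(fx = "numeric", fy = "numeric", cx = "numeric",
                 cy = "numeric", width = "numeric", height = "numeric",
                 pose = "RigidTransform", id = "character"),
  validity = function(object) {
    msg <- character()
    if (object@fx <= 0 || object@fy <= 0)
      msg <- c(msg, "focal lengths must be positive")
    if (object@cx < 0 || object@cx >= object@width)
      msg <- c(msg, "cx must lie in [0, width)")
    if (object@cy < 0 || object@cy >= object@height)
      msg <- c(msg, "cy must lie in [0, height)")
    if (object@pose@scale != 1)
      msg <- c(msg, "camera pose must be strictly rigid (scale 1)")
    if (length(msg)) msg else TRUE
  })

#' Construct a Camera
#'
#' @param fx,fy focal lengths (px).
#' @param cx,cy principal point (px).
#' @param width,height image size (px).
#' @param pose world-to-camera [RigidTransform-class].
#' @param id identifier string.
#' @return A [Camera-class] object.
#' @export
camera <- function(fx, fy, cx, cy, width, height,
                   pose = rigidTransform(frameFrom = "W", frameTo = "C"),
                   id = "cam") {
  new("Camera", fx = fx, fy = fy, cx = cx, cy = cy,
      width = width, height = height, pose = pose, id = id)
}

#' SphereMarker: a spherical fiducial of known radius
#'
#' 3D-printed spheres of precisely known radius are rigidly fixed around the
#' scene; their centres, expressed either in the scan-local frame S or the
#' camera world frame W, anchor the scene registration.
#'
#' @slot center length-3 centre (mm), in the frame named by \code{frame}.
#' @slot radius sphere radius (mm), positive.
#' @slot frame frame label of the centre.
#' @slot label marker identifier.
#' @export
setClass("SphereMarker",
  representation(center = "numeric", radius = "numeric", frame = "character",
                 label = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@center) != 3 || anyNA(object@center))
      msg <- c(msg, "center must be a finite 3-vector")
    if (object@radius <= 0) msg <- c(msg, "radius must be positive")
    if (length(msg)) msg else TRUE
  })

#' Construct a SphereMarker
#' @param center length-3 centre (mm).
#' @param radius radius (mm).
#' @param frame frame label (default "S").
#' @param label marker identifier.
#' @return A [SphereMarker-class] object.
#' @export
sphereMarker <- function(center, radius, frame = "S", label = "m") {
  new("SphereMarker", center = as.numeric(center), radius = radius,
      frame = frame, label = label)
}

#' Conic: a normalized 3x3 symmetric conic matrix
#'
#' Points \eqn{x} (homogeneous pixel coordinates) on the conic satisfy
#' \eqn{x^T E x = 0}. Conics are scale-equivalence classes; the stored matrix
#' is normalized to unit Frobenius norm with positive trace of the upper-left
#' 2x2 block, so that bilinear residuals \eqn{x^T E x} are comparable across
#' markers and images.
#'
#' @slot matrix normalized 3x3 symmetric matrix.
#' @export
setClass("Conic",
  representation(matrix = "matrix"),
  validity = function(object) {
    E <- object@matrix
    msg <- character()
    if (!all(dim(E) == c(3, 3))) msg <- c(msg, "conic matrix must be 3x3")
    else {
      if (max(abs(E - t(E))) > 1e-12)
        msg <- c(msg, "conic matrix must be symmetric")
      if (abs(sqrt(sum(E^2)) - 1) > 1e-9)
        msg <- c(msg, "conic matrix must have unit Frobenius norm")
      if (E[1, 1] + E[2, 2] < 0)
        msg <- c(msg, "upper-left 2x2 trace must be non-negative")
    }
    if (length(msg)) msg else TRUE
  })

## normalize an arbitrary conic matrix to the package convention
normalizeConicMatrix <- function(E) {
  E <- (E + t(E)) / 2
  n <- sqrt(sum(E^2))
  if (!is.finite(n) || n == 0) stop("degenerate conic: zero matrix")
  E <- E / n
  if (E[1, 1] + E[2, 2] < 0) E <- -E
  E
}

#' Construct a Conic from any matrix representative
#'
#' The input is symmetrized and normalized (unit Frobenius norm, positive
#' upper-left 2x2 trace).
#'
#' @param E 3x3 matrix representative of the conic.
#' @return A [Conic-class] object.
#' @export
conic <- function(E) new("Conic", matrix = normalizeConicMatrix(E))

#' SurfaceMesh: a triangulated surface in a labelled frame
#'
#' Vertex coordinates are in millimetres. A mesh with zero faces is permitted
#' and treated as a point cloud (e.g. raw scan samples); operations that need
#' surface area (Chamfer distance) require faces.
#'
#' @slot vertices n x 3 numeric matrix (mm).
#' @slot faces m x 3 integer matrix of 1-based vertex indices (0 rows allowed).
#' @slot frame frame label ("S" for scan-local).
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", faces = "matrix", frame = "character"),
  validity = function(object) {
    msg <- character()
    V <- object@vertices; F <- object@faces
    if (ncol(V) != 3) msg <- c(msg, "vertices must be n x 3")
    if (anyNA(V) || any(!is.finite(V)))
      msg <- c(msg, "vertices must be finite (no NaN)")
    if (ncol(F) != 3) msg <- c(msg, "faces must be m x 3")
    else if (nrow(F) > 0 && (min(F) < 1 || max(F) > nrow(V)))
      msg <- c(msg, "face indices out of range")
    if (length(msg)) msg else TRUE
  })

#' Construct a SurfaceMesh
#' @param vertices n x 3 matrix of vertex positions (mm).
#' @param faces m x 3 matrix of 1-based triangle indices; may have 0 rows.
#' @param frame frame label.
#' @return A [SurfaceMesh-class] object.
#' @export
surfaceMesh <- function(vertices, faces = matrix(integer(), 0, 3),
                        frame = "S") {
  storage.mode(faces) <- "integer"
  vertices <- as.matrix(vertices)
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  new("SurfaceMesh", vertices = vertices, faces = faces, frame = frame)
}

#' ObservationSet: outline points per (image, marker) pair
#'
#' Holds the sampled ellipse-outline points \eqn{x_{ijl}} that drive the
#' registration objective, together with the cameras (one per image) and the
#' markers (centres in frame S). Pairs may be missing (sparse visibility);
#' every present pair carries at least 5 outline points (an ellipse has five
#' degrees of freedom).
#'
#' @slot cameras named list of [Camera-class].
#' @slot markers named list of [SphereMarker-class] (frame S).
#' @slot entries data.frame with columns \code{image}, \code{marker},
#'   \code{x}, \code{y}: one row per outline point.
#' @export
setClass("ObservationSet",
  representation(cameras = "list", markers = "list", entries = "data.frame"),
  validity = function(object) {
    msg <- character()
    e <- object@entries
    need <- c("image", "marker", "x", "y")
    if (!all(need %in% names(e)))
      return("entries must have columns image, marker, x, y")
    if (length(object@cameras) < 1) msg <- c(msg, "at least 1 camera required")
    if (nrow(e) > 0) {
      cnt <- table(paste(e$image, e$marker, sep = "\r"))
      if (any(cnt < 5))
        msg <- c(msg, "every (image, marker) pair needs >= 5 outline points")
      if (length(unique(e$marker)) < 3)
        msg <- c(msg, "at least 3 distinct markers must be observed")
      if (!all(e$image %in% names(object@cameras)))
        msg <- c(msg, "entries reference unknown image ids")
      if (!all(e$marker %in% names(object@markers)))
        msg <- c(msg, "entries reference unknown marker labels")
    } else msg <- c(msg, "entries must be non-empty")
    if (length(msg)) msg else TRUE
  })

#' Construct an ObservationSet
#' @param cameras named list of [Camera-class] (names are image ids).
#' @param markers named list of [SphereMarker-class] (names are labels).
#' @param entries data.frame with columns image, marker, x, y.
#' @return An [ObservationSet-class] object.
#' @export
observationSet <- function(cameras, markers, entries) {
  if (is.null(names(cameras)))
    names(cameras) <- vapply(cameras, function(c) c@id, "")
  if (is.null(names(markers)))
    names(markers) <- vapply(markers, function(m) m@label, "")
  new("ObservationSet", cameras = cameras, markers = markers,
      entries = entries)
}

#' SphereFitResult: outcome of a fixed-radius sphere fit
#'
#' @slot marker the fitted [SphereMarker-class] (frame S).
#' @slot rmsResidualMm RMS of the spherical distance residual (mm).
#' @slot nSupportVertices number of mesh vertices in the final support band.
#' @slot converged logical.
#' @slot nIterations iterations used.
#' @slot rmsHistory two-column matrix (before, after): RMS residual on each
#'   iteration's support band before and after the centre update.
#' @export
setClass("SphereFitResult",
  representation(marker = "SphereMarker", rmsResidualMm = "numeric",
                 nSupportVertices = "integer", converged = "logical",
                 nIterations = "integer", rmsHistory = "matrix"),
  validity = function(object) {
    msg <- character()
    if (object@rmsResidualMm < 0) msg <- c(msg, "rmsResidualMm must be >= 0")
    if (object@nSupportVertices < 10)
      msg <- c(msg, "a valid fit needs >= 10 support vertices")
    if (length(msg)) msg else TRUE
  })

#' RegistrationResult: estimated scene-to-world transform and diagnostics
#'
#' @slot transform [RigidTransform-class] mapping S to W (scale slot carries
#'   the jointly estimated scale in similarity mode, 1 in rigid mode).
#' @slot scale estimated scale (1 in rigid mode).
#' @slot finalCost final value of the summed squared bilinear residual.
#' @slot initialCost cost at the initial estimate.
#' @slot perImageRms named numeric: RMS bilinear residual per image.
#' @slot nIterations LM iterations.
#' @slot converged logical.
#' @export
setClass("RegistrationResult",
  representation(transform = "RigidTransform", scale = "numeric",
                 finalCost = "numeric", initialCost = "numeric",
                 perImageRms = "numeric", nIterations = "integer",
                 converged = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@finalCost < 0) msg <- c(msg, "finalCost must be >= 0")
    if (object@finalCost > object@initialCost * (1 + 1e-12) + 1e-300)
      msg <- c(msg, "finalCost must not exceed initialCost")
    if (length(msg)) msg else TRUE
  })

#' EllipseDetection: one detected elliptical marker projection
#'
#' @slot conic fitted [Conic-class].
#' @slot outlinePoints k x 2 matrix of sub-pixel boundary points (px).
#' @slot supportPixelCount pixels in the connected component.
#' @slot imageId image identifier.
#' @slot markerLabel assigned marker label ("" until matched).
#' @export
setClass("EllipseDetection",
  representation(conic = "Conic", outlinePoints = "matrix",
                 supportPixelCount = "integer", imageId = "character",
                 markerLabel = "character"))

#' RadialErrorReport: aggregated radial registration errors
#'
#' Radial error is the deviation from tangency of a back-projected
#' outline ray with respect to the 3D sphere surface, in millimetres.
#'
#' @slot perPoint data.frame with columns image, marker, error_mm.
#' @slot perMarker data.frame with columns marker, n, mean_mm, median_mm.
#' @slot perImage data.frame with columns image, n, mean_mm, median_mm.
#' @slot meanMm overall mean over points.
#' @slot medianMm overall median over points.
#' @export
setClass("RadialErrorReport",
  representation(perPoint = "data.frame", perMarker = "data.frame",
                 perImage = "data.frame", meanMm = "numeric",
                 medianMm = "numeric"))
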