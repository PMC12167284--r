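#' @include AllClasses.R camera.R
NULL

## strip comments and blank lines from a COLMAP text file
colmapLines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

#' Read cameras from a COLMAP text model
#'
#' Parses \code{cameras.txt} (intrinsics) and \code{images.txt} (extrinsics)
#' in the COLMAP text-model dialect. Only the distortion-free PINHOLE and
#' SIMPLE_PINHOLE camera models are accepted; any other model is rejected by
#' name. Extrinsics are world-to-camera, quaternion scalar-first -- stored
#' unchanged in the returned [Camera-class] poses. Image names become camera
#' ids (falling back to image ids).
#'
#' @param camerasFile path to \code{cameras.txt}.
#' @param imagesFile path to \code{images.txt}.
#' @return named list of [Camera-class].
#' @export
readColmapPoses <- function(camerasFile, imagesFile) {
  cl <- colmapLines(camerasFile)
  intr <- list()
  for (i in seq_along(cl$lines)) {
    tk <- strsplit(trimws(cl$lines[i]), "\\s+")[[1]]
    if (length(tk) < 5)
      stop("malformed camera line ", cl$lineno[i], " in ", camerasFile)
    model <- tk[2]
    w <- as.numeric(tk[3]); h <- as.numeric(tk[4])
    par <- as.numeric(tk[-(1:4)])
    k <- switch(model,
      PINHOLE = {
        if (length(par) != 4)
          stop("malformed PINHOLE parameters at line ", cl$lineno[i])
        list(fx = par[1], fy = par[2], cx = par[3], cy = par[4])
      },
      SIMPLE_PINHOLE = {
        if (length(par) != 3)
          stop("malformed SIMPLE_PINHOLE parameters at line ", cl$lineno[i])
        list(fx = par[1], fy = par[1], cx = par[2], cy = par[3])
      },
      stop("unsupported camera model '", model,
           "' (only PINHOLE and SIMPLE_PINHOLE are supported)"))
    k$width <- w; k$height <- h
    intr[[tk[1]]] <- k
  }
  # images.txt alternates pose lines with (possibly empty) 2D-point lines;
  # keep blank lines so the pairing stays aligned, but skip leading ones
  rawLines <- readLines(imagesFile, warn = FALSE)
  keep <- !grepl("^\\s*#", rawLines)
  il <- list(lines = rawLines[keep], lineno = which(keep))
  while (length(il$lines) && !nzchar(trimws(il$lines[1]))) {
    il$lines <- il$lines[-1]; il$lineno <- il$lineno[-1]
  }
  cams <- list()
  i <- 1
  while (i <= length(il$lines)) {
    if (!nzchar(trimws(il$lines[i]))) { i <- i + 1; next }
    tk <- strsplit(trimws(il$lines[i]), "\\s+")[[1]]
    if (length(tk) < 10)
      stop("malformed image line ", il$lineno[i], " in ", imagesFile)
    q <- as.numeric(tk[2:5]); tv <- as.numeric(tk[6:8])
    if (anyNA(q) || anyNA(tv))
      stop("non-numeric pose at line ", il$lineno[i], " in ", imagesFile)
    camId <- tk[9]; name <- tk[10]
    k <- intr[[camId]]
    if (is.null(k))
      stop("image at line ", il$lineno[i], " references unknown camera id ",
           camId)
    R <- rotationFromQuaternion(q)
    pose <- rigidTransform(R, tv, frameFrom = "W", frameTo = "C")
    id <- if (nzchar(name)) sub("\\.[A-Za-z]+$", "", name) else tk[1]
    cams[[id]] <- camera(k$fx, k$fy, k$cx, k$cy, k$width, k$height,
                         pose = pose, id = id)
    i <- i + 2   # skip the 2D-point line
  }
  if (anyDuplicated(names(cams))) stop("duplicate image names in ", imagesFile)
  cams
}

#' Write cameras as a COLMAP text model
#'
#' Emits \code{cameras.txt} (one PINHOLE entry per camera) and
#' \code{images.txt} (world-to-camera quaternion and translation, empty
#' 2D-point lines) into \code{dir}.
#'
#' @param cameras named list of [Camera-class].
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeColmapModel <- function(cameras, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x) format(x, digits = 17, trim = TRUE, scientific = FALSE)
  camLines <- c("# Camera list: CAMERA_ID MODEL WIDTH HEIGHT PARAMS[]")
  imgLines <- c(
    "# Image list: IMAGE_ID QW QX QY QZ TX TY TZ CAMERA_ID NAME",
    "#   POINTS2D[] as (X Y POINT3D_ID)")
  for (i in seq_along(cameras)) {
    cam <- cameras[[i]]
    camLines <- c(camLines, paste(i, "PINHOLE", cam@width, cam@height,
                                  fmt(cam@fx), fmt(cam@fy), fmt(cam@cx),
                                  fmt(cam@cy)))
    q <- quaternionFromRotation(cam@pose@rotation)
    tv <- cam@pose@translation
    imgLines <- c(imgLines,
                  paste(i, fmt(q[1]), fmt(q[2]), fmt(q[3]), fmt(q[4]),
                        fmt(tv[1]), fmt(tv[2]), fmt(tv[3]), i,
                        paste0(cam@id, ".png")),
                  "")
  }
  writeLines(camLines, file.path(dir, "cameras.txt"))
  writeLines(imgLines, file.path(dir, "images.txt"))
  invisible(dir)
}

#' Read a robot pose table
#'
#' Delimited text with header comment lines declaring the convention, then
#' one row per image: \code{image_id qw qx qy qz tx ty tz}. The header line
#' \code{# convention: end_effector_to_base} (the forward-kinematics output)
#' is required; quaternions must be unit norm within 1e-9 and image ids
#' unique.
#'
#' @param path file path.
#' @return data.frame with columns image_id, qw..qz, tx..tz and attribute
#'   \code{convention}.
#' @export
readRobotPoses <- function(path) {
  lines <- readLines(path, warn = FALSE)
  conv <- grep("^#\\s*convention:", lines, value = TRUE)
  if (!length(conv))
    stop("robot pose table must declare '# convention: end_effector_to_base'")
  conv <- trimws(sub("^#\\s*convention:", "", conv[1]))
  if (conv != "end_effector_to_base")
    stop("unsupported robot pose convention '", conv, "'")
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) stop("no pose rows in ", path)
  toks <- strsplit(trimws(lines[keep]), "[[:space:],]+")
  bad <- which(lengths(toks) != 8)
  if (length(bad))
    stop("malformed pose row at line ", keep[bad[1]],
         ": expected 'image_id qw qx qy qz tx ty tz'")
  df <- data.frame(image_id = vapply(toks, `[[`, "", 1))
  num <- do.call(rbind, lapply(toks, function(tk) as.numeric(tk[2:8])))
  if (anyNA(num)) stop("non-numeric pose values in ", path)
  df[c("qw", "qx", "qy", "qz", "tx", "ty", "tz")] <- num
  qn <- sqrt(rowSums(num[, 1:4, drop = FALSE]^2))
  if (any(abs(qn - 1) > 1e-9))
    stop("non-unit quaternion for image ",
         df$image_id[which.max(abs(qn - 1))],
         " (|q| = ", format(max(qn)), ")")
  if (anyDuplicated(df$image_id))
    stop("duplicate image ids in robot pose table")
  attr(df, "convention") <- conv
  df
}

#' Camera poses from robot forward kinematics and a hand-eye transform
#'
#' Per row, the camera pose in the robot base frame is the end-effector pose
#' composed with the hand-eye transform (camera to end-effector); the base
#' frame serves as the world frame, so each returned pose is the
#' world-to-camera inverse of that composition.
#'
#' @param table a [readRobotPoses()] data.frame of end-effector-to-base
#'   poses.
#' @param handEye [RigidTransform-class] mapping camera frame C to
#'   end-effector frame EE.
#' @return named list of world-to-camera [RigidTransform-class] (names are
#'   image ids).
#' @export
robotToCameraPoses <- function(table, handEye) {
  if (handEye@frameFrom != "C" || handEye@frameTo != "EE")
    stop("hand-eye transform must map frame C to frame EE (got ",
         handEye@frameFrom, " to ", handEye@frameTo, ")")
  out <- lapply(seq_len(nrow(table)), function(i) {
    Tee <- rigidTransform(
      rotationFromQuaternion(as.numeric(table[i, c("qw", "qx", "qy", "qz")])),
      as.numeric(table[i, c("tx", "ty", "tz")]),
      frameFrom = "EE", frameTo = "B")
    Tcb <- compose(Tee, handEye)            # camera-to-base
    pose <- invertTransform(Tcb)            # base(world)-to-camera
    pose@frameFrom <- "W"; pose@frameTo <- "C"
    pose
  })
  names(out) <- table$image_id
  out
}
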