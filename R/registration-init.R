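#' @include AllClasses.R camera.R transforms.R
NULL

## Grunert's P3P: three unit bearing vectors (rows of Fm, camera frame) and
## three 3D points (rows of Pw). Returns a list of candidate rigid maps
## (R, t) taking the point frame into the camera frame.
p3pSolve <- function(Fm, Pw) {
  a <- sqrt(sum((Pw[2, ] - Pw[3, ])^2))
  b <- sqrt(sum((Pw[1, ] - Pw[3, ])^2))
  cc <- sqrt(sum((Pw[1, ] - Pw[2, ])^2))
  if (min(a, b, cc) < 1e-9) return(list())    # coincident points
  ca <- sum(Fm[2, ] * Fm[3, ])
  cb <- sum(Fm[1, ] * Fm[3, ])
  cg <- sum(Fm[1, ] * Fm[2, ])
  a2 <- a^2; b2 <- b^2; c2 <- cc^2
  q1 <- (a2 - c2) / b2
  q2 <- (a2 + c2) / b2
  q3 <- (b2 - c2) / b2
  q4 <- (b2 - a2) / b2
  A4 <- (q1 - 1)^2 - 4 * c2 / b2 * ca^2
  A3 <- 4 * (q1 * (1 - q1) * cb - (1 - q2) * ca * cg + 2 * c2 / b2 * ca^2 * cb)
  A2 <- 2 * (q1^2 - 1 + 2 * q1^2 * cb^2 + 2 * q3 * ca^2 -
             4 * q2 * ca * cb * cg + 2 * q4 * cg^2)
  A1 <- 4 * (-q1 * (1 + q1) * cb + 2 * a2 / b2 * cg^2 * cb -
             (1 - q2) * ca * cg)
  A0 <- (1 + q1)^2 - 4 * a2 / b2 * cg^2
  coefs <- c(A0, A1, A2, A3, A4)
  if (all(abs(coefs) < 1e-14)) return(list())
  roots <- tryCatch(polyroot(coefs), error = function(e) complex())
  out <- list()
  for (v in roots) {
    if (abs(Im(v)) > 1e-8 * max(1, abs(Re(v)))) next
    v <- Re(v)
    den <- 1 + v^2 - 2 * v * cb
    if (den <= 1e-12) next
    s1 <- sqrt(b2 / den)
    denu <- 2 * (cg - v * ca)
    if (abs(denu) < 1e-12) next
    u <- ((-1 + q1) * v^2 - 2 * q1 * cb * v + 1 + q1) / denu
    if (u <= 0 || v <= 0) next
    s2 <- u * s1; s3 <- v * s1
    Xc <- rbind(s1 * Fm[1, ], s2 * Fm[2, ], s3 * Fm[3, ])
    # absolute orientation (Kabsch) on the three correspondences
    mp <- colMeans(Pw); mx <- colMeans(Xc)
    H <- crossprod(sweep(Pw, 2, mp), sweep(Xc, 2, mx))
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    t <- mx - as.numeric(R %*% mp)
    out[[length(out) + 1L]] <- list(R = R, t = t)
  }
  out
}

## unit bearing vectors (camera frame) for pixel centers, n x 2 -> n x 3
pixelBearings <- function(cam, px) {
  d <- cbind((px[, 1] - cam@cx) / cam@fx, (px[, 2] - cam@cy) / cam@fy, 1)
  d / sqrt(rowSums(d^2))
}

## project frame-S marker centres through a candidate S->C map, NA if behind
projectCandidates <- function(cam, RT, centersS) {
  Xc <- sweep(centersS %*% t(RT$R), 2, RT$t, "+")
  bad <- Xc[, 3] <= 1e-9
  px <- cbind(cam@fx * Xc[, 1] / Xc[, 3] + cam@cx,
              cam@fy * Xc[, 2] / Xc[, 3] + cam@cy)
  px[bad, ] <- NA_real_
  px
}

#' Default gating radius for correspondence search
#'
#' 25 px at the full 9504 px sensor width, scaled linearly with image width
#' and floored at 5 px; must exceed the worst-case perspective bias between
#' an ellipse centre and the projected sphere centre.
#'
#' @param cam a [Camera-class].
#' @return gating radius in pixels.
#' @export
defaultGatePx <- function(cam) max(5, 25 * cam@width / 9504)

#' Exhaustive PnP correspondence search in one image
#'
#' Finds the detection-to-marker correspondence and an initial scene pose
#' from a single image in which all markers are well visible. Four detected
#' ellipse centres are selected (largest support first) and every ordered
#' assignment of 4 of the M sphere centres to them is scored: a minimal P3P
#' solve on three pairs, the fourth pair for disambiguation, and the
#' remaining sphere centres projected and gated against the unassigned
#' detections. The best-scoring hypothesis wins; ties break by lowest summed
#' gated reprojection distance, then by assignment order. If no hypothesis
#' reaches M/2 inliers the next-ranked 4-subset of detections is tried.
#'
#' @param centers n x 2 matrix of detected ellipse centres (px), ordered by
#'   decreasing reliability (support).
#' @param cam the [Camera-class] of that image.
#' @param markers list of [SphereMarker-class] with centres in frame S.
#' @param gatePx gating radius in pixels (default [defaultGatePx()]).
#' @param maxSubsets maximum number of ranked 4-subsets of detections to try
#'   (default 15).
#' @return list with \code{transform} (S-to-W [RigidTransform-class]),
#'   \code{camFromS} (S-to-C), \code{assignment} (integer vector: for each
#'   detection row, the matched marker index or NA), \code{inliers} and
#'   \code{sumGatedDist}.
#' @export
pnpCorrespondenceSearch <- function(centers, cam, markers,
                                    gatePx = defaultGatePx(cam),
                                    maxSubsets = 15L) {
  centers <- as.matrix(centers)
  n <- nrow(centers)
  M <- length(markers)
  if (n < 4)
    stop("at least 4 ellipse centers are required for PnP initialization (got ",
         n, ")")
  if (M < 4) stop("at least 4 markers are required (got ", M, ")")
  centersS <- do.call(rbind, lapply(markers, function(m) m@center))
  bearings <- pixelBearings(cam, centers)
  subsets <- utils::combn(n, 4)
  nsub <- min(ncol(subsets), maxSubsets)
  perms3 <- as.matrix(expand.grid(j1 = seq_len(M), j2 = seq_len(M),
                                  j3 = seq_len(M)))
  perms3 <- perms3[perms3[, 1] != perms3[, 2] & perms3[, 1] != perms3[, 3] &
                   perms3[, 2] != perms3[, 3], , drop = FALSE]
  best <- NULL
  for (si in seq_len(nsub)) {
    det4 <- subsets[, si]
    Fm <- bearings[det4, , drop = FALSE]
    px4 <- centers[det4, , drop = FALSE]
    others <- setdiff(seq_len(n), det4)
    for (pi in seq_len(nrow(perms3))) {
      tri <- perms3[pi, ]
      sols <- p3pSolve(Fm[1:3, ], centersS[tri, , drop = FALSE])
      for (sol in sols) {
        proj <- projectCandidates(cam, sol, centersS)
        # the 3 base pairs must reproject within the gate
        d3 <- sqrt(rowSums((proj[tri, , drop = FALSE] - px4[1:3, ])^2))
        if (anyNA(d3) || any(d3 > gatePx)) next
        # 4th detection disambiguates: any unused marker within the gate
        rem <- setdiff(seq_len(M), tri)
        d4 <- sqrt((proj[rem, 1] - px4[4, 1])^2 +
                   (proj[rem, 2] - px4[4, 2])^2)
        for (k in which(!is.na(d4) & d4 <= gatePx)) {
          j4 <- rem[k]
          hyp <- c(tri, j4)
          # score remaining markers against unassigned detections
          remM <- setdiff(seq_len(M), hyp)
          assignment <- rep(NA_integer_, n)
          assignment[det4] <- hyp
          score <- 4L
          sumd <- sum(d3) + d4[k]
          if (length(remM) && length(others)) {
            dm <- sqrt(outer(proj[remM, 1], centers[others, 1], "-")^2 +
                       outer(proj[remM, 2], centers[others, 2], "-")^2)
            dm <- matrix(dm, nrow = length(remM))
            dm[is.na(dm)] <- Inf    # markers projecting behind the camera
            usedDet <- logical(length(others))
            for (j in order(apply(dm, 1, min))) {
              dj <- dm[j, ]; dj[usedDet] <- Inf
              kk <- which.min(dj)
              if (is.finite(dj[kk]) && dj[kk] <= gatePx) {
                usedDet[kk] <- TRUE
                assignment[others[kk]] <- remM[j]
                score <- score + 1L
                sumd <- sumd + dj[kk]
              }
            }
          }
          if (is.null(best) || score > best$inliers ||
              (score == best$inliers && sumd < best$sumGatedDist - 1e-12)) {
            best <- list(camFromS = sol, assignment = assignment,
                         inliers = score, sumGatedDist = sumd)
          }
        }
      }
    }
    # a full house ends the search; a merely acceptable score may come from
    # an ill-conditioned (near-collinear) subset, so keep trying others
    if (!is.null(best) && best$inliers >= min(M, n)) break
  }
  if (is.null(best) || best$inliers * 2 < M)
    stop("initialization failed; choose an image with all markers well visible")
  TsC <- rigidTransform(best$camFromS$R, best$camFromS$t,
                        frameFrom = "S", frameTo = "C")
  best$camFromS <- TsC
  best$transform <- compose(invertTransform(cam@pose), TsC)
  best
}

#' Initial scene registration from one image (PnP)
#'
#' Thin wrapper around [pnpCorrespondenceSearch()] returning only the initial
#' S-to-W transform. The known perspective bias between ellipse centres and
#' projected sphere centres is tolerated here and eliminated by the conic
#' refinement, which never uses centres.
#'
#' @inheritParams pnpCorrespondenceSearch
#' @return The initial S-to-W [RigidTransform-class].
#' @export
initRegistrationPnP <- function(centers, cam, markers,
                                gatePx = defaultGatePx(cam)) {
  pnpCorrespondenceSearch(centers, cam, markers, gatePx)$transform
}
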