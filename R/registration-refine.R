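#' @include AllClasses.R conics.R registration-init.R
NULL

## Precompute per-(image, marker) blocks of an ObservationSet:
## projection matrix, homogeneous outline points, marker centre and radius.
obsBlocks <- function(obs) {
  e <- obs@entries
  key <- paste(e$image, e$marker, sep = "\r")
  split_idx <- split(seq_len(nrow(e)), key)
  lapply(split_idx, function(ix) {
    img <- e$image[ix[1]]; mk <- e$marker[ix[1]]
    cam <- obs@cameras[[img]]
    m <- obs@markers[[mk]]
    list(image = img, marker = mk,
         P = projectionMatrix(cam),
         X = cbind(e$x[ix], e$y[ix], 1),
         cS = m@center, r = m@radius)
  })
}

## residuals (and optionally the analytic Jacobian) of the conic bilinear
## objective at parameters p = (omega, t[, log s]).
## For each pair: c_W = s R0 exp([omega]x) c_S + t, rho = s r,
## D = dual sphere quadric, B = P D P', E = adj(B) normalized to unit
## Frobenius with positive upper-left 2x2 trace; residuals are x' E x.
conicObjective <- function(p, blocks, R0, s0, similarity, jacobian = FALSE) {
  omega <- p[1:3]; tv <- p[4:6]
  s <- if (similarity) s0 * exp(p[7]) else s0
  Eom <- rotationFromAxisAngle(omega)
  Rcur <- R0 %*% Eom
  np <- if (similarity) 7L else 6L
  Jr <- if (jacobian) so3RightJacobian(omega)
  res <- vector("list", length(blocks))
  J <- if (jacobian) vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    bl <- blocks[[b]]
    cw <- s * as.numeric(Rcur %*% bl$cS) + tv
    rho <- s * bl$r
    P <- bl$P; X <- bl$X
    D <- rbind(cbind(tcrossprod(cw) - rho^2 * diag(3), cw), c(cw, 1))
    B <- P %*% D %*% t(P)
    A <- adjugate3(B)
    n <- sqrt(sum(A^2))
    sgn <- if (A[1, 1] + A[2, 2] >= 0) 1 else -1
    Eh <- (sgn / n) * A
    res[[b]] <- rowSums((X %*% Eh) * X)
    if (jacobian) {
      detB <- sum(B[1, ] * A[, 1])
      # dc/dparam (3 x np) and drho/dparam (np)
      dC <- matrix(0, 3, np)
      dC[, 1:3] <- -s * (R0 %*% Eom %*% skew3(bl$cS) %*% Jr)
      dC[, 4:6] <- diag(3)
      drho <- numeric(np)
      if (similarity) {
        dC[, 7] <- s * as.numeric(Rcur %*% bl$cS)
        drho[7] <- s * bl$r
      }
      Jb <- matrix(0, nrow(X), np)
      for (k in seq_len(np)) {
        dck <- dC[, k]
        dD <- rbind(cbind(tcrossprod(dck, cw) + tcrossprod(cw, dck) -
                            2 * rho * drho[k] * diag(3), dck),
                    c(dck, 0))
        dB <- P %*% dD %*% t(P)
        dA <- (sum(A * t(dB)) / detB) * A - (A %*% dB %*% A) / detB
        dEh <- (sgn / n) * dA - Eh * (sum(A * dA) / n^2)
        Jb[, k] <- rowSums((X %*% dEh) * X)
      }
      J[[b]] <- Jb
    }
  }
  out <- list(residuals = unlist(res, use.names = FALSE))
  if (jacobian) out$jacobian <- do.call(rbind, J)
  out
}

#' Refine a scene registration by conic residual minimization
#'
#' Minimizes the summed squared bilinear conic residual
#' \eqn{\sum_{ijl} (x_{ijl}^T E_{ij} x_{ijl})^2} over the scene-to-world
#' transform, where \eqn{E_{ij}} is the projection of marker j into image i
#' under the current estimate, recomputed every iteration and normalized to
#' unit Frobenius norm (without a normalization the algebraic cost could be
#' driven to zero by conic scale alone). Rotation is parameterized by a
#' local axis-angle increment composed onto the initial rotation; in
#' similarity mode a log-scale parameter is estimated jointly and the marker
#' radii scale with it (the mesh is metric, the camera world need not be).
#' Solved with Levenberg-Marquardt using the analytic Jacobian.
#'
#' @param obs an [ObservationSet-class].
#' @param Tinit initial S-to-W [RigidTransform-class] (from
#'   [initRegistrationPnP()]).
#' @param mode "rigid" (6 parameters) or "similarity" (7 parameters).
#' @param maxIter maximum LM iterations (default 200).
#' @param ftol relative cost-change convergence tolerance (default 1e-10).
#' @param ptol parameter-step convergence tolerance (default 1e-12).
#' @return A [RegistrationResult-class].
#' @export
refineRegistration <- function(obs, Tinit, mode = c("rigid", "similarity"),
                               maxIter = 200L, ftol = 1e-10, ptol = 1e-12) {
  mode <- match.arg(mode)
  similarity <- mode == "similarity"
  blocks <- obsBlocks(obs)
  R0 <- Tinit@rotation
  s0 <- Tinit@scale
  p0 <- c(0, 0, 0, Tinit@translation, if (similarity) 0)
  fn <- function(p) conicObjective(p, blocks, R0, s0, similarity)$residuals
  jac <- function(p) conicObjective(p, blocks, R0, s0, similarity,
                                    jacobian = TRUE)$jacobian
  r0 <- fn(p0)
  initialCost <- sum(r0^2)
  fit <- minpack.lm::nls.lm(par = p0, fn = fn, jac = jac,
                            control = minpack.lm::nls.lm.control(
                              maxiter = maxIter, ftol = ftol, ptol = ptol,
                              gtol = 0))
  p <- fit$par
  finalCost <- sum(fn(p)^2)
  if (finalCost > initialCost * (1 + 1e-12) + 1e-300)
    stop("internal error: cost increased during refinement")
  Rhat <- R0 %*% rotationFromAxisAngle(p[1:3])
  shat <- if (similarity) s0 * exp(p[7]) else 1
  transform <- rigidTransform(Rhat, p[4:6], scale = shat,
                              frameFrom = Tinit@frameFrom,
                              frameTo = Tinit@frameTo)
  # per-image RMS of the bilinear residual at the solution
  rfin <- fn(p)
  imgs <- unlist(lapply(blocks, function(b)
    rep(b$image, nrow(b$X))), use.names = FALSE)
  perImage <- tapply(rfin^2, imgs, function(v) sqrt(mean(v)))
  new("RegistrationResult", transform = transform, scale = shat,
      finalCost = finalCost, initialCost = initialCost,
      perImageRms = c(perImage), nIterations = as.integer(fit$niter),
      converged = fit$info %in% 1:4)
}

setMethod("show", "RegistrationResult", function(object) {
  cat("RegistrationResult\n")
  show(object@transform)
  cat(sprintf("  scale: %.8g | cost: %.4g -> %.4g | %d iterations (%s)\n",
              object@scale, object@initialCost, object@finalCost,
              object@nIterations,
              if (object@converged) "converged" else "not converged"))
})
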