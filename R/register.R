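# Rigid inter-scan registration (prior -> current) and transform application.
# Multiresolution negative normalised cross-correlation minimised by gradient
# descent with step halving; same-modality scans make NCC the natural choice.

#' Registration configuration
#'
#' @param levels number of pyramid levels (each downsampled 2x by mean
#'   pooling).
#' @param maxIter maximum optimiser iterations per level.
#' @param tol convergence tolerance on the similarity value.
#' @param minOverlap minimum fraction of fixed-grid voxels that must sample
#'   inside the moving volume; below this the fields of view are considered
#'   non-overlapping.
#' @param presmooth Gaussian pre-smoothing sigma in voxels applied to both
#'   volumes before the pyramid is built; suppresses noise-local optima of
#'   the similarity without moving its deterministic optimum appreciably.
#' @param symmetric estimate both directions (moving to fixed and fixed to
#'   moving) and average the forward with the inverted backward transform;
#'   cancels most of the resampling-asymmetry error at twice the cost.
#' @return A named list of settings for \code{\link{estimateRigid}}.
#' @export
registrationConfig <- function(levels = 3L, maxIter = 200L, tol = 1e-6,
                               minOverlap = 0.1, presmooth = 0.8,
                               symmetric = TRUE) {
  list(levels = as.integer(levels), maxIter = as.integer(maxIter),
       tol = tol, minOverlap = minOverlap, presmooth = presmooth,
       symmetric = symmetric)
}

#' Resample a volume or mask through a rigid transform
#'
#' Samples the input on the target grid: \code{out(x) = vol(T^{-1}(x))} for
#' target world coordinates \code{x}, so applying the transform that maps the
#' moving image's world frame to the fixed image's world frame aligns the
#' moving image with the fixed grid. Out-of-field voxels are set to 0.
#'
#' @param vol A \linkS4class{VolumeImage}, \linkS4class{BinaryMask} or
#'   \linkS4class{LabelMask}.
#' @param transform A \linkS4class{RigidTransform} (moving world to fixed
#'   world).
#' @param target optional \linkS4class{VolumeImage} supplying the output grid;
#'   defaults to the input's own grid.
#' @param interpolation "trilinear" (images) or "nearest" (masks/labels).
#'   Trilinear interpolation of a label or binary mask is refused.
#' @return The resampled object, same class as the input, on the target grid.
#' @export
applyTransform <- function(vol, transform, target = NULL,
                           interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (interpolation == "trilinear" && (is(vol, "BinaryMask") || is(vol, "LabelMask")))
    stop("trilinear interpolation requested for a label-valued mask; use 'nearest'")
  if (is.null(target)) target <- vol
  M <- solve(vol@affine) %*% solve(transformMatrix(transform)) %*% target@affine
  res <- .resample_affine(vol@voxels, M, dim(target@voxels),
                          if (interpolation == "nearest") 1L else 0L, 0)
  out <- res$values
  if (is(vol, "BinaryMask"))
    return(binaryMask(out, target))
  if (is(vol, "LabelMask"))
    return(labelMask(out, target))
  volumeImage(out, spacing = target@spacing, affine = target@affine)
}

# mean-pool pyramid level; affine adjusted so world geometry is preserved
downsampleLevel <- function(vol) {
  v <- .downsample2_mean(vol@voxels)
  S <- diag(4)
  diag(S)[1:3] <- 2
  S[1:3, 4] <- 0.5  # coarse voxel 0 is the mean of fine voxels 0 and 1
  aff <- vol@affine %*% S
  volumeImage(v, spacing = sqrt(colSums(aff[1:3, 1:3]^2)), affine = aff)
}

negNCC <- function(movingVox, movingAffine, fixed, M4, minOverlap,
                   fgMask = NULL) {
  # same convention as applyTransform: fixed-grid voxel -> fixed world ->
  # (inverse of the moving-to-fixed map) -> moving world -> moving voxel
  M <- solve(movingAffine) %*% solve(M4) %*% fixed@affine
  res <- .resample_affine(movingVox, M, dim(fixed@voxels), 0L, 0)
  v <- res$valid
  if (!is.null(fgMask)) v <- v & fgMask
  if (mean(v) < minOverlap)
    return(NA_real_)
  a <- res$values[v]
  b <- fixed@voxels[v]
  sa <- sd(a); sb <- sd(b)
  if (sa == 0 || sb == 0) return(NA_real_)
  -mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

# Similarity support: the top-gradient voxels of the fixed image. Rigid
# alignment information is concentrated at edges; restricting the similarity
# to them makes the estimator markedly more efficient than uniform NCC,
# whose optimum flat interior noise can displace along the soft
# rotation/translation modes.
similaritySupport <- function(fixed, quantileCut = 0.9) {
  v <- fixed@voxels
  d <- dim(v)
  if (any(d < 8)) return(NULL)
  g2 <- array(0, d)
  g2[2:(d[1] - 1), , ] <- g2[2:(d[1] - 1), , ] +
    ((v[3:d[1], , ] - v[1:(d[1] - 2), , ]) / (2 * fixed@spacing[1]))^2
  g2[, 2:(d[2] - 1), ] <- g2[, 2:(d[2] - 1), ] +
    ((v[, 3:d[2], ] - v[, 1:(d[2] - 2), ]) / (2 * fixed@spacing[2]))^2
  g2[, , 2:(d[3] - 1)] <- g2[, , 2:(d[3] - 1)] +
    ((v[, , 3:d[3]] - v[, , 1:(d[3] - 2)]) / (2 * fixed@spacing[3]))^2
  thr <- quantile(g2, quantileCut)
  if (thr <= 0) return(NULL)
  g2 >= thr
}

# subset NCC objective builder at full resolution for one direction
subsetObjective <- function(mv, fx, minOverlap) {
  support <- similaritySupport(fx, 0.9)
  if (is.null(support)) return(NULL)
  supIdx <- arrayInd(which(support), dim(fx@voxels)) - 1L
  storage.mode(supIdx) <- "integer"
  supVals <- fx@voxels[support]
  Minv <- solve(mv@affine)
  function(M4) {  # M4: moving world -> fixed world
    M <- Minv %*% solve(M4) %*% fx@affine
    res <- .resample_points(mv@voxels, M, supIdx)
    v <- res$valid
    if (mean(v) < minOverlap) return(NA_real_)
    a <- res$values[v]
    b <- supVals[v]
    sa <- sd(a); sb <- sd(b)
    if (sa == 0 || sb == 0) return(NA_real_)
    -mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
  }
}

# refine candidate transforms on the summed forward+backward similarity
symmetricPolish <- function(moving, fixed, candidates, cfg) {
  smooth <- function(v) {
    if (cfg$presmooth <= 0) return(v)
    volumeImage(.gaussian_blur3d(v@voxels, rep(cfg$presmooth, 3)),
                spacing = v@spacing, affine = v@affine)
  }
  mv <- smooth(moving)
  fx <- smooth(fixed)
  fFwd <- subsetObjective(mv, fx, cfg$minOverlap)
  fBwd <- subsetObjective(fx, mv, cfg$minOverlap)
  if (is.null(fFwd) || is.null(fBwd)) return(candidates[[1]])
  center <- candidates[[1]]@center
  rotScale <- max(dim(moving@voxels) * moving@spacing) / 2
  fSym <- function(q) {
    M <- transformMatrix(rigidTransform(q[1:3] / rotScale, q[4:6], center))
    a <- fFwd(M)
    b <- fBwd(solve(M))
    if (is.na(a) || is.na(b)) return(1)
    a + b
  }
  qs <- lapply(candidates, function(tr) c(tr@angles * rotScale,
                                          tr@translation))
  vals <- vapply(qs, fSym, numeric(1))
  q <- qs[[which.min(vals)]]
  pol <- tryCatch(
    optim(q, fSym, method = "BFGS",
          control = list(reltol = 1e-12, maxit = 150,
                         ndeps = rep(0.25 * min(fixed@spacing), 6))),
    error = function(e) NULL)
  if (!is.null(pol) && pol$value < min(vals)) q <- pol$par
  rigidTransform(q[1:3] / rotScale, q[4:6], center)
}

#' Estimate the rigid transform aligning a moving to a fixed volume
#'
#' Multiresolution (coarse-to-fine) maximisation of normalised
#' cross-correlation over the six rigid parameters, using central-difference
#' gradients and gradient descent with step halving. The rotation centre is
#' the moving image's world centre. Deterministic given inputs and
#' configuration.
#'
#' @param moving,fixed \linkS4class{VolumeImage}s sharing an approximate field
#'   of view.
#' @param cfg configuration from \code{\link{registrationConfig}}.
#' @param init optional initial \linkS4class{RigidTransform}.
#' @return A \linkS4class{RigidTransform} mapping moving world to fixed world.
#' @export
estimateRigid <- function(moving, fixed, cfg = registrationConfig(),
                          init = NULL) {
  if (isTRUE(cfg$symmetric)) {
    cfgOnce <- cfg
    cfgOnce$symmetric <- FALSE
    fwd <- estimateRigid(moving, fixed, cfgOnce, init)
    bwd <- estimateRigid(fixed, moving, cfgOnce,
                         if (is.null(init)) NULL else invertTransform(init))
    bwdInv <- rigidFromMatrix(solve(transformMatrix(bwd)),
                              center = fwd@center)
    avg <- rigidTransform((fwd@angles + bwdInv@angles) / 2,
                          (fwd@translation + bwdInv@translation) / 2,
                          fwd@center)
    # consolidate on the joint two-direction similarity: the two one-way
    # estimates can settle in different noise basins, and their plain
    # average then lies on neither objective's floor
    best <- symmetricPolish(moving, fixed, list(avg, fwd, bwdInv), cfg)
    return(best)
  }
  d <- dim(moving@voxels)
  center <- as.vector(voxelToWorld(moving, matrix((d - 1) / 2, 1)))
  extent <- d * moving@spacing
  rotScale <- max(extent) / 2  # 1 unit of scaled angle ~ 1 mm at the surface

  smooth <- function(v) {
    if (cfg$presmooth <= 0) return(v)
    volumeImage(.gaussian_blur3d(v@voxels, rep(cfg$presmooth, 3)),
                spacing = v@spacing, affine = v@affine)
  }
  pyrM <- list(smooth(moving))
  pyrF <- list(smooth(fixed))
  for (l in seq_len(cfg$levels - 1L)) {
    if (any(dim(pyrM[[l]]@voxels) < 16L) || any(dim(pyrF[[l]]@voxels) < 16L))
      break
    pyrM[[l + 1L]] <- downsampleLevel(pyrM[[l]])
    pyrF[[l + 1L]] <- downsampleLevel(pyrF[[l]])
  }

  # scaled parameters q: q[1:3]*rotScale = mm-equivalent rotation, q[4:6] mm
  q <- c(0, 0, 0, 0, 0, 0)
  if (!is.null(init))
    q <- c(init@angles * rotScale, init@translation)
  toTransform <- function(q)
    rigidTransform(q[1:3] / rotScale, q[4:6], center)

  for (lev in rev(seq_along(pyrM))) {
    mv <- pyrM[[lev]]
    fx <- pyrF[[lev]]
    # coarse levels keep a broad (or full) support for capture range;
    # the sharp top-decile support is reserved for the precision levels,
    # where a sparse support would otherwise admit false optima
    support <- if (lev == 1L) similaritySupport(fx, 0.9) else NULL
    if (!is.null(support)) {
      # evaluate only the support points: an order of magnitude cheaper,
      # which pays for the basin-escape restarts below
      supIdx <- arrayInd(which(support), dim(fx@voxels)) - 1L
      storage.mode(supIdx) <- "integer"
      supVals <- fx@voxels[support]
      Minv <- solve(mv@affine)
      f <- function(q) {
        M <- Minv %*% solve(transformMatrix(toTransform(q))) %*% fx@affine
        res <- .resample_points(mv@voxels, M, supIdx)
        v <- res$valid
        if (mean(v) < cfg$minOverlap) return(NA_real_)
        a <- res$values[v]
        b <- supVals[v]
        sa <- sd(a); sb <- sd(b)
        if (sa == 0 || sb == 0) return(NA_real_)
        -mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
      }
    } else {
      f <- function(q) negNCC(mv@voxels, mv@affine, fx,
                              transformMatrix(toTransform(q)),
                              cfg$minOverlap)
    }
    cur <- f(q)
    if (is.na(cur))
      stop("non-overlapping fields of view: similarity undefined")
    step <- 1
    eps <- 0.25 * min(fx@spacing)
    maxMove <- 2 * max(fx@spacing)
    smallStreak <- 0L
    for (it in seq_len(cfg$maxIter)) {
      # central differences give the gradient and the diagonal curvature
      # from the same evaluations; preconditioning by the curvature keeps
      # the flat rotation axes moving at the same pace as translations
      fp <- fm <- numeric(6)
      for (i in 1:6) {
        e <- numeric(6); e[i] <- eps
        fp[i] <- f(q + e); fm[i] <- f(q - e)
      }
      bad <- is.na(fp) | is.na(fm)
      g <- ifelse(bad, 0, (fp - fm) / (2 * eps))
      if (all(g == 0)) break
      h <- ifelse(bad, NA, (fp + fm - 2 * cur) / eps^2)
      h[!is.finite(h) | h <= 0] <- NA
      if (all(is.na(h))) h <- rep(1, 6)
      hFloor <- max(h, na.rm = TRUE) * 1e-2
      h[is.na(h)] <- hFloor
      h <- pmax(h, hFloor)
      newton <- -g / h
      dn <- sqrt(sum(newton^2))
      if (dn > maxMove) newton <- newton * maxMove / dn
      steepest <- -g / sqrt(sum(g^2)) * maxMove
      improved <- FALSE
      for (dirn in list(newton, steepest)) {
        s <- step
        while (s > 1e-5) {
          cand <- q + s * dirn
          fc <- f(cand)
          if (!is.na(fc) && fc < cur - 1e-14) {
            smallStreak <- if ((cur - fc) < cfg$tol) smallStreak + 1L else 0L
            q <- cand
            cur <- fc
            improved <- TRUE
            step <- min(s * 2, 1)
            break
          }
          s <- s / 2
        }
        if (improved) break
      }
      # converged once gains stay below tol for several successive
      # iterations; a single grazing step must not abort the level
      if (!improved || smallStreak >= 5L) break
    }
    if (lev == 1L) {
      # Finest-level polish. Two failure modes remain after the pyramid:
      # (a) soft coupled rotation/translation valleys that axis-wise
      # preconditioned descent follows too slowly -- a quasi-Newton run
      # tracks the full 6x6 curvature; (b) noise-induced local minima a
      # fraction of a degree away from the global optimum -- deterministic
      # perturbed restarts on each rotation axis escape those basins.
      fSafe <- function(qq) {
        v <- f(qq)
        if (is.na(v)) 1 else v
      }
      polish <- function(q0) tryCatch(
        optim(q0, fSafe, method = "BFGS",
              control = list(reltol = 1e-12, maxit = 150,
                             ndeps = rep(eps, 6))),
        error = function(e) NULL)
      best <- list(par = q, value = cur)
      p0 <- polish(q)
      if (!is.null(p0) && p0$value < best$value) best <- p0
      pert <- 0.9 * pi / 180 * rotScale
      for (axis in 1:3)
        for (sgn in c(-1, 1)) {
          q0 <- best$par
          q0[axis] <- q0[axis] + sgn * pert
          pr <- polish(q0)
          if (!is.null(pr) && pr$value < best$value) best <- pr
        }
      q <- best$par
    }
  }
  toTransform(q)
}

#' Serialise a rigid transform to JSON
#' @param transform A \linkS4class{RigidTransform}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeTransform <- function(transform, path) {
  jsonlite::write_json(list(angles_rad = transform@angles,
                            translation_mm = transform@translation,
                            center_mm = transform@center),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read a rigid transform from JSON
#' @param path file written by \code{\link{writeTransform}}, or any JSON with
#'   fields angles_rad, translation_mm, center_mm.
#' @return A \linkS4class{RigidTransform}.
#' @export
readTransform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigidTransform(x$angles_rad, x$translation_mm, x$center_mm)
}
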