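# The simultaneous multi-channel segmentation model: a 3D U-Net whose
# single-channel input layer is replaced by a multi-channel layer. The
# 1-channel variant (standalone baseline), the 2-channel variant
# (current + registered prior scan) and the 3-channel variant (+ registered
# prior lesion mask) share the backbone; only the first convolution differs.

#' Build a segmentation model
#'
#' @param inChannels 1 (standalone), 2 (current + registered prior) or
#'   3 (+ registered prior lesion mask).
#' @param levels number of resolution levels (2x down/upsampling between
#'   levels).
#' @param baseFilters filters at the finest level, doubling per level.
#' @param outChannels 1 (current-scan probability) or 2 (current and prior
#'   probabilities).
#' @param seed integer seed for the weight initialisation.
#' @return A \linkS4class{SegModel}.
#' @export
buildModel <- function(inChannels, levels = 4L, baseFilters = 16L,
                       outChannels = if (inChannels == 1L) 1L else 2L,
                       seed = 1L) {
  if (!inChannels %in% 1:3) stop("inChannels must be 1, 2 or 3")
  set.seed(seed)
  w <- initUnetWeights(as.integer(inChannels), as.integer(outChannels),
                       as.integer(levels), as.integer(baseFilters))
  new("SegModel", inChannels = as.integer(inChannels),
      outChannels = as.integer(outChannels), levels = as.integer(levels),
      baseFilters = as.integer(baseFilters), weights = w,
      seed = as.integer(seed))
}

#' Total number of trainable parameters
#' @param model A \linkS4class{SegModel}.
#' @return integer parameter count.
#' @export
modelParameterCount <- function(model) {
  n <- 0
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else n <<- n + length(x)
    invisible(NULL)
  }
  walk(model@weights)
  n
}

#' Per-layer parameter shapes
#'
#' Useful for architecture audits: two models differing only in
#' \code{inChannels} differ only in the first convolution's shapes.
#' @param model A \linkS4class{SegModel}.
#' @return named list of dim vectors, one entry per weight array.
#' @export
modelLayerShapes <- function(model) {
  out <- list()
  walk <- function(x, path) {
    if (is.list(x)) {
      nm <- if (is.null(names(x))) as.character(seq_along(x)) else names(x)
      for (i in seq_along(x)) walk(x[[i]], paste(path, nm[i], sep = "."))
    } else out[[path]] <<- if (is.null(dim(x))) length(x) else dim(x)
  }
  walk(model@weights, "w")
  out
}

#' Training configuration
#'
#' @param patchSize cubic patch edge in voxels (must be divisible by
#'   2^(levels-1) of the model).
#' @param batchSize patches per optimisation step.
#' @param steps number of optimisation steps (0 returns the model unchanged).
#' @param lr Adam learning rate.
#' @param lesionFraction share of patches centred inside a ground-truth
#'   lesion; the rest are centred uniformly in the brain ROI.
#' @param seed seed controlling patch sampling order.
#' @return A named list of training settings.
#' @export
trainConfig <- function(patchSize = 32L, batchSize = 2L, steps = 200L,
                        lr = 1e-3, lesionFraction = 0.5, seed = 1L) {
  stopifnot(lesionFraction >= 0, lesionFraction <= 1, patchSize >= 8)
  list(patchSize = as.integer(patchSize), batchSize = as.integer(batchSize),
       steps = as.integer(steps), lr = lr, lesionFraction = lesionFraction,
       seed = as.integer(seed))
}

#' Prepare a phantom study for training or inference
#'
#' Resamples the prior scan and masks onto the current grid through the given
#' transform (the estimated one in the pipeline, the ground-truth one when
#' training on phantoms), computes the brain ROI of the current scan and
#' z-score-normalises both scans within it.
#'
#' @param study A \linkS4class{PhantomStudy}.
#' @param transform prior-to-current \linkS4class{RigidTransform}; defaults to
#'   the study's ground truth.
#' @return A list of aligned arrays: current, prior, priorMask (0/1),
#'   gtCurrent, gtPrior (0/1), roi, plus the shared geometry.
#' @export
prepareTrainingStudy <- function(study, transform = gtTransform(study)) {
  cur <- study@currentVolume
  roi <- brainROI(cur)
  curN <- normalizeIntensity(cur, roi)
  priorRes <- applyTransform(study@priorVolume, transform, target = cur,
                             interpolation = "trilinear")
  priorN <- normalizeIntensity(priorRes, roi)
  priorMaskRes <- applyTransform(study@priorMask, transform, target = cur,
                                 interpolation = "nearest")
  list(current = curN@voxels, prior = priorN@voxels,
       priorMask = (priorMaskRes@voxels > 0) * 1,
       gtCurrent = (study@currentMask@voxels > 0) * 1,
       gtPrior = (priorMaskRes@voxels > 0) * 1,
       roi = roi@voxels, geometry = cur)
}

extractPatch <- function(arr, start, ps) {
  arr[start[1]:(start[1] + ps - 1), start[2]:(start[2] + ps - 1),
      start[3]:(start[3] + ps - 1), drop = FALSE]
}

#' Sample aligned training patches from a prepared study
#'
#' Each sample holds spatially aligned cubic patches of the current scan, the
#' registered prior scan, the registered prior lesion mask, and the
#' ground-truth masks at both timepoints. A \code{lesionFraction} share of
#' samples is centred on a random ground-truth lesion voxel of the current
#' scan; the rest are centred uniformly inside the brain ROI.
#'
#' @param prep output of \code{\link{prepareTrainingStudy}}.
#' @param patchSize cubic patch edge (voxels); must fit inside the grid.
#' @param lesionFraction value in [0, 1].
#' @param n number of samples.
#' @param seed optional seed; when NULL the current RNG stream is used.
#' @return list of samples, each with arrays current, prior, priorMask,
#'   gtCurrent, gtPrior of dim (patchSize^3) and the 1-based patch start.
#' @export
samplePatches <- function(prep, patchSize, lesionFraction, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- dim(prep$current)
  ps <- as.integer(patchSize)
  if (any(ps > d)) stop("patch does not fit inside the volume grid")
  lesionIdx <- which(prep$gtCurrent > 0)
  roiIdx <- which(prep$roi > 0)
  if (!length(roiIdx)) stop("empty brain ROI")
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    useLesion <- runif(1) < lesionFraction
    if (useLesion && !length(lesionIdx))
      stop("lesion-centred patches requested but the ground-truth mask is empty")
    centerLinear <- if (useLesion) lesionIdx[sample.int(length(lesionIdx), 1)]
                    else roiIdx[sample.int(length(roiIdx), 1)]
    center <- arrayInd(centerLinear, d)
    start <- pmin(pmax(as.integer(center) - ps %/% 2L, 1L), d - ps + 1L)
    samples[[i]] <- list(
      current = extractPatch(prep$current, start, ps),
      prior = extractPatch(prep$prior, start, ps),
      priorMask = extractPatch(prep$priorMask, start, ps),
      gtCurrent = extractPatch(prep$gtCurrent, start, ps),
      gtPrior = extractPatch(prep$gtPrior, start, ps),
      start = start)
  }
  samples
}

stackChannels <- function(arrays) {
  d <- dim(arrays[[1]])
  out <- array(0, c(d, length(arrays)))
  for (i in seq_along(arrays)) out[, , , i] <- arrays[[i]]
  out
}

sampleToInput <- function(s, inChannels) {
  chans <- switch(inChannels,
                  list(s$current),
                  list(s$current, s$prior),
                  list(s$current, s$prior, s$priorMask))
  stackChannels(chans)
}

# output channel order: 1 = current scan, 2 = prior scan (when present)
sampleToTarget <- function(s, outChannels) {
  if (outChannels == 1L) stackChannels(list(s$gtCurrent))
  else stackChannels(list(s$gtCurrent, s$gtPrior))
}

#' Train a segmentation model on prepared studies
#'
#' Minimises soft-Dice + binary cross-entropy (equal weights) with Adam on
#' seeded patch batches; returns the weights with the best running loss.
#' Fully deterministic for a fixed seed, data and configuration.
#'
#' @param model A \linkS4class{SegModel}.
#' @param preps list of prepared studies from
#'   \code{\link{prepareTrainingStudy}}; at least one must contain a lesion.
#' @param cfg a \code{\link{trainConfig}}.
#' @param verbose print the loss every 25 steps.
#' @return the trained \linkS4class{SegModel} (best-loss weights) with a
#'   "history" attribute holding the per-step loss.
#' @export
trainModel <- function(model, preps, cfg = trainConfig(), verbose = FALSE) {
  if (!length(preps)) stop("at least one training study is required")
  if (!any(vapply(preps, function(p) any(p$gtCurrent > 0), logical(1))))
    stop("at least one training study must contain a lesion")
  if (cfg$steps == 0L) return(model)
  set.seed(cfg$seed)
  weights <- model@weights
  state <- list(t = 0, m = zerosLike(weights), v = zerosLike(weights))
  best <- list(loss = Inf, weights = weights)
  history <- numeric(cfg$steps)
  for (step in seq_len(cfg$steps)) {
    studyIdx <- sample.int(length(preps), 1)
    batch <- samplePatches(preps[[studyIdx]], cfg$patchSize,
                           cfg$lesionFraction, cfg$batchSize)
    grads <- NULL
    lossAcc <- 0
    for (s in batch) {
      x <- sampleToInput(s, model@inChannels)
      y <- sampleToTarget(s, model@outChannels)
      fw <- unetForward(weights, x, model@levels)
      ls <- diceBceLoss(fw$logits, y)
      if (!is.finite(ls$loss))
        stop("training diverged (non-finite loss) at step ", step)
      g <- unetBackward(weights, fw$cache, ls$dlogits, model@levels)
      grads <- if (is.null(grads)) g else mapTree(`+`, grads, g)
      lossAcc <- lossAcc + ls$loss
    }
    grads <- mapTree(function(g) g / length(batch), grads)
    upd <- adamStep(weights, grads, state, cfg$lr)
    weights <- upd$weights
    state <- upd$state
    history[step] <- lossAcc / length(batch)
    if (history[step] < best$loss)
      best <- list(loss = history[step], weights = weights)
    if (verbose && step %% 25L == 0L)
      message(sprintf("step %d: loss %.4f", step, history[step]))
  }
  model@weights <- best$weights
  attr(model, "history") <- history
  model
}

gaussianWindowWeights <- function(ps) {
  x <- seq_len(ps) - (ps + 1) / 2
  g <- exp(-0.5 * (x / (ps / 8))^2)
  outer(outer(g, g), g)
}

windowStarts <- function(dimLen, ps) {
  stride <- max(1L, ps %/% 2L)
  unique(c(seq(1L, dimLen - ps + 1L, by = stride), dimLen - ps + 1L))
}

#' Sliding-window inference on a registered scan pair
#'
#' Runs the model over the full grid with 50\%-overlap cubic windows and
#' Gaussian-weighted averaging of overlapping window probabilities.
#' Deterministic.
#'
#' @param model A \linkS4class{SegModel}.
#' @param current current-scan \linkS4class{VolumeImage} (normalised).
#' @param registeredPrior prior scan resampled onto the current grid
#'   (normalised); required when \code{inChannels >= 2}.
#' @param registeredPriorMask 0/1 prior lesion mask on the current grid;
#'   required when \code{inChannels == 3}.
#' @param patchSize inference window edge (voxels).
#' @return named list of probability \linkS4class{VolumeImage}s: "current",
#'   plus "prior" when the model has two output channels.
#' @export
predictPair <- function(model, current, registeredPrior = NULL,
                        registeredPriorMask = NULL, patchSize = 32L) {
  arrays <- list(current@voxels)
  if (model@inChannels >= 2L) {
    if (is.null(registeredPrior))
      stop("model has ", model@inChannels,
           " input channels but no registered prior scan was provided")
    if (!all(dim(registeredPrior@voxels) == dim(current@voxels)))
      stop("current and registered prior must share one grid")
    arrays <- c(arrays, list(registeredPrior@voxels))
  }
  if (model@inChannels == 3L) {
    if (is.null(registeredPriorMask))
      stop("3-channel model requires the registered prior lesion mask")
    if (!all(dim(registeredPriorMask@voxels) == dim(current@voxels)))
      stop("prior mask grid mismatch")
    arrays <- c(arrays, list((registeredPriorMask@voxels > 0) * 1))
  }
  if (length(arrays) != model@inChannels)
    stop("number of inputs does not match the model's channel count")

  d <- dim(current@voxels)
  ps <- as.integer(patchSize)
  pad <- pmax(0L, ps - d)
  dP <- d + pad
  chans <- lapply(arrays, function(a) {
    out <- array(0, dP)
    out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- a
    out
  })
  acc <- array(0, c(dP, model@outChannels))
  wacc <- array(0, dP)
  wWin <- gaussianWindowWeights(ps)
  for (sz in windowStarts(dP[3], ps))
    for (sy in windowStarts(dP[2], ps))
      for (sx in windowStarts(dP[1], ps)) {
        start <- c(sx, sy, sz)
        x <- stackChannels(lapply(chans, extractPatch, start = start, ps = ps))
        fw <- unetForward(model@weights, x, model@levels)
        p <- sigmoidStable(fw$logits)
        ix <- sx:(sx + ps - 1); iy <- sy:(sy + ps - 1); iz <- sz:(sz + ps - 1)
        for (c in seq_len(model@outChannels))
          acc[ix, iy, iz, c] <- acc[ix, iy, iz, c] + p[, , , c] * wWin
        wacc[ix, iy, iz] <- wacc[ix, iy, iz] + wWin
      }
  result <- list()
  chanNames <- if (model@outChannels == 2L) c("current", "prior") else "current"
  for (c in seq_len(model@outChannels)) {
    pm <- (acc[, , , c] / wacc)[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])]
    dim(pm) <- d
    result[[chanNames[c]]] <- volumeImage(pm, spacing = current@spacing,
                                          affine = current@affine)
  }
  result
}

#' Standalone-pairs inference: a single scan in both input channels
#'
#' Runs a 2-channel model on a single scan by duplicating it into both input
#' channels, the inference mode used when no prior scan exists (first
#' timepoint).
#'
#' @param model a 2-channel \linkS4class{SegModel}.
#' @param scan a normalised \linkS4class{VolumeImage}.
#' @param patchSize inference window edge.
#' @return As \code{\link{predictPair}}.
#' @export
predictStandalonePairs <- function(model, scan, patchSize = 32L) {
  if (model@inChannels != 2L)
    stop("standalone-pairs inference requires a 2-channel model")
  predictPair(model, scan, scan, patchSize = patchSize)
}

#' Save a model to disk with an embedded JSON header
#'
#' The file is JSON throughout: a header with the architecture and seed, and
#' flattened weight arrays with their dims.
#'
#' @param model A \linkS4class{SegModel}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
saveModel <- function(model, path) {
  flat <- list()
  walk <- function(x, path0) {
    if (is.list(x)) {
      nm <- if (is.null(names(x))) as.character(seq_along(x)) else names(x)
      for (i in seq_along(x)) walk(x[[i]], c(path0, nm[i]))
    } else {
      flat[[paste(path0, collapse = "/")]] <<-
        list(dim = if (is.null(dim(x))) length(x) else dim(x),
             values = as.vector(x))
    }
  }
  walk(model@weights, character(0))
  jsonlite::write_json(list(
    header = list(inChannels = model@inChannels,
                  outChannels = model@outChannels, levels = model@levels,
                  baseFilters = model@baseFilters, seed = model@seed),
    weights = flat), path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Load a model saved by \code{\link{saveModel}}
#' @param path file path.
#' @return A \linkS4class{SegModel}.
#' @export
loadModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  h <- lapply(x$header, as.integer)
  model <- buildModel(h$inChannels, h$levels, h$baseFilters, h$outChannels,
                      h$seed)
  w <- model@weights
  for (key in names(x$weights)) {
    parts <- strsplit(key, "/", fixed = TRUE)[[1]]
    entry <- x$weights[[key]]
    val <- entry$values
    if (length(entry$dim) > 1) dim(val) <- entry$dim
    w <- assignPath(w, parts, val)
  }
  model@weights <- w
  validObject(model)
  model
}

assignPath <- function(tree, parts, value) {
  p <- parts[1]
  idx <- suppressWarnings(as.integer(p))
  key <- if (!is.na(idx) && is.null(names(tree))) idx else p
  if (length(parts) == 1L) tree[[key]] <- value
  else tree[[key]] <- assignPath(tree[[key]], parts[-1], value)
  tree
}
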