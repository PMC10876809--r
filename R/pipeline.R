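# End-to-end pipeline: brain ROI -> rigid registration -> simultaneous
# segmentation -> lesion extraction -> matching -> change classification and
# volumetric quantification, with reproducible on-disk reports.

PIPELINE_SCENARIOS <- c("standalone_single", "standalone_pairs",
                        "simultaneous", "simultaneous_with_prior")

# order-insensitive 32-bit FNV-1a over a string; used to stamp reports with
# a config fingerprint without external dependencies
fnv1a <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte (b < 256); keep h as a double to stay
    # clear of the 32-bit integer range
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply in exact double arithmetic (split at 2^16
    # so no intermediate product exceeds 2^53)
    h0 <- h %% 65536
    h1 <- h %/% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full longitudinal analysis on one scan pair
#'
#' Executes the pipeline steps in order: brain region of interest in each
#' scan, rigid registration of the prior to the current scan, simultaneous
#' lesion detection and segmentation with the scenario's model, discrete
#' lesion extraction, bipartite lesion matching, change classification and
#' volumetric quantification. All outputs (masks, transform, matching graph,
#' change report, log with config hash) are written under \code{outDir}.
#' Reruns with an identical configuration and seed produce byte-identical
#' JSON reports.
#'
#' @param current current-scan \linkS4class{VolumeImage} or NIfTI path.
#' @param model A \linkS4class{SegModel} (channel count must match the
#'   scenario) or a path readable by \code{\link{loadModel}}.
#' @param scenario one of "standalone_single", "standalone_pairs",
#'   "simultaneous", "simultaneous_with_prior".
#' @param prior prior-scan \linkS4class{VolumeImage} or path; required for
#'   the simultaneous scenarios.
#' @param priorMask prior lesion \linkS4class{LabelMask}/\linkS4class{BinaryMask}
#'   or path; required for "simultaneous_with_prior".
#' @param outDir output directory; NULL skips writing.
#' @param brainMask optional externally supplied brain
#'   \linkS4class{BinaryMask} (bypasses the built-in ROI extraction).
#' @param threshold probability threshold for \code{\link{binarize}}.
#' @param patchSize inference window edge (voxels).
#' @param registrationCfg settings from \code{\link{registrationConfig}}.
#' @param seed integer recorded in the log (the pipeline itself is
#'   deterministic).
#' @return list with elements transform, priorLesions, currentLesions,
#'   graph, report, roi, probability maps.
#' @export
runPipeline <- function(current, model, scenario, prior = NULL,
                        priorMask = NULL, outDir = NULL, brainMask = NULL,
                        threshold = 0.5, patchSize = 32L,
                        registrationCfg = registrationConfig(), seed = 0L) {
  scenario <- match.arg(scenario, PIPELINE_SCENARIOS)
  needPrior <- scenario %in% c("simultaneous", "simultaneous_with_prior")
  if (needPrior && is.null(prior))
    stop("scenario '", scenario, "' requires a prior scan")
  if (scenario == "simultaneous_with_prior" && is.null(priorMask))
    stop("scenario 'simultaneous_with_prior' requires the prior lesion mask")
  if (is.character(current)) current <- readVolume(current)
  if (is.character(prior)) prior <- readVolume(prior)
  if (is.character(priorMask)) {
    pm <- readVolume(priorMask)
    priorMask <- labelMask(pm@voxels, pm)
  }
  if (is.character(model)) model <- loadModel(model)
  wantChannels <- switch(scenario, standalone_single = 1L,
                         standalone_pairs = 2L, simultaneous = 2L,
                         simultaneous_with_prior = 3L)
  if (model@inChannels != wantChannels)
    stop("model has ", model@inChannels, " input channels but scenario '",
         scenario, "' needs ", wantChannels)

  # Step 1: brain ROI; Step 2: registration
  roi <- brainROI(current, mask = brainMask)
  curN <- normalizeIntensity(current, roi)
  transform <- rigidTransform()
  priorN <- NULL
  priorMaskOnCur <- NULL
  if (!is.null(prior)) {
    transform <- estimateRigid(prior, current, registrationCfg)
    priorRes <- applyTransform(prior, transform, target = current,
                               interpolation = "trilinear")
    priorN <- normalizeIntensity(priorRes, roi)
    if (!is.null(priorMask))
      priorMaskOnCur <- applyTransform(priorMask, transform,
                                       target = current,
                                       interpolation = "nearest")
  }

  # Step 3: simultaneous detection and segmentation
  probs <- switch(scenario,
    standalone_single = predictPair(model, curN, patchSize = patchSize),
    standalone_pairs = predictStandalonePairs(model, curN,
                                              patchSize = patchSize),
    simultaneous = predictPair(model, curN, priorN, patchSize = patchSize),
    simultaneous_with_prior = predictPair(model, curN, priorN,
                                          priorMaskOnCur,
                                          patchSize = patchSize))

  # Step 4: lesion extraction and matching (prior output lives on the
  # current grid already, so the graph uses the identity transform)
  currentLesions <- extractLesions(binarize(probs$current, threshold), roi,
                                   timepoint = "current")
  priorLesions <- NULL
  graph <- NULL
  report <- NULL
  if (!is.null(probs$prior)) {
    priorLesions <- extractLesions(binarize(probs$prior, threshold), roi,
                                   timepoint = "prior")
    graph <- buildMatchingGraph(priorLesions, currentLesions,
                                rigidTransform())
    report <- classifyChanges(graph)
    report <- quantifyChanges(report, graph, priorLesions, currentLesions)
  }

  result <- list(transform = transform, roi = roi,
                 probabilities = probs, currentLesions = currentLesions,
                 priorLesions = priorLesions, graph = graph, report = report,
                 scenario = scenario, seed = as.integer(seed))

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeVolume(currentLesions@labels,
                file.path(outDir, "current_lesions.nii.gz"))
    writeVolume(roi, file.path(outDir, "brain_roi.nii.gz"))
    if (!is.null(priorLesions))
      writeVolume(priorLesions@labels,
                  file.path(outDir, "prior_lesions.nii.gz"))
    writeTransform(transform, file.path(outDir, "transform.json"))
    writeLesionTable(currentLesions, file.path(outDir, "current_lesions.csv"))
    if (!is.null(report)) writeChangeReport(report, graph, outDir)
    cfg <- list(scenario = scenario, threshold = threshold,
                patchSize = as.integer(patchSize), seed = as.integer(seed),
                registration = registrationCfg,
                model = list(inChannels = model@inChannels,
                             outChannels = model@outChannels,
                             levels = model@levels,
                             baseFilters = model@baseFilters,
                             seed = model@seed))
    cfgJson <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(config = cfg,
                              config_hash = fnv1a(as.character(cfgJson))),
                         file.path(outDir, "run_log.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  result
}
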