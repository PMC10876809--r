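# Evaluation metrics: size-stratified detection precision/recall with greedy
# one-to-one lesion matching, Dice, average symmetric surface distance,
# matching-edge and change-class precision/recall, and the two-sample
# scenario comparison t-test.

sizeClassPredicate <- function(sizeClass, thresholds = c(5, 10)) {
  switch(sizeClass,
         ">10mm" = function(d) d > thresholds[2],
         ">5mm" = function(d) d > thresholds[1],
         "<10mm" = function(d) d < thresholds[2],
         "All" = function(d) rep(TRUE, length(d)),
         stop("unknown size class: ", sizeClass))
}

# greedy one-to-one assignment of predicted to ground-truth lesions by
# descending voxel overlap; returns matched id pairs
greedyLesionMatch <- function(predLesions, gtLesions) {
  p <- predLesions@labels@voxels
  g <- gtLesions@labels@voxels
  if (!all(dim(p) == dim(g))) stop("lesion sets must share one grid")
  both <- p > 0 & g > 0
  pairs <- data.frame(pred = integer(0), gt = integer(0))
  if (any(both)) {
    tab <- as.data.frame(table(pred = p[both], gt = g[both]),
                         stringsAsFactors = FALSE)
    tab <- tab[tab$Freq > 0, , drop = FALSE]
    tab$pred <- as.integer(tab$pred)
    tab$gt <- as.integer(tab$gt)
    tab <- tab[order(-tab$Freq, tab$pred, tab$gt), , drop = FALSE]
    usedP <- integer(0)
    usedG <- integer(0)
    for (i in seq_len(nrow(tab))) {
      if (tab$pred[i] %in% usedP || tab$gt[i] %in% usedG) next
      pairs <- rbind(pairs, data.frame(pred = tab$pred[i], gt = tab$gt[i]))
      usedP <- c(usedP, tab$pred[i])
      usedG <- c(usedG, tab$gt[i])
    }
  }
  pairs
}

#' Size-stratified lesion detection precision and recall for one scan
#'
#' Predicted lesions are matched one-to-one to ground-truth lesions greedily
#' by descending voxel overlap; a predicted lesion overlapping an unmatched
#' ground-truth lesion in at least one voxel is a true positive, any other
#' prediction a false positive, and unmatched ground-truth lesions are false
#' negatives. Size-class membership is decided by the ground-truth lesion's
#' diameter for TP/FN and by the prediction's own diameter for FP. A scan
#' with no ground-truth lesions and no predictions in the class scores 1.0 on
#' both metrics (nothing to find, nothing found).
#'
#' @param predLesions,gtLesions \linkS4class{LesionSet}s on one grid.
#' @param sizeClass one of ">10mm", ">5mm", "<10mm", "All".
#' @return named numeric c(precision, recall).
#' @export
detectionPR <- function(predLesions, gtLesions, sizeClass = "All") {
  inClass <- sizeClassPredicate(sizeClass)
  pairs <- greedyLesionMatch(predLesions, gtLesions)
  pt <- predLesions@table
  gt <- gtLesions@table
  tpClass <- sum(inClass(gt$diameter_mm[match(pairs$gt, gt$id)]))
  fnIds <- setdiff(gt$id, pairs$gt)
  fnClass <- sum(inClass(gt$diameter_mm[match(fnIds, gt$id)]))
  fpIds <- setdiff(pt$id, pairs$pred)
  fpClass <- sum(inClass(pt$diameter_mm[match(fpIds, pt$id)]))
  precision <- if (tpClass + fpClass == 0) 1 else tpClass / (tpClass + fpClass)
  recall <- if (tpClass + fnClass == 0) 1 else tpClass / (tpClass + fnClass)
  c(precision = precision, recall = recall)
}

maskArray <- function(m) if (is(m, "VolumeImage")) m@voxels else m

#' Dice overlap of two masks
#'
#' 2|A n B| / (|A| + |B|); two empty masks give 1.0 by convention (perfect
#' agreement on absence).
#'
#' @param maskA,maskB binary masks (arrays or \linkS4class{BinaryMask}s) on
#'   one grid.
#' @return Dice score in [0, 1].
#' @export
diceCoef <- function(maskA, maskB) {
  a <- maskArray(maskA)
  b <- maskArray(maskB)
  if (!all(dim(a) == dim(b))) stop("masks must share one grid")
  sa <- sum(a != 0)
  sb <- sum(b != 0)
  if (sa + sb == 0) return(1)
  2 * sum(a != 0 & b != 0) / (sa + sb)
}

#' Average symmetric surface distance (mm)
#'
#' Surfaces are the mask voxels with at least one 6-neighbour background
#' voxel; distances are Euclidean between surface-voxel centres in world mm.
#' ASSD = (sum of A-to-B nearest distances + sum of B-to-A nearest distances)
#' divided by the total surface voxel count. Computed only between non-empty
#' masks (the per-lesion metric is evaluated on detected pairs).
#'
#' @param maskA,maskB non-empty binary masks on one grid.
#' @param spacing voxel spacing in mm; taken from the masks when they are
#'   \linkS4class{BinaryMask}s.
#' @return ASSD in mm.
#' @export
assd <- function(maskA, maskB, spacing = NULL) {
  if (is.null(spacing)) {
    if (is(maskA, "VolumeImage")) spacing <- maskA@spacing
    else stop("spacing required for plain-array masks")
  }
  a <- maskArray(maskA)
  b <- maskArray(maskB)
  if (!all(dim(a) == dim(b))) stop("masks must share one grid")
  if (sum(a != 0) == 0 || sum(b != 0) == 0)
    stop("assd requires two non-empty masks")
  sa <- .surface_voxels((a != 0) * 1)
  sb <- .surface_voxels((b != 0) * 1)
  saMM <- sweep(sa, 2, spacing, "*")
  sbMM <- sweep(sb, 2, spacing, "*")
  (.sum_min_dist(saMM, sbMM) + .sum_min_dist(sbMM, saMM)) /
    (nrow(sa) + nrow(sb))
}

edgeKeys <- function(graph) {
  e <- graph@edges
  if (!nrow(e)) character(0) else paste(e$prior, e$current, sep = "->")
}

#' Matching-edge precision and recall
#'
#' A true-positive edge is present in both the ground-truth and the computed
#' graph; a false-positive edge is computed but not in the ground truth; a
#' false-negative edge is in the ground truth but missing from the computed
#' graph.
#'
#' @param computed,gt \linkS4class{MatchingGraph}s over aligned lesion id
#'   spaces.
#' @return named numeric c(precision, recall); an empty side counts as 1.0.
#' @export
graphEdgePR <- function(computed, gt) {
  ce <- edgeKeys(computed)
  ge <- edgeKeys(gt)
  tp <- length(intersect(ce, ge))
  precision <- if (!length(ce)) 1 else tp / length(ce)
  recall <- if (!length(ge)) 1 else tp / length(ge)
  c(precision = precision, recall = recall)
}

#' Per-class change-classification precision and recall
#'
#' Lesions are identified across the two reports by (timepoint, id); for each
#' change class c, precision = |computed_c n gt_c| / |computed_c| and
#' recall = |computed_c n gt_c| / |gt_c|. Classes empty on one side are
#' reported as 1.0 with an "empty" flag attribute.
#'
#' @param computed,gt \linkS4class{ChangeReport}s with aligned lesion ids.
#' @return data.frame(class, precision, recall) with attribute "empty_classes".
#' @export
changeClassPR <- function(computed, gt) {
  key <- function(df) paste(df$timepoint, df$id, sep = ":")
  emptyClasses <- character(0)
  out <- lapply(c("existing", "new", "disappeared"), function(cl) {
    cs <- key(computed@classes[computed@classes$class == cl, , drop = FALSE])
    gs <- key(gt@classes[gt@classes$class == cl, , drop = FALSE])
    tp <- length(intersect(cs, gs))
    if (!length(cs) || !length(gs))
      emptyClasses <<- c(emptyClasses, cl)
    data.frame(class = cl,
               precision = if (!length(cs)) 1 else tp / length(cs),
               recall = if (!length(gs)) 1 else tp / length(gs))
  })
  res <- do.call(rbind, out)
  attr(res, "empty_classes") <- emptyClasses
  res
}

#' Two-sample scenario comparison (Student t-test, pooled variance)
#'
#' Independent two-tailed t-test between per-scan metric values of two
#' scenarios, with the significance threshold (0.01) reported alongside.
#'
#' @param metricA,metricB numeric vectors of per-scan metric values, each of
#'   length >= 2.
#' @param alpha significance threshold (default 0.01).
#' @return list(t, p, significant, alpha).
#' @export
compareScenarios <- function(metricA, metricB, alpha = 0.01) {
  stopifnot(length(metricA) >= 2, length(metricB) >= 2)
  n1 <- length(metricA); n2 <- length(metricB)
  pooled <- ((n1 - 1) * var(metricA) + (n2 - 1) * var(metricB)) / (n1 + n2 - 2)
  if (pooled == 0) stop("zero pooled variance: t statistic undefined")
  tt <- t.test(metricA, metricB, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       significant = tt$p.value < alpha, alpha = alpha)
}

#' Mean and standard deviation of per-scan detection metrics
#'
#' Convenience aggregation across scans: applies \code{\link{detectionPR}}
#' per scan and size class and reports mean and standard deviation, the
#' layout used for detection result tables.
#'
#' @param predList,gtList lists of per-scan \linkS4class{LesionSet}s.
#' @param sizeClasses character vector of size classes.
#' @return data.frame(class, precision_mean, precision_sd, recall_mean,
#'   recall_sd, n_scans).
#' @export
detectionSummary <- function(predList, gtList,
                             sizeClasses = c(">10mm", ">5mm", "<10mm", "All")) {
  stopifnot(length(predList) == length(gtList))
  do.call(rbind, lapply(sizeClasses, function(cl) {
    pr <- vapply(seq_along(predList), function(i)
      detectionPR(predList[[i]], gtList[[i]], cl), numeric(2))
    data.frame(class = cl,
               precision_mean = mean(pr[1, ]), precision_sd = sd(pr[1, ]),
               recall_mean = mean(pr[2, ]), recall_sd = sd(pr[2, ]),
               n_scans = length(predList))
  }))
}
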