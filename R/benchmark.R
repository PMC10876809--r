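# Published clinical benchmark numbers for the four inference scenarios
# (simultaneous with prior / simultaneous / standalone pairs / standalone
# single), by lesion size class. Shipped as data so the reported relative
# precision improvements can be recomputed from their inputs.

#' Published per-scenario detection and segmentation benchmark
#'
#' Mean and standard deviation of detection precision/recall and
#' segmentation Dice/ASSD for the four inference scenarios on the clinical
#' test set, stratified by sphere-equivalent diameter class. These numbers
#' come from an evaluation on private clinical data and are used only as
#' inputs to worked-example computations; the package does not reproduce
#' them.
#'
#' @return data.frame with one row per (size class, scenario).
#' @export
publishedBenchmark <- function() {
  read.csv(system.file("extdata", "published_benchmark.csv",
                       package = "longimets"),
           check.names = FALSE, stringsAsFactors = FALSE)
}

#' Relative precision improvement of the prior-informed scenario
#'
#' Computes 100 * (P_best - P_ref) / P_best where P_best is the
#' simultaneous-with-prior detection precision in the given size class and
#' P_ref is the reference precision: either the midrange of the other three
#' scenarios' precisions ("midrange") or the standalone-single baseline
#' ("standalone_single").
#'
#' @param sizeClass one of ">10mm", ">5mm", "<10mm", "All".
#' @param reference "midrange" or "standalone_single".
#' @param benchmark benchmark table (default \code{\link{publishedBenchmark}}).
#' @return improvement in percent.
#' @export
precisionImprovement <- function(sizeClass,
                                 reference = c("midrange",
                                               "standalone_single"),
                                 benchmark = publishedBenchmark()) {
  reference <- match.arg(reference)
  rows <- benchmark[benchmark$size_class == sizeClass, , drop = FALSE]
  if (!nrow(rows)) stop("unknown size class: ", sizeClass)
  best <- rows$precision_mean[rows$scenario == "simultaneous_with_prior"]
  ref <- if (reference == "standalone_single")
    rows$precision_mean[rows$scenario == "standalone_single"]
  else {
    others <- rows$precision_mean[rows$scenario != "simultaneous_with_prior"]
    (min(others) + max(others)) / 2
  }
  100 * (best - ref) / best
}
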