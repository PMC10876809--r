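# Longitudinal analysis: the bipartite lesion-matching graph, change
# classification (existing / new / disappeared) and volumetric quantification
# of lesion changes.

#' Build the bipartite lesion matching graph
#'
#' The prior label mask is resampled onto the current grid through the rigid
#' transform (nearest-neighbour); an edge (i, j) is created whenever resampled
#' prior lesion i and current lesion j share at least one voxel. Lesions left
#' unmatched by voxel overlap are rescued by a centroid-distance criterion
#' (threshold max(3 mm, half the sum of the equivalent radii)), which absorbs
#' slice-thickness effects on thin lesions; rescue edges are marked.
#'
#' @param priorLesions \linkS4class{LesionSet} from the prior scan (on its own
#'   grid).
#' @param currentLesions \linkS4class{LesionSet} from the current scan.
#' @param transform \linkS4class{RigidTransform} mapping prior world to
#'   current world.
#' @return A \linkS4class{MatchingGraph}.
#' @export
buildMatchingGraph <- function(priorLesions, currentLesions, transform) {
  stopifnot(is(priorLesions, "LesionSet"), is(currentLesions, "LesionSet"))
  curLab <- currentLesions@labels
  priorOnCur <- applyTransform(priorLesions@labels, transform,
                               target = curLab, interpolation = "nearest")
  p <- priorOnCur@voxels
  q <- curLab@voxels
  both <- p > 0 & q > 0
  edges <- data.frame(prior = integer(0), current = integer(0),
                      overlap = integer(0), rescued = logical(0))
  if (any(both)) {
    tab <- table(prior = p[both], current = q[both])
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    df <- df[df$Freq > 0, , drop = FALSE]
    edges <- data.frame(prior = as.integer(df$prior),
                        current = as.integer(df$current),
                        overlap = as.integer(df$Freq), rescued = FALSE)
  }
  pt <- priorLesions@table
  ct <- currentLesions@table
  unmatchedP <- setdiff(pt$id, edges$prior)
  unmatchedC <- setdiff(ct$id, edges$current)
  if (length(unmatchedP) && length(unmatchedC)) {
    pCent <- transformPoints(transform, as.matrix(
      pt[match(unmatchedP, pt$id), c("centroid_x", "centroid_y", "centroid_z")]))
    cCent <- as.matrix(
      ct[match(unmatchedC, ct$id), c("centroid_x", "centroid_y", "centroid_z")])
    for (a in seq_along(unmatchedP))
      for (b in seq_along(unmatchedC)) {
        dist <- sqrt(sum((pCent[a, ] - cCent[b, ])^2))
        rSum <- pt$diameter_mm[match(unmatchedP[a], pt$id)] / 2 +
          ct$diameter_mm[match(unmatchedC[b], ct$id)] / 2
        if (dist < max(3, 0.5 * rSum))
          edges <- rbind(edges, data.frame(
            prior = unmatchedP[a], current = unmatchedC[b],
            overlap = 0L, rescued = TRUE))
      }
  }
  rownames(edges) <- NULL
  new("MatchingGraph", priorNodes = as.integer(pt$id),
      currentNodes = as.integer(ct$id), edges = edges)
}

#' Classify lesion changes from the matching graph
#'
#' A prior lesion with at least one edge is existing (persistent), with none
#' disappeared; a current lesion with at least one edge is existing, with none
#' new.
#'
#' @param graph A \linkS4class{MatchingGraph}.
#' @return A \linkS4class{ChangeReport} with classes and scan-level counts
#'   (volumetrics are filled in by \code{\link{quantifyChanges}}).
#' @export
classifyChanges <- function(graph) {
  pClass <- ifelse(graph@priorNodes %in% graph@edges$prior, "existing",
                   "disappeared")
  cClass <- ifelse(graph@currentNodes %in% graph@edges$current, "existing",
                   "new")
  classes <- rbind(
    if (length(graph@priorNodes)) data.frame(
      timepoint = "prior", id = graph@priorNodes, class = pClass) else NULL,
    if (length(graph@currentNodes)) data.frame(
      timepoint = "current", id = graph@currentNodes, class = cClass)
    else NULL)
  if (is.null(classes))
    classes <- data.frame(timepoint = character(0), id = integer(0),
                          class = character(0))
  counts <- list(
    prior_total = length(graph@priorNodes),
    current_total = length(graph@currentNodes),
    existing_prior = sum(pClass == "existing"),
    disappeared = sum(pClass == "disappeared"),
    existing_current = sum(cClass == "existing"),
    new = sum(cClass == "new"))
  new("ChangeReport", classes = classes,
      groups = data.frame(), counts = counts, totals = list())
}

# connected components of the bipartite graph via union-find
graphComponents <- function(graph) {
  nodes <- c(paste0("p", graph@priorNodes, recycle0 = TRUE),
             paste0("c", graph@currentNodes, recycle0 = TRUE))
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (nrow(graph@edges))
    for (i in seq_len(nrow(graph@edges))) {
      a <- find(paste0("p", graph@edges$prior[i]))
      b <- find(paste0("c", graph@edges$current[i]))
      if (a != b) parent[[a]] <- b
    }
  roots <- vapply(nodes, find, character(1))
  split(nodes, roots)
}

#' Quantify volumetric lesion changes per matched group
#'
#' Groups are the connected components of the matching graph (so splits and
#' merges are quantified jointly). Each group reports the summed prior and
#' current volumes (cc), the absolute change and the relative change
#' (100 * delta / prior); groups with no prior lesion ("new") have an
#' undefined relative change, reported as NA.
#'
#' @param report \linkS4class{ChangeReport} from \code{\link{classifyChanges}}.
#' @param graph the \linkS4class{MatchingGraph} the report came from.
#' @param priorLesions,currentLesions the \linkS4class{LesionSet}s.
#' @return the completed \linkS4class{ChangeReport} with groups and per-scan
#'   volume totals.
#' @export
quantifyChanges <- function(report, graph, priorLesions, currentLesions) {
  comps <- graphComponents(graph)
  pt <- priorLesions@table
  ct <- currentLesions@table
  rows <- lapply(seq_along(comps), function(i) {
    members <- comps[[i]]
    pIds <- as.integer(sub("^p", "", members[startsWith(members, "p")]))
    cIds <- as.integer(sub("^c", "", members[startsWith(members, "c")]))
    priorCc <- sum(pt$volume_cc[pt$id %in% pIds])
    currentCc <- sum(ct$volume_cc[ct$id %in% cIds])
    kind <- if (!length(pIds)) "new"
            else if (!length(cIds)) "disappeared" else "existing"
    data.frame(
      group = i,
      prior_ids = paste(sort(pIds), collapse = ";"),
      current_ids = paste(sort(cIds), collapse = ";"),
      kind = kind, prior_cc = priorCc, current_cc = currentCc,
      delta_cc = currentCc - priorCc,
      delta_pct = if (priorCc > 0) 100 * (currentCc - priorCc) / priorCc
                  else NA_real_)
  })
  groups <- if (length(rows)) do.call(rbind, rows)
            else data.frame(group = integer(0), prior_ids = character(0),
                            current_ids = character(0), kind = character(0),
                            prior_cc = numeric(0), current_cc = numeric(0),
                            delta_cc = numeric(0), delta_pct = numeric(0))
  report@groups <- groups
  report@totals <- list(prior_cc = sum(pt$volume_cc),
                        current_cc = sum(ct$volume_cc))
  validObject(report)
  report
}

#' Write a change report to disk
#'
#' Writes a machine-readable JSON report (graph, classes, counts, volumetric
#' groups) and a human-readable CSV group summary.
#'
#' @param report a completed \linkS4class{ChangeReport}.
#' @param graph the corresponding \linkS4class{MatchingGraph}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeChangeReport <- function(report, graph, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(
    edges = graph@edges, classes = report@classes, counts = report@counts,
    groups = report@groups, totals = report@totals
  ), file.path(dir, "change_report.json"), digits = NA, auto_unbox = FALSE,
    na = "null")
  write.csv(report@groups, file.path(dir, "change_groups.csv"),
            row.names = FALSE)
  invisible(dir)
}
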