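# helpers building LesionSets directly from hand-placed blocks
blockMask <- function(dim, blocks) {
  v <- array(0, dim)
  for (b in blocks)
    v[b$x[1]:b$x[2], b$y[1]:b$y[2], b$z[1]:b$z[2]] <- 1
  v
}

makeSet <- function(dim, blocks, timepoint) {
  geom <- volumeImage(array(0, dim), spacing = c(1, 1, 1))
  extractLesions(binaryMask(blockMask(dim, blocks), geom), roi = NULL,
                 timepoint = timepoint, minVoxels = 1)
}

test_that("coincident lesions match one-to-one and the extra one is new", {
  d <- c(28, 28, 28)
  # prior: lesions 1 (large) and 2; current: B and D coincide with them,
  # A is somewhere else entirely
  prior <- makeSet(d, list(
    list(x = c(4, 9), y = c(4, 9), z = c(4, 9)),       # "1"
    list(x = c(18, 21), y = c(18, 21), z = c(18, 21))   # "2"
  ), "prior")
  current <- makeSet(d, list(
    list(x = c(4, 9), y = c(4, 9), z = c(4, 9)),       # "B"
    list(x = c(18, 21), y = c(18, 21), z = c(18, 21)),  # "D"
    list(x = c(4, 6), y = c(18, 20), z = c(4, 6))       # "A"
  ), "current")
  g <- buildMatchingGraph(prior, current, rigidTransform())
  e <- graphEdges(g)
  expect_equal(nrow(e), 2)
  expect_false(any(e$rescued))
  # pairings follow spatial coincidence: match ids via centroids
  pt <- lesionTable(prior)
  ct <- lesionTable(current)
  for (i in seq_len(nrow(e))) {
    pc <- pt[pt$id == e$prior[i], c("centroid_x", "centroid_y", "centroid_z")]
    cc <- ct[ct$id == e$current[i], c("centroid_x", "centroid_y", "centroid_z")]
    expect_lt(sqrt(sum((pc - cc)^2)), 1e-9)
  }
  rep <- classifyChanges(g)
  cl <- changeClasses(rep)
  expect_equal(sum(cl$class == "existing"), 4)  # both prior + their matches
  expect_equal(sum(cl$class == "new"), 1)
  expect_equal(sum(cl$class == "disappeared"), 0)
  cnt <- changeCounts(rep)
  expect_equal(cnt$prior_total, cnt$existing_prior + cnt$disappeared)
  expect_equal(cnt$current_total, cnt$existing_current + cnt$new)
})

test_that("identical timepoints give a perfect one-to-one matching", {
  st <- smallStudy()
  set <- lesionSetFromLabels(st@currentMask, "current")
  setP <- lesionSetFromLabels(st@currentMask, "prior")
  g <- buildMatchingGraph(setP, set, rigidTransform())
  expect_equal(nrow(graphEdges(g)), nrow(lesionTable(set)))
  expect_equal(graphEdges(g)$prior, graphEdges(g)$current)
})

test_that("a split lesion produces two edges from one prior node", {
  d <- c(24, 24, 24)
  prior <- makeSet(d, list(list(x = c(6, 17), y = c(8, 13), z = c(8, 13))),
                   "prior")
  current <- makeSet(d, list(
    list(x = c(6, 10), y = c(8, 13), z = c(8, 13)),
    list(x = c(13, 17), y = c(8, 13), z = c(8, 13))
  ), "current")
  g <- buildMatchingGraph(prior, current, rigidTransform())
  e <- graphEdges(g)
  expect_equal(nrow(e), 2)
  expect_equal(unique(e$prior), 1L)
  rep <- classifyChanges(g)
  rep <- quantifyChanges(rep, g, prior, current)
  expect_equal(nrow(changeGroups(rep)), 1)  # split quantified jointly
})

test_that("nearby non-overlapping lesions are rescued by centroid distance", {
  d <- c(24, 24, 24)
  prior <- makeSet(d, list(list(x = c(8, 9), y = c(8, 10), z = c(8, 10))),
                   "prior")
  current <- makeSet(d, list(list(x = c(10, 11), y = c(8, 10), z = c(8, 10))),
                     "current")
  g <- buildMatchingGraph(prior, current, rigidTransform())
  e <- graphEdges(g)
  expect_equal(nrow(e), 1)
  expect_true(e$rescued)
  expect_equal(e$overlap, 0L)
})

test_that("volumetric quantification reports absolute and relative change", {
  d <- c(24, 24, 24)
  # 500 voxels = 0.5 cc at 1 mm isotropic, growing to 750 voxels = 0.75 cc
  prior <- makeSet(d, list(list(x = c(5, 14), y = c(5, 14), z = c(5, 9))),
                   "prior")
  current <- makeSet(d, list(list(x = c(5, 14), y = c(5, 14), z = c(5, 12)),
                             list(x = c(20, 22), y = c(20, 22), z = c(20, 22))),
                     "current")
  expect_equal(lesionTable(prior)$volume_cc, 0.5)
  g <- buildMatchingGraph(prior, current, rigidTransform())
  rep <- quantifyChanges(classifyChanges(g), g, prior, current)
  grp <- changeGroups(rep)
  matched <- grp[grp$kind == "existing", ]
  expect_equal(matched$prior_cc, 0.5)
  expect_equal(matched$current_cc, 0.8)
  expect_equal(matched$delta_cc, 0.3)
  expect_equal(matched$delta_pct, 60)
  newGrp <- grp[grp$kind == "new", ]
  expect_equal(newGrp$prior_cc, 0)
  expect_true(is.na(newGrp$delta_pct))
  # totals are conserved sums of per-lesion volumes
  expect_equal(rep@totals$current_cc, sum(lesionTable(current)$volume_cc))
})

test_that("an empty current scan classifies every prior lesion as disappeared", {
  d <- c(24, 24, 24)
  prior <- makeSet(d, list(list(x = c(5, 10), y = c(5, 10), z = c(5, 10))),
                   "prior")
  current <- makeSet(d, list(), "current")
  g <- buildMatchingGraph(prior, current, rigidTransform())
  rep <- quantifyChanges(classifyChanges(g), g, prior, current)
  expect_equal(changeCounts(rep)$disappeared, 1)
  grp <- changeGroups(rep)
  expect_equal(grp$kind, "disappeared")
  expect_equal(grp$delta_pct, -100)
  expect_equal(grp$delta_cc, -lesionTable(prior)$volume_cc)
})

test_that("matching is consistent under the inverse transform on phantoms", {
  st <- smallStudy()
  priorSet <- lesionSetFromLabels(st@priorMask, "prior")
  currentSet <- lesionSetFromLabels(st@currentMask, "current")
  g1 <- buildMatchingGraph(priorSet, currentSet, st@gtTransform)
  # rebuild in the prior frame: current lesions mapped backwards
  g2 <- buildMatchingGraph(currentSet, priorSet,
                           invertTransform(st@gtTransform))
  e1 <- graphEdges(g1)[, c("prior", "current")]
  e2 <- graphEdges(g2)[, c("current", "prior")]
  names(e2) <- c("prior", "current")
  expect_equal(e1[order(e1$prior, e1$current), ],
               e2[order(e2$prior, e2$current), ],
               ignore_attr = TRUE)
})

test_that("change reports serialise to disk", {
  st <- smallStudy()
  priorSet <- lesionSetFromLabels(st@priorMask, "prior")
  currentSet <- lesionSetFromLabels(st@currentMask, "current")
  g <- buildMatchingGraph(priorSet, currentSet, st@gtTransform)
  rep <- quantifyChanges(classifyChanges(g), g, priorSet, currentSet)
  dir <- tempfile()
  writeChangeReport(rep, g, dir)
  expect_true(file.exists(file.path(dir, "change_report.json")))
  back <- jsonlite::read_json(file.path(dir, "change_report.json"),
                              simplifyVector = TRUE)
  expect_equal(nrow(back$edges), nrow(graphEdges(g)))
})
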