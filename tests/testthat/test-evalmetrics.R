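lesionsFromBlocks <- function(dim, blocks, timepoint = "current") {
  v <- array(0, dim)
  for (b in blocks)
    v[b$x[1]:b$x[2], b$y[1]:b$y[2], b$z[1]:b$z[2]] <- 1
  geom <- volumeImage(array(0, dim))
  extractLesions(binaryMask(v, geom), roi = NULL, timepoint = timepoint,
                 minVoxels = 1)
}

test_that("detection precision/recall follow the one-to-one matching rules", {
  d <- c(30, 30, 30)
  gt <- lesionsFromBlocks(d, list(
    list(x = c(4, 7), y = c(4, 7), z = c(4, 7)),
    list(x = c(14, 17), y = c(14, 17), z = c(14, 17)),
    list(x = c(24, 27), y = c(24, 27), z = c(24, 27))))
  # perfect predictions
  expect_equal(unname(detectionPR(gt, gt, "All")), c(1, 1))
  # 2 hits + 1 spurious: precision 2/3, recall 2/3
  pred <- lesionsFromBlocks(d, list(
    list(x = c(4, 7), y = c(4, 7), z = c(4, 7)),
    list(x = c(14, 17), y = c(14, 17), z = c(14, 17)),
    list(x = c(24, 27), y = c(4, 7), z = c(24, 27))))
  pr <- detectionPR(pred, gt, "All")
  expect_equal(unname(pr), c(2 / 3, 2 / 3))
  # two disjoint predictions on one GT lesion: one TP, one FP
  pred2 <- lesionsFromBlocks(d, list(
    list(x = c(4, 7), y = c(4, 7), z = c(4, 5)),
    list(x = c(4, 7), y = c(4, 7), z = c(7, 8))))
  pr2 <- detectionPR(pred2, gt, "All")
  expect_equal(unname(pr2), c(1 / 2, 1 / 3))
  # both empty in a class: defined as 1.0
  none <- lesionsFromBlocks(d, list())
  expect_equal(unname(detectionPR(none, none, ">10mm")), c(1, 1))
})

test_that("greedy matching is one-to-one on random lesion fields", {
  set.seed(31)
  for (i in 1:5) {
    d <- c(20, 20, 20)
    geom <- volumeImage(array(0, d))
    mk <- function() binaryMask(randomBlobMask(d, nBlobs = 3), geom)
    p <- extractLesions(mk(), minVoxels = 1)
    g <- extractLesions(mk(), minVoxels = 1)
    pairs <- longimets:::greedyLesionMatch(p, g)
    expect_equal(anyDuplicated(pairs$pred), 0)
    expect_equal(anyDuplicated(pairs$gt), 0)
  }
})

test_that("precision never rises with spurious predictions; recall never falls with hits", {
  d <- c(30, 30, 30)
  gt <- lesionsFromBlocks(d, list(list(x = c(4, 7), y = c(4, 7), z = c(4, 7)),
                                  list(x = c(14, 17), y = c(14, 17),
                                       z = c(14, 17))))
  hit1 <- list(x = c(4, 7), y = c(4, 7), z = c(4, 7))
  spurious <- list(x = c(24, 27), y = c(24, 27), z = c(24, 27))
  hit2 <- list(x = c(14, 17), y = c(14, 17), z = c(14, 17))
  p1 <- detectionPR(lesionsFromBlocks(d, list(hit1)), gt, "All")
  p2 <- detectionPR(lesionsFromBlocks(d, list(hit1, spurious)), gt, "All")
  expect_lte(p2[["precision"]], p1[["precision"]])
  p3 <- detectionPR(lesionsFromBlocks(d, list(hit1, hit2)), gt, "All")
  expect_gte(p3[["recall"]], p1[["recall"]])
})

test_that("Dice matches arithmetic cases and is symmetric", {
  a <- array(0, c(10, 10, 10)); a[1:2, 1:2, 1:2] <- 1   # 8 voxels
  b <- array(0, c(10, 10, 10)); b[1:2, 1:2, 2:3] <- 1   # 8 voxels, overlap 4
  expect_equal(diceCoef(a, a), 1)
  expect_equal(diceCoef(a, b), 0.5)
  z <- array(0, c(10, 10, 10))
  expect_equal(diceCoef(a, z), 0)
  expect_equal(diceCoef(z, z), 1)  # empty-vs-empty convention
  set.seed(4)
  for (i in 1:5) {
    m1 <- randomBlobMask()
    m2 <- randomBlobMask()
    expect_equal(diceCoef(m1, m2), diceCoef(m2, m1))
  }
})

test_that("ASSD matches arithmetic cases and the brute-force oracle", {
  d <- c(12, 12, 12)
  a <- array(0, d); a[3, 3, 3] <- 1
  b <- array(0, d); b[6, 3, 3] <- 1
  expect_equal(assd(a, a, spacing = c(1, 1, 1)), 0)
  expect_equal(assd(a, b, spacing = c(1, 1, 1)), 3)
  # anisotropic spacing turns 3 voxels into 9 mm along z
  b2 <- array(0, d); b2[3, 3, 6] <- 1
  expect_equal(assd(a, b2, spacing = c(1, 1, 3)), 9)
  set.seed(9)
  for (i in 1:10) {
    m1 <- randomBlobMask()
    m2 <- randomBlobMask()
    sp <- c(1, runif(1, 0.5, 2), runif(1, 0.5, 3))
    expect_equal(assd(m1, m2, spacing = sp), oracleASSD(m1, m2, sp),
                 tolerance = 1e-9)
    expect_equal(assd(m1, m2, spacing = sp), assd(m2, m1, spacing = sp))
  }
  expect_error(assd(a, array(0, d), spacing = c(1, 1, 1)), "non-empty")
})

test_that("edge precision/recall are set arithmetic on the graphs", {
  mkGraph <- function(edges, np = 2L, nc = 4L)
    new("MatchingGraph", priorNodes = seq_len(np), currentNodes = seq_len(nc),
        edges = data.frame(prior = edges$p, current = edges$c,
                           overlap = 5L, rescued = FALSE))
  gt <- mkGraph(list(p = c(1L, 2L), c = c(2L, 4L)))
  expect_equal(unname(graphEdgePR(gt, gt)), c(1, 1))
  half <- mkGraph(list(p = 1L, c = 2L))
  expect_equal(unname(graphEdgePR(half, gt)), c(1, 0.5))
  extra <- mkGraph(list(p = c(1L, 2L, 2L), c = c(2L, 4L, 3L)))
  expect_equal(unname(graphEdgePR(extra, gt)), c(2 / 3, 1))
})

test_that("change-class precision/recall compare per-lesion labels", {
  mkRep <- function(classes)
    new("ChangeReport", classes = classes, groups = data.frame(),
        counts = list(), totals = list())
  gt <- mkRep(data.frame(
    timepoint = c("prior", "prior", "current", "current"),
    id = c(1L, 2L, 1L, 2L),
    class = c("existing", "disappeared", "existing", "new")))
  perfect <- changeClassPR(gt, gt)
  expect_true(all(perfect$precision == 1) && all(perfect$recall == 1))
  # one existing current lesion miscalled as new
  wrong <- mkRep(data.frame(
    timepoint = c("prior", "prior", "current", "current"),
    id = c(1L, 2L, 1L, 2L),
    class = c("existing", "disappeared", "new", "new")))
  pr <- changeClassPR(wrong, gt)
  expect_lt(pr$recall[pr$class == "existing"], 1)
  expect_lt(pr$precision[pr$class == "new"], 1)
  # single-class degenerate case
  one <- mkRep(data.frame(timepoint = "current", id = 1L, class = "new"))
  prOne <- changeClassPR(one, one)
  expect_equal(prOne$precision[prOne$class == "new"], 1)
  expect_true("existing" %in% attr(prOne, "empty_classes"))
})

test_that("scenario comparison agrees with the textbook pooled t-test", {
  a <- c(1, 2, 3)
  b <- c(2, 4, 7)
  res <- compareScenarios(a, b)
  oracle <- oracleStudentT(a, b)
  expect_equal(res$t, unname(oracle["t"]), tolerance = 1e-9)
  expect_equal(res$p, unname(oracle["p"]), tolerance = 1e-9)
  same <- compareScenarios(c(1, 2, 3), c(3, 2, 1))
  expect_equal(same$t, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)
  far <- compareScenarios(c(1, 2, 3), c(11, 12, 13))
  expect_true(abs(far$t) > 5 && far$p < 0.01 && far$significant)
  expect_error(compareScenarios(c(1, 1), c(1, 1)), "variance")
})

test_that("precision improvements recompute the published worked examples", {
  expect_equal(precisionImprovement("All", "midrange"),
               (0.83 - 0.765) / 0.83 * 100, tolerance = 1e-12)
  expect_equal(precisionImprovement("<10mm", "standalone_single"),
               (0.72 - 0.63) / 0.72 * 100, tolerance = 1e-12)
})
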