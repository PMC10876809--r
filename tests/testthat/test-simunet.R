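test_that("channel variants share the backbone except the first convolution", {
  m1 <- buildModel(1, levels = 3, baseFilters = 4, outChannels = 1, seed = 2)
  m2 <- buildModel(2, levels = 3, baseFilters = 4, outChannels = 1, seed = 2)
  s1 <- modelLayerShapes(m1)
  s2 <- modelLayerShapes(m2)
  expect_setequal(names(s1), names(s2))
  for (nm in names(s1)) {
    if (grepl("enc.1.conv1.W", nm, fixed = TRUE)) {
      expect_equal(s1[[nm]][4], 1)
      expect_equal(s2[[nm]][4], 2)
      expect_equal(s1[[nm]][-4], s2[[nm]][-4])
    } else {
      expect_equal(s1[[nm]], s2[[nm]], info = nm)
    }
  }
  # parameter count difference is exactly the extra input-channel kernel
  expect_equal(modelParameterCount(m2) - modelParameterCount(m1), 27 * 4)
  expect_error(buildModel(4), "1, 2 or 3")
})

test_that("weight initialisation is seeded and reproducible", {
  a <- buildModel(2, levels = 2, baseFilters = 2, seed = 11)
  b <- buildModel(2, levels = 2, baseFilters = 2, seed = 11)
  expect_identical(a@weights, b@weights)
  c <- buildModel(2, levels = 2, baseFilters = 2, seed = 12)
  expect_false(identical(a@weights, c@weights))
})

test_that("forward pass produces probabilities strictly inside (0,1)", {
  m <- buildModel(2, levels = 2, baseFilters = 2, seed = 1)
  z <- volumeImage(array(0, c(16, 16, 16)))
  p <- predictPair(m, z, z, patchSize = 16)
  expect_true(all(p$current@voxels > 0 & p$current@voxels < 1))
  expect_equal(dim(p$current@voxels), c(16, 16, 16))
})

test_that("patch sampling honours the lesion fraction and stays aligned", {
  st <- smallStudy()
  prep <- prepareTrainingStudy(st)
  batch <- samplePatches(prep, 16, lesionFraction = 1, n = 10, seed = 3)
  for (s in batch) {
    expect_gt(sum(s$gtCurrent), 0)
    # channel alignment: the prior patch is the registered prior volume read
    # at exactly the same indices
    idx <- s$start
    expect_identical(s$prior,
                     prep$prior[idx[1]:(idx[1] + 15), idx[2]:(idx[2] + 15),
                                idx[3]:(idx[3] + 15)])
  }
  # with lesionFraction 0, centres are uniform in the ROI and the rate of
  # positive-containing patches follows the exact per-centre probability
  # (computed by enumerating every possible centre) up to binomial noise
  batch0 <- samplePatches(prep, 16, lesionFraction = 0, n = 200, seed = 4)
  hasLesion <- vapply(batch0, function(s) sum(s$gtCurrent) > 0, logical(1))
  d <- dim(prep$gtCurrent)
  cs <- apply(prep$gtCurrent, c(2, 3), cumsum)
  cs <- aperm(apply(cs, c(1, 3), cumsum), c(2, 1, 3))
  cs <- aperm(apply(cs, c(1, 2), cumsum), c(2, 3, 1))
  pad <- array(0, d + 1)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- cs
  boxHasLesion <- function(center) {
    s <- pmin(pmax(center - 8L, 1L), d - 15L)
    e <- s + 16L  # 1-based inclusive end + 1, for the padded cumsum
    tot <- pad[e[1], e[2], e[3]] - pad[s[1], e[2], e[3]] -
      pad[e[1], s[2], e[3]] - pad[e[1], e[2], s[3]] +
      pad[s[1], s[2], e[3]] + pad[s[1], e[2], s[3]] +
      pad[e[1], s[2], s[3]] - pad[s[1], s[2], s[3]]
    tot > 0
  }
  centers <- arrayInd(which(prep$roi > 0), d)
  pExp <- mean(apply(centers, 1, boxHasLesion))
  expect_lt(abs(mean(hasLesion) - pExp),
            3 * sqrt(pExp * (1 - pExp) / 200) + 0.01)
  emptyPrep <- prep
  emptyPrep$gtCurrent <- array(0, dim(prep$gtCurrent))
  expect_error(samplePatches(emptyPrep, 16, 1, 1), "empty")
})

test_that("zero training steps leave the model untouched", {
  st <- smallStudy()
  prep <- prepareTrainingStudy(st)
  m <- buildModel(2, levels = 2, baseFilters = 2, seed = 1)
  out <- trainModel(m, list(prep), trainConfig(patchSize = 16, steps = 0))
  expect_identical(out@weights, m@weights)
})

test_that("training is deterministic and reduces the loss", {
  st <- smallStudy()
  prep <- prepareTrainingStudy(st)
  m <- buildModel(2, levels = 2, baseFilters = 2, seed = 1)
  cfg <- trainConfig(patchSize = 16, batchSize = 1, steps = 30, lr = 3e-3,
                     seed = 13)
  a <- trainModel(m, list(prep), cfg)
  b <- trainModel(m, list(prep), cfg)
  expect_equal(attr(a, "history"), attr(b, "history"), tolerance = 1e-6)
  expect_identical(a@weights, b@weights)
  h <- attr(a, "history")
  expect_lt(mean(tail(h, 5)), mean(head(h, 5)))
})

test_that("a window equal to the volume reduces to a single forward pass", {
  m <- buildModel(2, levels = 2, baseFilters = 2, seed = 4)
  set.seed(8)
  v <- volumeImage(array(rnorm(16^3), c(16, 16, 16)))
  w <- volumeImage(array(rnorm(16^3), c(16, 16, 16)))
  p <- predictPair(m, v, w, patchSize = 16)
  x <- array(0, c(16, 16, 16, 2))
  x[, , , 1] <- v@voxels
  x[, , , 2] <- w@voxels
  direct <- longimets:::sigmoidStable(
    longimets:::unetForward(m@weights, x, m@levels)$logits)
  expect_equal(p$current@voxels, direct[, , , 1], tolerance = 1e-12)
  expect_equal(p$prior@voxels, direct[, , , 2], tolerance = 1e-12)
})

test_that("stitched inference has no seams on constant input", {
  m <- buildModel(2, levels = 2, baseFilters = 2, seed = 4)
  v <- volumeImage(array(0.5, c(24, 24, 24)))
  p <- predictPair(m, v, v, patchSize = 16)$current@voxels
  interior <- p[5:20, 5:20, 5:20]
  expect_lt(max(interior) - min(interior), 0.05)
})

test_that("inference is translation-consistent by one window stride", {
  m <- buildModel(1, levels = 2, baseFilters = 2, outChannels = 1, seed = 9)
  set.seed(21)
  v <- array(rnorm(16 * 16 * 48), c(16, 16, 48))
  shifted <- array(0, dim(v))
  shifted[, , 9:48] <- v[, , 1:40]
  p1 <- predictPair(m, volumeImage(v), patchSize = 16)$current@voxels
  p2 <- predictPair(m, volumeImage(shifted), patchSize = 16)$current@voxels
  expect_equal(p2[, , 25:32], p1[, , 17:24], tolerance = 1e-10)
})

test_that("standalone-pairs inference duplicates the scan into both channels", {
  m <- buildModel(2, levels = 2, baseFilters = 2, seed = 4)
  set.seed(5)
  v <- volumeImage(array(rnorm(16^3), c(16, 16, 16)))
  a <- predictStandalonePairs(m, v, patchSize = 16)
  b <- predictPair(m, v, v, patchSize = 16)
  expect_identical(a$current@voxels, b$current@voxels)
  m1 <- buildModel(1, levels = 2, baseFilters = 2, seed = 4)
  expect_error(predictStandalonePairs(m1, v), "2-channel")
  expect_error(predictPair(m, v), "prior")
})

test_that("models round-trip through the JSON weight format", {
  m <- buildModel(3, levels = 2, baseFilters = 2, seed = 6)
  path <- tempfile(fileext = ".json")
  saveModel(m, path)
  back <- loadModel(path)
  expect_equal(back@weights, m@weights, tolerance = 1e-12)
  expect_identical(back@inChannels, m@inChannels)
  expect_identical(back@outChannels, m@outChannels)
})
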