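test_that("empty configuration yields empty masks and no edges", {
  st <- generateStudy(phantomConfig(grid_shape = c(32, 32, 32),
                                    n_existing = 0, n_new = 0,
                                    n_disappeared = 0, seed = 3))
  expect_true(all(st@priorMask@voxels == 0))
  expect_true(all(st@currentMask@voxels == 0))
  expect_equal(nrow(st@gtEdges), 0)
})

test_that("component counts match the scripted change scenario", {
  st <- generateStudy(phantomConfig(grid_shape = c(48, 48, 48),
                                    n_existing = 2, n_new = 1,
                                    n_disappeared = 1, seed = 7))
  expect_equal(oracleComponentCount(st@priorMask@voxels != 0), 3)
  expect_equal(oracleComponentCount(st@currentMask@voxels != 0), 3)
  expect_equal(nrow(st@gtEdges), 2)
})

test_that("identical seeds reproduce the study bit-identically; different seeds differ", {
  cfg <- function(s) phantomConfig(grid_shape = c(32, 32, 32), n_existing = 1,
                                   n_new = 1, n_disappeared = 0,
                                   diameter_range_mm = c(5, 7), seed = s)
  a <- generateStudy(cfg(7))
  b <- generateStudy(cfg(7))
  expect_identical(a@currentVolume@voxels, b@currentVolume@voxels)
  expect_identical(a@priorVolume@voxels, b@priorVolume@voxels)
  expect_identical(a@priorMask@voxels, b@priorMask@voxels)
  c <- generateStudy(cfg(8))
  lesCentroid <- function(st) colMeans(which(st@currentMask@voxels == 1,
                                             arr.ind = TRUE))
  expect_gt(max(abs(lesCentroid(a) - lesCentroid(c))), 0.5)
})

test_that("component-count conservation holds over random configurations", {
  set.seed(99)
  for (i in 1:15) {
    ne <- sample(0:3, 1); nn <- sample(0:2, 1); nd <- sample(0:2, 1)
    st <- generateStudy(phantomConfig(
      grid_shape = c(44, 44, 44), n_existing = ne, n_new = nn,
      n_disappeared = nd, diameter_range_mm = c(5, 8), seed = 1000 + i))
    expect_equal(oracleComponentCount(st@priorMask@voxels != 0), ne + nd)
    expect_equal(oracleComponentCount(st@currentMask@voxels != 0), ne + nn)
    expect_equal(nrow(st@gtEdges), ne)
  }
})

test_that("existing lesions overlap their pair after the true transform", {
  st <- smallStudy()
  mapped <- applyTransform(st@priorMask, st@gtTransform,
                           target = st@currentMask, interpolation = "nearest")
  for (i in seq_len(nrow(st@gtEdges))) {
    overlap <- sum(mapped@voxels == st@gtEdges$prior[i] &
                     st@currentMask@voxels == st@gtEdges$current[i])
    expect_gte(overlap, 1)
  }
})

test_that("lesions are hyperintense by at least 80% of the nominal contrast", {
  st <- smallStudy()
  cfg <- st@config
  les <- st@currentMask@voxels > 0
  ext <- cfg$grid_shape * cfg$spacing_mm
  pts <- longimets:::gridWorldCoords(st@currentVolume)
  semi <- longimets:::BRAIN_FRACTION * ext
  brain <- ((pts[, 1] / semi[1])^2 + (pts[, 2] / semi[2])^2 +
              (pts[, 3] / semi[3])^2) <= 1
  tissue <- brain & !as.vector(les)
  delta <- mean(st@currentVolume@voxels[les]) -
    mean(st@currentVolume@voxels[array(tissue, dim(les))])
  expect_gte(delta, 0.8 * cfg$lesion_contrast * cfg$noise_sigma)
})

test_that("invalid configurations and impossible placements fail loudly", {
  expect_error(phantomConfig(grid_shape = c(16, 32, 32)), "32")
  expect_error(phantomConfig(diameter_range_mm = c(1, 5)), "diameter_range_mm")
  expect_error(phantomConfig(n_existing = -1), "counts")
  expect_error(phantomConfig(growth_factor_range = c(0, 1)),
               "growth_factor_range")
  # far too many large lesions for a small brain
  expect_error(
    generateStudy(phantomConfig(grid_shape = c(32, 32, 32), n_existing = 30,
                                n_new = 0, n_disappeared = 0,
                                diameter_range_mm = c(8, 10), seed = 1)),
    "relax|impossible")
})

test_that("studies round-trip through the on-disk layout", {
  st <- generateStudy(phantomConfig(grid_shape = c(32, 32, 32), n_existing = 1,
                                    n_new = 0, n_disappeared = 1,
                                    diameter_range_mm = c(5, 8), seed = 5))
  dir <- tempfile()
  writeStudy(st, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "prior.nii.gz", "current.nii.gz", "prior_mask.nii.gz",
    "current_mask.nii.gz", "ground_truth.json")))))
  back <- readVolume(file.path(dir, "current.nii.gz"))
  expect_identical(back@voxels, st@currentVolume@voxels)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$gt_transform,
               c(st@gtTransform@angles, st@gtTransform@translation))
})
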