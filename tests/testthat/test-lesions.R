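test_that("binarization applies the >= tie rule and validates inputs", {
  base <- volumeImage(array(0.4, c(8, 8, 8)))
  expect_equal(sum(binarize(base, 0.5)@voxels), 0)
  v <- array(0.2, c(8, 8, 8))
  v[1:5] <- 0.5   # exactly at threshold: included
  v[6:8] <- 0.9
  out <- binarize(volumeImage(v), 0.5)
  expect_equal(sum(out@voxels), 8)
  gtLike <- volumeImage(array(rbinom(8^3, 1, 0.3), c(8, 8, 8)))
  for (thr in c(0.1, 0.5, 0.9))
    expect_equal(binarize(gtLike, thr)@voxels, gtLike@voxels)
  expect_error(binarize(base, 0), "threshold")
  expect_error(binarize(base, 1), "threshold")
})

test_that("diameter/volume conversion follows the sphere-equivalent convention", {
  expect_equal(diameterVolume(10), 0.5236, tolerance = 1e-4)
  expect_equal(round(diameterVolume(10), 2), 0.52)
  expect_equal(round(diameterVolume(5), 2), 0.07)
  expect_equal(equivDiameter(0), 0)
  # strict monotonicity and exact round trip
  v <- seq(0.001, 5, length.out = 50)
  d <- equivDiameter(v)
  expect_true(all(diff(d) > 0))
  expect_equal(diameterVolume(d), v, tolerance = 1e-9)
  expect_error(equivDiameter(-1), "non-negative")
})

test_that("extraction measures volumes exactly and orders labels deterministically", {
  v <- array(0, c(20, 20, 20))
  v[3:5, 3:5, 3:5] <- 1          # 27 voxels
  v[12:15, 12:15, 12:15] <- 1    # 64 voxels
  geom <- volumeImage(array(0, c(20, 20, 20)), spacing = c(1, 1, 1))
  les <- extractLesions(binaryMask(v, geom), roi = NULL)
  tab <- lesionTable(les)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$volume_cc, c(0.064, 0.027))  # descending volume order
  expect_equal(tab$volume_cc[2], 27 * 1 / 1000)
  expect_equal(tab$n_voxels, c(64, 27))
  # volume conservation: total equals voxel count times voxel volume
  expect_equal(sum(tab$volume_cc), sum(v) * prod(geom@spacing) / 1000)
})

test_that("diagonally touching voxels merge under 26-connectivity", {
  v <- array(0, c(10, 10, 10))
  v[3, 3, 3] <- 1
  v[4, 4, 4] <- 1  # touches only at a corner
  geom <- volumeImage(array(0, c(10, 10, 10)))
  les26 <- extractLesions(binaryMask(v, geom), minVoxels = 1)
  expect_equal(nrow(lesionTable(les26)), 1)
  expect_equal(oracleComponentCount(v, 26), 1)
  expect_equal(oracleComponentCount(v, 6), 2)
  les6 <- extractLesions(binaryMask(v, geom), minVoxels = 1, connectivity = 6)
  expect_equal(nrow(lesionTable(les6)), 2)
})

test_that("ROI and minimum-size filters drop the right components", {
  v <- array(0, c(24, 24, 24))
  v[4:6, 4:6, 4:6] <- 1       # inside ROI
  v[20:22, 20:22, 20:22] <- 1  # outside ROI
  v[12, 12, 12] <- 1           # single voxel
  geom <- volumeImage(array(0, c(24, 24, 24)))
  roiArr <- array(0, c(24, 24, 24))
  roiArr[1:12, 1:12, 1:12] <- 1
  roi <- binaryMask(roiArr, geom)
  les <- extractLesions(binaryMask(v, geom), roi)
  expect_equal(nrow(lesionTable(les)), 1)
  expect_equal(lesionTable(les)$n_voxels, 27)
  # empty masks give an empty set, not an error
  empty <- extractLesions(binaryMask(array(0, c(24, 24, 24)), geom), roi)
  expect_equal(nrow(lesionTable(empty)), 0)
})

test_that("size stratification uses strict inequalities on the four classes", {
  tab <- data.frame(id = 1:3, timepoint = "current", n_voxels = 1,
                    volume_cc = diameterVolume(c(4, 7, 12)),
                    diameter_mm = c(4, 7, 12),
                    centroid_x = 0, centroid_y = 0, centroid_z = 0)
  s <- stratifyLesions(tab)
  expect_equal(s[[">10mm"]]$diameter_mm, 12)
  expect_equal(s[[">5mm"]]$diameter_mm, c(7, 12))
  expect_equal(s[["<10mm"]]$diameter_mm, c(4, 7))
  expect_equal(s[["All"]]$diameter_mm, c(4, 7, 12))
  # boundary diameter: in neither strict class, but in >5mm and All
  tab10 <- tab[1, ]
  tab10$diameter_mm <- 10
  s10 <- stratifyLesions(tab10)
  expect_equal(nrow(s10[[">10mm"]]), 0)
  expect_equal(nrow(s10[["<10mm"]]), 0)
  expect_equal(nrow(s10[[">5mm"]]), 1)
  expect_equal(nrow(s10[["All"]]), 1)
  sEmpty <- stratifyLesions(tab[0, ])
  expect_true(all(vapply(sEmpty, nrow, integer(1)) == 0))
})
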