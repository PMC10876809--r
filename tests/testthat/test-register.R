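test_that("self-registration returns the identity", {
  st <- smallStudy()
  est <- estimateRigid(st@currentVolume, st@currentVolume)
  expect_lt(max(abs(est@angles)), 1e-3)
  expect_lt(max(abs(est@translation)), 0.1)
})

test_that("a known rigid offset is recovered within tolerance", {
  cfg <- phantomConfig(n_existing = 2, n_new = 1,
                       n_disappeared = 1, diameter_range_mm = c(6, 12),
                       rigid_offset = c(0.052, -0.03, 0.02, 5, -3, 2),
                       seed = 7)
  st <- generateStudy(cfg)
  est <- estimateRigid(st@priorVolume, st@currentVolume)
  gt <- st@gtTransform
  expect_lt(max(abs(est@angles - gt@angles)) * 180 / pi, 0.5)
  expect_lt(max(abs(est@translation - gt@translation)),
            max(st@currentVolume@spacing) / 2)
})

test_that("forward and backward registrations are inverse-consistent", {
  st <- smallStudy()
  ab <- estimateRigid(st@priorVolume, st@currentVolume)
  ba <- estimateRigid(st@currentVolume, st@priorVolume)
  comp <- composeTransforms(ba, ab)
  expect_lt(max(abs(comp@angles)) * 180 / pi, 0.5)
  expect_lt(max(abs(comp@translation)), max(st@currentVolume@spacing) / 2)
})

test_that("non-overlapping fields of view are refused", {
  a <- volumeImage(array(rnorm(32^3, 100, 5), c(32, 32, 32)))
  b <- volumeImage(array(rnorm(32^3, 100, 5), c(32, 32, 32)),
                   affine = {
                     A <- diag(4); A[1:3, 4] <- c(500, 500, 500); A
                   })
  expect_error(estimateRigid(a, b), "overlap")
})

test_that("identity transform leaves voxels unchanged", {
  st <- smallStudy()
  out <- applyTransform(st@currentVolume, rigidTransform())
  expect_equal(out@voxels, st@currentVolume@voxels, tolerance = 1e-12)
})

test_that("whole-voxel translation with nearest interpolation is an array shift", {
  v <- array(rnorm(20 * 20 * 20), c(20, 20, 20))
  vol <- volumeImage(v, spacing = c(1, 1, 1))
  k <- 3
  # translate by +k mm along x: content moves k voxels up in index space
  tr <- rigidTransform(translation = c(k, 0, 0))
  out <- applyTransform(vol, tr, interpolation = "nearest")
  expect_equal(out@voxels[(k + 1):20, , ], v[1:(20 - k), , ])
  expect_true(all(out@voxels[1:k, , ] == 0))
})

test_that("transform round trip keeps in-brain intensities within 2% RMS", {
  st <- smallStudy()
  # a smooth volume: voxel noise has no spatial structure an interpolating
  # round trip could preserve, so assess on the smoothed phantom
  smooth <- volumeImage(
    longimets:::.gaussian_blur3d(st@currentVolume@voxels, rep(1.5, 3)),
    spacing = st@currentVolume@spacing, affine = st@currentVolume@affine)
  tr <- rigidTransform(c(0.04, -0.02, 0.03), c(3, -2, 1))
  fwd <- applyTransform(smooth, tr)
  back <- applyTransform(fwd, invertTransform(tr))
  roi <- brainROI(st@currentVolume)
  core <- longimets:::.morph_ball(roi@voxels, 4, smooth@spacing, FALSE) == 1
  err <- back@voxels[core] - smooth@voxels[core]
  rng <- diff(range(smooth@voxels))
  expect_lt(sqrt(mean(err^2)), 0.02 * rng)
})

test_that("label masks require nearest interpolation and stay label-valued", {
  st <- smallStudy()
  expect_error(applyTransform(st@priorMask, rigidTransform(),
                              interpolation = "trilinear"), "nearest")
  out <- applyTransform(st@priorMask, st@gtTransform,
                        target = st@currentMask, interpolation = "nearest")
  expect_true(all(out@voxels %in% c(0, seq_len(3))))
})

test_that("transforms serialise to JSON and back", {
  tr <- rigidTransform(c(0.01, 0.02, -0.03), c(1.5, -2.5, 3.5),
                       center = c(1, 2, 3))
  path <- tempfile(fileext = ".json")
  writeTransform(tr, path)
  back <- readTransform(path)
  expect_equal(back@angles, tr@angles)
  expect_equal(back@translation, tr@translation)
  expect_equal(back@center, tr@center)
})
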