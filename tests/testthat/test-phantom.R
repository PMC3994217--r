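# Phantom tests use coarse voxels where possible; the voxel-count oracle for
# a cylinder slice is the lattice count itself, so checks compare against
# closed-form volumes with discretization tolerances.

test_that("ground truth of a muscle cylinder is the closed-form volume", {
  prof <- PhantomProfile(cylinderSeries(40, 3))
  ph <- generatePhantom(prof, spacingMm = 2)
  expect_equal(groundTruthTotalL(ph), 1.27324, tolerance = 1e-5)
  # no fat ring: both ground truths coincide
  expect_equal(groundTruthNoFatL(ph), groundTruthTotalL(ph), tolerance = 1e-12)
})

test_that("phantom ground truth equals the frustum model of its outer series", {
  s <- taperingLegSeries()
  prof <- PhantomProfile(s, fatFraction = 0.2, boneFraction = 0.2)
  ph <- generatePhantom(prof, spacingMm = 3)
  expect_equal(groundTruthTotalL(ph), totalVolumeL(totalVolume(s)),
               tolerance = 1e-12)
  expect_lte(groundTruthNoFatL(ph), groundTruthTotalL(ph))
})

test_that("threshold volumetry recovers the cylinder volume at 1 mm", {
  prof <- PhantomProfile(cylinderSeries(40, 3))
  ph <- generatePhantom(prof, spacingMm = 1)
  v <- ctVolume(ph, thresholdHu = -200)
  expect_equal(v, 1.27324, tolerance = 0.01)
})

test_that("no-fat threshold volumetry matches the lean ground truth", {
  prof <- PhantomProfile(taperingLegSeries(), fatFraction = 0.25,
                         boneFraction = 0.25)
  ph <- generatePhantom(prof, spacingMm = 1)
  expect_equal(ctVolume(ph, -20), groundTruthNoFatL(ph), tolerance = 0.02)
  expect_equal(ctVolume(ph, -200), groundTruthTotalL(ph), tolerance = 0.02)
})

test_that("no-fat segmentation is never larger than the total segmentation", {
  set.seed(401)
  for (i in 1:5) {
    n <- sample(3:8, 1)
    s <- CircumferenceSeries(sort(runif(n, 25, 60), decreasing = TRUE), "leg")
    prof <- PhantomProfile(s, fatFraction = runif(1, 0, 0.4),
                           boneFraction = runif(1, 0.15, 0.3),
                           noiseSdHu = sample(c(0, 10), 1))
    ph <- generatePhantom(prof, spacingMm = 2, seed = i)
    expect_lte(ctVolume(ph, -20), ctVolume(ph, -200))
  }
})

test_that("a threshold above every tissue segments nothing", {
  prof <- PhantomProfile(cylinderSeries(40, 3))
  ph <- generatePhantom(prof, spacingMm = 2)
  expect_identical(ctVolume(ph, 800), 0)
  # array method: pure air volume
  air <- array(-1000, dim = c(10, 10, 10))
  expect_identical(ctVolume(air, thresholdHu = -200, spacingMm = 1), 0)
})

test_that("phantom generation is bit-deterministic for a fixed seed", {
  prof <- PhantomProfile(cylinderSeries(40, 3), fatFraction = 0.2,
                         boneFraction = 0.2, noiseSdHu = 12)
  a <- generatePhantom(prof, spacingMm = 2, seed = 77)
  b <- generatePhantom(prof, spacingMm = 2, seed = 77)
  expect_identical(a@hu, b@hu)
  c <- generatePhantom(prof, spacingMm = 2, seed = 78)
  expect_false(identical(a@hu, c@hu))
})

test_that("too-coarse spacing is rejected", {
  prof <- PhantomProfile(CircumferenceSeries(c(10, 10), "arm"))
  # outer radius 10/(2*pi) cm = 15.9 mm: under 2 voxels at 10 mm spacing
  expect_error(generatePhantom(prof, spacingMm = 10),
               "resolution too coarse", class = "limbvolValidationError")
  expect_silent(generatePhantom(prof, spacingMm = 5))
})

test_that("labels and HU are voxelwise consistent and ordered", {
  prof <- PhantomProfile(taperingLegSeries(), fatFraction = 0.25,
                         boneFraction = 0.25)
  ph <- generatePhantom(prof, spacingMm = 3)
  hu <- defaultTissueHu()
  for (lab in 0:3) {
    vox <- ph@hu[ph@labels == lab]
    if (length(vox)) expect_true(all(vox == hu[lab + 1]))
  }
})

test_that("simulated tape measurement recovers the defining circumferences", {
  # cylinder: every level within 1%
  prof <- PhantomProfile(cylinderSeries(40, 3))
  ph <- generatePhantom(prof, spacingMm = 1)
  m <- measurePhantomCircumferences(ph)
  expect_equal(circumferences(m), rep(40, 3), tolerance = 0.01)

  # conical taper: per-level match against the analytic circumference
  s <- CircumferenceSeries(c(50, 45, 40, 35, 30), "leg")
  ph2 <- generatePhantom(PhantomProfile(s), spacingMm = 1)
  m2 <- measurePhantomCircumferences(ph2)
  expect_equal(circumferences(m2), circumferences(s), tolerance = 0.01)
  expect_equal(levelPositions(m2), levelPositions(s))

  # round trip through the frustum model
  expect_equal(totalVolumeL(totalVolume(m2)), totalVolumeL(totalVolume(s)),
               tolerance = 0.02)
})

test_that("phantoms survive a NIfTI round trip", {
  prof <- PhantomProfile(cylinderSeries(40, 3), fatFraction = 0.2,
                         boneFraction = 0.2)
  ph <- generatePhantom(prof, spacingMm = 2)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  writePhantomNifti(ph, path)
  back <- readPhantomNifti(path)
  expect_equal(voxelSpacing(back), 2, tolerance = 1e-6)
  expect_equal(ctVolume(back, -200), ctVolume(ph, -200), tolerance = 1e-12)
  expect_identical(back@labels, ph@labels)
  # tape simulation still works without the analytic radii table
  m <- measurePhantomCircumferences(back)
  expect_equal(circumferences(m), rep(40, 3), tolerance = 0.02)
})

test_that("phantom profiles survive a JSON round trip", {
  s <- taperingLegSeries()
  prof <- PhantomProfile(s, fatFraction = seq(0.3, 0.1,
                                              length.out = nLevels(s)),
                         boneFraction = 0.2, noiseSdHu = 8)
  path <- withr::local_tempfile(fileext = ".json")
  writePhantomProfile(prof, path)
  back <- readPhantomProfile(path)
  expect_equal(circumferences(back@series), circumferences(s))
  expect_equal(back@fatFraction, prof@fatFraction)
  expect_equal(back@boneFraction, prof@boneFraction)
  expect_equal(back@tissueHu, prof@tissueHu)
  expect_equal(back@noiseSdHu, 8)
})
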