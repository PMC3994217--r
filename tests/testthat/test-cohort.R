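# Cohort-level tests run at coarse voxel spacing (2 mm) and small n so the
# suite stays fast; the full study conditions are exercised once in the
# acceptance tests.

test_that("cohorts honour the limb counts", {
  coh <- simulateCohort(CohortSpec(nLegs = 0, nArms = 5, seed = 9))
  lt <- vapply(subjects(coh), `[[`, character(1), "limbType")
  expect_identical(lt, rep("arm", 5))
  expect_error(CohortSpec(nLegs = 0, nArms = 0), "at least one")
})

test_that("cohort simulation is deterministic per seed", {
  a <- simulateCohort(CohortSpec(nLegs = 3, nArms = 2, seed = 42))
  b <- simulateCohort(CohortSpec(nLegs = 3, nArms = 2, seed = 42))
  for (i in seq_along(subjects(a))) {
    expect_identical(circumferences(subjects(a)[[i]]$seriesTape),
                     circumferences(subjects(b)[[i]]$seriesTape))
    expect_identical(subjects(a)[[i]]$phantomSeed,
                     subjects(b)[[i]]$phantomSeed)
  }
  c <- simulateCohort(CohortSpec(nLegs = 3, nArms = 2, seed = 43))
  expect_false(identical(circumferences(subjects(a)[[1]]$seriesTape),
                         circumferences(subjects(c)[[1]]$seriesTape)))
})

test_that("cohort simulation leaves the caller's RNG stream untouched", {
  set.seed(606)
  before <- .Random.seed
  invisible(simulateCohort(CohortSpec(nLegs = 2, nArms = 1, seed = 99)))
  expect_identical(.Random.seed, before)
})

test_that("with zero tape noise the circumference volume is the ground truth", {
  coh <- simulateCohort(CohortSpec(nLegs = 3, nArms = 2, seed = 11,
                                   tapeNoiseSdCm = 0))
  st <- suppressWarnings(runValidationStudy(coh, withCT = FALSE))
  m <- measurements(st)
  expect_equal(m$tapeVolumeL, m$groundTruthTotalL, tolerance = 1e-12)
})

test_that("noise-free cohorts give a near-perfect pooled volume correlation", {
  coh <- simulateCohort(CohortSpec(nLegs = 4, nArms = 2, seed = 21,
                                   tapeNoiseSdCm = 0, ctNoiseSdHu = 0))
  st <- suppressWarnings(runValidationStudy(coh, spacingMm = 2))
  expect_gte(panels(st)[["circ_vs_ct"]]@r, 0.999)
  # mean contract: group means of the two measures differ by < 2%
  gm <- groupMeans(st)
  for (limb in c("leg", "arm")) {
    tape <- gm$mean[gm$limbType == limb & gm$variable == "tapeVolumeL"]
    ct <- gm$mean[gm$limbType == limb & gm$variable == "ctTotalL"]
    expect_lt(abs(tape - ct) / ct, 0.02)
  }
})

test_that("the IBW-corrected panel outperforms the bare IBW panel", {
  coh <- simulateCohort(CohortSpec(nLegs = 10, nArms = 4, seed = 31))
  st <- runValidationStudy(coh, spacingMm = 2)
  expect_gt(panels(st)[["corr_vs_nofat"]]@r, panels(st)[["ibw_leg"]]@r)
})

test_that("decoupling girth from height removes the IBW correlation", {
  coh <- simulateCohort(CohortSpec(nLegs = 10, nArms = 0, seed = 41,
                                   heightLink = FALSE))
  st <- suppressWarnings(runValidationStudy(coh, withCT = FALSE))
  p <- panels(st)[["ibw_leg"]]
  expect_lt(abs(p@r), 0.6)
  expect_gt(p@p, 0.05)
})

test_that("undersized groups are skipped with a warning, not an error", {
  coh <- simulateCohort(CohortSpec(nLegs = 3, nArms = 2, seed = 51))
  w <- capture_warnings(st <- runValidationStudy(coh, withCT = FALSE))
  expect_length(w, 3)  # one per skipped arm panel
  expect_true(all(grepl("skipped", w)))
  expect_false("abw_arm" %in% names(panels(st)))
  expect_true("abw_leg" %in% names(panels(st)))
})

test_that("study measurements carry consistent anthropometrics", {
  coh <- simulateCohort(CohortSpec(nLegs = 3, nArms = 2, seed = 61))
  st <- suppressWarnings(runValidationStudy(coh, withCT = FALSE))
  m <- measurements(st)
  expect_equal(m$bmi, m$weightKg / (m$heightCm / 100)^2, tolerance = 1e-12)
  expect_equal(m$correctedVolumeL, m$tapeVolumeL * m$quotient,
               tolerance = 1e-12)
  expect_true(all(m$quotient > 0))
})
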