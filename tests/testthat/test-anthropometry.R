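test_that("BMI follows the WHO definition", {
  expect_equal(bodyMassIndex(100, 200), 25, tolerance = 1e-13)
  expect_equal(bodyMassIndex(80, 180), 80 / 1.8^2, tolerance = 1e-13)
  expect_equal(bodyMassIndex(45.4, 152.4), 45.4 / 1.524^2, tolerance = 1e-13)
  expect_error(bodyMassIndex(-70, 180), class = "limbvolValidationError")
  expect_error(bodyMassIndex(70, 0), class = "limbvolValidationError")
})

test_that("BMI is invariant under the k^2-weight / k-height rescaling", {
  set.seed(201)
  for (i in 1:20) {
    w <- runif(1, 45, 140); h <- runif(1, 150, 200); k <- runif(1, 0.5, 2)
    expect_equal(bodyMassIndex(k^2 * w, k * h), bodyMassIndex(w, h),
                 tolerance = 1e-12)
  }
})

test_that("ideal body weight matches the sex-specific linear formula", {
  expect_equal(idealBodyWeight("male", 152.4), 49.9, tolerance = 1e-12)
  expect_equal(idealBodyWeight("female", 152.4), 45.4, tolerance = 1e-12)
  expect_equal(idealBodyWeight("male", 180), 49.9 + 0.89 * 27.6,
               tolerance = 1e-12)
  expect_equal(idealBodyWeight("male", 180), 74.464, tolerance = 1e-12)
  expect_error(idealBodyWeight("other", 170), "sex",
               class = "limbvolValidationError")
})

test_that("IBW is affine with slope 0.89 and a constant 4.5 kg sex gap", {
  heights <- seq(110, 220, by = 7)
  m <- vapply(heights, function(h) idealBodyWeight("male", h), numeric(1))
  f <- vapply(heights, function(h) idealBodyWeight("female", h), numeric(1))
  expect_equal(diff(m) / diff(heights), rep(0.89, length(heights) - 1),
               tolerance = 1e-12)
  expect_equal(m - f, rep(4.5, length(heights)), tolerance = 1e-12)
})

test_that("patient anthropometrics validate and derive consistently", {
  p <- PatientAnthro("m", 180, 95)
  expect_equal(p@sex, "male")
  expect_equal(bodyMassIndex(p), 95 / 1.8^2, tolerance = 1e-12)
  expect_equal(idealBodyWeight(p), 74.464, tolerance = 1e-12)
  expect_equal(correctionQuotient(p), 74.464 / 95, tolerance = 1e-12)
  # metre-entered heights are caught
  expect_error(PatientAnthro("f", 1.65, 60), "metres",
               class = "limbvolValidationError")
  expect_error(PatientAnthro("f", 165, -2), class = "limbvolValidationError")
})

test_that("IBW correction rescales volume by the quotient", {
  # quotient exactly 1: volume unchanged
  pEq <- PatientAnthro("male", 152.4, 49.9)
  expect_equal(ibwCorrectedVolume(10, pEq)$volumeL, 10, tolerance = 1e-12)

  # IBW 70 / ABW 100 -> 7.0 L (male height for IBW = 70: 175.0112... use direct)
  h <- 152.4 + (70 - 49.9) / 0.89
  p <- PatientAnthro("male", h, 100)
  out <- ibwCorrectedVolume(10, p)
  expect_equal(out$volumeL, 7, tolerance = 1e-9)
  expect_false(out$clamped)

  # a class-III obesity quotient of 0.5 halves any volume
  p5 <- PatientAnthro("male", 152.4, 99.8)
  expect_equal(correctionQuotient(p5), 0.5, tolerance = 1e-12)
  for (v in c(0.5, 2, 8.1, 12)) {
    expect_equal(ibwCorrectedVolume(v, p5)$volumeL, v / 2, tolerance = 1e-12)
  }

  # linearity in volume
  set.seed(202)
  pr <- PatientAnthro("female", 168, 88)
  v <- runif(5, 1, 12)
  outs <- vapply(v, function(x) ibwCorrectedVolume(x, pr)$volumeL, numeric(1))
  expect_equal(outs, v * correctionQuotient(pr), tolerance = 1e-12)
})

test_that("the cap-at-one clamp is opt-in and reported", {
  underweight <- PatientAnthro("male", 180, 60)  # IBW 74.464 > ABW
  expect_gt(correctionQuotient(underweight), 1)

  uncapped <- ibwCorrectedVolume(8, underweight)
  expect_equal(uncapped$volumeL, 8 * correctionQuotient(underweight),
               tolerance = 1e-12)
  expect_false(uncapped$clamped)

  capped <- ibwCorrectedVolume(8, underweight, capAtOne = TRUE)
  expect_equal(capped$volumeL, 8, tolerance = 1e-12)
  expect_true(capped$clamped)
  expect_equal(capped$rawQuotient, correctionQuotient(underweight))
})
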