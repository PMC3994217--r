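test_that("frustum volume reduces to the cylinder and cone closed forms", {
  # equal circumferences: V = h * C^2 / (4*pi)
  expect_equal(frustumVolume(40, 40, 5), 5 * 40^2 / (4 * pi), tolerance = 1e-13)
  expect_equal(frustumVolume(40, 40, 5), 636.6198, tolerance = 1e-7)
  # zero distal circumference: V = h * C^2 / (12*pi)
  expect_equal(frustumVolume(40, 0, 5), 5 * 40^2 / (12 * pi), tolerance = 1e-13)
  expect_equal(frustumVolume(40, 0, 5), 212.2066, tolerance = 1e-7)
  # generic taper, frozen from the quadrature oracle
  expect_equal(frustumVolume(40, 30, 5), 490.7277, tolerance = 1e-7)
})

test_that("frustum volume matches quadrature of the linear-taper solid", {
  set.seed(101)
  for (i in 1:200) {
    c1 <- runif(1, 0, 80)
    c2 <- runif(1, 0, 80)
    h <- runif(1, 0.5, 20)
    expect_equal(frustumVolume(c1, c2, h), quadratureTaperVolume(c1, c2, h),
                 tolerance = 1e-9)
  }
})

test_that("frustum volume is monotone in circumference and height", {
  set.seed(102)
  for (i in 1:50) {
    c1 <- runif(1, 1, 70); c2 <- runif(1, 1, 70); h <- runif(1, 1, 10)
    d <- runif(1, 0.1, 10)
    expect_gte(frustumVolume(c1 + d, c2, h), frustumVolume(c1, c2, h))
    expect_gte(frustumVolume(c1, c2 + d, h), frustumVolume(c1, c2, h))
    expect_gt(frustumVolume(c1, c2, h + d), frustumVolume(c1, c2, h))
  }
})

test_that("frustum volume validates its inputs by name", {
  expect_error(frustumVolume(-1, 30, 5), "circProximal",
               class = "limbvolValidationError")
  expect_error(frustumVolume(40, -2, 5), "circDistal",
               class = "limbvolValidationError")
  expect_error(frustumVolume(40, 30, 0), "'h'",
               class = "limbvolValidationError")
})

test_that("total volume sums one frustum per adjacent level pair", {
  expect_equal(totalVolumeL(totalVolume(cylinderSeries(40, 3))), 1.27324,
               tolerance = 1e-5)
  expect_equal(totalVolumeL(totalVolume(CircumferenceSeries(c(40, 30), "leg"))),
               0.4907277, tolerance = 1e-6)
  res <- totalVolume(taperingLegSeries())
  expect_length(segmentVolumes(res), nLevels(taperingLegSeries()) - 1L)
  expect_equal(totalVolumeL(res), sum(segmentVolumes(res)) / 1000,
               tolerance = 1e-12)
})

test_that("volumes scale quadratically with circumference", {
  s1 <- CircumferenceSeries(c(10, 10), "arm")
  s2 <- CircumferenceSeries(c(20, 20), "arm")
  expect_equal(totalVolumeL(totalVolume(s2)), 4 * totalVolumeL(totalVolume(s1)),
               tolerance = 1e-12)
  set.seed(103)
  circ <- runif(8, 20, 60)
  k <- 1.7
  v1 <- totalVolume(CircumferenceSeries(circ, "leg"))
  v2 <- totalVolume(CircumferenceSeries(k * circ, "leg"))
  expect_equal(segmentVolumes(v2), k^2 * segmentVolumes(v1),
               tolerance = 1e-12)
})

test_that("series validation rejects malformed inputs", {
  expect_error(CircumferenceSeries(c(40), "leg"), "at least 2")
  expect_error(CircumferenceSeries(c(40, -3), "leg"),
               class = "limbvolValidationError")
  # zero circumference legal only at the terminal distal level
  expect_silent(CircumferenceSeries(c(40, 30, 0), "leg"))
  expect_error(CircumferenceSeries(c(40, 0, 30), "leg"), "terminal")
  expect_error(CircumferenceSeries(c(40, 40), "leg",
                                   positionsCm = c(5, 5)),
               "strictly increasing")
  expect_error(CircumferenceSeries(c(40, 40), "fin"), "limb")
})

test_that("non-uniform level positions are honoured", {
  s <- CircumferenceSeries(c(40, 40, 40), "leg", positionsCm = c(0, 5, 12))
  expect_equal(totalVolumeL(totalVolume(s)), 12 * 40^2 / (4 * pi) / 1000,
               tolerance = 1e-12)
})

test_that("tourniquet subtraction removes proximal segments and conserves volume", {
  res <- totalVolume(cylinderSeries(40, 4))  # 3 cylinder segments, 1.90986 L
  expect_equal(totalVolumeL(res), 1.90986, tolerance = 1e-5)

  adj <- subtractAboveLevel(res, 1)
  expect_equal(totalVolumeL(adj), 1.27324, tolerance = 1e-5)
  expect_identical(excludedSegments(adj), 1L)

  expect_equal(totalVolumeL(subtractAboveLevel(res, 0)), totalVolumeL(res))
  expect_identical(totalVolumeL(subtractAboveLevel(res, 3)), 0)

  # conservation holds exactly for arbitrary series and levels
  set.seed(104)
  for (i in 1:20) {
    n <- sample(3:15, 1)
    s <- CircumferenceSeries(runif(n, 20, 65), "leg")
    r <- totalVolume(s)
    lev <- sample(0:(n - 1), 1)
    a <- subtractAboveLevel(r, lev)
    expect_equal(excludedVolumeL(a) + totalVolumeL(a), totalVolumeL(r),
                 tolerance = 1e-14)
  }

  expect_error(subtractAboveLevel(res, 4), "out of range",
               class = "limbvolValidationError")
  expect_error(subtractAboveLevel(res, -1), class = "limbvolValidationError")
})

test_that("cumulative volumes run proximal to distal and honour exclusions", {
  res <- totalVolume(cylinderSeries(40, 4))
  cum <- cumulativeVolumeL(res)
  expect_equal(cum[3], totalVolumeL(res), tolerance = 1e-12)
  expect_true(all(diff(cum) >= 0))
  adj <- subtractAboveLevel(res, 2)
  expect_equal(cumulativeVolumeL(adj)[3], totalVolumeL(adj), tolerance = 1e-12)
  expect_equal(cumulativeVolumeL(adj)[1], 0)
})
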