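# Shared fixtures and the independent geometry oracle.

# Numerical-quadrature oracle for the volume of a linearly tapering circular
# solid: integrate pi * r(z)^2 with r interpolated between the end radii.
# Independent of the closed-form frustum expression under test.
quadratureTaperVolume <- function(circProximal, circDistal, h) {
  r1 <- circProximal / (2 * pi)
  r2 <- circDistal / (2 * pi)
  f <- function(z) pi * (r1 + (r2 - r1) * z / h)^2
  stats::integrate(f, 0, h, rel.tol = 1e-12, abs.tol = 0)$value
}

cylinderSeries <- function(circ = 40, nLevels = 3, limb = "leg") {
  CircumferenceSeries(rep(circ, nLevels), limbType = limb)
}

taperingLegSeries <- function() {
  CircumferenceSeries(c(60, 55, 50, 45, 40, 36, 33, 30, 28, 26, 24, 23, 22),
                      limbType = "leg")
}

# Small, quickly rasterizable cohort for study-level tests.
tinyCohortSpec <- function(...) {
  CohortSpec(nLegs = 6, nArms = 4, seed = 301, ...)
}

writeSheet <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
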