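# Calibration, least-squares shifting, parametric time warping.

jitteredSet <- function(nSamples = 6, seed = 21, jitterSd = 0.003,
                        points = 4096, width_hz = 30) {
  # broad lines (default 30 Hz ~ 24 points at 4096) so that shifted
  # segments overlap smoothly and shift recovery is well conditioned
  groups <- sort(rep(c("A", "B"), length.out = nSamples))
  plan <- simulationPlan(
    n_samples = nSamples,
    peaks = list(peakSpec(0.0, 1, width_hz), peakSpec(2.0, 1, width_hz),
                 peakSpec(5.0, 2, width_hz)),
    ppm_jitter_sd = jitterSd, noise_sd = 0,
    factor_assignment = groups, seed = seed)
  list(plan = plan, set = simulateSpectrumSet(plan, smallAxis(points)))
}

# the jitters the generator actually applied, in (fractional) axis points
appliedJitterPoints <- function(plan, points) {
  jit <- nmrflow:::withSeed(plan$seed, nmrflow:::drawJitter(plan))
  jit / (10 / (points - 1))
}

test_that("calibration puts every reference apex on the point nearest the nominal shift", {
  fx <- jitteredSet()
  set <- fx$set
  cal <- calibrateSpectra(set, ppmZone(-0.2, 0.2), 0.0)
  ppm <- ppmAxis(cal)
  target <- which.min(abs(ppm))
  for (r in seq_len(nrow(intensities(cal)))) {
    reg <- which(ppm > -0.2 & ppm < 0.2)
    expect_equal(reg[which.max(intensities(cal)[r, reg])], target)
  }
  # already-calibrated input: identity
  cal2 <- calibrateSpectra(cal, ppmZone(-0.2, 0.2), 0.0)
  expect_identical(intensities(cal2), intensities(cal))
  # a constructed +5-point shift is undone exactly
  m <- intensities(cal)
  m[2, ] <- c(rep(0, 5), m[2, 1:(ncol(m) - 5)])
  shifted <- matrixSet(m, ppm)
  back <- calibrateSpectra(shifted, ppmZone(-0.2, 0.2), 0.0)
  n <- ncol(m)
  expect_equal(unname(intensities(back)[2, 1:(n - 5)]),
               unname(intensities(cal)[2, 1:(n - 5)]))
})

test_that("calibration refuses an apex sitting on the zone edge", {
  ppm <- seq(9.5, -0.5, length.out = 1024)
  m <- matrix(0, 1, 1024)
  m[1, ] <- seq_len(1024) / 1024          # monotone: apex at zone edge
  expect_error(calibrateSpectra(matrixSet(m, ppm), ppmZone(4, 5), 4.5),
               "zone edge")
})

test_that("least-squares alignment recovers constructed jitter exactly and reduces dispersion", {
  fx <- jitteredSet(nSamples = 6, seed = 33)
  set <- fx$set
  jit <- appliedJitterPoints(fx$plan, 4096)
  zone <- ppmZone(1.8, 2.2)                # the 2.0 ppm singlet (peak 2)
  res <- alignZoneLS(set, zone, max_shift = 12)
  # recovered shifts undo the applied jitter up to the common offset of
  # the mean reference (alignment fixes relative, not absolute, position);
  # on the descending axis a +ppm jitter is a -index displacement, undone
  # by a +index shift
  resid <- res$report$shifts - jit[, 2]
  expect_lt(max(abs(resid - mean(resid))), 1)
  expect_lt(res$report$dispersion_after, res$report$dispersion_before)
  expect_true(res$report$accepted)
  # out-of-zone points untouched, bit for bit
  out <- which(!(ppmAxis(set) >= 1.8 & ppmAxis(set) <= 2.2))
  expect_identical(intensities(res$set)[, out], intensities(set)[, out])
  # identical spectra give all-zero shifts
  again <- alignZoneLS(res$set, zone, max_shift = 12)
  expect_true(all(again$report$shifts == 0))
  # mean absolute apex misalignment after alignment is below one point
  ppm <- ppmAxis(res$set)
  reg <- which(ppm > 1.8 & ppm < 2.2)
  apexes <- apply(intensities(res$set)[, reg], 1, which.max)
  expect_lt(mean(abs(apexes - stats::median(apexes))), 1)
})

test_that("jitter beyond the search range leaves that spectrum unchanged with a warning", {
  fx <- jitteredSet(nSamples = 4, seed = 11, jitterSd = 0)
  m <- intensities(fx$set)
  ppm <- ppmAxis(fx$set)
  idx <- which(ppm >= 1.8 & ppm <= 2.2)
  # move sample 3's singlet by +8 points, search only +/-5
  seg <- m[3, idx]
  m[3, idx] <- c(rep(seg[1], 8), seg[1:(length(idx) - 8)])
  set <- matrixSet(m, ppm)
  expect_warning(res <- alignZoneLS(set, ppmZone(1.8, 2.2), max_shift = 5),
                 "boundary")
  expect_equal(res$report$shifts[3], 0)
  expect_equal(unname(intensities(res$set)[3, ]), unname(m[3, ]))
})

test_that("alignment on a factor subset leaves other spectra untouched", {
  fx <- jitteredSet(nSamples = 6, seed = 13)
  res <- alignZoneLS(fx$set, ppmZone(1.8, 2.2),
                     selection = list(factor = "group", level = "A"),
                     max_shift = 12)
  b <- subsetByFactor(fx$set, "group", "B")
  expect_identical(intensities(res$set)[b, ], intensities(fx$set)[b, ])
  expect_true(all(res$report$shifts[b] == 0))
})

test_that("alignment zones may not overlap excluded zones", {
  fx <- jitteredSet(nSamples = 2, seed = 2, jitterSd = 0)
  set <- zeroZones(fx$set, ppmZone(1.9, 2.0))
  expect_error(alignZoneLS(set, ppmZone(1.8, 2.2)), "excluded")
})

test_that("parametric warping returns the identity warp for identical spectra", {
  fx <- jitteredSet(nSamples = 3, seed = 5, jitterSd = 0)
  res <- alignZonePTW(fx$set, ppmZone(1.7, 2.3), degree = 2)
  for (r in 1:3)
    expect_equal(res$report$coefficients[r, ], c(0, 1, 0), tolerance = 1e-6)
  expect_identical(intensities(res$set), intensities(fx$set))
})

test_that("parametric warping recovers a known linear warp", {
  ppm <- seq(9.5, -0.5, length.out = 4096)
  zone <- ppmZone(2.5, 3.5)
  idx <- which(ppm >= 2.5 & ppm <= 3.5)
  pattern <- lorentzianProfile(list(peakSpec(2.8, 1, 30),
                                    peakSpec(3.2, 0.7, 30)), ppm, 500)
  n <- 41
  m <- matrix(rep(pattern, each = n), n, length(ppm))
  a0 <- 2.0; a1 <- 1.001
  x <- seq_along(idx)
  warped <- stats::approx(x, pattern[idx], xout = a0 + a1 * x, rule = 2)$y
  m[n, idx] <- warped
  set <- matrixSet(m, ppm)
  res <- alignZonePTW(set, zone, degree = 1)
  aHat <- res$report$coefficients[n, ]
  # recovered warp is the inverse of the applied warp, within 0.1 point
  # RMS over the zone (reference contamination by the one warped row is
  # below that level at n = 41)
  inv <- (x - a0) / a1
  rec <- aHat[1] + aHat[2] * x
  expect_lt(sqrt(mean((rec - inv)^2)), 0.1)
  # the recovered warp fits at least as well as the true inverse
  obj <- function(a) {
    w <- stats::approx(x, warped, xout = a[1] + a[2] * x, rule = 2)$y
    sum((w - colMeans(m[, idx]))^2)
  }
  expect_lte(obj(aHat), obj(c(-a0 / a1, 1 / a1)) + 1e-9)
})

test_that("warping falls back to identity when dispersion would grow", {
  # two spectra with different peak counts in the zone: the caveat case
  ppm <- seq(9.5, -0.5, length.out = 2048)
  m <- rbind(lorentzianProfile(list(peakSpec(3.0, 1, 30)), ppm, 500),
             lorentzianProfile(list(peakSpec(2.8, 1, 30),
                                    peakSpec(3.2, 1, 30)), ppm, 500))
  set <- matrixSet(m, ppm)
  res <- suppressWarnings(alignZonePTW(set, ppmZone(2.5, 3.5), degree = 2))
  expect_lte(res$report$dispersion_after, res$report$dispersion_before)
  if (!res$report$accepted)
    expect_identical(intensities(res$set), intensities(set))
  # flat segment: singular, unchanged with a warning
  flat <- matrixSet(matrix(1, 2, 2048), ppm)
  ws <- testthat::capture_warnings(r2 <- alignZonePTW(flat, ppmZone(2.5, 3.5)))
  expect_true(any(grepl("singular|flat", ws)))
  expect_identical(intensities(r2$set), intensities(flat))
})
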