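# Bucketing strategies, integration, SNR, filtering, normalization.

test_that("uniform bucketing tiles the zone and applies the half-width rule", {
  set <- matrixSet(matrix(1, 1, 4096), seq(9.5, -0.5, length.out = 4096))
  bt <- uniformBuckets(set, ppmZone(3, 4), 0.04)
  expect_equal(length(bt), 25)
  b <- buckets(bt)
  expect_equal(b$ppm_max[1], 4)
  expect_equal(b$ppm_min[25], 3, tolerance = 1e-9)
  expect_equal(b$ppm_max - b$ppm_min, rep(0.04, 25), tolerance = 1e-9)
  # remainder below half width is dropped
  expect_equal(length(uniformBuckets(set, ppmZone(3, 4), 0.3)), 3)
  # remainder at least half width is kept
  expect_equal(length(uniformBuckets(set, ppmZone(3, 4), 0.4)), 3)
  expect_error(uniformBuckets(set, ppmZone(3, 4), 1e-4), "spacing")
})

test_that("buckets are clipped against excluded zones and never intersect them", {
  set <- matrixSet(matrix(1, 1, 4096), seq(9.5, -0.5, length.out = 4096))
  set <- zeroZones(set, ppmZone(3.45, 3.55))
  bt <- uniformBuckets(set, ppmZone(3, 4), 0.2)
  b <- buckets(bt)
  expect_true(all(b$ppm_min >= 3.55 | b$ppm_max <= 3.45))
  # the straddling bucket was split into two clips
  expect_equal(length(bt), 6)
  expect_error(uniformBuckets(set, ppmZone(3.46, 3.54), 0.02), "excluded")
})

test_that("adaptive binning separates two singlets at the valley and keeps one peak whole", {
  ppm <- seq(9.5, -0.5, length.out = 4096)
  peaks <- list(peakSpec(3.8, 1, 30), peakSpec(4.4, 0.9, 30))
  m <- do.call(rbind, lapply(1:3, function(i)
    lorentzianProfile(peaks, ppm, 500)))
  set <- matrixSet(m, ppm)
  bt <- aibBuckets(set, ppmZone(3.5, 4.7), noise_floor = 1e-4)
  b <- buckets(bt)
  expect_equal(nrow(b), 2)
  # the shared edge sits in the inter-peak valley
  reg <- which(ppm >= 3.9 & ppm <= 4.3)
  valleyPpm <- ppm[reg][which.min(m[1, reg])]
  d <- 10 / 4095
  expect_lt(abs(b$ppm_min[1] - valleyPpm), 2.5 * d)
  # apexes are inside their buckets
  expect_true(b$ppm_min[1] < 4.4 & b$ppm_max[1] > 4.4)
  expect_true(b$ppm_min[2] < 3.8 & b$ppm_max[2] > 3.8)
  # a single-peak zone stays one bucket
  one <- aibBuckets(set, ppmZone(3.5, 4.1), noise_floor = 1e-4)
  expect_equal(length(one), 1)
  expect_error(aibBuckets(set, ppmZone(3.5, 3.5001), noise_floor = 1e-4),
               "at least 3")
})

test_that("adaptive binning returns no buckets for pure noise", {
  ppm <- seq(9.5, -0.5, length.out = 512)
  set.seed(7)
  m <- matrix(rnorm(3 * 512, sd = 0.01), 3, 512)
  set <- matrixSet(m, ppm)
  bt <- aibBuckets(set, ppmZone(2, 8), noise_floor = 0.05)
  expect_equal(length(bt), 0)
})

test_that("adaptive binning equals the brute-force recursive maximizer on small zones", {
  ppm <- seq(9.5, -0.5, length.out = 256)   # zones below hold <= 64 points
  set.seed(11)
  for (rep in 1:5) {
    centers <- runif(2, 4.1, 5.9)
    m <- do.call(rbind, lapply(1:2, function(i)
      lorentzianProfile(list(peakSpec(centers[1], runif(1, 0.5, 2), 60),
                             peakSpec(centers[2], runif(1, 0.5, 2), 60)),
                        ppm, 500) + rnorm(256, sd = 0.01)))
    set <- matrixSet(m, ppm)
    zone <- ppmZone(4, 6)
    idx <- which(ppm >= 4 & ppm <= 6)
    expect_lte(length(idx), 64)
    segs <- m[, idx, drop = FALSE]
    vN <- 2 * 0.05^(2 * 0.5)
    want <- bruteAib(segs, 1L, ncol(segs), 0.5, vN)
    want <- Filter(function(b) bruteAibValue(segs, b[1], b[2], 0.5) > vN, want)
    got <- aibBuckets(set, zone, resolution_exp = 0.5, noise_floor = 0.05)
    expect_equal(length(got), length(want))
    if (length(want)) {
      d <- 10 / 255
      gotB <- buckets(got)
      for (k in seq_along(want)) {
        expect_equal(gotB$ppm_max[k], ppm[idx[want[[k]][1]]] + d / 2,
                     tolerance = 1e-9)
        expect_equal(gotB$ppm_min[k],
                     max(ppm[idx[want[[k]][2]]] - d / 2, 4), tolerance = 1e-9)
      }
    }
  }
})

test_that("manual buckets sort descending and reject overlaps", {
  bt <- manualBuckets(list(c(1, 1.2), c(5, 5.5), c(3, 3.1)))
  expect_equal(length(bt), 3)
  expect_equal(buckets(bt)$ppm_max, c(5.5, 3.1, 1.2))
  expect_error(manualBuckets(list(c(1, 2), c(1, 2))), "overlap")
  expect_error(manualBuckets(list(c(1, 2), c(1.5, 2.5))), "overlap")
  expect_error(manualBuckets(list(c(2, 1))), "ppm_min < ppm_max")
})

test_that("integration matches closed forms and is additive under bucket splits", {
  P <- 2001
  ppm <- seq(10, 0, length.out = P)      # spacing exactly 0.005
  d <- 0.005
  h <- 3
  set <- matrixSet(matrix(h, 1, P), ppm)
  bt <- manualBuckets(list(c(2, 3)))     # width 1, edges on grid points
  expect_equal(integrateBuckets(set, bt, "sum")[1, 1], h * 1,
               tolerance = d * h)
  expect_equal(integrateBuckets(set, bt, "trapezoid")[1, 1], h * 1,
               tolerance = 1e-12)
  # Lorentzian in a wide bucket: analytic area pi * height * HWHM
  w <- 10                                 # Hz -> 0.02 ppm
  lor <- matrixSet(matrix(lorentzianProfile(list(peakSpec(5, 2, w)),
                                            ppm, 500), 1, P), ppm)
  btw <- manualBuckets(list(c(3.5, 6.5)))
  expect_lt(abs(integrateBuckets(lor, btw, "sum")[1, 1] /
                  (pi * 2 * (w / 500) / 2) - 1), 0.02)
  # split additivity is exact for the sum rule
  whole <- manualBuckets(list(c(3.5, 6.5)))
  split <- manualBuckets(list(c(3.5, 4.9937), c(4.9937, 6.5)))
  expect_equal(sum(integrateBuckets(lor, split, "sum")[1, ]),
               integrateBuckets(lor, whole, "sum")[1, 1], tolerance = 1e-14)
  # zero spectrum integrates to a zero row
  zero <- matrixSet(matrix(0, 1, P), ppm)
  expect_true(all(integrateBuckets(zero, split) == 0))
})

test_that("SNR is calibrated against a known noise level", {
  P <- 4096
  ppm <- seq(9.5, -0.5, length.out = P)
  sigma <- 0.01
  nz <- ppmZone(8, 9.4)
  nidx <- which(ppm >= 8 & ppm <= 9.4)
  set.seed(5)
  m <- matrix(0, 2, P)
  for (r in 1:2) {
    m[r, ] <- lorentzianProfile(list(peakSpec(3, 10 * 2 * sigma, 10)),
                                ppm, 500)
    m[r, nidx] <- rnorm(length(nidx), sd = sigma)
  }
  set <- matrixSet(m, ppm)
  bt <- manualBuckets(list(c(2.8, 3.2), c(5, 5.4)))
  sm <- snrMatrix(set, bt, nz)
  tol <- 3 / sqrt(2 * (length(nidx) - 1))
  expect_equal(unname(sm[, "B3.0000"]), c(10, 10), tolerance = tol)
  # bucket holding only the far Lorentzian tail scores near zero
  expect_lt(max(sm[, "B5.2000"]), 0.05)
  # degenerate noise zone errors
  flat <- matrixSet(matrix(1, 1, P), ppm)
  expect_error(snrMatrix(flat, bt, nz), "degenerate")
})

test_that("a noise-only bucket scores like the expected maximum of m Gaussians", {
  P <- 4096
  ppm <- seq(9.5, -0.5, length.out = P)
  sigma <- 0.01
  set.seed(9)
  m <- matrix(rnorm(P, sd = sigma), 1, P)
  set <- matrixSet(m, ppm)
  bucket <- ppmZone(5, 5 + 63 * (10 / (P - 1)))  # ~64 points
  bt <- manualBuckets(list(c(bucket@ppmMin, bucket@ppmMax)))
  sm <- snrMatrix(set, bt, ppmZone(8, 9.4))
  # Monte-Carlo oracle for max-of-m Gaussians over 2 sd
  mc <- replicate(500, max(rnorm(64)) / 2)
  expect_lt(sm[1, 1], 5)
  expect_lt(abs(sm[1, 1] - mean(mc)), 4 * stats::sd(mc) + 1)
})

test_that("SNR filtering removes exactly the failing buckets and is monotone", {
  sm <- matrix(c(10, 10, 10,   1, 2, 1,   10, 2.5, 10), 3, 3,
               dimnames = list(paste0("S", 1:3), c("a", "b", "c")))
  dm <- sm * 2
  f <- filterBySnr(dm, sm, threshold = 3, min_fraction = 0.5)
  expect_equal(colnames(f$dm), c("a", "c"))
  expect_equal(f$kept, c(a = TRUE, b = FALSE, c = TRUE))
  # min_fraction 1 with one failing spectrum per bucket removes all
  sm2 <- matrix(c(10, 1, 10,  1, 10, 10,  10, 10, 1), 3, 3,
                dimnames = dimnames(sm))
  expect_equal(ncol(filterBySnr(sm2 * 2, sm2, 3, 1)$dm), 0)
  # monotone: raising the threshold never keeps more buckets
  kept <- vapply(c(1, 2.5, 3, 10, 11),
                 function(th) sum(filterBySnr(dm, sm, th, 0.5)$kept),
                 numeric(1))
  expect_true(all(diff(kept) <= 0))
  # all above threshold: everything kept
  expect_true(all(filterBySnr(dm, sm * 0 + 10, 3, 1)$kept))
})

test_that("constant-sum normalization scales every row to 100", {
  dm <- matrix(c(1, 2, 3, 4), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_identical(normalizeMatrix(dm, "none"), dm)
  n <- normalizeMatrix(dm, "constant_sum")
  expect_equal(unname(rowSums(n)), c(100, 100))
  dm[1, ] <- 0
  expect_error(normalizeMatrix(dm, "constant_sum"), "positive")
})

test_that("bucket tables survive the TSV round trip", {
  bt <- manualBuckets(list(c(1, 1.25), c(4.1, 4.4)))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeBucketTable(bt, f)
  rt <- readBucketTable(f)
  expect_equal(buckets(rt), buckets(bt))
})
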