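# Shared fixtures and independent oracles for the test suite.

smallAxis <- function(points = 2048L)
  spectralAxis(sfoMHz = 500, ppmMin = -0.5, ppmMax = 9.5, points = points)

# build a SpectrumSet straight from an intensity matrix
matrixSet <- function(m, ppm, groups = rep("A", nrow(m))) {
  spectrumSet(m, ppm,
              data.frame(sample_id = sprintf("S%02d", seq_len(nrow(m))),
                         group = groups, stringsAsFactors = FALSE))
}

# independent oracle: direct discrete-Fourier sum of a FID evaluated at
# the ppm values `ppmOut` (first point halved, matching the transform
# contract); O(N*P), keep inputs small
oracleDftSpectrum <- function(fid, ppmOut) {
  x <- fid@signal
  x[1] <- x[1] / 2
  dwell <- fid@dwellUs * 1e-6
  f <- (ppmOut - fid@o1Hz / fid@sfoMHz) * fid@sfoMHz
  n <- seq_along(x) - 1
  vapply(f, function(ff) sum(x * exp(-2i * pi * ff * n * dwell)) * dwell,
         complex(1))
}

# full width at half maximum around the apex, by linear interpolation
measureFwhm <- function(ppm, y) {
  a <- which.max(y)
  half <- y[a] / 2
  iL <- a
  while (iL > 1 && y[iL] > half) iL <- iL - 1
  iR <- a
  while (iR < length(y) && y[iR] > half) iR <- iR + 1
  xL <- ppm[iL] + (ppm[iL + 1] - ppm[iL]) *
    (half - y[iL]) / (y[iL + 1] - y[iL])
  xR <- ppm[iR - 1] + (ppm[iR] - ppm[iR - 1]) *
    (half - y[iR - 1]) / (y[iR] - y[iR - 1])
  abs(xL - xR)
}

# independent brute-force adaptive-binning oracle: direct recursion over
# every split of every bin, no shared code with the implementation
bruteAibValue <- function(segs, i1, i2, R) {
  sub <- segs[, i1:i2, drop = FALSE]
  mx <- apply(sub, 1, max)
  sum(pmax((mx - segs[, i1]) * (mx - segs[, i2]), 0)^R)
}

bruteAib <- function(segs, i1, i2, R, vNoise) {
  n <- i2 - i1 + 1
  if (n < 3) return(list(c(i1, i2)))
  parent <- bruteAibValue(segs, i1, i2, R)
  bestJ <- NA; bestSum <- -Inf; bl <- NA; br <- NA
  for (j in i1:(i2 - 1)) {
    vl <- bruteAibValue(segs, i1, j, R)
    vr <- bruteAibValue(segs, j + 1, i2, R)
    if (vl + vr > bestSum) { bestSum <- vl + vr; bestJ <- j; bl <- vl; br <- vr }
  }
  if (bestSum > parent && bl > vNoise && br > vNoise)
    c(bruteAib(segs, i1, bestJ, R, vNoise),
      bruteAib(segs, bestJ + 1, i2, R, vNoise))
  else list(c(i1, i2))
}

# exhaustive 1-degree grid oracle for the autophase penalty, scanned
# around a centre guess
gridPhaseOracle <- function(spectrum, ppm, center, halfwidth = 15) {
  s <- spectrum / max(Mod(spectrum))
  pen <- function(a) {
    re <- Re(phaseSpectrum(s, ppm, a[1], a[2]))
    sum(pmin(re, 0)^2)
  }
  pts <- as.matrix(expand.grid(p0 = center[1] + (-halfwidth:halfwidth),
                               p1 = center[2] + (-halfwidth:halfwidth)))
  vals <- apply(pts, 1, pen)
  vmin <- min(vals)
  plateau <- pts[vals <= vmin + 1e-14, , drop = FALSE]
  colMeans(plateau)
}
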