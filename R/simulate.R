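#' Describe one resonance pattern
#'
#' A peak is a first-order multiplet of up to three equally spaced
#' Lorentzian sub-lines with binomial intensity ratios (singlet 1,
#' doublet 1:1, triplet 1:2:1). `height` is the total pattern amplitude:
#' sub-line heights are `height` times the normalized binomial weights, so
#' the pattern area is proportional to `height` irrespective of
#' multiplicity and a singlet's apex equals `height` exactly.
#'
#' @param center_ppm chemical shift of the pattern centre (ppm).
#' @param height pattern amplitude (arbitrary units, > 0).
#' @param width_hz full width at half maximum of each sub-line (Hz, > 0).
#' @param multiplicity 1 (singlet), 2 (doublet) or 3 (triplet).
#' @param j_hz coupling constant: spacing between adjacent sub-lines (Hz);
#'   ignored for singlets.
#' @return a `peakSpec` list.
#' @export
peakSpec <- function(center_ppm, height, width_hz, multiplicity = 1L, j_hz = 0) {
  stopifnot(height > 0, width_hz > 0, multiplicity >= 1)
  if (multiplicity > 3) stop("multiplicity > 3 not supported")
  structure(list(center_ppm = center_ppm, height = height,
                 width_hz = width_hz, multiplicity = as.integer(multiplicity),
                 j_hz = j_hz), class = "peakSpec")
}

# expand a peak into its Lorentzian sub-lines (centres in ppm, heights)
subLines <- function(peak, sfoMHz) {
  m <- peak$multiplicity
  jPpm <- peak$j_hz / sfoMHz
  if (m == 1L) {
    data.frame(center = peak$center_ppm, height = peak$height,
               width_hz = peak$width_hz)
  } else if (m == 2L) {
    data.frame(center = peak$center_ppm + c(-0.5, 0.5) * jPpm,
               height = rep(peak$height / 2, 2), width_hz = peak$width_hz)
  } else {
    data.frame(center = peak$center_ppm + c(-1, 0, 1) * jPpm,
               height = peak$height * c(0.25, 0.5, 0.25),
               width_hz = peak$width_hz)
  }
}

#' Plan a synthetic spectra set
#'
#' The plan fixes everything the generator draws: the peak list, the
#' per-sample random shift of each peak centre (the chemical-shift
#' variability, e.g. from pH differences, that alignment exists to fix),
#' an additive polynomial baseline drift, white noise, and multiplicative
#' group effects tied to experimental-factor levels. A plan plus a seed is
#' fully deterministic: the random stream is consumed in a documented
#' order (all jitters first, then all noise, sample-major), so identical
#' plans yield bit-identical spectra.
#'
#' @param n_samples number of spectra.
#' @param peaks list of [peakSpec()] objects.
#' @param ppm_jitter_sd standard deviation of the per-(sample, peak)
#'   centre shift (ppm, >= 0).
#' @param baseline_coeffs polynomial coefficients `c0, c1, ...` of the
#'   additive baseline evaluated in the normalized coordinate
#'   `u = (ppm - ppmMin)/(ppmMax - ppmMin)`.
#' @param noise_sd additive white-noise standard deviation (>= 0).
#' @param factor_assignment character vector of length `n_samples` giving
#'   each sample's level of the factor `group` (default: all `"A"`).
#' @param group_effects data.frame with columns `level`, `peak` (1-based
#'   index into `peaks`) and `factor` (multiplicative height effect), or
#'   NULL.
#' @param seed integer random seed.
#' @return a `simulationPlan` list.
#' @export
simulationPlan <- function(n_samples, peaks, ppm_jitter_sd = 0,
                           baseline_coeffs = 0, noise_sd = 0,
                           factor_assignment = NULL, group_effects = NULL,
                           seed = 1L) {
  stopifnot(n_samples >= 1, noise_sd >= 0, ppm_jitter_sd >= 0)
  if (inherits(peaks, "peakSpec")) peaks <- list(peaks)
  if (is.null(factor_assignment))
    factor_assignment <- rep("A", n_samples)
  if (length(factor_assignment) != n_samples)
    stop("factor_assignment must have one level per sample")
  structure(list(n_samples = as.integer(n_samples), peaks = peaks,
                 ppm_jitter_sd = ppm_jitter_sd,
                 baseline_coeffs = baseline_coeffs, noise_sd = noise_sd,
                 factor_assignment = as.character(factor_assignment),
                 group_effects = group_effects, seed = as.integer(seed)),
            class = "simulationPlan")
}

#' Evaluate a sum of Lorentzian patterns on a ppm grid
#'
#' Each sub-line contributes `h / (1 + ((ppm - c) / (w/2))^2)` with `w`
#' its FWHM converted to ppm. Used both by the spectrum simulator and as
#' the analytic reference when checking the FID processing chain.
#'
#' @param peaks list of [peakSpec()] objects.
#' @param ppm numeric grid (ppm).
#' @param sfoMHz spectrometer frequency (MHz), to convert Hz widths.
#' @param heights optional vector overriding each pattern's height.
#' @param centerShift optional per-peak additive centre shift (ppm).
#' @return numeric vector of intensities on `ppm`.
#' @export
lorentzianProfile <- function(peaks, ppm, sfoMHz, heights = NULL,
                              centerShift = NULL) {
  y <- numeric(length(ppm))
  for (k in seq_along(peaks)) {
    p <- peaks[[k]]
    if (!is.null(heights)) p$height <- heights[k]
    if (!is.null(centerShift)) p$center_ppm <- p$center_ppm + centerShift[k]
    sl <- subLines(p, sfoMHz)
    hw <- (sl$width_hz / sfoMHz) / 2   # HWHM in ppm
    for (i in seq_len(nrow(sl)))
      y <- y + sl$height[i] / (1 + ((ppm - sl$center[i]) / hw[i])^2)
  }
  y
}

# per-sample pattern heights after group effects
effectiveHeights <- function(plan) {
  base <- vapply(plan$peaks, `[[`, numeric(1), "height")
  H <- matrix(base, nrow = plan$n_samples, ncol = length(base), byrow = TRUE)
  ge <- plan$group_effects
  if (!is.null(ge)) for (i in seq_len(nrow(ge))) {
    rows <- plan$factor_assignment == ge$level[i]
    H[rows, ge$peak[i]] <- H[rows, ge$peak[i]] * ge$factor[i]
  }
  H
}

# the full jitter matrix (samples x peaks), always drawn so that the
# stream position is identical whether or not jitter is used
drawJitter <- function(plan) {
  K <- length(plan$peaks)
  matrix(stats::rnorm(plan$n_samples * K), nrow = plan$n_samples,
         byrow = TRUE) * plan$ppm_jitter_sd
}

checkPeaksInAxis <- function(plan, axis) {
  for (p in plan$peaks) {
    sl <- subLines(p, axis@sfoMHz)
    if (any(sl$center < axis@ppmMin) || any(sl$center > axis@ppmMax))
      stop(sprintf("peak at %.4f ppm falls outside the axis [%.4f, %.4f]",
                   p$center_ppm, axis@ppmMin, axis@ppmMax))
  }
  invisible(TRUE)
}

#' Simulate a set of frequency-domain spectra
#'
#' Renders every sample as the sum of its Lorentzian patterns (centres
#' jittered per sample and peak), plus the polynomial baseline, plus white
#' Gaussian noise, on the uniform descending ppm grid defined by `axis`.
#'
#' @param plan a [simulationPlan()].
#' @param axis a [spectralAxis()].
#' @return a [SpectrumSet-class] with sample ids `S01, S02, ...` and one
#'   factor column `group`.
#' @export
simulateSpectrumSet <- function(plan, axis) {
  stopifnot(inherits(plan, "simulationPlan"), is(axis, "SpectralAxis"))
  checkPeaksInAxis(plan, axis)
  P <- axis@points
  ppm <- seq(axis@ppmMax, axis@ppmMin, length.out = P)
  u <- (ppm - axis@ppmMin) / (axis@ppmMax - axis@ppmMin)
  base <- numeric(P)
  for (j in seq_along(plan$baseline_coeffs))
    base <- base + plan$baseline_coeffs[j] * u^(j - 1)
  H <- effectiveHeights(plan)
  withSeed(plan$seed, {
    jit <- drawJitter(plan)
    noise <- matrix(stats::rnorm(plan$n_samples * P), nrow = plan$n_samples,
                    byrow = TRUE) * plan$noise_sd
    m <- matrix(0, plan$n_samples, P)
    for (s in seq_len(plan$n_samples))
      m[s, ] <- lorentzianProfile(plan$peaks, ppm, axis@sfoMHz,
                                  heights = H[s, ], centerShift = jit[s, ]) +
        base + noise[s, ]
    sd <- data.frame(sample_id = sprintf("S%02d", seq_len(plan$n_samples)),
                     group = plan$factor_assignment,
                     stringsAsFactors = FALSE)
    spectrumSet(m, ppm, sd)
  })
}

#' Simulate one free induction decay
#'
#' Generates the complex time-domain signal
#' `sum_k a_k exp(i 2 pi nu_k t - pi w_k t)` over the dwell grid implied
#' by the axis spectral width, where `nu_k` is each sub-line's offset from
#' the carrier (placed at the centre of the ppm window) and `w_k` its FWHM
#' in Hz. Amplitudes are `a_k = h_k * pi * w_k` so that the Fourier
#' transform of the FID (see [transformFid()]) reproduces the
#' frequency-domain simulation of the same plan: the analytic transform of
#' a unit exponential decay has apex `1/(pi w)`.
#'
#' Centre jitter is drawn from the same random stream as
#' [simulateSpectrumSet()], so sample `s` of the FID simulation carries
#' exactly the jitter of spectrum `s`. Noise and baseline drift are
#' frequency-domain artefacts in this generator and are not added to FIDs.
#'
#' @param plan a [simulationPlan()].
#' @param axis a [spectralAxis()]; `points` is the number of complex FID
#'   points.
#' @param sample which sample of the plan to render (1-based).
#' @return a [FidRecord-class].
#' @export
simulateFid <- function(plan, axis, sample = 1L) {
  stopifnot(inherits(plan, "simulationPlan"), is(axis, "SpectralAxis"),
            sample >= 1, sample <= plan$n_samples)
  checkPeaksInAxis(plan, axis)
  swPpm <- axis@ppmMax - axis@ppmMin
  swHz <- swPpm * axis@sfoMHz
  dwell <- 1 / swHz
  carrier <- (axis@ppmMax + axis@ppmMin) / 2
  H <- effectiveHeights(plan)
  jit <- withSeed(plan$seed, drawJitter(plan))
  t <- (seq_len(axis@points) - 1) * dwell
  sig <- complex(real = numeric(axis@points), imaginary = numeric(axis@points))
  for (k in seq_along(plan$peaks)) {
    p <- plan$peaks[[k]]
    p$height <- H[sample, k]
    p$center_ppm <- p$center_ppm + jit[sample, k]
    sl <- subLines(p, axis@sfoMHz)
    for (i in seq_len(nrow(sl))) {
      nu <- (sl$center[i] - carrier) * axis@sfoMHz          # Hz from carrier
      a <- sl$height[i] * pi * sl$width_hz[i]
      sig <- sig + a * exp((2i * pi * nu - pi * sl$width_hz[i]) * t)
    }
  }
  fidRecord(sig, dwellUs = dwell * 1e6, sfoMHz = axis@sfoMHz,
            swPpm = swPpm, o1Hz = carrier * axis@sfoMHz,
            vendor = "synthetic",
            sampleId = sprintf("S%02d", as.integer(sample)))
}

# sw in ppm derived from an axis spec (used by both domains)
setMethod("show", "SpectralAxis", function(object) {
  cat(sprintf("SpectralAxis: %d points, %.4f .. %.4f ppm @ %.2f MHz\n",
              object@points, object@ppmMin, object@ppmMax, object@sfoMHz))
})
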