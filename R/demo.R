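#' The canonical synthetic 1H study
#'
#' A six-sample, two-group plant-extract-like 1H fixture at 500 MHz used
#' throughout the examples, tests and the acceptance script: a TSP-like
#' reference singlet at 0 ppm (1 mM equivalent), three analyte patterns
#' with known concentrations and proton counts (singlet 0.25 mM/1H at
#' 2 ppm, doublet 0.5 mM/2H at 3.2 ppm, triplet 2 mM/3H at 5.5 ppm —
#' pattern heights are `conc * nH` relative to the reference since all
#' lines share one 1.5 Hz width), plus a marker singlet at 8 ppm doubled
#' in group B. Peak centres jitter by 0.003 ppm sd between samples, the
#' chemical-shift variability alignment exists to remove.
#'
#' @param n_samples number of samples (split into groups A/B).
#' @param seed random seed.
#' @param ppm_jitter_sd per-(sample, peak) centre shift sd (ppm).
#' @param noise_sd white-noise sd (arbitrary units; reference apex = 1).
#' @param baseline_coeffs additive polynomial drift coefficients.
#' @return a [simulationPlan()].
#' @export
demoPlan <- function(n_samples = 6L, seed = 42L, ppm_jitter_sd = 0.003,
                     noise_sd = 0.002, baseline_coeffs = 0) {
  groups <- rep(c("A", "B"), length.out = n_samples)
  simulationPlan(
    n_samples = n_samples,
    peaks = list(
      peakSpec(0.0, height = 1.0, width_hz = 1.5),                  # TSP ref
      peakSpec(2.0, height = 0.25, width_hz = 1.5),                 # 0.25 mM, 1H
      peakSpec(3.2, height = 1.0, width_hz = 1.5, multiplicity = 2,
               j_hz = 7),                                           # 0.5 mM, 2H
      peakSpec(5.5, height = 6.0, width_hz = 1.5, multiplicity = 3,
               j_hz = 7),                                           # 2 mM, 3H
      peakSpec(8.0, height = 0.5, width_hz = 1.5)),                 # marker
    ppm_jitter_sd = ppm_jitter_sd,
    baseline_coeffs = baseline_coeffs,
    noise_sd = noise_sd,
    factor_assignment = sort(groups),
    group_effects = data.frame(level = "B", peak = 5L, factor = 2),
    seed = seed)
}

#' @rdname demoPlan
#' @param points axis points (default 8192).
#' @export
demoAxis <- function(points = 8192L) {
  spectralAxis(sfoMHz = 500, ppmMin = -0.5, ppmMax = 9.5, points = points)
}

#' Concentrations and proton counts of the demo analytes
#'
#' The ground truth of [demoPlan()]: bucket centres, proton counts and
#' true concentrations, plus the matching manual bucket ranges
#' (+/- 0.1 ppm) used for quantification.
#'
#' @return a data.frame with columns `center`, `protons`, `conc_mM`,
#'   `metabolite`.
#' @export
demoTruth <- function() {
  data.frame(
    center = c(0.0, 2.0, 3.2, 5.5),
    protons = c(1L, 1L, 2L, 3L),
    conc_mM = c(1.0, 0.25, 0.5, 2.0),
    metabolite = c("TSP", "analyte1", "analyte2", "analyte3"),
    stringsAsFactors = FALSE)
}
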