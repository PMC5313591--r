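---
title: "Processing 1D NMR spectra sets with nmrflow"
author: "nmrflow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing 1D NMR spectra sets with nmrflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrflow)
```

# Scope and model of the data

nmrflow processes *sets* of 1D (1H or 13C) NMR spectra the way an
NMR-based metabolomics study needs them processed: N free induction
decays acquired with the same number of points become an N x P matrix of
real absorptive spectra on one shared, uniformly spaced, descending ppm
axis (`SpectrumSet`), carrying a sample table of experimental-factor
levels. Every subsequent operation — baseline correction, chemical-shift
calibration, zone-wise alignment, bucketing, signal-to-noise filtering,
quantification and export — acts on that container, on the full set or on
the subset belonging to one factor level, and records itself in the
set's provenance as a plain-text macro command. A workflow tuned on one
study can therefore be replayed verbatim, in batch, on a comparable one.

Two analysis routes are supported downstream of processing. In the
*fingerprinting* route the whole usable axis is divided into buckets
(uniform or adaptive), filtered on signal-to-noise, and exported as a
data matrix for multivariate statistics. In the *targeted* route the
analyst names the ppm ranges to integrate, corrects the baseline locally
under each one, and exports a five-table quantification workbook.

# The processing chain

## From FID to spectrum

A `FidRecord` carries the complex time-domain signal plus dwell time,
spectrometer frequency, spectral width, carrier offset and digital-filter
group delay. `transformFid()`:

1. circularly left-shifts by the rounded group delay (Bruker digital
   filters), correcting any fractional remainder with a first-order
   phase — a documented assumption, since vendors do not publish one
   canonical scheme;
2. halves the first time-domain point (the trapezoid-rule end
   correction, which suppresses the constant baseline offset a plain DFT
   of a causal signal produces);
3. zero-fills to a power of two, transforms, scales by the dwell time so
   intensities match the continuous-transform convention (a unit
   exponential decay of full width `w` Hz peaks at `1/(pi w)`), and maps
   frequencies to ppm with the carrier at `o1Hz / sfoMHz`.

With this convention the transform of a synthetic FID reproduces the
frequency-domain simulation of the same peaks to about 1e-6 of the apex
in the real (absorption) channel; the residual sits in the dispersion
channel and, at spectrum edges, in the aliased periodic tails of the
discrete transform — which is why the strictest comparison tests widen
the spectral window until those tails drop below tolerance.

Exponential apodization (`apodize()`) trades resolution for
signal-to-noise; the 0.3 Hz default is a conventional 1H choice, not a
recommendation derived from data.

## Automatic phasing

`autophase()` minimizes the negative-intensity penalty
`sum(min(0, Re)^2)` — appropriate for spectra whose correctly phased
form is predominantly positive. An entropy-based objective was
considered and rejected: it needs more tuning and delivers the same
answer on Lorentzian mixtures. One genuine subtlety drove the search
design: on a clean absorptive spectrum the penalty is *exactly zero on a
small neighbourhood* of the true phase (misphasing by a fraction of a
degree produces dispersion admixtures too small to push any point
negative), so gradient or simplex refinement cannot localize the optimum
within that plateau, and any answer inside it is equally "optimal" under
the objective. The implementation therefore scans a 10-degree coarse
grid, then a 1-degree and a 0.25-degree local grid, and returns the
*centre* of the zero plateau, which brackets the true phase; Nelder-Mead
refinement is used only when no zero plateau exists (noisy data). On
clean synthetic spectra with peaks spread across the window this
recovers known dephasings to well under a degree; a warning status flags
inputs (e.g. pure noise) where the best phasing still leaves a
substantial negative fraction. Consequently a sub-degree residual phase
error — and the proportional dispersion admixture — is the accuracy
floor of *any* negativity-based autophaser; exact spectral restoration
requires the exact angles.

## Baseline correction

The global method is asymmetric least squares: a Whittaker smoother with
a second-difference penalty (`smoothing`, default 1e7 for axes of a few
thousand points) under asymmetric weights (`asymmetry` on positive
residuals, default 0.05), iterated to weight convergence (at most 10
rounds). Two parameters, robust in dense peak regions, and fast through
a sparse banded solve. The weighting is deliberately envelope-seeking:
with small `asymmetry` the baseline tracks the lower envelope of the
noise, which biases the corrected noise floor upward by roughly one
noise standard deviation. Where that bias matters more than peak
rejection (e.g. quality checks on peak-free regions), a moderate
`asymmetry` of 0.3-0.5 is the right setting; the tests document both
regimes.

The local method is the targeted-route workhorse: inside a user zone
only, the straight chord joining the zone-edge intensities (each edge
estimated as the mean of the 3 outermost in-zone points) is subtracted.
This removes the shoulder an intense neighbour casts under a small
singlet, doublet or triplet, so its integral is no longer polluted. It
is pattern-agnostic and exactly zone-confined — points outside the zone
are bit-identical. It is *not* a deconvolution: heavily overlapped
patterns are out of scope. Note the chord also removes the pattern's own
tail level at the zone edges, so quantitative comparisons should put the
calibration standard through the same zone protocol — which is how the
package's own checks define the oracle.

Solvent and contaminant regions are removed with `zeroZones()`: in-zone
intensities become exactly 0 and the zones are recorded on the set so no
bucketing strategy will ever produce a bucket intersecting them.

## Calibration and alignment

`calibrateSpectra()` shifts each whole spectrum by an integer number of
points so the apex of a reference resonance (TSP/DSS at 0 ppm, say)
lands on the axis point nearest its nominal shift.

Peak positions also wander *between* samples (pH, ionic strength), and
two zone-wise aligners fix that. `alignZoneLS()` picks, per spectrum,
the integer shift in `[-max_shift, max_shift]` minimizing the squared
distance to the reference (the pointwise mean over the selection — mean
rather than median because it matches the least-squares objective);
candidates are scanned in order of increasing magnitude so the smallest
equally good shift wins, vacated points take the zone-edge value (zero
filling would create steps that corrupt adjacent buckets), and a best
shift on the search boundary is treated as out of range: that spectrum
is left unchanged with a warning. `alignZonePTW()` fits a polynomial
coordinate warp `w(x) = a0 + a1 x (+ a2 x^2)` by deterministic
Nelder-Mead (identity start, 200-iteration cap, 1e-8 tolerance,
parameter scaling `1, 1e-3, 1e-6` to keep the simplex conditioned) and
applies it by linear interpolation. Warping assumes every spectrum has
the same number of peaks in the zone; when it does not, the dispersion
check below fails and the data come back unchanged.

Every alignment reports a dispersion statistic — the mean over in-zone
axis points of the across-spectra standard deviation — before and after.
If the statistic would not decrease, the operation rolls itself back and
warns: accepted alignments never increase dispersion, by construction.
Alignment fixes *relative* position: recovered shifts match the applied
displacements up to the common offset of the mean reference, which is
zero when the displacements average out (and calibration handles the
absolute anchor).

## Bucketing, SNR, filtering

Three strategies produce a `BucketTable` (descending centre order,
pairwise disjoint, labels `B<centre to 4 decimals>`):

* `uniformBuckets()` tiles a zone with fixed-width buckets; a final
  partial bucket survives only if at least half the nominal width;
  buckets are clipped against excluded zones, straddlers split.
* `aibBuckets()` is adaptive intelligent binning: recursive edge
  placement maximizing the bin value
  `sum over spectra of ((Imax - Ileft)(Imax - Iright))^R` (default
  `R = 0.5`). A split is accepted only if the children's summed value
  exceeds the parent's and both children exceed the noise minimum
  `N * noise_floor^(2R)` — the value a bin whose maximum sits at the
  noise floor would score, which is our concrete reading of "the same
  formula on a noise-only bin". Leaves below that minimum are dropped,
  so pure-noise zones yield no buckets. The recursion needs no reference
  spectrum and no bucket-width parameter.
* `manualBuckets()` takes explicit ppm ranges, the targeted route.

`integrateBuckets()` uses half-open membership `(ppm_min, ppm_max]` for
the `sum` rule — contiguous buckets never share a point, making
integration exactly additive under bucket splitting — and closed
membership for the trapezoid rule, so a constant of height h over a
grid-aligned bucket of width w integrates to exactly `h*w`.

`snrMatrix()` estimates each spectrum's noise as the standard deviation
of a linearly detrended, user-asserted signal-free zone (at least 32
points) and reports `max in-bucket intensity / (2 * noise_sd)` — the
peak-to-peak convention halved; a convention must be fixed for the
matrix to be reproducible and this one is stated in the export metadata.
`filterBySnr()` keeps a bucket iff at least `min_fraction` of spectra
reach the threshold; it is monotone in the threshold by construction.

## Quantification and export

`quantify()` applies the standard internal-reference proportionality

$$\mathrm{conc}(s,b) = C_{\mathrm{ref}}
  \frac{A(s,b) / n\mathrm{H}_b}{A(s,\mathrm{ref}) / n\mathrm{H}_{\mathrm{ref}}}$$

— integrals normalized by proton counts against a bucket of known
concentration. It is scale-equivariant per spectrum: rescaling all of a
spectrum's integrals leaves its concentrations unchanged.
`exportQhnmr()` writes one workbook with exactly five sheets (`samples`,
`buckets`, `snr`, `data_matrix`, `quantifications`), defaults pre-filled
for the analyst to adjust, full-precision numbers, and the formula above
in the document properties. `exportMatrix()` writes statistics-ready TSV
flavors, including the single-table layout (sample, class = first
factor, buckets) that online statistics tools ingest directly.

The workbook writer/reader is a minimal XLSX layer built directly on the
zip container format with deflate streams and CRC-32 computed in
package code; archive timestamps are fixed, so identical tables always
produce byte-identical files — which is what makes SOP replays
verifiable by checksum.

# Macros and batch replay

Every set-transforming operation appends one line `OP key=value ...` to
the set's provenance; `writeMacro()`/`readMacro()` persist such lines
with a versioned header, and `replayMacro()` executes them against a raw
study directory (one vendor experiment directory per sample plus a
`samples.tsv` factor table), logging each step and aborting with the
failing command's index. ppm parameters are serialized to 4 decimals;
operations accept full precision, so the bit-identical replay guarantee
holds for 4-decimal zone specifications — which all shipped workflows
use. Two replays of one macro on one study produce byte-identical
exports. The `inst/scripts/nmrflow` Rscript exposes `process`,
`buckets`, `export`, `simulate` and `inspect` verbs over these
functions.

# The synthetic-data generator

`simulationPlan()` + `simulateSpectrumSet()`/`simulateFid()` generate
everything the test suite and acceptance script consume; no acquired
data are required or included. A plan fixes Lorentzian patterns
(singlet/doublet/triplet with binomial 1, 1:1, 1:2:1 sub-line ratios —
the first-order approximation; Gaussian/Voigt lineshapes are out of
scope since liquid-state 1D lines are Lorentzian to good accuracy),
per-(sample, peak) Gaussian centre jitter, a polynomial baseline in the
normalized axis coordinate, white Gaussian noise, and multiplicative
factor-level effects on pattern heights. One random stream per plan,
consumed in documented order (all jitters first, then all noise,
sample-major), makes identical plans bit-identical and lets the FID
renderer reuse exactly the jitter of the corresponding spectrum. FID
amplitudes are scaled `h * pi * w` so transform and frequency-domain
simulation agree in apex height.

The canonical study (`demoPlan()`, `demoAxis()`) is a six-sample,
two-group 1H fixture at 500 MHz, 8192 points over -0.5..9.5 ppm: a
TSP-like 1 mM reference singlet at 0 ppm, analytes at 0.25 mM/1H,
0.5 mM/2H and 2 mM/3H (heights `conc * nH` relative to the reference,
all lines 1.5 Hz wide), a group-B marker at 8 ppm, 0.003 ppm centre
jitter and 0.002 noise sd — chemical-shift variability and noise levels
typical of plant-extract 1H work. These sizes keep every check on one
CPU core in seconds while leaving peaks several points wide.

What the generator does *not* emulate — and what passing tests therefore
do not demonstrate — includes solvent-suppression artifacts, 13C
satellites, field-inhomogeneity lineshape distortion, rolling baselines
correlated with peak density, ringing from truncated FIDs, and
peak-count differences between samples except where a test constructs
them explicitly. Results on real spectra depend on acquisition quality
in ways no synthetic fixture certifies.

# Numerical choices and degenerate inputs

* Zones are closed ppm intervals; a zone must contain at least 8 points
  for baseline/alignment work (3 for adaptive binning). Zones outside
  the axis, overlapping an excluded zone, or with a calibration apex on
  the zone edge raise errors naming the offender.
* Integer-shift ties break toward the smaller magnitude (negative
  first); the scan order is fixed, so results are deterministic.
* The SNR noise zone is rejected as degenerate when its detrended
  standard deviation is zero to within 1e-10 of the data scale.
* Vendor readers validate declared sizes against file sizes and raise
  format errors naming the file; unknown word types and missing
  parameters are refused, not guessed. Bruker group delay falls back
  from GRPDLY to the DECIM/DSPFVS table, else 0.
* int32 fixtures quantize to the nearest integer — writers do not
  rescale, so small-amplitude signals should be scaled before writing;
  float64 (Bruker DTYPA=2) round trips exactly, Varian float32 to ~1e-7.

# Known limitations

Single-procno 1D data only; no JEOL/Magritek formats; no linear
prediction, reference deconvolution or time-domain solvent filtering; no
peak-model deconvolution for crowded regions (the local chord assumes
separable patterns); normalization beyond constant-sum is delegated to
downstream statistics tools; nmrML support targets this package's own
minimal dialect of the format, not the full schema.
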