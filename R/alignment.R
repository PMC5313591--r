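# Chemical-shift calibration and zone-wise alignment. Both aligners use
# the pointwise mean of the selected spectra as reference and fall back to
# identity (with a warning) whenever the across-spectra dispersion (mean
# over in-zone axis points of the across-spectra standard deviation) would
# not decrease.

zoneDispersion <- function(m, idx, rows) {
  if (length(rows) < 2) return(0)
  mean(apply(m[rows, idx, drop = FALSE], 2, stats::sd))
}

checkNotExcluded <- function(set, zone) {
  ex <- excludedZones(set)
  if (nrow(ex) && any(zone@ppmMin < ex[, 2] & zone@ppmMax > ex[, 1]))
    stop(sprintf("zone [%.4f, %.4f] overlaps an excluded zone",
                 zone@ppmMin, zone@ppmMax))
}

# shift a segment by s points (positive = towards higher index), filling
# vacated points with the segment's own edge value
shiftSegment <- function(seg, s) {
  L <- length(seg)
  src <- seq_len(L) - s
  out <- seg[pmin(pmax(src, 1L), L)]
  out
}

#' Calibrate the ppm axis against a reference resonance
#'
#' Locates the apex of the reference resonance (e.g. TSP/DSS) inside the
#' zone for every spectrum and shifts each whole spectrum by an integer
#' number of points so the apex lands on the axis point nearest
#' `ref_ppm`. Vacated edge points are filled with 0.
#'
#' @param set a [SpectrumSet-class].
#' @param zone a [PpmZone-class] containing the reference resonance in
#'   every spectrum.
#' @param ref_ppm nominal chemical shift of the reference (ppm).
#' @return the calibrated [SpectrumSet-class].
#' @export
calibrateSpectra <- function(set, zone, ref_ppm) {
  stopifnot(is(set, "SpectrumSet"), is(zone, "PpmZone"))
  ppm <- ppmAxis(set)
  idx <- stopIfZoneOutside(ppm, zone, minPoints = 3L)
  target <- which.min(abs(ppm - ref_ppm))
  m <- intensities(set)
  P <- ncol(m)
  for (r in seq_len(nrow(m))) {
    seg <- m[r, idx]
    a <- which.max(seg)
    if (a == 1L || a == length(idx))
      stop("calibration apex at zone edge for sample ",
           sampleNames(set)[r], "; widen the zone")
    s <- target - idx[a]
    if (s != 0) {
      src <- seq_len(P) - s
      ok <- src >= 1 & src <= P
      row <- numeric(P)
      row[ok] <- m[r, src[ok]]
      m[r, ] <- row
    }
  }
  set <- setIntensities(set, m)
  addProvenance(set, sprintf("CALIBRATE zone=%s:%s ref=%s",
                             fmtPpm(zone@ppmMin), fmtPpm(zone@ppmMax),
                             fmtPpm(ref_ppm)))
}

#' Zone alignment by least-squares integer shifting
#'
#' For every selected spectrum, finds the integer shift `s` in
#' `[-max_shift, max_shift]` minimizing the squared difference between
#' the shifted in-zone segment and the reference (the pointwise mean over
#' the selection), and applies it within the zone only; vacated points
#' take the zone-edge value. Shifts are scanned in order of increasing
#' magnitude so the smallest equally good shift wins. A spectrum whose
#' best shift sits on the search boundary is judged out of range: it is
#' left unchanged with a warning. If the dispersion statistic does not
#' decrease the whole alignment is rolled back.
#'
#' @param set a [SpectrumSet-class].
#' @param zone a [PpmZone-class].
#' @param selection optional subset (row indices or
#'   `list(factor=, level=)`); non-selected spectra are untouched.
#' @param max_shift maximum shift magnitude in points (>= 1).
#' @return `list(set, report)`: the aligned set and an alignment report
#'   (`zone`, `method`, `shifts`, `dispersion_before`, `dispersion_after`,
#'   `accepted`, `warnings`).
#' @export
alignZoneLS <- function(set, zone, selection = NULL, max_shift = 20L) {
  stopifnot(is(set, "SpectrumSet"), is(zone, "PpmZone"), max_shift >= 1)
  checkNotExcluded(set, zone)
  ppm <- ppmAxis(set)
  idx <- stopIfZoneOutside(ppm, zone, minPoints = 8L)
  rows <- resolveSelection(set, selection)
  m <- intensities(set)
  ref <- colMeans(m[rows, idx, drop = FALSE])
  candidates <- order(abs(seq(-max_shift, max_shift)))  # 0, -1, 1, -2, ...
  candidates <- seq(-max_shift, max_shift)[candidates]
  shifts <- integer(nrow(m))
  warns <- character(0)
  before <- zoneDispersion(m, idx, rows)
  m2 <- m
  for (r in rows) {
    seg <- m[r, idx]
    sse <- vapply(candidates,
                  function(s) sum((shiftSegment(seg, s) - ref)^2), numeric(1))
    s <- candidates[which.min(sse)]
    if (abs(s) == max_shift) {
      warns <- c(warns, sprintf(
        "sample %s: optimal shift at search boundary (%+d); left unchanged",
        sampleNames(set)[r], s))
      s <- 0L
    }
    shifts[r] <- s
    if (s != 0) m2[r, idx] <- shiftSegment(seg, s)
  }
  after <- zoneDispersion(m2, idx, rows)
  accepted <- after <= before + 1e-12
  if (!accepted) {
    warns <- c(warns, "alignment increased dispersion; data left unchanged")
    m2 <- m
    after <- before
    shifts[] <- 0L
  }
  for (w in warns) warning(w, call. = FALSE)
  set <- setIntensities(set, m2)
  set <- addProvenance(set, sprintf("ALIGN_LS zone=%s:%s max=%d%s",
                                    fmtPpm(zone@ppmMin), fmtPpm(zone@ppmMax),
                                    as.integer(max_shift),
                                    selSuffix(selection)))
  list(set = set,
       report = list(zone = zone, method = "least_squares", shifts = shifts,
                     dispersion_before = before, dispersion_after = after,
                     accepted = accepted, warnings = warns))
}

ptwObjective <- function(a, seg, ref, x) {
  w <- a[1] + a[2] * x + if (length(a) == 3) a[3] * x^2 else 0
  warped <- stats::approx(x, seg, xout = w, rule = 2)$y
  sum((warped - ref)^2)
}

#' Zone alignment by parametric time warping
#'
#' Warps each selected spectrum's in-zone segment with a low-order
#' polynomial coordinate map `w(x) = a0 + a1 x (+ a2 x^2)` (point
#' coordinates, identity start), chosen to minimize the squared
#' difference between the linearly interpolated warped segment and the
#' reference (pointwise mean over the selection). Suits regions where all
#' spectra carry the same number of peaks; when they do not, the
#' dispersion check fails and the data are returned unchanged with a
#' warning. Deterministic Nelder-Mead refinement, 200 iterations cap,
#' tolerance 1e-8.
#'
#' @param set a [SpectrumSet-class].
#' @param zone a [PpmZone-class].
#' @param selection optional subset.
#' @param degree 1 or 2 (warp polynomial degree).
#' @return `list(set, report)` as in [alignZoneLS()], with `coefficients`
#'   (one row per spectrum) in the report.
#' @export
alignZonePTW <- function(set, zone, selection = NULL, degree = 1L) {
  stopifnot(is(set, "SpectrumSet"), is(zone, "PpmZone"), degree %in% 1:2)
  checkNotExcluded(set, zone)
  ppm <- ppmAxis(set)
  idx <- stopIfZoneOutside(ppm, zone, minPoints = 8L)
  rows <- resolveSelection(set, selection)
  m <- intensities(set)
  ref <- colMeans(m[rows, idx, drop = FALSE])
  x <- seq_along(idx)
  init <- if (degree == 1L) c(0, 1) else c(0, 1, 0)
  coefs <- matrix(NA_real_, nrow(m), degree + 1)
  warns <- character(0)
  before <- zoneDispersion(m, idx, rows)
  m2 <- m
  for (r in rows) {
    seg <- m[r, idx]
    if (stats::sd(seg) < 1e-12) {
      warns <- c(warns, sprintf("sample %s: flat segment, warp singular",
                                sampleNames(set)[r]))
      coefs[r, ] <- init
      next
    }
    o0 <- ptwObjective(init, seg, ref, x)
    # coefficient scales differ by orders of magnitude (a0 ~ points,
    # a1 ~ 1e-3 around 1, a2 ~ 1e-6); parscale keeps the simplex usable
    scales <- c(1, 1e-3, 1e-6)[seq_len(degree + 1)]
    opt <- stats::optim(init, ptwObjective, seg = seg, ref = ref, x = x,
                        method = "Nelder-Mead",
                        control = list(maxit = 200, reltol = 1e-8,
                                       parscale = scales))
    a <- if (opt$value < o0 - 1e-12 * (1 + o0)) opt$par else init
    coefs[r, ] <- a
    if (!all(a == init)) {
      w <- a[1] + a[2] * x + if (degree == 2L) a[3] * x^2 else 0
      m2[r, idx] <- stats::approx(x, seg, xout = w, rule = 2)$y
    }
  }
  after <- zoneDispersion(m2, idx, rows)
  accepted <- after <= before + 1e-12
  if (!accepted) {
    warns <- c(warns, "warping increased dispersion; data left unchanged")
    m2 <- m
    after <- before
    coefs[rows, ] <- matrix(init, length(rows), degree + 1, byrow = TRUE)
  }
  for (w in warns) warning(w, call. = FALSE)
  set <- setIntensities(set, m2)
  set <- addProvenance(set, sprintf("ALIGN_PTW zone=%s:%s degree=%d%s",
                                    fmtPpm(zone@ppmMin), fmtPpm(zone@ppmMax),
                                    as.integer(degree), selSuffix(selection)))
  list(set = set,
       report = list(zone = zone, method = "ptw", coefficients = coefs,
                     dispersion_before = before, dispersion_after = after,
                     accepted = accepted, warnings = warns))
}
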