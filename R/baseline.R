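#' Global baseline correction (asymmetric least squares)
#'
#' Estimates each spectrum's slowly varying baseline with a Whittaker
#' smoother under asymmetric weighting — points above the current
#' baseline (peaks) get weight `asymmetry`, points below get
#' `1 - asymmetry` — and subtracts it. Weights are re-estimated until they
#' stop changing (at most 10 iterations). Two parameters only: the
#' second-difference penalty `smoothing` and the weight `asymmetry`.
#'
#' @param set a [SpectrumSet-class].
#' @param smoothing second-difference penalty weight (> 0); larger values
#'   give stiffer baselines. Default 1e7 suits axes of a few thousand
#'   points.
#' @param asymmetry weight of positive residuals, in (0, 1); small values
#'   (default 0.05) let peaks stand above the baseline.
#' @param selection optional subset (row indices or
#'   `list(factor=, level=)`); other spectra are untouched.
#' @return the corrected [SpectrumSet-class].
#' @export
globalBaseline <- function(set, smoothing = 1e7, asymmetry = 0.05,
                           selection = NULL) {
  stopifnot(is(set, "SpectrumSet"), smoothing > 0,
            asymmetry > 0, asymmetry < 1)
  m <- intensities(set)
  if (!all(is.finite(m))) stop("non-finite intensities in SpectrumSet")
  rows <- resolveSelection(set, selection)
  p <- ncol(m)
  D <- Matrix::bandSparse(p - 2, p, k = 0:2,
                          diagonals = list(rep(1, p - 2), rep(-2, p - 2),
                                           rep(1, p - 2)))
  DtD <- smoothing * Matrix::crossprod(D)
  for (r in rows) {
    y <- m[r, ]
    w <- rep(1, p)
    for (it in 1:10) {
      z <- as.numeric(Matrix::solve(Matrix::Diagonal(x = w) + DtD, w * y))
      wNew <- ifelse(y > z, asymmetry, 1 - asymmetry)
      if (all(wNew == w)) break
      w <- wNew
    }
    m[r, ] <- y - z
  }
  set <- setIntensities(set, m)
  addProvenance(set, sprintf("GBASELINE smoothing=%g asymmetry=%g%s",
                             smoothing, asymmetry, selSuffix(selection)))
}

selSuffix <- function(selection) {
  if (is.list(selection) && !is.null(selection$factor))
    sprintf(" factor=%s level=%s", selection$factor, selection$level)
  else ""
}

#' Local (zone-confined) baseline correction
#'
#' Inside the zone only, subtracts the straight chord joining the
#' zone-edge intensities (each edge value is the mean of the 3 outermost
#' in-zone points on that side). This removes the shoulder an intense
#' neighbouring peak casts under a small pattern so its integral is no
#' longer polluted, while leaving everything outside the zone untouched.
#'
#' @param set a [SpectrumSet-class].
#' @param zone a [PpmZone-class] of at least 8 points.
#' @param selection optional subset (row indices or
#'   `list(factor=, level=)`).
#' @return the corrected [SpectrumSet-class].
#' @export
localBaseline <- function(set, zone, selection = NULL) {
  stopifnot(is(set, "SpectrumSet"), is(zone, "PpmZone"))
  idx <- stopIfZoneOutside(ppmAxis(set), zone, minPoints = 8L)
  m <- intensities(set)
  rows <- resolveSelection(set, selection)
  L <- length(idx)
  frac <- (seq_len(L) - 1) / (L - 1)
  for (r in rows) {
    seg <- m[r, idx]
    left <- mean(seg[1:3])
    right <- mean(seg[(L - 2):L])
    m[r, idx] <- seg - (left + (right - left) * frac)
  }
  set <- setIntensities(set, m)
  addProvenance(set, sprintf("LBASELINE zone=%s:%s%s", fmtPpm(zone@ppmMin),
                             fmtPpm(zone@ppmMax), selSuffix(selection)))
}

#' Zero solvent/contaminant zones
#'
#' Sets intensities inside the given zones to exactly 0 in every spectrum
#' and records the zones as excluded, so no bucketing strategy will ever
#' create a bucket intersecting them.
#'
#' @param set a [SpectrumSet-class].
#' @param zones a [PpmZone-class] or list of them.
#' @return the modified [SpectrumSet-class].
#' @export
zeroZones <- function(set, zones) {
  stopifnot(is(set, "SpectrumSet"))
  if (is(zones, "PpmZone")) zones <- list(zones)
  if (!length(zones)) return(set)
  m <- intensities(set)
  for (z in zones) {
    idx <- zoneIndices(ppmAxis(set), z)
    if (length(idx)) m[, idx] <- 0
  }
  set <- setIntensities(set, m)
  add <- do.call(rbind, lapply(zones, function(z) c(z@ppmMin, z@ppmMax)))
  set@excluded <- mergeIntervals(rbind(set@excluded, add))
  addProvenance(set, paste0("ZERO zones=",
    paste(vapply(zones, function(z)
      paste0(fmtPpm(z@ppmMin), ":", fmtPpm(z@ppmMax)), character(1)),
      collapse = ",")))
}
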