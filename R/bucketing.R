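# Bucketing strategies, integration, SNR matrix and bucket filtering.
#
# Point membership conventions: integration with the `sum` rule and the
# SNR maximum use half-open intervals (ppm_min, ppm_max] on the
# descending axis, so contiguous buckets never share a point and
# splitting a bucket is exactly additive; the trapezoid rule uses closed
# intervals so a bucket whose edges sit on grid points integrates a
# constant of height h over width w to exactly h*w.

bucketIndicesHalfOpen <- function(ppm, lo, hi) which(ppm > lo & ppm <= hi)
bucketIndicesClosed <- function(ppm, lo, hi) which(ppm >= lo & ppm <= hi)

checkBucketsVsExcluded <- function(bt, excluded) {
  b <- buckets(bt)
  if (!nrow(b) || is.null(excluded) || !nrow(excluded)) return(invisible())
  for (i in seq_len(nrow(b))) {
    if (any(b$ppm_min[i] < excluded[, 2] - 1e-12 &
            b$ppm_max[i] > excluded[, 1] + 1e-12))
      stop("bucket ", b$label[i], " intersects an excluded zone")
  }
  invisible()
}

#' Uniform bucketing
#'
#' Tiles the zone with contiguous buckets of fixed width starting at the
#' high-ppm edge. A final partial bucket is kept only if it is at least
#' half the nominal width. Buckets are clipped against the set's excluded
#' zones (a straddling bucket is split); clips without point support are
#' dropped.
#'
#' @param set a [SpectrumSet-class].
#' @param zone a [PpmZone-class].
#' @param width_ppm bucket width (ppm), larger than the axis spacing.
#' @return a [BucketTable-class].
#' @export
uniformBuckets <- function(set, zone, width_ppm) {
  stopifnot(is(set, "SpectrumSet"), is(zone, "PpmZone"))
  ppm <- ppmAxis(set)
  stopIfZoneOutside(ppm, zone)
  d <- (ppm[1] - ppm[length(ppm)]) / (length(ppm) - 1)
  if (width_ppm <= d) stop("width_ppm must exceed the axis spacing")
  span <- zone@ppmMax - zone@ppmMin
  nFull <- floor(span / width_ppm + 1e-9)
  his <- zone@ppmMax - (seq_len(nFull) - 1) * width_ppm
  los <- his - width_ppm
  rem <- span - nFull * width_ppm
  if (rem >= width_ppm / 2 - 1e-12) {
    his <- c(his, zone@ppmMin + rem)
    los <- c(los, zone@ppmMin)
  }
  ex <- excludedZones(set)
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_along(his)) {
    pieces <- subtractIntervals(los[i], his[i], ex)
    for (j in seq_len(nrow(pieces)))
      if (length(bucketIndicesHalfOpen(ppm, pieces[j, 1], pieces[j, 2])))
        out <- rbind(out, pieces[j, ])
  }
  if (!nrow(out)) {
    if (!is.null(ex) && nrow(ex)) stop("zone is fully excluded")
    stop("no buckets with point support in zone")
  }
  bucketTable(data.frame(ppm_min = out[, 1], ppm_max = out[, 2]))
}

# bin value of points [i1..i2] of segment matrix segs (spectra in rows)
aibValue <- function(segs, i1, i2, R) {
  sub <- segs[, i1:i2, drop = FALSE]
  mx <- apply(sub, 1, max)
  v <- (mx - segs[, i1]) * (mx - segs[, i2])
  sum(pmax(v, 0)^R)
}

aibSplit <- function(segs, i1, i2, R, vNoise) {
  if (i2 - i1 + 1 < 3) return(list(c(i1, i2)))
  vb <- aibValue(segs, i1, i2, R)
  bestSum <- -Inf; bestJ <- NA_integer_; bestL <- NA; bestR <- NA
  for (j in i1:(i2 - 1)) {
    vl <- aibValue(segs, i1, j, R)
    vr <- aibValue(segs, j + 1, i2, R)
    if (vl + vr > bestSum) {
      bestSum <- vl + vr; bestJ <- j; bestL <- vl; bestR <- vr
    }
  }
  if (bestSum > vb && bestL > vNoise && bestR > vNoise) {
    c(aibSplit(segs, i1, bestJ, R, vNoise),
      aibSplit(segs, bestJ + 1, i2, R, vNoise))
  } else list(c(i1, i2))
}

#' Adaptive intelligent binning
#'
#' Recursively places bin edges inside existing bins. The value of a bin
#' is `sum over spectra of ((Imax - Ileft)(Imax - Iright))^R`; every
#' interior split point is evaluated and the best split is accepted only
#' if the summed value of the two children exceeds the parent's and both
#' children exceed the noise minimum `N * noise_floor^(2R)` (the value a
#' bin whose maximum sits at the noise floor would score). Recursion
#' stops when no split is accepted; leaf bins below the noise minimum are
#' discarded, so pure-noise zones yield no buckets. Deterministic; needs
#' no reference spectrum and only the two parameters below.
#'
#' @param set a [SpectrumSet-class].
#' @param zone a [PpmZone-class] of at least 3 points, not overlapping an
#'   excluded zone.
#' @param resolution_exp exponent R in (0, 1]; default 0.5.
#' @param noise_floor intensity scale of noise-only regions (same units
#'   as the spectra).
#' @return a [BucketTable-class] (possibly empty).
#' @export
aibBuckets <- function(set, zone, resolution_exp = 0.5, noise_floor) {
  stopifnot(is(set, "SpectrumSet"), is(zone, "PpmZone"),
            resolution_exp > 0, resolution_exp <= 1, noise_floor >= 0)
  checkNotExcluded(set, zone)
  ppm <- ppmAxis(set)
  idx <- stopIfZoneOutside(ppm, zone, minPoints = 3L)
  segs <- intensities(set)[, idx, drop = FALSE]
  vNoise <- nrow(segs) * noise_floor^(2 * resolution_exp)
  leaves <- aibSplit(segs, 1L, ncol(segs), resolution_exp, vNoise)
  keep <- Filter(function(b) aibValue(segs, b[1], b[2], resolution_exp) > vNoise,
                 leaves)
  if (!length(keep)) return(bucketTable(data.frame(ppm_min = numeric(0),
                                                   ppm_max = numeric(0))))
  d <- (ppm[1] - ppm[length(ppm)]) / (length(ppm) - 1)
  df <- do.call(rbind, lapply(keep, function(b) {
    data.frame(ppm_min = max(ppm[idx[b[2]]] - d / 2, zone@ppmMin),
               ppm_max = min(ppm[idx[b[1]]] + d / 2, zone@ppmMax))
  }))
  bucketTable(df)
}

#' Manual bucket definition
#'
#' Explicit ppm ranges to integrate, the targeted-metabolomics route.
#'
#' @param ranges two-column matrix/data.frame of `(ppm_min, ppm_max)`
#'   rows, or a list of length-2 vectors; any order.
#' @return a [BucketTable-class] in descending-centre order.
#' @export
manualBuckets <- function(ranges) {
  if (is.list(ranges) && !is.data.frame(ranges))
    ranges <- do.call(rbind, ranges)
  ranges <- as.matrix(as.data.frame(ranges)[, 1:2])
  if (any(ranges[, 1] >= ranges[, 2]))
    stop("every range needs ppm_min < ppm_max")
  o <- order(-(ranges[, 1] + ranges[, 2]) / 2)
  ranges <- ranges[o, , drop = FALSE]
  if (nrow(ranges) > 1) for (i in 2:nrow(ranges)) {
    if (ranges[i, 2] > ranges[i - 1, 1] + 1e-12)
      stop(sprintf("overlapping ranges: [%.4f, %.4f] and [%.4f, %.4f]",
                   ranges[i, 1], ranges[i, 2],
                   ranges[i - 1, 1], ranges[i - 1, 2]))
  }
  bucketTable(data.frame(ppm_min = ranges[, 1], ppm_max = ranges[, 2]))
}

#' Integrate buckets into the data matrix
#'
#' For every spectrum and bucket, sums the in-bucket intensities times
#' the axis spacing (`sum`) or applies the trapezoidal rule
#' (`trapezoid`). Rows are keyed by sample id, columns by bucket label.
#'
#' @param set a [SpectrumSet-class].
#' @param bucketTable a [BucketTable-class].
#' @param method `"sum"` or `"trapezoid"`.
#' @return N x B numeric matrix (the data matrix).
#' @export
integrateBuckets <- function(set, bucketTable, method = c("sum", "trapezoid")) {
  method <- match.arg(method)
  stopifnot(is(set, "SpectrumSet"), is(bucketTable, "BucketTable"))
  checkBucketsVsExcluded(bucketTable, excludedZones(set))
  b <- buckets(bucketTable)
  ppm <- ppmAxis(set)
  m <- intensities(set)
  d <- (ppm[1] - ppm[length(ppm)]) / (length(ppm) - 1)
  out <- matrix(0, nrow(m), nrow(b),
                dimnames = list(sampleNames(set), b$label))
  for (i in seq_len(nrow(b))) {
    if (method == "sum") {
      idx <- bucketIndicesHalfOpen(ppm, b$ppm_min[i], b$ppm_max[i])
      if (length(idx))
        out[, i] <- rowSums(m[, idx, drop = FALSE]) * d
    } else {
      idx <- bucketIndicesClosed(ppm, b$ppm_min[i], b$ppm_max[i])
      if (length(idx) >= 2) {
        sub <- m[, idx, drop = FALSE]
        out[, i] <- d * (rowSums(sub) - (sub[, 1] + sub[, ncol(sub)]) / 2)
      } else if (length(idx) == 1) out[, i] <- 0
    }
  }
  out
}

#' Signal-to-noise ratio matrix
#'
#' Per spectrum, the noise level is the standard deviation of the
#' (linearly detrended) points of a user-asserted signal-free noise zone;
#' `SNR(s, b) = max in-bucket intensity / (2 * noise_sd)`, clipped at 0.
#'
#' @param set a [SpectrumSet-class].
#' @param bucketTable a [BucketTable-class].
#' @param noise_zone a signal-free [PpmZone-class] of at least 32 points.
#' @return N x B matrix of SNR values (same keys as the data matrix).
#' @export
snrMatrix <- function(set, bucketTable, noise_zone) {
  stopifnot(is(set, "SpectrumSet"), is(bucketTable, "BucketTable"),
            is(noise_zone, "PpmZone"))
  checkBucketsVsExcluded(bucketTable, excludedZones(set))
  ppm <- ppmAxis(set)
  nidx <- stopIfZoneOutside(ppm, noise_zone, minPoints = 32L)
  m <- intensities(set)
  x <- seq_along(nidx)
  noiseSd <- apply(m[, nidx, drop = FALSE], 1, function(y) {
    s <- stats::sd(stats::lm.fit(cbind(1, x), y)$residuals)
    if (s < 1e-10 * (1 + max(abs(y)))) 0 else s   # numerically flat
  })
  if (any(noiseSd == 0))
    stop("degenerate noise zone (zero standard deviation) for sample(s): ",
         paste(sampleNames(set)[noiseSd == 0], collapse = ", "))
  b <- buckets(bucketTable)
  out <- matrix(0, nrow(m), nrow(b),
                dimnames = list(sampleNames(set), b$label))
  for (i in seq_len(nrow(b))) {
    idx <- bucketIndicesClosed(ppm, b$ppm_min[i], b$ppm_max[i])
    if (length(idx))
      out[, i] <- pmax(apply(m[, idx, drop = FALSE], 1, max), 0) /
        (2 * noiseSd)
  }
  out
}

#' Filter buckets on signal-to-noise
#'
#' Keeps a bucket iff the fraction of spectra with `SNR >= threshold` is
#' at least `min_fraction`; removal is column-wise only.
#'
#' @param dm data matrix (N x B).
#' @param sm SNR matrix with identical keys.
#' @param threshold SNR threshold (> 0).
#' @param min_fraction required fraction of passing spectra, in (0, 1].
#' @param bucketTable optional [BucketTable-class] to subset alongside.
#' @return `list(dm, sm, bucketTable, kept)` with surviving columns.
#' @export
filterBySnr <- function(dm, sm, threshold = 3, min_fraction = 0.5,
                        bucketTable = NULL) {
  stopifnot(threshold > 0, min_fraction > 0, min_fraction <= 1,
            identical(dim(dm), dim(sm)))
  frac <- colMeans(sm >= threshold)
  kept <- frac >= min_fraction
  bt <- bucketTable
  if (!is.null(bt)) {
    bk <- buckets(bt)[kept, , drop = FALSE]
    rownames(bk) <- NULL
    bt <- new("BucketTable", buckets = bk)
  }
  list(dm = dm[, kept, drop = FALSE], sm = sm[, kept, drop = FALSE],
       bucketTable = bt, kept = kept)
}

#' Normalize the data matrix
#'
#' `constant_sum` scales each spectrum's row to sum exactly 100 (total
#' intensity normalization); `none` returns the matrix unchanged.
#'
#' @param dm data matrix.
#' @param method `"none"` or `"constant_sum"`.
#' @return the normalized matrix.
#' @export
normalizeMatrix <- function(dm, method = c("none", "constant_sum")) {
  method <- match.arg(method)
  if (method == "none") return(dm)
  rs <- rowSums(dm)
  if (any(rs <= 0))
    stop("constant_sum requires strictly positive row sums; offending: ",
         paste(rownames(dm)[rs <= 0], collapse = ", "))
  sweep(dm, 1, rs / 100, "/")
}

#' Write / read a bucket table as TSV
#'
#' Columns `label`, `ppm_min`, `ppm_max`, tab-separated.
#'
#' @param bucketTable a [BucketTable-class].
#' @param path file path.
#' @return `path` (write) or a [BucketTable-class] (read).
#' @export
writeBucketTable <- function(bucketTable, path) {
  utils::write.table(buckets(bucketTable), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeBucketTable
#' @export
readBucketTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  bucketTable(df)
}
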