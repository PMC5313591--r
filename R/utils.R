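# internal helpers shared across modules

# indices of axis points inside a closed zone (axis is descending)
zoneIndices <- function(ppm, zone) {
  which(ppm >= zone@ppmMin & ppm <= zone@ppmMax)
}

stopIfZoneOutside <- function(ppm, zone, minPoints = 1L) {
  if (zone@ppmMax > ppm[1] + 1e-9 || zone@ppmMin < ppm[length(ppm)] - 1e-9)
    stop(sprintf("zone [%.4f, %.4f] lies outside the ppm axis [%.4f, %.4f]",
                 zone@ppmMin, zone@ppmMax, ppm[length(ppm)], ppm[1]))
  idx <- zoneIndices(ppm, zone)
  if (length(idx) < minPoints)
    stop(sprintf("zone [%.4f, %.4f] contains %d point(s); at least %d required",
                 zone@ppmMin, zone@ppmMax, length(idx), minPoints))
  idx
}

# run expr with a private RNG state seeded from `seed`; restores the
# caller's .Random.seed afterwards so simulation never perturbs user code
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

# append a macro line to a set's provenance
addProvenance <- function(set, line) {
  set@provenance <- c(set@provenance, line)
  set
}

# replace the intensity matrix, keeping everything else
setIntensities <- function(set, m) {
  dimnames(m) <- dimnames(set@intensities)
  set@intensities <- m
  set
}

fmtPpm <- function(x) sprintf("%.4f", x)

# resolve an optional (factor, level) selection to row indices
resolveSelection <- function(set, selection) {
  if (is.null(selection)) return(seq_len(nrow(set@intensities)))
  if (is.numeric(selection) || is.integer(selection)) {
    sel <- as.integer(selection)
    if (any(sel < 1 | sel > nrow(set@intensities)))
      stop("selection indices out of range")
    return(sel)
  }
  if (is.list(selection) && !is.null(selection$factor))
    return(subsetByFactor(set, selection$factor, selection$level))
  stop("selection must be NULL, row indices, or list(factor=, level=)")
}

# merge an interval into a k x 2 matrix of disjoint intervals (union)
mergeIntervals <- function(mat) {
  if (!nrow(mat)) return(mat)
  o <- order(mat[, 1])
  mat <- mat[o, , drop = FALSE]
  out <- mat[1, , drop = FALSE]
  if (nrow(mat) > 1) for (i in 2:nrow(mat)) {
    last <- nrow(out)
    if (mat[i, 1] <= out[last, 2]) {
      out[last, 2] <- max(out[last, 2], mat[i, 2])
    } else out <- rbind(out, mat[i, , drop = FALSE])
  }
  colnames(out) <- c("min", "max")
  out
}

# subtract a set of exclusion intervals from [lo, hi]; returns kept pieces
subtractIntervals <- function(lo, hi, excl) {
  pieces <- matrix(c(lo, hi), ncol = 2)
  if (!is.null(excl) && nrow(excl)) for (i in seq_len(nrow(excl))) {
    nxt <- matrix(numeric(0), ncol = 2)
    for (j in seq_len(nrow(pieces))) {
      a <- pieces[j, 1]; b <- pieces[j, 2]
      e1 <- excl[i, 1]; e2 <- excl[i, 2]
      if (e2 <= a || e1 >= b) { nxt <- rbind(nxt, c(a, b)); next }
      if (e1 > a) nxt <- rbind(nxt, c(a, e1))
      if (e2 < b) nxt <- rbind(nxt, c(e2, b))
    }
    pieces <- nxt
    if (!nrow(pieces)) break
  }
  pieces
}
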