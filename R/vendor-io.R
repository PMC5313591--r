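# Readers for Bruker, Varian/Agilent and nmrML inputs, the sample/factor
# metadata table, and SpectrumSet assembly.

parseJcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  m <- regmatches(lines, regexec("^##\\$?([A-Za-z_0-9]+)= *(.*)$", lines))
  out <- list()
  for (x in m) if (length(x) == 3) {
    v <- suppressWarnings(as.numeric(x[3]))
    out[[x[2]]] <- if (is.na(v)) x[3] else v
  }
  out
}

jcampNeed <- function(p, keys, path) {
  miss <- setdiff(keys, names(p))
  if (length(miss))
    stop("missing parameter(s) ", paste(miss, collapse = ", "), " in ", path)
}

# Bruker digital-filter group delays by DSPFVS / DECIM for firmware
# generations that predate the GRPDLY parameter
.dspTable <- local({
  decim <- c(2, 3, 4, 6, 8, 12, 16, 24, 32, 48, 64, 96, 128, 192, 256,
             384, 512, 768, 1024, 1536, 2048)
  d10 <- c(44.75, 33.5, 66.625, 59.0833, 68.5625, 60.375, 69.5313,
           61.0208, 70.0156, 61.3438, 70.2578, 61.5052, 70.3789, 61.5859,
           70.4395, 61.6263, 70.4697, 61.6465, 70.4849, 61.6566, 70.4924)
  d11 <- c(46, 36.5, 48, 50.1667, 53.25, 69.5, 72.25, 70.1667, 72.75,
           70.5, 73, 70.6667, 72.5, 71.3333, 72.25, 71.6667, 72.125,
           71.8333, 72.0625, 71.9167, 72.0313)
  d12 <- c(46.311, 36.53, 47.87, 50.229, 53.289, 69.551, 71.6, 70.184,
           72.138, 70.528, 72.348, 70.7, 72.524, 71.3667, 72.2108,
           71.6667, 72.1294, 71.8333, 72.0435, 71.9167, 72.0313)
  list(`10` = stats::setNames(d10, decim), `11` = stats::setNames(d11, decim),
       `12` = stats::setNames(d12, decim))
})

lookupGroupDelay <- function(p) {
  if (!is.null(p$GRPDLY) && is.numeric(p$GRPDLY) && p$GRPDLY >= 0)
    return(p$GRPDLY)
  if (!is.null(p$DSPFVS) && !is.null(p$DECIM)) {
    tab <- .dspTable[[as.character(as.integer(p$DSPFVS))]]
    if (!is.null(tab)) {
      v <- tab[as.character(as.integer(p$DECIM))]
      if (!is.na(v)) return(unname(v))
    }
  }
  0
}

#' Read a Bruker raw FID directory
#'
#' Parses `acqus` (JCAMP-DX) and decodes the `fid` binary with the
#' declared byte order (BYTORDA) and word type (DTYPA: 0 = int32,
#' 2 = float64). The digital-filter group delay is taken from GRPDLY when
#' present, else from the DECIM/DSPFVS lookup table, else 0.
#'
#' @param directory a Bruker experiment directory containing `fid` and
#'   `acqus`.
#' @param sampleId sample identifier; defaults to the directory name.
#' @return a [FidRecord-class].
#' @export
readBrukerFid <- function(directory, sampleId = basename(directory)) {
  fidPath <- file.path(directory, "fid")
  acqPath <- file.path(directory, "acqus")
  if (!file.exists(fidPath)) stop("missing file: ", fidPath)
  if (!file.exists(acqPath)) stop("missing file: ", acqPath)
  p <- parseJcamp(acqPath)
  jcampNeed(p, c("TD", "SW", "SFO1", "BYTORDA", "DTYPA"), acqPath)
  td <- as.integer(p$TD)
  dtypa <- as.integer(p$DTYPA)
  if (!dtypa %in% c(0L, 2L)) stop("unknown DTYPA ", dtypa, " in ", acqPath)
  size <- if (dtypa == 0L) 4L else 8L
  endian <- if (as.integer(p$BYTORDA) == 0L) "little" else "big"
  nbytes <- file.size(fidPath)
  if (nbytes != td * size)
    stop(sprintf("fid file %s has %d bytes; TD=%d %s words require %d",
                 fidPath, nbytes, td,
                 if (dtypa == 0L) "int32" else "float64", td * size))
  con <- file(fidPath, "rb")
  on.exit(close(con))
  inter <- if (dtypa == 0L)
    readBin(con, "integer", n = td, size = 4L, endian = endian)
  else readBin(con, "double", n = td, size = 8L, endian = endian)
  sig <- complex(real = inter[seq(1, td, 2)], imaginary = inter[seq(2, td, 2)])
  fidRecord(sig, dwellUs = 1e6 / (p$SW * p$SFO1), sfoMHz = p$SFO1,
            swPpm = p$SW, o1Hz = if (is.null(p$O1)) 0 else p$O1,
            groupDelay = lookupGroupDelay(p), vendor = "bruker",
            sampleId = sampleId)
}

#' Read a Bruker processed spectrum (`1r`)
#'
#' Reads `SI` int32 words scaled by `2^NC_proc`; the ppm axis is the
#' uniform descending grid with first point at `OFFSET` and spacing
#' `(SW_p / SF) / (SI - 1)`.
#'
#' @param directory directory containing `1r` and `procs`.
#' @return `list(spectrum, ppm, sfMHz)`.
#' @export
readBruker1r <- function(directory) {
  rPath <- file.path(directory, "1r")
  pPath <- file.path(directory, "procs")
  if (!file.exists(rPath)) stop("missing file: ", rPath)
  if (!file.exists(pPath)) stop("missing file: ", pPath)
  p <- parseJcamp(pPath)
  jcampNeed(p, c("SI", "OFFSET", "SW_p", "SF"), pPath)
  si <- as.integer(p$SI)
  endian <- if (is.null(p$BYTORDP) || as.integer(p$BYTORDP) == 0L)
    "little" else "big"
  if (file.size(rPath) != si * 4L)
    stop(sprintf("1r file %s has %d bytes; SI=%d int32 words require %d",
                 rPath, file.size(rPath), si, si * 4L))
  con <- file(rPath, "rb")
  on.exit(close(con))
  v <- readBin(con, "integer", n = si, size = 4L, endian = endian)
  nc <- if (is.null(p$NC_proc)) 0 else p$NC_proc
  swPpm <- p$SW_p / p$SF
  ppm <- p$OFFSET - (seq_len(si) - 1) * swPpm / (si - 1)
  list(spectrum = v * 2^nc, ppm = ppm, sfMHz = p$SF)
}

parseProcpar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  i <- 1
  while (i < length(lines)) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(tok) >= 11 && grepl("^[A-Za-z]", tok[1])) {
      vals <- strsplit(trimws(lines[i + 1]), "[ \t]+")[[1]]
      nv <- suppressWarnings(as.integer(vals[1]))
      if (!is.na(nv) && length(vals) >= nv + 1) {
        num <- suppressWarnings(as.numeric(vals[1 + seq_len(nv)]))
        out[[tok[1]]] <- if (anyNA(num)) vals[1 + seq_len(nv)] else num
      }
      i <- i + 3
    } else i <- i + 1
  }
  out
}

#' Read a Varian/Agilent FID directory
#'
#' Parses `procpar` (np, sw, sfrq, tof) and decodes the big-endian
#' block-format `fid` binary (file header, block header(s), interleaved
#' real/imaginary words; float32 when the status float bit is set).
#'
#' @param directory directory containing `fid` and `procpar`.
#' @param sampleId sample identifier; defaults to the directory name.
#' @return a [FidRecord-class].
#' @export
readVarianFid <- function(directory, sampleId = basename(directory)) {
  fidPath <- file.path(directory, "fid")
  ppPath <- file.path(directory, "procpar")
  if (!file.exists(fidPath)) stop("missing file: ", fidPath)
  if (!file.exists(ppPath)) stop("missing file: ", ppPath)
  p <- parseProcpar(ppPath)
  for (k in c("np", "sw", "sfrq")) if (is.null(p[[k]]))
    stop("missing procpar key `", k, "` in ", ppPath)
  con <- file(fidPath, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", n = 6, size = 4L, endian = "big")
  vs <- readBin(con, "integer", n = 2, size = 2L, endian = "big")
  nbheaders <- readBin(con, "integer", n = 1, size = 4L, endian = "big")
  np <- hdr[3]; ebytes <- hdr[4]; status <- vs[2]
  if (length(nbheaders) != 1 || np <= 0 || ebytes <= 0)
    stop("malformed fid block header in ", fidPath)
  if (np != p$np[1])
    stop(sprintf("np mismatch: header says %d, procpar says %d", np, p$np[1]))
  invisible(readBin(con, "raw", n = 28L * nbheaders))   # skip block header
  isFloat <- bitwAnd(status, 0x8L) != 0L
  inter <- if (isFloat)
    readBin(con, "double", n = np, size = ebytes, endian = "big")
  else readBin(con, "integer", n = np, size = ebytes, endian = "big")
  if (length(inter) != np) stop("truncated fid data in ", fidPath)
  sig <- complex(real = inter[seq(1, np, 2)], imaginary = inter[seq(2, np, 2)])
  fidRecord(sig, dwellUs = 1e6 / p$sw[1], sfoMHz = p$sfrq[1],
            swPpm = p$sw[1] / p$sfrq[1],
            o1Hz = if (is.null(p$tof)) 0 else p$tof[1],
            vendor = "varian", sampleId = sampleId)
}

#' Read a 1D nmrML file
#'
#' Decodes the first 1D acquisition (base64 float64 pairs, optionally
#' zlib-compressed) together with its axis parameters.
#'
#' @param path nmrML file.
#' @param sampleId sample identifier.
#' @return a [FidRecord-class].
#' @export
readNmrML <- function(path, sampleId = sub("\\.nmrML$", "", basename(path))) {
  doc <- xml2::read_xml(path)
  if (length(xml2::xml_find_all(doc, ".//acquisition2D")) ||
      length(xml2::xml_find_all(doc, ".//acquisitionMultiD")))
    stop("unsupported dimensionality: only 1D nmrML is supported")
  a1 <- xml2::xml_find_first(doc, ".//acquisition1D")
  if (inherits(a1, "xml_missing")) stop("no acquisition1D element in ", path)
  ps <- xml2::xml_find_first(a1, ".//acquisitionParameterSet")
  fd <- xml2::xml_find_first(a1, ".//fidData")
  if (inherits(ps, "xml_missing") || inherits(fd, "xml_missing"))
    stop("acquisitionParameterSet or fidData element absent in ", path)
  comp <- xml2::xml_attr(fd, "compressed")
  if (!comp %in% c("none", "zlib", NA))
    stop("unsupported compression flag: ", comp)
  raw <- jsonlite::base64_dec(gsub("[[:space:]]", "", xml2::xml_text(fd)))
  if (identical(comp, "zlib")) raw <- memDecompress(raw, "gzip")
  inter <- readBin(raw, "double", n = length(raw) / 8, size = 8L,
                   endian = "little")
  sig <- complex(real = inter[seq(1, length(inter), 2)],
                 imaginary = inter[seq(2, length(inter), 2)])
  num <- function(a) as.numeric(xml2::xml_attr(ps, a))
  n <- num("numberOfDataPoints")
  if (!is.na(n) && n != length(sig))
    stop("numberOfDataPoints inconsistent with payload in ", path)
  sw <- num("sweepWidthPpm"); sf <- num("irradiationFrequencyMHz")
  gd <- num("groupDelay"); o1 <- num("carrierOffsetHz")
  fidRecord(sig, dwellUs = 1e6 / (sw * sf), sfoMHz = sf, swPpm = sw,
            o1Hz = if (is.na(o1)) 0 else o1,
            groupDelay = if (is.na(gd)) 0 else gd,
            vendor = "synthetic", sampleId = sampleId)
}

#' Read the sample/factor metadata table
#'
#' UTF-8 TSV with a header row; the first column is the sample identifier
#' (renamed `sample_id`), remaining columns are experimental factors.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readSampleTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8", check.names = FALSE)
  if (ncol(df) < 2) stop("sample table needs sample_id plus >= 1 factor column")
  colnames(df)[1] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  for (j in 2:ncol(df)) {
    df[[j]] <- as.character(df[[j]])
    if (any(!nzchar(df[[j]])))
      stop("empty factor level in column ", colnames(df)[j])
  }
  df
}

#' Assemble spectra and metadata into a SpectrumSet
#'
#' All spectra must share one axis (same point count and ppm grid); rows
#' of the resulting matrix follow the order of the sample table.
#'
#' @param spectra named list (names = sample ids) of `list(spectrum, ppm)`
#'   elements, e.g. from [readBruker1r()] or [transformFid()].
#' @param sampleTable data.frame from [readSampleTable()].
#' @return a [SpectrumSet-class].
#' @export
assembleSpectrumSet <- function(spectra, sampleTable) {
  ids <- names(spectra)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("spectra must be a named list keyed by sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample_id among spectra: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  if (anyDuplicated(sampleTable$sample_id))
    stop("duplicate sample_id in sample table")
  lens <- vapply(spectra, function(s) length(s$spectrum), integer(1))
  if (length(unique(lens)) > 1) {
    ref <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
    bad <- ids[lens != ref]
    stop("point-count mismatch for sample(s): ", paste(bad, collapse = ", "))
  }
  ppm <- spectra[[1]]$ppm
  for (s in spectra) if (max(abs(s$ppm - ppm)) > 1e-6)
    stop("spectra do not share a common ppm axis")
  miss <- setdiff(ids, sampleTable$sample_id)
  if (length(miss))
    stop("sample(s) missing from the sample table: ",
         paste(miss, collapse = ", "))
  keep <- sampleTable$sample_id %in% ids
  st <- sampleTable[keep, , drop = FALSE]
  rownames(st) <- NULL
  m <- do.call(rbind, lapply(st$sample_id, function(id) spectra[[id]]$spectrum))
  spectrumSet(m, ppm, st)
}

#' Select spectra by experimental-factor level
#'
#' @param set a [SpectrumSet-class].
#' @param factor factor column name.
#' @param level level to select.
#' @return integer row indices, in set order.
#' @export
subsetByFactor <- function(set, factor, level) {
  sd <- sampleData(set)
  if (!factor %in% colnames(sd)) stop("unknown factor: ", factor)
  idx <- which(sd[[factor]] == level)
  if (!length(idx))
    stop("level `", level, "` not present in factor `", factor, "`")
  idx
}
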