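# On-disk vendor-format fixture writers. These emit the minimal set of
# files and parameters the readers in vendor-io.R require, so a complete
# synthetic study can live on disk in real vendor layouts.

writeJcamp <- function(params, path, title = "acquisition parameters") {
  lines <- c(sprintf("##TITLE= %s", title), "##JCAMPDX= 5.0",
             sprintf("##$%s= %s", names(params),
                     vapply(params, function(v) format(v, digits = 17,
                            scientific = FALSE), character(1))),
             "##END=")
  writeLines(lines, path)
}

#' Write a minimal Bruker experiment directory
#'
#' Creates `acqus` (JCAMP-DX parameters: TD, SW, SFO1, O1, BYTORDA, DTYPA,
#' GRPDLY) and the `fid` binary with interleaved real/imaginary words in
#' the declared byte order. `dtypa = 0` stores int32 (values are rounded:
#' pre-scale small signals to preserve dynamic range), `dtypa = 2` stores
#' float64 exactly.
#'
#' @param fid a [FidRecord-class].
#' @param directory target directory (created if needed).
#' @param dtypa 0 (int32) or 2 (float64).
#' @param bytorda 0 (little endian) or 1 (big endian).
#' @return the directory path, invisibly.
#' @export
writeBrukerFixture <- function(fid, directory, dtypa = 0L, bytorda = 0L) {
  stopifnot(is(fid, "FidRecord"), dtypa %in% c(0L, 2L), bytorda %in% c(0L, 1L))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  n <- length(fid@signal)
  writeJcamp(list(TD = 2L * n, SW = fid@swPpm, SFO1 = fid@sfoMHz,
                  O1 = fid@o1Hz, BYTORDA = bytorda, DTYPA = dtypa,
                  GRPDLY = fid@groupDelay),
             file.path(directory, "acqus"))
  inter <- as.vector(rbind(Re(fid@signal), Im(fid@signal)))
  endian <- if (bytorda == 0L) "little" else "big"
  con <- file(file.path(directory, "fid"), "wb")
  on.exit(close(con))
  if (dtypa == 0L) {
    writeBin(as.integer(round(inter)), con, size = 4L, endian = endian)
  } else {
    writeBin(as.double(inter), con, size = 8L, endian = endian)
  }
  invisible(directory)
}

#' Write a minimal Bruker processed-spectrum directory
#'
#' Creates `procs` (SI, OFFSET, SW_p, SF, NC_proc, BYTORDP, DTYPP) and the
#' `1r` binary of int32 words. Stored integers are `round(y / 2^NC_proc)`;
#' readers rescale by `2^NC_proc`.
#'
#' @param spectrum numeric intensities, first point = highest ppm.
#' @param ppm strictly decreasing axis; must be uniform.
#' @param sfMHz spectrometer frequency (MHz).
#' @param directory target directory.
#' @param ncProc NC_proc scaling exponent.
#' @param bytordp 0 little, 1 big endian.
#' @return the directory path, invisibly.
#' @export
writeBruker1rFixture <- function(spectrum, ppm, sfMHz, directory,
                                 ncProc = 0L, bytordp = 0L) {
  stopifnot(length(spectrum) == length(ppm))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  si <- length(spectrum)
  swPpm <- ppm[1] - ppm[si]
  writeJcamp(list(SI = si, OFFSET = ppm[1], SW_p = swPpm * sfMHz,
                  SF = sfMHz, NC_proc = ncProc, BYTORDP = bytordp,
                  DTYPP = 0L),
             file.path(directory, "procs"), title = "processing parameters")
  endian <- if (bytordp == 0L) "little" else "big"
  con <- file(file.path(directory, "1r"), "wb")
  on.exit(close(con))
  writeBin(as.integer(round(spectrum / 2^ncProc)), con, size = 4L,
           endian = endian)
  invisible(directory)
}

#' Write a minimal Varian/Agilent experiment directory
#'
#' Creates `procpar` (np, sw, sfrq, tof) and the big-endian block-format
#' `fid` binary: one 32-byte file header, one 28-byte block header, then
#' `np` float32 words (interleaved real/imaginary).
#'
#' @param fid a [FidRecord-class].
#' @param directory target directory.
#' @return the directory path, invisibly.
#' @export
writeVarianFixture <- function(fid, directory) {
  stopifnot(is(fid, "FidRecord"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  n <- length(fid@signal)
  np <- 2L * n
  swHz <- fid@swPpm * fid@sfoMHz
  pp <- c(np = np, sw = swHz, sfrq = fid@sfoMHz, tof = fid@o1Hz)
  lines <- character(0)
  for (k in names(pp)) {
    lines <- c(lines,
               paste(k, "1 1 1e18 -1e18 0 2 0 0 0 1"),
               paste("1", format(pp[[k]], digits = 17, scientific = FALSE)),
               "0")
  }
  writeLines(lines, file.path(directory, "procpar"))

  con <- file(file.path(directory, "fid"), "wb")
  on.exit(close(con))
  ebytes <- 4L
  tbytes <- np * ebytes
  status <- 0x1L + 0x8L + 0x10L            # data | float | complex
  # file header: nblocks ntraces np ebytes tbytes bbytes (int32),
  # vers_id status (int16), nbheaders (int32) -- all big-endian
  writeBin(c(1L, 1L, np, ebytes, tbytes, tbytes + 28L), con, size = 4L,
           endian = "big")
  writeBin(c(0L, status), con, size = 2L, endian = "big")
  writeBin(1L, con, size = 4L, endian = "big")
  # block header: scale status index mode (int16), ctcount (int32),
  # lpval rpval lvl tlt (float32)
  writeBin(c(0L, status, 1L, 0L), con, size = 2L, endian = "big")
  writeBin(1L, con, size = 4L, endian = "big")
  writeBin(numeric(4), con, size = 4L, endian = "big")
  inter <- as.vector(rbind(Re(fid@signal), Im(fid@signal)))
  writeBin(as.double(inter), con, size = 4L, endian = "big")
  invisible(directory)
}

#' Write an nmrML file for a FID
#'
#' Emits a minimal 1D nmrML document: acquisition parameters as attributes
#' and the complex FID as base64-encoded little-endian float64 pairs,
#' optionally zlib-compressed.
#'
#' @param fid a [FidRecord-class].
#' @param path output file.
#' @param compressed logical; zlib-compress the binary payload.
#' @return `path`, invisibly.
#' @export
writeNmrML <- function(fid, path, compressed = FALSE) {
  stopifnot(is(fid, "FidRecord"))
  inter <- as.vector(rbind(Re(fid@signal), Im(fid@signal)))
  raw <- writeBin(as.double(inter), raw(), size = 8L, endian = "little")
  if (compressed) raw <- memCompress(raw, "gzip")   # zlib stream
  b64 <- jsonlite::base64_enc(raw)
  doc <- xml2::xml_new_root("nmrML", version = "1.0")
  acq <- xml2::xml_add_child(doc, "acquisition")
  a1 <- xml2::xml_add_child(acq, "acquisition1D")
  xml2::xml_add_child(a1, "acquisitionParameterSet",
    numberOfDataPoints = as.character(length(fid@signal)),
    sweepWidthPpm = format(fid@swPpm, digits = 17),
    irradiationFrequencyMHz = format(fid@sfoMHz, digits = 17),
    carrierOffsetHz = format(fid@o1Hz, digits = 17),
    groupDelay = format(fid@groupDelay, digits = 17))
  fd <- xml2::xml_add_child(a1, "fidData",
    byteFormat = "complex128",
    compressed = if (compressed) "zlib" else "none",
    encodedLength = as.character(nchar(b64)))
  xml2::xml_set_text(fd, b64)
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write the sample/factor metadata table
#'
#' UTF-8 tab-separated text with a header row; first column `sample_id`,
#' remaining columns experimental-factor levels.
#'
#' @param sampleData data.frame, first column `sample_id`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSampleTable <- function(sampleData, path) {
  stopifnot(colnames(sampleData)[1] == "sample_id")
  utils::write.table(sampleData, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Materialize a simulated study as a vendor-format directory tree
#'
#' Simulates every sample of the plan as a FID and writes one Bruker (or
#' Varian) experiment directory per sample, named by sample id, plus a
#' `samples.tsv` factor table — the on-disk layout the batch pipeline and
#' CLI consume.
#'
#' @param plan a [simulationPlan()].
#' @param axis a [spectralAxis()].
#' @param directory root directory to create.
#' @param format `"bruker"` (float64 words, exact) or `"varian"`.
#' @return `directory`, invisibly.
#' @export
simulateStudyDir <- function(plan, axis, directory, format = "bruker") {
  format <- match.arg(format, c("bruker", "varian"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  ids <- sprintf("S%02d", seq_len(plan$n_samples))
  for (s in seq_len(plan$n_samples)) {
    fid <- simulateFid(plan, axis, sample = s)
    d <- file.path(directory, ids[s])
    if (format == "bruker") writeBrukerFixture(fid, d, dtypa = 2L)
    else writeVarianFixture(fid, d)
  }
  writeSampleTable(data.frame(sample_id = ids, group = plan$factor_assignment,
                              stringsAsFactors = FALSE),
                   file.path(directory, "samples.tsv"))
  invisible(directory)
}
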