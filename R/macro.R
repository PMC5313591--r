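# Recordable macro workflow: every processing step is one line
# `OP key=value ...` (ppm values to 4 decimals), so a workflow tuned
# interactively on one spectra set becomes a diff-able, human-editable
# SOP replayable in batch on comparable sets.

.macroOps <- c("PROCESS", "CALIBRATE", "ALIGN_LS", "ALIGN_PTW", "GBASELINE",
               "LBASELINE", "ZERO", "BUCKET_UNIFORM", "BUCKET_AIB",
               "BUCKET_MANUAL", "SNR_FILTER", "NORMALIZE", "EXPORT_MATRIX",
               "EXPORT_QHNMR")

.macroHeader <- "# nmrflow macro v1"

#' Parse one macro line
#'
#' @param line text `OP key=value ...`.
#' @return `list(op, params)` with `params` a named character vector.
#' @export
parseMacroCommand <- function(line) {
  tok <- strsplit(trimws(line), "[ \t]+")[[1]]
  op <- tok[1]
  if (!op %in% .macroOps) stop("unknown macro op: ", op)
  params <- character(0)
  if (length(tok) > 1) {
    kv <- regmatches(tok[-1], regexec("^([A-Za-z_0-9]+)=(.*)$", tok[-1]))
    bad <- vapply(kv, length, integer(1)) != 3
    if (any(bad)) stop("malformed macro parameter(s): ",
                       paste(tok[-1][bad], collapse = " "))
    params <- stats::setNames(vapply(kv, `[`, character(1), 3),
                              vapply(kv, `[`, character(1), 2))
  }
  list(op = op, params = params)
}

#' Serialize a parsed macro command back to its line form
#'
#' @param cmd `list(op, params)` as returned by [parseMacroCommand()].
#' @return the macro line.
#' @export
serializeMacroCommand <- function(cmd) {
  if (!length(cmd$params)) return(cmd$op)
  paste(cmd$op, paste(names(cmd$params), cmd$params, sep = "=",
                      collapse = " "))
}

parseZoneParam <- function(s) {
  v <- as.numeric(strsplit(s, ":", fixed = TRUE)[[1]])
  if (length(v) != 2 || anyNA(v)) stop("malformed zone parameter: ", s)
  ppmZone(v[1], v[2])
}

parseZonesParam <- function(s) {
  lapply(strsplit(s, ",", fixed = TRUE)[[1]], parseZoneParam)
}

cmdSelection <- function(p) {
  if ("factor" %in% names(p))
    list(factor = unname(p[["factor"]]), level = unname(p[["level"]]))
  else NULL
}

num <- function(p, key, default = NULL) {
  if (key %in% names(p)) as.numeric(p[[key]]) else default
}

#' Apply one recorded command to a spectra set
#'
#' Dispatches a set-transforming macro command (calibration, alignment,
#' baseline, zone zeroing) to the corresponding operation; the operation
#' itself appends the command to the set's provenance, so replaying a
#' set's provenance on the raw input reproduces it exactly.
#'
#' @param set a [SpectrumSet-class].
#' @param command a macro line or a parsed command list.
#' @return the transformed [SpectrumSet-class].
#' @export
recordCommand <- function(set, command) {
  cmd <- if (is.character(command)) parseMacroCommand(command) else command
  p <- cmd$params
  sel <- cmdSelection(p)
  switch(cmd$op,
    CALIBRATE = calibrateSpectra(set, parseZoneParam(p[["zone"]]),
                                 num(p, "ref")),
    ALIGN_LS = alignZoneLS(set, parseZoneParam(p[["zone"]]), sel,
                           max_shift = num(p, "max", 20))$set,
    ALIGN_PTW = alignZonePTW(set, parseZoneParam(p[["zone"]]), sel,
                             degree = num(p, "degree", 1))$set,
    GBASELINE = globalBaseline(set, smoothing = num(p, "smoothing", 1e7),
                               asymmetry = num(p, "asymmetry", 0.05),
                               selection = sel),
    LBASELINE = localBaseline(set, parseZoneParam(p[["zone"]]), sel),
    ZERO = zeroZones(set, parseZonesParam(p[["zones"]])),
    stop("op ", cmd$op, " is not a set transformation"))
}

#' Write / read a macro file
#'
#' Line-oriented plain text, one command per line, with a versioned
#' header; blank lines and `#` comments are ignored on read.
#'
#' @param lines character vector of macro lines.
#' @param path file path.
#' @return `path` (write) / character vector of command lines (read).
#' @export
writeMacro <- function(lines, path) {
  writeLines(c(.macroHeader, lines), path)
  invisible(path)
}

#' @rdname writeMacro
#' @export
readMacro <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

readStudyFids <- function(inputDir, sampleTable) {
  fids <- list()
  for (id in sampleTable$sample_id) {
    d <- file.path(inputDir, id)
    if (file.exists(file.path(d, "acqus")))
      fids[[id]] <- readBrukerFid(d, sampleId = id)
    else if (file.exists(file.path(d, "procpar")))
      fids[[id]] <- readVarianFid(d, sampleId = id)
    else stop("no Bruker or Varian data found for sample ", id, " in ", d)
  }
  fids
}

#' Replay a macro on a raw spectra-set directory in batch
#'
#' Executes the macro's commands in order against the study found in
#' `inputDir` (one vendor experiment directory per sample plus a
#' `samples.tsv` factor table): FID processing, set transformations,
#' bucketing, SNR filtering and exports. Each step is logged to stderr
#' with its parameters and timing; any step error aborts with a message
#' naming the failing command index.
#'
#' @param macroFile macro file path (see [writeMacro()]).
#' @param inputDir raw study directory.
#' @param outDir output directory for exports (created if needed).
#' @param samplesFile path of the sample table; default
#'   `inputDir/samples.tsv`.
#' @param logLevel `"info"` (log each step) or `"quiet"`.
#' @return invisibly, `list(set, bucketTable, dm, sm, reports, files)`.
#' @export
replayMacro <- function(macroFile, inputDir, outDir = NULL,
                        samplesFile = file.path(inputDir, "samples.tsv"),
                        logLevel = "info") {
  lines <- readMacro(macroFile)
  sampleTable <- readSampleTable(samplesFile)
  if (!is.null(outDir)) dir.create(outDir, recursive = TRUE,
                                   showWarnings = FALSE)
  st <- list(set = NULL, bucketTable = NULL, dm = NULL, sm = NULL,
             reports = list(), files = character(0))
  needSet <- function() if (is.null(st$set))
    stop("no spectra set yet; PROCESS must come first")
  for (i in seq_along(lines)) {
    cmd <- tryCatch(parseMacroCommand(lines[i]),
                    error = function(e) stop(sprintf(
                      "macro command %d failed to parse: %s", i,
                      conditionMessage(e)), call. = FALSE))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      p <- cmd$params
      switch(cmd$op,
        PROCESS = {
          fids <- readStudyFids(inputDir, sampleTable)
          params <- processingParams(
            zero_fill_to = if ("zf" %in% names(p) && p[["zf"]] != "auto")
              as.integer(p[["zf"]]) else NULL,
            line_broadening_hz = num(p, "lb", 0.3),
            phase0_deg = num(p, "phi0", 0), phase1_deg = num(p, "phi1", 0),
            autophase = identical(unname(p["autophase"]), "1"))
          st$set <- processFids(fids, params, sampleTable)
        },
        BUCKET_UNIFORM = {
          needSet()
          st$bucketTable <- uniformBuckets(st$set,
                                           parseZoneParam(p[["zone"]]),
                                           num(p, "width"))
        },
        BUCKET_AIB = {
          needSet()
          st$bucketTable <- aibBuckets(st$set, parseZoneParam(p[["zone"]]),
                                       resolution_exp = num(p, "r", 0.5),
                                       noise_floor = num(p, "noise"))
        },
        BUCKET_MANUAL = {
          needSet()
          rg <- lapply(parseZonesParam(p[["ranges"]]),
                       function(z) c(z@ppmMin, z@ppmMax))
          st$bucketTable <- manualBuckets(rg)
        },
        SNR_FILTER = {
          needSet()
          if (is.null(st$bucketTable)) stop("no bucket table to filter")
          method <- if ("method" %in% names(p)) p[["method"]] else "sum"
          st$dm <- integrateBuckets(st$set, st$bucketTable, method)
          st$sm <- snrMatrix(st$set, st$bucketTable,
                             parseZoneParam(p[["noise"]]))
          f <- filterBySnr(st$dm, st$sm, threshold = num(p, "threshold", 3),
                           min_fraction = num(p, "minfrac", 0.5),
                           bucketTable = st$bucketTable)
          st$dm <- f$dm; st$sm <- f$sm; st$bucketTable <- f$bucketTable
        },
        NORMALIZE = {
          if (is.null(st$dm)) stop("no data matrix to normalize")
          st$dm <- normalizeMatrix(st$dm, p[["method"]])
        },
        EXPORT_MATRIX = {
          if (is.null(st$dm)) {
            needSet()
            if (is.null(st$bucketTable)) stop("no bucket table to integrate")
            st$dm <- integrateBuckets(st$set, st$bucketTable,
                                      if ("method" %in% names(p))
                                        p[["method"]] else "sum")
          }
          if (is.null(outDir)) stop("EXPORT_MATRIX requires an output directory")
          flavor <- if ("flavor" %in% names(p)) p[["flavor"]] else "generic_tsv"
          st$files <- c(st$files,
                        exportMatrix(st$dm, st$sm, sampleData(st$set),
                                     file.path(outDir, "matrix"), flavor))
        },
        EXPORT_QHNMR = {
          needSet()
          if (is.null(st$bucketTable)) stop("no bucket table to export")
          if (is.null(outDir)) stop("EXPORT_QHNMR requires an output directory")
          method <- if ("method" %in% names(p)) p[["method"]] else "sum"
          if (is.null(st$dm))
            st$dm <- integrateBuckets(st$set, st$bucketTable, method)
          if (is.null(st$sm) && "noise" %in% names(p))
            st$sm <- snrMatrix(st$set, st$bucketTable,
                               parseZoneParam(p[["noise"]]))
          qs <- NULL
          if ("ref" %in% names(p)) {
            bi <- buckets(st$bucketTable)[, "label", drop = FALSE]
            bi$metabolite <- bi$label
            bi$protons <- 1L
            if ("protons" %in% names(p)) {
              for (kv in strsplit(p[["protons"]], ",")[[1]]) {
                lv <- strsplit(kv, ":", fixed = TRUE)[[1]]
                bi$protons[bi$label == lv[1]] <- as.integer(lv[2])
              }
            }
            qs <- quantSpec(bi, ref_label = p[["ref"]],
                            ref_concentration = num(p, "conc", 1),
                            ref_protons = as.integer(num(p, "refprotons", 1)))
          }
          f <- file.path(outDir, "qhnmr.xlsx")
          exportQhnmr(st$set, st$bucketTable, st$dm, st$sm, qs, f)
          st$files <- c(st$files, f)
        },
        ALIGN_LS = {
          needSet()
          out <- alignZoneLS(st$set, parseZoneParam(p[["zone"]]),
                             cmdSelection(p), max_shift = num(p, "max", 20))
          st$reports[[length(st$reports) + 1]] <- out$report
          st$set <- out$set
        },
        ALIGN_PTW = {
          needSet()
          out <- alignZonePTW(st$set, parseZoneParam(p[["zone"]]),
                              cmdSelection(p), degree = num(p, "degree", 1))
          st$reports[[length(st$reports) + 1]] <- out$report
          st$set <- out$set
        },
        { # remaining set transformations share one path
          needSet()
          st$set <- recordCommand(st$set, cmd)
        })
      TRUE
    }, error = function(e) e)
    if (inherits(res, "error"))
      stop(sprintf("macro command %d (%s) failed: %s", i, cmd$op,
                   conditionMessage(res)), call. = FALSE)
    if (logLevel != "quiet")
      message(sprintf("[%s] %-14s %.2fs %s",
                      format(Sys.time(), "%H:%M:%S"), cmd$op,
                      proc.time()[["elapsed"]] - t0,
                      serializeMacroCommand(cmd)))
  }
  invisible(st)
}
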