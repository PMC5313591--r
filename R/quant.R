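#' Quantification specification for the qHNMR workbook
#'
#' Associates each bucket with a metabolite name and proton count and
#' names the internal reference: a bucket of known concentration (e.g.
#' TSP at 1 mM) whose integral anchors the proportionality.
#'
#' @param bucketInfo data.frame with columns `label`, `metabolite`,
#'   `protons` (integer >= 1), one row per bucket to quantify.
#' @param ref_label label of the reference bucket.
#' @param ref_concentration reference concentration (e.g. mM).
#' @param ref_protons proton count of the reference resonance (>= 1).
#' @return a `quantSpec` list.
#' @export
quantSpec <- function(bucketInfo, ref_label, ref_concentration, ref_protons) {
  stopifnot(all(c("label", "metabolite", "protons") %in% colnames(bucketInfo)),
            all(bucketInfo$protons >= 1), ref_protons >= 1,
            ref_concentration > 0)
  if (!ref_label %in% bucketInfo$label)
    stop("ref_label must appear in bucketInfo")
  structure(list(bucketInfo = bucketInfo, ref_label = ref_label,
                 ref_concentration = ref_concentration,
                 ref_protons = as.integer(ref_protons)),
            class = "quantSpec")
}

#' Internal-reference quantification
#'
#' The standard qHNMR proportionality: per spectrum `s` and bucket `b`,
#' `conc(s, b) = ref_concentration * (A(s, b) / nH_b) /
#' (A(s, ref) / nH_ref)` — integrals normalized by proton counts against
#' the internal reference. Scale-equivariant: rescaling a whole spectrum
#' leaves its concentrations unchanged.
#'
#' @param dm data matrix from [integrateBuckets()].
#' @param qs a [quantSpec()].
#' @return N x B matrix of concentrations in the reference's units.
#' @export
quantify <- function(dm, qs) {
  stopifnot(inherits(qs, "quantSpec"))
  if (!qs$ref_label %in% colnames(dm))
    stop("reference bucket ", qs$ref_label, " absent from data matrix")
  aref <- dm[, qs$ref_label]
  if (any(aref <= 0))
    stop("reference bucket integral must be > 0 in every spectrum; ",
         "offending: ",
         paste(rownames(dm)[aref <= 0], collapse = ", "))
  bi <- qs$bucketInfo[qs$bucketInfo$label %in% colnames(dm), , drop = FALSE]
  out <- matrix(NA_real_, nrow(dm), nrow(bi),
                dimnames = list(rownames(dm), bi$label))
  refPerH <- aref / qs$ref_protons
  for (i in seq_len(nrow(bi)))
    out[, i] <- qs$ref_concentration *
      (dm[, bi$label[i]] / bi$protons[i]) / refPerH
  out
}

#' Export the qHNMR workbook
#'
#' Writes one XLSX workbook with exactly five sheets — `samples`,
#' `buckets`, `snr`, `data_matrix`, `quantifications` — the complete
#' record a targeted quantification needs. The `samples` and `buckets`
#' sheets are pre-filled with defaults (factor levels; metabolite = label
#' and protons = 1 where no [quantSpec()] is given) to be adjusted by the
#' analyst; the quantification formula is stored in the workbook's
#' document properties. Numbers are written at full precision.
#'
#' @param set a [SpectrumSet-class].
#' @param bucketTable a [BucketTable-class].
#' @param dm,sm data and SNR matrices with matching keys.
#' @param qs a [quantSpec()], or NULL (empty quantifications sheet, with
#'   a warning).
#' @param path output `.xlsx`.
#' @return `path`, invisibly.
#' @export
exportQhnmr <- function(set, bucketTable, dm, sm, qs = NULL, path) {
  b <- buckets(bucketTable)
  ids <- sampleNames(set)
  if (!identical(rownames(dm), ids) || !identical(rownames(sm), ids))
    stop("data/SNR matrix rows do not match the sample table")
  if (!identical(colnames(dm), b$label) || !identical(colnames(sm), b$label))
    stop("data/SNR matrix columns do not match the bucket table")
  bsheet <- b
  bsheet$metabolite <- b$label
  bsheet$protons <- 1
  if (!is.null(qs)) {
    m <- match(b$label, qs$bucketInfo$label)
    ok <- !is.na(m)
    bsheet$metabolite[ok] <- qs$bucketInfo$metabolite[m[ok]]
    bsheet$protons[ok] <- qs$bucketInfo$protons[m[ok]]
    q <- quantify(dm, qs)
    qsheet <- data.frame(sample_id = ids, as.data.frame(q),
                         check.names = FALSE)
  } else {
    warning("no quantification spec; writing empty quantifications sheet")
    qsheet <- data.frame()
  }
  sheets <- list(
    samples = sampleData(set),
    buckets = bsheet,
    snr = data.frame(sample_id = ids, as.data.frame(sm), check.names = FALSE),
    data_matrix = data.frame(sample_id = ids, as.data.frame(dm),
                             check.names = FALSE),
    quantifications = qsheet)
  writeXlsx(sheets, path, description = paste0(
    "conc(s,b) = ref_concentration * (A(s,b)/nH_b) / (A(s,ref)/nH_ref)",
    if (!is.null(qs)) sprintf("; ref=%s %g per %dH", qs$ref_label,
                              qs$ref_concentration, qs$ref_protons) else ""))
  invisible(path)
}

#' @rdname exportQhnmr
#' @details `readQhnmr()` reads the workbook back as a named list of the
#'   five tables.
#' @export
readQhnmr <- function(path) readXlsx(path)

#' Export statistics-ready data matrices
#'
#' `generic_tsv` writes the data matrix (rows = samples, columns =
#' buckets), the SNR matrix and a companion sample-factor table as
#' separate TSV files; `metaboanalyst` writes one table with sample names
#' in column 1, the class label (the first factor column) in column 2 and
#' buckets after — directly ingestible by that tool.
#'
#' @param dm data matrix.
#' @param sm SNR matrix (may be NULL for the metaboanalyst flavor).
#' @param sampleTable data.frame, first column `sample_id`.
#' @param prefix output path prefix; files get `_datamatrix.tsv`,
#'   `_snrmatrix.tsv`, `_samples.tsv` or `_metaboanalyst.tsv` suffixes.
#' @param flavor `"generic_tsv"` or `"metaboanalyst"`.
#' @return character vector of the files written, invisibly.
#' @export
exportMatrix <- function(dm, sm = NULL, sampleTable, prefix,
                         flavor = c("generic_tsv", "metaboanalyst")) {
  flavor <- match.arg(flavor)
  if (ncol(dm) == 0) stop("no buckets to export")
  wTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    path
  }
  if (flavor == "generic_tsv") {
    files <- wTsv(data.frame(sample_id = rownames(dm), as.data.frame(dm),
                             check.names = FALSE),
                  paste0(prefix, "_datamatrix.tsv"))
    if (!is.null(sm))
      files <- c(files, wTsv(data.frame(sample_id = rownames(sm),
                                        as.data.frame(sm),
                                        check.names = FALSE),
                             paste0(prefix, "_snrmatrix.tsv")))
    files <- c(files, wTsv(sampleTable, paste0(prefix, "_samples.tsv")))
  } else {
    cls <- sampleTable[[2]][match(rownames(dm), sampleTable$sample_id)]
    files <- wTsv(data.frame(Sample = rownames(dm), Class = cls,
                             as.data.frame(dm), check.names = FALSE),
                  paste0(prefix, "_metaboanalyst.tsv"))
  }
  invisible(files)
}
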