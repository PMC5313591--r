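# Minimal XLSX writer/reader. An XLSX workbook is a zip archive of XML
# parts; the archive is assembled directly (deflate streams obtained by
# stripping the zlib wrapper from memCompress output, CRC-32 computed
# table-driven) so no spreadsheet library is required. Cells are written
# as inline strings or plain numbers at full precision; fixed archive
# timestamps keep byte-identical output for identical tables.

.crcTable <- local({
  tab <- integer(256)
  for (n in 0:255) {
    cc <- n
    for (k in 1:8)
      cc <- if (bitwAnd(cc, 1L) != 0L)
        bitwXor(bitwShiftR(cc, 1L), -306674912L)  # 0xEDB88320
      else bitwShiftR(cc, 1L)
    tab[n + 1] <- cc
  }
  tab
})

crc32 <- function(bytes) {
  cc <- -1L
  b <- as.integer(bytes)
  for (i in seq_along(b))
    cc <- bitwXor(bitwShiftR(cc, 8L),
                  .crcTable[bitwAnd(bitwXor(cc, b[i]), 255L) + 1L])
  bitwXor(cc, -1L)
}

# raw deflate stream of `bytes` (zlib wrapper stripped)
deflateRaw <- function(bytes) {
  z <- memCompress(bytes, "gzip")      # yields a zlib stream
  z[3:(length(z) - 4)]
}

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

# write a zip archive; files = named list of raw vectors
writeZip <- function(files, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(length(files))
  central <- raw(0)
  pos <- 0L
  dosTime <- 0L; dosDate <- 33L         # fixed 1980-01-01, determinism
  for (i in seq_along(files)) {
    name <- charToRaw(names(files)[i])
    data <- files[[i]]
    comp <- deflateRaw(data)
    crc <- crc32(data)
    offsets[i] <- pos
    hdr <- c(u32(67324752L), u16(20L), u16(0L), u16(8L), u16(dosTime),
             u16(dosDate), u32(crc), u32(length(comp)), u32(length(data)),
             u16(length(name)), u16(0L))
    writeBin(c(hdr, name, comp), con)
    pos <- pos + length(hdr) + length(name) + length(comp)
    central <- c(central, u32(33639248L), u16(20L), u16(20L), u16(0L),
                 u16(8L), u16(dosTime), u16(dosDate), u32(crc),
                 u32(length(comp)), u32(length(data)), u16(length(name)),
                 u16(0L), u16(0L), u16(0L), u16(0L), u32(0L),
                 u32(offsets[i]), name)
  }
  writeBin(central, con)
  writeBin(c(u32(101010256L), u16(0L), u16(0L), u16(length(files)),
             u16(length(files)), u32(length(central)), u32(pos),
             u16(0L)), con)
  invisible(path)
}

xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

colLetter <- function(j) {
  out <- ""
  while (j > 0) {
    out <- paste0(LETTERS[(j - 1) %% 26 + 1], out)
    j <- (j - 1) %/% 26
  }
  out
}

sheetXml <- function(df) {
  rows <- character(nrow(df) + 1)
  hdr <- vapply(seq_along(df), function(j)
    sprintf('<c r="%s1" t="inlineStr"><is><t>%s</t></is></c>',
            colLetter(j), xmlEscape(colnames(df)[j])), character(1))
  rows[1] <- sprintf('<row r="1">%s</row>', paste(hdr, collapse = ""))
  isNum <- vapply(df, is.numeric, logical(1))
  for (i in seq_len(nrow(df))) {
    cells <- character(0)
    for (j in seq_along(df)) {
      v <- df[i, j]
      if (is.na(v)) next
      ref <- paste0(colLetter(j), i + 1)
      cells <- c(cells, if (isNum[j])
        sprintf('<c r="%s"><v>%s</v></c>', ref, sprintf("%.17g", v))
      else
        sprintf('<c r="%s" t="inlineStr"><is><t>%s</t></is></c>', ref,
                xmlEscape(as.character(v))))
    }
    rows[i + 1] <- sprintf('<row r="%d">%s</row>', i + 1,
                           paste(cells, collapse = ""))
  }
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
         '<worksheet xmlns="http://schemas.openxmlformats.org/',
         'spreadsheetml/2006/main"><sheetData>',
         paste(rows, collapse = ""), '</sheetData></worksheet>')
}

#' Write a multi-sheet XLSX workbook
#'
#' Each element of `sheets` (a named list of data.frames) becomes one
#' worksheet; the first row carries the column names, numeric columns are
#' written at full precision, everything else as inline strings.
#'
#' @param sheets named list of data.frames.
#' @param path output `.xlsx` path.
#' @param description optional text stored in the workbook's core
#'   document properties.
#' @return `path`, invisibly.
#' @export
writeXlsx <- function(sheets, path, description = "") {
  stopifnot(is.list(sheets), length(names(sheets)) == length(sheets))
  n <- length(sheets)
  ct <- paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    paste(sprintf('<Override PartName="/xl/worksheets/sheet%d.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
                  seq_len(n)), collapse = ""),
    '<Override PartName="/docProps/core.xml" ContentType="application/vnd.openxmlformats-package.core-properties+xml"/>',
    '</Types>')
  rels <- paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    '<Relationship Id="rId2" Type="http://schemas.openxmlformats.org/package/2006/relationships/metadata/core-properties" Target="docProps/core.xml"/>',
    '</Relationships>')
  wb <- paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships"><sheets>',
    paste(sprintf('<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
                  xmlEscape(names(sheets)), seq_len(n), seq_len(n)),
          collapse = ""),
    '</sheets></workbook>')
  wbrels <- paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    paste(sprintf('<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>',
                  seq_len(n), seq_len(n)), collapse = ""),
    '</Relationships>')
  core <- paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<cp:coreProperties xmlns:cp="http://schemas.openxmlformats.org/package/2006/metadata/core-properties" ',
    'xmlns:dc="http://purl.org/dc/elements/1.1/">',
    '<dc:description>', xmlEscape(description), '</dc:description>',
    '</cp:coreProperties>')
  files <- list(`[Content_Types].xml` = charToRaw(ct),
                `_rels/.rels` = charToRaw(rels),
                `xl/workbook.xml` = charToRaw(wb),
                `xl/_rels/workbook.xml.rels` = charToRaw(wbrels),
                `docProps/core.xml` = charToRaw(core))
  for (i in seq_len(n))
    files[[sprintf("xl/worksheets/sheet%d.xml", i)]] <-
      charToRaw(sheetXml(as.data.frame(sheets[[i]])))
  writeZip(files, path)
  invisible(path)
}

#' Read an XLSX workbook written by [writeXlsx()]
#'
#' @param path `.xlsx` file.
#' @return named list of data.frames (columns numeric where every
#'   non-empty cell is numeric).
#' @export
readXlsx <- function(path) {
  tmp <- tempfile("xlsx")
  utils::unzip(path, exdir = tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  wb <- xml2::read_xml(file.path(tmp, "xl", "workbook.xml"))
  sheetNodes <- xml2::xml_find_all(wb, "//*[local-name()='sheet']")
  names <- xml2::xml_attr(sheetNodes, "name")
  rids <- xml2::xml_attr(sheetNodes, "id")
  rl <- xml2::read_xml(file.path(tmp, "xl", "_rels", "workbook.xml.rels"))
  relNodes <- xml2::xml_find_all(rl, "//*[local-name()='Relationship']")
  targets <- stats::setNames(xml2::xml_attr(relNodes, "Target"),
                             xml2::xml_attr(relNodes, "Id"))
  out <- list()
  for (i in seq_along(names)) {
    sh <- xml2::read_xml(file.path(tmp, "xl", targets[[rids[i]]]))
    rowNodes <- xml2::xml_find_all(sh, "//*[local-name()='row']")
    cellList <- lapply(rowNodes, function(r)
      xml2::xml_find_all(r, ".//*[local-name()='c']"))
    refs <- lapply(cellList, function(cs) xml2::xml_attr(cs, "r"))
    ncolMax <- 0L
    colOf <- function(ref) {
      letters <- gsub("[0-9]", "", ref)
      v <- 0L
      for (ch in strsplit(letters, "")[[1]]) v <- v * 26L + match(ch, LETTERS)
      v
    }
    parsed <- list()
    for (k in seq_along(rowNodes)) {
      cs <- cellList[[k]]
      cols <- vapply(refs[[k]], colOf, integer(1))
      ncolMax <- max(ncolMax, if (length(cols)) max(cols) else 0L)
      vals <- character(length(cs)); isStr <- logical(length(cs))
      for (j in seq_along(cs)) {
        t <- xml2::xml_attr(cs[j], "t")
        if (identical(t, "inlineStr")) {
          vals[j] <- xml2::xml_text(
            xml2::xml_find_first(cs[j], ".//*[local-name()='t']"))
          isStr[j] <- TRUE
        } else {
          vals[j] <- xml2::xml_text(
            xml2::xml_find_first(cs[j], ".//*[local-name()='v']"))
        }
      }
      parsed[[k]] <- list(cols = cols, vals = vals, isStr = isStr)
    }
    if (!length(parsed) || ncolMax == 0L) { out[[names[i]]] <- data.frame(); next }
    grid <- matrix(NA_character_, length(parsed), ncolMax)
    strCol <- logical(ncolMax)
    for (k in seq_along(parsed)) {
      grid[k, parsed[[k]]$cols] <- parsed[[k]]$vals
      if (k > 1)      # header row is always string
        strCol[parsed[[k]]$cols] <- strCol[parsed[[k]]$cols] | parsed[[k]]$isStr
    }
    header <- grid[1, ]
    body <- grid[-1, , drop = FALSE]
    df <- as.data.frame(matrix(nrow = nrow(body), ncol = ncolMax))
    for (j in seq_len(ncolMax)) {
      df[[j]] <- if (strCol[j]) body[, j] else as.numeric(body[, j])
    }
    colnames(df) <- header
    out[[names[i]]] <- df
  }
  out
}
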