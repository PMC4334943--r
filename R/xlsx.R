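# Minimal Office Open XML workbook writer.
#
# Workbooks here are plain text tables, so the writer targets exactly that:
# one inline-string worksheet per sheet, no shared strings, no formats, no
# formulas. Entries are stored uncompressed in the ZIP container, with a
# fixed modification timestamp so output bytes depend only on content.
# Reading is delegated to readxl (see spreadsheet.R).

crc32_env <- new.env(parent = emptyenv())

crc32_table <- function() {
  if (is.null(crc32_env$tab)) {
    tab <- integer(256)
    for (n in 0:255) {
      cc <- n
      for (k in 1:8) {
        cc <- if (bitwAnd(cc, 1L))
          bitwXor(bitwShiftR(cc, 1L), -306674912L)  # 0xEDB88320
        else bitwShiftR(cc, 1L)
      }
      tab[n + 1L] <- cc
    }
    crc32_env$tab <- tab
  }
  crc32_env$tab
}

crc32 <- function(data) {
  tab <- crc32_table()
  crc <- -1L
  for (b in as.integer(data)) {
    crc <- bitwXor(bitwShiftR(crc, 8L), tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  crc <- bitwXor(crc, -1L)
  if (crc < 0) crc + 4294967296 else as.numeric(crc)
}

u16 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256))
u32 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                            (x %/% 65536) %% 256, (x %/% 16777216) %% 256))

# Store-method ZIP with a constant timestamp (deterministic bytes).
zip_write <- function(path, entries) {
  dos_date <- (2015 - 1980) * 512 + 1 * 32 + 1   # 2015-01-01
  dos_time <- 0
  locals <- list(); centrals <- list()
  offset <- 0
  for (name in names(entries)) {
    data <- entries[[name]]
    nm <- charToRaw(name)
    crc <- crc32(data)
    sz <- length(data)
    head <- c(as.raw(c(0x50, 0x4b, 0x03, 0x04)), u16(20), u16(0), u16(0),
              u16(dos_time), u16(dos_date), u32(crc), u32(sz), u32(sz),
              u16(length(nm)), u16(0), nm)
    locals[[name]] <- c(head, data)
    centrals[[name]] <- c(as.raw(c(0x50, 0x4b, 0x01, 0x02)), u16(20), u16(20),
                          u16(0), u16(0), u16(dos_time), u16(dos_date),
                          u32(crc), u32(sz), u32(sz), u16(length(nm)),
                          u16(0), u16(0), u16(0), u16(0), u32(0),
                          u32(offset), nm)
    offset <- offset + length(locals[[name]])
  }
  cd <- do.call(c, unname(centrals))
  eocd <- c(as.raw(c(0x50, 0x4b, 0x05, 0x06)), u16(0), u16(0),
            u16(length(entries)), u16(length(entries)),
            u32(length(cd)), u32(offset), u16(0))
  con <- tryCatch(suppressWarnings(file(path, "wb")),
                  error = function(e) abort_io(sprintf("cannot write '%s'", path)))
  on.exit(close(con))
  writeBin(do.call(c, c(unname(locals), list(cd, eocd))), con)
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub('"', "&quot;", x, fixed = TRUE)
  x
}

col_letter <- function(j) {
  out <- ""
  while (j > 0) {
    out <- paste0(LETTERS[(j - 1) %% 26 + 1], out)
    j <- (j - 1) %/% 26
  }
  out
}

XML_DECL <- '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n'

sheet_xml <- function(mat) {
  rows <- character(0)
  if (length(mat) && nrow(mat)) {
    letters_ <- vapply(seq_len(ncol(mat)), col_letter, "")
    rows <- vapply(seq_len(nrow(mat)), function(i) {
      vals <- mat[i, ]
      keep <- which(!is.na(vals) & nzchar(vals))
      if (!length(keep)) return(sprintf('<row r="%d"/>', i))
      cells <- sprintf(
        '<c r="%s%d" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
        letters_[keep], i, xml_escape(vals[keep]))
      sprintf('<row r="%d">%s</row>', i, paste(cells, collapse = ""))
    }, "")
  }
  paste0(XML_DECL,
         '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
         "<sheetData>", paste(rows, collapse = ""), "</sheetData></worksheet>")
}

# sheets: named list of character matrices (NA or "" = blank cell).
write_xlsx_minimal <- function(sheets, path) {
  n <- length(sheets)
  stopifnot(n >= 1, !is.null(names(sheets)))
  sheet_parts <- sprintf("xl/worksheets/sheet%d.xml", seq_len(n))
  types <- paste0(
    XML_DECL,
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    paste(sprintf('<Override PartName="/%s" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
                  sheet_parts), collapse = ""),
    '<Override PartName="/xl/styles.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.styles+xml"/>',
    "</Types>")
  root_rels <- paste0(
    XML_DECL,
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    "</Relationships>")
  workbook <- paste0(
    XML_DECL,
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    "<sheets>",
    paste(sprintf('<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
                  xml_escape(names(sheets)), seq_len(n), seq_len(n)),
          collapse = ""),
    "</sheets></workbook>")
  wb_rels <- paste0(
    XML_DECL,
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    paste(sprintf('<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>',
                  seq_len(n), seq_len(n)), collapse = ""),
    sprintf('<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/styles" Target="styles.xml"/>',
            n + 1L),
    "</Relationships>")
  styles <- paste0(
    XML_DECL,
    '<styleSheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    '<fonts count="1"><font><sz val="11"/><name val="Calibri"/></font></fonts>',
    '<fills count="1"><fill><patternFill patternType="none"/></fill></fills>',
    '<borders count="1"><border/></borders>',
    '<cellStyleXfs count="1"><xf/></cellStyleXfs>',
    '<cellXfs count="1"><xf xfId="0"/></cellXfs>',
    "</styleSheet>")
  entries <- c(
    stats::setNames(list(charToRaw(types)), "[Content_Types].xml"),
    stats::setNames(list(charToRaw(root_rels)), "_rels/.rels"),
    stats::setNames(list(charToRaw(workbook)), "xl/workbook.xml"),
    stats::setNames(list(charToRaw(wb_rels)), "xl/_rels/workbook.xml.rels"),
    stats::setNames(list(charToRaw(styles)), "xl/styles.xml"),
    stats::setNames(lapply(sheets, function(m) charToRaw(sheet_xml(m))), sheet_parts)
  )
  zip_write(path, entries)
}
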