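# Minimal OOXML spreadsheet writer.
#
# Writes a single-sheet .xlsx: an uncompressed ("stored") zip container with
# the five required parts and inline strings, which every spreadsheet reader
# (including readxl) accepts. Numeric cells are written as numbers, text as
# inline strings, missing cells are omitted. Kept deliberately small: the
# package only needs to emit template files, not general workbooks.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

col_letter <- function(j) {
  out <- ""
  while (j > 0) {
    r <- (j - 1) %% 26
    out <- paste0(LETTERS[r + 1], out)
    j <- (j - 1) %/% 26
  }
  out
}

sheet_xml <- function(df) {
  letters_ <- vapply(seq_len(ncol(df)), col_letter, character(1))
  cell <- function(i, j, v) {
    ref <- paste0(letters_[j], i)
    if (is.na(v)) return("")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num) && !is.character(v)) {
      paste0("<c r=\"", ref, "\"><v>", format(num, digits = 15,
                                              scientific = FALSE),
             "</v></c>")
    } else {
      paste0("<c r=\"", ref, "\" t=\"inlineStr\"><is><t>",
             xml_escape(as.character(v)), "</t></is></c>")
    }
  }
  rows <- character(nrow(df) + 1)
  rows[1] <- paste0("<row r=\"1\">",
                    paste0(vapply(seq_len(ncol(df)), function(j)
                      cell(1, j, names(df)[j]), character(1)),
                      collapse = ""), "</row>")
  for (i in seq_len(nrow(df))) {
    cells <- vapply(seq_len(ncol(df)), function(j) {
      v <- df[[j]][i]
      if (is.na(v)) return("")
      num <- suppressWarnings(as.numeric(v))
      ref <- paste0(letters_[j], i + 1)
      if (!is.na(num)) {
        paste0("<c r=\"", ref, "\"><v>",
               format(num, digits = 15, scientific = FALSE), "</v></c>")
      } else {
        paste0("<c r=\"", ref, "\" t=\"inlineStr\"><is><t>",
               xml_escape(as.character(v)), "</t></is></c>")
      }
    }, character(1))
    rows[i + 1] <- paste0("<row r=\"", i + 1, "\">",
                          paste0(cells, collapse = ""), "</row>")
  }
  paste0("<?xml version=\"1.0\" encoding=\"UTF-8\" standalone=\"yes\"?>",
         "<worksheet xmlns=\"http://schemas.openxmlformats.org/",
         "spreadsheetml/2006/main\"><sheetData>",
         paste0(rows, collapse = ""), "</sheetData></worksheet>")
}

# CRC-32 (IEEE 802.3 polynomial), table-driven, on a raw vector
crc32_table <- local({
  tab <- integer(256)
  poly <- -306674912L  # 0xEDB88320 as a signed 32-bit integer
  for (i in 0:255) {
    cc <- i
    for (k in 1:8) {
      cc <- if (bitwAnd(cc, 1L) != 0L)
        bitwXor(bitwShiftR(cc, 1L), poly) else bitwShiftR(cc, 1L)
    }
    tab[i + 1] <- cc
  }
  tab
})

crc32 <- function(bytes) {
  cc <- -1L
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    cc <- bitwXor(bitwShiftR(cc, 8L),
                  crc32_table[bitwAnd(bitwXor(cc, b[i]), 255L) + 1L])
  }
  bitwXor(cc, -1L)
}

write_u16 <- function(con, x) writeBin(as.integer(x), con, size = 2,
                                       endian = "little")
write_u32 <- function(con, x) writeBin(as.integer(x), con, size = 4,
                                       endian = "little")

# stored (method 0) zip archive from a named list of character contents
write_stored_zip <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  dos_date <- 19685L  # fixed date stamp for reproducible output
  offsets <- integer(length(entries))
  crcs <- integer(length(entries))
  sizes <- integer(length(entries))
  names_raw <- lapply(names(entries), charToRaw)
  data_raw <- lapply(entries, function(x) charToRaw(enc2utf8(x)))

  for (i in seq_along(entries)) {
    offsets[i] <- seek(con)
    crcs[i] <- crc32(data_raw[[i]])
    sizes[i] <- length(data_raw[[i]])
    write_u32(con, 0x04034b50)           # local file header
    write_u16(con, 20); write_u16(con, 0); write_u16(con, 0)
    write_u16(con, 0); write_u16(con, dos_date)
    write_u32(con, crcs[i])
    write_u32(con, sizes[i]); write_u32(con, sizes[i])
    write_u16(con, length(names_raw[[i]])); write_u16(con, 0)
    writeBin(names_raw[[i]], con)
    writeBin(data_raw[[i]], con)
  }
  cd_start <- seek(con)
  for (i in seq_along(entries)) {
    write_u32(con, 0x02014b50)           # central directory entry
    write_u16(con, 20); write_u16(con, 20); write_u16(con, 0)
    write_u16(con, 0); write_u16(con, 0); write_u16(con, dos_date)
    write_u32(con, crcs[i])
    write_u32(con, sizes[i]); write_u32(con, sizes[i])
    write_u16(con, length(names_raw[[i]]))
    write_u16(con, 0); write_u16(con, 0); write_u16(con, 0)
    write_u16(con, 0); write_u32(con, 0)
    write_u32(con, offsets[i])
    writeBin(names_raw[[i]], con)
  }
  cd_size <- seek(con) - cd_start
  write_u32(con, 0x06054b50)             # end of central directory
  write_u16(con, 0); write_u16(con, 0)
  write_u16(con, length(entries)); write_u16(con, length(entries))
  write_u32(con, cd_size); write_u32(con, cd_start)
  write_u16(con, 0)
  invisible(path)
}

#' Write a dataset as a single-sheet Excel workbook
#'
#' Counterpart of [write_indicator_data()] for the `.xlsx` format: writes
#' the canonical 20 template columns with the on-disk headers. Numeric
#' cells are stored as numbers, text cells as inline strings.
#'
#' @param data An `ineq_data` object or a raw template tibble.
#' @param path Output file path (`.xlsx`).
#' @return `path`, invisibly.
#' @export
write_indicator_xlsx <- function(data, path) {
  rows <- if (inherits(data, "ineq_data")) dataset_rows(data) else
    tibble::as_tibble(data)
  out <- rows[, TEMPLATE_COLUMNS]
  names(out) <- TEMPLATE_HEADERS
  write_minimal_xlsx(out, path)
}

write_minimal_xlsx <- function(df, path) {
  ct <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\" standalone=\"yes\"?>",
    "<Types xmlns=\"http://schemas.openxmlformats.org/package/2006/",
    "content-types\">",
    "<Default Extension=\"rels\" ContentType=\"application/vnd.",
    "openxmlformats-package.relationships+xml\"/>",
    "<Default Extension=\"xml\" ContentType=\"application/xml\"/>",
    "<Override PartName=\"/xl/workbook.xml\" ContentType=\"application/",
    "vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml\"/>",
    "<Override PartName=\"/xl/worksheets/sheet1.xml\" ContentType=",
    "\"application/vnd.openxmlformats-officedocument.spreadsheetml.",
    "worksheet+xml\"/></Types>")
  rels <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\" standalone=\"yes\"?>",
    "<Relationships xmlns=\"http://schemas.openxmlformats.org/package/",
    "2006/relationships\"><Relationship Id=\"rId1\" Type=\"http://schemas.",
    "openxmlformats.org/officeDocument/2006/relationships/officeDocument\"",
    " Target=\"xl/workbook.xml\"/></Relationships>")
  wb <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\" standalone=\"yes\"?>",
    "<workbook xmlns=\"http://schemas.openxmlformats.org/spreadsheetml/",
    "2006/main\" xmlns:r=\"http://schemas.openxmlformats.org/",
    "officeDocument/2006/relationships\"><sheets>",
    "<sheet name=\"Sheet1\" sheetId=\"1\" r:id=\"rId1\"/>",
    "</sheets></workbook>")
  wb_rels <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\" standalone=\"yes\"?>",
    "<Relationships xmlns=\"http://schemas.openxmlformats.org/package/",
    "2006/relationships\"><Relationship Id=\"rId1\" Type=\"http://schemas.",
    "openxmlformats.org/officeDocument/2006/relationships/worksheet\" ",
    "Target=\"worksheets/sheet1.xml\"/></Relationships>")
  entries <- list(
    "[Content_Types].xml" = ct,
    "_rels/.rels" = rels,
    "xl/workbook.xml" = wb,
    "xl/_rels/workbook.xml.rels" = wb_rels,
    "xl/worksheets/sheet1.xml" = sheet_xml(df)
  )
  write_stored_zip(entries, path)
  invisible(path)
}
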