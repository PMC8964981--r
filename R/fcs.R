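# Minimal FCS 3.0 writer/reader (list mode, 32-bit float, little-endian).
# Covers exactly the files this package emits: one DATA segment, marker
# names in $PnN and $PnS. Not a general-purpose FCS implementation.

#' Write a cell-by-marker matrix as FCS 3.0
#'
#' @param mat Numeric matrix (cells x markers) with column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(mat, path) {
  mat <- as.matrix(mat)
  if (is.null(colnames(mat))) abort("matrix must have marker column names")
  npar <- ncol(mat)
  tot <- nrow(mat)
  delim <- "/"
  kw <- c(
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0", "$PAR" = as.character(npar), "$TOT" = as.character(tot)
  )
  for (i in seq_len(npar)) {
    kw[sprintf("$P%dN", i)] <- colnames(mat)[i]
    kw[sprintf("$P%dS", i)] <- colnames(mat)[i]
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dR", i)] <- "262144"
  }
  build_text <- function(kw) {
    paste0(delim, paste0(names(kw), delim, unname(kw), delim, collapse = ""))
  }
  # data offsets depend on TEXT length, which depends on the offsets; two
  # passes with fixed-width offset fields make it stable
  header_len <- 58
  kw["$BEGINDATA"] <- sprintf("%8d", 0)
  kw["$ENDDATA"] <- sprintf("%8d", 0)
  text <- build_text(kw)
  text_begin <- header_len
  text_end <- text_begin + nchar(text) - 1
  data_begin <- text_end + 1
  data_end <- data_begin + 4 * npar * tot - 1
  kw["$BEGINDATA"] <- sprintf("%8d", data_begin)
  kw["$ENDDATA"] <- sprintf("%8d", data_end)
  text <- build_text(kw)
  stopifnot(nchar(text) == text_end - text_begin + 1)
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_begin, text_end, data_begin, data_end, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.vector(t(mat)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an FCS file written by [write_fcs()]
#'
#' @param path FCS file path.
#' @return Numeric matrix (cells x markers), column names from `$PnN`.
#' @export
read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58, useBytes = TRUE)
  if (substr(header, 1, 6) != "FCS3.0") abort("not an FCS 3.0 file")
  off <- as.integer(trimws(substring(header, seq(11, 51, by = 8),
                                     seq(18, 58, by = 8))))
  text_begin <- off[1]; text_end <- off[2]
  seek(con, text_begin)
  text <- readChar(con, text_end - text_begin + 1, useBytes = TRUE)
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  kw <- setNames(parts[seq(2, length(parts), by = 2)],
                 parts[seq(1, length(parts), by = 2)])
  npar <- as.integer(kw["$PAR"])
  tot <- as.integer(kw["$TOT"])
  data_begin <- as.integer(trimws(kw["$BEGINDATA"]))
  if (is.na(data_begin) || data_begin == 0) data_begin <- off[3]
  seek(con, data_begin)
  vals <- readBin(con, "numeric", n = npar * tot, size = 4,
                  endian = "little")
  mat <- matrix(vals, nrow = tot, byrow = TRUE)
  colnames(mat) <- unname(kw[sprintf("$P%dN", seq_len(npar))])
  mat
}
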