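#' Read an event matrix
#'
#' Reads events-by-channels data from a delimited text file (comma- or
#' tab-separated, autodetected, with an optional header row of channel names)
#' or from an FCS 3.0/3.1 file. Values are returned exactly as stored: no
#' compensation or transformation (log/logicle) is applied, the matrix is
#' clustered as read.
#'
#' @param path file to read.
#' @param format `"auto"` (by extension: `.fcs` means FCS), `"delimited"` or
#'   `"fcs"`.
#' @param channels optional character vector restricting and ordering the
#'   channels; unknown names are an error.
#' @return numeric matrix, events as rows, channel names as column names.
#' @export
readEvents <- function(path, format = c("auto", "delimited", "fcs"),
                       channels = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs"
              else "delimited"
  mat <- switch(format,
                delimited = readDelimitedEvents(path),
                fcs = readFCSEvents(path))
  if (!is.null(channels)) {
    missing <- setdiff(channels, colnames(mat))
    if (length(missing))
      stop("unknown channel name(s): ", paste(missing, collapse = ", "))
    mat <- mat[, channels, drop = FALSE]
  }
  mat
}

readDelimitedEvents <- function(path) {
  dt <- data.table::fread(path, header = "auto", sep = "auto",
                          data.table = FALSE, colClasses = NULL)
  bad <- !vapply(dt, is.numeric, logical(1))
  if (any(bad))
    stop("non-numeric values in delimited input, column(s): ",
         paste(names(dt)[bad], collapse = ", "))
  mat <- as.matrix(dt)
  if (is.null(colnames(mat)) || any(colnames(mat) == ""))
    colnames(mat) <- paste0("ch", seq_len(ncol(mat)))
  asEventMatrix(mat)
}

# Minimal FCS 3.0/3.1 reader: 58-byte ASCII header with segment offsets, a
# delimiter-separated TEXT segment, and a list-mode DATA segment of float,
# double or integer events. Covers the keywords this package needs
# ($PAR/$TOT/$DATATYPE/$BYTEORD/$MODE/$PnN/$PnB); no analysis segment, no
# compensation.
readFCSEvents <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", 58L))
  version <- substr(header, 1L, 6L)
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("unsupported FCS version: ", version)
  off <- function(a, b) as.numeric(trimws(substr(header, a, b)))
  textBeg <- off(11, 18); textEnd <- off(19, 26)
  dataBeg <- off(27, 34); dataEnd <- off(35, 42)

  seek(con, textBeg)
  text <- rawToChar(readBin(con, "raw", textEnd - textBeg + 1L))
  delim <- substr(text, 1L, 1L)
  tokens <- strsplit(substring(text, 2L), delim, fixed = TRUE)[[1L]]
  if (length(tokens) %% 2L == 1L)
    tokens <- tokens[-length(tokens)]
  kw <- stats::setNames(tokens[seq(2L, length(tokens), 2L)],
                        toupper(trimws(tokens[seq(1L, length(tokens), 2L)])))

  npar <- as.integer(kw[["$PAR"]])
  ntot <- as.integer(kw[["$TOT"]])
  dtype <- toupper(trimws(kw[["$DATATYPE"]]))
  mode <- toupper(trimws(kw[["$MODE"]]))
  if (!identical(mode, "L"))
    stop("only list-mode ($MODE L) FCS data is supported")
  byteord <- trimws(kw[["$BYTEORD"]])
  endian <- if (byteord %in% c("1,2,3,4", "1,2")) "little"
            else if (byteord %in% c("4,3,2,1", "2,1")) "big"
            else stop("unsupported $BYTEORD: ", byteord)
  if (dataBeg == 0 && !is.null(kw[["$BEGINDATA"]]))
    dataBeg <- as.numeric(kw[["$BEGINDATA"]])
  if (dataEnd == 0 && !is.null(kw[["$ENDDATA"]]))
    dataEnd <- as.numeric(kw[["$ENDDATA"]])

  bits <- vapply(seq_len(npar), function(i)
    as.integer(kw[[paste0("$P", i, "B")]]), integer(1))
  seek(con, dataBeg)
  nvals <- npar * ntot
  vals <- switch(dtype,
    F = readBin(con, "numeric", nvals, size = 4L, endian = endian),
    D = readBin(con, "numeric", nvals, size = 8L, endian = endian),
    I = {
      if (length(unique(bits)) != 1L || !bits[1L] %in% c(16L, 32L))
        stop("integer FCS data requires uniform $PnB of 16 or 32")
      readBin(con, "integer", nvals, size = bits[1L] / 8L,
              signed = bits[1L] > 16L, endian = endian)
    },
    stop("unsupported $DATATYPE: ", dtype))
  if (length(vals) != nvals)
    stop("FCS data segment shorter than $PAR * $TOT values")
  mat <- matrix(as.numeric(vals), nrow = ntot, ncol = npar, byrow = TRUE)
  colnames(mat) <- vapply(seq_len(npar), function(i) {
    nm <- kw[[paste0("$P", i, "N")]]
    if (is.null(nm) || !nzchar(nm)) paste0("ch", i) else nm
  }, character(1))
  asEventMatrix(mat)
}

#' Write event labels
#'
#' One component id per line, in input event order.
#'
#' @param path output file.
#' @param labels integer vector, one 1-based component id per event.
#' @export
writeLabels <- function(path, labels) {
  if (length(labels) < 1L)
    stop("'labels' must contain at least one label")
  labels <- as.integer(labels)
  if (anyNA(labels) || min(labels) < 1L)
    stop("labels must be positive integers")
  writeLines(as.character(labels), path)
  invisible(NULL)
}

#' Read event labels written by [writeLabels()]
#'
#' @param path file with one integer label per line.
#' @return integer vector.
#' @export
readLabels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  as.integer(readLines(path))
}
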