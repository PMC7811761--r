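# Minimal FCS 3.1 list-mode I/O: float32 data, $PnN channel names,
# little/big endian. Covers what the assay pipeline needs; not a general
# cytometry-standard implementation (no analysis segment, no $PnE scaling).

FCS_DATA_START <- 4096L  # TEXT segment padded to a fixed size on write

read_fcs_text <- function(con, begin, end) {
  seek(con, begin)
  raw_txt <- readBin(con, "raw", n = end - begin + 1L)
  txt <- rawToChar(raw_txt)
  delim <- substr(txt, 1L, 1L)
  parts <- strsplit(substring(txt, 2L), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2L == 1L) parts <- parts[-length(parts)]
  keys <- parts[seq(1L, length(parts), by = 2L)]
  vals <- parts[seq(2L, length(parts), by = 2L)]
  stats::setNames(as.list(trimws(vals)), trimws(keys))
}

read_fcs_matrix <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", n = 58L)
  if (length(header) < 58L)
    stop("format error in FCS header: file truncated (", length(header),
         " bytes): ", path)
  version <- rawToChar(header[1:6])
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("format error in FCS header: unsupported version '", version, "'")
  offs <- suppressWarnings(as.integer(
    vapply(0:5, function(i) rawToChar(header[(11 + 8 * i):(18 + 8 * i)]),
           character(1))))
  if (any(is.na(offs[1:2])))
    stop("format error in FCS header: unreadable TEXT segment offsets")
  kw <- read_fcs_text(con, offs[1], offs[2])
  need <- function(k) {
    v <- kw[[k]]
    if (is.null(v)) stop("format error in FCS TEXT segment: missing ", k)
    v
  }
  data_begin <- offs[3]
  data_end <- offs[4]
  if (is.na(data_begin) || data_begin == 0L) {
    data_begin <- as.integer(need("$BEGINDATA"))
    data_end <- as.integer(need("$ENDDATA"))
  }
  npar <- as.integer(need("$PAR"))
  ntot <- as.integer(need("$TOT"))
  dtype <- need("$DATATYPE")
  if (!dtype %in% c("F", "D"))
    stop("format error in FCS DATA segment: unsupported $DATATYPE ", dtype)
  if (!identical(need("$MODE"), "L"))
    stop("format error in FCS DATA segment: only list mode ($MODE L) supported")
  byteord <- need("$BYTEORD")
  endian <- if (byteord %in% c("1,2,3,4", "1,2")) "little" else "big"
  size <- if (dtype == "F") 4L else 8L
  seek(con, data_begin)
  n_values <- npar * ntot
  vals <- readBin(con, "numeric", n = n_values, size = size, endian = endian)
  if (length(vals) < n_values)
    stop("format error in FCS DATA segment: expected ", n_values,
         " values, read ", length(vals))
  chans <- vapply(seq_len(npar), function(i) {
    v <- kw[[sprintf("$P%dN", i)]]
    if (is.null(v)) sprintf("P%d", i) else v
  }, character(1))
  matrix(vals, nrow = ntot, ncol = npar, byrow = TRUE,
         dimnames = list(NULL, chans))
}

write_fcs_matrix <- function(values, path) {
  npar <- ncol(values)
  ntot <- nrow(values)
  data_begin <- FCS_DATA_START
  data_end <- data_begin + 4L * npar * ntot - 1L
  kw <- c("$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
          "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
          "$BEGINDATA" = as.character(data_begin),
          "$ENDDATA" = as.character(data_end),
          "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
          "$NEXTDATA" = "0", "$PAR" = as.character(npar),
          "$TOT" = as.character(ntot))
  for (i in seq_len(npar)) {
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dN", i)] <- colnames(values)[i]
    kw[sprintf("$P%dR", i)] <- format(ceiling(max(values[, i], 1)),
                                      scientific = FALSE)
  }
  delim <- "/"
  text <- paste0(delim, paste0(names(kw), delim, unname(kw), delim,
                               collapse = ""))
  text_begin <- 58L
  text_end <- text_begin + nchar(text, type = "bytes") - 1L
  if (text_end >= data_begin)
    stop("FCS TEXT segment overflow (too many channels)")
  pad8 <- function(x) formatC(x, width = 8, flag = " ")
  header <- paste0("FCS3.1    ", pad8(text_begin), pad8(text_end),
                   pad8(data_begin), pad8(data_end), pad8(0), pad8(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  writeBin(raw(data_begin - text_end - 1L), con)
  # row-major per the list-mode convention: event by event
  writeBin(as.numeric(t(values)), con, size = 4L, endian = "little")
  invisible(path)
}
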