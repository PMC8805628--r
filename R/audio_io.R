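# Minimal readers/writers for the two stimulus-side interchange formats:
# RIFF PCM WAV and Praat TextGrid / TSV phoneme alignments. Only the
# subset of each format needed here is supported (PCM integer and IEEE
# float WAV; IntervalTier TextGrids).

#' Read a PCM WAV file
#'
#' Supports uncompressed PCM (8/16/24/32-bit integer) and 32/64-bit IEEE
#' float mono or multichannel files. Samples are returned in [-1, 1].
#'
#' @param path path to a `.wav` file.
#' @return A list with `samples` (numeric vector for mono, channels x n
#'   matrix otherwise), `fs` (Hz) and `bits`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  invisible(readBin(con, "integer", 1L, 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    abort_bad_arg(sprintf("'%s' is not a RIFF/WAVE file.", path))
  }
  fmt <- NULL; dat <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (id == "fmt ") {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        code = readBin(raw[1:2], "integer", 1L, 2L, endian = "little"),
        channels = readBin(raw[3:4], "integer", 1L, 2L, endian = "little"),
        fs = readBin(raw[5:8], "integer", 1L, 4L, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1L, 2L, endian = "little")
      )
    } else if (id == "data") {
      dat <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
    if (!is.null(fmt) && !is.null(dat)) break
  }
  if (is.null(fmt) || is.null(dat)) abort_bad_arg("malformed WAV file.")
  bytes <- fmt$bits %/% 8L
  n <- length(dat) %/% bytes
  x <- switch(as.character(fmt$code),
    "1" = {
      if (fmt$bits == 8L) {
        (as.numeric(readBin(dat, "integer", n, 1L, signed = FALSE)) - 128) / 128
      } else if (fmt$bits == 24L) {
        m <- matrix(as.integer(dat), nrow = 3L)
        v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
        v <- ifelse(v >= 2^23, v - 2^24, v)
        v / 2^23
      } else {
        readBin(dat, "integer", n, bytes, signed = TRUE, endian = "little") /
          2^(fmt$bits - 1L)
      }
    },
    "3" = readBin(dat, "double", n, bytes, endian = "little"),
    abort_bad_arg(sprintf("unsupported WAV format code %d.", fmt$code))
  )
  if (fmt$channels > 1L) {
    x <- matrix(x, nrow = fmt$channels)
  }
  list(samples = x, fs = fmt$fs, bits = fmt$bits)
}

#' Write a 16-bit PCM WAV file
#'
#' @param samples numeric vector (mono) or channels x n matrix in [-1, 1].
#' @param fs sampling rate in Hz.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, fs, path) {
  if (is.matrix(samples)) {
    nch <- nrow(samples); x <- as.vector(samples)
  } else {
    nch <- 1L; x <- samples
  }
  x <- as.integer(round(pmax(-1, pmin(1, x)) * 32767))
  datlen <- length(x) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + datlen), con, 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(c(1L, nch), con, 2L, endian = "little")
  writeBin(as.integer(fs), con, 4L, endian = "little")
  writeBin(as.integer(fs * nch * 2L), con, 4L, endian = "little")
  writeBin(as.integer(c(nch * 2L, 16L)), con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(datlen, con, 4L, endian = "little")
  writeBin(x, con, 2L, endian = "little")
  invisible(path)
}

#' Read a phoneme alignment
#'
#' Reads either a Praat TextGrid (the first IntervalTier, or the tier named
#' by `tier`) or a delimited table with columns `phoneme`, `onset`,
#' `offset` in seconds. Empty-text intervals (silence) are dropped from
#' TextGrids.
#'
#' @param path path to a `.TextGrid` or `.tsv`/`.txt` file.
#' @param tier optional TextGrid tier name.
#' @return A tibble with columns `phoneme`, `onset`, `offset`.
#' @export
read_alignment <- function(path, tier = NULL) {
  if (grepl("\\.textgrid$", path, ignore.case = TRUE)) {
    return(read_textgrid(path, tier))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("phoneme", "onset", "offset") %in% names(tab))) {
    abort_bad_arg("alignment table needs columns phoneme, onset, offset.")
  }
  tibble::as_tibble(tab[c("phoneme", "onset", "offset")])
}

#' @rdname read_alignment
#' @param alignment tibble with `phoneme`, `onset`, `offset`.
#' @export
write_alignment <- function(alignment, path) {
  utils::write.table(alignment[c("phoneme", "onset", "offset")], path,
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_textgrid <- function(path, tier = NULL) {
  lines <- readLines(path, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  # split into item blocks; keep interval tiers only
  items <- strsplit(txt, "item\\s*\\[[0-9]+\\]\\s*:")[[1]][-1]
  if (length(items) == 0L) abort_bad_arg("no tiers found in TextGrid.")
  get_field <- function(block, key) {
    m <- regmatches(block, regexec(paste0(key, '\\s*=\\s*"([^"]*)"'), block))[[1]]
    if (length(m) < 2L) NA_character_ else m[2]
  }
  keep <- NULL
  for (it in items) {
    if (!grepl("IntervalTier", it)) next
    nm <- get_field(it, "name")
    if (is.null(tier) || identical(nm, tier)) { keep <- it; break }
  }
  if (is.null(keep)) abort_bad_arg("requested tier not found in TextGrid.")
  ints <- strsplit(keep, "intervals\\s*\\[[0-9]+\\]\\s*:")[[1]][-1]
  num <- function(block, key) {
    m <- regmatches(block,
      regexec(paste0(key, "\\s*=\\s*([0-9eE+.-]+)"), block))[[1]]
    if (length(m) < 2L) NA_real_ else as.numeric(m[2])
  }
  out <- tibble::tibble(
    phoneme = vapply(ints, get_field, character(1), key = "text",
      USE.NAMES = FALSE),
    onset = vapply(ints, num, numeric(1), key = "xmin", USE.NAMES = FALSE),
    offset = vapply(ints, num, numeric(1), key = "xmax", USE.NAMES = FALSE)
  )
  out <- out[!is.na(out$phoneme) & nzchar(trimws(out$phoneme)), ]
  out$phoneme <- trimws(out$phoneme)
  tibble::as_tibble(out, .name_repair = "minimal")
}
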