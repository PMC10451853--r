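## Recording and catalog I/O.
##
## The monitoring hardware this pipeline targets records mono WAV at 300 kHz
## with 16-bit resolution; every shape contract downstream (1025 x 586
## spectrograms, 586 MFCC frames) assumes that rate, so other sample rates are
## rejected outright instead of being resampled. WAV reading/writing is a
## small RIFF/PCM16 codec implemented here because no installed package
## provides one.

SAMPLE_RATE <- 300000L

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples numeric vector of amplitudes in \[-1, 1\] (values are clipped).
#' @param path output file path.
#' @param sample_rate_hz sample rate, default 300000.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate_hz = SAMPLE_RATE) {
  stopifnot(is.numeric(samples), length(samples) > 0)
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(sample_rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate_hz * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path WAV file path.
#' @return list with `samples` (numeric in \[-1, 1\]) and `sample_rate_hz`.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, "integer", size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    stop("not a RIFF/WAVE file: ", path)
  sample_rate <- NULL; n_channels <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      sample_rate <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 2, endian = "little")
      bits <- readBin(con, "integer", size = 2, endian = "little")
      n_channels <- fmt[2]
      if (size > 16) readBin(con, "raw", n = size - 16L)
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", n = size %/% 2L, size = 2,
                         endian = "little", signed = TRUE)
      break
    } else {
      readBin(con, "raw", n = size)
    }
  }
  if (is.null(samples)) stop("corrupt WAV (no data chunk): ", path)
  if (!identical(n_channels, 1L)) stop("only mono WAV is supported: ", path)
  if (!identical(bits, 16L)) stop("only 16-bit PCM is supported: ", path)
  list(samples = samples / 32767, sample_rate_hz = sample_rate)
}

#' Load a recording, enforcing the 300 kHz contract
#'
#' Reads a mono PCM16 WAV file and returns a `bat_recording`. A sample rate
#' other than 300 kHz is an error (no silent resampling: the spectrogram and
#' MFCC shape contracts assume 300 kHz). Metadata (class label, collection,
#' measurement height) is joined from `catalog` when given.
#'
#' @param path WAV file path.
#' @param catalog optional catalog data.frame (see [read_catalog()]); matched
#'   on `basename(file)`.
#' @return a `bat_recording`: list with `samples`, `sample_rate_hz`,
#'   `duration_s` and `meta`.
#' @export
load_recording <- function(path, catalog = NULL) {
  w <- read_wav(path)
  if (w$sample_rate_hz != SAMPLE_RATE)
    stop("sample rate ", w$sample_rate_hz, " Hz rejected; this pipeline ",
         "requires ", SAMPLE_RATE, " Hz recordings")
  meta <- list(class_label = NA_character_, collection = NA_character_,
               height_m = NA_real_)
  if (!is.null(catalog)) {
    i <- match(basename(path), basename(catalog$file))
    if (!is.na(i)) {
      meta$class_label <- catalog$class[i]
      meta$collection <- catalog$collection[i]
      meta$height_m <- catalog$height_m[i]
    }
  }
  new_recording(w$samples, meta = meta)
}

#' Construct a recording object in memory
#'
#' @param samples numeric amplitudes in \[-1, 1\].
#' @param meta list with any of `class_label`, `collection`, `height_m`.
#' @return a `bat_recording`.
#' @export
new_recording <- function(samples, meta = list()) {
  structure(
    list(samples = samples,
         sample_rate_hz = SAMPLE_RATE,
         duration_s = length(samples) / SAMPLE_RATE,
         meta = meta),
    class = "bat_recording")
}

#' @export
print.bat_recording <- function(x, ...) {
  cat(sprintf("<bat_recording> %.2f s @ %d Hz, class=%s collection=%s height=%s\n",
              x$duration_s, x$sample_rate_hz,
              x$meta$class_label %||% NA, x$meta$collection %||% NA,
              x$meta$height_m %||% NA))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a recording catalog
#'
#' A catalog is the manifest of a collection: one row per WAV file with its
#' class label, collection id (location-year), measurement height and
#' duration. An optional `split` column records train/val/test assignment.
#'
#' @param catalog data.frame with columns `file`, `class`, `collection`,
#'   `height_m`, `duration_s` (and optionally `split`).
#' @param path CSV path.
#' @return `write_catalog`: `path` invisibly; `read_catalog`: the data.frame.
#' @export
write_catalog <- function(catalog, path) {
  req <- c("file", "class", "collection", "height_m", "duration_s")
  miss <- setdiff(req, names(catalog))
  if (length(miss) > 0)
    stop("catalog is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(catalog$file))
    stop("catalog file paths must be unique")
  ok <- tryCatch({
    write.csv(catalog, path, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("catalog write failed: ", conditionMessage(ok))
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  cat_df <- read.csv(path, stringsAsFactors = FALSE)
  bad <- setdiff(unique(cat_df$class), bat_taxonomy()$label)
  if (length(bad) > 0)
    stop("catalog contains labels outside the taxonomy: ",
         paste(bad, collapse = ", "))
  cat_df
}
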