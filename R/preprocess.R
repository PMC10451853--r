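## Preprocessing: 1 s segments, spectrograms, MFCC matrices, dataset splits.
##
## The canonical analysis setting is an STFT with 2048-sample Hann windows
## (6.8 ms at 300 kHz), 75% overlap (hop 512) and centered, reflect-padded
## framing, which turns a 1 s segment into exactly 1 + floor(300000/512) = 586
## frames over 1025 linear frequency bins (0-150 kHz). MFCCs use the same hop
## with a 128-band mel filterbank and 20 kept coefficients, giving a 20 x 586
## matrix, ~98% smaller than the spectrogram.

#' Cut a recording into 1 s segments (recycling rule)
#'
#' Bat recordings are segmented over the first 80% of their length into
#' non-overlapping 1 s segments starting at t = 0; together with the
#' generator's interpulse-interval cap this guarantees at least one pulse per
#' segment (the trailing 20% is post-trigger tail). Noise recordings are
#' segmented over their full length.
#'
#' @param rec a `bat_recording`.
#' @param recording_id identifier propagated to the segments (used by splits
#'   to keep all segments of one recording in the same partition).
#' @return list of segments: each a list with `samples` (300,000 values),
#'   `offset_s`, `class_label`, `collection`, `height_m`, `recording_id`.
#' @export
recycle_segments <- function(rec, recording_id = "rec") {
  stopifnot(inherits(rec, "bat_recording"))
  is_noise <- identical(rec$meta$class_label, "noise")
  usable <- if (is_noise) rec$duration_s else 0.8 * rec$duration_s
  count <- floor(usable)
  if (count < 1) {
    warning("recording shorter than the minimum segmentable length; ",
            "zero segments produced")
    return(list())
  }
  lapply(seq_len(count) - 1L, function(k) {
    list(samples = rec$samples[k * SAMPLE_RATE + seq_len(SAMPLE_RATE)],
         offset_s = k,
         class_label = rec$meta$class_label %||% NA_character_,
         collection = rec$meta$collection %||% NA_character_,
         height_m = rec$meta$height_m %||% NA_real_,
         recording_id = recording_id)
  })
}

seg_samples <- function(x) {
  if (inherits(x, "bat_recording")) x$samples
  else if (is.list(x) && !is.null(x$samples)) x$samples
  else as.numeric(x)
}

#' Compute a normalized linear-frequency spectrogram
#'
#' Magnitude STFT with Hann window, centered reflect-padded framing, converted
#' to dB and min-max normalized per image to \[0, 1\]. With the defaults a 1 s
#' 300 kHz segment yields exactly 1025 x 586 (frequency x time). An all-zero
#' input returns an all-zero image (normalization guard).
#'
#' @param x a segment, `bat_recording`, or numeric sample vector.
#' @param n_fft FFT window size (default 2048).
#' @param hop hop between windows (default 512, i.e. 75% overlap).
#' @param normalize if `FALSE`, return the dB image without min-max scaling.
#' @return matrix (n_fft/2 + 1) x (1 + floor(n/hop)).
#' @export
compute_spectrogram <- function(x, n_fft = 2048L, hop = 512L, normalize = TRUE) {
  x <- seg_samples(x)
  n <- length(x)
  if (n < n_fft) stop("input shorter than one analysis window")
  half <- n_fft %/% 2L
  # centered framing: reflect-pad half a window on each side
  xp <- c(x[(half + 1L):2L], x, x[(n - 1L):(n - half)])
  n_frames <- 1L + n %/% hop
  idx <- outer(seq_len(n_fft), (seq_len(n_frames) - 1L) * hop, `+`)
  frames <- matrix(xp[idx], nrow = n_fft)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(n_fft) / n_fft))   # periodic Hann
  mag <- Mod(mvfft(frames * w))[seq_len(half + 1L), , drop = FALSE]
  db <- 20 * log10(pmax(mag, 1e-10))
  if (!normalize) return(db)
  rng <- range(db)
  if (rng[2] - rng[1] < 1e-12) return(db * 0)
  (db - rng[1]) / (rng[2] - rng[1])
}

mel_hz <- function(m) 700 * (10^(m / 2595) - 1)
hz_mel <- function(f) 2595 * log10(1 + f / 700)

mel_filterbank <- function(n_mels, n_fft, sr, fmin = 0, fmax = sr / 2) {
  n_bins <- n_fft %/% 2L + 1L
  freqs <- (seq_len(n_bins) - 1L) * sr / n_fft
  pts <- mel_hz(seq(hz_mel(fmin), hz_mel(fmax), length.out = n_mels + 2L))
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- pts[m]; ce <- pts[m + 1]; hi <- pts[m + 2]
    up <- (freqs - lo) / (ce - lo)
    down <- (hi - freqs) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Compute an MFCC matrix
#'
#' Mel-frequency cepstral coefficients on the same hop as the spectrogram:
#' power STFT -> mel filterbank -> dB -> orthonormal DCT-II, keeping the first
#' `n_mfcc` coefficients. With the defaults a 1 s segment yields 20 x 586,
#' ~98% fewer elements than the 1025 x 586 spectrogram.
#'
#' @inheritParams compute_spectrogram
#' @param n_mfcc number of coefficients kept (default 20).
#' @param n_mels mel filterbank size (default 128, spanning 0-150 kHz).
#' @return matrix n_mfcc x n_frames.
#' @export
compute_mfcc <- function(x, n_mfcc = 20L, n_mels = 128L, n_fft = 2048L,
                         hop = 512L) {
  x <- seg_samples(x)
  n <- length(x)
  half <- n_fft %/% 2L
  xp <- c(x[(half + 1L):2L], x, x[(n - 1L):(n - half)])
  n_frames <- 1L + n %/% hop
  idx <- outer(seq_len(n_fft), (seq_len(n_frames) - 1L) * hop, `+`)
  frames <- matrix(xp[idx], nrow = n_fft)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(n_fft) / n_fft))
  pow <- Mod(mvfft(frames * w))[seq_len(half + 1L), , drop = FALSE]^2
  melpow <- mel_filterbank(n_mels, n_fft, SAMPLE_RATE) %*% pow
  meldb <- 10 * log10(pmax(melpow, 1e-10))
  m <- seq_len(n_mels) - 0.5
  dct <- vapply(seq_len(n_mfcc) - 1L,
                function(k) cos(pi * k * m / n_mels), numeric(n_mels))
  dct <- t(dct) * sqrt(2 / n_mels)
  dct[1, ] <- dct[1, ] / sqrt(2)
  dct %*% meldb
}

#' Frequency of maximum spectral energy
#'
#' The peak frequency of a waveform, measured on the magnitude spectrum of
#' the whole signal. Frequencies below `fmin_khz` are ignored so the noise
#' floor's DC/low-frequency content cannot win.
#'
#' @param x numeric samples, segment or `bat_recording`.
#' @param fmin_khz lower bound of the search range in kHz.
#' @return peak frequency in kHz.
#' @export
peak_frequency <- function(x, fmin_khz = 5) {
  x <- seg_samples(x)
  n <- length(x)
  mag <- Mod(fft(x))[seq_len(n %/% 2L)]
  freqs <- (seq_len(n %/% 2L) - 1) * (SAMPLE_RATE / n)
  keep <- freqs >= fmin_khz * 1000
  freqs[keep][which.max(mag[keep])] / 1000
}

#' Stratified train/val/test split at recording granularity
#'
#' Each class is sampled individually so the three partitions preserve the
#' class imbalance (60:20:20 by default, largest-remainder rounding within a
#' class). The split is assigned per recording, so recycled segments of one
#' recording can never straddle partitions. Classes with fewer than 5
#' recordings are flagged with a warning (they still get a best-effort split).
#'
#' @param catalog catalog data.frame (one row per recording).
#' @param ratios train/val/test proportions summing to 1.
#' @param seed RNG seed.
#' @return the catalog with a `split` column (`"train"`, `"val"`, `"test"`).
#' @export
stratified_split <- function(catalog, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  if (abs(sum(ratios) - 1) > 1e-8) stop("split ratios must sum to 1")
  if (any(ratios < 0)) stop("split ratios must be non-negative")
  set.seed(seed)
  catalog$split <- NA_character_
  parts <- c("train", "val", "test")
  for (cls in sort(unique(catalog$class))) {
    rows <- which(catalog$class == cls)
    n <- length(rows)
    if (n < 5)
      warning("class ", cls, " has only ", n,
              " recordings; split is unreliable (rare class)")
    x <- ratios * n
    cnt <- floor(x)
    rem <- as.integer(n - sum(cnt))
    if (rem > 0) {
      ord <- order(x - cnt, decreasing = TRUE)
      cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
    }
    shuffled <- sample(rows)
    catalog$split[shuffled] <- rep(parts, times = cnt)
  }
  catalog
}

#' Segment a set of recordings and compute features
#'
#' Convenience wrapper used by the experiment harnesses: recycles every
#' recording into 1 s segments and computes the requested feature per segment.
#'
#' @param recordings list of `bat_recording`s.
#' @param type `"mfcc"` or `"spectrogram"`.
#' @param ids optional recording identifiers (default `rec1`, `rec2`, ...).
#' @param ... passed to [compute_mfcc()] / [compute_spectrogram()].
#' @return list with `features` (list of matrices), `labels`, `recording_id`,
#'   `collection`, `height_m` vectors.
#' @export
segment_features <- function(recordings, type = c("mfcc", "spectrogram"),
                             ids = NULL, ...) {
  type <- match.arg(type)
  if (is.null(ids)) ids <- paste0("rec", seq_along(recordings))
  segs <- list(); labels <- c(); rid <- c(); coll <- c(); hgt <- c()
  for (i in seq_along(recordings)) {
    for (s in recycle_segments(recordings[[i]], ids[i])) {
      f <- if (type == "mfcc") compute_mfcc(s$samples, ...)
           else compute_spectrogram(s$samples, ...)
      segs[[length(segs) + 1L]] <- f
      labels <- c(labels, s$class_label)
      rid <- c(rid, s$recording_id)
      coll <- c(coll, s$collection)
      hgt <- c(hgt, s$height_m)
    }
  }
  list(features = segs, labels = labels, recording_id = rid,
       collection = coll, height_m = hgt)
}
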