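## Synthetic ultrasonic-soundscape generator.
##
## Field recordings of bat echolocation from monitoring masts are typically
## access-restricted, so the package ships a generator that emulates the
## statistical structure the pipeline assumes: frequency-modulated
## echolocation pulse trains whose frequency of maximum energy falls in the
## class's diagnostic band, interpulse intervals giving several pulses per
## second, and the two observed noise regimes (stationary: persistent
## narrowband tones and periodic click trains that mimic pulse trains;
## non-stationary: broadband transients at Poisson times), with
## per-collection noise mixtures and class imbalance.
##
## Pulse model: a two-part FM down-sweep. A steep low-amplitude initial sweep
## (peak + 30 kHz down to peak + ~3 kHz) is followed by a shallow terminal
## sweep through the peak frequency under a Hann amplitude envelope, so the
## measured frequency of maximum spectral energy lands at the sampled peak
## frequency. The peak is drawn per pulse from the class band with a small
## interior margin.

NOISE_FLOOR_SD <- 0.005

#' Pulse parameters for a bat class
#'
#' @param class_label a bat class label from [bat_taxonomy()].
#' @param peak_band_khz peak-frequency band c(lo, hi) in kHz; defaults to the
#'   class's taxonomy band.
#' @param pulse_dur_ms pulse duration in ms.
#' @param ipi_ms interpulse interval in ms (must be >= `pulse_dur_ms`).
#' @param snr_db pulse peak amplitude over the noise floor, in dB.
#' @return a validated `pulse_params` list.
#' @export
pulse_params <- function(class_label, peak_band_khz = NULL, pulse_dur_ms = 5,
                         ipi_ms = 100, snr_db = 30) {
  if (is.null(peak_band_khz)) peak_band_khz <- peak_band(class_label)
  lo <- peak_band_khz[1]; hi <- peak_band_khz[2]
  if (!(lo < hi)) stop("peak band must satisfy lo < hi")
  if (lo <= 0 || hi >= SAMPLE_RATE / 2000)
    stop("peak band must lie inside (0, ", SAMPLE_RATE / 2000, ") kHz (Nyquist)")
  if (pulse_dur_ms <= 0) stop("pulse_dur_ms must be > 0")
  if (ipi_ms < pulse_dur_ms) stop("ipi_ms must be >= pulse_dur_ms")
  if (!is.finite(snr_db)) stop("snr_db must be finite")
  structure(list(class_label = class_label, peak_band_khz = c(lo, hi),
                 pulse_dur_ms = pulse_dur_ms, ipi_ms = ipi_ms,
                 snr_db = snr_db),
            class = "pulse_params")
}

#' Synthesize one echolocation pulse
#'
#' Draws the peak frequency from the class band (with a 20% interior margin,
#' at most 1 kHz) and returns the waveform of a single FM down-sweep whose
#' frequency of maximum spectral energy lies at that peak. Uses the current
#' RNG stream; seed with `set.seed()` for reproducibility.
#'
#' @param params a `pulse_params` object.
#' @return numeric waveform of length `pulse_dur_ms` ms at 300 kHz.
#' @export
synth_pulse <- function(params) {
  stopifnot(inherits(params, "pulse_params"))
  band <- params$peak_band_khz
  margin <- min(1, 0.2 * diff(band))
  f_peak <- runif(1, band[1] + margin, band[2] - margin) * 1000
  n <- round(params$pulse_dur_ms / 1000 * SAMPLE_RATE)
  u <- seq(0, 1, length.out = n)
  n1 <- round(0.3 * n)
  slope <- 2 * min(3, diff(band)) * 1000    # shallow terminal sweep, Hz
  f_hi <- min(f_peak + 30000, SAMPLE_RATE / 2 - 10000)
  # shallow sweep passes through f_peak exactly where the Hann envelope
  # peaks (u = 0.5), so the measured peak energy lands on f_peak
  f2 <- f_peak + slope * (0.5 - u[(n1 + 1):n])
  f1 <- f_hi + (f2[1] - f_hi) * (seq_len(n1) / n1)^0.7
  f_inst <- c(f1, f2)
  phase <- 2 * pi * cumsum(f_inst) / SAMPLE_RATE
  env <- 0.5 * (1 - cos(2 * pi * u))        # Hann amplitude envelope
  env[seq_len(n1)] <- env[seq_len(n1)] * 0.35
  amp <- NOISE_FLOOR_SD * 10^(params$snr_db / 20)
  amp * env * sin(phase)
}

#' Synthesize a recording containing a pulse train
#'
#' Places pulses of the given class at (jittered) interpulse intervals over a
#' white Gaussian noise floor. The effective interval is capped at 1000 ms so
#' that every 1 s window contains at least one pulse, which is what the 80%
#' segment-recycling rule downstream relies on.
#'
#' @param class_label bat class label.
#' @param duration_s recording duration in seconds, between 1 and 16.
#' @param ipi_ms nominal interpulse interval in ms (> 1000 is rejected).
#' @param ipi_jitter uniform jitter fraction applied to each interval.
#' @param floor_sd standard deviation of the Gaussian noise floor.
#' @param ... further arguments passed to [pulse_params()].
#' @return a `bat_recording`.
#' @export
synth_pulse_train <- function(class_label, duration_s, ipi_ms = 100,
                              ipi_jitter = 0.2, floor_sd = NOISE_FLOOR_SD, ...) {
  if (duration_s < 1 || duration_s > 16)
    stop("duration_s must be between 1 and 16 s")
  if (ipi_ms > 1000)
    stop("ipi_ms > 1000 ms would break the one-pulse-per-second guarantee")
  params <- pulse_params(class_label, ipi_ms = ipi_ms, ...)
  n <- round(duration_s * SAMPLE_RATE)
  x <- rnorm(n, sd = floor_sd)
  t_s <- runif(1, 0.002, 0.010)
  while (TRUE) {
    p <- synth_pulse(params)
    i0 <- round(t_s * SAMPLE_RATE)
    if (i0 + length(p) > n) break
    x[i0 + seq_along(p)] <- x[i0 + seq_along(p)] + p
    step <- min(ipi_ms * (1 + runif(1, -ipi_jitter, ipi_jitter)), 1000)
    t_s <- t_s + step / 1000
  }
  new_recording(pmax(-1, pmin(1, x)), meta = list(class_label = class_label))
}

#' Noise profile
#'
#' Three kinds of interference are emulated. `stationary_tonal`: a persistent
#' narrowband tone (slow amplitude and frequency drift) such as the ~30 kHz
#' signal common in field recordings. `stationary_pulsed`: a periodic train of
#' short broadband clicks that visually mimics a bat pulse train.
#' `nonstationary_broadband`: broadband transients at Poisson times.
#'
#' @param kind one of `"stationary_tonal"`, `"stationary_pulsed"`,
#'   `"nonstationary_broadband"`.
#' @param center_khz tone center frequency (tonal kind only).
#' @param width_khz tone drift width (tonal kind only).
#' @param click_rate_hz click rate (pulsed kind only).
#' @param transient_rate_hz expected transients per second (broadband kind only).
#' @param level_db level over the noise floor, in dB.
#' @return a validated `noise_profile` list.
#' @export
noise_profile <- function(kind, center_khz = 30, width_khz = 1,
                          click_rate_hz = 10, transient_rate_hz = 2,
                          level_db = 25) {
  kinds <- c("stationary_tonal", "stationary_pulsed", "nonstationary_broadband")
  if (!kind %in% kinds)
    stop("kind must be one of: ", paste(kinds, collapse = ", "))
  if (!is.finite(level_db)) stop("level_db must be finite")
  p <- list(kind = kind, level_db = level_db)
  if (kind == "stationary_tonal") {
    if (center_khz <= 0 || center_khz >= SAMPLE_RATE / 2000)
      stop("center_khz outside (0, Nyquist)")
    p$center_khz <- center_khz; p$width_khz <- width_khz
  } else if (kind == "stationary_pulsed") {
    if (!is.finite(click_rate_hz) || click_rate_hz <= 0)
      stop("click_rate_hz must be positive and finite")
    p$click_rate_hz <- click_rate_hz
  } else {
    if (!is.finite(transient_rate_hz) || transient_rate_hz < 0)
      stop("transient_rate_hz must be >= 0 and finite")
    p$transient_rate_hz <- transient_rate_hz
  }
  structure(p, class = "noise_profile")
}

#' Synthesize a noise recording
#'
#' @param profile a `noise_profile`.
#' @param duration_s duration in seconds (>= 1).
#' @param floor_sd standard deviation of the Gaussian noise floor.
#' @return a `bat_recording` with class label `"noise"`.
#' @export
synth_noise <- function(profile, duration_s, floor_sd = NOISE_FLOOR_SD) {
  stopifnot(inherits(profile, "noise_profile"))
  if (duration_s < 1) stop("noise recordings must be at least 1 s")
  n <- round(duration_s * SAMPLE_RATE)
  x <- rnorm(n, sd = floor_sd)
  amp <- floor_sd * 10^(profile$level_db / 20)
  if (profile$kind == "stationary_tonal") {
    # slow FM drift within +- width and slow AM, both on a ~20 Hz time scale
    k <- max(2, ceiling(duration_s * 20))
    drift <- stats::approx(seq(0, 1, length.out = k),
                           runif(k, -1, 1), xout = seq(0, 1, length.out = n))$y
    am <- stats::approx(seq(0, 1, length.out = k),
                        runif(k, 0.6, 1), xout = seq(0, 1, length.out = n))$y
    f_inst <- (profile$center_khz + profile$width_khz * drift) * 1000
    x <- x + amp * am * sin(2 * pi * cumsum(f_inst) / SAMPLE_RATE)
  } else if (profile$kind == "stationary_pulsed") {
    period <- 1 / profile$click_rate_hz
    click_n <- round(0.001 * SAMPLE_RATE)
    env <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = click_n)))
    t_s <- runif(1, 0, 0.5 * period)
    while (round(t_s * SAMPLE_RATE) + click_n < n) {
      i0 <- round(t_s * SAMPLE_RATE)
      x[i0 + seq_len(click_n)] <- x[i0 + seq_len(click_n)] +
        amp * env * rnorm(click_n)
      t_s <- t_s + period * (1 + runif(1, -0.05, 0.05))
    }
  } else {
    n_ev <- rpois(1, profile$transient_rate_hz * duration_s)
    ev_n <- round(0.005 * SAMPLE_RATE)
    env <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = ev_n)))
    if (n_ev > 0) {
      starts <- sort(runif(n_ev, 0, max(duration_s - 0.005, 0)))
      for (t_s in starts) {
        i0 <- round(t_s * SAMPLE_RATE)
        x[i0 + seq_len(ev_n)] <- x[i0 + seq_len(ev_n)] +
          amp * runif(1, 0.5, 1) * env * rnorm(ev_n)
      }
    }
  }
  new_recording(pmax(-1, pmin(1, x)), meta = list(class_label = "noise"))
}

#' Default noise profiles
#'
#' A small palette used by collection configs: a ~30 kHz tone, a 10 Hz click
#' train and 2/s broadband transients.
#' @return named list of `noise_profile`s.
#' @export
default_noise_profiles <- function() {
  list(tonal = noise_profile("stationary_tonal", center_khz = 30),
       pulsed = noise_profile("stationary_pulsed", click_rate_hz = 10),
       broadband = noise_profile("nonstationary_broadband", transient_rate_hz = 2))
}

#' Collection configuration
#'
#' A collection is a location-year unit of the monitoring design. Its class
#' mix fixes per-class recording counts (imbalance included); its noise mix
#' weights the noise profiles, either globally or per measurement height (a
#' named list keyed by height), which lets collections and heights carry
#' distinct noise structure.
#'
#' @param collection_id e.g. `"east_2019"`.
#' @param class_mix named integer vector of per-class recording counts.
#' @param noise_mix numeric weights over `noise_profiles` (must sum to 1), or
#'   a named list of such weight vectors keyed by height (`"10"`, `"35"`, ...).
#' @param heights_m subset of c(10, 35, 65, 95).
#' @param seed RNG seed; a fixed seed makes [synth_collection()] byte-identical.
#' @param noise_profiles named list of `noise_profile`s.
#' @param bat_dur_range,noise_dur_range duration ranges in seconds.
#' @return a validated `collection_config`.
#' @export
collection_config <- function(collection_id, class_mix, noise_mix = NULL,
                              heights_m = c(10, 35, 65, 95), seed = 1L,
                              noise_profiles = default_noise_profiles(),
                              bat_dur_range = c(2, 16),
                              noise_dur_range = c(1, 4)) {
  if (any(class_mix < 0)) stop("class counts must be >= 0")
  bad <- setdiff(names(class_mix), bat_taxonomy()$label)
  if (length(bad) > 0) stop("unknown class(es) in class_mix: ",
                            paste(bad, collapse = ", "))
  if (!all(heights_m %in% c(10, 35, 65, 95)))
    stop("heights_m must be a subset of {10, 35, 65, 95}")
  if (is.null(noise_mix))
    noise_mix <- rep(1 / length(noise_profiles), length(noise_profiles))
  check_w <- function(w) {
    if (abs(sum(w) - 1) > 1e-8) stop("noise weights must sum to 1")
    if (length(w) != length(noise_profiles))
      stop("noise weights must match noise_profiles")
  }
  if (is.list(noise_mix)) lapply(noise_mix, check_w) else check_w(noise_mix)
  structure(list(collection_id = collection_id, class_mix = class_mix,
                 noise_mix = noise_mix, heights_m = heights_m,
                 seed = as.integer(seed), noise_profiles = noise_profiles,
                 bat_dur_range = bat_dur_range,
                 noise_dur_range = noise_dur_range),
            class = "collection_config")
}

# Generate the recordings of a collection in memory. Returns list(recordings,
# catalog) where catalog rows carry file names that synth_collection() uses
# when writing WAVs.
synth_recordings <- function(config) {
  set.seed(config$seed)
  recs <- list(); rows <- list(); k <- 0
  for (cls in names(config$class_mix)) {
    cnt <- config$class_mix[[cls]]
    if (cnt == 0) next
    for (i in seq_len(cnt)) {
      k <- k + 1
      height <- sample(config$heights_m, 1)
      if (cls == "noise") {
        dur <- runif(1, config$noise_dur_range[1], config$noise_dur_range[2])
        w <- if (is.list(config$noise_mix))
          config$noise_mix[[as.character(height)]] else config$noise_mix
        prof <- config$noise_profiles[[
          sample(length(config$noise_profiles), 1, prob = w)]]
        rec <- synth_noise(prof, dur)
      } else {
        dur <- runif(1, config$bat_dur_range[1], config$bat_dur_range[2])
        rec <- synth_pulse_train(cls, dur)
      }
      rec$meta$collection <- config$collection_id
      rec$meta$height_m <- height
      recs[[k]] <- rec
      rows[[k]] <- data.frame(
        file = sprintf("%s_%s_%04d.wav", config$collection_id, cls, i),
        class = cls, collection = config$collection_id, height_m = height,
        duration_s = rec$duration_s, stringsAsFactors = FALSE)
    }
  }
  list(recordings = recs, catalog = do.call(rbind, rows))
}

#' Synthesize a collection of WAV files plus catalog
#'
#' Writes one WAV per recording into `out_dir` together with `catalog.csv`.
#' Per-class counts match `class_mix` exactly; a fixed seed reproduces the
#' files byte for byte.
#'
#' @param config a `collection_config`.
#' @param out_dir output directory (created if needed).
#' @return the catalog data.frame, invisibly.
#' @export
synth_collection <- function(config, out_dir) {
  stopifnot(inherits(config, "collection_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- synth_recordings(config)
  gen$catalog$file <- file.path(out_dir, gen$catalog$file)
  for (i in seq_along(gen$recordings))
    write_wav(gen$recordings[[i]]$samples, gen$catalog$file[i])
  write_catalog(gen$catalog, file.path(out_dir, "catalog.csv"))
  invisible(gen$catalog)
}

#' Scale a class mix preserving imbalance (largest-remainder rounding)
#'
#' Scales per-class counts by `factor` and rounds so the total equals
#' `round(sum(counts) * factor)`: floors are taken first and remaining units
#' go to the classes with the largest fractional remainders (ties broken by
#' original order).
#'
#' @param counts named numeric vector of per-class counts.
#' @param factor positive scale factor.
#' @return named integer vector.
#' @export
#' @examples
#' scale_class_mix(c(P_pip = 17761, P_nat = 723), 1 / 100)
scale_class_mix <- function(counts, factor) {
  if (factor <= 0) stop("factor must be positive")
  x <- counts * factor
  fl <- floor(x)
  target <- round(sum(counts) * factor)
  extra <- as.integer(target - sum(fl))
  out <- fl
  if (extra > 0) {
    ord <- order(x - fl, decreasing = TRUE)
    out[ord[seq_len(extra)]] <- out[ord[seq_len(extra)]] + 1
  }
  stats::setNames(as.integer(out), names(counts))
}
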