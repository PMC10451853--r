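# Oracle used below: pulse/click counting by thresholding the per-millisecond
# amplitude envelope, independent of how the generator places pulses.
count_events <- function(x, thr = 5 * 0.005) {
  n_bins <- length(x) %/% 300L
  env <- vapply(seq_len(n_bins), function(b)
    max(abs(x[(b - 1L) * 300L + 1:300])), numeric(1))
  r <- rle(env > thr)
  sum(r$values)
}

test_that("pulse parameters are validated", {
  expect_error(pulse_params("P_pip", peak_band_khz = c(50, 42)), "lo < hi")
  expect_error(pulse_params("P_pip", peak_band_khz = c(140, 160)), "Nyquist")
  expect_error(pulse_params("P_pip", pulse_dur_ms = 0), "pulse_dur_ms")
  expect_error(pulse_params("P_pip", ipi_ms = 2, pulse_dur_ms = 5), "ipi_ms")
  expect_error(pulse_params("P_pip", snr_db = -Inf), "finite")
})

test_that("pulse peak energy lands in the class band (spectral validity)", {
  set.seed(11)
  for (cls in c("P_pip", "P_nat", "N_noc")) {
    band <- peak_band(cls)
    pk <- replicate(40, peak_frequency(synth_pulse(pulse_params(cls))))
    expect_true(all(pk >= band[1] & pk <= band[2]),
                info = paste(cls, "peaks in", min(pk), "-", max(pk)))
  }
})

test_that("pulses and pulse trains are deterministic under a fixed seed", {
  p <- pulse_params("P_pip")
  set.seed(123); a <- synth_pulse(p)
  set.seed(123); b <- synth_pulse(p)
  expect_identical(a, b)
  set.seed(99); r1 <- synth_pulse_train("P_nat", 2)
  set.seed(99); r2 <- synth_pulse_train("P_nat", 2)
  expect_identical(r1$samples, r2$samples)
})

test_that("pulse trains respect the interpulse interval", {
  set.seed(21)
  r <- synth_pulse_train("P_pip", 2, ipi_ms = 100)
  n <- count_events(r$samples)
  expect_gte(n, 16)   # ~20 expected at 100 ms IPI with +-20% jitter
  expect_lte(n, 24)
  r1 <- synth_pulse_train("P_pip", 1, ipi_ms = 1000)
  expect_equal(count_events(r1$samples), 1)
  expect_error(synth_pulse_train("P_pip", 2, ipi_ms = 1500), "1000 ms")
  expect_error(synth_pulse_train("P_pip", 0.5), "between 1 and 16")
  # every 1 s window of the first 80% contains at least one pulse
  set.seed(22)
  r3 <- synth_pulse_train("N_noc", 5, ipi_ms = 700)
  for (k in 0:3)
    expect_gte(count_events(r3$samples[k * 300000 + 1:300000]), 1)
})

test_that("pulse train peak energies stay in band within a recording", {
  set.seed(31)
  r <- synth_pulse_train("P_nat", 3)
  pk <- peak_frequency(r)
  expect_gte(pk, 35); expect_lte(pk, 40)
})

test_that("noise kinds produce their characteristic structure", {
  set.seed(41)
  # tonal: dominant spectral ridge at the center frequency in every frame
  r <- synth_noise(noise_profile("stationary_tonal", center_khz = 30), 1)
  S <- compute_spectrogram(r$samples)
  ridge_khz <- (apply(S, 2, which.max) - 1) * (300 / 2048)
  expect_true(all(abs(ridge_khz - 30) < 2.5))
  # pulsed: ~30 clicks at 10 Hz over 3 s
  r2 <- synth_noise(noise_profile("stationary_pulsed", click_rate_hz = 10), 3)
  n <- count_events(r2$samples)
  expect_gte(n, 26); expect_lte(n, 34)
  # zero-rate broadband: floor only
  r3 <- synth_noise(noise_profile("nonstationary_broadband",
                                  transient_rate_hz = 0), 1)
  expect_lte(max(abs(r3$samples)), 6 * 0.005)
  expect_error(noise_profile("purple"), "kind must be")
  expect_error(noise_profile("stationary_pulsed", click_rate_hz = 0),
               "click_rate_hz")
})

test_that("collections conserve class counts and are reproducible", {
  cfg <- collection_config(
    "east_2019", class_mix = c(P_pip = 4, noise = 4),
    seed = 7, bat_dur_range = c(1.3, 2), noise_dur_range = c(1, 1.5))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cat1 <- synth_collection(cfg, d1)
  cat2 <- synth_collection(cfg, d2)
  expect_equal(nrow(cat1), 8)
  expect_equal(as.vector(table(cat1$class)), c(4, 4))
  expect_equal(cat1$duration_s, cat2$duration_s)
  h1 <- unname(tools::md5sum(sort(list.files(d1, "\\.wav$", full.names = TRUE))))
  h2 <- unname(tools::md5sum(sort(list.files(d2, "\\.wav$", full.names = TRUE))))
  expect_identical(h1, h2)   # byte-identical output under a fixed seed
})

test_that("class-mix scaling uses largest-remainder rounding", {
  expect_equal(scale_class_mix(c(P_pip = 17761, P_nat = 723), 1 / 100),
               c(P_pip = 178L, P_nat = 7L))
  set.seed(5)
  for (i in 1:10) {
    counts <- stats::setNames(sample(1000, 4), letters[1:4])
    f <- runif(1, 0.01, 0.5)
    out <- scale_class_mix(counts, f)
    expect_equal(sum(out), round(sum(counts) * f))
    expect_true(all(abs(out - counts * f) <= 1))
  }
})
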