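test_that("encoder bottleneck honors its shape contract", {
  ae <- build_autoencoder(seed = 1)
  set.seed(2)
  S <- matrix(runif(1025 * 586), 1025, 586)
  lat <- encode(ae, S)
  expect_equal(dim(lat), c(129L, 74L, 8L))
  v <- latent_vector(lat)
  expect_length(v, 76368L)
  # ~87% element reduction relative to the spectrogram
  expect_equal(round(100 * (1 - 76368 / (1025 * 586)), 1), 87.3)
  expect_error(encode(ae, array(0, c(4, 4, 2))), "single-channel")
})

test_that("builds and inference are deterministic under seeds", {
  a <- build_autoencoder(seed = 9)
  b <- build_autoencoder(seed = 9)
  expect_identical(a$layers, b$layers)
  set.seed(1)
  S <- matrix(runif(129 * 74), 129, 74)
  expect_identical(encode(a, S), encode(a, S))
  r <- ae_reconstruct(a, S)
  expect_equal(dim(r), dim(S))
  expect_true(all(is.finite(encode(a, S * 0))))   # degenerate input
})

test_that("training reduces reconstruction loss with a full-length history", {
  set.seed(12)
  imgs <- lapply(1:6, function(i) {
    r <- synth_noise(noise_profile("stationary_tonal"), 1)
    do.call(compute_spectrogram, c(list(r$samples), FA_SPEC_FAST))
  })
  tr <- train_autoencoder(build_autoencoder(seed = 3), imgs,
                          ae_config(epochs = 3, seed = 3))
  expect_length(tr$history, 3)
  expect_lt(tr$history[3], tr$history[1])
  expect_error(train_autoencoder(build_autoencoder(seed = 1), imgs[1]),
               "at least 2")
})

test_that("ae_config defaults follow the reference optimizer settings", {
  cfg <- ae_config()
  expect_equal(cfg$learning_rate, 1e-4)
  expect_equal(cfg$batch_size, 1L)
  expect_equal(cfg$epochs, 10L)
})

test_that("PSNR follows its closed form with an Inf sentinel", {
  A <- matrix(0, 10, 10)
  B <- matrix(0.1, 10, 10)          # MSE = 0.01
  expect_equal(psnr(A, B), 20)
  expect_identical(psnr(A, A), Inf)
  # the formula inverts: MSE 10^(-2.8448) gives 28.448 dB
  C <- matrix(sqrt(10^(-2.8448)), 10, 10)
  expect_equal(psnr(A, C), 28.448, tolerance = 1e-6)
  expect_error(psnr(A, matrix(0, 5, 5)), "shape mismatch")
})

test_that("SSIM matches the reference implementation and its ideal cases", {
  expect_equal(ssim(matrix(0.4, 9, 9), matrix(0.4, 9, 9)), 1)
  set.seed(7)
  A <- matrix(runif(40 * 30), 40, 30)
  B <- A
  for (i in 2:39) for (j in 2:29) B[i, j] <- mean(A[(i - 1):(i + 1),
                                                    (j - 1):(j + 1)])
  expect_equal(ssim(A, A), 1)
  # frozen reference value from scikit-image structural_similarity
  # (win 7, uniform windows, data_range 1) on this exact fixture
  expect_equal(ssim(A, B), 0.2235767360, tolerance = 1e-9)
  # blurring depresses structural similarity far more than pixel error:
  # the blurred copy keeps a decent PSNR but loses most of its SSIM
  expect_gt(psnr(A, B), 10)
  expect_lt(ssim(A, B), 0.5)
  expect_error(ssim(A, matrix(0, 5, 5)), "shape mismatch")
})

test_that("reconstruction preserves the dominant frequency ridge", {
  # memorization limit: trained on one idealized tonal spectrogram (bright
  # narrowband ridge over a dim background), the per-frame argmax of the
  # reconstruction must stay within 2 bins of the input ridge. The learning
  # rate is raised for this tiny two-image set so memorization happens within
  # a short epoch budget; optimizer defaults are untouched elsewhere.
  set.seed(15)
  H <- 129; W <- 74; centre <- 30
  bg <- matrix(runif(H * W, 0.05, 0.2), H, W)
  prof <- exp(-0.5 * ((seq_len(H) - centre) / 1.5)^2)
  img <- bg + outer(prof, runif(W, 0.85, 1)); img[img > 1] <- 1
  tr <- train_autoencoder(build_autoencoder(seed = 2), list(img, img),
                          ae_config(learning_rate = 3e-3, epochs = 40,
                                    seed = 2))
  expect_lt(tr$history[40], tr$history[1] / 20)  # memorized
  R <- ae_reconstruct(tr$model, img)
  dev <- abs(apply(R, 2, which.max) - apply(img, 2, which.max))
  expect_lte(stats::median(dev), 2)
  expect_gte(mean(dev <= 2), 0.85)
})
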