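test_that("classifier contracts: shapes, score range, tie-break, K check", {
  expect_error(build_classifier(1), "K must be >= 2")
  m <- build_classifier(2, classes = c("bat", "noise"))
  expect_equal(m$input_shape, c(20L, 586L))
  # pooling chain 20x586 -> 10x293 -> 5x146 -> 2x73, flattened at 32 channels
  expect_equal(chirpnet:::clf_flat_dim(c(20L, 586L)), 32L * 2L * 73L)
  set.seed(1)
  x <- matrix(runif(20 * 586), 20, 586)
  pr <- clf_predict(m, x)
  expect_equal(dim(pr$scores), c(1L, 2L))
  expect_true(all(pr$scores > 0 & pr$scores < 1))
  m4 <- build_classifier(4, input_shape = c(20L, 147L))
  pr4 <- clf_predict(m4, matrix(runif(20 * 147), 20, 147))
  expect_equal(ncol(pr4$scores), 4L)
  # deterministic, order-preserving batch prediction
  xs <- lapply(1:3, function(i) matrix(runif(20 * 586), 20, 586))
  p1 <- clf_predict(m, xs); p2 <- clf_predict(m, xs)
  expect_identical(p1, p2)
  expect_equal(p1$scores[2, ], clf_predict(m, xs[[2]])$scores[1, ])
  # equal scores resolve to the lowest class index
  mz <- m
  mz$layers[[16]]$W[] <- 0; mz$layers[[16]]$b[] <- 0
  expect_equal(clf_predict(mz, x)$labels, "bat")
})

test_that("clf_config defaults mirror the reference task settings", {
  expect_equal(clf_config("batnoise")$epochs, 10L)
  expect_equal(clf_config("genus")$epochs, 50L)
  expect_equal(clf_config("species")$epochs, 25L)
  cfg <- clf_config("genus")
  expect_equal(cfg$learning_rate, 1e-4)
  expect_equal(cfg$batch_size, 32L)
  expect_equal(cfg$runs, 5L)
})

test_that("training validates labels and reproduces runs under seeds", {
  sf <- make_mfcc_corpus(c("P_pip", "N_noc"), 6, seed = 20)
  shape <- dim(sf$features[[1]])
  m <- build_classifier(3, classes = c("N_noc", "P_pip", "noise"),
                        input_shape = shape)
  expect_error(train_classifier(m, sf$features, sf$labels,
                                clf_config("species", epochs = 1)),
               "absent from training labels: noise")
  cfg <- clf_config("species", epochs = 1, runs = 2, seed = 5)
  r1 <- train_classifier_runs(sf$features, sf$labels, config = cfg)
  r2 <- train_classifier_runs(sf$features, sf$labels, config = cfg)
  expect_length(r1, 2)
  expect_identical(r1[[1]]$model$layers, r2[[1]]$model$layers)
  expect_false(identical(r1[[1]]$model$layers, r1[[2]]$model$layers))
})

test_that("the architecture overfits a small separable set (capacity)", {
  sf <- make_mfcc_corpus(c("P_pip", "N_noc", "noise"), 9, seed = 30)
  tr <- train_classifier(
    build_classifier(3, classes = sort(unique(sf$labels)),
                     input_shape = dim(sf$features[[1]]), seed = 1),
    sf$features, sf$labels, clf_config("species", epochs = 18, seed = 1))
  pr <- clf_predict(tr$model, sf$features)
  cm <- confusion(sf$labels, pr$labels, tr$model$classes)
  f1 <- f1_from_confusion(cm)$f1
  expect_true(all(f1 > 0.9))
  expect_lt(tr$history[length(tr$history)], tr$history[1] / 3)
})

test_that("the model keys on frequency content: band swap flips predictions", {
  set.seed(44)
  low_band <- c(25, 31); high_band <- c(55, 61)
  mk <- function(band, n) lapply(seq_len(n), function(i)
    synth_pulse_train("P_pip", 1.3, peak_band_khz = band))
  recs <- c(mk(low_band, 10), mk(high_band, 10))
  labs <- rep(c("low", "high"), each = 10)
  feats <- lapply(recs, function(r)
    do.call(compute_mfcc, c(list(r$samples), FA_MFCC_FAST)))
  tr <- train_classifier(
    build_classifier(2, classes = c("high", "low"),
                     input_shape = dim(feats[[1]]), seed = 2),
    feats, labs, clf_config("species", epochs = 12, seed = 2))
  # fresh recordings with the two bands swapped between the labels
  swapped <- c(mk(high_band, 5), mk(low_band, 5))
  sw_feats <- lapply(swapped, function(r)
    do.call(compute_mfcc, c(list(r$samples), FA_MFCC_FAST)))
  pred <- clf_predict(tr$model, sw_feats)$labels
  expect_gte(mean(pred == rep(c("high", "low"), each = 5)), 0.8)
})

test_that("decreasing band overlap raises downstream 2-class F1", {
  set.seed(55)
  run_f1_for_bands <- function(band_b) {
    mk <- function(band, n) lapply(seq_len(n), function(i)
      synth_pulse_train("P_pip", 1.3, peak_band_khz = band))
    recs <- c(mk(c(38, 44), 24), mk(band_b, 24))
    labs <- rep(c("A", "B"), each = 24)
    feats <- lapply(recs, function(r)
      do.call(compute_mfcc, c(list(r$samples), FA_MFCC_FAST)))
    tr_ix <- c(1:16, 25:40)
    te_ix <- setdiff(seq_along(labs), tr_ix)
    tr <- train_classifier(
      build_classifier(2, classes = c("A", "B"),
                       input_shape = dim(feats[[1]]), seed = 3),
      feats[tr_ix], labs[tr_ix],
      clf_config("species", epochs = 12, seed = 3,
                 learning_rate = 1e-3, batch_size = 8))
    pred <- clf_predict(tr$model, feats[te_ix])$labels
    mean(f1_from_confusion(confusion(labs[te_ix], pred, c("A", "B")))$f1)
  }
  f1_heavy_overlap <- run_f1_for_bands(c(39, 45))   # 5 of 6 kHz shared
  f1_disjoint <- run_f1_for_bands(c(52, 58))        # no overlap
  expect_gt(f1_disjoint, f1_heavy_overlap)
  expect_gt(f1_disjoint, 0.9)
})
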