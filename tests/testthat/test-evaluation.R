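test_that("F1 follows its closed form with the 0/0 convention", {
  expect_equal(f1_score(2, 1, 0), 0.8)
  expect_equal(f1_score(0, 0, 0), 0)
  expect_equal(f1_score(1, 1, 1), 0.5)
  expect_equal(f1_score(c(2, 0), c(1, 0), c(0, 0)), c(0.8, 0))
  expect_error(f1_score(-1, 0, 0), "non-negative")
})

test_that("confusion matrices are margin-consistent and normalizable", {
  true <- c("a", "a", "b", "b", "b")
  pred <- c("a", "b", "b", "b", "a")
  cm <- confusion(true, pred)
  expect_equal(rowSums(cm), c(a = 2, b = 3))
  expect_equal(sum(cm), 5)
  expect_equal(unname(diag(cm)), c(1, 2))
  # perfect predictions give a diagonal matrix
  expect_equal(sum(confusion(true, true)) , sum(diag(confusion(true, true))))
  # single predicted class: one nonzero column
  cm0 <- confusion(true, rep("a", 5))
  expect_equal(unname(colSums(cm0 > 0)), c(2, 0))
  nm <- normalize_confusion(cm)
  expect_equal(unname(rowSums(nm)), c(1, 1))
  expect_error(confusion(true, c(pred[-5], "zz"), classes = c("a", "b")),
               "outside the class set")
  expect_error(confusion(true, pred[-1]), "equal length")
})

test_that("f1_from_confusion agrees with brute-force margins on random labels", {
  set.seed(8)
  for (i in 1:25) {
    K <- sample(2:5, 1)
    n <- sample(10:60, 1)
    true <- sample(letters[1:K], n, replace = TRUE)
    pred <- sample(letters[1:K], n, replace = TRUE)
    cm <- confusion(true, pred, letters[1:K])
    rep_df <- f1_from_confusion(cm)
    for (k in seq_len(K)) {
      cls <- letters[k]
      tp <- sum(true == cls & pred == cls)
      fp <- sum(true != cls & pred == cls)
      fn <- sum(true == cls & pred != cls)
      expect_equal(rep_df$f1[k], f1_score(tp, fp, fn))
    }
  }
})

test_that("the directed pair design matches the 2x2 location-year layout", {
  ids <- c("east_2019", "west_2019", "east_2020", "west_2020")
  pairs <- collection_pairs(ids)
  expect_equal(nrow(pairs), 8L)
  expect_true(all(pairs$train != pairs$test))
  # every pair shares a location or a year
  for (i in seq_len(nrow(pairs))) {
    a <- strsplit(pairs$train[i], "_")[[1]]
    b <- strsplit(pairs$test[i], "_")[[1]]
    expect_true(a[1] == b[1] || a[2] == b[2])
  }
  # 3 collections with one odd location-year: only sharing pairs remain
  expect_equal(nrow(collection_pairs(c("east_2019", "west_2019"))), 2L)
})

test_that("cross-collection evaluation runs the directed design end to end", {
  collections <- list(
    east_2019 = c(make_bat_recs("P_pip", 6, dur = 1.3),
                  make_bat_recs("N_noc", 6, dur = 1.3)),
    west_2019 = c(make_bat_recs("P_pip", 6, dur = 1.3),
                  make_bat_recs("N_noc", 6, dur = 1.3)))
  set.seed(80)
  res <- suppressWarnings(cross_collection_eval(
    collections, task = "genus",
    config = clf_config("genus", epochs = 2, runs = 1, seed = 1),
    feature_args = FA_MFCC_FAST))
  expect_equal(nrow(res$pairs), 2L)
  expect_length(res$per_pair, 2L)
  expect_setequal(res$classes, c("Pipistrellus", "Nyctaloid"))
  expect_setequal(unique(res$summary$partition), c("train", "val", "test"))
  expect_true(all(res$summary$f1_mean >= 0 & res$summary$f1_mean <= 1))
  # reports serialize losslessly
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(res$summary, f, row.names = FALSE)
  expect_equal(read.csv(f, stringsAsFactors = FALSE), res$summary)
})

test_that("joined evaluation reports per-partition F1 and a confusion matrix", {
  set.seed(81)
  collections <- list(
    east_2019 = c(make_bat_recs("P_pip", 8, dur = 1.3),
                  make_noise_recs(8)),
    west_2019 = c(make_bat_recs("P_pip", 8, dur = 1.3),
                  make_noise_recs(8)))
  res <- suppressWarnings(joined_eval(
    collections, task = "batnoise",
    config = clf_config("batnoise", epochs = 2, runs = 2, seed = 2),
    feature_args = FA_MFCC_FAST))
  expect_setequal(res$classes, c("bat", "noise"))
  expect_equal(nrow(res$report), 6L)   # 3 partitions x 2 classes
  expect_equal(dim(res$confusion), c(2L, 2L))
  expect_equal(nrow(res$runs_f1$test), 2L)
  expect_error(joined_eval(collections, task = "nonsense"), "unknown task")
})
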