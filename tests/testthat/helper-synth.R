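# Shared fixture builders. Everything is generated in code at test time.
#
# Reduced analysis settings used by compute-heavy tests: the networks are
# fully convolutional / size-parameterized, so the same code paths run at
# lower time-frequency resolution while the canonical 1025x586 / 20x586
# contracts are checked once in dedicated shape tests.
FA_MFCC_FAST <- list(n_fft = 2048L, hop = 2048L)   # 20 x 147 MFCC
FA_SPEC_FAST <- list(n_fft = 256L, hop = 4096L)    # 129 x 74 spectrogram

make_bat_recs <- function(cls, n, dur = 1.3, ...) {
  lapply(seq_len(n), function(i) synth_pulse_train(cls, dur, ...))
}

make_noise_recs <- function(n, profile = NULL, dur = 1) {
  profs <- default_noise_profiles()
  lapply(seq_len(n), function(i) {
    p <- if (is.null(profile)) profs[[sample(length(profs), 1)]] else profile
    synth_noise(p, dur)
  })
}

# small labeled MFCC corpus at reduced resolution
make_mfcc_corpus <- function(classes, n_per_class, dur = 1.3, seed = 1) {
  set.seed(seed)
  recs <- unlist(lapply(classes, function(cls)
    if (cls == "noise") make_noise_recs(n_per_class)
    else make_bat_recs(cls, n_per_class, dur = dur)), recursive = FALSE)
  do.call(segment_features, c(list(recordings = recs, type = "mfcc"),
                              FA_MFCC_FAST))
}

# Streaming corpus builder for the larger acceptance corpora: each recording
# is synthesized, featurized and discarded so full waveforms (MBs apiece)
# are never all held in memory at once. Returns the segment_features layout.
make_task_sf <- function(class_counts, dur = 2.6, feature_args = FA_MFCC_FAST) {
  features <- list(); labels <- c(); rid <- c()
  k <- 0
  for (cls in names(class_counts)) {
    for (i in seq_len(class_counts[[cls]])) {
      k <- k + 1
      rec <- if (cls == "noise")
        synth_noise(default_noise_profiles()[[sample(3, 1)]], dur)
      else synth_pulse_train(cls, dur)
      id <- sprintf("rec%04d", k)
      for (s in recycle_segments(rec, id)) {
        features[[length(features) + 1L]] <-
          do.call(compute_mfcc, c(list(s$samples), feature_args))
        labels <- c(labels, cls)
        rid <- c(rid, id)
      }
    }
  }
  list(features = features, labels = labels, recording_id = rid,
       collection = rep(NA_character_, length(labels)),
       height_m = rep(NA_real_, length(labels)))
}
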