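# chirpnet

Neural-network analysis of bat echolocation soundscapes in R.

Passive acoustic monitoring of bats — for instance microphones mounted at
10–95 m on wind-test-field masts — produces months of ultrasonic audio
(mono WAV, 300 kHz, 16-bit) in which frequency-modulated echolocation
pulse trains are buried in diverse technical noise. Manually labeling
these recordings is slow and expensive. `chirpnet` is for bioacousticians
and quantitative ecologists who want an automated, end-to-end, fully
testable version of a two-stage analysis of such data:

* **Unsupervised stage** — linear spectrograms (1025 × 586 per 1 s
  segment, from a 2048-point STFT at 75% overlap) are compressed by a
  small convolutional autoencoder into 8 × 129 × 74 latent feature maps
  (≈87% fewer elements) and projected to 2-D with UMAP, with a
  silhouette-scored grid search over `n_neighbors` and `min_dist`. This
  reveals how noise structure varies across measurement heights and
  location–year collections.
* **Supervised stage** — a compact CNN (three conv/pool/batch-norm blocks,
  16/32/32 channels, a 128-unit hidden layer and sigmoid outputs) trained
  on 20 × 586 MFCC matrices performs bat/noise, genus and species
  classification. Performance is scored per class with
  `F1 = 2·TP / (2·TP + FP + FN)`, reported as mean ± sd over repeated
  runs, and stress-tested with directed cross-collection validation
  (train on one location–year, test on another), joined-data training,
  and a hybrid-class experiment (`P_low`, calls in the 40–42 kHz band
  shared by *P. pipistrellus* and *P. nathusii*).

Because field datasets of this kind are access-restricted, the package
includes a synthetic soundscape generator: FM pulse trains whose frequency
of maximum energy falls in each class's diagnostic band (e.g. 42–50 kHz
for *P. pipistrellus*), interpulse intervals giving several pulses per
second, stationary noise (narrowband tones, periodic click trains) and
non-stationary broadband transients, with per-collection noise mixtures
and realistic class imbalance. The convolutional engine itself
(im2col convolutions, transposed convolutions, max-pooling, batch-norm,
ADAM) is implemented in the package with RcppArmadillo kernels and is
verified against numerical gradients in the test suite.

## Worked example

```r
library(chirpnet)
set.seed(42)

# 1. synthesize a tiny labeled collection (2 bat classes + noise)
recs <- c(
  lapply(1:20, function(i) synth_pulse_train("P_pip", duration_s = 2.6)),
  lapply(1:20, function(i) synth_pulse_train("N_noc", duration_s = 2.6)),
  lapply(1:20, function(i) synth_noise(default_noise_profiles()$tonal, 1))
)
peak_frequency(recs[[1]])        # 47.0  -- inside P_pip's 42-50 kHz band

# 2. canonical features for one 1 s segment
seg <- recycle_segments(recs[[1]], "rec1")[[1]]
dim(compute_spectrogram(seg))    # 1025  586
dim(compute_mfcc(seg))           # 20  586

# 3. autoencoder bottleneck
dim(encode(build_autoencoder(seed = 1), compute_spectrogram(seg)))
# 129  74   8   (87.3% fewer elements than the spectrogram)

# 4. genus classification on reduced-resolution MFCCs (quick demo setting)
res <- joined_eval(
  recs, task = "genus",
  config = clf_config("genus", epochs = 15, runs = 2, seed = 1),
  feature_args = list(n_fft = 2048, hop = 2048))
res$report[res$report$partition == "test", ]
```

The demo (a few minutes on one core) prints:

```
 partition        class   f1_mean f1_sd n_runs
      test    Nyctaloid 0.9333333     0      2
      test Pipistrellus 0.9411765     0      2
              predicted
true           Nyctaloid Pipistrellus
  Nyctaloid            7            1
  Pipistrellus         0            8
```

i.e. on held-out test segments the two genus classes (*N. noctula* folds
into the Nyctaloid group; *P. pipistrellus* into Pipistrellus) are
recovered with per-class F1 ≈ 0.93–0.94 from frequency content alone —
the signature the full-scale pipeline is designed around. `joined_eval`
also returns the mean test confusion matrix over runs;
`cross_collection_eval` and `hybrid_class_experiment` run the other two
evaluation designs, and `run_noise_by_height` / `run_genus_vs_noise` run
the unsupervised protocols.

A staged end-to-end run (simulate → preprocess → autoencoder → cluster →
classify, with caching and a JSON run manifest) is available through
`run_pipeline()` / `validate_config()` or the thin CLI at
`inst/cli/chirpnet.R`:

```sh
Rscript inst/cli/chirpnet.R run-all --config config.yaml --out out/ --seed 1
```

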