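## Compact CNN classifier on MFCC matrices.
##
## Feature extractor: conv1 3x3 (16 ch) and conv2 3x3 (32 ch), conv3 2x2
## (32 ch), all stride 1, each followed by ReLU, 2x2 max-pool (stride 2) and
## batch-norm. On the 20 x 586 MFCC input the pooling chain is
## 20x586 -> 10x293 -> 5x146 -> 2x73. Classifier head: a 128-unit fully
## connected layer with ReLU, then a K-way fully connected output with
## sigmoid scores. Training uses per-class binary cross-entropy against
## one-hot targets (computed in the numerically stable logit form); the
## predicted label is the argmax score with a lowest-index tie-break.

clf_flat_dim <- function(input_shape) {
  h <- input_shape[1]; w <- input_shape[2]
  for (i in 1:3) { h <- h %/% 2L; w <- w %/% 2L }
  as.integer(32L * h * w)
}

#' Build the compact CNN classifier
#'
#' @param K number of output classes (>= 2).
#' @param classes optional character vector of class names (length K); label
#'   order fixes the output units.
#' @param input_shape input matrix shape, default c(20, 586).
#' @param seed RNG seed for initialization.
#' @return a `bat_classifier` model handle.
#' @export
build_classifier <- function(K, classes = NULL, input_shape = c(20L, 586L),
                             seed = 1L) {
  if (K < 2) stop("K must be >= 2")
  if (!is.null(classes) && length(classes) != K)
    stop("classes must have length K")
  sympad <- c(1L, 1L, 1L, 1L)
  layers <- list(
    layer_conv(1, 16, 3, pad = sympad), layer_relu(),
    layer_pool(ceil_mode = FALSE), layer_batchnorm(16),
    layer_conv(16, 32, 3, pad = sympad), layer_relu(),
    layer_pool(ceil_mode = FALSE), layer_batchnorm(32),
    layer_conv(32, 32, 2, pad = c(0L, 1L, 0L, 1L)), layer_relu(),
    layer_pool(ceil_mode = FALSE), layer_batchnorm(32),
    layer_flatten(),
    layer_dense(clf_flat_dim(input_shape), 128L), layer_relu(),
    layer_dense(128L, as.integer(K))
  )
  structure(list(layers = nn_init(layers, seed = seed), K = as.integer(K),
                 classes = classes, input_shape = as.integer(input_shape)),
            class = "bat_classifier")
}

#' Number of trainable parameters of a model
#' @param model a `bat_classifier` or `bat_autoencoder`.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$layers, function(l)
    length(l$W) + length(l$b) + length(l$gamma) + length(l$beta), numeric(1)))
}

#' @export
print.bat_classifier <- function(x, ...) {
  cat(sprintf("<bat_classifier> K=%d on %dx%d MFCC input, %d parameters\n",
              x$K, x$input_shape[1], x$input_shape[2], n_parameters(x)))
  invisible(x)
}

clf_check_input <- function(x, input_shape) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!identical(dim(x)[1:2], as.integer(input_shape)))
    stop("classifier input must be ", input_shape[1], " x ", input_shape[2])
  x
}

#' Predict class scores for MFCC matrices
#'
#' Deterministic inference pass. Scores are sigmoid outputs in (0, 1), one
#' per class; the predicted label is the class with the maximum score, ties
#' broken toward the lowest class index.
#'
#' @param model a trained `bat_classifier`.
#' @param mfccs a single MFCC matrix or a list of them.
#' @return list with `scores` (n x K matrix) and `labels` (character or index
#'   vector of length n, order-preserving).
#' @export
clf_predict <- function(model, mfccs) {
  if (!is.list(mfccs)) mfccs <- list(mfccs)
  xs <- lapply(mfccs, clf_check_input, input_shape = model$input_shape)
  # inference in bounded chunks: forward caches are per-sample, so pushing
  # a whole dataset through at once would hold them all in memory
  chunks <- split(seq_along(xs), ceiling(seq_along(xs) / 64))
  outs <- vector("list", length(xs))
  for (ch in chunks) {
    fw <- nn_forward(model$layers, xs[ch], train = FALSE, keep_cache = FALSE)
    outs[ch] <- fw$out
    if (length(chunks) > 1) gc(FALSE)  # large-vector churn; keep RSS bounded
  }
  scores <- plogis(do.call(rbind, outs))
  idx <- apply(scores, 1, which.max)      # which.max: lowest index on ties
  labels <- if (!is.null(model$classes)) model$classes[idx] else idx
  list(scores = scores, labels = labels)
}

#' Classifier training configuration
#'
#' Defaults are the reference training protocol for this design: ADAM, learning rate 1e-4, batch
#' size 32, and task-specific epochs of 10 (bat/noise), 50 (genus) and 25
#' (species); five repeated runs.
#'
#' @param task `"batnoise"`, `"genus"` or `"species"` (sets default epochs).
#' @param epochs override the task default.
#' @param learning_rate ADAM learning rate.
#' @param batch_size samples per gradient step.
#' @param runs number of repeated runs for mean/std reporting.
#' @param seed base RNG seed; run r uses `seed + r - 1`.
#' @return a `clf_config` list.
#' @export
clf_config <- function(task = c("batnoise", "genus", "species"), epochs = NULL,
                       learning_rate = 1e-4, batch_size = 32L, runs = 5L,
                       seed = 1L) {
  task <- match.arg(task)
  if (is.null(epochs))
    epochs <- c(batnoise = 10L, genus = 50L, species = 25L)[[task]]
  stopifnot(epochs >= 1, learning_rate > 0, batch_size >= 1, runs >= 1)
  structure(list(task = task, epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), runs = as.integer(runs),
                 seed = as.integer(seed)),
            class = "clf_config")
}

#' Train the classifier
#'
#' Minimizes the sum over classes of binary cross-entropy between sigmoid
#' scores and one-hot targets. Every class of the model must be present in
#' the training labels.
#'
#' @param model a `bat_classifier` (its `classes` field fixes the label set;
#'   if `NULL` it is taken from the sorted unique labels).
#' @param features list of MFCC matrices.
#' @param labels character vector of true labels, parallel to `features`.
#' @param config a [clf_config()].
#' @param verbose print per-epoch losses.
#' @return list with `model` (trained) and `history` (per-epoch mean loss).
#' @export
train_classifier <- function(model, features, labels, config = clf_config(),
                             verbose = FALSE) {
  stopifnot(inherits(model, "bat_classifier"))
  if (is.null(model$classes)) model$classes <- sort(unique(labels))
  missing_cls <- setdiff(model$classes, unique(labels))
  if (length(missing_cls) > 0)
    stop("class(es) absent from training labels: ",
         paste(missing_cls, collapse = ", "))
  if (length(features) != length(labels))
    stop("features and labels must be parallel")
  y_idx <- match(labels, model$classes)
  if (anyNA(y_idx)) stop("labels outside the model's class set")
  xs_all <- lapply(features, clf_check_input, input_shape = model$input_shape)
  onehot <- lapply(y_idx, function(i) { y <- numeric(model$K); y[i] <- 1; y })

  set.seed(config$seed)
  layers <- model$layers
  state <- adam_init(layers)
  t <- 0L
  history <- numeric(config$epochs)
  n <- length(xs_all)
  for (ep in seq_len(config$epochs)) {
    ord <- sample(n)
    losses <- numeric(0)
    for (start in seq(1, n, by = config$batch_size)) {
      sel <- ord[start:min(start + config$batch_size - 1, n)]
      B <- length(sel)
      fw <- nn_forward(layers, xs_all[sel], train = TRUE)
      layers <- fw$layers
      bl <- 0
      dys <- vector("list", B)
      for (k in seq_len(B)) {
        z <- fw$out[[k]]; y <- onehot[[sel[k]]]
        # stable per-class BCE on logits: log(1 + e^z) - y z
        bl <- bl + sum(pmax(z, 0) - y * z + log1p(exp(-abs(z))))
        dys[[k]] <- (plogis(z) - y) / B
      }
      bl <- bl / B
      if (!is.finite(bl))
        stop("non-finite training loss at epoch ", ep)
      losses <- c(losses, bl)
      bw <- nn_backward(layers, fw$cache, dys)
      t <- t + 1L
      upd <- adam_step(layers, bw$grads, state, config$learning_rate, t)
      layers <- upd$layers
      state <- upd$state
    }
    history[ep] <- mean(losses)
    if (verbose)
      message(sprintf("epoch %d/%d: loss %.5f", ep, config$epochs, history[ep]))
  }
  model$layers <- layers
  list(model = model, history = history)
}

#' Train repeated runs of the classifier
#'
#' Trains `config$runs` independent models (weight initialization, shuffling
#' and any subsampling reseeded per run with `config$seed + run - 1`), the
#' repeated-runs protocol behind all mean +/- std reports.
#'
#' @inheritParams train_classifier
#' @param classes label set (fixes output order across runs).
#' @param balance if `TRUE`, subsample the majority classes to the minority
#'   count per run (used for the bat/noise task).
#' @return list of per-run lists with `model` and `history`.
#' @export
train_classifier_runs <- function(features, labels, classes = sort(unique(labels)),
                                  config = clf_config(), balance = FALSE,
                                  verbose = FALSE) {
  input_shape <- dim(features[[1]])
  lapply(seq_len(config$runs), function(r) {
    run_seed <- config$seed + r - 1L
    feats <- features; labs <- labels
    if (balance) {
      set.seed(run_seed)
      m <- min(table(labs))
      keep <- unlist(lapply(split(seq_along(labs), labs),
                            function(ix) sample(ix, m)))
      feats <- feats[keep]; labs <- labs[keep]
    }
    model <- build_classifier(length(classes), classes = classes,
                              input_shape = input_shape, seed = run_seed)
    cfg <- config; cfg$seed <- run_seed
    train_classifier(model, feats, labs, cfg, verbose = verbose)
  })
}
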