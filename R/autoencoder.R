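## Convolutional autoencoder for linear spectrograms.
##
## Encoder: three (3x3 conv, stride 1, same padding) + ReLU + 2x2 max-pool
## (stride 2, ceil mode) + batch-norm blocks with channel widths 1->16->12->8.
## On a 1025 x 586 spectrogram the spatial chain is 1025->513->257->129 and
## 586->293->147->74, so the bottleneck is 8 x 129 x 74 = 76,368 elements,
## ~87% fewer than the 600,650-pixel input. Decoder: three stride-2 3x3
## transposed convolutions (8->16->16->16) + ReLU + batch-norm, then a final
## 4x4 convolution down to one channel, center-cropped to the input size
## (the stride-2 upsampling overshoots by a few pixels).
##
## The network is fully convolutional, so it accepts spectrograms of any size
## >= one pooling chain; reduced-resolution images can be used for quick
## experiments while the canonical contract is checked at 1025 x 586.

AE_BOTTLENECK_CHANNELS <- 8L

ae_layers <- function() {
  sympad <- c(1L, 1L, 1L, 1L)
  list(
    layer_conv(1, 16, 3, pad = sympad), layer_relu(),
    layer_pool(ceil_mode = TRUE), layer_batchnorm(16),
    layer_conv(16, 12, 3, pad = sympad), layer_relu(),
    layer_pool(ceil_mode = TRUE), layer_batchnorm(12),
    layer_conv(12, 8, 3, pad = sympad), layer_relu(),
    layer_pool(ceil_mode = TRUE), layer_batchnorm(8),
    layer_convt(8, 16, 3, stride = 2), layer_relu(), layer_batchnorm(16),
    layer_convt(16, 16, 3, stride = 2), layer_relu(), layer_batchnorm(16),
    layer_convt(16, 16, 3, stride = 2), layer_relu(), layer_batchnorm(16),
    layer_conv(16, 1, 4)
  )
}

AE_ENCODER_DEPTH <- 12L   # layers 1..12 form the encoder

#' Build the convolutional autoencoder
#'
#' @param seed RNG seed for weight initialization; two builds with the same
#'   seed have identical parameters.
#' @return a `bat_autoencoder` model handle.
#' @export
build_autoencoder <- function(seed = 1L) {
  structure(list(layers = nn_init(ae_layers(), seed = seed)),
            class = "bat_autoencoder")
}

#' @export
print.bat_autoencoder <- function(x, ...) {
  np <- sum(vapply(x$layers, function(l)
    length(l$W) + length(l$b) + length(l$gamma) + length(l$beta), numeric(1)))
  cat(sprintf("<bat_autoencoder> 3-block encoder (16/12/8) + 3-block decoder (16/16/16), %d parameters\n",
              round(np)))
  invisible(x)
}

ae_check_input <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (length(dim(x)) != 3L || dim(x)[3] != 1L)
    stop("autoencoder input must be a single-channel image (H x W matrix)")
  if (dim(x)[1] < 8L || dim(x)[2] < 8L)
    stop("input too small for three 2x2 poolings")
  x
}

crop_center <- function(y, H, W) {
  d <- dim(y)
  oh <- (d[1] - H) %/% 2L; ow <- (d[2] - W) %/% 2L
  y[oh + seq_len(H), ow + seq_len(W), , drop = FALSE]
}

#' Autoencoder forward pass (reconstruction)
#'
#' @param model a `bat_autoencoder`.
#' @param x spectrogram matrix (values in \[0, 1\]).
#' @return reconstruction matrix of identical shape.
#' @export
ae_reconstruct <- function(model, x) {
  xi <- ae_check_input(x)
  fw <- nn_forward(model$layers, list(xi), train = FALSE, keep_cache = FALSE)
  y <- crop_center(fw$out[[1]], dim(xi)[1], dim(xi)[2])
  matrix(y, nrow = dim(xi)[1])
}

#' Encode a spectrogram into its latent representation
#'
#' Runs the encoder only and returns the bottleneck feature map
#' (ceil(H/8) x ceil(W/8) x 8; 129 x 74 x 8 for a canonical 1025 x 586
#' spectrogram). Deterministic for a fixed model (inference mode).
#'
#' @param model a `bat_autoencoder`.
#' @param x spectrogram matrix.
#' @return 3-d array (h x w x 8).
#' @export
encode <- function(model, x) {
  xi <- ae_check_input(x)
  fw <- nn_forward(model$layers[seq_len(AE_ENCODER_DEPTH)], list(xi),
                   train = FALSE, keep_cache = FALSE)
  fw$out[[1]]
}

#' Flatten a latent feature map into a vector
#'
#' @param latent output of [encode()].
#' @return numeric vector (length 76,368 for canonical input).
#' @export
latent_vector <- function(latent) as.vector(latent)

#' Autoencoder training configuration
#'
#' Defaults are the reference training protocol for this architecture: ADAM with
#' learning rate 1e-4, batch size 1, 10 epochs, mean-squared reconstruction
#' error.
#'
#' @param learning_rate ADAM learning rate.
#' @param batch_size images per gradient step.
#' @param epochs training epochs.
#' @param seed RNG seed for shuffling.
#' @return an `ae_config` list.
#' @export
ae_config <- function(learning_rate = 1e-4, batch_size = 1L, epochs = 10L,
                      seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1)
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "ae_config")
}

#' Train the autoencoder for reconstruction
#'
#' Minimizes per-image mean squared reconstruction error with ADAM. Batch
#' normalization uses batch statistics during training and running statistics
#' at inference. Training aborts with diagnostics if the loss becomes
#' non-finite.
#'
#' @param model a `bat_autoencoder`.
#' @param images list of spectrogram matrices (>= 2, all the same size).
#' @param config an [ae_config()].
#' @param verbose print per-epoch losses.
#' @return list with `model` (trained) and `history` (per-epoch mean loss,
#'   length `epochs`).
#' @export
train_autoencoder <- function(model, images, config = ae_config(),
                              verbose = FALSE) {
  stopifnot(inherits(model, "bat_autoencoder"))
  if (length(images) < 2) stop("need at least 2 training images")
  images <- lapply(images, ae_check_input)
  set.seed(config$seed)
  layers <- model$layers
  state <- adam_init(layers)
  t <- 0L
  history <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample(length(images))
    losses <- numeric(0)
    for (start in seq(1, length(ord), by = config$batch_size)) {
      batch <- images[ord[start:min(start + config$batch_size - 1, length(ord))]]
      fw <- nn_forward(layers, batch, train = TRUE)
      layers <- fw$layers
      B <- length(batch)
      dys <- vector("list", B)
      bl <- 0
      for (k in seq_len(B)) {
        H <- dim(batch[[k]])[1]; W <- dim(batch[[k]])[2]
        rec <- crop_center(fw$out[[k]], H, W)
        diff <- rec - batch[[k]]
        bl <- bl + mean(diff^2)
        d <- array(0, dim = dim(fw$out[[k]]))
        oh <- (dim(d)[1] - H) %/% 2L; ow <- (dim(d)[2] - W) %/% 2L
        d[oh + seq_len(H), ow + seq_len(W), ] <- 2 * diff / (H * W * B)
        dys[[k]] <- d
      }
      bl <- bl / B
      if (!is.finite(bl))
        stop("non-finite reconstruction loss at epoch ", ep,
             " (step ", t + 1, "); try a lower learning rate")
      losses <- c(losses, bl)
      bw <- nn_backward(layers, fw$cache, dys)
      t <- t + 1L
      upd <- adam_step(layers, bw$grads, state, config$learning_rate, t)
      layers <- upd$layers
      state <- upd$state
    }
    history[ep] <- mean(losses)
    if (verbose)
      message(sprintf("epoch %d/%d: mse %.6f", ep, config$epochs, history[ep]))
  }
  model$layers <- layers
  list(model = model, history = history)
}

#' Peak signal-to-noise ratio between two images
#'
#' `10 * log10(peak^2 / MSE)` with peak 1 (images are expected in \[0, 1\]).
#' Identical images return `Inf`.
#'
#' @param reference,reconstruction equal-shaped numeric matrices.
#' @return PSNR in dB.
#' @export
psnr <- function(reference, reconstruction) {
  if (!identical(dim(reference), dim(reconstruction)))
    stop("psnr: shape mismatch")
  mse <- mean((reference - reconstruction)^2)
  if (mse == 0) return(Inf)
  10 * log10(1 / mse)
}

#' Structural similarity index (SSIM) between two images
#'
#' Standard SSIM with 7x7 uniform local windows and the usual stabilizing
#' constants C1 = (0.01 L)^2, C2 = (0.03 L)^2 for dynamic range L = 1. Local
#' statistics use unbiased variance/covariance over each fully-interior
#' window; the score is the mean of the local SSIM map. Identical images
#' score 1.
#'
#' @param reference,reconstruction equal-shaped numeric matrices in \[0, 1\].
#' @param win window side length (odd, default 7).
#' @return SSIM in \[-1, 1\].
#' @export
ssim <- function(reference, reconstruction, win = 7L) {
  if (!identical(dim(reference), dim(reconstruction)))
    stop("ssim: shape mismatch")
  if (min(dim(reference)) < win) stop("image smaller than the SSIM window")
  C1 <- 0.01^2; C2 <- 0.03^2
  n <- win * win
  box <- function(m) {
    # valid-mode box sum via integral image
    s <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed integral image
    s <- t(s)
    s <- rbind(0, cbind(0, s))
    H <- nrow(m); W <- ncol(m)
    s[(win + 1):(H + 1), (win + 1):(W + 1)] - s[1:(H - win + 1), (win + 1):(W + 1)] -
      s[(win + 1):(H + 1), 1:(W - win + 1)] + s[1:(H - win + 1), 1:(W - win + 1)]
  }
  mu_x <- box(reference) / n
  mu_y <- box(reconstruction) / n
  # unbiased local (co)variances, matching the conventional implementation
  vx <- (box(reference^2) - n * mu_x^2) / (n - 1)
  vy <- (box(reconstruction^2) - n * mu_y^2) / (n - 1)
  cxy <- (box(reference * reconstruction) - n * mu_x * mu_y) / (n - 1)
  map <- ((2 * mu_x * mu_y + C1) * (2 * cxy + C2)) /
    ((mu_x^2 + mu_y^2 + C1) * (vx + vy + C2))
  mean(map)
}

#' Clamp an image to \[0, 1\]
#' @param x numeric matrix/array.
#' @return clamped input.
#' @export
clamp01 <- function(x) { x[x < 0] <- 0; x[x > 1] <- 1; x }
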