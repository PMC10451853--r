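## Minimal convolutional-network engine backing the autoencoder and classifier.
##
## A network is a list of layer descriptors; feature maps are (H, W, C) arrays
## and a batch is a plain list of them. Forward/backward passes are exact
## (verified by numerical gradient checks in the test suite); the heavy
## convolution kernels live in src/convops.cpp. Only the pieces these two
## architectures need are implemented: valid convolutions with caller-side
## padding, stride-2 transposed convolutions, 2x2 max-pooling (floor or ceil
## mode), per-channel batch normalization, dense layers and ReLU.

as_map <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
}

pad_map <- function(x, pad) {
  # pad = c(top, bottom, left, right), zero padding
  if (all(pad == 0L)) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1] + pad[1] + pad[2], d[2] + pad[3] + pad[4], d[3]))
  out[pad[1] + seq_len(d[1]), pad[3] + seq_len(d[2]), ] <- x
  out
}

unpad_map <- function(x, pad) {
  if (all(pad == 0L)) return(x)
  d <- dim(x)
  x[pad[1] + seq_len(d[1] - pad[1] - pad[2]),
    pad[3] + seq_len(d[2] - pad[3] - pad[4]), , drop = FALSE]
}

## ---- layer constructors -----------------------------------------------------

layer_conv <- function(c_in, c_out, kh, kw = kh, stride = 1L,
                       pad = c(0L, 0L, 0L, 0L)) {
  list(type = "conv", c_in = c_in, c_out = c_out, kh = kh, kw = kw,
       stride = stride, pad = pad,
       W = NULL, b = NULL)
}

layer_convt <- function(c_in, c_out, kh, kw = kh, stride = 2L) {
  list(type = "convt", c_in = c_in, c_out = c_out, kh = kh, kw = kw,
       stride = stride, W = NULL, b = NULL)
}

layer_relu <- function() list(type = "relu")

layer_pool <- function(ceil_mode = FALSE) list(type = "pool", ceil_mode = ceil_mode)

layer_batchnorm <- function(channels, eps = 1e-5, momentum = 0.1) {
  list(type = "batchnorm", channels = channels, eps = eps, momentum = momentum,
       gamma = rep(1, channels), beta = rep(0, channels),
       running_mean = rep(0, channels), running_var = rep(1, channels))
}

layer_flatten <- function() list(type = "flatten")

layer_dense <- function(n_in, n_out) {
  list(type = "dense", n_in = n_in, n_out = n_out, W = NULL, b = NULL)
}

## ---- initialization ---------------------------------------------------------

nn_init <- function(layers, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      fan_in <- l$kh * l$kw * l$c_in
      l$W <- matrix(stats::rnorm(l$c_out * fan_in, sd = sqrt(2 / fan_in)),
                    nrow = l$c_out)
      l$b <- rep(0, l$c_out)
    } else if (l$type == "convt") {
      fan_in <- l$kh * l$kw * l$c_in
      l$W <- matrix(stats::rnorm(l$c_in * l$kh * l$kw * l$c_out,
                                 sd = sqrt(2 / fan_in)),
                    nrow = l$c_in)
      l$b <- rep(0, l$c_out)
    } else if (l$type == "dense") {
      l$W <- matrix(stats::rnorm(l$n_out * l$n_in, sd = sqrt(2 / l$n_in)),
                    nrow = l$n_out)
      l$b <- rep(0, l$n_out)
    }
    layers[[i]] <- l
  }
  layers
}

## ---- forward ----------------------------------------------------------------

# Returns list(out = list of outputs, cache = per-layer caches, layers = layers)
# `layers` is returned because batchnorm updates its running statistics when
# train = TRUE. With keep_cache = FALSE no backward caches are retained
# (inference mode for encode/predict), keeping memory per call bounded.
nn_forward <- function(layers, xs, train = FALSE, keep_cache = TRUE) {
  xs <- lapply(xs, as_map)
  cache <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      # im2col once; the column matrix is cached and reused by the backward
      # pass (weight gradient and col2im data gradient)
      xp <- lapply(xs, pad_map, pad = l$pad)
      dp <- dim(xp[[1]])
      ho <- (dp[1] - l$kh) %/% l$stride + 1L
      wo <- (dp[2] - l$kw) %/% l$stride + 1L
      if (keep_cache) {
        cols <- lapply(xp, cpp_im2col, kh = l$kh, kw = l$kw, stride = l$stride)
        xs <- lapply(cols, function(cc)
          array(t(l$W %*% cc + l$b), dim = c(ho, wo, l$c_out)))
        cache[[i]] <- list(cols = cols, dp = dp, ho = ho, wo = wo)
      } else {
        xs <- lapply(xp, function(x) {
          cc <- cpp_im2col(x, l$kh, l$kw, l$stride)
          array(t(l$W %*% cc + l$b), dim = c(ho, wo, l$c_out))
        })
      }
    } else if (l$type == "convt") {
      xin <- xs
      xs <- lapply(xs, cpp_convt_fw, W = l$W, b = l$b, kh = l$kh, kw = l$kw,
                   stride = l$stride)
      cache[[i]] <- list(x = xin)
    } else if (l$type == "relu") {
      masks <- lapply(xs, function(x) x > 0)
      xs <- Map(function(x, m) x * m, xs, masks)
      cache[[i]] <- list(masks = masks)
    } else if (l$type == "pool") {
      res <- lapply(xs, cpp_maxpool, ceil_mode = l$ceil_mode)
      dims <- lapply(xs, dim)
      xs <- lapply(res, `[[`, "out")
      cache[[i]] <- list(idx = lapply(res, `[[`, "idx"), dims = dims)
    } else if (l$type == "batchnorm") {
      bn <- bn_forward(l, xs, train)
      xs <- bn$out
      cache[[i]] <- bn$cache
      layers[[i]] <- bn$layer
    } else if (l$type == "flatten") {
      dims <- lapply(xs, dim)
      xs <- lapply(xs, as.vector)
      cache[[i]] <- list(dims = dims)
    } else if (l$type == "dense") {
      X <- do.call(cbind, xs)              # n_in x batch
      Y <- l$W %*% X + l$b
      cache[[i]] <- list(X = X)
      xs <- lapply(seq_len(ncol(Y)), function(k) Y[, k])
    } else {
      stop("unknown layer type: ", l$type)
    }
    if (!keep_cache) cache[i] <- list(NULL)
  }
  list(out = xs, cache = cache, layers = layers)
}

bn_forward <- function(l, xs, train) {
  C <- l$channels
  d <- dim(xs[[1]])
  hw <- d[1] * d[2]
  if (train) {
    N <- hw * length(xs)
    sums <- Reduce(`+`, lapply(xs, function(x) .colSums(x, hw, C)))
    mu <- sums / N
    sq <- Reduce(`+`, lapply(xs, function(x) .colSums(x * x, hw, C)))
    v <- pmax(sq / N - mu^2, 0)
    l$running_mean <- (1 - l$momentum) * l$running_mean + l$momentum * mu
    l$running_var <- (1 - l$momentum) * l$running_var + l$momentum * v
  } else {
    mu <- l$running_mean
    v <- l$running_var
    N <- NA_real_
  }
  inv_std <- 1 / sqrt(v + l$eps)
  mu_e <- rep(mu, each = hw)
  inv_e <- rep(inv_std, each = hw)
  ge <- rep(l$gamma, each = hw)
  be <- rep(l$beta, each = hw)
  xhat <- lapply(xs, function(x) array((x - mu_e) * inv_e, dim = d))
  out <- lapply(xhat, function(x) array(x * ge + be, dim = d))
  list(out = out,
       cache = list(xhat = xhat, inv_std = inv_std, N = N, train = train,
                    hw = hw),
       layer = l)
}

## ---- backward ---------------------------------------------------------------

# dys: list of gradients w.r.t. the network outputs (same structure as outputs).
# Returns list(grads = per-layer parameter gradients, dxs = input gradients).
nn_backward <- function(layers, cache, dys) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    cc <- cache[[i]]
    if (l$type == "conv") {
      dW <- 0; db <- 0
      dxs <- vector("list", length(dys))
      for (k in seq_along(dys)) {
        dy_mat <- t(matrix(dys[[k]], cc$ho * cc$wo, l$c_out))
        dW <- dW + dy_mat %*% t(cc$cols[[k]])
        db <- db + rowSums(dy_mat)
        dx <- cpp_col2im(crossprod(l$W, dy_mat), cc$dp[1], cc$dp[2], l$c_in,
                         l$kh, l$kw, l$stride)
        dxs[[k]] <- unpad_map(dx, l$pad)
      }
      grads[[i]] <- list(W = dW, b = as.vector(db))
      dys <- dxs
    } else if (l$type == "convt") {
      dW <- 0; db <- 0
      dxs <- vector("list", length(dys))
      for (k in seq_along(dys)) {
        r <- cpp_convt_bw(cc$x[[k]], l$W, as_map(dys[[k]]), l$kh, l$kw, l$stride)
        dW <- dW + r$dW; db <- db + r$db
        dxs[[k]] <- r$dx
      }
      grads[[i]] <- list(W = dW, b = as.vector(db))
      dys <- dxs
    } else if (l$type == "relu") {
      dys <- Map(function(d, m) d * m, dys, cc$masks)
    } else if (l$type == "pool") {
      dys <- Map(function(d, idx, dm) cpp_maxpool_bw(as_map(d), idx, dm[1], dm[2]),
                 dys, cc$idx, cc$dims)
    } else if (l$type == "batchnorm") {
      r <- bn_backward(l, cc, dys)
      grads[[i]] <- r$grads
      dys <- r$dxs
    } else if (l$type == "flatten") {
      dys <- Map(function(d, dm) array(d, dim = dm), dys, cc$dims)
    } else if (l$type == "dense") {
      D <- do.call(cbind, dys)             # n_out x batch
      grads[[i]] <- list(W = D %*% t(cc$X), b = rowSums(D))
      DX <- t(l$W) %*% D
      dys <- lapply(seq_len(ncol(DX)), function(k) DX[, k])
    }
  }
  list(grads = grads, dxs = dys)
}

bn_backward <- function(l, cc, dys) {
  C <- l$channels
  hw <- cc$hw
  d <- dim(dys[[1]])
  dgamma <- Reduce(`+`, Map(function(dy, xh)
    .colSums(dy * xh, hw, C), dys, cc$xhat))
  dbeta <- Reduce(`+`, lapply(dys, function(dy) .colSums(dy, hw, C)))
  ge <- rep(l$gamma, each = hw)
  inv_e <- rep(cc$inv_std, each = hw)
  if (isTRUE(cc$train)) {
    N <- cc$N
    # sum(dxhat) = gamma * dbeta; sum(dxhat * xhat) = gamma * dgamma
    s1e <- rep(l$gamma * dbeta, each = hw)
    s2e <- rep(l$gamma * dgamma, each = hw)
    dxs <- Map(function(dy, xh)
      array((inv_e / N) * (N * dy * ge - s1e - xh * s2e), dim = d),
      dys, cc$xhat)
  } else {
    dxs <- lapply(dys, function(dy) array(dy * ge * inv_e, dim = d))
  }
  list(grads = list(gamma = dgamma, beta = dbeta), dxs = dxs)
}

## ---- Adam optimizer ---------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (l$type %in% c("conv", "convt", "dense")) {
      list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
    } else if (l$type == "batchnorm") {
      list(mg = l$gamma * 0, vg = l$gamma * 0, mb = l$beta * 0, vb = l$beta * 0)
    } else NULL
  })
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  corr1 <- 1 - beta1^t
  corr2 <- 1 - beta2^t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / corr1) / (sqrt(v / corr2) + eps)
    list(p = p, m = m, v = v)
  }
  for (i in seq_along(layers)) {
    l <- layers[[i]]; g <- grads[[i]]; s <- state[[i]]
    if (is.null(g)) next
    if (l$type %in% c("conv", "convt", "dense")) {
      u <- upd(l$W, g$W, s$mW, s$vW); l$W <- u$p; s$mW <- u$m; s$vW <- u$v
      u <- upd(l$b, g$b, s$mb, s$vb); l$b <- u$p; s$mb <- u$m; s$vb <- u$v
    } else if (l$type == "batchnorm") {
      u <- upd(l$gamma, g$gamma, s$mg, s$vg); l$gamma <- u$p; s$mg <- u$m; s$vg <- u$v
      u <- upd(l$beta, g$beta, s$mb, s$vb); l$beta <- u$p; s$mb <- u$m; s$vb <- u$v
    }
    layers[[i]] <- l; state[[i]] <- s
  }
  list(layers = layers, state = state)
}
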