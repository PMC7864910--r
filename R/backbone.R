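#' Activation functions
#'
#' The three activations relevant to the mobile-network family: `relu`
#' (`max(0, x)`), `relu6` (`min(max(0, x), 6)`, the capped variant used by
#' MobileNetV2) and `swish` (`x * sigmoid(x)`, the smooth self-gated
#' activation EfficientNet adopts in place of relu6).
#'
#' @param x Numeric vector/matrix.
#' @param kind `"relu"`, `"relu6"` or `"swish"`.
#' @return Elementwise activation values.
#' @export
#' @examples
#' activation(7, "relu6")   # 6
#' activation(0, "swish")   # 0
activation <- function(x, kind = c("swish", "relu", "relu6")) {
  kind <- match.arg(kind)
  switch(kind,
    relu = pmax(0, x),
    relu6 = pmin(pmax(0, x), 6),
    swish = x * plogis(x)
  )
}

activation_grad <- function(x, kind) {
  switch(kind,
    relu = (x > 0) * 1,
    relu6 = (x > 0 & x < 6) * 1,
    swish = {
      s <- plogis(x)
      s + x * s * (1 - s)
    }
  )
}

# Fixed 3x3 filter bank: blur, Sobel-x, Sobel-y, Laplacian. Applied at the
# stage's native resolution, before pooling, so higher-resolution stages see
# sharper edge responses from the same parameters.
filter_bank <- function() {
  list(
    blur = matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1) / 16, 3, 3),
    sobel_x = matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3),
    sobel_y = matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3),
    laplace = matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  )
}

# 3x3 convolution of an n x h x w array by shifted sums (zero padding).
conv3x3 <- function(images, kernel) {
  d <- dim(images)
  n <- d[1]; h <- d[2]; w <- d[3]
  out <- array(0, d)
  for (di in -1:1) {
    for (dj in -1:1) {
      kv <- kernel[di + 2, dj + 2]
      if (kv == 0) next
      ri <- max(1, 1 - di):min(h, h - di)
      rj <- max(1, 1 - dj):min(w, w - dj)
      out[, ri, rj] <- out[, ri, rj] + kv * images[, ri + di, rj + dj]
    }
  }
  out
}

# Adaptive average pooling of an n x h x w array to an n x g x g array.
adaptive_pool <- function(images, g) {
  d <- dim(images)
  n <- d[1]; h <- d[2]; w <- d[3]
  if (h < g || w < g) abort("image smaller than the pooling grid")
  bi <- floor((seq_len(h) - 1) * g / h) + 1
  bj <- floor((seq_len(w) - 1) * g / w) + 1
  out <- array(0, c(n, g, g))
  cnt <- matrix(0, g, g)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      out[, bi[i], bj[j]] <- out[, bi[i], bj[j]] + images[, i, j]
      cnt[bi[i], bj[j]] <- cnt[bi[i], bj[j]] + 1
    }
  }
  sweep_div <- rep(cnt, each = n)
  out / array(sweep_div, c(n, g, g))
}

#' Resize a stack of images
#'
#' Area-average downsampling when the target divides the source, pixel
#' replication when the source divides the target, nearest-neighbour
#' otherwise. Used by the progressive-resizing harness to derive each
#' stage's input from the native-resolution images.
#'
#' @param images n x h x w array (square images).
#' @param size Target side length.
#' @return n x size x size array.
#' @export
resize_images <- function(images, size) {
  h <- dim(images)[2]
  if (size == h) return(images)
  if (size < h && h %% size == 0) return(adaptive_pool(images, size))
  idx <- pmin(h, floor((seq_len(size) - 0.5) * h / size) + 1)
  images[, idx, idx, drop = FALSE]
}

#' Reference convolutional backbone
#'
#' A deliberately small, resolution-agnostic image classifier for desk-scale
#' experiments: a fixed 3x3 filter bank (blur, Sobel-x, Sobel-y, Laplacian)
#' at the input resolution, adaptive average pooling of each channel to a
#' `grid x grid` map, one fully connected hidden layer with a configurable
#' activation, and a C-node sigmoid head. Only the two dense layers are
#' learned, so parameters transfer unchanged between input resolutions —
#' the property progressive resizing relies on.
#'
#' @param n_classes Output dimension C.
#' @param grid Pooling grid side (default 8; feature dim = 4 * grid^2).
#' @param hidden Hidden layer width.
#' @param act Hidden activation kind, see [activation()].
#' @param seed Seed for the parameter initialization.
#' @return A list of class `cbf_model` with the parameter matrices.
#' @export
tiny_backbone <- function(n_classes, grid = 8, hidden = 16,
                          act = "swish", seed = 1L) {
  d_in <- 4 * grid^2
  withr::with_seed(seed, {
    params <- list(
      W1 = matrix(rnorm(d_in * hidden, 0, sqrt(2 / d_in)), d_in, hidden),
      b1 = rep(0, hidden),
      W2 = matrix(rnorm(hidden * n_classes, 0, sqrt(2 / hidden)),
                  hidden, n_classes),
      b2 = rep(0, n_classes)
    )
  })
  structure(list(params = params, grid = grid, hidden = hidden, act = act,
                 n_classes = n_classes),
            class = "cbf_model")
}

#' Extract backbone features from images
#'
#' The deterministic (parameter-free) front half of [tiny_backbone()]:
#' filter bank then pooling, flattened to an n x (4 grid^2) matrix.
#' Features are standardized channelwise by the filter-bank response scale.
#'
#' @param model A `cbf_model`.
#' @param images n x h x w array at the stage resolution.
#' @return n x (4 * grid^2) feature matrix.
#' @export
backbone_features <- function(model, images) {
  g <- model$grid
  n <- dim(images)[1]
  bank <- filter_bank()
  # derivative-of-Gaussian convention: gradients and the Laplacian are taken
  # on the blurred image so the finest-scale noise, which only exists at the
  # higher resolutions, does not leak into the edge channels; this keeps the
  # pooled features stable across input resolutions, which the
  # progressive-resizing warm start relies on.
  smooth <- conv3x3(conv3x3(images, bank$blur), bank$blur)
  feats <- lapply(bank, function(kern) {
    pooled <- adaptive_pool(conv3x3(smooth, kern), g)
    m <- matrix(pooled, n, g * g)
    m / max(stats::sd(m), 1e-8)
  })
  do.call(cbind, feats)
}

#' Forward pass of the reference backbone
#'
#' @param model A `cbf_model`.
#' @param x Feature matrix from [backbone_features()], or an n x h x w image
#'   array (features are extracted first).
#' @return n x C matrix of sigmoid probabilities.
#' @export
predict_backbone <- function(model, x) {
  if (length(dim(x)) == 3L) x <- backbone_features(model, x)
  fwd <- backbone_forward(model, x)
  fwd$p
}

backbone_forward <- function(model, x) {
  pr <- model$params
  a <- sweep(x %*% pr$W1, 2, pr$b1, "+")
  h <- activation(a, model$act)
  z <- sweep(h %*% pr$W2, 2, pr$b2, "+")
  list(a = a, h = h, z = z, p = plogis(z))
}

# Gradients of the batch loss w.r.t. the dense parameters. dLdp comes from
# batch_loss_grad(); the sigmoid head contributes p(1-p).
backbone_backward <- function(model, x, fwd, dLdp) {
  dLdz <- dLdp * fwd$p * (1 - fwd$p)
  dW2 <- t(fwd$h) %*% dLdz
  db2 <- colSums(dLdz)
  dH <- dLdz %*% t(model$params$W2)
  dA <- dH * activation_grad(fwd$a, model$act)
  dW1 <- t(x) %*% dA
  db1 <- colSums(dA)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

# ---- optimizers ------------------------------------------------------------

#' Optimizer factory
#'
#' `"adam"` is standard Adam; `"ranger"` combines rectified Adam (variance
#' warm-up of the adaptive step) with Lookahead slow weights (k = 5,
#' interpolation 0.5), a pairing that converges in few epochs on the
#' weighted-loss runs.
#'
#' @param name `"adam"` or `"ranger"`.
#' @param lr Learning rate; default 1e-2 suits the small dense head trained
#'   from scratch.
#' @param beta1,beta2 Moment decay rates.
#' @param eps Numerical stabilizer.
#' @param la_k,la_alpha Lookahead sync period and interpolation (ranger).
#' @return A list of class `cbf_optimizer` with `init(params)` and
#'   `step(state, params, grads)` functions.
#' @export
make_optimizer <- function(name = c("adam", "ranger"), lr = 1e-2,
                           beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                           la_k = 5L, la_alpha = 0.5) {
  name <- match.arg(name)
  init <- function(params) {
    list(t = 0L,
         m = purrr::map(params, ~ .x * 0),
         v = purrr::map(params, ~ .x * 0),
         slow = params)
  }
  step <- function(state, params, grads) {
    state$t <- state$t + 1L
    t <- state$t
    rho_inf <- 2 / (1 - beta2) - 1
    for (nm in names(params)) {
      g <- grads[[nm]]
      state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
      state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
      mhat <- state$m[[nm]] / (1 - beta1^t)
      if (name == "adam") {
        vhat <- state$v[[nm]] / (1 - beta2^t)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      } else {
        rho_t <- rho_inf - 2 * t * beta2^t / (1 - beta2^t)
        if (rho_t > 4) {
          vhat <- sqrt(state$v[[nm]] / (1 - beta2^t))
          r <- sqrt(((rho_t - 4) * (rho_t - 2) * rho_inf) /
                      ((rho_inf - 4) * (rho_inf - 2) * rho_t))
          params[[nm]] <- params[[nm]] - lr * r * mhat / (vhat + eps)
        } else {
          params[[nm]] <- params[[nm]] - lr * mhat
        }
      }
    }
    if (name == "ranger" && state$t %% la_k == 0L) {
      for (nm in names(params)) {
        state$slow[[nm]] <- state$slow[[nm]] +
          la_alpha * (params[[nm]] - state$slow[[nm]])
        params[[nm]] <- state$slow[[nm]]
      }
    }
    list(state = state, params = params)
  }
  structure(list(name = name, lr = lr, init = init, step = step),
            class = "cbf_optimizer")
}
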