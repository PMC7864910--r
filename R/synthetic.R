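#' Configuration for the synthetic imbalanced multilabel image generator
#'
#' The generator emulates the statistical shape of a chest-radiograph label
#' table — highly skewed per-class prevalences (a rare finding near 0.2%, a
#' common one near 18%) with independent multilabel co-occurrence — while
#' keeping the imaging trivial: each class owns a fixed geometric template
#' that is stamped, scaled by `signal_strength`, onto a Gaussian noise
#' background. Fixed templates make the Bayes-optimal scorer analytic
#' (a matched filter), so metric and training code can be validated against
#' a known ceiling.
#'
#' @param n_samples Number of images, `>= 1`.
#' @param prevalence Per-class positive probability in (0, 1); its length
#'   sets the class count C. Default spans 0.5%-30% over five classes.
#' @param image_size Pixels per side, `>= 16`.
#' @param signal_strength Template amplitude (pixel units), `> 0`.
#' @param noise_sd Background noise standard deviation, `>= 0`. The default
#'   4 makes the per-pixel SNR 0.25 so single pixels are uninformative and a
#'   classifier must integrate over the template's support.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A list of class `cbf_sim_config`.
#' @export
synthetic_config <- function(n_samples = 2000,
                             prevalence = c(0.005, 0.02, 0.08, 0.15, 0.30),
                             image_size = 64, signal_strength = 1,
                             noise_sd = 4, seed = 1L) {
  if (n_samples < 1) abort("n_samples must be >= 1")
  if (any(prevalence <= 0 | prevalence >= 1)) {
    abort("prevalences must lie strictly in (0, 1)")
  }
  if (image_size < 16) abort("image_size must be >= 16")
  if (signal_strength <= 0) abort("signal_strength must be > 0")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  structure(list(n_samples = as.integer(n_samples), prevalence = prevalence,
                 C = length(prevalence), image_size = as.integer(image_size),
                 signal_strength = signal_strength, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cbf_sim_config")
}

#' Fixed geometric template of a synthetic class
#'
#' Class `k` owns a deterministic primitive — disks, squares and rings
#' cycling over a 3 x 3 grid of anchor cells in unit coordinates — rendered
#' as a 0/1 mask at any resolution. Positions and shapes never depend on the
#' seed, so the same class looks the same across datasets and resolutions.
#'
#' @param k Class index, `>= 1`.
#' @param image_size Pixels per side.
#' @return An `image_size` x `image_size` 0/1 matrix.
#' @export
class_template <- function(k, image_size) {
  cell <- (k - 1L) %% 9L
  shape <- (k - 1L) %% 3L
  cx <- (cell %% 3L) / 3 + 1 / 6
  cy <- (cell %/% 3L) / 3 + 1 / 6
  xs <- (seq_len(image_size) - 0.5) / image_size
  dx <- outer(rep(1, image_size), xs) - cx
  dy <- outer(xs, rep(1, image_size)) - cy
  r <- sqrt(dx^2 + dy^2)
  mask <- switch(shape + 1L,
    r <= 0.09,                              # disk
    abs(dx) <= 0.08 & abs(dy) <= 0.08,      # square
    r >= 0.055 & r <= 0.1                   # ring
  )
  mask * 1
}

#' Generate a synthetic imbalanced multilabel image dataset
#'
#' Labels are drawn independently per class as Bernoulli(prevalence_k); each
#' positive class stamps its [class_template()] scaled by `signal_strength`
#' onto an i.i.d. Gaussian noise background. Deterministic given
#' `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `cbf_sim` with elements `images` (n x s x s
#'   array), `labels` (n x C binary matrix, class names as columns),
#'   `label_table` (a `cbf_labels` tibble in the data-I/O dialect) and
#'   `config`.
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "cbf_sim_config"))
  n <- config$n_samples
  s <- config$image_size
  C <- config$C
  classes <- sprintf("Class%02d", seq_len(C))
  withr::with_seed(config$seed, {
    labels <- sapply(seq_len(C), function(k) rbinom(n, 1L, config$prevalence[k]))
    labels <- matrix(as.integer(labels), n, C, dimnames = list(NULL, classes))
    images <- array(rnorm(n * s * s, 0, config$noise_sd), dim = c(n, s, s))
  })
  for (k in seq_len(C)) {
    idx <- which(labels[, k] == 1L)
    if (length(idx) == 0L) next
    tpl <- config$signal_strength * class_template(k, s)
    images[idx, , ] <- images[idx, , , drop = FALSE] +
      rep(tpl, each = length(idx))
  }
  findings <- purrr::map(seq_len(n), function(i) classes[labels[i, ] == 1L])
  tbl <- new_label_table(
    tibble::tibble(image_id = sprintf("img%06d.png", seq_len(n)),
                   findings = findings),
    classes
  )
  structure(list(images = images, labels = labels, label_table = tbl,
                 config = config),
            class = "cbf_sim")
}

#' Convert a label table to an n x C binary matrix
#'
#' @param labels A `cbf_labels` tibble.
#' @param vocabulary Class order for the columns.
#' @return Binary matrix with one row per record.
#' @export
label_matrix <- function(labels, vocabulary = attr(labels, "vocabulary")) {
  m <- sapply(vocabulary, function(cl) {
    purrr::map_int(labels$findings, ~ as.integer(cl %in% .x))
  })
  matrix(as.integer(m), nrow(labels), length(vocabulary),
         dimnames = list(NULL, vocabulary))
}

#' Matched-filter scores for a synthetic dataset
#'
#' Near-Bayes-optimal scorer for [generate_synthetic()] output: the score of
#' image i for class k is the inner product of the image with class k's
#' template (the matched filter under Gaussian noise), squashed to (0, 1) by
#' a logistic centred on half the expected positive response. Used to test
#' metrics and to bound achievable performance.
#'
#' @param images n x s x s array from [generate_synthetic()].
#' @param config The [synthetic_config()] that produced the images.
#' @return An n x C score matrix in (0, 1).
#' @export
bayes_scores <- function(images, config) {
  stopifnot(inherits(config, "cbf_sim_config"))
  s <- dim(images)[2]
  if (s != config$image_size || dim(images)[3] != s) {
    abort("image dimensions do not match the config")
  }
  n <- dim(images)[1]
  flat <- matrix(images, n, s * s)
  out <- matrix(0, n, config$C,
                dimnames = list(NULL, sprintf("Class%02d", seq_len(config$C))))
  for (k in seq_len(config$C)) {
    tpl <- as.vector(class_template(k, s))
    m <- sum(tpl)
    resp <- flat %*% tpl
    mu_pos <- config$signal_strength * m
    sd_resp <- config$noise_sd * sqrt(m)
    scale <- if (sd_resp > 0) sd_resp else 1
    out[, k] <- plogis((resp - mu_pos / 2) / scale)
  }
  out
}

#' Write a synthetic dataset to disk
#'
#' Output directory layout: `images/` with one 8-bit grayscale PNG per
#' sample, `labels.csv` in the chest-radiograph label dialect and
#' `config.yaml` with the generator settings.
#'
#' @param sim A `cbf_sim` list.
#' @param dir Output directory (created if missing).
#' @param write_images Set `FALSE` to skip the PNG files.
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(sim, dir, write_images = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_label_table(sim$label_table, file.path(dir, "labels.csv"))
  cfg <- unclass(sim$config)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  if (write_images) {
    img_dir <- file.path(dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    rng <- range(sim$images)
    span <- if (diff(rng) > 0) diff(rng) else 1
    for (i in seq_len(dim(sim$images)[1])) {
      px <- (sim$images[i, , ] - rng[1]) / span
      png::writePNG(px, file.path(img_dir, sim$label_table$image_id[i]))
    }
  }
  invisible(dir)
}
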