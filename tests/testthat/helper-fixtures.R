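# Shared fixtures built in code.

# The 14-class chest-radiograph count table packaged with cbfocal.
cxr_counts <- function() read_class_counts(cxr14_counts_path())

# Write a small label CSV and return its path.
write_label_fixture <- function(rows, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "labels.csv")
  writeLines(c("Image Index,Finding Labels", rows), path)
  path
}

toy_vocab <- c("Hernia", "Pneumonia", "Edema")

# Independent extended-precision route for the effective-number weight:
# alpha = 1 / sum_{j=0}^{n-1} beta^j (geometric-series identity), summed
# directly rather than through the closed form under test.
alpha_series_oracle <- function(n, beta) {
  if (beta == 0) return(1)
  1 / sum(beta^(0:(n - 1)))
}

# Tiny deterministic weight table for loss tests.
toy_weights <- function(omega_pos, omega_neg, classes = NULL) {
  C <- length(omega_pos)
  classes <- classes %||% sprintf("Class%02d", seq_len(C))
  cbfocal:::new_weight_table(
    tibble::tibble(class = classes, n_pos = NA_integer_, alpha = NA_real_,
                   alpha_norm = NA_real_, omega_pos = omega_pos,
                   omega_neg = omega_neg, clamped = FALSE),
    beta = NA_real_, mode = "manual", floor = 0
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Scalar reference loop for the batch loss: the slow, obviously-correct
# double loop over samples and class nodes.
batch_loss_loop <- function(scores, labels, weights, params, family) {
  total <- 0
  for (i in seq_len(nrow(scores))) {
    for (k in seq_len(ncol(scores))) {
      p <- min(max(scores[i, k], 1e-7), 1 - 1e-7)
      y <- labels[i, k]
      p_t <- if (y == 1) p else 1 - p
      w <- if (y == 1) weights$omega_pos[k] else weights$omega_neg[k]
      l <- -log(p_t)
      if (family == "focal") l <- params$alpha * (1 - p_t)^params$gamma * l
      total <- total + w * l
    }
  }
  total / nrow(scores)
}
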