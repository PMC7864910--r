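#' Focal / cross-entropy loss parameters
#'
#' @param alpha Global balance factor of the focal term, in `[0, 1]`
#'   (the literature recommends `[0.25, 0.75]`; 0.5 is the default used for
#'   the weighted focal experiments).
#' @param gamma Focusing exponent, `>= 0`; `gamma = 0` turns the focal loss
#'   into ordinary cross entropy.
#' @return A list of class `cbf_focal_params`.
#' @export
focal_params <- function(alpha = 0.5, gamma = 1) {
  if (alpha < 0 || alpha > 1) abort("alpha must lie in [0, 1]")
  if (gamma < 0) abort("gamma must be >= 0")
  structure(list(alpha = alpha, gamma = gamma), class = "cbf_focal_params")
}

CLIP_EPS <- 1e-7

clip_probs <- function(p) {
  if (any(p < -1e-6 | p > 1 + 1e-6, na.rm = TRUE)) {
    abort("scores must be probabilities in [0, 1]")
  }
  pmin(pmax(p, CLIP_EPS), 1 - CLIP_EPS)
}

#' Per-node weighted loss
#'
#' Loss of a single sigmoid node with prediction `p` and binary label `y`,
#' in the two-sided p_t convention: `p_t = p` when `y = 1` and `1 - p` when
#' `y = 0`, with the class weight chosen by the label state
#' (`omega_pos_k` for a positive, `omega_neg_k` for a negative). Family
#' `"bce"` gives \eqn{\omega\,(-\log p_t)}; family `"focal"` gives
#' \eqn{\omega\,\alpha\,(1-p_t)^\gamma\,(-\log p_t)}. Probabilities are
#' clipped to `[1e-7, 1 - 1e-7]` before the log. All arguments vectorize.
#'
#' @param p Predicted probabilities in `[0, 1]`.
#' @param y Binary labels.
#' @param omega_pos_k,omega_neg_k Class weights applied at positive/negative
#'   label states.
#' @param params A [focal_params()] list (ignored by family `"bce"`).
#' @param family `"bce"` or `"focal"`.
#' @return Nonnegative numeric vector of per-node losses.
#' @export
#' @examples
#' node_loss(0.5, 1, 1, 1, focal_params(0.5, 1), "focal")  # 0.25 * log 2
node_loss <- function(p, y, omega_pos_k, omega_neg_k,
                      params = focal_params(), family = c("focal", "bce")) {
  family <- match.arg(family)
  if (!all(y %in% c(0, 1))) abort("labels must be binary")
  p <- clip_probs(p)
  p_t <- ifelse(y == 1, p, 1 - p)
  omega <- ifelse(y == 1, omega_pos_k, omega_neg_k)
  base <- -log(p_t)
  if (family == "focal") {
    omega * params$alpha * (1 - p_t)^params$gamma * base
  } else {
    omega * base
  }
}

check_batch_args <- function(scores, labels, weights) {
  scores <- as.matrix(scores)
  labels <- as.matrix(labels)
  if (!identical(dim(scores), dim(labels))) {
    abort("score and label matrices differ in shape")
  }
  if (ncol(scores) != nrow(weights)) {
    abort("weight table does not cover the score columns")
  }
  cn <- colnames(scores)
  if (!is.null(cn) && !identical(cn, weights$class)) {
    abort("class order of scores and weight table disagree")
  }
  list(scores = scores, labels = labels)
}

#' Weighted batch loss over an n x C sigmoid output
#'
#' Per-sample loss is the sum over the C class nodes of [node_loss()], with
#' the weight at each node selected by the ground-truth label state;
#' reduction `"mean"` then averages over samples (batch-size invariant),
#' `"sum"` adds them.
#'
#' @param scores n x C matrix of probabilities.
#' @param labels n x C binary matrix, same shape and class order.
#' @param weights A `cbf_weights` tibble covering the C classes in column
#'   order.
#' @param params A [focal_params()] list.
#' @param family `"focal"` or `"bce"`.
#' @param reduction `"mean"` or `"sum"`.
#' @return A single nonnegative number.
#' @export
batch_loss <- function(scores, labels, weights, params = focal_params(),
                       family = c("focal", "bce"),
                       reduction = c("mean", "sum")) {
  family <- match.arg(family)
  reduction <- match.arg(reduction)
  m <- check_batch_args(scores, labels, weights)
  wp <- matrix(weights$omega_pos, nrow(m$scores), ncol(m$scores), byrow = TRUE)
  wn <- matrix(weights$omega_neg, nrow(m$scores), ncol(m$scores), byrow = TRUE)
  per_node <- node_loss(m$scores, m$labels, wp, wn, params, family)
  total <- sum(per_node)
  if (reduction == "mean") total / nrow(m$scores) else total
}

#' Gradient of the batch loss with respect to the scores
#'
#' Analytic derivative of [batch_loss()] in the clipped region; entries at
#' the clip boundary use the clipped probability, so the gradient is always
#' finite.
#'
#' @inheritParams batch_loss
#' @return An n x C matrix, `d loss / d scores`.
#' @export
batch_loss_grad <- function(scores, labels, weights, params = focal_params(),
                            family = c("focal", "bce"),
                            reduction = c("mean", "sum")) {
  family <- match.arg(family)
  reduction <- match.arg(reduction)
  m <- check_batch_args(scores, labels, weights)
  p <- clip_probs(m$scores)
  y <- m$labels
  wp <- matrix(weights$omega_pos, nrow(p), ncol(p), byrow = TRUE)
  wn <- matrix(weights$omega_neg, nrow(p), ncol(p), byrow = TRUE)
  omega <- ifelse(y == 1, wp, wn)
  p_t <- ifelse(y == 1, p, 1 - p)
  # d p_t / d p = +1 for y = 1, -1 for y = 0
  sgn <- ifelse(y == 1, 1, -1)
  if (family == "bce") {
    dldpt <- -1 / p_t
    g <- omega * dldpt * sgn
  } else {
    a <- params$alpha
    gam <- params$gamma
    q <- 1 - p_t
    # d/dp_t [ q^gamma * (-log p_t) ] = gamma q^(gamma-1) log(p_t) - q^gamma / p_t
    dldpt <- if (gam == 0) {
      -1 / p_t
    } else {
      gam * q^(gam - 1) * log(p_t) - q^gam / p_t
    }
    g <- omega * a * dldpt * sgn
  }
  # outside the clipped region the loss is constant in p
  g[m$scores < CLIP_EPS | m$scores > 1 - CLIP_EPS] <- 0
  if (reduction == "mean") g / nrow(p) else g
}

#' Compare the analytic loss gradient with central finite differences
#'
#' Diagnostic for the loss implementation: perturbs every score entry by
#' `h` and returns the largest absolute relative deviation between the
#' finite-difference quotient and [batch_loss_grad()].
#'
#' @inheritParams batch_loss
#' @param h Step size for central differences.
#' @return Maximum relative deviation (scalar).
#' @export
loss_gradient_check <- function(scores, labels, weights,
                                params = focal_params(),
                                family = c("focal", "bce"), h = 1e-6) {
  family <- match.arg(family)
  scores <- as.matrix(scores)
  g <- batch_loss_grad(scores, labels, weights, params, family)
  num <- matrix(0, nrow(scores), ncol(scores))
  for (i in seq_len(nrow(scores))) {
    for (j in seq_len(ncol(scores))) {
      up <- scores; up[i, j] <- scores[i, j] + h
      dn <- scores; dn[i, j] <- scores[i, j] - h
      num[i, j] <- (batch_loss(up, labels, weights, params, family) -
                      batch_loss(dn, labels, weights, params, family)) / (2 * h)
    }
  }
  scale <- pmax(abs(g), abs(num), 1e-8)
  max(abs(g - num) / scale)
}
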