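#' Effective-number class weight
#'
#' The effective number of samples of a class with `n_k` positives is the
#' saturating sum \eqn{(1-\beta^{n_k})/(1-\beta)}; its reciprocal scaled by
#' \eqn{1-\beta} is the raw class weight
#' \deqn{\alpha_k(\beta) = \frac{1-\beta}{1-\beta^{n_k}}.}
#' \eqn{\beta = 0} gives uniform weights (\eqn{\alpha_k = 1});
#' \eqn{\beta \to 1} recovers inverse-frequency weighting
#' (\eqn{\alpha_k \to 1/n_k}). Evaluated as
#' `(1 - beta) / (-expm1(n * log1p(beta - 1)))` so that \eqn{\beta^{n_k}}
#' near 0 or 1 never degrades precision.
#'
#' @param n_k Positive sample count(s), integer >= 1. Vectorized.
#' @param beta Smoothing hyperparameter in `[0, 1)`.
#' @return Numeric vector of raw weights, same length as `n_k`.
#' @export
#' @examples
#' effective_number_alpha(227, 0.9998)
#' effective_number_alpha(1000, 1 - 1e-9) * 1000  # ~ 1: inverse frequency
effective_number_alpha <- function(n_k, beta) {
  if (length(beta) != 1L || is.na(beta) || beta < 0 || beta >= 1) {
    abort("beta must be a single value in [0, 1)")
  }
  if (any(n_k < 1)) abort("n_k must be >= 1")
  if (beta == 0) return(rep(1, length(n_k)))
  (1 - beta) / (-expm1(n_k * log1p(beta - 1)))
}

#' Sample-count rule for beta
#'
#' The smoothing parameter tied to a sample count N: `beta = (N - 1) / N`,
#' i.e. `1 - 1/N`, so the effective-number sum saturates on the scale of the
#' dataset.
#'
#' @param N Sample count, integer >= 2.
#' @return A single beta in `[0.5, 1)`.
#' @export
#' @examples
#' beta_from_sample_count(50000)  # 0.99998
beta_from_sample_count <- function(N) {
  if (length(N) != 1L || is.na(N) || N < 2) abort("N must be >= 2")
  (N - 1) / N
}

#' Default beta grid
#'
#' The five candidate values used for grid search, expressed as offsets from
#' one: `1 - 2e-6`, `1 - 2e-5`, `1 - 2e-4`, `1 - 7e-4`, `1 - 2e-3`.
#'
#' @return Numeric vector of five betas, increasing in `1 - beta`.
#' @export
default_beta_grid <- function() {
  1 - c(2e-6, 2e-5, 2e-4, 7e-4, 2e-3)
}

#' Normalize raw class weights
#'
#' With \eqn{N(\beta) = \sum_k \alpha_k(\beta)}, mode `"paper-c"` rescales to
#' a mean weight of one, \eqn{\tilde\alpha_k = C\,\alpha_k/N(\beta)} (sum
#' equals the class count C); mode `"sum-to-one"` rescales to
#' \eqn{\alpha_k/N(\beta)} (sum equals 1), which keeps every weight in
#' (0, 1) and hence every derived negative weight positive.
#'
#' @param alpha Positive raw weights, one per class.
#' @param mode `"paper-c"` (default) or `"sum-to-one"`.
#' @return Numeric vector of normalized weights.
#' @export
normalize_alphas <- function(alpha, mode = c("paper-c", "sum-to-one")) {
  mode <- match.arg(mode)
  if (length(alpha) == 0L) abort("empty weight vector")
  if (any(alpha <= 0)) abort("raw weights must be positive")
  s <- sum(alpha)
  if (mode == "paper-c") length(alpha) * alpha / s else alpha / s
}

#' Split a normalized weight into positive and negative pattern weights
#'
#' The positive-pattern weight of class k is its normalized effective-number
#' weight, \eqn{\omega_{k+} = \tilde\alpha_k}; the negative-pattern weight is
#' the complement \eqn{\omega_{k-} = 1 - \omega_{k+}}. Under `"paper-c"`
#' normalization rare classes get \eqn{\tilde\alpha_k > 1}, driving the
#' complement negative; such weights are floored at `floor`, flagged and
#' warned about.
#'
#' @param alpha_norm Normalized weights.
#' @param floor Lower bound for the negative-pattern weight (default 0).
#' @return A tibble with columns `omega_pos`, `omega_neg`, `clamped`.
#' @export
pos_neg_weights <- function(alpha_norm, floor = 0) {
  if (floor < 0) abort("floor must be >= 0")
  omega_pos <- alpha_norm
  omega_neg <- 1 - omega_pos
  clamped <- omega_neg < floor
  if (any(clamped)) {
    warn(paste0(sum(clamped), " negative-pattern weight(s) below ", floor,
                " floored; their class weights exceed 1 after normalization"))
    omega_neg[clamped] <- floor
  }
  tibble::tibble(omega_pos = omega_pos, omega_neg = omega_neg,
                 clamped = clamped)
}

#' Class-balanced positive/negative weight table
#'
#' End-to-end weighting pipeline: effective-number raw weights from the
#' per-class positive counts, normalization, and the positive/negative
#' split. This is the weighting used by [batch_loss()] during training.
#'
#' @param counts A `cbf_counts` tibble (training-split counts; the weighting
#'   is defined on the training set).
#' @param beta Smoothing parameter in `[0, 1)`; default ties it to the total
#'   sample count via [beta_from_sample_count()].
#' @param mode Normalization mode, see [normalize_alphas()].
#' @param floor Negative-weight floor, see [pos_neg_weights()].
#' @return A `cbf_weights` tibble with columns `class`, `n_pos`, `alpha`,
#'   `alpha_norm`, `omega_pos`, `omega_neg`, `clamped`; `beta`, `mode` and
#'   `floor` are stored as attributes.
#' @export
#' @examples
#' counts <- read_class_counts(cxr14_counts_path())
#' class_weights(counts, beta = 0.9998)
class_weights <- function(counts, beta = beta_from_sample_count(counts$total[1L]),
                          mode = c("paper-c", "sum-to-one"), floor = 0) {
  mode <- match.arg(mode)
  if (any(counts$positives < 1L)) {
    abort(paste0("class '", counts$class[counts$positives < 1L][1L],
                 "' has no positive samples; its weight is undefined"))
  }
  alpha <- effective_number_alpha(counts$positives, beta)
  alpha_norm <- normalize_alphas(alpha, mode)
  omega <- pos_neg_weights(alpha_norm, floor)
  new_weight_table(
    tibble::tibble(class = counts$class, n_pos = counts$positives,
                   alpha = alpha, alpha_norm = alpha_norm,
                   omega_pos = omega$omega_pos, omega_neg = omega$omega_neg,
                   clamped = omega$clamped),
    beta = beta, mode = mode, floor = floor
  )
}

new_weight_table <- function(tbl, beta, mode, floor) {
  structure(tbl, beta = beta, mode = mode, floor = floor,
            class = c("cbf_weights", class(tibble::tibble())))
}

#' Prevalence (inverse-frequency) weights
#'
#' The classical weighting: \eqn{\omega_{k+} = (P_k+N_k)/P_k} and
#' \eqn{\omega_{k-} = (P_k+N_k)/N_k}, the reciprocals of the positive and
#' negative prevalences.
#'
#' @param counts A `cbf_counts` tibble with `P_k >= 1` and `N_k >= 1`.
#' @return A `cbf_weights` tibble (omega columns populated; `alpha` columns
#'   `NA` since no effective-number smoothing is involved).
#' @export
prevalence_weights <- function(counts) {
  bad <- counts$positives < 1L | counts$negatives < 1L
  if (any(bad)) {
    abort(paste0("class '", counts$class[bad][1L],
                 "' has an empty positive or negative set"))
  }
  tot <- counts$positives + counts$negatives
  new_weight_table(
    tibble::tibble(class = counts$class, n_pos = counts$positives,
                   alpha = NA_real_, alpha_norm = NA_real_,
                   omega_pos = tot / counts$positives,
                   omega_neg = tot / counts$negatives,
                   clamped = FALSE),
    beta = NA_real_, mode = "prevalence", floor = 0
  )
}

#' Tie the negative-pattern weight to the positive one
#'
#' The class-balanced configuration that ignores the positive/negative split
#' and applies one effective-number weight to both label states:
#' \eqn{\omega_{k-} := \omega_{k+}}. Idempotent.
#'
#' @param weights A `cbf_weights` tibble with `omega_pos` populated.
#' @return A copy with `omega_neg` overwritten and the mode annotated.
#' @export
cui_mode <- function(weights) {
  out <- weights
  out$omega_neg <- out$omega_pos
  out$clamped <- FALSE
  mode <- attr(out, "mode")
  if (!grepl("\\+tied$", mode)) attr(out, "mode") <- paste0(mode, "+tied")
  out
}

#' Read / write a weight table
#'
#' CSV with columns `class,n_pos,alpha,alpha_norm,omega_pos,omega_neg,clamped`
#' preceded by a `#` comment line recording beta, mode and floor, so a
#' written table round-trips including its provenance.
#'
#' @param weights A `cbf_weights` tibble.
#' @param path CSV path.
#' @return `path` invisibly / the re-read `cbf_weights` tibble.
#' @export
write_weight_table <- function(weights, path) {
  hdr <- sprintf("# beta=%.17g mode=%s floor=%.17g",
                 attr(weights, "beta"), attr(weights, "mode"),
                 attr(weights, "floor"))
  body <- readr::format_csv(tibble::as_tibble(weights))
  writeLines(c(hdr, sub("\n$", "", body)), path)
  invisible(path)
}

#' @rdname write_weight_table
#' @export
read_weight_table <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- regmatches(hdr, regexec(
    "beta=([^ ]+) mode=([^ ]+) floor=([^ ]+)", hdr))[[1L]]
  if (length(meta) != 4L) abort("missing weight-table provenance header")
  raw <- readr::read_csv(path, comment = "#", col_types = "ciddddl",
                         progress = FALSE)
  new_weight_table(tibble::as_tibble(raw),
                   beta = as.numeric(meta[2L]), mode = meta[3L],
                   floor = as.numeric(meta[4L]))
}
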