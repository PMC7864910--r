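#' Random-classifier AU-PRC baseline
#'
#' The area under the precision-recall curve attained by a scorer that ranks
#' at random is the positive prevalence, `P / (P + N)`. Unlike the fixed 0.5
#' AUROC baseline it moves with class balance: 0.50 for balanced classes,
#' about 0.09 when negatives outnumber positives tenfold, 0.0020 for a class
#' with 227 positives among 112,120 images.
#'
#' @param P Positive count(s), `>= 1`. Vectorized.
#' @param N Negative count(s), `>= 0`.
#' @return Baseline AU-PRC in (0, 1].
#' @export
#' @examples
#' auprc_baseline(1000, 1000)   # 0.5
#' auprc_baseline(100, 1000)    # ~0.09
auprc_baseline <- function(P, N) {
  if (any(P < 1)) abort("need at least one positive sample")
  if (any(N < 0)) abort("negative count cannot be negative")
  if (any(P + N == 0)) abort("empty sample set")
  P / (P + N)
}

#' Area under the ROC curve
#'
#' Rank-based estimator: the probability that a uniformly drawn positive
#' outscores a uniformly drawn negative, with ties receiving average rank
#' (i.e. counted one half).
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Binary labels, same length.
#' @return AUROC in `[0, 1]`, or `NA` (with a warning) when only one label
#'   state is present.
#' @export
#' @examples
#' auroc(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0))  # 0.75
auroc <- function(scores, labels) {
  if (length(scores) != length(labels)) abort("scores/labels length mismatch")
  if (!all(labels %in% c(0, 1))) abort("labels must be binary")
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  if (P == 0L || N == 0L) {
    warn("AUROC undefined with a single label state; returning NA")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-interpolated average-precision estimator: thresholds descend through
#' the distinct score values and each recall increment contributes its
#' precision, \eqn{AP = \sum_i (R_i - R_{i-1}) P_i}. No trapezoidal
#' interpolation is applied, which avoids the known optimistic bias of
#' linearly interpolated PR curves. Tied scores enter at a single threshold.
#'
#' @inheritParams auroc
#' @return Average precision in `(0, 1]`, or `NA` (with a warning) when no
#'   positive is present.
#' @export
#' @examples
#' auprc(c(0.9, 0.8, 0.4), c(1, 0, 1))  # 0.8333...
auprc <- function(scores, labels) {
  if (length(scores) != length(labels)) abort("scores/labels length mismatch")
  if (!all(labels %in% c(0, 1))) abort("labels must be binary")
  P <- sum(labels == 1)
  if (P == 0L) {
    warn("AU-PRC undefined without positives; returning NA")
    return(NA_real_)
  }
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  tp <- cumsum(y)
  n_seen <- seq_along(y)
  # keep only the last index of each tied-score block
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last]
  n_seen <- n_seen[last]
  precision <- tp / n_seen
  recall <- tp / P
  sum(diff(c(0, recall)) * precision)
}

#' Truncate to a fixed number of decimals
#'
#' Reporting convention for baseline AU-PRC columns: digits beyond the
#' requested precision are dropped, not rounded (2776/112120 = 0.024759
#' reports as 0.0247). Full precision is retained internally everywhere.
#'
#' @param x Numeric vector.
#' @param digits Decimal places kept.
#' @return Truncated values.
#' @export
truncate_decimals <- function(x, digits = 4) {
  trunc(x * 10^digits) / 10^digits
}

#' Per-class and macro evaluation report
#'
#' Computes AUROC, average precision, the prevalence baseline of the
#' evaluation set itself, and the lift (AU-PRC minus its baseline) for each
#' class. Classes without a positive in `labels` get `NA` metrics and are
#' excluded from macro averages, which are unweighted means over the valid
#' classes.
#'
#' @param scores n x C matrix of probabilities (column names = classes).
#' @param labels n x C binary matrix, same shape/order.
#' @param classes Optional class names; defaults to the column names.
#' @return A `cbf_metrics` tibble with columns `class`, `n_pos`, `n_neg`,
#'   `auroc`, `auprc`, `auprc_baseline`, `lift`. Macro averages are
#'   available through [glance.cbf_metrics()].
#' @export
evaluate_scores <- function(scores, labels, classes = colnames(scores)) {
  scores <- as.matrix(scores)
  labels <- as.matrix(labels)
  if (!identical(dim(scores), dim(labels))) {
    abort("score and label matrices differ in shape")
  }
  C <- ncol(scores)
  if (is.null(classes)) classes <- paste0("Class", sprintf("%02d", seq_len(C)))
  rows <- purrr::map(seq_len(C), function(k) {
    y <- labels[, k]
    np <- sum(y == 1)
    nn <- sum(y == 0)
    if (np == 0L || nn == 0L) {
      return(tibble::tibble(class = classes[k], n_pos = np, n_neg = nn,
                            auroc = NA_real_, auprc = NA_real_,
                            auprc_baseline = NA_real_, lift = NA_real_))
    }
    bl <- auprc_baseline(np, nn)
    ap <- auprc(scores[, k], y)
    tibble::tibble(class = classes[k], n_pos = np, n_neg = nn,
                   auroc = auroc(scores[, k], y), auprc = ap,
                   auprc_baseline = bl, lift = ap - bl)
  })
  structure(dplyr::bind_rows(rows),
            class = c("cbf_metrics", class(tibble::tibble())))
}

#' Macro summary of a metric report
#'
#' One-row tibble of unweighted means over classes with at least one
#' positive and one negative.
#'
#' @param x A `cbf_metrics` tibble.
#' @param ... Unused.
#' @return A tibble with `n_classes`, `macro_auroc`, `macro_auprc`,
#'   `macro_auprc_baseline`, `macro_lift`.
#' @export
glance.cbf_metrics <- function(x, ...) {
  valid <- !is.na(x$auroc)
  tibble::tibble(
    n_classes = sum(valid),
    macro_auroc = mean(x$auroc[valid]),
    macro_auprc = mean(x$auprc[valid]),
    macro_auprc_baseline = mean(x$auprc_baseline[valid]),
    macro_lift = mean(x$lift[valid])
  )
}

#' Write / read a metric report
#'
#' CSV with one row per class plus a closing `"Average"` row holding the
#' macro means (computed from full-precision values). JSON output carries
#' the same content as a list.
#'
#' @param report A `cbf_metrics` tibble.
#' @param path Output path; format chosen by extension (`.csv` or `.json`).
#' @return `path` invisibly; `read_metric_report()` returns the per-class
#'   `cbf_metrics` tibble (the Average row is recomputed, not trusted).
#' @export
write_metric_report <- function(report, path) {
  g <- glance.cbf_metrics(report)
  avg <- tibble::tibble(class = "Average", n_pos = NA_integer_,
                        n_neg = NA_integer_, auroc = g$macro_auroc,
                        auprc = g$macro_auprc,
                        auprc_baseline = g$macro_auprc_baseline,
                        lift = g$macro_lift)
  full <- dplyr::bind_rows(tibble::as_tibble(report), avg)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(full, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  } else {
    readr::write_csv(full, path, progress = FALSE)
  }
  invisible(path)
}

#' @rdname write_metric_report
#' @export
read_metric_report <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_csv(path, col_types = "ciidddd", progress = FALSE)
  }
  raw <- raw[raw$class != "Average", , drop = FALSE]
  raw$n_pos <- as.integer(raw$n_pos)
  raw$n_neg <- as.integer(raw$n_neg)
  structure(tibble::as_tibble(raw),
            class = c("cbf_metrics", class(tibble::tibble())))
}
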