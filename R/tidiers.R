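#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a training fit
#'
#' @param x A `cbf_fit`.
#' @param ... Unused.
#' @return The per-epoch history tibble (stage, epoch, training loss,
#'   validation macro AUROC and AU-PRC).
#' @export
tidy.cbf_fit <- function(x, ...) x$history

#' @rdname tidy.cbf_fit
#' @export
tidy.cbf_two_stage <- function(x, ...) x$history

#' One-row summary of a training fit
#'
#' @param x A `cbf_fit`.
#' @param ... Unused.
#' @return Tibble with the stage, best epoch, best validation macro AUROC,
#'   loss family and weighting mode.
#' @export
glance.cbf_fit <- function(x, ...) {
  w <- x$loss$weights
  tibble::tibble(
    stage = x$plan$stage_index,
    input_size = x$plan$input_size,
    batch_size = x$plan$batch_size,
    best_epoch = x$best_epoch,
    best_val_macro_auroc = x$best_val_auroc,
    family = x$loss$family,
    weight_mode = if (is.null(w)) "unit" else attr(w, "mode")
  )
}

#' @rdname glance.cbf_fit
#' @export
glance.cbf_two_stage <- function(x, ...) {
  out <- dplyr::bind_rows(purrr::map(x$stages, glance.cbf_fit))
  out$best <- seq_len(nrow(out)) == x$best_stage
  out
}

#' Tidy a metric report
#'
#' @param x A `cbf_metrics` tibble.
#' @param ... Unused.
#' @return The underlying per-class tibble.
#' @export
tidy.cbf_metrics <- function(x, ...) tibble::as_tibble(x)

#' Tidy a weight table
#'
#' @param x A `cbf_weights` tibble.
#' @param ... Unused.
#' @return The per-class tibble with `beta` and `mode` as columns.
#' @export
tidy.cbf_weights <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$beta <- attr(x, "beta")
  out$mode <- attr(x, "mode")
  out
}
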