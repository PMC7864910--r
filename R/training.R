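#' Plan a training stage
#'
#' One stage of the progressive-image-resizing protocol: an input
#' resolution, a batch size, an epoch budget, an optimizer and optionally a
#' warm-start checkpoint from the previous stage.
#'
#' @param stage_index 1 or 2 (a third stage is accepted but off by default
#'   in [run_two_stage()], since extra stages saturate quickly).
#' @param input_size Side length the images are resized to.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch budget, `>= 1`.
#' @param optimizer `"adam"` or `"ranger"`.
#' @param lr Learning rate.
#' @param patience Early-stopping patience in epochs on validation macro
#'   AUROC (`Inf` disables).
#' @param warm_start `NULL` or a checkpoint list from a previous stage.
#' @return A list of class `cbf_stage_plan`.
#' @export
stage_plan <- function(stage_index = 1L, input_size = 32, batch_size = 32,
                       max_epochs = 6, optimizer = "adam", lr = 1e-2,
                       patience = Inf, warm_start = NULL) {
  if (max_epochs < 1) abort("max_epochs must be >= 1")
  if (input_size < 16) abort("input_size must be >= 16")
  if (batch_size < 1) abort("batch_size must be >= 1")
  structure(list(stage_index = as.integer(stage_index),
                 input_size = as.integer(input_size),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 optimizer = optimizer, lr = lr, patience = patience,
                 warm_start = warm_start),
            class = "cbf_stage_plan")
}

#' Derive the next progressive-resizing stage
#'
#' The default doubling rule: the follow-up stage doubles the input size and
#' halves the batch size, warm-starting from the given checkpoint. The
#' learning rate drops by `lr_decay` because the follow-up stage is a
#' fine-tuning pass: restarting the optimizer at the full rate on a
#' warm-started model can destroy the checkpoint it inherits before the
#' first validation snapshot.
#'
#' @param plan The previous `cbf_stage_plan`.
#' @param warm_start Checkpoint to start from.
#' @param lr_decay Multiplier on the previous stage's learning rate.
#' @return A `cbf_stage_plan` for the next stage.
#' @export
next_stage_plan <- function(plan, warm_start = NULL, lr_decay = 0.25) {
  stage_plan(stage_index = plan$stage_index + 1L,
             input_size = plan$input_size * 2L,
             batch_size = max(1L, plan$batch_size %/% 2L),
             max_epochs = plan$max_epochs, optimizer = plan$optimizer,
             lr = plan$lr * lr_decay, patience = plan$patience,
             warm_start = warm_start)
}

#' Loss configuration block
#'
#' @param family `"focal"` or `"bce"`.
#' @param alpha,gamma Focal parameters, see [focal_params()].
#' @param weights A `cbf_weights` tibble, or `NULL` for unweighted training
#'   (all weights 1 on both label states).
#' @return A list of class `cbf_loss_config`.
#' @export
loss_config <- function(family = c("focal", "bce"), alpha = 0.5, gamma = 1,
                        weights = NULL) {
  family <- match.arg(family)
  structure(list(family = family, params = focal_params(alpha, gamma),
                 weights = weights),
            class = "cbf_loss_config")
}

unit_weights <- function(classes) {
  new_weight_table(
    tibble::tibble(class = classes, n_pos = NA_integer_, alpha = NA_real_,
                   alpha_norm = NA_real_, omega_pos = 1, omega_neg = 1,
                   clamped = FALSE),
    beta = NA_real_, mode = "unit", floor = 0
  )
}

#' Train one stage
#'
#' Resizes the images to the stage resolution, extracts backbone features
#' once, then runs minibatch gradient descent on the weighted loss. After
#' every epoch the validation split is scored and summarized into a metric
#' report; the checkpoint with the best validation macro AUROC is kept.
#' Deterministic given `seed` (shuffling and initialization are the only
#' random elements).
#'
#' @param model A `cbf_model`, typically [tiny_backbone()].
#' @param images n x h x w array at native resolution.
#' @param labels n x C binary label matrix.
#' @param train_idx,val_idx Row indices of the training and validation
#'   splits.
#' @param plan A [stage_plan()].
#' @param loss A [loss_config()].
#' @param seed Integer seed for shuffling.
#' @param feature_cache Optional environment used to memoize the
#'   deterministic backbone features per input size (keyed by
#'   `"<grid>x<input_size>"`), shared safely across stages and across runs
#'   on the same images.
#' @return A list of class `cbf_fit`: `model` (best checkpoint), `history`
#'   (per-epoch tibble with training loss and validation macro metrics),
#'   `best_epoch`, `plan`, `loss`, `classes`.
#' @export
train_stage <- function(model, images, labels, train_idx, val_idx, plan,
                        loss = loss_config(), seed = 1L,
                        feature_cache = NULL) {
  if (length(train_idx) == 0L) abort("empty training set")
  classes <- colnames(labels)
  weights <- loss$weights %||% unit_weights(classes)
  if (!identical(weights$class, classes)) {
    abort("weight table classes do not match the label columns")
  }
  if (!is.null(plan$warm_start)) {
    ws <- plan$warm_start
    if (!identical(dim(ws$params$W2), dim(model$params$W2)) ||
        !identical(dim(ws$params$W1), dim(model$params$W1))) {
      abort("warm-start checkpoint incompatible with the model")
    }
    model$params <- ws$params
  }
  key <- paste0(model$grid, "x", plan$input_size)
  feats <- if (!is.null(feature_cache) && !is.null(feature_cache[[key]])) {
    feature_cache[[key]]
  } else {
    f <- backbone_features(model, resize_images(images, plan$input_size))
    if (!is.null(feature_cache)) feature_cache[[key]] <- f
    f
  }
  x_tr <- feats[train_idx, , drop = FALSE]
  y_tr <- labels[train_idx, , drop = FALSE]
  x_va <- feats[val_idx, , drop = FALSE]
  y_va <- labels[val_idx, , drop = FALSE]

  opt <- make_optimizer(plan$optimizer, lr = plan$lr)
  state <- opt$init(model$params)
  n_tr <- nrow(x_tr)
  bs <- min(plan$batch_size, n_tr)
  best <- list(auroc = -Inf, params = model$params, epoch = 0L)
  history <- list()
  stall <- 0L
  for (epoch in seq_len(plan$max_epochs)) {
    ord <- withr::with_seed(seed + epoch, sample.int(n_tr))
    starts <- seq(1, n_tr, by = bs)
    epoch_loss <- 0
    for (s0 in starts) {
      idx <- ord[s0:min(s0 + bs - 1, n_tr)]
      xb <- x_tr[idx, , drop = FALSE]
      yb <- y_tr[idx, , drop = FALSE]
      fwd <- backbone_forward(model, xb)
      l <- batch_loss(fwd$p, yb, weights, loss$params, loss$family)
      dLdp <- batch_loss_grad(fwd$p, yb, weights, loss$params, loss$family)
      grads <- backbone_backward(model, xb, fwd, dLdp)
      upd <- opt$step(state, model$params, grads)
      state <- upd$state
      model$params <- upd$params
      epoch_loss <- epoch_loss + l * length(idx)
    }
    epoch_loss <- epoch_loss / n_tr
    val_report <- evaluate_scores(predict_backbone(model, x_va), y_va,
                                  classes = classes)
    g <- glance.cbf_metrics(val_report)
    history[[epoch]] <- tibble::tibble(
      stage = plan$stage_index, epoch = epoch, train_loss = epoch_loss,
      val_macro_auroc = g$macro_auroc, val_macro_auprc = g$macro_auprc
    )
    if (!is.na(g$macro_auroc) && g$macro_auroc > best$auroc) {
      best <- list(auroc = g$macro_auroc, params = model$params,
                   epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= plan$patience) break
    }
  }
  model$params <- best$params
  structure(list(model = model, history = dplyr::bind_rows(history),
                 best_epoch = best$epoch, best_val_auroc = best$auroc,
                 plan = plan, loss = loss, classes = classes),
            class = "cbf_fit")
}

#' Two-stage progressive-image-resizing training
#'
#' Runs stage 1 at the base resolution, derives stage 2 by the
#' double-size/half-batch rule, warm-starts it from stage 1's best
#' checkpoint, and returns both histories with the overall best model
#' (higher validation macro AUROC of the two stage bests). The second pass
#' at doubled resolution acts both as continued training and as a
#' resolution augmentation, which is what lets it squeeze out extra
#' performance without overfitting the base resolution.
#'
#' @inheritParams train_stage
#' @param stage1 The stage-1 [stage_plan()].
#' @param n_stages Number of stages (default 2; a third stage rarely helps).
#' @return A list of class `cbf_two_stage`: `stages` (list of `cbf_fit`),
#'   `history` (bound tibble), `best_stage`, `model`.
#' @export
run_two_stage <- function(model, images, labels, train_idx, val_idx,
                          stage1 = stage_plan(), loss = loss_config(),
                          seed = 1L, n_stages = 2L, feature_cache = NULL) {
  fits <- vector("list", n_stages)
  plan <- stage1
  for (s in seq_len(n_stages)) {
    fits[[s]] <- train_stage(model, images, labels, train_idx, val_idx,
                             plan, loss, seed = seed + 1000L * (s - 1L),
                             feature_cache = feature_cache)
    if (s < n_stages) {
      plan <- next_stage_plan(plan, warm_start = fits[[s]]$model)
    }
  }
  best_stage <- which.max(purrr::map_dbl(fits, "best_val_auroc"))
  structure(list(stages = fits,
                 history = dplyr::bind_rows(purrr::map(fits, "history")),
                 best_stage = best_stage,
                 model = fits[[best_stage]]$model),
            class = "cbf_two_stage")
}

#' Grid search over the smoothing parameter beta
#'
#' Trains one stage-1 model per candidate beta (deduplicated, with a
#' warning if duplicates are dropped) under a fixed plan and selects the
#' beta with the best validation macro AUROC; ties break toward the larger
#' beta.
#'
#' @inheritParams train_stage
#' @param counts Training-split `cbf_counts` used to build each beta's
#'   weight table.
#' @param betas Candidate betas in `[0, 1)`; default [default_beta_grid()].
#' @param mode,floor Weight-table options, see [class_weights()].
#' @param family,alpha,gamma Loss options, see [loss_config()].
#' @return A list: `best_beta`, `results` (per-beta tibble with validation
#'   macro AUROC/AU-PRC), `fits`.
#' @export
grid_search_beta <- function(model, images, labels, train_idx, val_idx,
                             counts, betas = default_beta_grid(),
                             plan = stage_plan(), mode = "paper-c",
                             floor = 0, family = "focal", alpha = 0.5,
                             gamma = 1, seed = 1L) {
  if (length(betas) == 0L) abort("empty beta grid")
  if (any(betas < 0 | betas >= 1)) abort("betas must lie in [0, 1)")
  if (anyDuplicated(betas)) {
    warn("duplicate betas dropped from the grid")
    betas <- unique(betas)
  }
  fits <- purrr::map(betas, function(b) {
    w <- suppressWarnings(class_weights(counts, beta = b, mode = mode,
                                        floor = floor))
    train_stage(model, images, labels, train_idx, val_idx, plan,
                loss_config(family, alpha, gamma, weights = w), seed = seed)
  })
  results <- tibble::tibble(
    beta = betas,
    val_macro_auroc = purrr::map_dbl(fits, "best_val_auroc"),
    val_macro_auprc = purrr::map_dbl(
      fits, ~ max(.x$history$val_macro_auprc, na.rm = TRUE))
  )
  # ties toward larger beta
  ord <- order(results$val_macro_auroc, results$beta, decreasing = TRUE)
  list(best_beta = results$beta[ord[1L]], results = results, fits = fits)
}

#' Save / load a training checkpoint
#'
#' Single-file serialized parameters plus the model geometry and class
#' vocabulary, so a reloaded checkpoint evaluates identically.
#'
#' @param fit A `cbf_fit` (or `cbf_two_stage`).
#' @param path Output file.
#' @return `path` invisibly; `load_checkpoint()` returns a `cbf_model` with
#'   the stored vocabulary in the `"classes"` attribute.
#' @export
save_checkpoint <- function(fit, path) {
  model <- if (inherits(fit, "cbf_two_stage")) fit$model else fit$model
  classes <- if (inherits(fit, "cbf_two_stage")) {
    fit$stages[[1L]]$classes
  } else {
    fit$classes
  }
  saveRDS(list(params = model$params, grid = model$grid,
               hidden = model$hidden, act = model$act,
               n_classes = model$n_classes, classes = classes), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- structure(list(params = ck$params, grid = ck$grid,
                          hidden = ck$hidden, act = ck$act,
                          n_classes = ck$n_classes),
                     class = "cbf_model")
  attr(model, "classes") <- ck$classes
  model
}
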