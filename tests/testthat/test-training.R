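# Small shared training fixture: one synthetic dataset + split, built once.
train_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(n_samples = 400, image_size = 32,
                              prevalence = c(0.08, 0.2, 0.35),
                              noise_sd = 2, seed = 12)
      sim <- generate_synthetic(cfg)
      split <- make_split(sim$label_table,
                          fractions = c(train = 0.75, val = 0.25), seed = 12)
      cache <<- list(sim = sim,
                     tr = which(split$partition == "train"),
                     va = which(split$partition == "val"))
    }
    cache
  }
})

test_that("activations match their definitions", {
  expect_equal(activation(7, "relu6"), 6)
  expect_equal(activation(-3, "relu"), 0)
  expect_equal(activation(-3, "relu6"), 0)
  expect_equal(activation(0, "swish"), 0)
  x <- seq(-4, 4, by = 0.5)
  expect_equal(activation(x, "swish"), x * plogis(x))
  expect_equal(activation(x, "relu"), pmax(0, x))
  expect_error(activation(1, "gelu"), "arg")
})

test_that("stage plans encode the double-size half-batch rule", {
  p1 <- stage_plan(input_size = 32, batch_size = 32, max_epochs = 3)
  p2 <- next_stage_plan(p1)
  expect_identical(p2$input_size, 64L)
  expect_identical(p2$batch_size, 16L)
  expect_identical(p2$stage_index, 2L)
  expect_error(stage_plan(max_epochs = 0), "max_epochs")
})

test_that("a training stage learns, logs and selects by validation AUROC", {
  fx <- train_fixture()
  model <- tiny_backbone(3, seed = 1)
  plan <- stage_plan(input_size = 16, batch_size = 32, max_epochs = 4)
  fit <- train_stage(model, fx$sim$images, fx$sim$labels, fx$tr, fx$va,
                     plan, loss_config("focal"), seed = 1)
  expect_s3_class(fit, "cbf_fit")
  expect_identical(nrow(fit$history), 4L)
  # training loss decreases over the run
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
  expect_equal(fit$best_val_auroc,
               max(fit$history$val_macro_auroc))
  # determinism
  fit2 <- train_stage(model, fx$sim$images, fx$sim$labels, fx$tr, fx$va,
                      plan, loss_config("focal"), seed = 1)
  expect_identical(fit$history, fit2$history)
  expect_error(train_stage(model, fx$sim$images, fx$sim$labels, integer(0),
                           fx$va, plan, loss_config("focal")), "empty")
})

test_that("batches larger than the dataset degrade to single-batch epochs", {
  fx <- train_fixture()
  model <- tiny_backbone(3, seed = 2)
  plan <- stage_plan(input_size = 16, batch_size = 10000, max_epochs = 2)
  fit <- train_stage(model, fx$sim$images, fx$sim$labels, fx$tr, fx$va,
                     plan, loss_config("bce"), seed = 2)
  expect_identical(nrow(fit$history), 2L)
})

test_that("the first batch of an unweighted run matches plain BCE", {
  fx <- train_fixture()
  model <- tiny_backbone(3, seed = 3)
  images16 <- resize_images(fx$sim$images, 16)
  feats <- backbone_features(model, images16)
  idx <- fx$tr[1:32]
  p <- predict_backbone(model, feats[idx, , drop = FALSE])
  y <- fx$sim$labels[idx, ]
  w <- cbfocal:::unit_weights(colnames(y))
  ref <- -mean(rowSums(y * log(pmax(p, 1e-7)) +
                         (1 - y) * log(pmax(1 - p, 1e-7))))
  expect_equal(batch_loss(p, y, w, focal_params(1, 0), "focal"), ref,
               tolerance = 1e-6)
  expect_equal(batch_loss(p, y, w, family = "bce"), ref, tolerance = 1e-6)
})

test_that("two-stage training derives stage 2 and warm-starts from stage 1", {
  fx <- train_fixture()
  model <- tiny_backbone(3, seed = 4)
  two <- run_two_stage(model, fx$sim$images, fx$sim$labels, fx$tr, fx$va,
                       stage1 = stage_plan(input_size = 16, batch_size = 32,
                                           max_epochs = 3),
                       loss = loss_config("focal"), seed = 4)
  expect_length(two$stages, 2)
  expect_identical(two$stages[[2]]$plan$input_size, 32L)
  expect_identical(two$stages[[2]]$plan$batch_size, 16L)
  expect_identical(unique(two$history$stage), c(1L, 2L))
  # warm start: stage 2 begins from stage 1's best parameters
  ws <- two$stages[[2]]$plan$warm_start
  expect_identical(ws$params, two$stages[[1]]$model$params)
  # incompatible warm start is rejected
  other <- tiny_backbone(3, grid = 4, seed = 1)
  bad <- stage_plan(warm_start = other)
  expect_error(train_stage(model, fx$sim$images, fx$sim$labels, fx$tr,
                           fx$va, bad, loss_config("focal")),
               "incompatible")
})

test_that("warm-started stage 2 starts better than a cold start", {
  fx <- train_fixture()
  wins <- sapply(1:5, function(seed) {
    model <- tiny_backbone(3, seed = seed)
    s1 <- train_stage(model, fx$sim$images, fx$sim$labels, fx$tr, fx$va,
                      stage_plan(input_size = 16, batch_size = 32,
                                 max_epochs = 3),
                      loss_config("bce"), seed = seed)
    p2 <- stage_plan(stage_index = 2, input_size = 32, batch_size = 16,
                     max_epochs = 1, warm_start = s1$model)
    warm <- train_stage(model, fx$sim$images, fx$sim$labels, fx$tr, fx$va,
                        p2, loss_config("bce"), seed = seed)
    cold <- train_stage(model, fx$sim$images, fx$sim$labels, fx$tr, fx$va,
                        stage_plan(stage_index = 2, input_size = 32,
                                   batch_size = 16, max_epochs = 1),
                        loss_config("bce"), seed = seed)
    warm$history$val_macro_auroc[1] >= cold$history$val_macro_auroc[1]
  })
  expect_gte(sum(wins), 3)
})

test_that("checkpoints reproduce validation metrics exactly", {
  fx <- train_fixture()
  model <- tiny_backbone(3, seed = 5)
  fit <- train_stage(model, fx$sim$images, fx$sim$labels, fx$tr, fx$va,
                     stage_plan(input_size = 16, batch_size = 32,
                                max_epochs = 2),
                     loss_config("focal"), seed = 5)
  feats <- backbone_features(fit$model, resize_images(fx$sim$images, 16))
  before <- evaluate_scores(
    predict_backbone(fit$model, feats[fx$va, , drop = FALSE]),
    fx$sim$labels[fx$va, ], classes = fit$classes)
  path <- file.path(withr::local_tempdir(), "ck.rds")
  save_checkpoint(fit, path)
  re <- load_checkpoint(path)
  expect_identical(attr(re, "classes"), fit$classes)
  after <- evaluate_scores(
    predict_backbone(re, feats[fx$va, , drop = FALSE]),
    fx$sim$labels[fx$va, ], classes = fit$classes)
  expect_identical(before$auroc, after$auroc)
  expect_identical(before$auprc, after$auprc)
})

test_that("beta grid search returns one winner per unique beta", {
  fx <- train_fixture()
  counts <- count_classes(fx$sim$label_table[fx$tr, ],
                          vocabulary = colnames(fx$sim$labels))
  model <- tiny_backbone(3, seed = 6)
  plan <- stage_plan(input_size = 16, batch_size = 64, max_epochs = 2)
  gs <- grid_search_beta(model, fx$sim$images, fx$sim$labels, fx$tr, fx$va,
                         counts, betas = c(0.9, 0.999), plan = plan, seed = 6)
  expect_identical(nrow(gs$results), 2L)
  expect_true(gs$best_beta %in% c(0.9, 0.999))
  expect_identical(
    gs$best_beta,
    gs$results$beta[order(gs$results$val_macro_auroc, gs$results$beta,
                          decreasing = TRUE)][1])
  single <- grid_search_beta(model, fx$sim$images, fx$sim$labels, fx$tr,
                             fx$va, counts, betas = 0.99, plan = plan,
                             seed = 6)
  expect_identical(single$best_beta, 0.99)
  expect_warning(
    grid_search_beta(model, fx$sim$images, fx$sim$labels, fx$tr, fx$va,
                     counts, betas = c(0.9, 0.9), plan = plan, seed = 6),
    "duplicate")
  expect_error(
    grid_search_beta(model, fx$sim$images, fx$sim$labels, fx$tr, fx$va,
                     counts, betas = numeric(0), plan = plan), "empty")
})

test_that("optimizers step in the descent direction on a quadratic", {
  # minimize f(w) = sum(w^2)/2; gradient = w
  for (nm in c("adam", "ranger")) {
    opt <- make_optimizer(nm, lr = 0.1)
    params <- list(w = c(3, -2))
    state <- opt$init(params)
    for (i in 1:500) {
      upd <- opt$step(state, params, list(w = params$w))
      state <- upd$state
      params <- upd$params
    }
    expect_lt(sum(params$w^2), 1e-3)
  }
})

test_that("fits expose tidy/glance summaries", {
  fx <- train_fixture()
  model <- tiny_backbone(3, seed = 7)
  fit <- train_stage(model, fx$sim$images, fx$sim$labels, fx$tr, fx$va,
                     stage_plan(input_size = 16, batch_size = 64,
                                max_epochs = 2),
                     loss_config("bce"), seed = 7)
  td <- tidy(fit)
  expect_true(all(c("epoch", "train_loss", "val_macro_auroc") %in% names(td)))
  gl <- glance(fit)
  expect_identical(gl$family, "bce")
  expect_identical(gl$weight_mode, "unit")
})
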