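test_that("prevalence weights are the inverse class frequencies", {
  balanced <- prevalence_weights(new_class_counts("x", 50, 100))
  expect_equal(balanced$omega_pos, 2)
  expect_equal(balanced$omega_neg, 2)

  hernia <- prevalence_weights(new_class_counts("Hernia", 227, 112120))
  expect_equal(hernia$omega_pos, 112120 / 227, tolerance = 1e-12)
  expect_equal(hernia$omega_pos, 493.92, tolerance = 1e-4)
  expect_equal(hernia$omega_neg, 1.0020, tolerance = 1e-4)

  expect_error(prevalence_weights(new_class_counts("z", 0, 10)), "z")
})

test_that("effective-number weight matches its limits and frozen values", {
  expect_equal(effective_number_alpha(1, 0.77), 1)
  expect_equal(effective_number_alpha(12345, 0), 1)
  # frozen from a 60-digit evaluation of (1-b)/(1-b^n)
  expect_equal(effective_number_alpha(227, 0.9998), 4.50560251663560e-3,
               tolerance = 1e-12)
  # beta -> 1 recovers inverse frequency
  expect_equal(effective_number_alpha(1000, 1 - 1e-9) * 1000, 1,
               tolerance = 1e-4)
  expect_error(effective_number_alpha(10, 1), "beta")
  expect_error(effective_number_alpha(0, 0.5), "n_k")
})

test_that("effective-number weight is monotone in n and beta", {
  ns <- c(1, 2, 5, 10, 100, 1000, 10000)
  for (beta in c(0.3, 0.9, 0.9998)) {
    a <- effective_number_alpha(ns, beta)
    # strictly decreasing until beta^n saturates below double precision
    expect_true(all(diff(a) <= 0), info = paste("beta", beta))
    expect_true(all(diff(a[1:4]) < 0), info = paste("beta", beta))
  }
  for (n in c(2, 10, 500)) {
    a <- sapply(c(0.1, 0.5, 0.9, 0.999), effective_number_alpha, n_k = n)
    expect_true(all(diff(a) < 0), info = paste("n", n))
  }
})

test_that("closed form agrees with the series oracle on random (n, beta)", {
  withr::with_seed(42, {
    ns <- sample(1:3000, 1000, replace = TRUE)
    betas <- runif(1000, 0, 0.9999)
  })
  got <- mapply(function(n, b) effective_number_alpha(n, b), ns, betas)
  want <- mapply(alpha_series_oracle, ns, betas)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("normalization modes hit their sum identities", {
  counts <- cxr_counts()
  alpha <- effective_number_alpha(counts$positives, 0.9998)
  apc <- normalize_alphas(alpha, "paper-c")
  as1 <- normalize_alphas(alpha, "sum-to-one")
  expect_equal(sum(apc), 14, tolerance = 1e-9)
  expect_equal(sum(as1), 1, tolerance = 1e-9)
  # frozen from the same 60-digit evaluation
  expect_equal(apc[counts$class == "Hernia"], 6.451079153707162,
               tolerance = 1e-9)
  expect_equal(apc[counts$class == "Infiltration"], 0.2918152417341092,
               tolerance = 1e-9)
  # symmetry: equal raw weights normalize to 1 under paper-c
  expect_equal(normalize_alphas(rep(0.37, 6), "paper-c"), rep(1, 6))
  expect_error(normalize_alphas(numeric(0)), "empty")
})

test_that("positive/negative split is complementary and clamps below floor", {
  w <- pos_neg_weights(c(0.5, 0.292))
  expect_equal(w$omega_pos + w$omega_neg, c(1, 1))
  expect_equal(w$omega_neg[2], 0.708)
  expect_false(any(w$clamped))

  expect_warning(wc <- pos_neg_weights(c(6.45, 0.3), floor = 0), "floored")
  expect_equal(wc$omega_neg[1], 0)
  expect_true(wc$clamped[1])
  expect_false(wc$clamped[2])
})

test_that("beta follows the (N-1)/N sample-count rule", {
  expect_equal(beta_from_sample_count(2), 0.5)
  expect_equal(beta_from_sample_count(10), 0.9)
  expect_equal(beta_from_sample_count(50000), 1 - 2e-5)
  expect_error(beta_from_sample_count(1), "N")
  # the packaged grid brackets the rule on either side
  expect_equal(default_beta_grid(),
               c(1 - 2e-6, 1 - 2e-5, 1 - 2e-4, 1 - 7e-4, 1 - 2e-3))
})

test_that("beta = 0 collapses the scheme to the degenerate corner", {
  counts <- new_class_counts(letters[1:4], c(3, 10, 50, 200), 300)
  w <- suppressWarnings(class_weights(counts, beta = 0))
  expect_equal(w$alpha, rep(1, 4))
  expect_equal(w$alpha_norm, rep(1, 4))
  expect_equal(w$omega_pos, rep(1, 4))
  expect_equal(w$omega_neg, rep(0, 4))
})

test_that("tying the negative weight to the positive one is idempotent", {
  counts <- cxr_counts()
  w <- suppressWarnings(class_weights(counts, beta = 0.9998))
  t1 <- cui_mode(w)
  expect_equal(t1$omega_neg, t1$omega_pos)
  expect_identical(cui_mode(t1)$omega_neg, t1$omega_neg)
  expect_match(attr(t1, "mode"), "\\+tied$")
  expect_match(attr(cui_mode(t1), "mode"), "^[^+]+\\+tied$")
  # the complementarity invariant is deliberately broken here
  expect_false(isTRUE(all.equal(t1$omega_pos + t1$omega_neg, rep(1, 14))))
})

test_that("the full weight pipeline round-trips through CSV", {
  counts <- cxr_counts()
  w <- suppressWarnings(class_weights(counts, beta = 0.9998, floor = 0))
  expect_true(w$clamped[w$class == "Hernia"])
  expect_equal(sum(w$alpha_norm), 14, tolerance = 1e-9)
  unclamped <- !w$clamped
  expect_equal(w$omega_pos[unclamped] + w$omega_neg[unclamped],
               rep(1, sum(unclamped)))
  path <- file.path(withr::local_tempdir(), "weights.csv")
  write_weight_table(w, path)
  back <- read_weight_table(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(w),
               tolerance = 1e-12)
  expect_equal(attr(back, "beta"), 0.9998)
  expect_identical(attr(back, "mode"), "paper-c")
})
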