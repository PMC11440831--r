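test_that("filter progression follows the doubling rule", {
  cfg <- unet_config(depth = 4L, base_filters = 64L,
                     input_shape = c(1088L, 512L), n_classes = 2L)
  # expand the stated rule independently: double per level down
  expected <- 64L * as.integer(2^(0:4))
  expect_identical(unet_filter_sequence(cfg), expected)
  expect_identical(tail(expected, 1), 1024L)  # bottleneck
  cfg32 <- unet_config(4L, 32L, c(512L, 512L), 5L)
  expect_identical(unet_filter_sequence(cfg32)[1], 32L)
})

test_that("indivisible input sizes are a configuration error", {
  expect_error(unet_config(4L, 8L, c(100L, 64L), 2L), "divisible")
  expect_silent(unet_config(4L, 8L, c(96L, 64L), 2L))
})

test_that("forward pass preserves spatial shape and normalizes probabilities", {
  cfg <- unet_config(depth = 3L, base_filters = 4L,
                     input_shape = c(48L, 24L), n_classes = 5L, seed = 2L)
  m <- build_unet(cfg)
  x <- matrix(runif(48 * 24), 48, 24)
  p <- unet_predict(m, x)
  expect_equal(dim(p), c(48, 24, 5))
  sums <- apply(p, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  expect_true(all(p >= 0))
})

test_that("dice loss matches its closed forms", {
  t <- matrix(0, 8, 8); t[3:6, 3:6] <- 1
  expect_equal(dice_loss(t, t), 0)                 # identity -> 0 exactly
  disj <- 1 - t
  expect_equal(dice_loss(disj, t, smooth = 0), 1)  # disjoint -> 1
  expect_gt(dice_loss(disj, t, smooth = 1), 0.98)
  half <- matrix(0, 8, 8); half[1:4, ] <- 1        # half the pixels
  expect_equal(dice_loss(matrix(0.5, 8, 8), half, smooth = 0), 0.5)
  # both empty -> 0 by the smoothing convention
  expect_equal(dice_loss(matrix(0, 4, 4), matrix(0, 4, 4)), 0)
})

test_that("dice loss is bounded and decreases as overlap grows", {
  # enumerate all pairs of 4-pixel binary masks against a brute-force
  # oracle, and check monotonicity at fixed totals
  combos <- expand.grid(rep(list(0:1), 4))
  for (i in seq_len(nrow(combos))) {
    for (j in seq_len(nrow(combos))) {
      a <- matrix(as.numeric(combos[i, ]), 2, 2)
      b <- matrix(as.numeric(combos[j, ]), 2, 2)
      l <- dice_loss(a, b)
      oracle <- 1 - (2 * sum(a * b) + 1) / (sum(a) + sum(b) + 1)
      expect_equal(l, oracle)
      expect_gte(l, 0); expect_lte(l, 1)
    }
  }
  # same totals (|A| = |B| = 2), increasing overlap 0, 1, 2
  a <- matrix(c(1, 1, 0, 0), 2, 2)
  l0 <- dice_loss(matrix(c(0, 0, 1, 1), 2, 2), a)
  l1 <- dice_loss(matrix(c(1, 0, 1, 0), 2, 2), a)
  l2 <- dice_loss(a, a)
  expect_true(l0 > l1 && l1 > l2)
})

test_that("random probability maps agree with the brute-force multi-class oracle", {
  set.seed(3)
  p <- array(runif(6 * 6 * 3), c(6, 6, 3))
  for (i in 1:6) for (j in 1:6) p[i, j, ] <- p[i, j, ] / sum(p[i, j, ])
  y <- to_onehot(matrix(sample(0:2, 36, TRUE), 6, 6), 3)
  got <- dice_loss(p, y, smooth = 1)
  per_class <- sapply(2:3, function(c) {
    num <- 0; dp <- 0; dg <- 0
    for (i in 1:6) for (j in 1:6) {
      num <- num + p[i, j, c] * y[i, j, c]
      dp <- dp + p[i, j, c]; dg <- dg + y[i, j, c]
    }
    1 - (2 * num + 1) / (dp + dg + 1)
  })
  expect_equal(got, mean(per_class))
})

test_that("training can overfit a single easy sample", {
  ph <- generate_l3_sample(small_spec(seed = 20L))
  sample1 <- list(list(x = normalize_hu(ph$hu),
                       y = to_onehot(ph$labels$labels, 5L)))
  cfg <- unet_config(depth = 2L, base_filters = 8L,
                     input_shape = dim(ph$hu), n_classes = 5L, seed = 3L)
  fit <- train_model(build_unet(cfg), sample1, sample1,
                     train_config(learning_rate = 5e-3, batch_size = 1L,
                                  max_epochs = 50L, patience = 50L,
                                  seed = 4L))
  expect_gte(max(fit$history$val_dice), 0.95)
})

test_that("early stopping halts after patience epochs without improvement", {
  ph <- generate_l3_sample(small_spec(seed = 21L))
  s <- list(list(x = normalize_hu(ph$hu),
                 y = to_onehot(ph$labels$labels, 5L)))
  cfg <- unet_config(2L, 4L, dim(ph$hu), 5L, seed = 5L)
  # learning rate too small to move the validation loss by min_delta
  fit <- train_model(build_unet(cfg), s, s,
                     train_config(learning_rate = 1e-12, batch_size = 1L,
                                  max_epochs = 50L, patience = 3L,
                                  min_delta = 1e-4, seed = 6L))
  expect_equal(nrow(fit$history), 1 + 3)
})

test_that("training histories are reproducible given the seed", {
  phs <- lapply(30:32, function(s) {
    p <- generate_l3_sample(small_spec(seed = s))
    list(x = normalize_hu(p$hu), y = to_onehot(p$labels$labels, 5L))
  })
  cfg <- unet_config(2L, 4L, dim(phs[[1]]$x), 5L, seed = 7L)
  tc <- train_config(learning_rate = 1e-3, batch_size = 2L,
                     max_epochs = 3L, patience = 3L, seed = 8L)
  f1 <- train_model(build_unet(cfg), phs[1:2], phs[3], tc)
  f2 <- train_model(build_unet(cfg), phs[1:2], phs[3], tc)
  expect_identical(f1$history, f2$history)
})

test_that("the returned checkpoint attains the best validation DICE", {
  phs <- lapply(40:43, function(s) {
    p <- generate_l3_sample(small_spec(seed = s))
    list(x = normalize_hu(p$hu), y = to_onehot(p$labels$labels, 5L))
  })
  cfg <- unet_config(2L, 6L, dim(phs[[1]]$x), 5L, seed = 9L)
  tc <- train_config(learning_rate = 2e-3, batch_size = 2L,
                     max_epochs = 6L, patience = 6L, seed = 10L)
  fit <- train_model(build_unet(cfg), phs[1:3], phs[4], tc)
  redone <- bodycomp:::evaluate_samples(fit$model, phs[4])
  expect_equal(unname(redone["dice"]), max(fit$history$val_dice),
               tolerance = 1e-12)
  expect_equal(fit$history$val_dice[fit$best_epoch],
               max(fit$history$val_dice))
})

test_that("checkpoints round-trip through save_model / load_model", {
  m <- build_unet(unet_config(2L, 4L, c(16L, 16L), 2L, seed = 11L))
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  x <- matrix(runif(256), 16, 16)
  expect_identical(unet_predict(m, x), unet_predict(m2, x))
  unlink(path)
})

test_that("k-fold partitions are disjoint, exhaustive and reproducible", {
  phs <- lapply(1:10, function(s) {
    p <- generate_l3_sample(small_spec(seed = 100L + s))
    list(x = normalize_hu(p$hu), y = to_onehot(p$labels$labels, 5L))
  })
  cfg <- unet_config(2L, 2L, dim(phs[[1]]$x), 5L, seed = 12L)
  tc <- train_config(learning_rate = 1e-3, batch_size = 4L,
                     max_epochs = 1L, patience = 1L, seed = 13L)
  cv <- run_kfold_cv(phs, cfg, tc, k = 5L, seed = 14L)
  expect_equal(sort(unique(cv$assignments)), 1:5)
  expect_equal(tabulate(cv$assignments), rep(2L, 5))  # each sample once
  expect_equal(nrow(cv$folds), 5)
  expect_equal(unname(cv$mean["dice"]), mean(cv$folds$dice))
  cv2 <- run_kfold_cv(phs, cfg, tc, k = 5L, seed = 15L)
  expect_false(identical(cv$assignments, cv2$assignments))
  expect_equal(tabulate(cv2$assignments), rep(2L, 5))
  expect_error(run_kfold_cv(phs[1:3], cfg, tc, k = 5L), "at least")
})

test_that("a reduced network learns the tissue task from 20 clean phantoms", {
  specs <- cohort_specs(20, flat_spec(),
                        variability = list(body_scale = c(0.9, 1.1)),
                        seed = 55L)
  samples <- lapply(specs, function(sp) {
    s <- generate_l3_sample(sp)
    list(x = normalize_hu(s$hu), y = to_onehot(s$labels$labels, 5L))
  })
  cfg <- unet_config(depth = 3L, base_filters = 8L,
                     input_shape = dim(samples[[1]]$x), n_classes = 5L,
                     seed = 16L)
  tc <- train_config(learning_rate = 2e-3, batch_size = 4L,
                     max_epochs = 10L, patience = 10L, seed = 17L)
  fit <- train_model(build_unet(cfg), samples[1:16], samples[17:20], tc)
  expect_gte(max(fit$history$val_dice), 0.8)
})
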