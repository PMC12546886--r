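# Surrogate network: standalone ops, splitting, small-scale training.
# (The full 2,000-record recovery property lives in test-acceptance.R.)

test_that("conv2d matches a direct double-loop sum and the identity kernel", {
  set.seed(1)
  x <- matrix(rnorm(49), 7, 7)
  w <- matrix(rnorm(9), 3, 3)
  y <- conv2d(x, w, b = 0.5)
  # independent double-loop oracle
  for (i in c(1, 3, 5)) {
    for (j in c(2, 4)) {
      acc <- 0.5
      for (m in 0:2) for (n in 0:2) acc <- acc + x[i + m, j + n] * w[m + 1, n + 1]
      expect_equal(y[i, j], acc)
    }
  }
  # 1x1 unit kernel with zero bias reproduces the input exactly
  expect_equal(conv2d(x, matrix(1, 1, 1), 0), x)
})

test_that("attention_pool is a softmax-weighted mean", {
  F <- rbind(c(1, 2), c(3, 4))
  eq <- attention_pool(F, c(0.7, 0.7), d_k = 1)
  expect_equal(eq$pooled, colMeans(F))
  expect_equal(sum(eq$alpha), 1)
  sat <- attention_pool(F, c(0, 50), d_k = 1)
  expect_equal(sat$pooled, c(3, 4), tolerance = 1e-9)
  w <- attention_pool(F, c(0, log(3)), d_k = 1)
  expect_equal(unname(w$alpha), c(0.25, 0.75))
  expect_error(attention_pool(F[0, , drop = FALSE], numeric(0)), "empty")
})

test_that("multitask_loss weights per-task MSEs plus L2", {
  p <- matrix(rnorm(40), 5, 8)
  expect_equal(multitask_loss(p, p, task_weights(lambda_reg = 0)), 0)
  expect_equal(multitask_loss(p, p, task_weights(lambda_reg = 0.1),
                              param_sqnorm = 7), 0.7)
  t <- p
  t[, 1] <- p[, 1] + sqrt(2)
  t[, 2] <- p[, 2] + 2
  tw <- task_weights(w = c(0.5, 0.5, rep(0, 6)), lambda_reg = 0)
  expect_equal(multitask_loss(p, t, tw), 0.5 * 2 + 0.5 * 4)
})

test_that("cyclical_lr is triangular with peak at t = 0", {
  sched <- training_schedule(lr_min = 1e-4, lr_max = 1e-2, cycle = 200)
  expect_equal(cyclical_lr(0, sched), 1e-2)
  expect_equal(cyclical_lr(200, sched), 1e-4)
  expect_equal(cyclical_lr(100, sched), (1e-2 + 1e-4) / 2)
  t <- 0:900
  lr <- cyclical_lr(t, sched)
  expect_true(all(lr >= 1e-4 - 1e-15 & lr <= 1e-2 + 1e-15))
  expect_equal(cyclical_lr(t, sched), cyclical_lr(t + 400, sched))
})

test_that("split_dataset partitions whole batches 70/15/15", {
  ids <- rep(sprintf("b%02d", 1:20), each = 5)
  sp <- split_dataset(ids, sched = training_schedule(rng_seed = 4))
  parts <- table(sp$batches)
  expect_equal(unname(parts[c("train", "val", "test")]), c(14L, 3L, 3L),
               ignore_attr = TRUE)
  # no id leaks across partitions
  expect_length(intersect(ids[sp$train], ids[sp$val]), 0)
  expect_length(intersect(ids[sp$train], ids[sp$test]), 0)
  expect_length(intersect(ids[sp$val], ids[sp$test]), 0)
  expect_error(split_dataset(c("a", "a", "b")), "fewer batches")
  # stratification: balanced two-variety fixture stays balanced
  ids2 <- rep(sprintf("b%02d", 1:40), each = 2)
  strata <- rep(rep(c("v1", "v2"), each = 20), each = 2)
  sp2 <- split_dataset(ids2, strata, training_schedule(rng_seed = 5))
  tab <- table(strata[sp2$train])
  chi <- chisq.test(tab, p = c(0.5, 0.5))
  expect_gt(chi$p.value, 0.05)
})

test_that("network_config enforces the fused and output dimensions", {
  cfg <- network_config()
  expect_equal(cfg$fusion_dim, 2176)
  expect_error(network_config(fusion_dim = 2000), "fusion_dim")
  expect_error(network_config(output_dim = 4), "fixed at 8")
})

test_that("forward pass conforms to the published layer shapes", {
  m <- build_network(rng_seed = 2)
  img <- array(0, dim = c(2, 64, 64, 3))
  sq <- array(0, dim = c(2, 50, 128))
  sh <- network_shapes(m, img, sq)
  expect_equal(sh$conv1, c(64, 64, 32))
  expect_equal(sh$pool2, c(16, 16, 64))
  expect_equal(sh$lstm1, c(50, 256))
  expect_equal(sh$fused, 2176)
  expect_equal(sh$output, 8)
  expect_true(all(sh$checked))
  out <- predict_surrogate(m, img, sq)
  expect_equal(dim(out), c(2, 8))
  expect_true(all(is.finite(out)))
})

test_that("small-scale training learns, is deterministic, and attributes dose", {
  v <- default_varieties()
  fx <- generate_dataset(varieties = v, rng_seed = 8, n_per_variety = 100,
                         include_arrays = TRUE, noiseless = TRUE)
  sched <- training_schedule(max_epochs = 3, cycle = 40, rng_seed = 13)
  fit1 <- train_surrogate(build_network(rng_seed = 5), fx, sched)
  expect_lt(tail(fit1$history$train_loss, 1), fit1$history$train_loss[1])
  # determinism: identical final loss for an identical run
  fit2 <- train_surrogate(build_network(rng_seed = 5), fx, sched)
  expect_identical(fit1$history$train_loss, fit2$history$train_loss)
  # split manifest partitions are disjoint by construction
  expect_length(intersect(fit1$split$train, fit1$split$test), 0)
  # permutation attribution: dose channel beats the null channel
  groups <- list(dose = list(type = "sequence", channels = 9),
                 null = list(type = "sequence", channels = 10),
                 temperature = list(type = "sequence", channels = 3))
  imp <- permutation_attribution(fit1$model, fx, fit1$split$test, groups,
                                 rng_seed = 3)
  expect_equal(sum(imp), 1)
  expect_gt(imp[["dose"]], imp[["null"]])
  expect_error(
    permutation_attribution(fit1$model, fx, fit1$split$test,
                            list(bad = list(type = "wavelet")),
                            rng_seed = 3),
    "unknown")
})

test_that("training on pure-noise targets yields near-zero test R^2", {
  v <- default_varieties()
  fx <- generate_dataset(varieties = v, rng_seed = 9, n_per_variety = 200,
                         include_arrays = TRUE, noiseless = TRUE)
  set.seed(77)
  fx$targets[] <- rnorm(length(fx$targets))
  fit <- train_surrogate(build_network(rng_seed = 6), fx,
                         training_schedule(max_epochs = 3, cycle = 40,
                                           rng_seed = 14))
  expect_lt(max(abs(fit$metrics$r2)), 0.15)
})
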