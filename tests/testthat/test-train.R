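# Splits, early stopping, optimizer determinism, prediction contracts.

test_that("calibration split gives 700/100/200 on 1000 windows", {
  ds <- make_windows(rnorm(1000, 120, 5), rnorm(1000, 70, 4))
  sp <- split_dataset(ds, train_config())
  expect_length(sp$train, 700)
  expect_length(sp$val, 100)
  expect_length(sp$test, 200)
  # chronological: train strictly precedes val precedes test
  expect_lt(max(sp$train$t_end), min(sp$val$t_end))
  expect_lt(max(sp$val$t_end), min(sp$test$t_end))
  # partition property
  idx <- attr(sp, "indices")
  expect_setequal(c(idx$train, idx$val, idx$test), seq_len(1000))
  expect_length(c(idx$train, idx$val, idx$test), 1000)
})

test_that("LOSO split isolates the held-out subject", {
  ds <- make_windows(rnorm(300, 120, 5),
                     subject_id = rep(c("s1", "s2", "s3"), each = 100),
                     t_end = rep(1:100, 3))
  sp <- split_dataset(ds, train_config(), mode = "loso", holdout_subject = "s2")
  expect_true(all(sp$test$subject_id == "s2"))
  expect_length(sp$test, 100)
  expect_false(any(c(sp$train$subject_id, sp$val$subject_id) == "s2"))
  # 87.5 / 12.5 of the remaining subjects
  expect_length(sp$train, 2 * 87)
  expect_length(sp$val, 2 * 13)
  idx <- attr(sp, "indices")
  expect_setequal(c(idx$train, idx$val, idx$test), seq_len(300))
  expect_error(split_dataset(ds, train_config(), mode = "loso",
                             holdout_subject = "s9"), "absent")
  expect_error(split_dataset(ds, train_config(), mode = "loso"), "holdout")
})

test_that("early stopping halts exactly patience epochs after the best", {
  es <- early_stopper(10)
  losses <- c(1.0, 0.8, 0.5, rep(0.5, 20))  # plateau after epoch 3
  stopped_at <- NA
  for (e in seq_along(losses)) {
    if (es$update(losses[e], e)$stop) { stopped_at <- e; break }
  }
  expect_equal(es$best_epoch, 3L)
  expect_equal(stopped_at, 13)  # 10 epochs after the best one
  # an improvement resets the patience counter
  es2 <- early_stopper(3)
  seq2 <- c(1, 0.9, 0.95, 0.95, 0.85, 0.9, 0.9, 0.9)
  stops <- vapply(seq_along(seq2), function(e) es2$update(seq2[e], e)$stop,
                  logical(1))
  expect_equal(which(stops)[1], 8)
  expect_equal(es2$best_epoch, 5L)
})

test_that("train config invariants are enforced", {
  expect_error(train_config(split = c(train = 0.8, val = 0.1, test = 0.2)),
               "sum to 1")
  expect_error(train_config(patience = 60, max_epochs = 50), "patience")
})

tiny_training_task <- function(n = 96, L = 125, seed = 1) {
  # targets are an exact linear readout of the amplitude of a planted
  # mid-band sinusoid
  set.seed(seed)
  amp <- runif(n, 0.5, 2)
  t <- (seq_len(L) - 1) / 125
  X <- array(0, dim = c(n, L, 1))
  for (i in seq_len(n)) {
    X[i, , 1] <- amp[i] * sin(2 * pi * 3 * t) + 0.02 * rnorm(L)
  }
  make_win <- make_windows(100 + 20 * amp, 60 + 10 * amp, t_end = seq_len(n))
  make_win$X <- X
  make_win
}

test_that("two fits with the same seed give identical weights", {
  ds <- tiny_training_task()
  tc <- train_config(max_epochs = 3, patience = 2, batch_size = 32, seed = 9)
  sp <- split_dataset(ds, tc)
  cfg <- bp_net_config(in_channels = 1, scale = 1 / 16,
                       layers_per_block = c(1, 1, 1, 1), bn_momentum = 0.9)
  r1 <- fit(bp_net(cfg, seed = 4), sp$train, sp$val, tc)
  r2 <- fit(bp_net(cfg, seed = 4), sp$train, sp$val, tc)
  expect_identical(net_checksum(r1$net), net_checksum(r2$net))
  expect_identical(r1$history$val_loss, r2$history$val_loss)
  # history invariants
  h <- r1$history
  expect_lte(h$best_epoch, h$stopped_epoch)
  expect_lte(h$stopped_epoch, tc$max_epochs)
})

test_that("a reduced model learns a planted linear readout", {
  ds <- tiny_training_task(n = 240, seed = 2)
  tc <- train_config(max_epochs = 30, patience = 10, batch_size = 32, seed = 1)
  sp <- split_dataset(ds, tc)
  cfg <- bp_net_config(in_channels = 1, scale = 1 / 8,
                       layers_per_block = c(1, 1, 1, 1), bn_momentum = 0.9)
  res <- fit(bp_net(cfg, seed = 1), sp$train, sp$val, tc)
  # final validation MSE under 10% of the (standardized) target variance
  expect_lt(min(res$history$val_loss), 0.1)
})

test_that("prediction is order-aligned and attention rows sum to 1", {
  ds <- tiny_training_task(n = 40, seed = 3)
  net <- bp_net(bp_net_config(in_channels = 1, scale = 1 / 16,
                              layers_per_block = c(1, 1, 1, 1)), seed = 2)
  pr <- predict(net, ds)
  expect_length(pr$sbp_hat, length(ds))
  expect_length(pr$dbp_hat, length(ds))
  expect_equal(rowSums(pr$attention), rep(1, length(ds)), tolerance = 1e-5)
  # permuting the dataset permutes the outputs identically
  perm <- sample(length(ds))
  pr2 <- predict(net, ds[perm])
  expect_equal(pr2$sbp_hat, pr$sbp_hat[perm], tolerance = 1e-10)
  expect_equal(pr2$attention, pr$attention[perm, ], tolerance = 1e-10)
})

test_that("non-finite loss aborts with a diagnostic", {
  ds <- tiny_training_task(n = 48, seed = 5)
  ds$X[3, 10, 1] <- NaN  # corrupt sample -> non-finite forward loss
  tc <- train_config(max_epochs = 5, patience = 2, batch_size = 16, seed = 1)
  sp <- split_dataset(ds, tc)
  cfg <- bp_net_config(in_channels = 1, scale = 1 / 16,
                       layers_per_block = c(1, 1, 1, 1))
  expect_error(fit(bp_net(cfg, seed = 1), sp$train, sp$val, tc), "diverged")
})
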