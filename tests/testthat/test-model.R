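# Network architecture: shape arithmetic, GRU cell semantics, attention.

test_that("pooling chain reproduces the ceil-division lengths", {
  expect_equal(cnn_out_length(625), 8L)
  expect_equal(cnn_out_length(209, n_pools = 1), 70L)
  expect_equal(cnn_out_length(81), 1L)
  # 81 -> 27 -> 9 -> 3 -> 1 step by step
  expect_equal(Reduce(function(L, .) cufflessbp:::pool_out_len(L),
                      1:4, accumulate = TRUE, init = 81),
               c(81, 27, 9, 3, 1))
})

test_that("full-size encoder maps 625 x 3 to 8 x 512 through 209/70/24", {
  net <- cache_get("full_net", function() bp_net(bp_net_config(), seed = 1))
  x <- matrix(stats::rnorm(625 * 3), 625, 3)
  enc <- cnn_encode(net, x)
  expect_equal(dim(enc), c(8L, 512L))
  fw <- forward(net, x)
  expect_equal(fw$shapes$block1, c(209L, 64L))
  expect_equal(fw$shapes$block2, c(70L, 128L))
  expect_equal(fw$shapes$block3, c(24L, 256L))
  expect_equal(fw$shapes$block4, c(8L, 512L))
  expect_equal(fw$shapes$bigru, c(8L, 128L))
  expect_equal(fw$shapes$head, 2L)
  # input length 81 collapses to one time step
  x81 <- matrix(stats::rnorm(81 * 3), 81, 3)
  expect_equal(dim(cnn_encode(net, x81)), c(1L, 512L))
  # channel mismatch is a shape error
  expect_error(forward(net, matrix(0, 625, 2)), "channel mismatch")
})

test_that("gru_cell follows the gate equations in closed-form cases", {
  # all-zero weights, scalar h_prev = 1: z = r = 0.5, h~ = 0, h = 0.5
  w0 <- list(Wz = matrix(0, 2, 1), Wr = matrix(0, 2, 1), Wh = matrix(0, 2, 1),
             bz = 0, br = 0, bh = 0)
  h <- gru_cell(1, 0, w0)
  g <- attr(h, "gates")
  expect_equal(as.numeric(h), 0.5)
  expect_equal(as.numeric(g$z), 0.5)
  expect_equal(as.numeric(g$r), 0.5)
  expect_equal(as.numeric(g$h_cand), 0)
  # x-pathway of Wh = 1, h_prev = 0, x = 1: h = 0.5 * tanh(1)
  w1 <- w0
  w1$Wh[2, 1] <- 1
  expect_equal(as.numeric(gru_cell(0, 1, w1)), 0.5 * tanh(1), tolerance = 1e-9)
  expect_equal(0.5 * tanh(1), 0.38080, tolerance = 1e-4)
  # update gate driven to 0: h tracks h_prev regardless of x
  w2 <- w0
  w2$bz <- -30
  expect_equal(as.numeric(gru_cell(0.73, 5, w2)), 0.73, tolerance = 1e-9)
  expect_error(gru_cell(c(1, 2), c(1, 2), w0), "width")
})

test_that("gru_cell matches an independent scalar-loop oracle", {
  set.seed(11)
  for (case in 1:50) {
    H <- sample(1:6, 1); Fi <- sample(1:6, 1)
    w <- list(Wz = matrix(rnorm((H + Fi) * H), H + Fi, H),
              Wr = matrix(rnorm((H + Fi) * H), H + Fi, H),
              Wh = matrix(rnorm((H + Fi) * H), H + Fi, H),
              bz = rnorm(H), br = rnorm(H), bh = rnorm(H))
    h_prev <- rnorm(H); x <- rnorm(Fi)
    expect_equal(as.numeric(gru_cell(h_prev, x, w)),
                 gru_oracle(h_prev, x, w), tolerance = 1e-12)
  }
})

test_that("bigru output is the concatenation of forward and time-reversed passes", {
  set.seed(3)
  H <- 4; Fi <- 5; Tn <- 8
  wf <- gru_weights(Fi, H)
  wb <- gru_weights(Fi, H)
  x <- matrix(rnorm(Tn * Fi), Tn, Fi)
  out <- bigru(x, wf, wb)
  expect_equal(dim(out), c(Tn, 2 * H))
  # oracle: explicit gru_cell recursion, forward and on the reversed sequence
  h <- numeric(H)
  for (t in 1:Tn) {
    h <- as.numeric(gru_cell(h, x[t, ], wf))
    expect_equal(out[t, 1:H], h, tolerance = 1e-12)
  }
  g <- numeric(H)
  for (k in 1:Tn) {
    g <- as.numeric(gru_cell(g, x[Tn - k + 1, ], wb))
    expect_equal(out[Tn - k + 1, (H + 1):(2 * H)], g, tolerance = 1e-12)
  }
  # length-1 sequence: each half is one step from the zero state
  x1 <- x[1, , drop = FALSE]
  out1 <- bigru(x1, wf, wb)
  expect_equal(out1[1, 1:H], as.numeric(gru_cell(numeric(H), x[1, ], wf)),
               tolerance = 1e-12)
  expect_equal(out1[1, (H + 1):(2 * H)],
               as.numeric(gru_cell(numeric(H), x[1, ], wb)), tolerance = 1e-12)
})

test_that("attention weights normalize, reduce to uniform, and match hand softmax", {
  set.seed(4)
  H <- matrix(rnorm(8 * 128), 8, 128)
  p <- list(Ws = matrix(rnorm(128) * 0.2, 128, 1), b = 0.1)
  out <- attention_pool(H, p)
  expect_equal(sum(out$a), 1, tolerance = 1e-12)
  # v lies in the convex hull of the time-step vectors
  expect_true(all(out$v <= apply(H, 2, max) + 1e-12))
  expect_true(all(out$v >= apply(H, 2, min) - 1e-12))
  # zero parameters: uniform weights and the column mean
  p0 <- list(Ws = matrix(0, 128, 1), b = 0)
  out0 <- attention_pool(H, p0)
  expect_equal(out0$a, rep(1 / 8, 8), tolerance = 1e-12)
  expect_equal(out0$v, colMeans(H), tolerance = 1e-12)
  # N = 2 with scores (atanh-constructed) s = (0.5, 0): softmax by hand
  H2 <- matrix(c(atanh(0.5), 0), 2, 1)
  p2 <- list(Ws = matrix(1, 1, 1), b = 0)
  out2 <- attention_pool(H2, p2)
  expect_equal(out2$a, c(exp(0.5), 1) / (exp(0.5) + 1), tolerance = 1e-12)
})

test_that("forward emits two finite outputs and is deterministic at inference", {
  net <- bp_net(bp_net_config(in_channels = 2, scale = 1 / 16,
                              layers_per_block = c(1, 1, 1, 1)), seed = 5)
  x <- matrix(stats::rnorm(625 * 2), 625, 2)
  fw <- forward(net, x)
  expect_length(fw$sbp_hat, 1)
  expect_length(fw$dbp_hat, 1)
  expect_true(is.finite(fw$sbp_hat) && is.finite(fw$dbp_hat))
  # a batch of identical segments gives identical outputs (eval-mode BN)
  Xb <- array(0, dim = c(4, 625, 2))
  for (i in 1:4) Xb[i, , ] <- x
  fb <- forward(net, Xb)
  expect_equal(fb$sbp_hat, rep(fb$sbp_hat[1], 4), tolerance = 1e-12)
  expect_equal(fb$attention[2, ], fb$attention[1, ], tolerance = 1e-12)
  # rescaling the score weights changes a but keeps it a probability vector
  net2 <- net
  net2$params$attn$Ws <- net$params$attn$Ws * 2
  fw2 <- forward(net2, x)
  expect_equal(sum(fw2$attention), 1, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(fw2$attention, fw$attention)))
  expect_true(all(is.finite(fw2$attention)))
})
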