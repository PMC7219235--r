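# The BP regression network: VGG-style 1-D CNN encoder -> bidirectional GRU
# -> feed-forward attention -> affine head emitting (SBP, DBP).
#
# Full-size layout for a 625-sample, 3-channel window:
#   conv blocks (2,2,3,3 layers; 64/128/256/512 channels; kernel 3, BN+ReLU,
#   maxpool size 3 stride 3 with ceil lengths) : 625 -> 209 -> 70 -> 24 -> 8
#   Bi-GRU: 64 hidden per direction -> 8 x 128
#   attention: scalar tanh score per step, softmax weights, weighted sum
#   head: affine 128 -> 2

#' Network configuration
#'
#' @param in_channels number of input signals (1-3).
#' @param scale width multiplier: convolution channels are
#'   `base_channels * scale * c(1, 2, 4, 8)` and the GRU hidden size is
#'   `gru_hidden * scale`; `scale = 1` reproduces the full architecture,
#'   smaller values give the reduced models used for CPU-scale training.
#' @param layers_per_block convolution layers in each of the 4 blocks.
#' @param base_channels channels of the first block at `scale = 1`.
#' @param kernel convolution kernel size.
#' @param pool_size,pool_stride max-pooling size/stride (same-padding,
#'   ceil-division output lengths).
#' @param gru_hidden hidden nodes per GRU direction at `scale = 1`.
#' @param head_out outputs (2: SBP, DBP).
#' @param use_gru_bias include GRU bias vectors.
#' @param bn_eps,bn_momentum batch-norm epsilon / running-stat momentum.
#' @return object of class `bp_net_config`.
#' @export
bp_net_config <- function(in_channels = 3, scale = 1,
                          layers_per_block = c(2, 2, 3, 3),
                          base_channels = 64, kernel = 3,
                          pool_size = 3, pool_stride = 3,
                          gru_hidden = 64, head_out = 2,
                          use_gru_bias = TRUE,
                          bn_eps = 1e-3, bn_momentum = 0.99) {
  channels <- pmax(1L, as.integer(round(base_channels * scale * 2^(0:3))))
  gh <- max(1L, as.integer(round(gru_hidden * scale)))
  cfg <- list(
    in_channels = as.integer(in_channels),
    layers_per_block = as.integer(layers_per_block),
    channels = channels, kernel = as.integer(kernel),
    pool_size = as.integer(pool_size), pool_stride = as.integer(pool_stride),
    gru_hidden = gh, head_out = as.integer(head_out),
    use_gru_bias = use_gru_bias, bn_eps = bn_eps, bn_momentum = bn_momentum,
    scale = scale
  )
  if (cfg$in_channels < 1)
    stop_cfg("model config invalid: in_channels must be >= 1")
  if (cfg$kernel %% 2 != 1)
    stop_cfg("model config invalid: kernel must be odd for same padding")
  class(cfg) <- "bp_net_config"
  cfg
}

#' Temporal length after the convolutional encoder
#'
#' Applies the ceil-division pooling chain: with 4 pools of stride 3,
#' 625 -> 209 -> 70 -> 24 -> 8 and 81 -> 27 -> 9 -> 3 -> 1.
#'
#' @param L input length in samples.
#' @param n_pools number of pooling layers.
#' @param stride pooling stride.
#' @return output temporal length.
#' @export
cnn_out_length <- function(L, n_pools = 4, stride = 3) {
  for (i in seq_len(n_pools)) L <- pool_out_len(L, stride)
  as.integer(L)
}

#' Construct an untrained BP regression network
#'
#' Initialises all weights Glorot-uniform from `seed` (recorded in the
#' object); batch-norm running statistics start at mean 0, variance 1.
#'
#' @param config a [bp_net_config()].
#' @param seed integer seed for weight initialisation.
#' @return object of class `bp_net`.
#' @examples
#' net <- bp_net(bp_net_config(in_channels = 3, scale = 1 / 8), seed = 1)
#' @export
bp_net <- function(config = bp_net_config(), seed = 1L) {
  stopifnot(inherits(config, "bp_net_config"))
  set.seed(as.integer(seed))
  K <- config$kernel
  params <- list(conv = list())
  bn_state <- list(conv = list())
  cin <- config$in_channels
  for (blk in seq_along(config$layers_per_block)) {
    params$conv[[blk]] <- list()
    bn_state$conv[[blk]] <- list()
    cout <- config$channels[blk]
    for (ly in seq_len(config$layers_per_block[blk])) {
      params$conv[[blk]][[ly]] <- list(
        W = glorot(K * cin, cout, fan_in = K * cin, fan_out = K * cout),
        b = numeric(cout),
        gamma = rep(1, cout),
        beta = numeric(cout)
      )
      bn_state$conv[[blk]][[ly]] <- list(rm = numeric(cout), rv = rep(1, cout))
      cin <- cout
    }
  }
  H <- config$gru_hidden
  D <- 2L * H
  params$gru_f <- gru_weights(cin, H, config$use_gru_bias)
  params$gru_b <- gru_weights(cin, H, config$use_gru_bias)
  params$attn <- list(Ws = glorot(D, 1L), b = 0)
  params$head <- list(W = glorot(D, config$head_out), b = numeric(config$head_out))
  structure(list(
    config = config,
    params = params,
    bn_state = bn_state,
    target_center = c(sbp = 0, dbp = 0),
    target_scale = c(sbp = 1, dbp = 1),
    trained = FALSE,
    seed = as.integer(seed)
  ), class = "bp_net")
}

#' Feed-forward attention pooling
#'
#' Scores every time step with a single-layer perceptron
#' `s_i = tanh(Ws h_i + b)`, normalises the scores with softmax into weights
#' `a`, and returns the weighted sum `v = sum_i a_i h_i` together with `a`.
#'
#' @param H hidden sequence: T x D matrix (or B x T x D array).
#' @param p list with `Ws` (D x 1) and scalar `b`.
#' @return list with `v` (length-D vector, or B x D matrix) and `a`
#'   (length-T weights, or B x T matrix; each row sums to 1).
#' @export
attention_pool <- function(H, p) {
  single <- length(dim(H)) == 2
  if (single) H <- array(H, dim = c(1, dim(H)))
  d <- dim(H); B <- d[1]; Tn <- d[2]; D <- d[3]
  if (Tn < 1) stop_cfg("attention_pool: empty sequence")
  Hmat <- matrix(H, B * Tn, D)
  s <- tanh(matrix(Hmat %*% p$Ws + p$b, B, Tn))
  e <- exp(s - apply(s, 1, max))
  a <- e / rowSums(e)
  v <- matrix(0, B, D)
  for (t in seq_len(Tn)) v <- v + a[, t] * matrix(H[, t, , drop = FALSE], B, D)
  if (single) list(v = drop(v), a = drop(a)) else list(v = v, a = a)
}

# as_batch: accept L x C matrix, B x L x C array, or bp_windows
as_batch_array <- function(x, in_channels) {
  if (inherits(x, "bp_windows")) x <- x$X
  if (is.matrix(x)) x <- array(x, dim = c(1, dim(x)))
  if (length(dim(x)) != 3)
    stop_cfg("input must be a L x C segment or a B x L x C array")
  if (dim(x)[3] != in_channels)
    stop_cfg("channel mismatch: input has %d channel(s), model expects %d",
             dim(x)[3], in_channels)
  x
}

# Full forward pass. Returns predictions (standardized units), attention,
# and (optionally) caches for backprop plus the per-stage shape trace.
net_forward <- function(net, X, training = FALSE, keep_cache = FALSE) {
  cfg <- net$config
  X <- as_batch_array(X, cfg$in_channels)
  B <- dim(X)[1]
  shapes <- list(input = dim(X)[2:3])
  caches <- list(conv = list())
  a_cur <- X
  for (blk in seq_along(cfg$layers_per_block)) {
    caches$conv[[blk]] <- list()
    for (ly in seq_len(cfg$layers_per_block[blk])) {
      pp <- net$params$conv[[blk]][[ly]]
      st <- net$bn_state$conv[[blk]][[ly]]
      cv <- conv1d_fwd(a_cur, pp$W, pp$b, cfg$kernel)
      bn <- bn_fwd(cv$y, pp$gamma, pp$beta, st, training,
                   cfg$bn_eps, cfg$bn_momentum)
      if (training) net$bn_state$conv[[blk]][[ly]] <- bn$state
      relu_mask <- bn$out > 0
      act <- bn$out * relu_mask
      L <- cv$dims[2]
      a_cur <- array(act, dim = c(B, L, ncol(act)))
      if (keep_cache)
        caches$conv[[blk]][[ly]] <- list(conv = cv, bn = bn, mask = relu_mask)
    }
    pl <- maxpool_fwd(a_cur, cfg$pool_stride)
    if (keep_cache) caches$conv[[blk]]$pool <- pl
    a_cur <- pl$y
    shapes[[paste0("block", blk)]] <- dim(a_cur)[2:3]
  }
  feats <- a_cur  # B x T x C4
  fgru <- gru_layer_fwd(feats, net$params$gru_f, keep_cache)
  bgru <- gru_layer_fwd(reverse_time(feats), net$params$gru_b, keep_cache)
  Hseq <- abind3(fgru$states, reverse_time(bgru$states))
  shapes$bigru <- dim(Hseq)[2:3]
  att <- attention_pool(Hseq, net$params$attn)
  v <- if (is.matrix(att$v)) att$v else matrix(att$v, 1)
  a_w <- if (is.matrix(att$a)) att$a else matrix(att$a, 1)
  shapes$attention <- dim(v)[2]
  pred <- sweep(v %*% net$params$head$W, 2, net$params$head$b, "+")
  shapes$head <- ncol(pred)
  list(pred = pred, attention = a_w, shapes = shapes,
       caches = if (keep_cache) c(caches, list(
         feats = feats, fgru = fgru, bgru = bgru, Hseq = Hseq, att = att, v = v
       )) else NULL,
       net = net)
}

# Backward pass: dPred is B x 2 in standardized units; returns grads tree
# congruent with net$params.
net_backward <- function(net, fwd, dPred) {
  cfg <- net$config
  cc <- fwd$caches
  B <- nrow(dPred)
  g <- tree_zeros_like(net$params)
  # head
  g$head$W <- crossprod(cc$v, dPred)
  g$head$b <- colSums(dPred)
  dV <- tcrossprod(dPred, net$params$head$W)  # B x D
  # attention
  Hseq <- cc$Hseq
  d <- dim(Hseq); Tn <- d[2]; D <- d[3]
  a <- fwd$attention  # B x T
  dH <- array(0, dim = d)
  da <- matrix(0, B, Tn)
  for (t in seq_len(Tn)) {
    Ht <- matrix(Hseq[, t, , drop = FALSE], B, D)
    da[, t] <- rowSums(dV * Ht)
    dH[, t, ] <- a[, t] * dV
  }
  # softmax backward
  ds <- a * (da - rowSums(a * da))
  # tanh score backward: s = tanh(H Ws + b)
  Hmat <- matrix(Hseq, B * Tn, D)
  s <- tanh(matrix(Hmat %*% net$params$attn$Ws + net$params$attn$b, B, Tn))
  dspre <- ds * (1 - s^2)
  g$attn$Ws <- crossprod(Hmat, as.vector(dspre))
  g$attn$b <- sum(dspre)
  dH <- dH + array(tcrossprod(as.vector(dspre), net$params$attn$Ws),
                   dim = c(B, Tn, D))
  # split bigru halves
  H1 <- ncol(net$params$gru_f$Wz)
  dHf <- dH[, , seq_len(H1), drop = FALSE]
  dHb <- reverse_time(dH[, , (H1 + 1):(2 * H1), drop = FALSE])
  bf <- gru_layer_bwd(cc$fgru, net$params$gru_f, dHf)
  bb <- gru_layer_bwd(cc$bgru, net$params$gru_b, dHb)
  g$gru_f[names(bf$grads)] <- bf$grads
  g$gru_b[names(bb$grads)] <- bb$grads
  dFeats <- bf$dX + reverse_time(bb$dX)
  # conv blocks in reverse
  d_cur <- dFeats
  for (blk in rev(seq_along(cfg$layers_per_block))) {
    d_cur <- maxpool_bwd(cc$conv[[blk]]$pool, d_cur)
    for (ly in rev(seq_len(cfg$layers_per_block[blk]))) {
      lcache <- cc$conv[[blk]][[ly]]
      Cout <- ncol(lcache$bn$out)
      dAct <- matrix(d_cur, prod(dim(d_cur)[1:2]), Cout) * lcache$mask
      bnb <- bn_bwd(lcache$bn, net$params$conv[[blk]][[ly]]$gamma, dAct)
      g$conv[[blk]][[ly]]$gamma <- bnb$dgamma
      g$conv[[blk]][[ly]]$beta <- bnb$dbeta
      cvb <- conv1d_bwd(lcache$conv, net$params$conv[[blk]][[ly]]$W,
                        bnb$dx, cfg$kernel)
      g$conv[[blk]][[ly]]$W <- cvb$dW
      g$conv[[blk]][[ly]]$b <- cvb$db
      d_cur <- cvb$dx
    }
  }
  if (!net$config$use_gru_bias) {
    for (nm in c("gru_f", "gru_b"))
      for (bn in c("bz", "br", "bh")) g[[nm]][[bn]] <- g[[nm]][[bn]] * 0
  }
  g
}

#' Convolutional encoding of a segment
#'
#' Runs only the CNN stage: 4 blocks of (conv - BN - ReLU) x {2,2,3,3}
#' followed by max-pooling, reducing a 625-sample window to 8 time steps of
#' 512 features (at full scale).
#'
#' @param net a `bp_net`.
#' @param x segment (L x C matrix), batch array, or `bp_windows`.
#' @return feature sequence: T x C4 matrix for a single segment, otherwise
#'   B x T x C4 array.
#' @export
cnn_encode <- function(net, x) {
  cfg <- net$config
  single <- is.matrix(x)
  X <- as_batch_array(x, cfg$in_channels)
  a_cur <- X
  B <- dim(X)[1]
  for (blk in seq_along(cfg$layers_per_block)) {
    for (ly in seq_len(cfg$layers_per_block[blk])) {
      pp <- net$params$conv[[blk]][[ly]]
      st <- net$bn_state$conv[[blk]][[ly]]
      cv <- conv1d_fwd(a_cur, pp$W, pp$b, cfg$kernel)
      bn <- bn_fwd(cv$y, pp$gamma, pp$beta, st, FALSE, cfg$bn_eps, cfg$bn_momentum)
      a_cur <- array(bn$out * (bn$out > 0), dim = c(B, cv$dims[2], ncol(bn$out)))
    }
    a_cur <- maxpool_fwd(a_cur, cfg$pool_stride)$y
  }
  if (single) array(a_cur, dim = dim(a_cur)[2:3]) else a_cur
}

#' Forward pass of the full network
#'
#' @param net a `bp_net`.
#' @param x segment, batch array, or `bp_windows`.
#' @param training use batch statistics in batch norm (default FALSE: eval
#'   mode, running statistics; inference is deterministic).
#' @return list with `sbp_hat`, `dbp_hat` (mmHg), `attention` (B x T, rows
#'   sum to 1) and `shapes` (per-stage output shapes).
#' @export
forward <- function(net, x, training = FALSE) {
  fw <- net_forward(net, x, training = training)
  pred <- unstandardize_targets(net, fw$pred)
  list(sbp_hat = pred[, 1], dbp_hat = pred[, 2],
       attention = fw$attention, shapes = fw$shapes)
}

unstandardize_targets <- function(net, pred_std) {
  sweep(sweep(pred_std, 2, net$target_scale, "*"), 2, net$target_center, "+")
}

standardize_targets <- function(net, Y) {
  sweep(sweep(Y, 2, net$target_center, "-"), 2, net$target_scale, "/")
}

#' Predict BP for a windowed dataset
#'
#' @param object a trained `bp_net`.
#' @param newdata a `bp_windows` or B x L x C array.
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return list with `sbp_hat`, `dbp_hat` (mmHg, aligned with the dataset
#'   order) and `attention` (matrix, one row per window).
#' @export
predict.bp_net <- function(object, newdata, batch_size = 256L, ...) {
  X <- if (inherits(newdata, "bp_windows")) newdata$X else newdata
  X <- as_batch_array(X, object$config$in_channels)
  n <- dim(X)[1]
  sbp <- numeric(n); dbp <- numeric(n); attn <- NULL
  for (i0 in seq(1, n, by = batch_size)) {
    i1 <- min(n, i0 + batch_size - 1)
    fw <- forward(object, X[i0:i1, , , drop = FALSE])
    sbp[i0:i1] <- fw$sbp_hat
    dbp[i0:i1] <- fw$dbp_hat
    if (is.null(attn)) attn <- matrix(0, n, ncol(fw$attention))
    attn[i0:i1, ] <- fw$attention
  }
  list(sbp_hat = sbp, dbp_hat = dbp, attention = attn)
}

#' @export
print.bp_net <- function(x, ...) {
  cfg <- x$config
  np <- 0
  tree_map(x$params, function(p) { np <<- np + length(p); p })
  cat(sprintf(
    "<bp_net> in_channels=%d, conv %s x %s, Bi-GRU %d+%d, %d params%s\n",
    cfg$in_channels,
    paste(cfg$channels, collapse = "/"),
    paste(cfg$layers_per_block, collapse = "/"),
    cfg$gru_hidden, cfg$gru_hidden, np,
    if (x$trained) " (trained)" else " (untrained)"))
  invisible(x)
}

#' Layer-by-layer shape table
#'
#' Prints the architecture with the output shape of every stage for a given
#' input length, reproducing the ceil-division pooling chain
#' (625 -> 209 -> 70 -> 24 -> 8 at full scale).
#'
#' @param object a `bp_net`.
#' @param input_length input window length in samples (default 625).
#' @param ... unused.
#' @return invisibly, a data.frame of layer descriptions.
#' @export
summary.bp_net <- function(object, input_length = 625, ...) {
  cfg <- object$config
  rows <- list()
  L <- as.integer(input_length)
  cin <- cfg$in_channels
  for (blk in seq_along(cfg$layers_per_block)) {
    cout <- cfg$channels[blk]
    for (ly in seq_len(cfg$layers_per_block[blk])) {
      rows[[length(rows) + 1]] <- data.frame(
        network = "CNN", layer = "Conv + BN + ReLU",
        shape = sprintf("%d x %d", L, cin), out = cout)
      cin <- cout
    }
    rows[[length(rows) + 1]] <- data.frame(
      network = "CNN", layer = sprintf("Maxpool(size=%d)", cfg$pool_size),
      shape = sprintf("%d x %d", L, cin), out = NA)
    L <- pool_out_len(L, cfg$pool_stride)
  }
  rows[[length(rows) + 1]] <- data.frame(
    network = "Bi-GRU", layer = "Forward + Backward + Concat",
    shape = sprintf("%d x %d", L, cin), out = 2 * cfg$gru_hidden)
  rows[[length(rows) + 1]] <- data.frame(
    network = "Attention", layer = "score (tanh) + softmax + weighted sum",
    shape = sprintf("%d x %d", L, 2 * cfg$gru_hidden), out = 2 * cfg$gru_hidden)
  rows[[length(rows) + 1]] <- data.frame(
    network = "Head", layer = "1-layer perceptron",
    shape = sprintf("%d", 2 * cfg$gru_hidden), out = cfg$head_out)
  tab <- do.call(rbind, rows)
  print(tab, row.names = FALSE)
  invisible(tab)
}
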