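# Building blocks of the regression network, with hand-derived backprop.
# No deep-learning framework exists in this environment, and the network is
# the package's core contribution, so forward and backward passes are
# implemented directly in base R matrix code.
#
# Activation convention: a batch is an array B x L x C (windows x samples x
# channels); matrix views collapse (B, L) into rows with B varying fastest,
# which is exactly how R reshapes arrays, so matrix(a, B * L, C) is free.

## ---- parameter-tree helpers ----

tree_map <- function(x, f) {
  if (is.list(x)) lapply(x, tree_map, f = f) else f(x)
}

tree_map2 <- function(x, y, f) {
  if (is.list(x)) {
    out <- x
    for (nm in seq_along(x)) out[[nm]] <- tree_map2(x[[nm]], y[[nm]], f)
    out
  } else {
    f(x, y)
  }
}

tree_zeros_like <- function(x) tree_map(x, function(p) p * 0)

glorot <- function(nr, nc, fan_in = nr, fan_out = nc) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

bc_row <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

## ---- 1-D convolution (same padding, stride 1) ----

# x: B x L x Cin array; W: (K*Cin) x Cout; b: Cout
conv1d_fwd <- function(x, W, b, kernel) {
  d <- dim(x); B <- d[1]; L <- d[2]; Cin <- d[3]
  pad <- (kernel - 1L) / 2L
  xp <- array(0, dim = c(B, L + 2L * pad, Cin))
  xp[, (pad + 1L):(pad + L), ] <- x
  Xc <- matrix(0, B * L, kernel * Cin)
  for (k in seq_len(kernel)) {
    Xc[, ((k - 1L) * Cin + 1L):(k * Cin)] <-
      matrix(xp[, k:(k + L - 1L), , drop = FALSE], B * L, Cin)
  }
  y <- Xc %*% W
  y <- sweep(y, 2, b, "+")
  list(y = y, Xc = Xc, dims = c(B, L, Cin))
}

conv1d_bwd <- function(cache, W, dY, kernel) {
  B <- cache$dims[1]; L <- cache$dims[2]; Cin <- cache$dims[3]
  pad <- (kernel - 1L) / 2L
  dW <- crossprod(cache$Xc, dY)
  db <- colSums(dY)
  dXc <- tcrossprod(dY, W)
  dxp <- array(0, dim = c(B, L + 2L * pad, Cin))
  for (k in seq_len(kernel)) {
    dxp[, k:(k + L - 1L), ] <- dxp[, k:(k + L - 1L), , drop = FALSE] +
      array(dXc[, ((k - 1L) * Cin + 1L):(k * Cin)], dim = c(B, L, Cin))
  }
  list(dx = dxp[, (pad + 1L):(pad + L), , drop = FALSE], dW = dW, db = db)
}

## ---- batch normalization (per channel over batch x length) ----

bn_fwd <- function(y, gamma, beta, state, training, eps, momentum) {
  n <- nrow(y)
  if (training) {
    mu <- colMeans(y)
    va <- colMeans(y^2) - mu^2
    state$rm <- momentum * state$rm + (1 - momentum) * mu
    state$rv <- momentum * state$rv + (1 - momentum) * va
  } else {
    mu <- state$rm
    va <- state$rv
  }
  inv_std <- 1 / sqrt(va + eps)
  xhat <- sweep(y, 2, mu, "-")
  xhat <- sweep(xhat, 2, inv_std, "*")
  out <- sweep(xhat, 2, gamma, "*")
  out <- sweep(out, 2, beta, "+")
  list(out = out, xhat = xhat, inv_std = inv_std, state = state)
}

bn_bwd <- function(cache, gamma, dY) {
  n <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2, gamma, "*")
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dx <- dxhat - bc_row(s1 / n, n) - cache$xhat * bc_row(s2 / n, n)
  dx <- sweep(dx, 2, cache$inv_std, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## ---- max pooling, size = stride = 3, "same" (ceil) length arithmetic ----

pool_out_len <- function(L, stride = 3L) as.integer(ceiling(L / stride))

maxpool_fwd <- function(x, stride = 3L) {
  d <- dim(x); B <- d[1]; L <- d[2]; C <- d[3]
  Lout <- pool_out_len(L, stride)
  Lp <- Lout * stride
  xp <- array(-Inf, dim = c(B, Lp, C))
  xp[, seq_len(L), ] <- x
  slices <- lapply(seq_len(stride), function(k)
    xp[, seq(k, Lp, by = stride), , drop = FALSE])
  y <- slices[[1]]
  for (k in 2:stride) y <- pmax(y, slices[[k]])
  # first-argmax tie break
  sel <- vector("list", stride)
  taken <- array(FALSE, dim = dim(y))
  for (k in seq_len(stride)) {
    sel[[k]] <- (slices[[k]] == y) & !taken
    taken <- taken | sel[[k]]
  }
  list(y = y, sel = sel, L = L, stride = stride)
}

maxpool_bwd <- function(cache, dY) {
  stride <- cache$stride
  d <- dim(dY); B <- d[1]; Lout <- d[2]; C <- d[3]
  Lp <- Lout * stride
  dxp <- array(0, dim = c(B, Lp, C))
  for (k in seq_len(stride)) {
    dxp[, seq(k, Lp, by = stride), ] <- dY * cache$sel[[k]]
  }
  dxp[, seq_len(cache$L), , drop = FALSE]
}

## ---- Adam optimizer with inverse-time learning-rate decay ----

adam_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  t <- state$t
  lr_t <- lr / (1 + decay * t)
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  upd <- tree_map2(state$m, state$v, function(m, v)
    lr_t * (m / c1) / (sqrt(v / c2) + eps))
  params <- tree_map2(params, upd, function(p, u) p - u)
  list(params = params, state = state, lr_t = lr_t)
}
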