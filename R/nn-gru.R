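# Gated recurrent unit and bidirectional wrapper.
#
# The cell follows the update/reset/candidate equations with the blending
#   h_t = (1 - z_t) (x) h_{t-1} + z_t (x) h~_t,
# gates computed from the concatenation [h_{t-1}, x_t]. Biases are included
# (standard practice; the equations omit them) and can be disabled via the
# model config.

#' Initialise GRU weights
#'
#' @param input_size input feature size F.
#' @param hidden_size hidden size H.
#' @param use_bias include bias vectors (default TRUE).
#' @return list of `Wz`, `Wr`, `Wh` ((H+F) x H matrices acting on
#'   `[h_prev, x]`) and biases `bz`, `br`, `bh`.
#' @export
gru_weights <- function(input_size, hidden_size, use_bias = TRUE) {
  nf <- hidden_size + input_size
  w <- list(
    Wz = glorot(nf, hidden_size),
    Wr = glorot(nf, hidden_size),
    Wh = glorot(nf, hidden_size),
    bz = numeric(hidden_size),
    br = numeric(hidden_size),
    bh = numeric(hidden_size)
  )
  attr(w, "use_bias") <- use_bias
  w
}

#' One GRU step
#'
#' Computes the update gate `z`, reset gate `r`, candidate state
#' `h~ = tanh(Wh [r (x) h_prev, x] + bh)` and the new hidden state
#' `h = (1 - z) (x) h_prev + z (x) h~`.
#'
#' @param h_prev previous hidden state: vector of length H or matrix B x H.
#' @param x input: vector of length F or matrix B x F.
#' @param w weights as from [gru_weights()].
#' @return hidden state with the same shape as `h_prev`; gates available via
#'   attribute `gates` (list `z`, `r`, `h_cand`).
#' @examples
#' w <- list(Wz = matrix(0, 2, 1), Wr = matrix(0, 2, 1), Wh = matrix(0, 2, 1),
#'           bz = 0, br = 0, bh = 0)
#' gru_cell(1, 0, w)  # sigma(0) = 0.5, tanh(0) = 0 -> h = 0.5
#' @export
gru_cell <- function(h_prev, x, w) {
  vec_in <- is.null(dim(h_prev))
  h_prev <- rbind_as_matrix(h_prev)
  x <- rbind_as_matrix(x)
  if (nrow(h_prev) != nrow(x))
    stop_cfg("gru_cell: batch mismatch (%d vs %d)", nrow(h_prev), nrow(x))
  if (ncol(h_prev) + ncol(x) != nrow(w$Wz))
    stop_cfg("gru_cell: [h_prev, x] width %d does not match weights (%d rows)",
             ncol(h_prev) + ncol(x), nrow(w$Wz))
  hx <- cbind(h_prev, x)
  z <- sigmoid(sweep(hx %*% w$Wz, 2, w$bz, "+"))
  r <- sigmoid(sweep(hx %*% w$Wr, 2, w$br, "+"))
  rhx <- cbind(r * h_prev, x)
  h_cand <- tanh(sweep(rhx %*% w$Wh, 2, w$bh, "+"))
  h <- (1 - z) * h_prev + z * h_cand
  if (vec_in) h <- drop(h)
  attr(h, "gates") <- list(z = z, r = r, h_cand = h_cand)
  h
}

rbind_as_matrix <- function(x) {
  if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
}

# Forward over a sequence. x_arr: B x T x F. Returns states B x T x H and a
# cache for backprop.
gru_layer_fwd <- function(x_arr, w, keep_cache = FALSE) {
  d <- dim(x_arr); B <- d[1]; Tn <- d[2]; Fi <- d[3]
  H <- ncol(w$Wz)
  states <- array(0, dim = c(B, Tn, H))
  h <- matrix(0, B, H)
  cache <- if (keep_cache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    xt <- matrix(x_arr[, t, , drop = FALSE], B, Fi)
    h_prev <- h
    h <- gru_cell(h_prev, xt, w)
    g <- attr(h, "gates")
    attr(h, "gates") <- NULL
    states[, t, ] <- h
    if (keep_cache)
      cache[[t]] <- list(h_prev = h_prev, x = xt, z = g$z, r = g$r,
                         h_cand = g$h_cand)
  }
  list(states = states, cache = cache, dims = d)
}

# Backprop through time. dH: B x T x H gradient on every emitted state.
gru_layer_bwd <- function(fwd, w, dH) {
  d <- fwd$dims; B <- d[1]; Tn <- d[2]; Fi <- d[3]
  H <- ncol(w$Wz)
  g <- tree_zeros_like(w[c("Wz", "Wr", "Wh", "bz", "br", "bh")])
  dX <- array(0, dim = d)
  dh_next <- matrix(0, B, H)
  for (t in rev(seq_len(Tn))) {
    cc <- fwd$cache[[t]]
    dh <- matrix(dH[, t, , drop = FALSE], B, H) + dh_next
    z <- cc$z; r <- cc$r; hc <- cc$h_cand; hp <- cc$h_prev
    dz <- dh * (hc - hp)
    dhc <- dh * z
    dh_prev <- dh * (1 - z)
    # candidate path
    dah <- dhc * (1 - hc^2)
    rhx <- cbind(r * hp, cc$x)
    g$Wh <- g$Wh + crossprod(rhx, dah)
    g$bh <- g$bh + colSums(dah)
    dcomb <- tcrossprod(dah, w$Wh)
    d_rhp <- dcomb[, seq_len(H), drop = FALSE]
    dX[, t, ] <- dX[, t, , drop = FALSE] +
      array(dcomb[, (H + 1):(H + Fi), drop = FALSE], c(B, 1, Fi))
    dr <- d_rhp * hp
    dh_prev <- dh_prev + d_rhp * r
    # gates
    hx <- cbind(hp, cc$x)
    daz <- dz * z * (1 - z)
    g$Wz <- g$Wz + crossprod(hx, daz)
    g$bz <- g$bz + colSums(daz)
    dcz <- tcrossprod(daz, w$Wz)
    dh_prev <- dh_prev + dcz[, seq_len(H), drop = FALSE]
    dX[, t, ] <- dX[, t, , drop = FALSE] +
      array(dcz[, (H + 1):(H + Fi), drop = FALSE], c(B, 1, Fi))
    dar <- dr * r * (1 - r)
    g$Wr <- g$Wr + crossprod(hx, dar)
    g$br <- g$br + colSums(dar)
    dcr <- tcrossprod(dar, w$Wr)
    dh_prev <- dh_prev + dcr[, seq_len(H), drop = FALSE]
    dX[, t, ] <- dX[, t, , drop = FALSE] +
      array(dcr[, (H + 1):(H + Fi), drop = FALSE], c(B, 1, Fi))
    dh_next <- dh_prev
  }
  list(dX = dX, grads = g)
}

reverse_time <- function(x_arr) {
  x_arr[, rev(seq_len(dim(x_arr)[2])), , drop = FALSE]
}

#' Bidirectional GRU over a feature sequence
#'
#' Runs a forward pass left-to-right and a second pass right-to-left, then
#' concatenates the two hidden states at each time step, doubling the
#' feature width (64 + 64 = 128 at the default size).
#'
#' @param seq feature sequence: matrix T x F (one segment) or array B x T x F.
#' @param w_f,w_b forward / backward weights from [gru_weights()].
#' @return hidden sequence: T x 2H matrix (or B x T x 2H array for batches).
#' @export
bigru <- function(seq, w_f, w_b) {
  single <- length(dim(seq)) == 2
  if (single) seq <- array(seq, dim = c(1, dim(seq)))
  if (dim(seq)[2] < 1) stop_cfg("bigru: empty sequence")
  f <- gru_layer_fwd(seq, w_f)
  b <- gru_layer_fwd(reverse_time(seq), w_b)
  H <- abind3(f$states, reverse_time(b$states))
  if (single) H <- array(H, dim = dim(H)[2:3])
  H
}

# concatenate along the 3rd dim
abind3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , (da[3] + 1):(da[3] + db[3])] <- b
  out
}
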