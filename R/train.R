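# Training protocol: chronological 70/10/20 splits (calibration mode) or
# leave-one-subject-out (calibration-free), Adam (lr 1e-3, inverse-time
# decay 1e-4 per update), MSE loss over (SBP, DBP), early stopping with
# patience 10 within at most 50 epochs, batch size 512.

#' Training configuration
#'
#' @param lr Adam learning rate.
#' @param decay per-update inverse-time learning-rate decay:
#'   `lr_t = lr / (1 + decay * t)`.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience (validation MSE; must be smaller
#'   than `max_epochs`).
#' @param batch_size minibatch size.
#' @param split train/validation/test fractions (must sum to 1).
#' @param split_method `"chronological"` (default; contiguous in time, safe
#'   against leakage between heavily overlapping windows) or `"random"`.
#' @param seed seed controlling shuffling (and any split randomness).
#' @return object of class `bp_train_config`.
#' @export
train_config <- function(lr = 1e-3, decay = 1e-4, max_epochs = 50L,
                         patience = 10L, batch_size = 512L,
                         split = c(train = 0.7, val = 0.1, test = 0.2),
                         split_method = c("chronological", "random"),
                         seed = 1L) {
  split_method <- match.arg(split_method)
  if (abs(sum(split) - 1) > 1e-9)
    stop_cfg("train config invalid: split fractions must sum to 1")
  if (!(patience < max_epochs))
    stop_cfg("train config invalid: patience (%d) must be < max_epochs (%d)",
             patience, max_epochs)
  structure(list(lr = lr, decay = decay, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 split = split, split_method = split_method,
                 seed = as.integer(seed)),
            class = "bp_train_config")
}

#' Split a windowed dataset for training
#'
#' Calibration mode: a 70/10/20 train/validation/test split within each
#' subject, contiguous in time by default (windows overlap heavily, so
#' chronological splits limit leakage). LOSO mode: the held-out subject's
#' windows form the test set and the remaining subjects are split
#' 87.5/12.5 into train/validation.
#'
#' @param ds a `bp_windows`.
#' @param cfg a [train_config()].
#' @param mode `"calibration"` or `"loso"`.
#' @param holdout_subject subject id held out (required in LOSO mode).
#' @return list of `bp_windows`: `train`, `val`, `test`; the index sets
#'   (attribute `indices`) partition `seq_len(length(ds))`.
#' @export
split_dataset <- function(ds, cfg = train_config(),
                          mode = c("calibration", "loso"),
                          holdout_subject = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(ds, "bp_windows"))
  n <- length(ds)
  if (n < 10) stop_cfg("dataset too small to split (%d windows)", n)
  idx_tr <- integer(0); idx_va <- integer(0); idx_te <- integer(0)
  if (mode == "calibration") {
    for (sid in unique(ds$subject_id)) {
      i_s <- which(ds$subject_id == sid)
      i_s <- i_s[order(ds$t_end[i_s])]
      if (cfg$split_method == "random") {
        set.seed(derive_seed(cfg$seed, 3L))
        i_s <- sample(i_s)
      }
      ns <- length(i_s)
      n_tr <- floor(cfg$split["train"] * ns)
      n_va <- floor(cfg$split["val"] * ns)
      if (n_tr < 1 || n_va < 1 || ns - n_tr - n_va < 1)
        stop_cfg("subject %s too small for a non-empty split", sid)
      idx_tr <- c(idx_tr, i_s[seq_len(n_tr)])
      idx_va <- c(idx_va, i_s[(n_tr + 1):(n_tr + n_va)])
      idx_te <- c(idx_te, i_s[(n_tr + n_va + 1):ns])
    }
  } else {
    if (is.null(holdout_subject))
      stop_cfg("loso mode requires holdout_subject")
    if (!holdout_subject %in% ds$subject_id)
      stop_cfg("holdout subject '%s' absent from dataset", holdout_subject)
    idx_te <- which(ds$subject_id == holdout_subject)
    for (sid in setdiff(unique(ds$subject_id), holdout_subject)) {
      i_s <- which(ds$subject_id == sid)
      i_s <- i_s[order(ds$t_end[i_s])]
      ns <- length(i_s)
      n_tr <- floor(0.875 * ns)
      if (n_tr < 1 || ns - n_tr < 1)
        stop_cfg("subject %s too small for a non-empty split", sid)
      idx_tr <- c(idx_tr, i_s[seq_len(n_tr)])
      idx_va <- c(idx_va, i_s[(n_tr + 1):ns])
    }
    if (length(idx_tr) == 0)
      stop_cfg("loso mode needs at least one non-holdout subject")
  }
  out <- list(train = ds[idx_tr], val = ds[idx_va], test = ds[idx_te])
  attr(out, "indices") <- list(train = idx_tr, val = idx_va, test = idx_te)
  out
}

#' Early-stopping monitor
#'
#' Tracks the best validation loss; `update()` returns whether the epoch
#' improved on it and whether training should halt (after `patience`
#' consecutive epochs without improvement, i.e. exactly `patience` epochs
#' after the best one for a plateauing sequence).
#'
#' @param patience consecutive non-improving epochs tolerated.
#' @return environment with `update(loss, epoch)`, and fields `best`,
#'   `best_epoch`, `wait`.
#' @export
early_stopper <- function(patience) {
  es <- new.env(parent = emptyenv())
  es$best <- Inf
  es$best_epoch <- 0L
  es$wait <- 0L
  es$update <- function(loss, epoch) {
    improved <- is.finite(loss) && loss < es$best
    if (improved) {
      es$best <- loss
      es$best_epoch <- as.integer(epoch)
      es$wait <- 0L
    } else {
      es$wait <- es$wait + 1L
    }
    list(improved = improved, stop = es$wait >= patience)
  }
  es
}

#' Fit the BP network
#'
#' Trains with Adam (inverse-time decayed learning rate), MSE loss over the
#' standardized (SBP, DBP) pair, early stopping on validation MSE with
#' best-weight restoration. Deterministic given the seed (single-threaded).
#' Targets are internally z-scored from the training split; predictions are
#' returned in mmHg.
#'
#' @param object an untrained (or warm) `bp_net`.
#' @param train,val `bp_windows` splits.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch losses.
#' @param ... unused.
#' @return list with `net` (trained, best-validation weights) and `history`
#'   (class `bp_train_history`: per-epoch train/val loss, `best_epoch`,
#'   `stopped_epoch`).
#' @export
fit <- function(object, ...) UseMethod("fit")

#' @rdname fit
#' @export
fit.bp_net <- function(object, train, val, cfg = train_config(),
                       verbose = FALSE, ...) {
  net <- object
  stopifnot(inherits(train, "bp_windows"), inherits(val, "bp_windows"))
  if (length(train) == 0 || length(val) == 0)
    stop_cfg("training and validation splits must be non-empty")
  Ytr <- cbind(train$y_sbp, train$y_dbp)
  net$target_center <- colMeans(Ytr)
  sds <- apply(Ytr, 2, stats::sd)
  net$target_scale <- ifelse(is.finite(sds) & sds > 0, sds, 1)
  Ytr_s <- standardize_targets(net, Ytr)
  Yva_s <- standardize_targets(net, cbind(val$y_sbp, val$y_dbp))
  n <- length(train)
  opt <- adam_init(net$params)
  es <- early_stopper(cfg$patience)
  best_params <- net$params
  best_bn <- net$bn_state
  hist_tr <- numeric(0); hist_va <- numeric(0)
  set.seed(derive_seed(cfg$seed, 11L))
  stopped <- cfg$max_epochs
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_n <- 0
    for (i0 in seq(1, n, by = cfg$batch_size)) {
      bi <- ord[i0:min(n, i0 + cfg$batch_size - 1)]
      Xb <- train$X[bi, , , drop = FALSE]
      Yb <- Ytr_s[bi, , drop = FALSE]
      fw <- net_forward(net, Xb, training = TRUE, keep_cache = TRUE)
      net <- fw$net  # batch-norm running stats advanced
      err <- fw$pred - Yb
      loss <- mean(err^2)
      if (!is.finite(loss))
        stop_cfg("training diverged at epoch %d (non-finite loss)", epoch)
      dPred <- 2 * err / length(err)
      grads <- net_backward(net, fw, dPred)
      stp <- adam_step(net$params, grads, opt, cfg$lr, cfg$decay)
      net$params <- stp$params
      opt <- stp$state
      ep_loss <- ep_loss + loss * length(bi)
      ep_n <- ep_n + length(bi)
    }
    va_pred <- predict_std(net, val$X, cfg$batch_size)
    va_loss <- mean((va_pred - Yva_s)^2)
    hist_tr <- c(hist_tr, ep_loss / ep_n)
    hist_va <- c(hist_va, va_loss)
    upd <- es$update(va_loss, epoch)
    if (upd$improved) {
      best_params <- net$params
      best_bn <- net$bn_state
    }
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f%s", epoch,
                      ep_loss / ep_n, va_loss, if (upd$improved) " *" else ""))
    if (upd$stop) { stopped <- epoch; break }
  }
  net$params <- best_params
  net$bn_state <- best_bn
  net$trained <- TRUE
  history <- structure(list(
    train_loss = hist_tr, val_loss = hist_va,
    best_epoch = es$best_epoch, stopped_epoch = stopped
  ), class = "bp_train_history")
  list(net = net, history = history)
}

# batched forward in eval mode returning standardized predictions
predict_std <- function(net, X, batch_size = 256L) {
  n <- dim(X)[1]
  out <- matrix(0, n, net$config$head_out)
  for (i0 in seq(1, n, by = batch_size)) {
    i1 <- min(n, i0 + batch_size - 1)
    fw <- net_forward(net, X[i0:i1, , , drop = FALSE], training = FALSE)
    out[i0:i1, ] <- fw$pred
  }
  out
}

#' @export
print.bp_train_history <- function(x, ...) {
  cat(sprintf(
    "<bp_train_history> %d epoch(s), best epoch %d (val MSE %.5f), stopped at %d\n",
    length(x$train_loss), x$best_epoch,
    if (x$best_epoch >= 1) x$val_loss[x$best_epoch] else NA_real_,
    x$stopped_epoch))
  invisible(x)
}

#' @export
plot.bp_train_history <- function(x, ...) {
  ep <- seq_along(x$train_loss)
  graphics::plot(ep, x$train_loss, type = "l", xlab = "epoch",
                 ylab = "MSE (standardized)", ...)
  graphics::lines(ep, x$val_loss, lty = 2)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "val"), lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Parameter checksum of a network
#'
#' Sum-based checksum over all trainable parameters; used to assert seeded
#' training determinism.
#'
#' @param net a `bp_net`.
#' @return a single numeric value.
#' @export
net_checksum <- function(net) {
  acc <- 0
  tree_map(net$params, function(p) { acc <<- acc + sum(p * seq_along(p)); p })
  acc
}
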