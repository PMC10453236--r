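# Dice-loss RMSprop training loop with per-epoch metric logging and
# best-checkpoint selection by validation mean dice.

#' Training settings
#'
#' @param learning_rate RMSprop step size (default 0.001).
#' @param batch_size minibatch size (default 6).
#' @param epochs number of passes over the training set.
#' @param seed integer seed controlling initial shuffling and any other
#'   randomness in the loop.
#' @param alpha RMSprop squared-gradient smoothing constant.
#' @param eps RMSprop denominator offset.
#' @param momentum RMSprop momentum (0 disables).
#' @param weight_decay L2 penalty coefficient (0 disables).
#' @param smooth dice-loss smoothing term.
#' @return a `gctu_train_settings` list.
#' @export
train_settings <- function(learning_rate = 0.001, batch_size = 6L,
                           epochs = 10L, seed = 1L, alpha = 0.99,
                           eps = 1e-8, momentum = 0, weight_decay = 0,
                           smooth = 1e-6) {
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  s <- list(optimizer = "rmsprop", learning_rate = learning_rate,
            batch_size = as.integer(batch_size), epochs = as.integer(epochs),
            seed = as.integer(seed), alpha = alpha, eps = eps,
            momentum = momentum, weight_decay = weight_decay,
            smooth = smooth)
  class(s) <- "gctu_train_settings"
  s
}

rmsprop_init <- function(flat) {
  list(v = lapply(flat, zeros_like),
       mom = lapply(flat, zeros_like))
}

rmsprop_step <- function(flat, gw, state, s) {
  for (nm in names(flat)) {
    g <- gw[[nm]]
    if (s$weight_decay > 0) g <- g + s$weight_decay * flat[[nm]]
    state$v[[nm]] <- s$alpha * state$v[[nm]] + (1 - s$alpha) * g * g
    upd <- g / (sqrt(state$v[[nm]]) + s$eps)
    if (s$momentum > 0) {
      state$mom[[nm]] <- s$momentum * state$mom[[nm]] + upd
      upd <- state$mom[[nm]]
    }
    flat[[nm]] <- flat[[nm]] - s$learning_rate * upd
  }
  list(flat = flat, state = state)
}

#' Train a GC-TransUnet model
#'
#' RMSprop optimisation of the soft dice loss. Every epoch the model is
#' evaluated on the validation set; the weights with the best validation
#' mean dice are retained in the returned fit. The run is fully seeded
#' (shuffling and weight initialisation both derive from `settings$seed`
#' unless the model was built beforehand).
#'
#' @param model a [gc_transunet()] model (its toy-scale configurations
#'   train on a CPU in minutes).
#' @param train_set,val_set non-empty sample lists (`$image`, `$mask`).
#' @param settings a [train_settings()] object.
#' @param log_path optional CSV path for the per-epoch log.
#' @param checkpoint_path optional path; the best checkpoint is saved there.
#' @param verbose print per-epoch progress.
#' @return a `gctu_fit` list: `model` (best weights), `log` (data frame of
#'   epoch, loss and the six validation metrics), `best_epoch`, `settings`.
#' @export
fit_gc_transunet <- function(model, train_set, val_set = train_set,
                             settings = train_settings(),
                             log_path = NULL, checkpoint_path = NULL,
                             verbose = FALSE) {
  stopifnot(length(train_set) >= 1L, length(val_set) >= 1L)
  set.seed(settings$seed)
  flat <- nn_collect(model)
  state <- rmsprop_init(flat)
  n <- length(train_set)
  best <- list(midce = -Inf, params = flat, epoch = 0L)
  log <- NULL
  for (epoch in seq_len(settings$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / settings$batch_size))
    ep_loss <- 0
    for (bi in batches) {
      x <- stack_images(train_set[bi])
      t <- stack_masks(train_set[bi])
      fw <- model_fwd(model, x, train = TRUE)
      sg <- sigmoid_fwd(fw$y)
      loss <- dice_loss(sg$y, t, smooth = settings$smooth)
      if (!is.finite(loss)) {
        stop(sprintf("training aborted: non-finite loss at epoch %d", epoch),
             call. = FALSE)
      }
      ep_loss <- ep_loss + loss * length(bi)
      dprob <- dice_loss_grad(sg$y, t, smooth = settings$smooth)
      dlogits <- sigmoid_bwd(sg$cache, dprob)
      bw <- model_bwd(model, fw$cache, dlogits)
      upd <- rmsprop_step(flat, bw$gw[names(flat)], state, settings)
      flat <- upd$flat
      state <- upd$state
      model <- nn_restore(model, flat)
    }
    ep_loss <- ep_loss / n
    vm <- evaluate_model(model, val_set,
                         batch_size = settings$batch_size)
    row <- data.frame(epoch = epoch, loss = ep_loss,
                      midce = vm$midce, accuracy = vm$accuracy,
                      recall = vm$recall, miou = vm$miou,
                      fwavacc = vm$fwavacc, f1 = vm$f1)
    log <- rbind(log, row)
    if (vm$midce > best$midce) {
      best <- list(midce = vm$midce, params = flat, epoch = epoch,
                   bn = collect_bn_stats(model))
    }
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val midce %.4f",
                      epoch, ep_loss, vm$midce))
    }
  }
  model <- nn_restore(model, best$params)
  if (!is.null(best$bn)) restore_bn_stats(model, best$bn)
  if (!is.null(log_path)) utils::write.csv(log, log_path, row.names = FALSE)
  if (!is.null(checkpoint_path)) {
    save_checkpoint(model, checkpoint_path, seed = settings$seed)
  }
  fit <- list(model = model, log = log, best_epoch = best$epoch,
              settings = settings)
  class(fit) <- "gctu_fit"
  fit
}

#' @export
print.gctu_fit <- function(x, ...) {
  cat(sprintf("GC-TransUnet fit: %d epochs, best epoch %d (val midce %.4f)\n",
              nrow(x$log), x$best_epoch, max(x$log$midce)))
  invisible(x)
}

#' Plot the training curve of a fit
#'
#' @param x a `gctu_fit` from [fit_gc_transunet()].
#' @param ... passed to [graphics::matplot()].
#' @export
plot.gctu_fit <- function(x, ...) {
  graphics::matplot(x$log$epoch, cbind(x$log$loss, x$log$midce),
                    type = "l", lty = 1, col = c("firebrick", "steelblue"),
                    xlab = "epoch", ylab = "value", ...)
  graphics::legend("right", legend = c("train dice loss", "val mean dice"),
                   col = c("firebrick", "steelblue"), lty = 1, bty = "n")
}
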