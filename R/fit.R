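#' Training configuration
#'
#' Bundles the optimisation settings used to fit the denoising network:
#' Adam with learning rate 0.0005 and mean-squared-error loss are the method's
#' stated settings; epochs, batch size and the early-stopping policy are
#' package defaults, documented in the methods vignette.
#'
#' @param epochs maximum training epochs.
#' @param batch_size mini-batch size.
#' @param lr Adam learning rate.
#' @param folds cross-validation folds used by the experiment drivers.
#' @param val_fraction fraction of the training data held out for validation
#'   (0 disables validation and early stopping).
#' @param patience early-stopping patience in epochs without validation
#'   improvement.
#' @param deep_supervision train auxiliary per-decoder outputs jointly.
#' @param seed RNG seed for initialisation, shuffling and splits.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 100L, batch_size = 32L, lr = 5e-4,
                         folds = 5L, val_fraction = 0.1, patience = 10L,
                         deep_supervision = FALSE, seed = 1L) {
  if (lr < 0) stop("learning rate must be non-negative")
  if (folds < 2L) stop("folds must be >= 2")
  if (val_fraction < 0 || val_fraction >= 1) stop("val_fraction must lie in [0, 1)")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, folds = as.integer(folds), val_fraction = val_fraction,
                 patience = as.integer(patience),
                 deep_supervision = isTRUE(deep_supervision),
                 seed = as.integer(seed)),
            class = "train_config")
}

# resolve (x_hat, y_hat) training matrices from the accepted input forms
as_pair_matrices <- function(pairs) {
  if (inherits(pairs, "contaminated_pairs"))
    return(list(x = pairs$x_hat, y = pairs$y_hat, fs = pairs$fs))
  if (is.list(pairs) && all(c("x", "y") %in% names(pairs)))
    return(list(x = rbind(pairs$x), y = rbind(pairs$y), fs = pairs$fs))
  stop("pairs must be a contaminated_pairs object or a list with x and y matrices")
}

# mean training loss of one batch + gradient accumulation + optimizer step
train_batch <- function(net, opt, xb, tb, deep_supervision) {
  tp <- ad_tape()
  ad_zero_grads(net$params)
  fw <- net_forward_tape(tp, net, xb, train = TRUE)
  loss <- op_mse(tp, fw$final, tb)
  if (deep_supervision && !is.null(fw$sides)) {
    losses <- c(list(loss), lapply(fw$sides, function(s) op_mse(tp, s, tb)))
    loss <- op_mean_scalar(tp, losses)
  }
  if (!is.finite(loss$val))
    stop("non-finite training loss; inspect the input scaling and learning rate")
  ad_backward(tp, loss)
  adam_step(opt)
  loss$val
}

eval_loss <- function(net, y, x, batch_size) {
  pred <- net_forward(net, y, batch_size)
  mean((pred - x)^2)
}

#' Fit the 1D full-scale multi-residual denoising network
#'
#' Trains the encoder-decoder network to map normalized contaminated EEG
#' segments \eqn{\hat y} to their normalized clean counterparts \eqn{\hat x}
#' by minimising mean squared error with the Adam optimizer
#' (learning rate 0.0005 by default). Early stopping monitors the validation
#' loss and the best-validation weights are kept.
#'
#' @param pairs training data: a `contaminated_pairs` batch from
#'   [realize_pairs()]/[realize_split()], or a list with normalized matrices
#'   `x` (targets) and `y` (inputs), segments in rows.
#' @param spec an [arch_spec()]; defaults to a depth-3, `n_base = 8` network
#'   sized to the training segments.
#' @param config a [train_config()].
#' @param verbose print per-epoch losses.
#' @return An object of class `mrunet3p`: the trained network, loss history
#'   and training metadata. Supports [predict()], `print`, `summary`,
#'   [coef()], [residuals()] and [plot()].
#' @examples
#' \donttest{
#' eeg <- surrogate_bank("EEG", 40, seed = 1)
#' eog <- surrogate_bank("EOG", 40, seed = 2)
#' man <- build_scenario_dataset(eeg, eog = eog, scenario = "EOG",
#'                               snr_levels = 0, seed = 3)
#' tr <- realize_pairs(man, 0)
#' fit <- mrunet3p(tr, spec = arch_spec(depth = 2, n_base = 4,
#'                                      input_length = 512),
#'                 config = train_config(epochs = 2, val_fraction = 0),
#'                 verbose = FALSE)
#' z <- predict(fit, tr)
#' }
#' @export
mrunet3p <- function(pairs, spec = NULL, config = train_config(),
                     verbose = TRUE) {
  dat <- as_pair_matrices(pairs)
  x <- dat$x; y <- dat$y
  n <- nrow(x); len <- ncol(x)
  if (is.null(spec)) spec <- arch_spec(input_length = len,
                                       deep_supervision = config$deep_supervision)
  if (config$deep_supervision && !spec$deep_supervision)
    spec$deep_supervision <- TRUE
  if (len != spec$input_length)
    stop("segment length ", len, " does not match spec input_length ",
         spec$input_length)

  net <- assemble_network(spec, seed = config$seed)
  opt <- adam_state(net$params, lr = config$lr)

  idx <- withr::with_seed(config$seed + 1L, sample.int(n))
  n_val <- floor(config$val_fraction * n)
  val_idx <- idx[seq_len(n_val)]
  tr_idx <- idx[setdiff(seq_len(n), seq_len(n_val))]

  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best_val <- Inf; best_snapshot <- NULL; stale <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- withr::with_seed(config$seed + 1000L + epoch, sample(tr_idx))
    losses <- c()
    for (start in seq(1L, length(ord), by = config$batch_size)) {
      b <- ord[start:min(length(ord), start + config$batch_size - 1L)]
      xb <- mat_to_input(y[b, , drop = FALSE])
      tb <- mat_to_input(x[b, , drop = FALSE])
      losses <- c(losses, train_batch(net, opt, xb, tb, spec$deep_supervision))
    }
    vl <- if (n_val > 0L)
      eval_loss(net, y[val_idx, , drop = FALSE], x[val_idx, , drop = FALSE],
                config$batch_size) else NA_real_
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(losses),
                                         val_loss = vl))
    if (verbose)
      message(sprintf("epoch %3d  train MSE %.5f%s", epoch, mean(losses),
                      if (is.na(vl)) "" else sprintf("  val MSE %.5f", vl)))
    if (n_val > 0L) {
      if (vl < best_val - 1e-12) {
        best_val <- vl; stale <- 0L
        best_snapshot <- lapply(net$params, function(p) p$val)
      } else {
        stale <- stale + 1L
        if (stale >= config$patience) {
          if (verbose) message("early stop at epoch ", epoch)
          break
        }
      }
    }
  }
  if (!is.null(best_snapshot))
    for (i in seq_along(net$params)) net$params[[i]]$val <- best_snapshot[[i]]

  structure(list(net = net, spec = spec, config = config, history = history,
                 n_train = length(tr_idx), n_val = n_val,
                 best_val = if (n_val > 0L) best_val else NA_real_,
                 fs = dat$fs, data = pairs, call = match.call()),
            class = "mrunet3p")
}

#' @export
print.mrunet3p <- function(x, ...) {
  cat("Fitted 1D full-scale multi-residual denoising network\n")
  print(x$net)
  h <- x$history
  cat(sprintf("  trained %d epochs on %d segments (%d validation); final train MSE %.5f",
              nrow(h), x$n_train, x$n_val, h$train_loss[nrow(h)]))
  if (!is.na(x$best_val)) cat(sprintf(", best val MSE %.5f", x$best_val))
  cat("\n")
  invisible(x)
}

#' @export
summary.mrunet3p <- function(object, ...) {
  structure(list(fit = object), class = "summary.mrunet3p")
}

#' @export
print.summary.mrunet3p <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nResidual-path census (per decoder):\n")
  print(fit$net$structure, row.names = FALSE)
  cat(sprintf("\nDecoders: %d; incoming paths per decoder: %d; trainable parameters: %s\n",
              fit$spec$depth - 1L, fit$spec$depth,
              format(n_params(fit$net), big.mark = ",")))
  invisible(x)
}

#' Predict denoised segments
#'
#' @param object a fitted `mrunet3p` model.
#' @param newdata a `contaminated_pairs` batch or a matrix of normalized
#'   contaminated segments (rows); defaults to the training data.
#' @param batch_size forward mini-batch size.
#' @param ... unused.
#' @return Matrix of predicted normalized clean segments \eqn{\hat z}.
#' @export
predict.mrunet3p <- function(object, newdata = NULL, batch_size = 64L, ...) {
  if (is.null(newdata)) newdata <- object$data
  y <- if (inherits(newdata, "contaminated_pairs")) newdata$y_hat
       else rbind(newdata)
  net_forward(object$net, y, batch_size)
}

#' @export
residuals.mrunet3p <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  dat <- as_pair_matrices(newdata)
  predict(object, dat$y) - dat$x
}

#' @export
coef.mrunet3p <- function(object, ...) {
  vals <- lapply(object$net$params, function(p) p$val)
  names(vals) <- sprintf("param_%03d", seq_along(vals))
  vals
}

#' @export
plot.mrunet3p <- function(x, which = c("loss", "example"), segment = 1L, ...) {
  which <- match.arg(which)
  if (which == "loss") {
    h <- x$history
    graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                   ylab = "MSE loss", main = "Training history", ...)
    if (!all(is.na(h$val_loss))) {
      graphics::lines(h$epoch, h$val_loss, lty = 2)
      graphics::legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
    }
  } else {
    dat <- as_pair_matrices(x$data)
    z <- predict(x, dat$y[segment, , drop = FALSE])
    t_ax <- seq_len(ncol(z))
    graphics::plot(t_ax, dat$y[segment, ], type = "l", col = "grey60",
                   xlab = "sample", ylab = "normalized amplitude",
                   main = sprintf("Segment %d: noisy / clean / denoised", segment), ...)
    graphics::lines(t_ax, dat$x[segment, ], col = "black")
    graphics::lines(t_ax, z[1L, ], col = "red")
    graphics::legend("topright", c("noisy", "clean", "denoised"),
                     col = c("grey60", "black", "red"), lty = 1, bty = "n")
  }
  invisible(x)
}
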