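#' Mean squared reconstruction loss
#'
#' The training objective: `mean((g(M) - N)^2)` between the model output
#' and the clean (normal-dose) target. Non-negative, zero exactly when the
#' images coincide.
#'
#' @param model_output,normal_dose `image_grid`s or matrices, same shape.
#' @return Scalar MSE.
#' @export
mse_loss <- function(model_output, normal_dose) {
  a <- as_pixels(model_output); b <- as_pixels(normal_dose)
  check_same_shape(a, b)
  mean((a - b)^2)
}

#' Training configuration
#'
#' Defaults are the desk-scale study conditions: adaptive-moment gradient
#' descent (Adam), learning rate 1e-3, batch size 8, 30 epochs, an 80/20
#' train/validation split deterministic from the seed, and a single
#' recursion during training (the cascaded 2-channel input; recursion is
#' applied at inference). Training crops random `patch_side` patches when
#' images are larger.
#'
#' @param epochs Number of passes over the training split, `>= 1`.
#' @param batch_size Images per gradient step, `>= 1`.
#' @param learning_rate Adam step size, `> 0`.
#' @param seed Integer seed controlling the split, shuffling and crops.
#' @param train_fraction Fraction of pairs used for training, in (0, 1).
#' @param recursions_during_training Unrolled recursions the loss is
#'   applied through, `>= 1` (default 1).
#' @param patch_side Training crop side; images at or below this size are
#'   used whole.
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 30L, batch_size = 8L, learning_rate = 1e-3,
                         seed = 0L, train_fraction = 0.8,
                         recursions_during_training = 1L, patch_side = 64L) {
  if (epochs < 1 || batch_size < 1 || learning_rate <= 0)
    stop_invalid("epochs, batch_size must be >= 1 and learning_rate > 0")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_invalid("'train_fraction' must be in (0, 1)")
  if (recursions_during_training < 1)
    stop_invalid("'recursions_during_training' must be >= 1")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 train_fraction = train_fraction,
                 recursions_during_training =
                   as.integer(recursions_during_training),
                 patch_side = as.integer(patch_side)),
            class = "train_config")
}

# Forward through r unrolled recursions with caches; returns final output,
# loss and the parameter gradient (summed over recursions, since weights
# are shared).
train_step_grad <- function(model, m_px, target_px, r) {
  caches <- vector("list", r)
  out <- m_px
  for (n in seq_len(r)) {
    j <- array(c(m_px, out), c(dim(m_px), 2L))
    fw <- codec_forward(model, j, keep_cache = TRUE)
    caches[[n]] <- fw$cache
    out <- fw$y
  }
  loss <- mean((out - target_px)^2)
  gy <- 2 * (out - target_px) / length(out)
  gtot <- NULL
  for (n in rev(seq_len(r))) {
    bw <- codec_backward(model, caches[[n]], gy)
    gtot <- if (is.null(gtot)) bw$grads else params_add(gtot, bw$grads)
    if (n > 1L) gy <- bw$gx[, , 2]  # gradient into the previous output
  }
  list(loss = loss, grads = gtot, output = out)
}

#' Train the residual codec on paired data
#'
#' Minimizes the mean squared error between the model output `g(M)` and
#' the clean image over a dataset of [degrade()] pairs with Adam. The
#' model input at each step is the cascade stack of the degraded image
#' (duplicated on the first recursion). Fully reproducible from the
#' configuration seed. Aborts with a diagnostic if the loss becomes
#' non-finite.
#'
#' @param model A `denoiser_model` with `in_channels = 2`.
#' @param dataset Non-empty list of `degraded_pair`s.
#' @param config A [train_config()].
#' @return A list of class `train_result`: `model` (updated), `trace`
#'   (a `loss_trace` with per-epoch train/validation MSE).
#' @export
train <- function(model, dataset, config = train_config()) {
  if (length(dataset) < 1L) stop_invalid("'dataset' must be non-empty")
  if (!inherits(config, "train_config"))
    stop_invalid("'config' must be a train_config")
  if (model$config$in_channels != 2L)
    stop_invalid("training expects a 2-input-channel model (cascade input)")

  n <- length(dataset)
  with_seed(config$seed, {
    n_train <- max(1L, floor(config$train_fraction * n))
    idx <- sample.int(n)
    train_idx <- idx[seq_len(n_train)]
    val_idx <- setdiff(idx, train_idx)

    params <- model$params
    state <- adam_init(params)
    tr_loss <- val_loss <- numeric(config$epochs)
    r <- config$recursions_during_training

    for (ep in seq_len(config$epochs)) {
      order_ep <- sample(train_idx)
      batches <- split(order_ep, ceiling(seq_along(order_ep) /
                                           config$batch_size))
      ep_losses <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        gacc <- NULL; lacc <- 0
        for (i in batches[[bi]]) {
          pr <- crop_pair(dataset[[i]], config$patch_side)
          model$params <- params
          st <- train_step_grad(model, pr$m, pr$target, r)
          gacc <- if (is.null(gacc)) st$grads else params_add(gacc, st$grads)
          lacc <- lacc + st$loss
        }
        nb <- length(batches[[bi]])
        gacc <- params_scale(gacc, 1 / nb)
        lacc <- lacc / nb
        if (!is.finite(lacc))
          stop_invalid("training diverged: non-finite loss at epoch ", ep)
        up <- adam_step(params, gacc, state, lr = config$learning_rate)
        params <- up$params; state <- up$state
        ep_losses[bi] <- lacc
      }
      tr_loss[ep] <- mean(ep_losses)
      model$params <- params
      val_loss[ep] <- if (length(val_idx))
        mean(vapply(val_idx, function(i) {
          pr <- dataset[[i]]
          j <- cascade(pr$degraded, pr$degraded)
          mse_loss(codec_forward(model, j)$y, pr$clean$pixels)
        }, numeric(1))) else NA_real_
    }
    model$params <- params
    trace <- structure(list(train = tr_loss, validation = val_loss,
                            epochs = config$epochs),
                       class = "loss_trace")
    structure(list(model = model, trace = trace, config = config),
              class = "train_result")
  })
}

crop_pair <- function(pair, patch_side) {
  m <- pair$degraded$pixels; tg <- pair$clean$pixels
  if (nrow(m) > patch_side && ncol(m) > patch_side) {
    i <- sample.int(nrow(m) - patch_side + 1L, 1)
    j <- sample.int(ncol(m) - patch_side + 1L, 1)
    m <- m[i:(i + patch_side - 1L), j:(j + patch_side - 1L)]
    tg <- tg[i:(i + patch_side - 1L), j:(j + patch_side - 1L)]
  }
  list(m = m, target = tg)
}

#' @export
print.loss_trace <- function(x, ...) {
  cat(sprintf("<loss_trace> %d epochs; train MSE %.3g -> %.3g\n",
              x$epochs, x$train[1], x$train[x$epochs]))
  invisible(x)
}

#' @export
print.train_result <- function(x, ...) {
  print(x$model); print(x$trace)
  invisible(x)
}

#' Plot a training loss trace
#'
#' @param x A `loss_trace`.
#' @param y Ignored.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.loss_trace <- function(x, y, ...) {
  graphics::matplot(seq_len(x$epochs), cbind(x$train, x$validation),
                    type = "l", lty = 1:2, col = c("black", "grey40"),
                    xlab = "epoch", ylab = "MSE", log = "y", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1:2,
                   col = c("black", "grey40"), bty = "n")
  invisible(x)
}

#' Evaluate a model on paired data
#'
#' For every pair, reports the PSNR and SSIM of the recursive output
#' against the clean reference side by side with those of the degraded
#' input, plus their arithmetic means.
#'
#' @param model A `denoiser_model`.
#' @param dataset Non-empty list of `degraded_pair`s.
#' @param n_recursions Recursions at inference (default 3).
#' @return A list of class `denoise_eval`: `per_pair` (data frame with
#'   columns `pair`, `psnr_in`, `psnr_out`, `ssim_in`, `ssim_out`) and
#'   `aggregate` (named means).
#' @export
evaluate <- function(model, dataset, n_recursions = 3L) {
  if (length(dataset) < 1L) stop_invalid("'dataset' must be non-empty")
  rows <- lapply(seq_along(dataset), function(i) {
    pr <- dataset[[i]]
    out <- recursive_denoise(model, pr$degraded, n_total = n_recursions)
    data.frame(pair = i,
               psnr_in = psnr(pr$clean, pr$degraded),
               psnr_out = psnr(pr$clean, out),
               ssim_in = ssim(pr$clean, pr$degraded),
               ssim_out = ssim(pr$clean, out))
  })
  per_pair <- do.call(rbind, rows)
  agg <- colMeans(per_pair[, -1])
  structure(list(per_pair = per_pair, aggregate = agg,
                 n_recursions = n_recursions),
            class = "denoise_eval")
}

#' @export
print.denoise_eval <- function(x, ...) {
  cat(sprintf("<denoise_eval> %d pairs, %d recursion(s)\n",
              nrow(x$per_pair), x$n_recursions))
  cat(sprintf("  mean PSNR: %.2f dB in -> %.2f dB out (gain %+.2f dB)\n",
              x$aggregate["psnr_in"], x$aggregate["psnr_out"],
              x$aggregate["psnr_out"] - x$aggregate["psnr_in"]))
  cat(sprintf("  mean SSIM: %.4f in -> %.4f out\n",
              x$aggregate["ssim_in"], x$aggregate["ssim_out"]))
  invisible(x)
}

#' Fit the scalar linear residual toy model by gradient descent
#'
#' The smallest instance of residual learning: the whole residual branch
#' is one 1x1 linear layer, `g(m) = m + (w m + b)`, fitted to targets `n`
#' by Adam on the mean squared error. The optimum has the closed form of a
#' least-squares regression of `n - m` on `m`, which makes the routine a
#' convergence check for the optimizer.
#'
#' @param m Numeric vector of inputs (noisy values).
#' @param n Numeric vector of targets (clean values), same length.
#' @param steps Gradient steps.
#' @param lr Adam learning rate.
#' @return List with `w`, `b` and the final `loss`.
#' @export
fit_linear_residual <- function(m, n, steps = 3000L, lr = 0.02) {
  stopifnot(length(m) == length(n), length(m) >= 2L)
  params <- list(w = 0, b = 0)
  state <- adam_init(params)
  for (s in seq_len(steps)) {
    resid <- m + params$w * m + params$b - n
    grads <- list(w = 2 * mean(resid * m), b = 2 * mean(resid))
    up <- adam_step(params, grads, state, lr = lr)
    params <- up$params; state <- up$state
  }
  resid <- m + params$w * m + params$b - n
  list(w = params$w, b = params$b, loss = mean(resid^2))
}
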