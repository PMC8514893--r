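#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 log10(D^2 / MSE)` in decibels, where
#' `MSE = mean((reference - test)^2)` and `D` is the dynamic range (max
#' minus min representable pixel value). Identical images have zero MSE and
#' return `Inf`, a documented sentinel, never an error. The statistic is
#' symmetric in its two image arguments and strictly decreasing in MSE for
#' fixed `D`.
#'
#' A nonstandard `numerator = "D"` variant (ratio `D / MSE`) is available
#' for compatibility with definitions that omit the square; the default is
#' the standard squared form.
#'
#' @param reference,test `image_grid`s or numeric matrices, same shape.
#' @param D Dynamic range; default taken from `reference` when it is an
#'   `image_grid`, else 1. Must be `> 0`.
#' @param numerator `"D2"` (standard) or `"D"`.
#' @return PSNR in dB (possibly `Inf`).
#' @export
#' @examples
#' a <- image_grid(matrix(0, 4, 4))
#' b <- image_grid(matrix(1, 4, 4))
#' psnr(a, b)        # MSE = 1, D = 1 -> 0 dB
psnr <- function(reference, test, D = NULL, numerator = c("D2", "D")) {
  numerator <- match.arg(numerator)
  if (is.null(D)) {
    D <- if (inherits(reference, "image_grid")) reference$dynamic_range else 1
  }
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D <= 0)
    stop_invalid("'D' must be a positive scalar")
  p <- as_pixels(reference); q <- as_pixels(test)
  check_same_shape(p, q)
  mse <- mean((p - q)^2)
  if (mse == 0) return(Inf)
  num <- if (numerator == "D2") D^2 else D
  10 * log10(num / mse)
}

#' Structural similarity index
#'
#' `SSIM = (2 m_p m_q + z1)(2 cov_pq + z2) /
#'   ((m_p^2 + m_q^2 + z1)(var_p + var_q + z2))`,
#' where `m` are means, `var` variances (population, i.e. divisor `n`),
#' and `cov` the covariance. The spread terms enter the denominator as
#' variances (squared standard deviations), the canonical form. The
#' stabilizing constants default to `z1 = (0.01 D)^2`, `z2 = (0.03 D)^2`.
#'
#' In `"global"` mode (the default) the statistics are computed once over
#' the whole image; in `"windowed"` mode the same expression is averaged
#' over all sliding `window_side x window_side` windows (stride 1). A
#' window at least as large as the image reduces windowed mode to global
#' mode exactly.
#'
#' @param p,p_hat `image_grid`s or numeric matrices, same shape, at least
#'   2 pixels.
#' @param z1,z2 Positive stabilizing constants; defaults derived from `D`.
#' @param mode `"global"` or `"windowed"`.
#' @param window_side Window side for windowed mode, `>= 3`.
#' @param D Dynamic range used for the default constants; taken from `p`
#'   when it is an `image_grid`, else 1.
#' @return SSIM value (1 for identical images; `<= 1 + 1e-12` in global
#'   mode on real images with the standard constants).
#' @export
#' @examples
#' a <- image_grid(matrix(runif(64), 8, 8))
#' ssim(a, a)  # 1
ssim <- function(p, p_hat, z1 = NULL, z2 = NULL,
                 mode = c("global", "windowed"), window_side = 8L, D = NULL) {
  mode <- match.arg(mode)
  if (is.null(D)) D <- if (inherits(p, "image_grid")) p$dynamic_range else 1
  if (is.null(z1)) z1 <- (0.01 * D)^2
  if (is.null(z2)) z2 <- (0.03 * D)^2
  if (z1 <= 0 || z2 <= 0) stop_invalid("'z1' and 'z2' must be positive")
  x <- as_pixels(p); y <- as_pixels(p_hat)
  check_same_shape(x, y)
  if (length(x) < 2L) stop_invalid("SSIM needs at least 2 pixels")
  if (mode == "global" || window_side >= max(dim(x))) {
    return(ssim_stat(x, y, z1, z2))
  }
  if (window_side < 3L) stop_invalid("'window_side' must be >= 3")
  w <- min(window_side, nrow(x), ncol(x))
  nr <- nrow(x) - w + 1L; nc <- ncol(x) - w + 1L
  acc <- 0
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      acc <- acc + ssim_stat(x[i:(i + w - 1L), j:(j + w - 1L)],
                             y[i:(i + w - 1L), j:(j + w - 1L)], z1, z2)
    }
  }
  acc / (nr * nc)
}

# SSIM expression on whole-block statistics (population moments).
ssim_stat <- function(x, y, z1, z2) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2) / n
  vy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  ((2 * mx * my + z1) * (2 * cxy + z2)) /
    ((mx^2 + my^2 + z1) * (vx + vy + z2))
}

#' Metric report for one image pair
#'
#' Convenience wrapper computing both metrics for a (reference, test) pair.
#'
#' @inheritParams psnr
#' @param ... Passed to [ssim()].
#' @return A list with `psnr_db`, `ssim` and `n_pixels`.
#' @export
metric_report <- function(reference, test, D = NULL, ...) {
  list(psnr_db = psnr(reference, test, D = D),
       ssim = ssim(reference, test, D = D, ...),
       n_pixels = length(as_pixels(reference)))
}
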