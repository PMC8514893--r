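#' Cascade an output with the original input image
#'
#' Builds the 2-channel stack fed to the codec at each recursion: the
#' original noisy image `M` is carried alongside the previous output so no
#' information from the initial image is lost across recursions. Channel 1
#' always holds `M`, channel 2 the previous output `O_prev`; the first
#' recursion uses `cascade(M, M)`, duplicating `M` into both channels so
#' the network arity is constant.
#'
#' @param O_prev Previous recursion output (`image_grid` or matrix).
#' @param M The original input image (`image_grid` or matrix).
#' @return An `H x W x 2` array with attribute `dynamic_range`.
#' @export
#' @examples
#' m <- image_grid(matrix(runif(64), 8, 8))
#' j1 <- cascade(m, m)
#' identical(j1[, , 1], m$pixels)
cascade <- function(O_prev, M) {
  D <- if (inherits(M, "image_grid")) M$dynamic_range else 1
  o <- as_pixels(O_prev); m <- as_pixels(M)
  check_same_shape(o, m)
  out <- array(c(m, o), c(dim(m), 2L))
  attr(out, "dynamic_range") <- D
  out
}

#' Recursive denoising
#'
#' Applies the codec repeatedly: `J_1 = cascade(M, M)`,
#' `O_n = codec(J_n)`, `J_{n+1} = cascade(O_n, M)`, returning the final
#' `O_N`. The same model (shared weights) is used at every recursion; the
#' original image is re-injected through the cascade each time.
#'
#' @param model A 2-input-channel `denoiser_model`.
#' @param M Noisy input `image_grid`.
#' @param n_total Number of recursions `N >= 1` (default 3).
#' @param keep_history If `TRUE`, also return every intermediate `O_n`.
#' @return The denoised `image_grid`; with `keep_history`, a list with
#'   elements `output` and `history` (list of length `n_total`).
#' @export
recursive_denoise <- function(model, M, n_total = 3L, keep_history = FALSE) {
  if (n_total < 1) stop_invalid("'n_total' must be >= 1")
  if (model$config$in_channels != 2L)
    stop_invalid("recursive denoising needs a 2-input-channel model")
  if (!inherits(M, "image_grid")) M <- image_grid(as_pixels(M))
  history <- if (keep_history) vector("list", n_total) else NULL
  out <- M
  for (n in seq_len(n_total)) {
    out <- denoise_once(model, cascade(out, M))
    if (keep_history) history[[n]] <- out
  }
  if (keep_history) list(output = out, history = history) else out
}
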