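#' Residual codec configuration
#'
#' Architecture of the shallow residual encoder-decoder. The encoder has
#' `n_encoder_stages` resolution levels, each a residual unit followed by a
#' stride-2 downsampling convolution; the decoder mirrors it with
#' nearest-neighbour upsampling, a convolution, a skip-addition of the
#' matching encoder feature, and a residual unit. Channel width is constant
#' (`base_channels`) after the head convolution. The final (tail)
#' convolution maps back to one channel and is zero-initialized, so an
#' untrained model is exactly the identity on its designated input channel:
#' the network output is `G(M) + M`, residual learning.
#'
#' @param in_channels 2 for the recursion cascade (default), 1 standalone.
#' @param n_encoder_stages,n_decoder_stages Number of resolution levels;
#'   must be equal (the decoder mirrors the encoder).
#' @param base_channels Feature channels per layer.
#' @param kernel_side Odd convolution kernel side, `>= 1`.
#' @param activation `"relu"` or `"linear"`.
#' @param m_channel Index of the input channel holding the original image
#'   `M` added back by the final skip (channel 1 under [cascade()]).
#' @return A `codec_config` object.
#' @export
codec_config <- function(in_channels = 2L, n_encoder_stages = 2L,
                         n_decoder_stages = n_encoder_stages,
                         base_channels = 12L, kernel_side = 3L,
                         activation = c("relu", "linear"), m_channel = 1L) {
  activation <- match.arg(activation)
  if (n_encoder_stages != n_decoder_stages)
    stop_invalid("encoder and decoder must have the same number of stages")
  if (n_encoder_stages < 1L) stop_invalid("need at least one stage")
  if (kernel_side %% 2 != 1 || kernel_side < 1)
    stop_invalid("'kernel_side' must be odd and >= 1")
  if (base_channels < 1L) stop_invalid("'base_channels' must be >= 1")
  if (!m_channel %in% seq_len(in_channels))
    stop_invalid("'m_channel' must index an input channel")
  structure(list(in_channels = as.integer(in_channels),
                 n_stages = as.integer(n_encoder_stages),
                 base_channels = as.integer(base_channels),
                 kernel_side = as.integer(kernel_side),
                 activation = activation, m_channel = as.integer(m_channel)),
            class = "codec_config")
}

# ---- low-level layer helpers -------------------------------------------

# conv layer parameters: w is a (k*k*Cin) x Cout matrix (column-major
# flattening of the [k, k, Cin, Cout] kernel), b a length-Cout vector.
conv_layer_init <- function(k, cin, cout, zero = FALSE) {
  fan_in <- k * k * cin
  w <- if (zero) matrix(0, fan_in, cout)
       else matrix(rnorm(fan_in * cout, 0, sqrt(2 / fan_in)), fan_in, cout)
  list(w = w, b = numeric(cout))
}

conv_apply <- function(x, layer, k) {
  cpp_conv2d_same(x, layer$w, layer$b, k)
}

act_fun <- function(x, activation) {
  if (activation == "relu") pmax(x, 0) else x
}
act_grad <- function(pre, activation) {
  if (activation == "relu") (pre > 0) * 1 else array(1, dim(pre))
}

as_feature <- function(x) {
  if (inherits(x, "image_grid")) x <- x$pixels
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3L) stop_invalid("feature maps must be H x W x C arrays")
  x
}

# ---- residual unit (two stacked convolutions + skip) -------------------

#' Construct a residual unit
#'
#' The basic building block: two stacked convolution layers whose output
#' `F(O)` is added to the block input through a skip connection,
#' `O' = O + F(O, Q)`. When the input and output channel counts differ the
#' skip cannot be the identity and a 1x1 dimension-mapping convolution
#' `H_s` is used instead: `O' = F(O, Q) + H_s(O)` (see
#' [projection_skip()]).
#'
#' @param channels_in,channels_out Channel counts; `H_s` is created
#'   automatically when they differ.
#' @param kernel_side Odd kernel side.
#' @param activation `"relu"` or `"linear"` between the two convolutions.
#' @param seed Seed for the variance-scaled random initialization.
#' @return A `residual_unit` parameter object.
#' @export
residual_unit <- function(channels_in, channels_out = channels_in,
                          kernel_side = 3L,
                          activation = c("relu", "linear"), seed = 0L) {
  activation <- match.arg(activation)
  with_seed(seed, {
    u <- list(c1 = conv_layer_init(kernel_side, channels_in, channels_out),
              c2 = conv_layer_init(kernel_side, channels_out, channels_out),
              hs = if (channels_in != channels_out)
                matrix(rnorm(channels_in * channels_out,
                             0, sqrt(1 / channels_in)),
                       channels_in, channels_out) else NULL,
              kernel = as.integer(kernel_side), activation = activation,
              channels_in = as.integer(channels_in),
              channels_out = as.integer(channels_out))
    class(u) <- "residual_unit"
    u
  })
}

#' Forward pass of a residual unit
#'
#' Computes `O + F(O, Q)` where `F` is the two-convolution branch; with a
#' channel mismatch the skip goes through the unit's 1x1 mapping,
#' `F(O, Q) + H_s(O)`. With all branch weights zero the unit is the
#' identity (or the pure `H_s` map when channels differ).
#'
#' @param x Input feature map, `H x W x C` array (a matrix is treated as
#'   one channel), or an `image_grid`.
#' @param unit A [residual_unit()].
#' @return Feature map of shape `H x W x channels_out`.
#' @export
residual_unit_forward <- function(x, unit) {
  x <- as_feature(x)
  if (dim(x)[3] != unit$channels_in)
    stop_invalid("residual unit expects ", unit$channels_in,
                 " input channels, got ", dim(x)[3])
  k <- unit$kernel
  h <- act_fun(conv_apply(x, unit$c1, k), unit$activation)
  f <- conv_apply(h, unit$c2, k)
  skip <- if (is.null(unit$hs)) x else channel_map(x, unit$hs)
  skip + f
}

# 1x1 convolution expressed as a channel-space matrix product.
channel_map <- function(x, hs) {
  d <- dim(x)
  y <- matrix(x, d[1] * d[2], d[3]) %*% hs
  array(y, c(d[1], d[2], ncol(hs)))
}

#' Dimension-mapping skip connection
#'
#' Applies the 1x1 mapping `H_s` that reconciles channel counts so the
#' skip addition of a residual unit is well-formed. Intended only for
#' channel mismatches: when the map is square (input and output channel
#' counts already match) the function warns and returns the input
#' unchanged (identity behavior).
#'
#' @param x Feature map (`H x W x C` array or matrix).
#' @param hs `C_in x C_out` mapping matrix.
#' @return Mapped feature map.
#' @export
projection_skip <- function(x, hs) {
  x <- as_feature(x)
  if (!is.matrix(hs)) stop_invalid("'hs' must be a matrix")
  if (dim(x)[3] != nrow(hs))
    stop_invalid("'hs' must have one row per input channel")
  if (nrow(hs) == ncol(hs)) {
    warning("projection skip applied where channel counts already match; ",
            "returning input unchanged")
    return(x)
  }
  channel_map(x, hs)
}

# ---- full codec ---------------------------------------------------------

#' Build a residual encoder-decoder denoiser
#'
#' Assembles the codec described by a [codec_config()] with deterministic,
#' seed-fixed variance-scaled initialization. The tail convolution starts
#' at zero, so the freshly built model maps any input to its `m_channel`
#' unchanged (`g(M) = 0 + M`).
#'
#' @param config A [codec_config()].
#' @param seed Integer seed for parameter initialization.
#' @return A `denoiser_model` (list of `config` and `params`).
#' @export
#' @examples
#' m <- build_codec(codec_config(n_encoder_stages = 1, base_channels = 4), seed = 1)
#' n_parameters(m)
build_codec <- function(config = codec_config(), seed = 0L) {
  if (!inherits(config, "codec_config"))
    stop_invalid("'config' must be a codec_config")
  k <- config$kernel_side; B <- config$base_channels; S <- config$n_stages
  with_seed(seed, {
    params <- list(
      head = conv_layer_init(k, config$in_channels, B),
      enc = lapply(seq_len(S), function(s) unit_params(k, B)),
      down = lapply(seq_len(S), function(s) conv_layer_init(k, B, B)),
      bottom = unit_params(k, B),
      up = lapply(seq_len(S), function(s) conv_layer_init(k, B, B)),
      dec = lapply(seq_len(S), function(s) unit_params(k, B)),
      tail = conv_layer_init(k, B, 1L, zero = TRUE))
    structure(list(config = config, params = params),
              class = "denoiser_model")
  })
}

unit_params <- function(k, channels) {
  list(c1 = conv_layer_init(k, channels, channels),
       c2 = conv_layer_init(k, channels, channels))
}

#' @export
print.denoiser_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<denoiser_model> %d stage(s), %d channels, %dx%d ",
                     "kernels, %s, %d input channel(s), %d parameters\n"),
              cfg$n_stages, cfg$base_channels, cfg$kernel_side,
              cfg$kernel_side, cfg$activation, cfg$in_channels,
              n_parameters(x)))
  invisible(x)
}

#' Total parameter count of a model
#'
#' @param model A `denoiser_model`.
#' @return Integer count of scalar weights and biases.
#' @export
n_parameters <- function(model) {
  n <- 0L
  walk <- function(p) {
    for (el in p) {
      if (is.list(el)) walk(el)
      else n <<- n + length(el)
    }
  }
  walk(model$params)
  n
}

min_side_multiple <- function(config) 2L^config$n_stages

check_codec_input <- function(config, x) {
  d <- dim(x)
  m <- min_side_multiple(config)
  if (d[1] %% m != 0 || d[2] %% m != 0 || d[1] < m || d[2] < m)
    stop_invalid("input sides must be positive multiples of 2^n_stages = ",
                 m, " (got ", d[1], " x ", d[2], ")")
  if (d[3] != config$in_channels)
    stop_invalid("model expects ", config$in_channels,
                 " input channel(s), got ", d[3])
  invisible(TRUE)
}

downsample2 <- function(x) {
  x[seq(1, dim(x)[1], by = 2), seq(1, dim(x)[2], by = 2), , drop = FALSE]
}
upsample2 <- function(x) {
  x[rep(seq_len(dim(x)[1]), each = 2), rep(seq_len(dim(x)[2]), each = 2), ,
    drop = FALSE]
}

# Forward pass. Returns list(y = H x W output matrix, cache) where cache
# holds every intermediate needed by codec_backward.
codec_forward <- function(model, x, keep_cache = FALSE) {
  cfg <- model$config; p <- model$params
  k <- cfg$kernel_side; S <- cfg$n_stages; actv <- cfg$activation
  x <- as_feature(x)
  check_codec_input(cfg, x)

  cache <- if (keep_cache) list(x = x) else NULL
  head_pre <- conv_apply(x, p$head, k)
  a <- act_fun(head_pre, actv)
  if (keep_cache) cache$head_pre <- head_pre

  e <- vector("list", S)
  if (keep_cache) {
    cache$enc <- vector("list", S); cache$down <- vector("list", S)
  }
  for (s in seq_len(S)) {
    u <- unit_fwd(a, p$enc[[s]], k, actv, keep_cache)
    e[[s]] <- u$out
    if (keep_cache) cache$enc[[s]] <- u$cache
    pre <- conv_apply(e[[s]], p$down[[s]], k)
    a <- downsample2(act_fun(pre, actv))
    if (keep_cache) cache$down[[s]] <- list(input = e[[s]], pre = pre)
  }

  u <- unit_fwd(a, p$bottom, k, actv, keep_cache)
  a <- u$out
  if (keep_cache) cache$bottom <- u$cache

  if (keep_cache) {
    cache$up <- vector("list", S); cache$dec <- vector("list", S)
  }
  for (s in rev(seq_len(S))) {
    us <- upsample2(a)
    pre <- conv_apply(us, p$up[[s]], k)
    a <- act_fun(pre, actv) + e[[s]]
    if (keep_cache) cache$up[[s]] <- list(us = us, pre = pre)
    u <- unit_fwd(a, p$dec[[s]], k, actv, keep_cache)
    a <- u$out
    if (keep_cache) cache$dec[[s]] <- u$cache
  }

  tail_pre <- conv_apply(a, p$tail, k)
  if (keep_cache) cache$tail_in <- a
  y <- tail_pre[, , 1] + x[, , cfg$m_channel]
  list(y = y, cache = cache)
}

unit_fwd <- function(x, unit, k, actv, keep_cache) {
  h_pre <- conv_apply(x, unit$c1, k)
  h <- act_fun(h_pre, actv)
  f <- conv_apply(h, unit$c2, k)
  list(out = x + f,
       cache = if (keep_cache) list(x = x, h_pre = h_pre, h = h) else NULL)
}

#' Apply the denoiser once
#'
#' A single forward pass: the model output is `G(input) + M`, where `M` is
#' the designated original-image channel of the input and `G` the learned
#' residual mapping. For a 2-channel model feed a [cascade()] stack; a
#' 1-channel model takes an `image_grid` directly.
#'
#' @param model A `denoiser_model`.
#' @param input An `image_grid` (1-channel models) or an `H x W x C` array
#'   such as a [cascade()] stack. Sides must be multiples of
#'   `2^n_stages`.
#' @return Denoised `image_grid`.
#' @export
denoise_once <- function(model, input) {
  D <- if (inherits(input, "image_grid")) input$dynamic_range
       else attr(input, "dynamic_range") %||% 1
  out <- codec_forward(model, input, keep_cache = FALSE)
  if (!all(is.finite(out$y))) stop_invalid("model produced non-finite output")
  image_grid(out$y, D)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- checkpoint serialization ------------------------------------------

#' Save and load model checkpoints
#'
#' A checkpoint is a single JSON document holding the configuration and
#' every parameter array (with dimensions), so models round-trip exactly
#' through text files.
#'
#' @param model A `denoiser_model`.
#' @param path Checkpoint file path.
#' @return `write_checkpoint` returns `path` invisibly; `read_checkpoint`
#'   the restored `denoiser_model`.
#' @export
write_checkpoint <- function(model, path) {
  ser <- function(p) {
    if (is.list(p)) return(lapply(p, ser))
    list(dim = dim(p) %||% length(p), data = as.vector(p))
  }
  doc <- list(format = "rrednet-checkpoint-1",
              config = unclass(model$config),
              params = ser(model$params))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "rrednet-checkpoint-1"))
    stop_invalid("not an rrednet checkpoint: ", path)
  cfg <- do.call(codec_config, list(
    in_channels = doc$config$in_channels,
    n_encoder_stages = doc$config$n_stages,
    base_channels = doc$config$base_channels,
    kernel_side = doc$config$kernel_side,
    activation = doc$config$activation,
    m_channel = doc$config$m_channel))
  deser <- function(p) {
    if (is.list(p) && !is.null(p$data) && !is.null(p$dim)) {
      d <- as.integer(unlist(p$dim))
      v <- as.double(unlist(p$data))
      return(if (length(d) > 1L) array(v, d) else v)
    }
    lapply(p, deser)
  }
  structure(list(config = cfg, params = deser(doc$params)),
            class = "denoiser_model")
}
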