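# Reverse-mode gradients for the codec. Mirrors codec_forward step by
# step; returns gradients in the same nested structure as model$params,
# plus the gradient with respect to the input stack (needed when training
# through unrolled recursions).

codec_backward <- function(model, cache, gy) {
  cfg <- model$config; p <- model$params
  k <- cfg$kernel_side; S <- cfg$n_stages; actv <- cfg$activation
  g <- list()

  # tail: y = tail(a)[,,1] + x[,,m]
  g_tail_pre <- array(gy, c(dim(gy), 1L))
  bw <- cpp_conv2d_same_backward(cache$tail_in, p$tail$w, g_tail_pre, k)
  g$tail <- list(w = bw$gw, b = as.vector(bw$gb))
  ga <- bw$gx
  gx_m <- gy  # skip branch of the final residual add

  g$dec <- vector("list", S); g$up <- vector("list", S)
  g_skip <- vector("list", S)
  for (s in seq_len(S)) {
    ub <- unit_bwd(ga, p$dec[[s]], cache$dec[[s]], k, actv)
    g$dec[[s]] <- ub$g
    ga <- ub$gx
    # decoder input was act(up conv) + encoder skip
    g_skip[[s]] <- ga
    g_pre <- ga * act_grad(cache$up[[s]]$pre, actv)
    bw <- cpp_conv2d_same_backward(cache$up[[s]]$us, p$up[[s]]$w, g_pre, k)
    g$up[[s]] <- list(w = bw$gw, b = as.vector(bw$gb))
    ga <- blocksum2(bw$gx)
  }

  ub <- unit_bwd(ga, p$bottom, cache$bottom, k, actv)
  g$bottom <- ub$g
  ga <- ub$gx

  g$enc <- vector("list", S); g$down <- vector("list", S)
  for (s in rev(seq_len(S))) {
    # downsampling block: out = subsample(act(conv(e)))
    g_act <- zero_stuff2(ga, dim(cache$down[[s]]$pre))
    g_pre <- g_act * act_grad(cache$down[[s]]$pre, actv)
    bw <- cpp_conv2d_same_backward(cache$down[[s]]$input, p$down[[s]]$w,
                                   g_pre, k)
    g$down[[s]] <- list(w = bw$gw, b = as.vector(bw$gb))
    ge <- bw$gx + g_skip[[s]]  # encoder feature also feeds the decoder skip
    ub <- unit_bwd(ge, p$enc[[s]], cache$enc[[s]], k, actv)
    g$enc[[s]] <- ub$g
    ga <- ub$gx
  }

  g_head_pre <- ga * act_grad(cache$head_pre, actv)
  bw <- cpp_conv2d_same_backward(cache$x, p$head$w, g_head_pre, k)
  g$head <- list(w = bw$gw, b = as.vector(bw$gb))
  gx <- bw$gx
  gx[, , cfg$m_channel] <- gx[, , cfg$m_channel] + gx_m

  list(grads = g[names(model$params)], gx = gx)
}

# unit: out = x + F(x); F = c2(act(c1(x)))
unit_bwd <- function(g, unit, cache, k, actv) {
  bw2 <- cpp_conv2d_same_backward(cache$h, unit$c2$w, g, k)
  g_h_pre <- bw2$gx * act_grad(cache$h_pre, actv)
  bw1 <- cpp_conv2d_same_backward(cache$x, unit$c1$w, g_h_pre, k)
  list(g = list(c1 = list(w = bw1$gw, b = as.vector(bw1$gb)),
                c2 = list(w = bw2$gw, b = as.vector(bw2$gb))),
       gx = g + bw1$gx)
}

# adjoint of downsample2: scatter into the odd grid positions
zero_stuff2 <- function(g, full_dim) {
  out <- array(0, full_dim)
  out[seq(1, full_dim[1], by = 2), seq(1, full_dim[2], by = 2), ] <- g
  out
}

# adjoint of nearest-neighbour upsample2: sum each 2x2 block
blocksum2 <- function(g) {
  d <- dim(g)
  i1 <- seq(1, d[1], by = 2); i2 <- seq(2, d[1], by = 2)
  j1 <- seq(1, d[2], by = 2); j2 <- seq(2, d[2], by = 2)
  g[i1, j1, , drop = FALSE] + g[i1, j2, , drop = FALSE] +
    g[i2, j1, , drop = FALSE] + g[i2, j2, , drop = FALSE]
}

# ---- structured parameter arithmetic -----------------------------------

# Apply f elementwise across two parameter structures of identical shape.
map2_params <- function(a, b, f) {
  if (is.list(a)) return(mapply(map2_params, a, b, MoreArgs = list(f = f),
                                SIMPLIFY = FALSE))
  f(a, b)
}
map_params <- function(a, f) {
  if (is.list(a)) return(lapply(a, map_params, f = f))
  f(a)
}

params_zero_like <- function(p) map_params(p, function(x) x * 0)

params_add <- function(a, b) map2_params(a, b, `+`)
params_scale <- function(a, s) map_params(a, function(x) x * s)

params_max_abs <- function(p) {
  m <- 0
  walk <- function(q) {
    for (el in q) {
      if (is.list(el)) walk(el) else m <<- max(m, max(abs(el)))
    }
  }
  walk(p)
  m
}

# ---- Adam optimizer -----------------------------------------------------

adam_init <- function(params) {
  list(m = params_zero_like(params), v = params_zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map2_params(state$m, grads,
                         function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- map2_params(state$v, grads,
                         function(v, g) beta2 * v + (1 - beta2) * g^2)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- map2_params(state$m, state$v,
                     function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps))
  params <- map2_params(params, upd, `-`)
  list(params = params, state = state)
}
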