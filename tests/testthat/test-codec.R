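test_that("residual unit with zero weights is the identity", {
  u <- residual_unit(3, 3, seed = 1)
  u$c1$w[] <- 0; u$c1$b[] <- 0; u$c2$w[] <- 0; u$c2$b[] <- 0
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  expect_equal(residual_unit_forward(x, u), x)
})

test_that("identity kernels with linear activation double the input", {
  # both convolutions pass the input through unchanged, so F(O) = O and
  # the unit returns O + F(O) = 2 O
  u <- residual_unit(1, 1, kernel_side = 3, activation = "linear", seed = 1)
  ident <- matrix(0, 9, 1); ident[5, 1] <- 1  # center tap of a 3x3 kernel
  u$c1$w <- ident; u$c2$w <- ident
  u$c1$b[] <- 0; u$c2$b[] <- 0
  x <- array(rnorm(36), c(6, 6, 1))
  expect_equal(residual_unit_forward(x, u), 2 * x, tolerance = 1e-12)
})

test_that("chained residual units telescope: O_N = O_0 + sum of branches", {
  set.seed(2)
  units <- lapply(1:3, function(s) residual_unit(2, 2, seed = s))
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  o <- x
  branch_sum <- array(0, dim(x))
  for (u in units) {
    nxt <- residual_unit_forward(o, u)
    branch_sum <- branch_sum + (nxt - o)  # instrumented branch output
    o <- nxt
  }
  expect_equal(o, x + branch_sum, tolerance = 1e-6)
})

test_that("projection skip maps channels and warns on matching dims", {
  x <- array(rnorm(16), c(4, 4, 1))
  hs <- matrix(c(1, 0), 1, 2)  # 1 -> 2 channels, first mirrors the input
  y <- projection_skip(x, hs)
  expect_equal(dim(y), c(4, 4, 2))
  expect_equal(y[, , 1], x[, , 1])
  expect_equal(y[, , 2], matrix(0, 4, 4))
  expect_warning(res <- projection_skip(x, matrix(2, 1, 1)),
                 "already match")
  expect_equal(res, x)
  # zero H_s and zero branch give zero output through the unit
  u <- residual_unit(1, 2, seed = 3)
  u$c1$w[] <- 0; u$c1$b[] <- 0; u$c2$w[] <- 0; u$c2$b[] <- 0
  u$hs[] <- 0
  expect_equal(residual_unit_forward(x, u), array(0, c(4, 4, 2)))
})

test_that("build_codec is deterministic and counts parameters in closed form", {
  m1 <- build_codec(codec_config(), seed = 0)
  m2 <- build_codec(codec_config(), seed = 0)
  expect_identical(m1$params, m2$params)
  m3 <- build_codec(codec_config(), seed = 1)
  expect_false(identical(m1$params, m3$params))

  cfg <- codec_config(in_channels = 2, n_encoder_stages = 2,
                      base_channels = 8, kernel_side = 3)
  m <- build_codec(cfg, seed = 0)
  k2 <- 9; B <- 8; S <- 2
  conv_n <- function(cin, cout) k2 * cin * cout + cout
  unit_n <- conv_n(B, B) * 2
  expected <- conv_n(2, B) +           # head
    S * (unit_n + conv_n(B, B)) +      # encoder units + downsamplers
    unit_n +                           # bottleneck
    S * (conv_n(B, B) + unit_n) +      # upsamplers + decoder units
    conv_n(B, 1)                       # tail
  expect_equal(n_parameters(m), expected)
  expect_error(codec_config(n_encoder_stages = 2, n_decoder_stages = 3),
               "same number of stages")
})

test_that("freshly built codec is the identity on the M channel", {
  m <- build_codec(codec_config(), seed = 5)
  x <- matrix(runif(64 * 64), 64, 64)
  out <- denoise_once(m, cascade(matrix(rnorm(64 * 64), 64, 64), x))
  expect_identical(out$pixels, x)
  # all-zero input with the zero-initialized tail returns the zero channel
  z <- matrix(0, 64, 64)
  expect_identical(denoise_once(m, cascade(z, z))$pixels, z)
})

test_that("codec preserves shape and rejects invalid sizes", {
  m <- tiny_model(seed = 2, stages = 2, channels = 4)
  for (side in c(16, 32)) {
    x <- matrix(runif(side * side), side, side)
    out <- denoise_once(m, cascade(x, x))
    expect_equal(dim(out$pixels), c(side, side))
  }
  x <- matrix(runif(96 * 64), 96, 64)
  expect_equal(dim(denoise_once(m, cascade(x, x))$pixels), c(96, 64))
  bad <- matrix(runif(10 * 10), 10, 10)
  expect_error(denoise_once(m, cascade(bad, bad)), "multiples of 2")
})

test_that("output decomposes as M plus the separately extracted residual", {
  m <- tiny_model(seed = 7)
  set.seed(7)
  # give the tail nonzero weights so the residual branch is active
  m$params$tail$w <- matrix(rnorm(length(m$params$tail$w), 0, 0.05),
                            nrow(m$params$tail$w), 1)
  x <- matrix(runif(256), 16, 16)
  j <- cascade(x, x)
  out <- denoise_once(m, j)
  # run the network body without the final skip: subtract the M channel
  g_of_m <- out$pixels - j[, , m$config$m_channel]
  expect_equal(out$pixels, g_of_m + x, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(g_of_m, matrix(0, 16, 16))))
})

test_that("analytic gradients match finite differences", {
  mod <- tiny_model(seed = 3, stages = 1, channels = 2)
  set.seed(3)
  # jitter every parameter away from zero so no ReLU preactivation sits
  # exactly on the kink, where one-sided differences and the subgradient
  # legitimately disagree
  mod$params <- rrednet:::map_params(mod$params,
                                     function(x) x + rnorm(length(x), 0, 0.05))
  xs <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  tgt <- matrix(rnorm(64), 8, 8)
  fw <- rrednet:::codec_forward(mod, xs, keep_cache = TRUE)
  loss0 <- mean((fw$y - tgt)^2)
  expect_true(is.finite(loss0))
  gy <- 2 * (fw$y - tgt) / length(fw$y)
  bw <- rrednet:::codec_backward(mod, fw$cache, gy)
  expect_true(all(is.finite(unlist(bw$grads))))

  set_nested <- function(pp, path, val) {
    if (length(path) == 1) { pp[[path[[1]]]] <- val; return(pp) }
    pp[[path[[1]]]] <- set_nested(pp[[path[[1]]]], path[-1], val)
    pp
  }
  eps <- 1e-6
  for (path in list(list("head", "w"), list("enc", 1L, "c1", "w"),
                    list("down", 1L, "w"), list("up", 1L, "b"),
                    list("dec", 1L, "c2", "w"), list("tail", "w"))) {
    arr <- Reduce(function(a, k) a[[k]], path, mod$params)
    i <- 1L
    pm <- mod
    arr[i] <- arr[i] + eps
    pm$params <- set_nested(mod$params, path, arr)
    l1 <- mean((rrednet:::codec_forward(pm, xs)$y - tgt)^2)
    g_num <- (l1 - loss0) / eps
    g_an <- Reduce(function(a, k) a[[k]], path, bw$grads)[i]
    expect_equal(g_num, g_an, tolerance = 1e-3)
  }
})

test_that("checkpoints round-trip through JSON exactly", {
  m <- tiny_model(seed = 9)
  path <- tempfile(fileext = ".ckpt")
  write_checkpoint(m, path)
  m2 <- read_checkpoint(path)
  expect_equal(m2$params, m$params)
  expect_equal(unclass(m2$config), unclass(m$config))
  x <- matrix(runif(256), 16, 16)
  expect_identical(denoise_once(m, cascade(x, x))$pixels,
                   denoise_once(m2, cascade(x, x))$pixels)
})
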