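# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force formula evaluations and direct
# pointwise geometry checks.

# PSNR straight from its definition.
oracle_psnr <- function(ref, test, D = 1) {
  mse <- sum((ref - test)^2) / length(ref)
  if (mse == 0) return(Inf)
  10 * log10(D^2 / mse)
}

# Global SSIM from independently computed moments (population form).
oracle_ssim <- function(p, q, z1, z2) {
  n <- length(p)
  mp <- sum(p) / n; mq <- sum(q) / n
  vp <- sum((p - mp)^2) / n
  vq <- sum((q - mq)^2) / n
  cpq <- sum((p - mp) * (q - mq)) / n
  ((2 * mp * mq + z1) * (2 * cpq + z2)) /
    ((mp^2 + mq^2 + z1) * (vp + vq + z2))
}

# Pointwise in-ellipse test mirroring the documented geometry (fractional
# centers scaled by (U-1, V-1), semi-axes by min(U, V)), evaluated one
# pixel at a time with scalar arithmetic.
oracle_rasterize <- function(spec, U, V) {
  px <- matrix(spec$background_intensity, U, V)
  m <- min(U, V)
  for (i in seq_len(U)) {
    for (j in seq_len(V)) {
      for (e in spec$ellipses) {
        dr <- (i - 1) - e$center_row * (U - 1)
        dc <- (j - 1) - e$center_col * (V - 1)
        u <- cos(e$rotation) * dr + sin(e$rotation) * dc
        v <- -sin(e$rotation) * dr + cos(e$rotation) * dc
        if ((u / (e$semi_axis_a * m))^2 + (v / (e$semi_axis_b * m))^2 <= 1)
          px[i, j] <- e$intensity
      }
    }
  }
  px
}

# A tiny codec for fast structural tests.
tiny_model <- function(seed = 1, stages = 1L, channels = 3L,
                       in_channels = 2L) {
  build_codec(codec_config(in_channels = in_channels,
                           n_encoder_stages = stages,
                           base_channels = channels), seed = seed)
}

random_grid <- function(U = 8, V = 8, seed = 1) {
  set.seed(seed)
  image_grid(matrix(runif(U * V), U, V))
}
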