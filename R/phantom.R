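#' Phantom geometry specification
#'
#' A phantom is a flat background plus an ordered list of ellipses; later
#' ellipses overwrite earlier ones where they overlap, so a lesion listed
#' after the liver it sits in takes precedence. Centers and semi-axes are
#' fractional: centers in `[0, 1]` of the image extent, semi-axes as
#' fractions of the smaller image dimension.
#'
#' @param background_intensity Scalar background pixel value.
#' @param ellipses List of ellipses created by [ellipse_spec()].
#' @return A `phantom_spec` object.
#' @seealso [generate_phantom()], [sample_phantom_spec()]
#' @export
phantom_spec <- function(background_intensity = 0.05, ellipses = list()) {
  stopifnot(is.numeric(background_intensity), length(background_intensity) == 1L)
  for (e in ellipses) {
    if (!inherits(e, "ellipse_spec"))
      stop_invalid("all elements of 'ellipses' must be ellipse_spec objects")
  }
  structure(list(background_intensity = background_intensity,
                 ellipses = ellipses),
            class = "phantom_spec")
}

#' @param center_row,center_col Fractional center coordinates in `[0, 1]`.
#' @param semi_axis_a,semi_axis_b Positive semi-axes as fractions of the
#'   smaller image dimension.
#' @param rotation Rotation in radians (counter-clockwise, row/col frame).
#' @param intensity Pixel value painted inside the ellipse.
#' @param role One of `"body"`, `"liver"`, `"lesion"`, `"necrosis"`.
#' @rdname phantom_spec
#' @export
ellipse_spec <- function(center_row, center_col, semi_axis_a, semi_axis_b,
                         rotation = 0, intensity = 1,
                         role = c("body", "liver", "lesion", "necrosis")) {
  role <- match.arg(role)
  if (semi_axis_a <= 0 || semi_axis_b <= 0)
    stop_invalid("ellipse semi-axes must be positive")
  structure(list(center_row = center_row, center_col = center_col,
                 semi_axis_a = semi_axis_a, semi_axis_b = semi_axis_b,
                 rotation = rotation, intensity = intensity, role = role),
            class = "ellipse_spec")
}

#' Rasterize a phantom specification
#'
#' Paints each ellipse over the background in list order: the value at a
#' pixel is the intensity of the last ellipse containing it. Fractional
#' coordinates scale by `(U - 1, V - 1)` so 0 and 1 map to the first and
#' last pixel centers. Deterministic; `seed` is accepted for interface
#' symmetry with the randomized sampler but unused here.
#'
#' @param spec A [phantom_spec()].
#' @param U,V Image dimensions in pixels (both >= 8).
#' @param seed Ignored (rasterization is deterministic).
#' @return An `image_grid` with dynamic range 1.
#' @export
#' @examples
#' ph <- phantom_spec(0.2, list(ellipse_spec(0.5, 0.5, 0.25, 0.25, intensity = 1)))
#' img <- generate_phantom(ph, 64, 64)
generate_phantom <- function(spec, U, V, seed = 0L) {
  if (!inherits(spec, "phantom_spec")) stop_invalid("'spec' must be a phantom_spec")
  if (U < 8 || V < 8) stop_invalid("phantom dimensions must be at least 8 x 8")
  px <- matrix(spec$background_intensity, U, V)
  rows <- matrix(seq_len(U) - 1, U, V)
  cols <- matrix(rep(seq_len(V) - 1, each = U), U, V)
  m <- min(U, V)
  for (e in spec$ellipses) {
    cr <- e$center_row * (U - 1)
    cc <- e$center_col * (V - 1)
    a <- e$semi_axis_a * m
    b <- e$semi_axis_b * m
    dr <- rows - cr
    dc <- cols - cc
    # rotate into the ellipse frame
    u <- cos(e$rotation) * dr + sin(e$rotation) * dc
    v <- -sin(e$rotation) * dr + cos(e$rotation) * dc
    inside <- (u / a)^2 + (v / b)^2 <= 1
    px[inside] <- e$intensity
  }
  image_grid(px, 1)
}

#' Gaussian noise specification and field
#'
#' Pixelwise additive noise drawn i.i.d. from `Normal(mean, sigma^2)`,
#' the Gaussian component of the degradation model. `sigma = 0` gives the
#' degenerate constant field.
#'
#' @param mean Noise mean (offset), default 0.
#' @param sigma Noise standard deviation, `>= 0`.
#' @return `gaussian_noise_spec` returns the spec;
#'   `gaussian_noise_field` an `image_grid` of draws.
#' @export
gaussian_noise_spec <- function(mean = 0, sigma = 0.08) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
    stop_invalid("'sigma' must be a non-negative scalar")
  structure(list(mean = mean, sigma = sigma), class = "gaussian_noise_spec")
}

#' @param U,V Field dimensions.
#' @param spec A [gaussian_noise_spec()].
#' @param seed Integer seed; the field is reproducible for a fixed seed.
#' @rdname gaussian_noise_spec
#' @export
gaussian_noise_field <- function(U, V, spec = gaussian_noise_spec(), seed = 0L) {
  if (!inherits(spec, "gaussian_noise_spec"))
    stop_invalid("'spec' must be a gaussian_noise_spec")
  if (U < 1 || V < 1) stop_invalid("field dimensions must be positive")
  px <- with_seed(seed, matrix(rnorm(U * V, spec$mean, spec$sigma), U, V))
  image_grid(px, 1)
}

#' Streak artifact specification and field
#'
#' Streak (striped) artifacts are the structured, line-like corruption of
#' low-dose and sparse-view CT; unlike pixelwise Gaussian noise they are
#' spatially coherent. The model here is a sum of `n_streaks` straight
#' bands: each band is supported on a strip of width `width_pixels` about a
#' line through a uniformly random anchor pixel, with a boxcar or Gaussian
#' cross-section profile and a zero-mean random amplitude of scale
#' `amplitude_scale`. Orientations are drawn uniformly on `[0, pi)`, or,
#' with `orientation = "discrete"`, restricted to `n_angles` evenly spaced
#' projection angles as in sparse-view acquisition.
#'
#' @param n_streaks Number of bands, `>= 0`.
#' @param width_pixels Strip width in pixels, `> 0`.
#' @param amplitude_scale Scale of the zero-mean amplitudes (normal draws);
#'   0 gives an all-zero field.
#' @param profile `"boxcar"` (constant within the strip) or `"gaussian"`
#'   (falls off with distance from the line; width acts as 2 standard
#'   deviations).
#' @param orientation `"uniform"` or `"discrete"`.
#' @param n_angles Number of evenly spaced angles for `"discrete"`.
#' @param fixed_amplitude If not `NULL`, every band uses exactly this
#'   amplitude instead of a random draw (useful for testing).
#' @return `streak_spec` returns the spec; `streak_field` an `image_grid`.
#' @export
streak_spec <- function(n_streaks = 6L, width_pixels = 2, amplitude_scale = 0.05,
                        profile = c("boxcar", "gaussian"),
                        orientation = c("uniform", "discrete"),
                        n_angles = 8L, fixed_amplitude = NULL) {
  profile <- match.arg(profile)
  orientation <- match.arg(orientation)
  if (n_streaks < 0) stop_invalid("'n_streaks' must be >= 0")
  if (width_pixels <= 0) stop_invalid("'width_pixels' must be > 0")
  if (amplitude_scale < 0) stop_invalid("'amplitude_scale' must be >= 0")
  structure(list(n_streaks = as.integer(n_streaks),
                 width_pixels = width_pixels,
                 amplitude_scale = amplitude_scale, profile = profile,
                 orientation = orientation, n_angles = as.integer(n_angles),
                 fixed_amplitude = fixed_amplitude),
            class = "streak_spec")
}

#' @param U,V Field dimensions.
#' @param spec A [streak_spec()].
#' @param seed Integer seed.
#' @rdname streak_spec
#' @export
streak_field <- function(U, V, spec = streak_spec(), seed = 0L) {
  if (!inherits(spec, "streak_spec")) stop_invalid("'spec' must be a streak_spec")
  if (U < 1 || V < 1) stop_invalid("field dimensions must be positive")
  px <- matrix(0, U, V)
  if (spec$n_streaks == 0L ||
      (spec$amplitude_scale == 0 && is.null(spec$fixed_amplitude)))
    return(image_grid(px, 1))
  rows <- matrix(seq_len(U) - 1, U, V)
  cols <- matrix(rep(seq_len(V) - 1, each = U), U, V)
  with_seed(seed, {
    for (s in seq_len(spec$n_streaks)) {
      theta <- if (spec$orientation == "uniform") runif(1, 0, pi)
               else pi * (sample.int(spec$n_angles, 1) - 1) / spec$n_angles
      anchor_r <- runif(1, 0, U - 1)
      anchor_c <- runif(1, 0, V - 1)
      amp <- if (is.null(spec$fixed_amplitude))
        rnorm(1, 0, spec$amplitude_scale) else spec$fixed_amplitude
      # signed distance from each pixel to the line through the anchor with
      # direction (cos theta, sin theta) in (row, col) coordinates
      d <- -sin(theta) * (rows - anchor_r) + cos(theta) * (cols - anchor_c)
      if (spec$profile == "boxcar") {
        px <- px + amp * (abs(d) <= spec$width_pixels / 2)
      } else {
        sig <- spec$width_pixels / 2
        px <- px + amp * exp(-d^2 / (2 * sig^2))
      }
    }
  })
  image_grid(px, 1)
}

#' Degrade a clean image into a paired observation
#'
#' The degradation model is strictly additive: the observed image `I` is
#' the clean image `A` plus a noise field `N`, where `N` is the sum of an
#' i.i.d. Gaussian component and a streak component drawn under
#' independent sub-seeds split from `seed` (streams 1 and 2 of
#' [sub_seed()]). No clipping is applied, so the identity
#' `degraded - clean == noise_field` holds exactly, elementwise.
#'
#' @param clean An `image_grid` (the clean/normal-dose image `A`).
#' @param g A [gaussian_noise_spec()].
#' @param s A [streak_spec()].
#' @param seed Integer master seed.
#' @return A `degraded_pair`: list with `clean`, `degraded`, `noise_field`
#'   (all `image_grid`s) and `seed`.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(), 16, 16)
#' pr <- degrade(ph, gaussian_noise_spec(sigma = 0.1), streak_spec(2), seed = 7)
#' max(abs((pr$degraded$pixels - pr$clean$pixels) - pr$noise_field$pixels))
degrade <- function(clean, g = gaussian_noise_spec(), s = streak_spec(),
                    seed = 0L) {
  if (!inherits(clean, "image_grid")) stop_invalid("'clean' must be an image_grid")
  U <- nrow(clean$pixels); V <- ncol(clean$pixels)
  gn <- gaussian_noise_field(U, V, g, sub_seed(seed, 1L))
  st <- streak_field(U, V, s, sub_seed(seed, 2L))
  degraded <- image_grid(clean$pixels + (gn$pixels + st$pixels),
                         clean$dynamic_range)
  # store the realized noise as degraded - clean so the additive identity
  # holds bit-exactly in floating point (within 1 ulp of gn + st)
  noise <- image_grid(degraded$pixels - clean$pixels, clean$dynamic_range)
  structure(list(clean = clean, degraded = degraded, noise_field = noise,
                 seed = as.integer(seed)),
            class = "degraded_pair")
}

#' @export
print.degraded_pair <- function(x, ...) {
  cat(sprintf("<degraded_pair> %d x %d, seed %d\n",
              nrow(x$clean$pixels), ncol(x$clean$pixels), x$seed))
  invisible(x)
}

#' Sample a randomized liver-like phantom specification
#'
#' Draws an abdomen-like phantom: a large body ellipse, a liver ellipse
#' inside it, one to three lesions inside the liver, and with probability
#' 1/2 per lesion a darker necrotic core. Intensities are fixed at CT-like
#' normalized levels (body 0.3, liver 0.55, lesion 0.75, necrosis 0.25 on a
#' 0.05 background); geometry varies with the seed.
#'
#' @param seed Integer seed.
#' @return A [phantom_spec()].
#' @export
sample_phantom_spec <- function(seed = 0L) {
  with_seed(seed, {
    body <- ellipse_spec(0.5 + runif(1, -0.03, 0.03),
                         0.5 + runif(1, -0.03, 0.03),
                         runif(1, 0.40, 0.46), runif(1, 0.32, 0.40),
                         runif(1, -0.15, 0.15), 0.3, "body")
    liver <- ellipse_spec(0.45 + runif(1, -0.05, 0.05),
                          0.42 + runif(1, -0.05, 0.05),
                          runif(1, 0.18, 0.26), runif(1, 0.13, 0.2),
                          runif(1, 0, pi), 0.55, "liver")
    es <- list(body, liver)
    for (i in seq_len(sample.int(3L, 1))) {
      lr <- liver$center_row + runif(1, -0.06, 0.06)
      lc <- liver$center_col + runif(1, -0.06, 0.06)
      a <- runif(1, 0.03, 0.07)
      les <- ellipse_spec(lr, lc, a, a * runif(1, 0.6, 1),
                          runif(1, 0, pi), 0.75, "lesion")
      es <- c(es, list(les))
      if (runif(1) < 0.5) {
        es <- c(es, list(ellipse_spec(lr, lc, a * 0.4, a * 0.35,
                                      les$rotation, 0.25, "necrosis")))
      }
    }
    phantom_spec(0.05, es)
  })
}

#' Generate a paired synthetic dataset
#'
#' Produces `n_pairs` independent (clean, degraded) image pairs. Pair `i`
#' uses phantom seed `sub_seed(seed, 100 + i)` and degradation seed
#' `sub_seed(seed, 200 + i)`, so the whole corpus is reproducible from one
#' master seed while geometry varies across pairs. Defaults reflect the
#' desk-scale study conditions: 64 x 64 images, Gaussian sigma 0.08, six
#' streaks per image.
#'
#' @param n_pairs Number of pairs, `>= 1`.
#' @param U,V Image dimensions.
#' @param g A [gaussian_noise_spec()].
#' @param s A [streak_spec()].
#' @param seed Integer master seed.
#' @param phantom_sampler Function `(seed) -> phantom_spec`; defaults to
#'   [sample_phantom_spec()].
#' @return List of [degrade()] pairs.
#' @export
make_dataset <- function(n_pairs, U = 64L, V = 64L,
                         g = gaussian_noise_spec(sigma = 0.08),
                         s = streak_spec(n_streaks = 6L), seed = 0L,
                         phantom_sampler = sample_phantom_spec) {
  if (n_pairs < 1) stop_invalid("'n_pairs' must be >= 1")
  lapply(seq_len(n_pairs), function(i) {
    ph <- generate_phantom(phantom_sampler(sub_seed(seed, 100L + i)), U, V)
    degrade(ph, g, s, sub_seed(seed, 200L + i))
  })
}
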