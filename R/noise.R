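#' Plane-wave interference texture
#'
#' Thin-film interference and skin-layer patterns are approximated by plane
#' waves: \eqn{N_I(x, n, k) = [\cos(2\pi k^{-1} x\cdot n + \phi) + 1]/2},
#' a cosine of wavelength `k` pixels propagating along the unit direction
#' `n` with phase `phi`.
#'
#' @param shape image shape `c(H, W)` (rows, cols).
#' @param direction propagation direction, a 2-vector (normalized
#'   internally; must be nonzero).
#' @param k spatial scale (wavelength), pixels, > 0.
#' @param phi phase shift, radians.
#' @return an H x W matrix with values in \[0, 1\].
#' @export
interference_texture <- function(shape, direction, k, phi = 0) {
  if (k <= 0) stop("spatial scale k must be positive")
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) stop("direction must be nonzero")
  d <- direction / nrm
  H <- shape[1]; W <- shape[2]
  x <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)
  y <- matrix(rep(seq_len(H) - 0.5, times = W), H, W)
  (cos(2 * pi / k * (x * d[1] + y * d[2]) + phi) + 1) / 2
}

#' Perlin (lattice gradient) noise texture
#'
#' Classic 2D gradient noise: random unit gradients on a lattice with cell
#' size `k` pixels, quintic-fade interpolation of the corner dot products,
#' rescaled to \[0, 1\]. Produces the smooth cloudy patterns characteristic
#' of protein aggregate and precipitate. Uses R's global RNG.
#'
#' @param shape image shape `c(H, W)`.
#' @param k lattice cell size, pixels, > 0.
#' @return an H x W matrix with values in \[0, 1\].
#' @export
perlin_texture <- function(shape, k) {
  if (k <= 0) stop("spatial scale k must be positive")
  H <- shape[1]; W <- shape[2]
  gx <- floor(W / k) + 2L; gy <- floor(H / k) + 2L
  ga <- matrix(stats::runif(gx * gy, 0, 2 * pi), gy, gx)
  gxv <- cos(ga); gyv <- sin(ga)
  x <- (matrix(rep(seq_len(W) - 0.5, each = H), H, W)) / k
  y <- (matrix(rep(seq_len(H) - 0.5, times = W), H, W)) / k
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ix <- pmin(x0 + 1L, gx - 1L); iy <- pmin(y0 + 1L, gy - 1L)
  dot_at <- function(ox, oy) {
    idx <- (iy + oy) + (ix + ox - 1L) * gy
    gxv[idx] * (fx - ox) + gyv[idx] * (fy - oy)
  }
  fade <- function(t) t * t * t * (t * (t * 6 - 15) + 10)
  u <- fade(fx); v <- fade(fy)
  n00 <- dot_at(0L, 0L); n10 <- dot_at(1L, 0L)
  n01 <- dot_at(0L, 1L); n11 <- dot_at(1L, 1L)
  val <- (n00 * (1 - u) + n10 * u) * (1 - v) +
         (n01 * (1 - u) + n11 * u) * v
  # theoretical range is [-sqrt(1/2), sqrt(1/2)]
  out <- val / sqrt(2) + 0.5
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}

#' Histogram equalization of a noise texture
#'
#' Rank-based remap to a uniform \[0, 1\] distribution so that noise layers
#' built from different generators and spatial scales carry comparable
#' intensity histograms before averaging. Idempotent; a constant texture is
#' returned as all 0.5 by convention.
#'
#' @param texture numeric matrix.
#' @return matrix of the same shape with values in \[0, 1\] and a uniform
#'   empirical distribution (up to ties).
#' @export
histogram_equalize <- function(texture) {
  n <- length(texture)
  if (diff(range(texture)) < .Machine$double.eps) {
    out <- texture; out[] <- 0.5; return(out)
  }
  out <- texture
  out[] <- (rank(texture, ties.method = "average") - 1) / (n - 1)
  out
}

#' Specification of a noise layer
#'
#' A noise layer is the average of `N ~ U{1, 10}` histogram-equalized
#' textures with independently drawn spatial scales `k_i`, log-uniform
#' between a few pixels and the image diagonal.
#'
#' @param kind `"interference"` or `"perlin"`.
#' @param N texture count; `NULL` draws uniformly from `{1, ..., 10}` at
#'   build time.
#' @param k scales; `NULL` draws log-uniformly from `k_range` at build time.
#' @param k_range scale bounds in pixels; `NULL` means
#'   `c(4, image diagonal)`.
#' @return an object of class `noise_layer_spec`.
#' @export
noise_layer_spec <- function(kind = c("interference", "perlin"),
                             N = NULL, k = NULL, k_range = NULL) {
  kind <- match.arg(kind)
  if (!is.null(N) && (N < 1 || N > 10)) stop("N must be in 1..10")
  structure(list(kind = kind, N = N, k = k, k_range = k_range),
            class = "noise_layer_spec")
}

#' Build a noise layer
#'
#' Averages `N` histogram-equalized textures from the configured generator:
#' `L = (1/N) sum_i H[N(k_i)]`.
#'
#' @param spec a [noise_layer_spec()].
#' @param shape image shape `c(H, W)`.
#' @return an H x W matrix with values in \[0, 1\].
#' @export
build_noise_layer <- function(spec, shape) {
  H <- shape[1]; W <- shape[2]
  kr <- spec$k_range
  if (is.null(kr)) kr <- c(4, sqrt(H^2 + W^2))
  N <- if (is.null(spec$N)) sample(1:10, 1) else spec$N
  ks <- if (is.null(spec$k)) exp(stats::runif(N, log(kr[1]), log(kr[2])))
        else rep_len(spec$k, N)
  acc <- matrix(0, H, W)
  for (i in seq_len(N)) {
    tex <- if (spec$kind == "interference") {
      ang <- stats::runif(1, 0, 2 * pi)
      interference_texture(shape, c(cos(ang), sin(ang)), ks[i],
                           phi = stats::runif(1, 0, 2 * pi))
    } else perlin_texture(shape, ks[i])
    acc <- acc + histogram_equalize(tex)
  }
  acc / N
}

#' Blending parameters
#'
#' @param w_b weight of the base image (default 1).
#' @param c contrast constant scaling the noise weight (default 5, the
#'   value used during online augmentation).
#' @return an object of class `blend_params`.
#' @export
blend_params <- function(w_b = 1, c = 5) {
  stopifnot(w_b > 0, c >= 0)
  structure(list(w_b = w_b, c = c), class = "blend_params")
}

#' Blend a noise layer into a base image
#'
#' Per-pixel weighted average `A(b, l, w_l) = (w_b b + w_l l)/(w_b + w_l)`
#' with noise weights `w_l = c * sigma_b * l_alpha * 2^(-2 l + 1)`:
#' `sigma_b` is the standard deviation of the base image (so weak signals
#' are not overwhelmed), `l_alpha` is a second noise layer of the same kind
#' acting as a randomized transparency, and the factor `2^(-2 l + 1)`
#' reinforces dark noise values (up to x2 at l = 0) while suppressing
#' bright ones (down to x1/2 at l = 1), matching the predominantly dark
#' appearance of real precipitate patterns.
#'
#' @param base base image, values in \[0, 1\].
#' @param layer noise layer `l`, same shape.
#' @param l_alpha transparency layer, same shape.
#' @param params a [blend_params()].
#' @return blended image in \[0, 1\].
#' @export
blend <- function(base, layer, l_alpha, params = blend_params()) {
  if (!all(dim(base) == dim(layer)) || !all(dim(base) == dim(l_alpha)))
    stop("shape mismatch between base image and noise layers")
  sigma_b <- stats::sd(base)
  w_l <- params$c * sigma_b * l_alpha * 2^(-2 * layer + 1)
  out <- (params$w_b * base + w_l * layer) / (params$w_b + w_l)
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}
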