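#' Object-level augmentation
#'
#' Brightens or darkens individual crystals relative to their environment,
#' or faintly outlines their refractive borders, using the exact silhouette
#' masks. Each crystal is perturbed independently with probability
#' `prob_object`.
#'
#' @param ann an `annotated_image`.
#' @param prob_object per-crystal probability of being perturbed.
#' @param magnitude maximum absolute intensity offset (brighten/darken) or
#'   outline amplitude, in \[0, 1\] units.
#' @param sigma outline stroke width (pixels).
#' @return the `annotated_image` with a modified image.
#' @export
object_level_augment <- function(ann, prob_object = 0.5, magnitude = 0.1,
                                 sigma = 1) {
  img <- ann$image
  if (magnitude == 0) return(ann)
  for (i in seq_along(ann$polygons)) {
    if (stats::runif(1) > prob_object) next
    mode <- sample(c("brighten", "darken", "outline"), 1)
    if (mode == "outline") {
      amp <- stats::runif(1, 0.2, 1) * magnitude *
        sample(c(-1, 1), 1)
      poly <- ann$polygons[[i]]
      m <- nrow(poly)
      for (k in seq_len(m)) {
        j <- if (k == m) 1L else k + 1L
        img <- stroke_segment(img, poly[k, ], poly[j, ], sigma, amp)
      }
    } else {
      off <- stats::runif(1, 0.2, 1) * magnitude *
        if (mode == "brighten") 1 else -1
      idx <- rasterize_convex(ann$polygons[[i]],
                              ann$image_size[1], ann$image_size[2])
      img[idx] <- img[idx] + off
    }
  }
  img[img < 0] <- 0; img[img > 1] <- 1
  ann$image <- img
  ann
}

#' Draw random cubic splines over an image
#'
#' Emulates scratches and foreign residues: `n_splines` smooth curves
#' through random control points, rendered as Gaussian strokes of random
#' width and intensity.
#'
#' @param img image matrix in \[0, 1\].
#' @param n_splines number of curves (0 leaves the image untouched).
#' @param magnitude maximum absolute stroke intensity.
#' @param width_range stroke sigma range, pixels.
#' @param n_ctrl control points per spline.
#' @return the augmented image.
#' @export
draw_random_splines <- function(img, n_splines = 2, magnitude = 0.25,
                                width_range = c(0.5, 2), n_ctrl = 5) {
  if (n_splines == 0) return(img)
  H <- nrow(img); W <- ncol(img)
  for (s in seq_len(n_splines)) {
    cx <- stats::runif(n_ctrl, 0, W); cy <- stats::runif(n_ctrl, 0, H)
    tt <- seq_len(n_ctrl)
    dense <- seq(1, n_ctrl, length.out = 20 * n_ctrl)
    px <- stats::spline(tt, cx, xout = dense)$y
    py <- stats::spline(tt, cy, xout = dense)$y
    amp <- stats::runif(1, 0.2, 1) * magnitude * sample(c(-1, 1), 1)
    sg <- stats::runif(1, width_range[1], width_range[2])
    for (i in seq_len(length(dense) - 1)) {
      img <- stroke_segment(img, c(px[i], py[i]), c(px[i + 1], py[i + 1]),
                            sg, amp)
    }
  }
  img[img < 0] <- 0; img[img > 1] <- 1
  img
}

#' Rounded-corner overlay
#'
#' Simulates imaging of a round reactor volume: pixels outside a large
#' random disk are pulled toward a dark background level.
#'
#' @param img image matrix.
#' @param radius disk radius in pixels (`Inf` leaves the image unchanged);
#'   `NULL` draws uniformly between 0.6 and 1.4 of the half-diagonal.
#' @param level intensity assigned outside the disk.
#' @param feather soft transition width, pixels.
#' @return the augmented image.
#' @export
rounded_corners_overlay <- function(img, radius = NULL, level = 0.05,
                                    feather = 4) {
  H <- nrow(img); W <- ncol(img)
  half_diag <- sqrt(W^2 + H^2) / 2
  if (is.null(radius)) radius <- stats::runif(1, 0.6, 1.4) * half_diag
  if (!is.finite(radius)) return(img)
  cx <- W / 2 + stats::runif(1, -0.05, 0.05) * W
  cy <- H / 2 + stats::runif(1, -0.05, 0.05) * H
  x <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)
  y <- matrix(rep(seq_len(H) - 0.5, times = W), H, W)
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  wgt <- pmin(pmax((d - radius) / feather, 0), 1)   # 0 inside, 1 outside
  img * (1 - wgt) + level * wgt
}

#' Displace whole rows or columns of pixels
#'
#' Distorts crystal edges by shifting a random band of rows or columns by
#' an integer offset (edge-replicated fill), leaving the image shape
#' unchanged.
#'
#' @param img image matrix.
#' @param n_bands number of bands to displace.
#' @param max_offset maximum absolute shift, pixels.
#' @param max_band_width maximum band width, pixels.
#' @return the augmented image.
#' @export
displace_rows_cols <- function(img, n_bands = 3, max_offset = 4,
                               max_band_width = 8) {
  if (n_bands == 0 || max_offset == 0) return(img)
  H <- nrow(img); W <- ncol(img)
  for (b in seq_len(n_bands)) {
    off <- sample(c(-max_offset:-1, 1:max_offset), 1)
    wd <- sample(seq_len(max_band_width), 1)
    if (stats::runif(1) < 0.5) {            # rows, shifted horizontally
      r0 <- sample(seq_len(H - wd + 1), 1)
      rows <- r0:(r0 + wd - 1)
      src <- pmin(pmax(seq_len(W) - off, 1), W)
      img[rows, ] <- img[rows, src, drop = FALSE]
    } else {                                 # columns, shifted vertically
      c0 <- sample(seq_len(W - wd + 1), 1)
      cols <- c0:(c0 + wd - 1)
      src <- pmin(pmax(seq_len(H) - off, 1), H)
      img[, cols] <- img[src, cols, drop = FALSE]
    }
  }
  img
}

# separable Gaussian blur with edge renormalization
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  rad <- max(1L, ceiling(3 * sigma))
  kern <- exp(-(-rad:rad)^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  conv1 <- function(m) {   # along rows of m
    n <- nrow(m)
    K <- matrix(0, n, n)
    for (d in -rad:rad) {
      i <- seq_len(n)
      j <- pmin(pmax(i + d, 1), n)   # replicate edges
      K[cbind(i, j)] <- K[cbind(i, j)] + kern[d + rad + 1]
    }
    K %*% m
  }
  t(conv1(t(conv1(img))))
}

flip_poly_h <- function(poly, W) { poly[, 1] <- W - poly[, 1]; poly }
flip_poly_v <- function(poly, H) { poly[, 2] <- H - poly[, 2]; poly }
rot90_poly_cw <- function(poly, H) cbind(H - poly[, 2], poly[, 1])

# re-derive boxes from polygons after a geometric step
reboxed <- function(ann) {
  if (length(ann$polygons)) {
    rects <- do.call(rbind, lapply(ann$polygons, min_area_rect))
    ann$annotations[, c("cx", "cy", "w", "h", "theta")] <-
      as.data.frame(rects)
  }
  ann
}

#' Geometric augmentation: flips and right-angle rotations
#'
#' Applies a horizontal flip, vertical flip and a 90-degree clockwise
#' rotation count `k` to the image; silhouette polygons are transformed
#' exactly and the oriented boxes re-derived as their minimum-area
#' rectangles.
#'
#' @param ann an `annotated_image`.
#' @param hflip,vflip logical flips.
#' @param k90 number of 90-degree clockwise rotations (0..3).
#' @return the transformed `annotated_image`.
#' @export
geometric_augment <- function(ann, hflip = FALSE, vflip = FALSE, k90 = 0) {
  img <- ann$image
  W <- ann$image_size[1]; H <- ann$image_size[2]
  polys <- ann$polygons
  if (hflip) {
    img <- img[, ncol(img):1, drop = FALSE]
    polys <- lapply(polys, flip_poly_h, W = W)
  }
  if (vflip) {
    img <- img[nrow(img):1, , drop = FALSE]
    polys <- lapply(polys, flip_poly_v, H = H)
  }
  for (q in seq_len(k90 %% 4)) {
    img <- t(img[nrow(img):1, , drop = FALSE])
    polys <- lapply(polys, rot90_poly_cw, H = H)   # H = current height
    tmp <- W; W <- H; H <- tmp
  }
  ann$image <- img
  ann$polygons <- polys
  ann$image_size <- c(W, H)
  reboxed(ann)
}

#' Augmentation pipeline configuration
#'
#' Fixed-order step list with per-step probabilities and parameter ranges.
#' The default order — geometric, object-level, interference layer, Perlin
#' layer, splines, rounded corners, row/column displacement,
#' brightness/contrast, Gaussian blur, additive Gaussian noise — is a
#' repository convention (spatially structured effects first, pixel-level
#' camera effects last), configurable per step.
#'
#' @param probs named numeric vector overriding per-step probabilities
#'   (default 0.5 each).
#' @param params named list overriding per-step parameter lists.
#' @return an object of class `augmentation_config`.
#' @export
augmentation_config <- function(probs = NULL, params = NULL) {
  steps <- c("geometric", "object_level", "interference", "perlin",
             "splines", "rounded_corners", "displacement",
             "brightness_contrast", "blur", "gauss_noise")
  p <- stats::setNames(rep(0.5, length(steps)), steps)
  if (!is.null(probs)) {
    bad <- setdiff(names(probs), steps)
    if (length(bad)) stop("unknown augmentation step: ", bad[1])
    p[names(probs)] <- probs
  }
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  defaults <- list(
    object_level = list(prob_object = 0.5, magnitude = 0.1, sigma = 1),
    interference = list(c = 5),
    perlin = list(c = 5),
    splines = list(n_range = c(1, 4), magnitude = 0.25),
    rounded_corners = list(level = 0.05),
    displacement = list(n_bands = 3, max_offset = 4),
    brightness_contrast = list(brightness = c(-0.15, 0.15),
                               contrast = c(0.7, 1.3)),
    blur = list(sigma_range = c(0.3, 1.5)),
    gauss_noise = list(sd_range = c(0.005, 0.04))
  )
  if (!is.null(params)) for (nm in names(params))
    defaults[[nm]] <- utils::modifyList(defaults[[nm]], params[[nm]])
  structure(list(steps = steps, probs = p, params = defaults),
            class = "augmentation_config")
}

#' Apply the full augmentation pipeline
#'
#' Runs the configured steps in order, each fired with its configured
#' probability; geometric steps transform the annotations consistently
#' (polygons mapped exactly, boxes re-derived), all other steps leave the
#' annotations untouched. All intermediate images stay within \[0, 1\].
#' Deterministic under a fixed RNG seed.
#'
#' @param ann an `annotated_image` (or a bare image matrix, in which case
#'   one without annotations is built).
#' @param config an [augmentation_config()].
#' @return the augmented `annotated_image`.
#' @export
augment <- function(ann, config = augmentation_config()) {
  if (is.matrix(ann))
    ann <- structure(list(image = ann,
                          annotations = data.frame(), polygons = list(),
                          image_size = c(ncol(ann), nrow(ann))),
                     class = "annotated_image")
  for (step in config$steps) {
    if (stats::runif(1) > config$probs[[step]]) next
    prm <- config$params[[step]]
    shape <- dim(ann$image)
    ann <- switch(step,
      geometric = geometric_augment(ann,
        hflip = stats::runif(1) < 0.5, vflip = stats::runif(1) < 0.5,
        k90 = sample(0:3, 1)),
      object_level = object_level_augment(ann, prm$prob_object,
                                          prm$magnitude, prm$sigma),
      interference = ,
      perlin = {
        kind <- if (step == "perlin") "perlin" else "interference"
        l <- build_noise_layer(noise_layer_spec(kind), shape)
        la <- build_noise_layer(noise_layer_spec(kind), shape)
        ann$image <- blend(ann$image, l, la, blend_params(c = prm$c))
        ann
      },
      splines = {
        ns <- sample(prm$n_range[1]:prm$n_range[2], 1)
        ann$image <- draw_random_splines(ann$image, ns, prm$magnitude)
        ann
      },
      rounded_corners = {
        ann$image <- rounded_corners_overlay(ann$image, level = prm$level)
        ann
      },
      displacement = {
        ann$image <- displace_rows_cols(ann$image, prm$n_bands,
                                        prm$max_offset)
        ann
      },
      brightness_contrast = {
        b <- stats::runif(1, prm$brightness[1], prm$brightness[2])
        ct <- stats::runif(1, prm$contrast[1], prm$contrast[2])
        img <- (ann$image - 0.5) * ct + 0.5 + b
        img[img < 0] <- 0; img[img > 1] <- 1
        ann$image <- img
        ann
      },
      blur = {
        sg <- stats::runif(1, prm$sigma_range[1], prm$sigma_range[2])
        ann$image <- gaussian_blur(ann$image, sg)
        ann
      },
      gauss_noise = {
        sd_ <- stats::runif(1, prm$sd_range[1], prm$sd_range[2])
        img <- ann$image + matrix(stats::rnorm(length(ann$image), 0, sd_),
                                  nrow(ann$image))
        img[img < 0] <- 0; img[img > 1] <- 1
        ann$image <- img
        ann
      })
    stopifnot(all(ann$image >= 0 & ann$image <= 1))
  }
  ann
}

#' Online augmentation iterator
#'
#' Returns a closure producing a freshly augmented copy of `ann` on each
#' call, for use in training loops.
#'
#' @param ann an `annotated_image`.
#' @param config an [augmentation_config()].
#' @return a function of no arguments returning an `annotated_image`.
#' @export
augment_stream <- function(ann, config = augmentation_config()) {
  function() augment(ann, config)
}
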