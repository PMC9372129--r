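#' Preprocess a photomicrograph for detector input
#'
#' Converts RGB input to luminance grayscale and shifts its intensity
#' distribution onto a stored reference distribution (the one used during
#' training) by quantile mapping: each pixel is replaced by the reference
#' quantile at its own empirical quantile level. A constant image cannot be
#' mapped and is returned unshifted with a warning.
#'
#' @param image grayscale matrix in \[0, 1\] or RGB array (H x W x 3).
#' @param reference numeric vector of reference intensities (e.g. pixels
#'   of a training image), or `NULL` to skip the shift.
#' @param pixel_size microns per pixel (default 0.84, the calibration of
#'   the reference microscope camera).
#' @return an object of class `photomicrograph`: `image` (grayscale
#'   matrix) and `pixel_size`.
#' @export
preprocess_photomicrograph <- function(image, reference = NULL,
                                       pixel_size = 0.84) {
  stopifnot(pixel_size > 0)
  if (length(dim(image)) == 3) image <- rgb_to_gray(image)
  if (!is.null(reference)) {
    if (diff(range(image)) < .Machine$double.eps) {
      warning("constant image; intensity shift skipped")
    } else {
      u <- (rank(image, ties.method = "average") - 0.5) / length(image)
      out <- stats::quantile(reference, probs = u, names = FALSE, type = 7)
      image[] <- out
    }
  }
  structure(list(image = image, pixel_size = pixel_size),
            class = "photomicrograph")
}

#' Crystal size distribution from detections
#'
#' Converts detected oriented boxes to physical sizes: width `w` is the
#' box long side and height `h` the short side, both in microns
#' (`pixels * pixel_size`), with aspect ratio `r = w/h >= 1`.
#'
#' @param detections data.frame with `w`, `h` in pixels (long/short side).
#' @param pixel_size microns per pixel.
#' @param label optional label (e.g. a time stamp) attached to the result.
#' @return an object of class `size_distribution`: data.frame `w, h, r`
#'   (microns, microns, dimensionless) with attribute `label`.
#' @export
extract_csd <- function(detections, pixel_size = 0.84, label = NULL) {
  stopifnot(pixel_size > 0)
  if (is.null(detections) || nrow(detections) == 0) {
    out <- data.frame(w = numeric(0), h = numeric(0), r = numeric(0))
  } else {
    w <- pmax(detections$w, detections$h) * pixel_size
    h <- pmin(detections$w, detections$h) * pixel_size
    out <- data.frame(w = w, h = h, r = w / h)
  }
  structure(out, label = label, class = c("size_distribution", "data.frame"))
}

#' Summary statistics of a size distribution
#'
#' Medians and quartiles (linear-interpolation convention, quantile type 7)
#' for widths and heights, mean and sample standard deviation for the
#' aspect ratio. A single-crystal sample reports a standard deviation of 0
#' with `sd_defined = FALSE`.
#'
#' @param dist a `size_distribution`.
#' @return a list of class `csd_summary`.
#' @export
summarize_csd <- function(dist) {
  if (nrow(dist) == 0) stop("empty size distribution")
  q <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE,
                                   type = 7)
  qw <- q(dist$w); qh <- q(dist$h)
  sd_ok <- nrow(dist) > 1
  structure(list(
    n = nrow(dist),
    w_median = qw[2], w_q1 = qw[1], w_q3 = qw[3],
    h_median = qh[2], h_q1 = qh[1], h_q3 = qh[3],
    r_mean = mean(dist$r),
    r_sd = if (sd_ok) stats::sd(dist$r) else 0,
    sd_defined = sd_ok,
    label = attr(dist, "label")
  ), class = "csd_summary")
}

#' @export
print.csd_summary <- function(x, ...) {
  cat(sprintf("CSD summary (n = %d%s)\n", x$n,
              if (!is.null(x$label)) paste0(", ", x$label) else ""))
  cat(sprintf("  width  um: median %.2f [Q1 %.2f, Q3 %.2f]\n",
              x$w_median, x$w_q1, x$w_q3))
  cat(sprintf("  height um: median %.2f [Q1 %.2f, Q3 %.2f]\n",
              x$h_median, x$h_q1, x$h_q3))
  cat(sprintf("  aspect ratio: %.2f +/- %.2f\n", x$r_mean, x$r_sd))
  invisible(x)
}

#' Empirical cumulative distribution function of a size field
#'
#' @param dist a `size_distribution`.
#' @param field one of `"w"`, `"h"`, `"r"`.
#' @return a right-continuous step function (as from [stats::ecdf()]).
#' @export
csd_ecdf <- function(dist, field = c("w", "h", "r")) {
  field <- match.arg(field)
  if (nrow(dist) == 0) stop("empty size distribution")
  stats::ecdf(dist[[field]])
}

# exact P(D >= d) for the two-sample KS statistic by lattice-path counting:
# fraction of orderings whose ECDF difference ever reaches d
ks_exact_pvalue <- function(d, n1, n2) {
  # count monotone paths (0,0)->(n1,n2) staying strictly inside
  # |i/n1 - j/n2| < d; p = 1 - inside/choose(n1+n2, n1)
  u <- matrix(0, n1 + 1, n2 + 1)
  u[1, 1] <- 1
  for (i in 0:n1) for (j in 0:n2) {
    if (i == 0 && j == 0) next
    if (abs(i / n1 - j / n2) >= d - 1e-12) { u[i + 1, j + 1] <- 0; next }
    acc <- 0
    if (i > 0) acc <- acc + u[i, j + 1]
    if (j > 0) acc <- acc + u[i + 1, j]
    u[i + 1, j + 1] <- acc
  }
  1 - u[n1 + 1, n2 + 1] / choose(n1 + n2, n1)
}

# asymptotic Kolmogorov tail with the Stephens small-sample correction
ks_asymptotic_pvalue <- function(d, n1, n2) {
  ne <- n1 * n2 / (n1 + n2)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * d
  if (lambda < 1e-9) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided test on the maximum ECDF gap
#' \eqn{D = \sup_x |F_1(x) - F_2(x)|}, used to compare crystal size
#' distributions (e.g. from diluted vs undiluted samples). The p-value is
#' computed by exact lattice-path enumeration when `n1*n2 <= exact_limit`
#' and there are no cross-sample ties, and otherwise from the asymptotic
#' Kolmogorov distribution with a small-sample correction.
#'
#' @param x,y numeric samples (nonempty).
#' @param exact_limit switch-over product `n1*n2` for the exact p-value.
#' @return an object of class `ks_result`: `D`, `p`, `n1`, `n2`, `method`.
#' @export
ks_two_sample <- function(x, y, exact_limit = 1e4) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("empty sample")
  all_v <- sort(unique(c(x, y)))
  d <- max(abs(stats::ecdf(x)(all_v) - stats::ecdf(y)(all_v)))
  ties <- any(x %in% y)
  if (n1 * n2 <= exact_limit && !ties) {
    p <- ks_exact_pvalue(d, n1, n2)
    method <- "exact"
  } else {
    p <- ks_asymptotic_pvalue(d, n1, n2)
    method <- "asymptotic"
  }
  structure(list(D = d, p = p, n1 = n1, n2 = n2, method = method),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("Two-sample KS test: D = %.4f, p = %.4g (%s, n1 = %d, n2 = %d)\n",
              x$D, x$p, x$method, x$n1, x$n2))
  invisible(x)
}

#' Total detected crystal area
#'
#' Sum of oriented-box areas (or exact silhouette polygon areas when
#' supplied) converted to square microns.
#'
#' @param detections data.frame with `w`, `h` in pixels.
#' @param pixel_size microns per pixel.
#' @param polygons optional list of silhouette polygons (pixel vertices);
#'   when given, polygon areas are summed instead of box areas.
#' @return total area in um^2.
#' @export
total_crystal_area <- function(detections, pixel_size = 0.84,
                               polygons = NULL) {
  stopifnot(pixel_size > 0)
  if (!is.null(polygons)) {
    px2 <- sum(vapply(polygons, function(p) abs(polygon_area(p)), numeric(1)))
  } else {
    if (is.null(detections) || nrow(detections) == 0) return(0)
    px2 <- sum(detections$w * detections$h)
  }
  px2 * pixel_size^2
}

#' Linear trend between total crystal area and protein concentration
#'
#' Ordinary least squares of `c_P` on `a_tot` plus the Pearson correlation;
#' a utility for relating detected crystal growth to the supernatant
#' protein concentration.
#'
#' @param a_tot total crystal areas (um^2), one per time point.
#' @param c_p protein concentrations, matched to `a_tot`.
#' @return list of class `linear_trend`: `slope`, `intercept`,
#'   `correlation`, `n`.
#' @export
fit_linear_trend <- function(a_tot, c_p) {
  if (length(a_tot) != length(c_p) || length(a_tot) < 3)
    stop("need at least 3 paired points")
  fit <- stats::lm(c_p ~ a_tot)
  rho <- if (stats::sd(c_p) == 0 || stats::sd(a_tot) == 0) 0
         else stats::cor(a_tot, c_p)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 correlation = rho, n = length(a_tot)),
            class = "linear_trend")
}

#' Full CSD report for a detection table
#'
#' Convenience wrapper producing, per image (or per label group), the size
#' distribution summary, ECDF support points and the pairwise KS matrix of
#' crystal widths.
#'
#' @param dets detection data.frame with `image_id, w, h` (pixels).
#' @param pixel_size microns per pixel.
#' @return list of class `csd_report` with `summaries`, `ks_matrix`
#'   (p-values) and `groups`.
#' @export
csd_report <- function(dets, pixel_size = 0.84) {
  groups <- split(dets, dets$image_id)
  dists <- lapply(groups, extract_csd, pixel_size = pixel_size)
  sums <- lapply(dists, summarize_csd)
  g <- names(groups)
  ks <- matrix(NA_real_, length(g), length(g), dimnames = list(g, g))
  if (length(g) > 1) {
    for (i in seq_along(g)) for (j in seq_along(g)) {
      if (i < j) {
        ks[i, j] <- ks[j, i] <- ks_two_sample(dists[[i]]$w, dists[[j]]$w)$p
      }
    }
  }
  diag(ks) <- 1
  structure(list(groups = g, summaries = sums, ks_matrix = ks,
                 pixel_size = pixel_size),
            class = "csd_report")
}
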