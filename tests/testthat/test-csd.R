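test_that("photomicrograph preprocessing maps quantiles onto the
           reference", {
  set.seed(70)
  ref <- stats::rbeta(5000, 5, 2)
  img <- matrix(stats::runif(64 * 64), 64, 64)
  out <- preprocess_photomicrograph(img, ref)
  # output quantiles match the reference within one gray level
  probs <- seq(0.05, 0.95, by = 0.05)
  expect_lt(max(abs(stats::quantile(out$image, probs) -
                    stats::quantile(ref, probs))), 1 / 255)
  # image already matching the reference is a fixed point up to
  # quantization
  out2 <- preprocess_photomicrograph(out$image, ref)
  expect_lt(max(abs(out2$image - out$image)), 1 / 255)

  # RGB is collapsed to luminance, shape preserved
  rgb <- array(stats::runif(32 * 32 * 3), c(32, 32, 3))
  outc <- preprocess_photomicrograph(rgb, NULL)
  expect_equal(dim(outc$image), c(32, 32))
  gray <- array(0.42, c(8, 8, 3))
  outg <- preprocess_photomicrograph(gray, NULL)
  expect_equal(unique(as.vector(outg$image)), 0.42)

  expect_warning(preprocess_photomicrograph(matrix(0.5, 8, 8), ref),
                 "constant")
})

test_that("CSD extraction converts pixels to microns with canonical
           long/short sides", {
  dets <- data.frame(w = 10, h = 5)
  d <- extract_csd(dets, pixel_size = 0.84)
  expect_equal(d$w, 8.4)
  expect_equal(d$h, 4.2)
  expect_equal(d$r, 2)
  # canonicalization if sides arrive swapped
  d2 <- extract_csd(data.frame(w = 5, h = 10), pixel_size = 0.84)
  expect_equal(d2$w, 8.4)
  expect_true(all(extract_csd(data.frame(w = stats::runif(50, 1, 9),
                                         h = stats::runif(50, 1, 9)))$r >= 1))
  expect_equal(nrow(extract_csd(data.frame(w = numeric(0),
                                           h = numeric(0)))), 0)
  # doubling pixel size doubles lengths
  d3 <- extract_csd(dets, pixel_size = 1.68)
  expect_equal(d3$w, 2 * d$w)
})

test_that("summaries follow the linear-interpolation quantile
           convention", {
  d <- structure(data.frame(w = c(1, 2, 3, 4, 5), h = c(1, 1, 1, 1, 1) / 2,
                            r = c(2, 4, 6, 8, 10)),
                 class = c("size_distribution", "data.frame"))
  s <- summarize_csd(d)
  expect_equal(s$w_median, 3)
  expect_equal(s$w_q1, 2)
  expect_equal(s$w_q3, 4)
  expect_equal(s$r_mean, 6)
  expect_equal(s$r_sd, stats::sd(c(2, 4, 6, 8, 10)))

  # permutation invariance
  dp <- d[c(4, 1, 5, 3, 2), ]
  class(dp) <- class(d)
  sp <- summarize_csd(dp)
  expect_equal(sp$w_median, s$w_median)
  expect_equal(sp$r_mean, s$r_mean)

  one <- d[3, ]; class(one) <- class(d)
  s1 <- summarize_csd(one)
  expect_equal(s1$w_median, s1$w_q1)
  expect_equal(s1$w_median, s1$w_q3)
  expect_equal(s1$r_sd, 0)
  expect_false(s1$sd_defined)

  expect_error(summarize_csd(d[0, ]), "empty")
})

test_that("ECDF endpoints and counting behave", {
  d <- extract_csd(data.frame(w = c(3, 1, 2, 5, 4), h = rep(1, 5)),
                   pixel_size = 1)
  F <- csd_ecdf(d, "w")
  expect_equal(F(max(d$w)), 1)
  expect_equal(F(min(d$w) - 1e-9), 0)
  expect_equal(F(stats::median(d$w)), ceiling(5 / 2) / 5)
})

test_that("KS statistic and p-values match the enumeration oracle", {
  r <- ks_two_sample(c(1, 2, 3), c(1.5, 2.5, 3.5))
  expect_equal(r$D, 1 / 3)
  expect_equal(r$p, oracle_ks_pvalue(c(1, 2, 3), c(1.5, 2.5, 3.5)))

  x <- c(5, 5, 5); y <- c(1, 2, 3)
  expect_equal(ks_two_sample(x, y)$D, 1)
  r_eq <- ks_two_sample(c(1, 2, 4), c(1, 2, 4))
  expect_equal(r_eq$D, 0)
  expect_equal(r_eq$p, 1)

  set.seed(71)
  for (rep in 1:8) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- stats::rnorm(n1); y <- stats::rnorm(n2, 0.5)
    r <- ks_two_sample(x, y)
    expect_equal(r$method, "exact")
    expect_equal(r$p, oracle_ks_pvalue(x, y), tolerance = 1e-12)
    # D agrees with the standard implementation
    expect_equal(r$D, unname(suppressWarnings(
      stats::ks.test(x, y)$statistic)), tolerance = 1e-12)
  }
  expect_error(ks_two_sample(numeric(0), 1:3), "empty")
})

test_that("asymptotic p-value tracks the exact one at the sizes where it
           is used", {
  worst <- 0
  for (n in c(80, 100)) {
    for (k in 3:20) {
      d <- k / n
      worst <- max(worst, abs(pcsgen:::ks_exact_pvalue(d, n, n) -
                              pcsgen:::ks_asymptotic_pvalue(d, n, n)))
    }
  }
  expect_lt(worst, 0.05)
})

test_that("KS calibration: false-rejection rate near the nominal level", {
  set.seed(72)
  n_rep <- 400
  rej <- 0
  for (i in seq_len(n_rep)) {
    z <- stats::rnorm(60)
    r <- ks_two_sample(z[1:30], z[31:60])
    if (r$p < 0.05) rej <- rej + 1
  }
  expect_gt(rej / n_rep, 0.01)
  expect_lt(rej / n_rep, 0.09)
})

test_that("total area and linear trends behave", {
  expect_equal(total_crystal_area(data.frame(w = numeric(0),
                                             h = numeric(0))), 0)
  expect_equal(total_crystal_area(data.frame(w = 10, h = 5),
                                  pixel_size = 0.84), 50 * 0.84^2)
  d1 <- data.frame(w = c(10, 4), h = c(5, 2))
  expect_equal(total_crystal_area(d1),
               total_crystal_area(d1[1, , drop = FALSE]) +
               total_crystal_area(d1[2, , drop = FALSE]))
  # doubling pixel size quadruples areas
  expect_equal(total_crystal_area(d1, pixel_size = 2),
               4 * total_crystal_area(d1, pixel_size = 1))
  # polygon-mask areas when available
  tri <- list(rbind(c(0, 0), c(2, 0), c(0, 2)))
  expect_equal(total_crystal_area(NULL, pixel_size = 1, polygons = tri), 2)

  a <- c(1, 2, 3, 4, 5)
  expect_equal(fit_linear_trend(a, 2 * a + 1)$correlation, 1)
  expect_equal(fit_linear_trend(a, 2 * a + 1)$slope, 2)
  expect_equal(fit_linear_trend(a, rep(3, 5))$slope, 0)
  # recovery of a known slope from noisy data
  set.seed(73)
  x <- stats::runif(40, 0, 100)
  y <- 0.7 * x + 5 + stats::rnorm(40, 0, 2)
  tr <- fit_linear_trend(x, y)
  expect_equal(tr$slope, 0.7, tolerance = 0.05)
  expect_gt(tr$correlation, 0.99)
  expect_error(fit_linear_trend(1:2, 1:2), "at least 3")
})

test_that("csd_report assembles summaries and a symmetric KS matrix", {
  set.seed(74)
  dets <- data.frame(image_id = rep(c("t1", "t2"), each = 40),
                     w = c(stats::runif(40, 5, 20), stats::runif(40, 8, 30)),
                     h = c(stats::runif(40, 2, 10), stats::runif(40, 3, 12)))
  rep <- csd_report(dets, pixel_size = 0.84)
  expect_setequal(rep$groups, c("t1", "t2"))
  expect_equal(rep$ks_matrix["t1", "t2"], rep$ks_matrix["t2", "t1"])
  expect_equal(diag(rep$ks_matrix), c(t1 = 1, t2 = 1))
  expect_equal(rep$summaries[["t1"]]$n, 40)
})
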