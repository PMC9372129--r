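test_that("size classes split at 8^2 and 24^2 with boundaries going up", {
  expect_equal(size_class(7, 7), "small")      # a = 49 < 64
  expect_equal(size_class(8, 8), "medium")     # boundary 64 -> larger class
  expect_equal(size_class(48, 24), "large")    # a = 1152 > 576
  expect_equal(size_class(24, 24), "large")    # boundary 576 -> larger class
  expect_equal(size_class(30, 10), "medium")   # a = 300
  expect_equal(size_class(c(7, 8, 48), c(7, 8, 24)),
               c("small", "medium", "large"))
})

make_det <- function(image_id, cx, cy, w, h, theta, score) {
  data.frame(image_id = image_id, cx = cx, cy = cy, w = w, h = h,
             theta = theta, score = score)
}

test_that("greedy matching gives the expected TP/FP/FN counts", {
  gts <- make_det("a", c(10, 40), c(10, 40), c(10, 12), c(6, 8),
                  c(0, 0.4), c(1, 1))[, -7]
  # perfect detections
  perfect <- cbind(gts, score = 1)
  m <- match_detections(perfect, gts)
  expect_true(all(m$tp))
  expect_equal(sort(m$matched_gt), 1:2)

  # no detections: everything is a miss
  m0 <- match_detections(perfect[0, ], gts)
  expect_length(m0$tp, 0)
  expect_equal(m0$n_gt, 2)

  # 2 GTs, 3 dets with IoUs ~ {high, medium, low} at threshold 0.5:
  # 2 TPs, 1 FP
  dets <- make_det("a",
                   cx = c(10.2, 39, 70), cy = c(10.1, 41, 70),
                   w = c(10, 12, 10), h = c(6, 8, 6),
                   theta = c(0.02, 0.38, 0), score = c(0.9, 0.8, 0.7))
  m3 <- match_detections(dets, gts, 0.5)
  expect_equal(sum(m3$tp), 2)
  expect_equal(sum(!m3$tp), 1)
})

test_that("average precision reproduces hand-enumerated PR areas", {
  gts <- make_det("a", 10, 10, 10, 6, 0, 1)[, -7]
  # one GT, two detections; TP ranked above FP -> AP 100
  dets_good <- make_det("a", c(10, 60), c(10, 60), c(10, 10), c(6, 6),
                        c(0, 0), c(0.9, 0.5))
  m <- match_detections(dets_good, gts, 0.5)
  expect_equal(average_precision(list(m)), 100)
  # FP ranked above TP: precision at recall 1 is 0.5 -> AP 50 (101-point)
  dets_bad <- make_det("a", c(60, 10), c(60, 10), c(10, 10), c(6, 6),
                       c(0, 0), c(0.9, 0.5))
  m2 <- match_detections(dets_bad, gts, 0.5)
  expect_equal(average_precision(list(m2)), 50, tolerance = 0.5)
  # all FP -> 0
  dets_fp <- make_det("a", 60, 60, 10, 6, 0, 0.9)
  expect_equal(average_precision(list(match_detections(dets_fp, gts))), 0)
  # no ground truth -> NA with warning
  expect_warning(v <- average_precision(list(), n_gt = 0), "undefined")
  expect_true(is.na(v))
})

test_that("pooled AP equals the exhaustive PR oracle on random small
           instances", {
  set.seed(60)
  for (rep in 1:12) {
    n_img <- sample(1:3, 1)
    gts <- do.call(rbind, lapply(seq_len(n_img), function(i) {
      n <- sample(1:6, 1)
      make_det(paste0("im", i), stats::runif(n, 10, 90),
               stats::runif(n, 10, 90), stats::runif(n, 6, 20),
               stats::runif(n, 3, 10), stats::runif(n, -1.5, 1.5),
               rep(1, n))[, -7]
    }))
    # detections: jittered copies of some GTs plus pure noise
    base <- gts[stats::runif(nrow(gts)) < 0.8, , drop = FALSE]
    dets <- base
    dets$cx <- dets$cx + stats::rnorm(nrow(dets), 0, 2)
    dets$cy <- dets$cy + stats::rnorm(nrow(dets), 0, 2)
    dets$score <- stats::runif(nrow(dets))
    extra <- make_det(sample(unique(gts$image_id), 3, replace = TRUE),
                      stats::runif(3, 10, 90), stats::runif(3, 10, 90),
                      stats::runif(3, 6, 20), stats::runif(3, 3, 10),
                      stats::runif(3, -1.5, 1.5), stats::runif(3))
    dets <- rbind(dets, extra)
    for (th in c(0.3, 0.5, 0.75)) {
      pkg <- pcsgen:::ap_single(dets, gts, th)
      expect_equal(pkg, oracle_ap(dets, gts, th), tolerance = 1e-9)
    }
  }
})

test_that("AP invariances and monotonicity hold", {
  set.seed(61)
  gts <- make_det("a", stats::runif(8, 20, 100), stats::runif(8, 20, 100),
                  stats::runif(8, 8, 25), stats::runif(8, 4, 12),
                  stats::runif(8, -1.5, 1.5), rep(1, 8))[, -7]
  dets <- gts
  dets$cx <- dets$cx + stats::rnorm(8, 0, 1.5)
  dets$score <- stats::runif(8, 0.2, 0.9)

  # invariance under uniform positive rescaling of scores
  d2 <- dets; d2$score <- d2$score * 0.5
  expect_equal(pcsgen:::ap_single(dets, gts, 0.5),
               pcsgen:::ap_single(d2, gts, 0.5))

  # non-increasing in the IoU threshold
  aps <- vapply(seq(0.3, 0.9, by = 0.1),
                function(th) pcsgen:::ap_single(dets, gts, th), numeric(1))
  expect_true(all(diff(aps) <= 1e-9))

  # growing jitter cannot improve AP (property run)
  ap_at <- function(jit) {
    set.seed(99)
    dd <- gts
    dd$cx <- dd$cx + stats::rnorm(8, 0, jit)
    dd$cy <- dd$cy + stats::rnorm(8, 0, jit)
    dd$score <- stats::runif(8)
    evaluate_detections(dd, gts, iou_thresholds = 0.5)$AP
  }
  vals <- vapply(c(0, 2, 6, 15), ap_at, numeric(1))
  expect_true(all(diff(vals) <= 1e-9))
})

test_that("evaluate_detections reports per-class AP with the documented
           filtering rule", {
  set.seed(62)
  gts <- rbind(
    make_det("a", c(20, 60), c(20, 60), c(6, 6), c(5, 5), c(0, 0.5), 1),
    make_det("a", c(100, 140), c(100, 40), c(20, 18), c(12, 10), c(0.2, -0.3), 1),
    make_det("b", c(50, 120), c(50, 120), c(40, 60), c(30, 25), c(0, 1), 1)
  )[, -7]
  perfect <- cbind(gts, score = seq(0.95, 0.7, length.out = 6))
  rep <- evaluate_detections(perfect, gts)
  expect_equal(rep$AP, 100)
  expect_equal(rep$AP_s, 100)
  expect_equal(rep$AP_m, 100)
  expect_equal(rep$AP_l, 100)
  expect_equal(unname(rep$n_gt), c(6, 2, 2, 2))

  empty <- perfect[0, ]
  rep0 <- evaluate_detections(empty, gts, iou_thresholds = 0.5)
  expect_equal(rep0$AP, 0)

  bad_ids <- perfect; bad_ids$image_id <- "zzz"
  expect_error(evaluate_detections(bad_ids, gts), "share no image ids")
})
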