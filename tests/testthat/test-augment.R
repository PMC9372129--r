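test_that("object-level augmentation is local and monotone", {
  sc <- make_test_scene(seed = 40)
  ann <- render_scene(sc)
  # zero magnitude is the identity
  set.seed(1)
  expect_identical(object_level_augment(ann, magnitude = 0)$image,
                   ann$image)

  # force brighten on every crystal by trying seeds until modes hit
  set.seed(4)
  out <- object_level_augment(ann, prob_object = 1, magnitude = 0.15)
  near <- matrix(FALSE, nrow(ann$image), ncol(ann$image))
  W <- ann$image_size[1]; H <- ann$image_size[2]
  for (p in ann$polygons) near <- near | poly_band(p, W, H, 5)
  # pixels far from all crystals unchanged (outline strokes spill ~3 px)
  expect_identical(out$image[!near], ann$image[!near])
})

test_that("brightened masks gain mean intensity", {
  sc <- make_test_scene(seed = 41)
  ann <- render_scene(sc)
  # drive the internal RNG until a brighten step happens on crystal 1
  found <- FALSE
  for (seed in 1:50) {
    set.seed(seed)
    p <- stats::runif(1); mode <- sample(c("brighten", "darken", "outline"), 1)
    if (p <= 1 && mode == "brighten") { found <- TRUE; break }
  }
  expect_true(found)
  set.seed(seed)
  out <- object_level_augment(ann, prob_object = 1, magnitude = 0.2)
  msk <- crystal_mask(ann, 1)
  expect_gt(mean(out$image[msk]), mean(ann$image[msk]) - 1e-12)
})

test_that("splines, rounded corners and displacement behave at their
           identity limits", {
  set.seed(42)
  img <- matrix(stats::runif(64 * 64), 64, 64)
  expect_identical(draw_random_splines(img, n_splines = 0), img)
  set.seed(1)
  out <- draw_random_splines(img, n_splines = 2)
  expect_gt(sum(out != img), 0)
  set.seed(1)
  out2 <- draw_random_splines(img, n_splines = 2)
  expect_identical(out, out2)

  expect_identical(rounded_corners_overlay(img, radius = Inf), img)
  set.seed(2)
  rc <- rounded_corners_overlay(img, radius = 30, level = 0.05, feather = 2)
  expect_equal(rc[32, 32], img[32, 32])          # center untouched
  expect_equal(rc[1, 1], 0.05, tolerance = 1e-9) # corner at mask level

  expect_identical(displace_rows_cols(img, n_bands = 0), img)
  expect_identical(displace_rows_cols(img, max_offset = 0), img)
  # multiset of a shifted row preserved away from the border fill
  set.seed(3)
  sh <- displace_rows_cols(img, n_bands = 1, max_offset = 3)
  changed <- which(apply(sh != img, 1, any))
  if (length(changed)) {
    r <- changed[1]
    expect_gt(length(intersect(round(sh[r, ], 9), round(img[r, ], 9))), 50)
  }
})

test_that("all-probability-zero pipeline is the identity on image and
           annotations", {
  sc <- make_test_scene(seed = 43)
  ann <- render_scene(sc)
  cfg <- augmentation_config(probs = stats::setNames(
    rep(0, 10), c("geometric", "object_level", "interference", "perlin",
                  "splines", "rounded_corners", "displacement",
                  "brightness_contrast", "blur", "gauss_noise")))
  set.seed(1)
  out <- augment(ann, cfg)
  expect_identical(out$image, ann$image)
  expect_identical(out$annotations, ann$annotations)
  expect_identical(out$polygons, ann$polygons)
})

test_that("geometric transforms map boxes and polygons exactly", {
  sc <- make_test_scene(seed = 44)
  ann <- render_scene(sc)
  W <- ann$image_size[1]; H <- ann$image_size[2]

  rot <- geometric_augment(ann, k90 = 1)
  for (i in seq_len(nrow(ann$annotations))) {
    b0 <- ann$annotations[i, ]; b1 <- rot$annotations[i, ]
    # 90-degree rotation: (cx, cy) -> (H - cy, cx), sides preserved,
    # angle rotated by 90 degrees on the half circle
    expect_equal(b1$cx, H - b0$cy, tolerance = 1e-9)
    expect_equal(b1$cy, b0$cx, tolerance = 1e-9)
    expect_equal(b1$w, b0$w, tolerance = 1e-9)
    expect_equal(b1$h, b0$h, tolerance = 1e-9)
    expect_equal(angle_diff(b1$theta, b0$theta + pi / 2), 0,
                 tolerance = 1e-9)
    # polygon area preserved by the isometry
    expect_equal(abs(polygon_area(rot$polygons[[i]])),
                 abs(polygon_area(ann$polygons[[i]])), tolerance = 1e-9)
  }
  # four quarter turns restore the original annotations
  r4 <- geometric_augment(ann, k90 = 4)
  expect_equal(r4$annotations, ann$annotations, tolerance = 1e-9)
  expect_identical(r4$image, ann$image)

  fl <- geometric_augment(ann, hflip = TRUE)
  for (i in seq_len(nrow(ann$annotations))) {
    expect_equal(fl$annotations$cx[i], W - ann$annotations$cx[i],
                 tolerance = 1e-9)
    expect_equal(fl$annotations$cy[i], ann$annotations$cy[i],
                 tolerance = 1e-9)
  }
  # boxes are re-derived as min-area rects of the mapped polygons
  for (i in seq_len(nrow(fl$annotations))) {
    rr <- min_area_rect(fl$polygons[[i]])
    expect_equal(fl$annotations$w[i], rr$w, tolerance = 1e-9)
  }
})

test_that("full pipeline keeps images in [0,1], is deterministic, and
           keeps annotations inside the image", {
  sc <- make_test_scene(seed = 45)
  ann <- render_scene(sc)
  set.seed(9); a1 <- augment(ann)
  set.seed(9); a2 <- augment(ann)
  expect_identical(a1$image, a2$image)
  expect_identical(a1$annotations, a2$annotations)
  expect_true(all(a1$image >= 0 & a1$image <= 1))
  W <- a1$image_size[1]; H <- a1$image_size[2]
  for (p in a1$polygons) {
    expect_true(all(p[, 1] >= 0 & p[, 1] <= W))
    expect_true(all(p[, 2] >= 0 & p[, 2] <= H))
  }
  # a different seed produces a different augmentation
  set.seed(10); a3 <- augment(ann)
  expect_false(identical(a1$image, a3$image))
})
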