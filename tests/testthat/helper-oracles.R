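# Independent oracles used by the test suite. These re-derive results by
# brute force or alternative algorithms and must stay independent of the
# package implementations they check.

# minimum-area enclosing rectangle: plain double loop over hull edges,
# rotating every point explicitly (rotating-calipers theorem: the optimum
# is aligned with some hull edge)
oracle_min_rect_area <- function(points) {
  hull <- points[grDevices::chull(points), , drop = FALSE]
  m <- nrow(hull)
  best <- Inf
  for (i in seq_len(m)) {
    j <- if (i == m) 1 else i + 1
    e <- hull[j, ] - hull[i, ]
    ang <- atan2(e[2], e[1])
    xr <- yr <- numeric(m)
    for (k in seq_len(m)) {
      xr[k] <- cos(-ang) * hull[k, 1] - sin(-ang) * hull[k, 2]
      yr[k] <- sin(-ang) * hull[k, 1] + cos(-ang) * hull[k, 2]
    }
    best <- min(best, (max(xr) - min(xr)) * (max(yr) - min(yr)))
  }
  best
}

# convex polygon intersection by point collection + hull (independent of
# the Sutherland-Hodgman clipper used in the package)
oracle_intersection_area <- function(p1, p2) {
  inside <- function(pt, poly) {
    m <- nrow(poly)
    sgn <- 0
    for (i in seq_len(m)) {
      j <- if (i == m) 1 else i + 1
      cr <- (poly[j, 1] - poly[i, 1]) * (pt[2] - poly[i, 2]) -
        (poly[j, 2] - poly[i, 2]) * (pt[1] - poly[i, 1])
      if (abs(cr) > 1e-12) {
        if (sgn == 0) sgn <- sign(cr)
        else if (sign(cr) != sgn) return(FALSE)
      }
    }
    TRUE
  }
  seg_int <- function(a, b, c, d) {
    r <- b - a; s <- d - c
    den <- r[1] * s[2] - r[2] * s[1]
    if (abs(den) < 1e-14) return(NULL)
    t <- ((c[1] - a[1]) * s[2] - (c[2] - a[2]) * s[1]) / den
    u <- ((c[1] - a[1]) * r[2] - (c[2] - a[2]) * r[1]) / den
    if (t < -1e-12 || t > 1 + 1e-12 || u < -1e-12 || u > 1 + 1e-12)
      return(NULL)
    a + t * r
  }
  pts <- list()
  for (i in seq_len(nrow(p1)))
    if (inside(p1[i, ], p2)) pts[[length(pts) + 1]] <- p1[i, ]
  for (i in seq_len(nrow(p2)))
    if (inside(p2[i, ], p1)) pts[[length(pts) + 1]] <- p2[i, ]
  m1 <- nrow(p1); m2 <- nrow(p2)
  for (i in seq_len(m1)) for (k in seq_len(m2)) {
    p <- seg_int(p1[i, ], p1[if (i == m1) 1 else i + 1, ],
                 p2[k, ], p2[if (k == m2) 1 else k + 1, ])
    if (!is.null(p)) pts[[length(pts) + 1]] <- p
  }
  if (length(pts) < 3) return(0)
  P <- do.call(rbind, pts)
  h <- grDevices::chull(P)
  if (length(h) < 3) return(0)
  abs(pcsgen::polygon_area(P[h, ]))
}

# exhaustive PR tabulation for AP at one IoU threshold (pooled over
# images; greedy matching re-stated from the protocol definition)
oracle_ap <- function(dets, gts, iou_threshold) {
  flags <- numeric(0); scores <- numeric(0)
  for (id in unique(c(dets$image_id, gts$image_id))) {
    d <- dets[dets$image_id == id, , drop = FALSE]
    g <- gts[gts$image_id == id, , drop = FALSE]
    d <- d[order(-d$score), , drop = FALSE]
    used <- rep(FALSE, nrow(g))
    for (i in seq_len(nrow(d))) {
      ious <- rep(0, nrow(g))
      for (j in seq_len(nrow(g)))
        if (!used[j]) ious[j] <- pcsgen::rotated_iou(d[i, ], g[j, ])
      jbest <- if (nrow(g)) which.max(ious) else 0L
      hit <- length(jbest) == 1 && nrow(g) > 0 && ious[jbest] >= iou_threshold
      if (hit) used[jbest] <- TRUE
      flags <- c(flags, as.numeric(hit)); scores <- c(scores, d$score[i])
    }
  }
  n_gt <- nrow(gts)
  if (length(flags) == 0) return(0)
  o <- order(-scores); flags <- flags[o]
  prec <- cumsum(flags) / seq_along(flags)
  rec <- cumsum(flags) / n_gt
  grid <- seq(0, 1, by = 0.01)
  vals <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    sel <- which(rec >= grid[gi] - 1e-12)
    vals[gi] <- if (length(sel)) max(prec[sel]) else 0
  }
  mean(vals) * 100
}

# exact two-sample KS p-value by enumerating all C(n1+n2, n1) labelings
oracle_ks_pvalue <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  Dof <- function(xx, yy) {
    v <- sort(unique(c(xx, yy)))
    max(abs(stats::ecdf(xx)(v) - stats::ecdf(yy)(v)))
  }
  d_obs <- Dof(x, y)
  combs <- utils::combn(n1 + n2, n1)
  hits <- 0
  for (ci in seq_len(ncol(combs))) {
    xx <- pooled[combs[, ci]]; yy <- pooled[-combs[, ci]]
    if (Dof(xx, yy) >= d_obs - 1e-12) hits <- hits + 1
  }
  hits / ncol(combs)
}

# small fully-placed scene for renderer/augmentation tests
make_test_scene <- function(seed = 1, image_size = c(128, 128),
                            n_crystals = 3) {
  set.seed(seed)
  cfg <- scene_config(image_size = image_size, n_crystals = n_crystals,
                      shape = shape_config(image_side = min(image_size),
                                           a_max = (0.4 * min(image_size))^2))
  place_crystals(cfg)
}

# logical matrix of pixels within `dist` of a polygon's boundary or
# interior (brute-force point-to-segment distances)
poly_band <- function(poly, W, H, dist) {
  px <- rep(seq_len(W), each = H) - 0.5
  py <- rep(seq_len(H), times = W) - 0.5
  dmin <- rep(Inf, length(px))
  m <- nrow(poly)
  for (i in seq_len(m)) {
    j <- if (i == m) 1 else i + 1
    a <- poly[i, ]; b <- poly[j, ]
    d <- b - a; len2 <- sum(d^2)
    t <- if (len2 < 1e-12) rep(0, length(px))
         else pmin(pmax(((px - a[1]) * d[1] + (py - a[2]) * d[2]) / len2, 0), 1)
    dd <- sqrt((px - a[1] - t * d[1])^2 + (py - a[2] - t * d[2])^2)
    dmin <- pmin(dmin, dd)
  }
  inside <- pcsgen:::points_in_convex(px, py, poly)
  matrix(dmin <= dist | inside, H, W)
}

# finite-difference gradient magnitude of an image
grad_mag <- function(img) {
  gx <- img[, -1, drop = FALSE] - img[, -ncol(img), drop = FALSE]
  gy <- img[-1, , drop = FALSE] - img[-nrow(img), , drop = FALSE]
  list(gx = gx, gy = gy)
}
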