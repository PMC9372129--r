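#' Construct a rotated rectangle
#'
#' Canonical parameterization of an oriented box: center `(cx, cy)` in pixel
#' coordinates (origin top-left, x right, y down), side lengths with
#' `w >= h`, and `theta` in \eqn{[-\pi/2, \pi/2)} the angle of the `w` side
#' measured from the +x axis. If called with `w < h` the sides are swapped
#' and `theta` rotated by \eqn{\pi/2}; `theta` is always wrapped into the
#' canonical interval. Derived quantities: `r = w/h`, `a = w*h`,
#' `w = sqrt(a*r)`, `h = sqrt(a/r)`.
#'
#' @param cx,cy center, pixels.
#' @param w,h side lengths, pixels (> 0).
#' @param theta angle in radians.
#' @return a one-row data.frame of class `rotated_rect` with columns
#'   `cx, cy, w, h, theta`.
#' @export
rotated_rect <- function(cx, cy, w, h, theta) {
  stopifnot(w > 0, h > 0)
  if (w < h) { tmp <- w; w <- h; h <- tmp; theta <- theta + pi / 2 }
  theta <- wrap_angle(theta)
  structure(data.frame(cx = cx, cy = cy, w = w, h = h, theta = theta),
            class = c("rotated_rect", "data.frame"))
}

#' Wrap an angle into \eqn{[-\pi/2, \pi/2)}
#'
#' Rectangle angles live on a half-circle (a box is invariant under rotation
#' by \eqn{\pi}); this is the canonical representative.
#'
#' @param theta angle(s) in radians.
#' @return wrapped angle(s).
#' @export
wrap_angle <- function(theta) {
  ((theta + pi / 2) %% pi) - pi / 2
}

#' Absolute angular difference on the rectangle half-circle
#'
#' @param t1,t2 angles in radians.
#' @return the wrapped absolute difference, in \[0, pi/2\].
#' @export
angle_diff <- function(t1, t2) {
  d <- abs(wrap_angle(t1 - t2))
  pmin(d, pi - d)
}

#' Corner coordinates of a rotated rectangle
#'
#' @param rect a `rotated_rect` (one row).
#' @return a 4x2 matrix of corner coordinates in counterclockwise order
#'   (in image coordinates with y down).
#' @export
rect_corners <- function(rect) {
  ct <- cos(rect$theta); st <- sin(rect$theta)
  dx <- rect$w / 2; dy <- rect$h / 2
  base <- rbind(c(-dx, -dy), c(dx, -dy), c(dx, dy), c(-dx, dy))
  R <- rbind(c(ct, -st), c(st, ct))
  sweep(base %*% t(R), 2, c(rect$cx, rect$cy), `+`)
}

#' Signed polygon area (shoelace formula)
#'
#' @param pts an n x 2 matrix of vertices.
#' @return the signed area; positive for counterclockwise orientation in a
#'   y-up frame (clockwise on screen with y down).
#' @export
polygon_area <- function(pts) {
  n <- nrow(pts)
  if (is.null(n) || n < 3) return(0)
  x <- pts[, 1]; y <- pts[, 2]
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

#' Minimum-area enclosing rotated rectangle
#'
#' Computes the convex hull of the points and applies the rotating-calipers
#' principle: the minimum-area enclosing rectangle has one side collinear
#' with a hull edge, so it suffices to evaluate the axis-aligned bounding
#' box of the hull in each hull-edge frame and keep the smallest.
#'
#' @param points an n x 2 matrix (or data.frame) of pixel coordinates,
#'   n >= 3, not all collinear.
#' @return a `rotated_rect`.
#' @export
min_area_rect <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("need at least 3 points")
  hull_idx <- grDevices::chull(points)
  hull <- points[hull_idx, , drop = FALSE]
  m <- nrow(hull)
  if (m < 3 || abs(polygon_area(hull)) < 1e-12)
    stop("points are collinear")
  edges <- hull[c(2:m, 1), ] - hull
  ang <- atan2(edges[, 2], edges[, 1]) %% (pi / 2)
  ang <- unique(ang)
  # rotate hull into each candidate edge frame (vectorized over angles)
  ca <- cos(ang); sa <- sin(ang)
  xr <- outer(ca, hull[, 1]) + outer(sa, hull[, 2])   # length(ang) x m
  yr <- -outer(sa, hull[, 1]) + outer(ca, hull[, 2])
  xmin <- apply(xr, 1, min); xmax <- apply(xr, 1, max)
  ymin <- apply(yr, 1, min); ymax <- apply(yr, 1, max)
  areas <- (xmax - xmin) * (ymax - ymin)
  k <- which.min(areas)
  w <- xmax[k] - xmin[k]; h <- ymax[k] - ymin[k]
  cxr <- (xmin[k] + xmax[k]) / 2; cyr <- (ymin[k] + ymax[k]) / 2
  # rotate center back into image frame
  cx <- ca[k] * cxr - sa[k] * cyr
  cy <- sa[k] * cxr + ca[k] * cyr
  rotated_rect(cx, cy, w, h, ang[k])
}

# Clip a convex polygon by the half-plane on the left of segment a->b
# (Sutherland-Hodgman step).
clip_halfplane <- function(poly, a, b) {
  if (is.null(poly) || nrow(poly) == 0) return(poly)
  d <- (b[1] - a[1]) * (poly[, 2] - a[2]) - (b[2] - a[2]) * (poly[, 1] - a[1])
  n <- nrow(poly)
  out <- matrix(0, 2 * n, 2)
  cnt <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    di <- d[i]; dj <- d[j]
    if (di <= 0) { cnt <- cnt + 1; out[cnt, ] <- poly[i, ] }
    if ((di < 0) != (dj < 0) && di != dj) {
      t <- di / (di - dj)
      cnt <- cnt + 1
      out[cnt, ] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  out[seq_len(cnt), , drop = FALSE]
}

#' Intersection of two convex polygons
#'
#' Sutherland-Hodgman clipping of `p1` against each edge of `p2`. Both
#' polygons must be convex; vertex order may be either orientation.
#'
#' @param p1,p2 convex polygons as n x 2 matrices.
#' @return the intersection polygon (possibly with 0 rows).
#' @export
convex_intersection <- function(p1, p2) {
  # orient p2 clockwise in screen coords (negative shoelace in y-down frame)
  if (polygon_area(p2) > 0) p2 <- p2[rev(seq_len(nrow(p2))), , drop = FALSE]
  out <- p1
  m <- nrow(p2)
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    out <- clip_halfplane(out, p2[i, ], p2[j, ])
    if (is.null(out) || nrow(out) == 0) return(matrix(numeric(0), 0, 2))
  }
  out
}

#' Intersection-over-union of two rotated rectangles
#'
#' Exact rotated IoU via convex polygon clipping; used both by the
#' overlap constraint during crystal placement and by detection matching.
#'
#' @param rect1,rect2 `rotated_rect` objects (one row each).
#' @return IoU in \[0, 1\].
#' @export
rotated_iou <- function(rect1, rect2) {
  c1 <- rect_corners(rect1); c2 <- rect_corners(rect2)
  inter <- abs(polygon_area(convex_intersection(c1, c2)))
  a1 <- rect1$w * rect1$h; a2 <- rect2$w * rect2$h
  u <- a1 + a2 - inter
  if (u <= 0) return(0)
  inter / u
}

# point-in-convex-polygon test (vectorized over points); boundary counts in
points_in_convex <- function(px, py, poly) {
  if (polygon_area(poly) > 0) poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  n <- nrow(poly)
  inside <- rep(TRUE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    d <- (poly[j, 1] - poly[i, 1]) * (py - poly[i, 2]) -
      (poly[j, 2] - poly[i, 2]) * (px - poly[i, 1])
    inside <- inside & (d <= 1e-9)
  }
  inside
}
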