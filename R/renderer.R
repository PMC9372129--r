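#' Rendering configuration
#'
#' Parameters of the stylized bright-field renderer. The detection-relevant
#' signal for transparent crystals is the intensity gradient at their
#' visible edges; the renderer therefore composites Gaussian-profile edge
#' strokes (weighted by the material's refractive index) and a weak interior
#' transmission factor over a smooth light-driven background field, instead
#' of physically tracing rays. Geometry used for masks and boxes is exact
#' (projected polygons), never derived from pixels.
#'
#' @param bg_level background transmission level in \[0, 1\].
#' @param bg_gradient relative amplitude of the light-direction brightness
#'   ramp across the image.
#' @param edge_sigma Gaussian cross-profile standard deviation of edge
#'   strokes, pixels.
#' @param edge_amp stroke amplitude at the maximum refractive index
#'   (n = 1.8); actual amplitude scales linearly with `(n - 1)/0.8`.
#' @param edge_highlight fraction of the stroke re-added as a bright rim.
#' @param transparency interior dimming at n = 1.8 (0 = fully transparent).
#' @return an object of class `render_config`.
#' @export
render_config <- function(bg_level = 0.82, bg_gradient = 0.25,
                          edge_sigma = 1, edge_amp = 0.45,
                          edge_highlight = 0.35, transparency = 0.10) {
  stopifnot(bg_level > 0, bg_level <= 1, edge_sigma > 0)
  structure(list(bg_level = bg_level, bg_gradient = bg_gradient,
                 edge_sigma = edge_sigma, edge_amp = edge_amp,
                 edge_highlight = edge_highlight,
                 transparency = transparency),
            class = "render_config")
}

# rasterize a convex polygon; returns integer pixel indices into an H x W
# matrix (pixel (i,j) has center (j - 0.5, i - 0.5))
rasterize_convex <- function(poly, W, H) {
  xlo <- max(1L, floor(min(poly[, 1]) + 0.5)); xhi <- min(W, ceiling(max(poly[, 1]) + 0.5))
  ylo <- max(1L, floor(min(poly[, 2]) + 0.5)); yhi <- min(H, ceiling(max(poly[, 2]) + 0.5))
  if (xlo > xhi || ylo > yhi) return(integer(0))
  cols <- xlo:xhi; rows <- ylo:yhi
  px <- rep(cols, each = length(rows)) - 0.5
  py <- rep(rows, times = length(cols)) - 0.5
  idx <- rep(rows, times = length(cols)) + (rep(cols, each = length(rows)) - 1L) * H
  idx[points_in_convex(px, py, poly)]
}

# additive Gaussian-profile stroke along segment p1-p2 into img (H x W)
stroke_segment <- function(img, p1, p2, sigma, amp) {
  H <- nrow(img); W <- ncol(img)
  pad <- ceiling(3 * sigma)
  xlo <- max(1L, floor(min(p1[1], p2[1]) - pad)); xhi <- min(W, ceiling(max(p1[1], p2[1]) + pad))
  ylo <- max(1L, floor(min(p1[2], p2[2]) - pad)); yhi <- min(H, ceiling(max(p1[2], p2[2]) + pad))
  if (xlo > xhi || ylo > yhi) return(img)
  cols <- xlo:xhi; rows <- ylo:yhi
  px <- rep(cols, each = length(rows)) - 0.5
  py <- rep(rows, times = length(cols)) - 0.5
  d <- p2 - p1
  len2 <- sum(d^2)
  if (len2 < 1e-12) {
    dist2 <- (px - p1[1])^2 + (py - p1[2])^2
  } else {
    t <- pmin(pmax(((px - p1[1]) * d[1] + (py - p1[2]) * d[2]) / len2, 0), 1)
    dist2 <- (px - p1[1] - t * d[1])^2 + (py - p1[2] - t * d[2])^2
  }
  idx <- rep(rows, times = length(cols)) + (rep(cols, each = length(rows)) - 1L) * H
  keep <- dist2 <= (3 * sigma)^2   # truncate the profile: strokes are local
  img[idx[keep]] <- img[idx[keep]] + amp * exp(-dist2[keep] / (2 * sigma^2))
  img
}

# edges worth drawing: face-adjacency creases and silhouette edges, seen
# from the camera at the origin
visible_edges <- function(mesh, transform) {
  V <- t(transform$M %*% rbind(t(mesh$vertices), 1))[, 1:3]
  F <- mesh$faces
  nf <- nrow(F)
  normals <- matrix(0, nf, 3); vis <- logical(nf)
  for (i in seq_len(nf)) {
    a <- V[F[i, 1], ]; b <- V[F[i, 2], ]; c_ <- V[F[i, 3], ]
    nrm <- crossprod3(b - a, c_ - a)
    normals[i, ] <- nrm / sqrt(sum(nrm^2))
    vis[i] <- sum(nrm * (a + b + c_)) < 0   # faces the camera at origin
  }
  ekey <- character(0); e1 <- integer(0); e2 <- integer(0)
  f1 <- integer(0); f2 <- integer(0)
  env <- new.env(hash = TRUE)
  for (i in seq_len(nf)) {
    for (k in 1:3) {
      a <- F[i, k]; b <- F[i, if (k == 3) 1 else k + 1]
      key <- paste(min(a, b), max(a, b))
      prev <- env[[key]]
      if (is.null(prev)) env[[key]] <- c(min(a, b), max(a, b), i, 0L)
      else { prev[4] <- i; env[[key]] <- prev }
    }
  }
  keep <- list()
  for (key in ls(env)) {
    e <- env[[key]]
    fa <- e[3]; fb <- e[4]
    draw <- if (fb == 0L) vis[fa] else {
      crease <- sum(normals[fa, ] * normals[fb, ]) < 1 - 1e-6
      (vis[fa] != vis[fb]) || (vis[fa] && vis[fb] && crease)
    }
    if (draw) keep[[length(keep) + 1]] <- e[1:2]
  }
  do.call(rbind, keep)
}

#' Render a virtual scene to an annotated grayscale image
#'
#' Produces the base image for a [place_crystals()] scene: a smooth
#' background brightness field tilted toward the light source, weakly
#' transmitting crystal interiors, and Gaussian-profile strokes along the
#' projected silhouette and visible crease edges of each crystal, with
#' stroke contrast increasing monotonically in the refractive index
#' `(n - 1)`. Silhouette masks and oriented boxes come from the exact
#' projected geometry, not from the rendered pixels.
#'
#' @param scene a `scene_spec`.
#' @param config a [render_config()].
#' @return an object of class `annotated_image`: `image` (H x W matrix in
#'   \[0, 1\]), `annotations` (data.frame `id, cx, cy, w, h, theta`), and
#'   `polygons` (list of silhouette vertex matrices).
#' @export
render_scene <- function(scene, config = render_config()) {
  W <- scene$image_size[1]; H <- scene$image_size[2]
  # light-position-driven background ramp
  lx <- scene$light[1]; ly <- scene$light[2]
  lnorm <- sqrt(lx^2 + ly^2)
  ux <- if (lnorm > 1e-9) lx / lnorm else 0
  uy <- if (lnorm > 1e-9) ly / lnorm else 0
  xs <- (matrix(rep(seq_len(W) - 0.5, each = H), H, W) - W / 2) / W
  ys <- (matrix(rep(seq_len(H) - 0.5, times = W), H, W) - H / 2) / H
  img <- config$bg_level * (1 + config$bg_gradient * (xs * ux + ys * uy))

  for (cr in scene$crystals) {
    nn <- (cr$material$n - 1) / 0.8   # 0 at n=1, 1 at n=1.8
    idx <- rasterize_convex(cr$polygon, W, H)
    img[idx] <- img[idx] * (1 - config$transparency * nn)
    edges <- visible_edges(cr$mesh, cr$transform)
    pts <- project_vertices(cr$mesh, cr$transform, scene$camera)
    amp <- config$edge_amp * nn
    if (!is.null(edges)) for (i in seq_len(nrow(edges))) {
      img <- stroke_segment(img, pts[edges[i, 1], ], pts[edges[i, 2], ],
                            config$edge_sigma, -amp)
    }
    # bright rim slightly outside the silhouette
    poly <- cr$polygon
    ctr <- colMeans(poly)
    rel <- sweep(poly, 2, ctr)
    grow <- 1 + 2 * config$edge_sigma / pmax(sqrt(rowSums(rel^2)), 1e-9)
    rim <- sweep(rel * grow, 2, ctr, `+`)
    m <- nrow(rim)
    for (i in seq_len(m)) {
      j <- if (i == m) 1L else i + 1L
      img <- stroke_segment(img, rim[i, ], rim[j, ], config$edge_sigma,
                            amp * config$edge_highlight)
    }
  }
  img[img < 0] <- 0; img[img > 1] <- 1

  ann <- annotations_from_scene(scene)
  structure(list(image = img, annotations = ann$annotations,
                 polygons = ann$polygons, image_size = c(W, H)),
            class = "annotated_image")
}

#' Extract annotations from a scene
#'
#' Per crystal: the projected silhouette polygon (2D convex hull of the
#' projected vertices) and its minimum-area rotated rectangle — identical
#' to the values accepted by the placement fit.
#'
#' @param scene a `scene_spec`.
#' @return list with `annotations` (data.frame `id, cx, cy, w, h, theta`)
#'   and `polygons` (list of n x 2 matrices).
#' @export
annotations_from_scene <- function(scene) {
  n <- length(scene$crystals)
  if (n == 0)
    return(list(annotations = data.frame(id = integer(0), cx = numeric(0),
                                         cy = numeric(0), w = numeric(0),
                                         h = numeric(0), theta = numeric(0)),
                polygons = list()))
  rects <- do.call(rbind, lapply(scene$crystals, `[[`, "rect"))
  list(annotations = cbind(data.frame(id = seq_len(n)),
                           as.data.frame(rects)),
       polygons = lapply(scene$crystals, `[[`, "polygon"))
}

#' Rasterized silhouette mask of one annotated crystal
#'
#' @param ann an `annotated_image`.
#' @param i crystal index.
#' @return logical H x W matrix.
#' @export
crystal_mask <- function(ann, i) {
  W <- ann$image_size[1]; H <- ann$image_size[2]
  m <- matrix(FALSE, H, W)
  m[rasterize_convex(ann$polygons[[i]], W, H)] <- TRUE
  m
}
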