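#' Placement tolerances
#'
#' A fitted crystal pose is accepted once its projected minimum-area
#' rectangle \eqn{(r', a', \theta')} is close enough to the sampled target
#' \eqn{(r, a, \theta)}:
#' \eqn{|\sqrt{a'}-\sqrt{a}| < \Delta_a}, \eqn{|r'-r| < \Delta_r},
#' \eqn{|\theta'-\theta| < \Delta_\theta}. The defaults
#' (\eqn{\Delta_r = 0.2}, \eqn{\Delta_a = 2} px on the square-root-area
#' scale, \eqn{\Delta_\theta = 2} degrees) keep the realized dataset
#' distributions close to the statistical model while remaining cheap to
#' attain.
#'
#' @param d_r aspect-ratio tolerance, dimensionless.
#' @param d_a square-root-area tolerance, pixels.
#' @param d_theta angle tolerance, radians (default 2 degrees).
#' @return an object of class `placement_tolerances`.
#' @export
placement_tolerances <- function(d_r = 0.2, d_a = 2, d_theta = 2 * pi / 180) {
  stopifnot(d_r > 0, d_a > 0, d_theta > 0)
  structure(list(d_r = d_r, d_a = d_a, d_theta = d_theta),
            class = "placement_tolerances")
}

# deviations of an achieved rect from a target sample; all three
# inequalities are enforced, including the angle for near-square boxes
# (their minimum-area rectangle still carries a defined angle, and
# enforcing it keeps the realized angle distribution faithful)
placement_deviations <- function(rect, target, tol) {
  r2 <- rect$w / rect$h
  c(d_r = abs(r2 - target$r),
    d_a = abs(sqrt(rect$w * rect$h) - sqrt(target$a)),
    d_theta = angle_diff(rect$theta, target$theta))
}

#' Initial guess for the placement optimizer
#'
#' Because the mesh's dominant axis lies along x and the camera is
#' near-orthographic, the in-plane rotation `gamma` maps almost directly
#' onto the box angle and the scales map onto the box sides
#' `w = sqrt(a*r)`, `h = sqrt(a/r)`. The guess is `gamma0 = theta`,
#' `s_x0 = c*sqrt(a*r)`, `s_y0 = c*sqrt(a/r)`, where the calibration
#' constant `c` is measured after the initial translation by projecting the
#' mesh at unit scale and taking the reciprocal of its projected x-extent
#' per unit model length.
#'
#' @param target a one-row data.frame with `r`, `a`, `theta` (a target
#'   sample from [sample_rect()]).
#' @param camera a `camera_model`.
#' @param mesh a `crystal_mesh`.
#' @param alpha,beta the pre-drawn out-of-plane rotations.
#' @param t translation (camera frame) at which the crystal will sit.
#' @return list with `gamma0`, `s_x0`, `s_y0`, and the calibration `c`.
#' @export
initial_guess <- function(target, camera, mesh, alpha = 0, beta = 0,
                          t = c(0, 0, camera$depth)) {
  tr <- model_transform(alpha = alpha, beta = beta, gamma = 0,
                        s = c(1, 1, 1), t = t)
  pts <- project_vertices(mesh, tr, camera)
  ext_px <- diff(range(pts[, 1]))
  if (ext_px <= 0) stop("zero projected extent")
  # mesh x-extent is 1 model unit by convention, so px-per-unit = ext_px
  cc <- 1 / ext_px
  list(gamma0 = target$theta,
       s_x0 = cc * sqrt(target$a * target$r),
       s_y0 = cc * sqrt(target$a / target$r),
       c = cc)
}

#' Fit a crystal pose to a target rectangle
#'
#' Draws the out-of-plane rotations `alpha ~ U[0, 2*pi)`,
#' `beta ~ U[-pi/3, pi/3]` and the translation once, then adjusts only
#' `(gamma, s_x, s_y)` (with `s_z` tied to `s_y`) until the projected
#' minimum-area rectangle meets the tolerances. The solver is a
#' derivative-free multiplicative fixed-point update on the box sides and an
#' additive update on the angle, started from [initial_guess()]; if it
#' stalls, a Nelder-Mead polish of the maximum normalized deviation is run,
#' and up to `restarts` re-draws of `alpha`, `beta` are attempted before
#' signalling failure.
#'
#' @param mesh a `crystal_mesh`.
#' @param target one-row data.frame with `r`, `a`, `theta`.
#' @param camera a `camera_model`.
#' @param tol a [placement_tolerances()].
#' @param center desired pixel center `c(cx, cy)` of the crystal (default:
#'   image center); realized via the lateral translation.
#' @param depth_jitter relative jitter of the placement depth, drawn once.
#' @param max_iter fixed-point iterations per start.
#' @param restarts additional starts with re-drawn `alpha`, `beta`.
#' @return on success, a list of class `placement_fit` with the
#'   `model_transform`, the achieved `rect` (`rotated_rect`), the projected
#'   hull `polygon`, the recorded `deviations` and `n_eval`; on failure,
#'   `NULL`.
#' @export
fit_placement <- function(mesh, target, camera,
                          tol = placement_tolerances(),
                          center = NULL, depth_jitter = 0.05,
                          max_iter = 40, restarts = 3) {
  if (is.null(center)) center <- c(camera$cx, camera$cy)
  z <- camera$depth * (1 + stats::runif(1, -depth_jitter, depth_jitter))
  tx <- (center[1] - camera$cx) * z / camera$f
  ty <- (center[2] - camera$cy) * z / camera$f
  t <- c(tx, ty, z)
  n_eval <- 0L

  for (attempt in seq_len(restarts + 1)) {
    alpha <- stats::runif(1, 0, 2 * pi)
    beta <- stats::runif(1, -pi / 3, pi / 3)
    g <- initial_guess(target, camera, mesh, alpha, beta, t)
    par <- c(g$gamma0, g$s_x0, g$s_y0)

    eval_par <- function(par) {
      tr <- model_transform(alpha = alpha, beta = beta, gamma = par[1],
                            s = c(par[2], par[3], par[3]), t = t)
      pts <- project_vertices(mesh, tr, camera)
      rect <- min_area_rect(pts)
      list(tr = tr, pts = pts, rect = rect,
           dev = placement_deviations(rect, target, tol))
    }

    for (it in seq_len(max_iter)) {
      res <- eval_par(par)
      n_eval <- n_eval + 1L
      d <- res$dev
      if (d[1] < tol$d_r && d[2] < tol$d_a && d[3] < tol$d_theta) {
        hull <- res$pts[grDevices::chull(res$pts), , drop = FALSE]
        return(structure(list(transform = res$tr, rect = res$rect,
                              polygon = hull, deviations = d,
                              n_eval = n_eval, alpha = alpha, beta = beta),
                         class = "placement_fit"))
      }
      # multiplicative correction on sides, additive on angle
      w_t <- sqrt(target$a * target$r); h_t <- sqrt(target$a / target$r)
      par[1] <- par[1] + wrap_angle(target$theta - res$rect$theta)
      par[2] <- par[2] * max(min(w_t / res$rect$w, 4), 0.25)
      par[3] <- par[3] * max(min(h_t / res$rect$h, 4), 0.25)
    }

    # Nelder-Mead polish on the max normalized deviation
    obj <- function(p) {
      if (p[2] <= 0 || p[3] <= 0) return(10)
      d <- eval_par(p)$dev
      max(d[1] / tol$d_r, d[2] / tol$d_a, d[3] / tol$d_theta)
    }
    opt <- stats::optim(par, obj, method = "Nelder-Mead",
                        control = list(maxit = 200, reltol = 1e-8))
    n_eval <- n_eval + opt$counts[1]
    if (opt$value < 1) {
      res <- eval_par(opt$par)
      hull <- res$pts[grDevices::chull(res$pts), , drop = FALSE]
      return(structure(list(transform = res$tr, rect = res$rect,
                            polygon = hull, deviations = res$dev,
                            n_eval = n_eval, alpha = alpha, beta = beta),
                       class = "placement_fit"))
    }
  }
  NULL
}

#' Scene configuration
#'
#' @param image_size `c(width, height)` pixels; default 384 x 384.
#' @param n_crystals either a fixed count or a range `c(lo, hi)` sampled
#'   uniformly per image (default 5..20; the area bounds of the shape model
#'   make denser packing physically infeasible on a 384 px image).
#' @param overlap_cap maximum allowed rotated-box IoU between any two
#'   accepted crystals (default 0.25).
#' @param border_margin pixels the projected silhouette must keep clear of
#'   the image border.
#' @param shape a [shape_config()]; defaults to bounds tied to `image_size`.
#' @param camera a [camera_model()] for `image_size`.
#' @param tol a [placement_tolerances()].
#' @param n_range_refraction bounds of the uniform refractive-index draw.
#' @param max_attempts placement attempts per crystal slot before giving up.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(image_size = c(384, 384), n_crystals = c(5, 20),
                         overlap_cap = 0.25, border_margin = 1,
                         shape = NULL, camera = NULL,
                         tol = placement_tolerances(),
                         n_range_refraction = c(1.1, 1.8),
                         max_attempts = 40) {
  if (is.null(shape)) shape <- shape_config(image_side = min(image_size))
  if (is.null(camera)) camera <- camera_model(image_size = image_size)
  stopifnot(overlap_cap >= 0, max_attempts >= 1)
  structure(list(image_size = image_size, n_crystals = n_crystals,
                 overlap_cap = overlap_cap, border_margin = border_margin,
                 shape = shape, camera = camera, tol = tol,
                 n_range_refraction = n_range_refraction,
                 max_attempts = max_attempts),
            class = "scene_config")
}

#' Assemble a virtual scene of placed crystals
#'
#' Samples targets from the shape model and fits crystal poses until the
#' requested count is placed. A fitted crystal is rejected when its
#' projected silhouette touches the image border, its realized aspect ratio
#' exceeds `r_max`, or its rotated-box IoU with an already accepted crystal
#' exceeds the overlap cap; rejected targets are resampled. Every accepted
#' crystal receives a glass material with refractive index
#' `n ~ U[1.1, 1.8]`; a point light is drawn uniformly on an upper
#' hemisphere over the scene.
#'
#' All targets drawn along the way (accepted or not) are recorded in
#' `targets_drawn` — they are the raw, unbiased samples from the model that
#' bias checks should be run against.
#'
#' @param config a [scene_config()].
#' @return an object of class `scene_spec`: per-crystal entries (mesh,
#'   transform, material, achieved rect, silhouette polygon, target),
#'   `camera`, `light`, `targets_drawn`, and a `short` flag set when fewer
#'   crystals than requested could be placed.
#' @export
place_crystals <- function(config = scene_config()) {
  W <- config$image_size[1]; H <- config$image_size[2]
  n_req <- if (length(config$n_crystals) == 2)
    sample(config$n_crystals[1]:config$n_crystals[2], 1) else config$n_crystals
  crystals <- list()
  targets <- list()
  m <- config$border_margin

  for (slot in seq_len(n_req)) {
    placed <- FALSE
    for (att in seq_len(config$max_attempts)) {
      target <- sample_rect(1, config$shape)
      targets[[length(targets) + 1]] <- target
      w_t <- sqrt(target$a * target$r); h_t <- sqrt(target$a / target$r)
      half_diag <- sqrt(w_t^2 + h_t^2) / 2
      lo_x <- m + half_diag; hi_x <- W - m - half_diag
      lo_y <- m + half_diag; hi_y <- H - m - half_diag
      if (lo_x >= hi_x || lo_y >= hi_y) next  # target cannot fit at all
      center <- c(stats::runif(1, lo_x, hi_x), stats::runif(1, lo_y, hi_y))
      mesh <- generate_crystal_mesh()
      fit <- fit_placement(mesh, target, config$camera, config$tol,
                           center = center)
      if (is.null(fit)) next
      poly <- fit$polygon
      if (any(poly[, 1] < m | poly[, 1] > W - m |
              poly[, 2] < m | poly[, 2] > H - m)) next
      if (fit$rect$w / fit$rect$h > config$shape$r_max) next
      ok <- TRUE
      for (cr in crystals) {
        if (rotated_iou(fit$rect, cr$rect) > config$overlap_cap) { ok <- FALSE; break }
      }
      if (!ok) next
      crystals[[length(crystals) + 1]] <- list(
        mesh = mesh, transform = fit$transform,
        material = list(n = stats::runif(1, config$n_range_refraction[1],
                                         config$n_range_refraction[2])),
        rect = fit$rect, polygon = poly, target = target,
        deviations = fit$deviations)
      placed <- TRUE
      break
    }
    if (!placed) break
  }

  # light on an upper hemisphere above the scene center
  az <- stats::runif(1, 0, 2 * pi)
  el <- acos(stats::runif(1))  # uniform on the hemisphere
  rad <- 2 * config$camera$depth
  light <- rad * c(sin(el) * cos(az), sin(el) * sin(az), -cos(el)) +
    c(0, 0, config$camera$depth)

  structure(list(crystals = crystals, camera = config$camera,
                 light = light, image_size = config$image_size,
                 targets_drawn = do.call(rbind, targets),
                 n_requested = n_req,
                 short = length(crystals) < n_req,
                 config = config),
            class = "scene_spec")
}
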