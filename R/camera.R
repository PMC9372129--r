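#' Perspective camera model
#'
#' The scene lives in a right-handed camera frame: x to the right, y down
#' (matching image coordinates), z forward into the scene; the camera sits
#' at the origin looking along +z. A narrow field of view (default 5
#' degrees) keeps the projection near-orthographic, which is what makes the
#' linear initial guess of the placement optimizer accurate.
#'
#' @param image_size `c(width, height)` in pixels.
#' @param fov_deg vertical field of view, degrees.
#' @param depth nominal scene depth: the distance at which crystals are
#'   placed (model units; arbitrary because only the focal-length-to-depth
#'   ratio matters).
#' @param near near clipping plane; projecting a vertex at `z <= near`
#'   raises an error.
#' @return an object of class `camera_model`, with the derived focal length
#'   in pixels `f = (height/2)/tan(fov/2)`.
#' @export
camera_model <- function(image_size = c(384, 384), fov_deg = 5,
                         depth = NULL, near = 1e-3) {
  stopifnot(length(image_size) == 2, all(image_size > 0), fov_deg > 0)
  f <- (image_size[2] / 2) / tan(fov_deg * pi / 360)
  if (is.null(depth)) depth <- f / 2   # ~2 px per model unit at unit scale
  structure(list(image_size = image_size, fov_deg = fov_deg, f = f,
                 depth = depth, near = near,
                 cx = image_size[1] / 2, cy = image_size[2] / 2),
            class = "camera_model")
}

# 4x4 homogeneous building blocks ------------------------------------------

rot_x <- function(a) {
  c_ <- cos(a); s <- sin(a)
  rbind(c(1, 0, 0, 0), c(0, c_, -s, 0), c(0, s, c_, 0), c(0, 0, 0, 1))
}
rot_y <- function(b) {
  c_ <- cos(b); s <- sin(b)
  rbind(c(c_, 0, s, 0), c(0, 1, 0, 0), c(-s, 0, c_, 0), c(0, 0, 0, 1))
}
rot_z <- function(g) {
  c_ <- cos(g); s <- sin(g)
  rbind(c(c_, -s, 0, 0), c(s, c_, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1))
}
scale_mat <- function(sx, sy, sz) diag(c(sx, sy, sz, 1))
trans_mat <- function(t) rbind(cbind(diag(3), t), c(0, 0, 0, 1))

#' Model transform for crystal placement
#'
#' The full chain that maps a model vertex to the image plane is
#' `M = P C T Rz(gamma) Ry(beta) Rx(alpha) S(sx, sy, sz)` applied
#' right-to-left. This object holds the model part
#' `T Rz Ry Rx S`; the camera supplies `C` (identity: the scene is
#' expressed in the camera frame) and the perspective projection `P`.
#'
#' @param alpha,beta,gamma rotations about x, y, z in radians. `beta` must
#'   stay within \eqn{[-\pi/3, \pi/3]} so that in-plane box angles remain
#'   controlled by `gamma`.
#' @param s scale factors `c(sx, sy, sz)`, all > 0.
#' @param t translation `c(tx, ty, tz)` in camera-frame model units.
#' @return an object of class `model_transform` carrying the parameters and
#'   the composed 4x4 model matrix.
#' @export
model_transform <- function(alpha = 0, beta = 0, gamma = 0,
                            s = c(1, 1, 1), t = c(0, 0, 0)) {
  stopifnot(all(s > 0), length(t) == 3)
  if (beta < -pi / 3 - 1e-9 || beta > pi / 3 + 1e-9)
    stop("beta outside [-pi/3, pi/3]")
  M <- trans_mat(t) %*% rot_z(gamma) %*% rot_y(beta) %*% rot_x(alpha) %*%
    scale_mat(s[1], s[2], s[3])
  structure(list(alpha = alpha, beta = beta, gamma = gamma, s = s, t = t,
                 M = M),
            class = "model_transform")
}

#' Project mesh vertices onto the image plane
#'
#' Applies the model matrix, then the perspective projection
#' `px = cx + f*x/z`, `py = cy + f*y/z` (the composition `P C` of the
#' camera), returning one 2D pixel point per vertex.
#'
#' @param mesh a `crystal_mesh`.
#' @param transform a `model_transform`.
#' @param camera a `camera_model`.
#' @return an n x 2 matrix of pixel coordinates.
#' @export
project_vertices <- function(mesh, transform, camera) {
  V <- transform$M %*% rbind(t(mesh$vertices), 1)
  z <- V[3, ]
  if (any(z <= camera$near)) stop("vertex behind the camera near plane")
  cbind(camera$cx + camera$f * V[1, ] / z,
        camera$cy + camera$f * V[2, ] / z)
}
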