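#' Procedural convex crystal mesh
#'
#' Stand-in generator for a curated collection of 3D crystal models.
#' Produces convex prisms or (truncated) bipyramids: a convex cross-section
#' polygon in the y-z plane is extruded (or tapered to apexes) along x, the
#' dominant growth axis. The mesh is normalized so its x-extent is exactly 1
#' model unit, the dominant principal axis lies along x, and the y/z extent
#' ratio stays within \[0.5, 2\] — the conventions the placement optimizer's
#' initial guess relies on.
#'
#' Uses R's global RNG; seed with [set.seed()].
#'
#' @param family `"prism"`, `"bipyramid"`, or `"random"` (choose per call).
#' @param n_sides cross-section vertex count (>= 3); `NULL` draws 4..8.
#' @param elongation ratio of x-extent to cross-section diameter; `NULL`
#'   draws uniformly from `elongation_range`.
#' @param elongation_range range for the random elongation (default
#'   `c(1, 3)`; further anisotropy is produced by the per-axis scales of the
#'   placement fit, not baked into the mesh).
#' @param regular force an isotropic (regular-polygon) cross-section; useful
#'   for constructing reference solids such as cubes.
#' @param id mesh identifier string.
#' @return an object of class `crystal_mesh`: `vertices` (n x 3),
#'   `faces` (m x 3 vertex indices, outward-oriented), `id`.
#' @export
generate_crystal_mesh <- function(family = "random", n_sides = NULL,
                                  elongation = NULL,
                                  elongation_range = c(1, 3),
                                  regular = FALSE, id = NULL) {
  if (family == "random")
    family <- sample(c("prism", "bipyramid"), 1)
  if (!family %in% c("prism", "bipyramid")) stop("unknown mesh family")
  if (is.null(n_sides)) n_sides <- sample(4:8, 1)
  if (n_sides < 3) stop("cross-section needs at least 3 vertices")
  if (is.null(elongation))
    elongation <- stats::runif(1, elongation_range[1], elongation_range[2])
  if (elongation <= 0) stop("elongation must be positive")

  if (elongation < 1) stop("elongation must be >= 1 (dominant axis along x)")

  # convex cross-section: regular polygon, mildly anisotropic (y/z in [0.72, 1.39]),
  # rescaled to unit diameter so the x axis stays dominant
  ang <- seq(0, 2 * pi, length.out = n_sides + 1)[-(n_sides + 1)] +
    stats::runif(1, 0, 2 * pi / n_sides)
  ry <- 0.5 * stats::runif(1, 0.85, 1.18)
  rz <- if (regular) ry else 0.5 * stats::runif(1, 0.85, 1.18)
  yc <- ry * cos(ang); zc <- rz * sin(ang)
  dia <- max(diff(range(yc)), diff(range(zc)))
  yc <- yc / dia; zc <- zc / dia
  half <- elongation / 2

  if (family == "prism") {
    V <- rbind(cbind(-half, yc, zc), cbind(half, yc, zc))
    m <- n_sides
    i1 <- seq_len(m); i2 <- c(2:m, 1)
    side1 <- cbind(i1, i2, i2 + m)
    side2 <- cbind(i1, i2 + m, i1 + m)
    F <- rbind(side1, side2, fan_faces(1:m), fan_faces((m + 1):(2 * m)))
  } else {
    trunc <- stats::runif(1, 0, 0.5)  # 0 = sharp apex, >0 = truncated tip
    if (trunc < 0.05) {
      V <- rbind(cbind(0, yc, zc), c(-half, 0, 0), c(half, 0, 0))
      m <- n_sides
      i1 <- seq_len(m); i2 <- c(2:m, 1)
      F <- rbind(cbind(m + 1, i2, i1), cbind(m + 2, i1, i2))
    } else {
      V <- rbind(cbind(0, yc, zc),
                 cbind(-half, trunc * yc, trunc * zc),
                 cbind(half, trunc * yc, trunc * zc))
      m <- n_sides
      i1 <- seq_len(m); i2 <- c(2:m, 1)
      F <- rbind(cbind(i1, i2, i2 + m), cbind(i1, i2 + m, i1 + m),
                 cbind(i1, i1 + 2 * m, i2 + 2 * m),
                 cbind(i1, i2 + 2 * m, i2),
                 fan_faces((m + 1):(2 * m)),
                 fan_faces((2 * m + 1):(3 * m)))
    }
  }

  dimnames(V) <- NULL
  mesh <- normalize_mesh(structure(
    list(vertices = V, faces = unname(F),
         id = if (is.null(id)) sprintf("%s%d", family, n_sides) else id),
    class = "crystal_mesh"))
  orient_faces(mesh)
}

# triangle fan over a convex polygon given its vertex indices in ring order
fan_faces <- function(ring) {
  m <- length(ring)
  cbind(ring[1], ring[2:(m - 1)], ring[3:m])
}

# scale so x-extent == 1 and center at origin
normalize_mesh <- function(mesh) {
  V <- mesh$vertices
  ctr <- (apply(V, 2, max) + apply(V, 2, min)) / 2
  V <- sweep(V, 2, ctr)
  ext_x <- diff(range(V[, 1]))
  mesh$vertices <- V / ext_x
  mesh
}

# flip faces whose normal points toward the centroid (ensures outward winding)
orient_faces <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  for (i in seq_len(nrow(F))) {
    a <- V[F[i, 1], ]; b <- V[F[i, 2], ]; c_ <- V[F[i, 3], ]
    nrm <- crossprod3(b - a, c_ - a)
    if (sum(nrm * (a + b + c_) / 3) < 0) mesh$faces[i, ] <- F[i, c(1, 3, 2)]
  }
  mesh
}

crossprod3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Mesh extents along the coordinate axes
#'
#' @param mesh a `crystal_mesh`.
#' @return named numeric vector `c(x=, y=, z=)` of bounding-box extents.
#' @export
mesh_extents <- function(mesh) {
  e <- apply(mesh$vertices, 2, function(v) diff(range(v)))
  names(e) <- c("x", "y", "z")
  e
}

#' Validate crystal-mesh invariants
#'
#' Checks convexity (every vertex on the inner side of every face plane),
#' dominant axis along x, and y/z extent ratio within \[0.5, 2\].
#'
#' @param mesh a `crystal_mesh`.
#' @param tol tolerance for the convexity half-space test.
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
check_mesh <- function(mesh, tol = 1e-8) {
  V <- mesh$vertices; F <- mesh$faces
  stopifnot(is.matrix(V), ncol(V) == 3, is.matrix(F), ncol(F) == 3)
  e <- mesh_extents(mesh)
  if (e["x"] < max(e["y"], e["z"]) - tol)
    stop("dominant principal axis is not along x")
  ratio <- e["y"] / e["z"]
  if (ratio < 0.5 || ratio > 2)
    stop("y/z extent ratio outside [0.5, 2]")
  scale <- max(e)
  for (i in seq_len(nrow(F))) {
    a <- V[F[i, 1], ]
    nrm <- crossprod3(V[F[i, 2], ] - a, V[F[i, 3], ] - a)
    d <- (V %*% nrm - sum(nrm * a)) / sqrt(sum(nrm^2))
    if (any(d > tol * scale + 1e-9)) stop("mesh is not convex")
  }
  invisible(TRUE)
}

#' Read a triangle mesh from OBJ or ASCII STL
#'
#' Minimal importers for user-supplied crystal models. The imported mesh is
#' recentered, rescaled to unit x-extent and validated against the
#' `crystal_mesh` invariants (convexity, dominant x axis, near-equal y/z
#' extents); polygonal OBJ faces are fan-triangulated.
#'
#' @param path file path; format inferred from the extension
#'   (`.obj` or `.stl`).
#' @param id mesh identifier (default: file base name).
#' @return a validated `crystal_mesh`.
#' @export
read_mesh <- function(path, id = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE)
  if (ext == "obj") {
    vl <- lines[startsWith(lines, "v ")]
    fl <- lines[startsWith(lines, "f ")]
    V <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                               function(x) as.numeric(x[1:3])))
    F <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"),
      function(x) {
        idx <- as.integer(vapply(strsplit(x, "/"), `[`, "", 1))
        if (length(idx) < 3) stop("OBJ face with fewer than 3 vertices")
        cbind(idx[1], idx[2:(length(idx) - 1)], idx[3:length(idx)])
      }))
  } else if (ext == "stl") {
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    V <- do.call(rbind, lapply(strsplit(trimws(sub("vertex", "", vl)), "\\s+"),
                               as.numeric))
    if (nrow(V) %% 3 != 0) stop("malformed ASCII STL")
    key <- apply(round(V, 9), 1, paste, collapse = ",")
    uid <- match(key, unique(key))
    V <- V[!duplicated(key), , drop = FALSE]
    F <- matrix(uid, ncol = 3, byrow = TRUE)
  } else stop("unsupported mesh format: ", ext)
  mesh <- normalize_mesh(structure(list(vertices = V, faces = unname(F),
                                        id = id),
                                   class = "crystal_mesh"))
  mesh <- orient_faces(mesh)
  check_mesh(mesh)
  mesh
}
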