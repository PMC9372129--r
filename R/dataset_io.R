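#' Write / read a grayscale image
#'
#' Images are processed in float in \[0, 1\] and quantized to 8-bit only at
#' write time.
#'
#' @param img H x W matrix in \[0, 1\].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  png::writePNG(round(img * 255) / 255, path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- rgb_to_gray(img)
  img
}

rgb_to_gray <- function(arr) {
  if (dim(arr)[3] >= 3)
    0.2126 * arr[, , 1] + 0.7152 * arr[, , 2] + 0.0722 * arr[, , 3]
  else arr[, , 1]
}

#' Dataset generation configuration
#'
#' @param n_images number of images to generate (default 1,000; the
#'   full-scale dataset of several hundred thousand images is reachable by
#'   raising this, not a default).
#' @param image_size `c(width, height)`, pixels.
#' @param seed root seed; every image gets a deterministic child seed
#'   recorded in the manifest.
#' @param val_fraction fraction of images assigned to the validation split
#'   (default 0.03, the ratio used for the reference dataset).
#' @param scene a [scene_config()] (default built for `image_size`).
#' @param render_cfg a [render_config()].
#' @param augment_cfg an [augmentation_config()], used when
#'   `augment_validation` is set.
#' @param render if `FALSE`, only scenes/annotations are generated (fast
#'   path for distribution checks); no image files are written.
#' @param augment_validation also write an augmented copy of every
#'   validation image.
#' @return an object of class `dataset_config`.
#' @export
dataset_config <- function(n_images = 1000, image_size = c(384, 384),
                           seed = 1, val_fraction = 0.03,
                           scene = NULL, render_cfg = render_config(),
                           augment_cfg = augmentation_config(),
                           render = TRUE, augment_validation = FALSE) {
  stopifnot(n_images >= 1, val_fraction >= 0, val_fraction < 1)
  if (is.null(scene)) scene <- scene_config(image_size = image_size)
  structure(list(n_images = n_images, image_size = image_size, seed = seed,
                 val_fraction = val_fraction, scene = scene,
                 render_cfg = render_cfg, augment_cfg = augment_cfg,
                 render = render, augment_validation = augment_validation),
            class = "dataset_config")
}

child_seed <- function(root, i) {
  (as.double(root %% 1e6) * 1000003 + i * 7919) %% 2147483647
}

#' Generate a synthetic crystal dataset
#'
#' End-to-end orchestration: for each image a child seed is derived from
#' the root seed, a scene is assembled ([place_crystals()]), rendered
#' ([render_scene()]) and written as 8-bit grayscale PNG; annotations
#' (oriented boxes + silhouette polygons) are written as a native JSON
#' file and a manifest records the config, seeds, split assignment and
#' counts. Identical seeds produce byte-identical outputs.
#'
#' @param config a [dataset_config()].
#' @param out_dir output directory (created if missing).
#' @return the manifest, an object of class `dataset_manifest` (also
#'   written to `manifest.json`). When `config$render` is `FALSE` the
#'   records carry the raw sampled targets and annotations but no images
#'   are written.
#' @export
generate_dataset <- function(config, out_dir) {
  if (config$render) {
    dir.create(file.path(out_dir, "images"), recursive = TRUE,
               showWarnings = FALSE)
    if (config$augment_validation)
      dir.create(file.path(out_dir, "images_aug"), showWarnings = FALSE)
  } else dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  n <- config$n_images
  n_val <- round(config$val_fraction * n)
  split <- c(rep("val", n_val), rep("train", n - n_val))
  seeds <- vapply(seq_len(n), function(i) child_seed(config$seed, i),
                  numeric(1))
  records <- vector("list", n)
  targets <- vector("list", n)
  n_instances <- 0L

  for (i in seq_len(n)) {
    set.seed(seeds[i])
    scene <- place_crystals(config$scene)
    img_id <- sprintf("img_%05d", i)
    if (config$render) {
      ann <- render_scene(scene, config$render_cfg)
      write_image(ann$image, file.path(out_dir, "images",
                                       paste0(img_id, ".png")))
      if (config$augment_validation && split[i] == "val") {
        aug <- augment(ann, config$augment_cfg)
        write_image(aug$image, file.path(out_dir, "images_aug",
                                         paste0(img_id, ".png")))
      }
    } else ann <- list(annotations = annotations_from_scene(scene)$annotations,
                       polygons = annotations_from_scene(scene)$polygons)
    records[[i]] <- list(image_id = img_id, boxes = ann$annotations,
                         polygons = ann$polygons)
    targets[[i]] <- scene$targets_drawn
    n_instances <- n_instances + nrow(ann$annotations)
  }

  write_annotations(records, file.path(out_dir, "annotations.json"))
  manifest <- structure(list(
    n_images = n, n_instances = n_instances,
    image_size = config$image_size, root_seed = config$seed,
    child_seeds = seeds, split = split,
    rendered = config$render,
    targets_drawn = do.call(rbind, targets),
    shape = unclass(config$scene$shape)
  ), class = "dataset_manifest")
  jsonlite::write_json(
    list(n_images = n, n_instances = n_instances,
         image_size = config$image_size, root_seed = config$seed,
         child_seeds = seeds, split = split, rendered = config$render,
         shape = unclass(config$scene$shape)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  manifest
}

#' Write annotation records
#'
#' Native dialect: one JSON file with, per image, the oriented boxes
#' (`cx, cy, w, h` in pixels, `theta` in degrees) and silhouette polygons.
#' DOTA dialect: one text file per image under `path` (a directory), one
#' object per line as the 8 corner coordinates of the box followed by the
#' class name and a difficulty flag.
#'
#' @param records list of per-image records (`image_id`, `boxes`
#'   data.frame with columns `id, cx, cy, w, h, theta` in radians,
#'   `polygons` list).
#' @param path output file (native) or directory (DOTA).
#' @param dialect `"native"` or `"dota"`.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(records, path,
                              dialect = c("native", "dota")) {
  dialect <- match.arg(dialect)
  if (dialect == "native") {
    out <- lapply(records, function(rec) {
      b <- rec$boxes
      list(image_id = rec$image_id,
           boxes = data.frame(id = b$id, cx = b$cx, cy = b$cy,
                              w = b$w, h = b$h,
                              theta_deg = b$theta * 180 / pi),
           polygons = lapply(rec$polygons, function(p) unname(as.matrix(p))))
    })
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    for (rec in records) {
      lines <- character(0)
      b <- rec$boxes
      for (k in seq_len(nrow(b))) {
        corners <- rect_corners(b[k, ])
        lines <- c(lines, paste(paste(sprintf("%.2f", t(corners)),
                                      collapse = " "), "crystal", "0"))
      }
      writeLines(lines, file.path(path, paste0(rec$image_id, ".txt")))
    }
  }
  invisible(path)
}

#' Read native annotation records
#'
#' @param path path to a native-dialect JSON annotation file.
#' @return list of per-image records with `theta` converted back to
#'   radians.
#' @export
read_annotations <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  n <- length(raw$image_id)
  lapply(seq_len(n), function(i) {
    b <- raw$boxes[[i]]
    boxes <- data.frame(id = b$id, cx = b$cx, cy = b$cy, w = b$w, h = b$h,
                        theta = b$theta_deg * pi / 180)
    list(image_id = raw$image_id[i], boxes = boxes,
         polygons = lapply(raw$polygons[[i]], function(p) matrix(unlist(p),
                                                                 ncol = 2)))
  })
}

#' Read detections
#'
#' Native dialect: a JSON array of flat objects
#' `{image_id, cx, cy, w, h, theta_deg, score}`. DOTA-with-score dialect: a
#' directory of per-image text files whose lines carry the 8 box corner
#' coordinates, the class name and a confidence score. Scores must lie in
#' \[0, 1\]; malformed lines are reported with their line number.
#'
#' @param path JSON file or DOTA directory.
#' @return a data.frame `image_id, cx, cy, w, h, theta, score` (`theta` in
#'   radians).
#' @export
read_detections <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.txt$", full.names = TRUE)
    rows <- list()
    for (f in files) {
      img_id <- tools::file_path_sans_ext(basename(f))
      lines <- readLines(f, warn = FALSE)
      for (ln in seq_along(lines)) {
        if (!nzchar(trimws(lines[ln]))) next
        parts <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
        if (length(parts) != 10)
          stop(sprintf("%s line %d: expected 8 coordinates, class, score",
                       basename(f), ln))
        xy <- suppressWarnings(as.numeric(parts[1:8]))
        score <- suppressWarnings(as.numeric(parts[10]))
        if (any(is.na(xy)) || is.na(score))
          stop(sprintf("%s line %d: non-numeric field", basename(f), ln))
        if (score < 0 || score > 1)
          stop(sprintf("%s line %d: score %g outside [0, 1]",
                       basename(f), ln, score))
        rect <- min_area_rect(matrix(xy, ncol = 2, byrow = TRUE))
        rows[[length(rows) + 1]] <-
          data.frame(image_id = img_id, cx = rect$cx, cy = rect$cy,
                     w = rect$w, h = rect$h, theta = rect$theta,
                     score = score)
      }
    }
    if (!length(rows))
      return(data.frame(image_id = character(0), cx = numeric(0),
                        cy = numeric(0), w = numeric(0), h = numeric(0),
                        theta = numeric(0), score = numeric(0)))
    do.call(rbind, rows)
  } else {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = TRUE)
    if (length(raw) == 0 || (is.data.frame(raw) && nrow(raw) == 0))
      return(data.frame(image_id = character(0), cx = numeric(0),
                        cy = numeric(0), w = numeric(0), h = numeric(0),
                        theta = numeric(0), score = numeric(0)))
    if (any(raw$score < 0 | raw$score > 1))
      stop("detection score outside [0, 1]")
    data.frame(image_id = raw$image_id, cx = raw$cx, cy = raw$cy,
               w = raw$w, h = raw$h, theta = raw$theta_deg * pi / 180,
               score = raw$score)
  }
}

#' Write detections in the native JSON dialect
#'
#' @param dets data.frame `image_id, cx, cy, w, h, theta, score` (`theta`
#'   radians).
#' @param path output JSON path.
#' @return `path` invisibly.
#' @export
write_detections <- function(dets, path) {
  out <- data.frame(image_id = dets$image_id, cx = dets$cx, cy = dets$cy,
                    w = dets$w, h = dets$h,
                    theta_deg = dets$theta * 180 / pi, score = dets$score)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Flatten annotation records into a ground-truth table
#'
#' @param records output of [read_annotations()] or the records produced by
#'   [generate_dataset()].
#' @return a data.frame `image_id, id, cx, cy, w, h, theta`.
#' @export
annotations_table <- function(records) {
  do.call(rbind, lapply(records, function(rec) {
    if (nrow(rec$boxes) == 0) return(NULL)
    cbind(data.frame(image_id = rec$image_id), rec$boxes)
  }))
}
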