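#' Size class of an oriented box
#'
#' Classes follow the oriented-box area `a = w*h`: small for `a < 8^2`,
#' medium for `8^2 < a < 24^2`, large for `24^2 < a`. The boundary areas
#' (exactly 64 or 576 px^2, left open by the strict inequalities) are
#' assigned to the larger class.
#'
#' @param w,h box side lengths in pixels (vectorized).
#' @return character vector in `{"small", "medium", "large"}`.
#' @export
size_class <- function(w, h) {
  a <- w * h
  ifelse(a < 64, "small", ifelse(a < 576, "medium", "large"))
}

#' Match detections to ground truth in one image
#'
#' Greedy protocol: detections in descending score order, each matched to
#' the not-yet-matched ground-truth box of highest rotated IoU, provided
#' that IoU reaches the threshold; remaining detections are false
#' positives, unmatched ground-truth boxes false negatives.
#'
#' @param dets data.frame `cx, cy, w, h, theta, score` for one image.
#' @param gts data.frame `cx, cy, w, h, theta` for the same image.
#' @param iou_threshold minimum rotated IoU for a match.
#' @return list with `tp` (logical per detection, in descending score
#'   order), `scores` (the sorted scores), `matched_gt` (index or NA), and
#'   `n_gt`.
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5) {
  ord <- order(-dets$score)
  dets <- dets[ord, , drop = FALSE]
  nd <- nrow(dets); ng <- nrow(gts)
  tp <- logical(nd); matched <- rep(NA_integer_, nd)
  gt_used <- logical(ng)
  for (i in seq_len(nd)) {
    best <- 0; best_j <- 0L
    for (j in seq_len(ng)) {
      if (gt_used[j]) next
      iou <- rotated_iou(dets[i, ], gts[j, ])
      if (iou > best) { best <- iou; best_j <- j }
    }
    if (best_j > 0L && best >= iou_threshold) {
      tp[i] <- TRUE; matched[i] <- best_j; gt_used[best_j] <- TRUE
    }
  }
  list(tp = tp, scores = dets$score, matched_gt = matched, n_gt = ng)
}

# 101-point interpolated AP (x100) from pooled, score-sorted TP flags
ap_from_matches <- function(tp, scores, n_gt) {
  if (n_gt == 0) return(NA_real_)
  if (length(tp) == 0) return(0)
  ord <- order(-scores)
  tp <- tp[ord]
  cum_tp <- cumsum(tp)
  precision <- cum_tp / seq_along(tp)
  recall <- cum_tp / n_gt
  # precision envelope, evaluated on the 101-point recall grid
  prec_at <- vapply(seq(0, 1, by = 0.01), function(rc) {
    sel <- recall >= rc - 1e-12
    if (!any(sel)) 0 else max(precision[sel])
  }, numeric(1))
  mean(prec_at) * 100
}

#' Average precision over pooled images
#'
#' Pools per-image match results under a global score ordering and computes
#' the 101-point interpolated area under the precision-recall curve,
#' expressed as a percentage.
#'
#' @param match_results list of [match_detections()] results (one per
#'   image).
#' @param n_gt total ground-truth count; defaults to the sum over results.
#' @return AP percentage in \[0, 100\]; `NA` with a warning when there is
#'   no ground truth.
#' @export
average_precision <- function(match_results, n_gt = NULL) {
  if (is.null(n_gt)) n_gt <- sum(vapply(match_results, `[[`, 0, "n_gt"))
  if (n_gt == 0) {
    warning("no ground truth boxes; AP undefined")
    return(NA_real_)
  }
  tp <- unlist(lapply(match_results, `[[`, "tp"))
  sc <- unlist(lapply(match_results, `[[`, "scores"))
  ap_from_matches(tp, sc, n_gt)
}

ap_single <- function(dets, gts, iou_threshold, class = NULL) {
  if (!is.null(class)) {
    dets <- dets[size_class(dets$w, dets$h) == class, , drop = FALSE]
    gts <- gts[size_class(gts$w, gts$h) == class, , drop = FALSE]
  }
  ids <- unique(c(dets$image_id, gts$image_id))
  res <- lapply(ids, function(id) {
    match_detections(dets[dets$image_id == id, , drop = FALSE],
                     gts[gts$image_id == id, , drop = FALSE],
                     iou_threshold)
  })
  suppressWarnings(average_precision(res))
}

#' Evaluate rotated-box detections
#'
#' Computes overall AP and the small/medium/large size-class breakdown
#' (areas below 8^2, between 8^2 and 24^2, above 24^2 px^2), averaged over
#' the configured IoU thresholds (default COCO-style 0.50:0.05:0.95; pass
#' `iou_thresholds = 0.5` for the single-threshold convention). For a size
#' class, both ground truth and detections are filtered to the class by
#' their own box area; boxes outside it are ignored.
#'
#' @param dets data.frame `image_id, cx, cy, w, h, theta, score`.
#' @param gts data.frame `image_id, cx, cy, w, h, theta`.
#' @param iou_thresholds numeric vector of IoU thresholds.
#' @return an object of class `ap_report` with elements `AP`, `AP_s`,
#'   `AP_m`, `AP_l` (percentages; `NA` for classes without ground truth),
#'   the thresholds used and per-class ground-truth counts.
#' @export
evaluate_detections <- function(dets, gts,
                                iou_thresholds = seq(0.5, 0.95, by = 0.05)) {
  stopifnot(nrow(gts) > 0)
  if (nrow(dets) > 0 && !any(dets$image_id %in% gts$image_id))
    stop("detections and ground truth share no image ids")
  classes <- list(AP = NULL, AP_s = "small", AP_m = "medium", AP_l = "large")
  vals <- lapply(classes, function(cl) {
    aps <- vapply(iou_thresholds, function(th) ap_single(dets, gts, th, cl),
                  numeric(1))
    mean(aps)
  })
  gt_cls <- size_class(gts$w, gts$h)
  structure(c(vals,
              list(iou_thresholds = iou_thresholds,
                   n_gt = c(all = nrow(gts),
                            small = sum(gt_cls == "small"),
                            medium = sum(gt_cls == "medium"),
                            large = sum(gt_cls == "large")))),
            class = "ap_report")
}

#' @export
print.ap_report <- function(x, ...) {
  cat(sprintf("Rotated-box AP over IoU %s\n",
              paste(format(x$iou_thresholds), collapse = ",")))
  cat(sprintf("  AP %.2f | AP_s %.2f | AP_m %.2f | AP_l %.2f\n",
              x$AP, x$AP_s, x$AP_m, x$AP_l))
  cat("  ground truth per class:",
      paste(names(x$n_gt), x$n_gt, sep = "=", collapse = " "), "\n")
  invisible(x)
}
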