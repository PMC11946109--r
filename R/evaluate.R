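#' Match detections to ground truths at one IoU threshold
#'
#' Greedy confidence-ordered matching for one image and one class:
#' detections are visited in descending confidence (ties broken by the
#' original detection index, a stable sort); each detection is matched to
#' the unmatched ground truth with the highest IoU, provided that IoU
#' meets the threshold, with IoU ties broken by the lowest ground-truth
#' index. Each ground truth is matched at most once.
#'
#' @param det_boxes `n x 4` corner boxes of the detections.
#' @param conf length-`n` confidences.
#' @param gt_boxes `m x 4` corner boxes of the ground truths.
#' @param iou_threshold minimum IoU for a match.
#' @return list with `tp` (logical, in the original detection order),
#'   `det_gt` (matched ground-truth index or `NA`) and `gt_matched`
#'   (logical length `m`).
#' @export
match_detections <- function(det_boxes, conf, gt_boxes, iou_threshold = 0.5) {
  det_boxes <- as_box_matrix_or_empty(det_boxes)
  gt_boxes <- as_box_matrix_or_empty(gt_boxes)
  n <- nrow(det_boxes); m <- nrow(gt_boxes)
  tp <- logical(n); det_gt <- rep(NA_integer_, n); gtm <- logical(m)
  if (n == 0 || m == 0) return(list(tp = tp, det_gt = det_gt, gt_matched = gtm))
  iou <- box_iou_matrix(det_boxes, gt_boxes)
  for (i in order(-conf, seq_len(n))) {
    free <- which(!gtm)
    if (!length(free)) break
    ious <- iou[i, free]
    best <- free[order(-ious, free)][1]
    if (iou[i, best] >= iou_threshold) {
      tp[i] <- TRUE; det_gt[i] <- best; gtm[best] <- TRUE
    }
  }
  list(tp = tp, det_gt = det_gt, gt_matched = gtm)
}

as_box_matrix_or_empty <- function(b) {
  if (is.null(b) || NROW(b) == 0) return(matrix(0, 0, 4))
  as_box_matrix(b)
}

#' Average precision from pooled match flags
#'
#' All-points interpolated average precision: detections are ranked by
#' descending confidence (stable in the given order for ties), the
#' precision-recall curve is made monotone by taking the running maximum
#' of precision from the right, and the area under the resulting step
#' curve is integrated exactly.
#'
#' @param tp logical true-positive flags of all detections of one class.
#' @param conf their confidences.
#' @param n_gt number of ground-truth instances of the class.
#' @return AP in `[0, 1]`; 0 when `n_gt = 0` (a class with detections but
#'   no ground truth), and `NA` when there is nothing to score
#'   (`n_gt = 0` and no detections).
#' @export
average_precision <- function(tp, conf, n_gt) {
  if (n_gt == 0 && length(tp) == 0) return(NA_real_)
  if (n_gt == 0) return(0)
  if (length(tp) == 0) return(0)
  o <- order(-conf, seq_along(conf))
  tp <- tp[o]
  ctp <- cumsum(tp)
  prec <- ctp / seq_along(tp)
  rec <- ctp / n_gt
  # monotone precision envelope, then exact area under the step curve
  penv <- rev(cummax(rev(prec)))
  r_prev <- c(0, rec[-length(rec)])
  sum((rec - r_prev) * penv)
}

#' Evaluate detections against ground truth
#'
#' Computes per-class true/false-positive flags at the COCO threshold grid
#' (IoU 0.50 to 0.95 in steps of 0.05) and the resulting per-class average
#' precisions.
#'
#' @param detections list (one per image) of data.frames with columns
#'   `class` (0-based), `conf`, `x1`, `y1`, `x2`, `y2` (pixels).
#' @param labels list (one per image) of label data.frames with columns
#'   `class` (0-based) and normalized `cx`, `cy`, `w`, `h`.
#' @param num_classes number of classes.
#' @param image_size image side in pixels used to de-normalize labels.
#' @param thresholds IoU thresholds.
#' @return an object of class `"fishdet_eval"`: list with `ap` (a
#'   `num_classes x length(thresholds)` matrix, `NA` for unscoreable
#'   classes), `n_gt` per class, and `thresholds`.
#' @export
evaluate_detections <- function(detections, labels, num_classes,
                                image_size, thresholds = seq(0.5, 0.95, 0.05)) {
  stopifnot(length(detections) == length(labels))
  ap <- matrix(NA_real_, num_classes, length(thresholds))
  n_gt_cls <- numeric(num_classes)
  det_by_cls <- vector("list", num_classes)
  for (cl in seq_len(num_classes) - 1L) {
    tps <- vector("list", length(thresholds))
    confs <- numeric(0)
    n_gt <- 0
    for (im in seq_along(detections)) {
      d <- detections[[im]]
      d <- d[d$class == cl, , drop = FALSE]
      lab <- labels[[im]]
      lab <- lab[lab$class == cl, , drop = FALSE]
      gtb <- if (nrow(lab)) as_corner(cbind(lab$cx, lab$cy, lab$w, lab$h)) *
        image_size else matrix(0, 0, 4)
      n_gt <- n_gt + nrow(gtb)
      if (nrow(d) == 0) next
      db <- as.matrix(d[, c("x1", "y1", "x2", "y2")])
      confs <- c(confs, d$conf)
      for (ti in seq_along(thresholds)) {
        mr <- match_detections(db, d$conf, gtb, thresholds[ti])
        tps[[ti]] <- c(tps[[ti]], mr$tp)
      }
    }
    n_gt_cls[cl + 1] <- n_gt
    for (ti in seq_along(thresholds))
      ap[cl + 1, ti] <- average_precision(tps[[ti]] %||% logical(0), confs, n_gt)
  }
  structure(list(ap = ap, n_gt = n_gt_cls, thresholds = thresholds),
            class = "fishdet_eval")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize an evaluation into mAP metrics
#'
#' @param ev a [evaluate_detections()] result.
#' @param strata_counts optional per-class frequencies used for the
#'   head/middle/tail stratification; defaults to the evaluated
#'   ground-truth counts.
#' @return list with `map50`, `map5095`, `per_class` (data.frame of
#'   AP@0.5 and AP@0.5:0.95 per class) and `stratified` (mean AP@0.5
#'   within head/middle/tail class-frequency terciles).
#' @details Classes with no ground truth and no detections are excluded
#'   from every mean; classes with detections but no ground truth enter
#'   with AP 0. The stratification ranks scoreable classes by frequency
#'   (descending) and splits the ranking into three near-equal groups.
#' @export
map_summary <- function(ev, strata_counts = NULL) {
  stopifnot(inherits(ev, "fishdet_eval"))
  if (nrow(ev$ap) == 0) stop("empty class list")
  i50 <- which.min(abs(ev$thresholds - 0.5))
  ap50 <- ev$ap[, i50]
  ap_mean <- rowMeans(ev$ap)
  scoreable <- !is.na(ap50)
  per_class <- data.frame(class = seq_len(nrow(ev$ap)) - 1L,
                          n_gt = ev$n_gt, ap50 = ap50, ap5095 = ap_mean)
  counts <- strata_counts %||% ev$n_gt
  strat <- c(head = NA_real_, middle = NA_real_, tail = NA_real_)
  idx <- which(scoreable)
  if (length(idx) >= 3) {
    rk <- idx[order(-counts[idx], idx)]
    cut <- ceiling(length(rk) / 3)
    groups <- list(head = rk[seq_len(cut)],
                   middle = rk[(cut + 1):min(2 * cut, length(rk))],
                   tail = rk[(min(2 * cut, length(rk)) + 1):length(rk)])
    strat <- vapply(groups, function(g) mean(ap50[g]), 0)
  }
  list(map50 = mean(ap50[scoreable]),
       map5095 = mean(ap_mean[scoreable]),
       per_class = per_class, stratified = strat)
}
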