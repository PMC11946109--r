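#' Anchor points of the detection grid
#'
#' One prediction location per cell of each stride-8/16/32 feature map;
#' anchor centres sit at cell centres, `(j + 0.5) * stride` pixels.
#'
#' @param input_size square image side in pixels (multiple of 32).
#' @param strides feature-map strides.
#' @return list with `anchors` (`L x 2` matrix of x, y centres) and
#'   `strides` (length-`L` vector).
#' @export
make_anchors <- function(input_size, strides = c(8, 16, 32)) {
  xs <- list(); ss <- list()
  for (s in strides) {
    g <- input_size / s
    if (g != round(g)) stop("input_size must be divisible by every stride")
    cx <- ((seq_len(g) - 1) + 0.5) * s
    # row-major grid: rows (y) outer, columns (x) inner
    xs[[length(xs) + 1]] <- cbind(x = rep(cx, times = g), y = rep(cx, each = g))
    ss[[length(ss) + 1]] <- rep(s, g * g)
  }
  list(anchors = do.call(rbind, xs), strides = unlist(ss))
}

#' Encode ground-truth boxes as side offsets
#'
#' For a location inside a ground-truth box, the regression target is the
#' quadruple of distances from the anchor centre to the box's left, top,
#' right and bottom edges, in units of the location's stride, clamped to
#' `[0, reg_max - 0.01]` so the distribution-focal target always has a
#' right-bracketing bin.
#'
#' @param gt corner-form ground-truth boxes (pixels), one row per location.
#' @param anchors `n x 2` anchor centres (pixels).
#' @param strides stride per location.
#' @param reg_max upper bin index.
#' @return `n x 4` matrix of offsets (left, top, right, bottom).
#' @export
encode_box_targets <- function(gt, anchors, strides, reg_max = 16) {
  gt <- as_box_matrix(gt)
  if (is.null(dim(anchors))) anchors <- matrix(anchors, ncol = 2)
  off <- cbind(anchors[, 1] - gt[, 1], anchors[, 2] - gt[, 2],
               gt[, 3] - anchors[, 1], gt[, 4] - anchors[, 2]) / strides
  if (any(off < -1e-9)) stop("anchor centre lies outside its ground-truth box")
  pmin(pmax(off, 0), reg_max - 0.01)
}

#' Decode side offsets back to a corner box
#'
#' Inverse of [encode_box_targets()] (up to clamping).
#'
#' @param off `n x 4` offsets (left, top, right, bottom) in stride units.
#' @inheritParams encode_box_targets
#' @return `n x 4` corner boxes in pixels.
#' @export
decode_box_offsets <- function(off, anchors, strides) {
  if (is.null(dim(off))) off <- matrix(off, ncol = 4)
  if (is.null(dim(anchors))) anchors <- matrix(anchors, ncol = 2)
  cbind(anchors[, 1] - off[, 1] * strides, anchors[, 2] - off[, 2] * strides,
        anchors[, 1] + off[, 3] * strides, anchors[, 2] + off[, 4] * strides)
}

#' Task-aligned target assignment
#'
#' Matches prediction locations to ground-truth instances by the
#' task-aligned metric `m = s^alpha * IoU^beta`, where `s` is the predicted
#' score of the ground truth's class and IoU is between the decoded
#' predicted box and the ground truth. For each ground truth, the `topk`
#' candidate locations (among those whose anchor centre lies inside the
#' box) with the largest metric are selected; a location claimed by several
#' ground truths goes to the one with the highest IoU, ties broken by the
#' lowest ground-truth index, and candidate ties within a ground truth by
#' highest IoU then lowest location index — all deterministic.
#'
#' Soft classification targets follow the usual alignment normalization:
#' an assigned location's target at its class is
#' `m / max_g(m) * max_g(IoU)` for its ground truth `g`.
#'
#' @param pred_scores `L x C` matrix of predicted class probabilities.
#' @param pred_boxes `L x 4` decoded corner boxes (pixels).
#' @param gt_boxes `G x 4` corner boxes (pixels); `G = 0` is valid.
#' @param gt_class length-`G` 1-based class indices.
#' @param anchors,strides from [make_anchors()].
#' @param topk candidates kept per ground truth.
#' @param alpha,beta exponents of the alignment metric.
#' @return list with `fg` (logical length `L`), `gt_index`, `gt_class`
#'   (`NA` on background), `gt_box` (`L x 4`), `score` (alignment target,
#'   0 on background) and `cls_targets` (`L x C`).
#' @export
assign_targets <- function(pred_scores, pred_boxes, gt_boxes, gt_class,
                           anchors, strides, topk = 10,
                           alpha = 0.5, beta = 6) {
  L <- nrow(pred_scores); C <- ncol(pred_scores)
  empty <- list(fg = rep(FALSE, L), gt_index = rep(NA_integer_, L),
                gt_class = rep(NA_integer_, L),
                gt_box = matrix(0, L, 4), score = numeric(L),
                cls_targets = matrix(0, L, C))
  if (is.null(gt_boxes) || NROW(gt_boxes) == 0) return(empty)
  gt_boxes <- as_box_matrix(gt_boxes)
  G <- nrow(gt_boxes)

  inside <- outer(anchors[, 1], gt_boxes[, 1], ">") &
            outer(anchors[, 1], gt_boxes[, 3], "<") &
            outer(anchors[, 2], gt_boxes[, 2], ">") &
            outer(anchors[, 2], gt_boxes[, 4], "<")
  iou <- box_iou_matrix(pred_boxes, gt_boxes)
  sc <- pmax(pred_scores[, gt_class, drop = FALSE], 1e-9)
  metric <- sc^alpha * iou^beta
  metric[!inside] <- 0

  cand <- matrix(FALSE, L, G)
  for (g in seq_len(G)) {
    ok <- which(inside[, g])
    if (length(ok) == 0) next
    ord <- ok[order(-metric[ok, g], -iou[ok, g], ok)]
    cand[utils::head(ord, topk), g] <- TRUE
  }

  assigned_gt <- rep(NA_integer_, L)
  for (l in which(rowSums(cand) > 0)) {
    gs <- which(cand[l, ])
    assigned_gt[l] <- gs[order(-iou[l, gs], gs)][1]
  }

  fg <- !is.na(assigned_gt)
  out <- empty
  out$fg <- fg
  out$gt_index <- assigned_gt
  out$gt_class[fg] <- gt_class[assigned_gt[fg]]
  out$gt_box[fg, ] <- gt_boxes[assigned_gt[fg], , drop = FALSE]

  # alignment-normalized soft targets
  for (g in seq_len(G)) {
    idx <- which(fg & assigned_gt == g)
    if (length(idx) == 0) next
    mmax <- max(metric[idx, g])
    imax <- max(iou[idx, g])
    t <- if (mmax > 0) metric[idx, g] / mmax * imax else rep(0, length(idx))
    out$score[idx] <- t
    out$cls_targets[cbind(idx, gt_class[g])] <- t
  }
  out
}
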