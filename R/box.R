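#' Axis-aligned bounding boxes
#'
#' Boxes are plain numeric matrices with one box per row. Two representations
#' are used throughout the package:
#'
#' * `"center"`: `(cx, cy, w, h)` — centre coordinates plus width and height,
#'   either normalized to `[0, 1]` (label files) or in pixels.
#' * `"corner"`: `(x1, y1, x2, y2)` — top-left and bottom-right corners with
#'   `x1 <= x2`, `y1 <= y2`. All geometry (IoU, losses, matching) runs on
#'   corner form.
#'
#' Pixel boxes follow the 0-based, half-open convention: a box spanning
#' `x1 = 0, x2 = 4` covers pixel columns 0..3 and has width 4.
#'
#' @param boxes numeric vector of length 4 or matrix with 4 columns.
#' @return a numeric matrix with 4 columns in the requested representation.
#' @examples
#' as_corner(c(0.5, 0.5, 1, 1))   # unit square centred at (0.5, 0.5)
#' as_center(rbind(c(0, 0, 2, 2)))
#' @name boxes
NULL

as_box_matrix <- function(boxes) {
  if (is.null(dim(boxes))) boxes <- matrix(boxes, ncol = 4, byrow = TRUE)
  if (ncol(boxes) != 4) stop("boxes must have 4 columns")
  storage.mode(boxes) <- "double"
  boxes
}

#' @rdname boxes
#' @export
as_corner <- function(boxes) {
  b <- as_box_matrix(boxes)
  if (any(b[, 3] < 0) || any(b[, 4] < 0)) stop("box width/height must be >= 0")
  cbind(b[, 1] - b[, 3] / 2, b[, 2] - b[, 4] / 2,
        b[, 1] + b[, 3] / 2, b[, 2] + b[, 4] / 2)
}

#' @rdname boxes
#' @export
as_center <- function(boxes) {
  b <- as_box_matrix(boxes)
  if (any(b[, 3] < b[, 1]) || any(b[, 4] < b[, 2]))
    stop("corner boxes must satisfy x1 <= x2 and y1 <= y2")
  cbind((b[, 1] + b[, 3]) / 2, (b[, 2] + b[, 4]) / 2,
        b[, 3] - b[, 1], b[, 4] - b[, 2])
}

box_area <- function(b) {
  pmax(b[, 3] - b[, 1], 0) * pmax(b[, 4] - b[, 2], 0)
}

# Elementwise intersection/union terms for row-aligned corner boxes.
iou_terms <- function(a, b) {
  iw <- pmax(pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1]), 0)
  ih <- pmax(pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2]), 0)
  inter <- iw * ih
  union <- box_area(a) + box_area(b) - inter
  list(inter = inter, union = union, iw = iw, ih = ih)
}

#' Intersection over union of bounding boxes
#'
#' `box_iou()` computes the elementwise IoU of two row-aligned sets of boxes
#' (rows are recycled if one input has a single box). `box_iou_matrix()`
#' computes the full pairwise IoU matrix, as needed by target assignment and
#' detection matching.
#'
#' @param a,b corner-form boxes (`(x1, y1, x2, y2)` rows); a length-4 vector
#'   is treated as one box.
#' @param rep representation of the inputs, `"corner"` (default) or
#'   `"center"`; center-form inputs are converted.
#' @return `box_iou()`: numeric vector of IoU values in `[0, 1]`.
#'   `box_iou_matrix()`: a `nrow(a) x nrow(b)` matrix.
#' @details A pair in which *both* boxes are degenerate (zero area) has an
#'   empty union; such pairs are rejected with an error rather than given an
#'   arbitrary value.
#' @examples
#' box_iou(c(0, 0, 2, 2), c(1, 1, 3, 3))  # 1/7
#' @export
box_iou <- function(a, b, rep = c("corner", "center")) {
  rep <- match.arg(rep)
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  if (rep == "center") { a <- as_corner(a); b <- as_corner(b) }
  if (nrow(a) == 1 && nrow(b) > 1) a <- a[rep(1, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1 && nrow(a) > 1) b <- b[rep(1, nrow(a)), , drop = FALSE]
  if (nrow(a) != nrow(b)) stop("a and b must have the same number of boxes")
  t <- iou_terms(a, b)
  if (any(t$union <= 0))
    stop("degenerate box pair: both boxes have zero area")
  t$inter / t$union
}

#' @rdname box_iou
#' @export
box_iou_matrix <- function(a, b, rep = c("corner", "center")) {
  rep <- match.arg(rep)
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  if (rep == "center") { a <- as_corner(a); b <- as_corner(b) }
  n <- nrow(a); m <- nrow(b)
  if (n == 0 || m == 0) return(matrix(0, n, m))
  iw <- pmax(outer(a[, 3], b[, 3], pmin) - outer(a[, 1], b[, 1], pmax), 0)
  ih <- pmax(outer(a[, 4], b[, 4], pmin) - outer(a[, 2], b[, 2], pmax), 0)
  inter <- iw * ih
  union <- outer(box_area(a), box_area(b), "+") - inter
  out <- inter / union
  out[union <= 0] <- 0
  out
}
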