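# Independent oracles used across the suite.

# Brute-force IoU by rasterization. Axis-aligned rectangles factorize over
# the two axes, so each axis is rasterized independently on a fine 1-D grid
# of cell centres; areas are products of counted cell lengths. Deliberately
# naive counting, no geometry formulas.
raster_iou <- function(a, b, n = 40000) {
  axis_lengths <- function(lo, hi, i1, i2) {
    xs <- seq(lo, hi, length.out = n + 1)[-1] - (hi - lo) / (2 * n)
    cw <- (hi - lo) / n
    in1 <- xs > i1[1] & xs < i1[2]
    in2 <- xs > i2[1] & xs < i2[2]
    c(sum(in1), sum(in2), sum(in1 & in2)) * cw
  }
  lx <- axis_lengths(min(a[1], b[1]), max(a[3], b[3]),
                     c(a[1], a[3]), c(b[1], b[3]))
  ly <- axis_lengths(min(a[2], b[2]), max(a[4], b[4]),
                     c(a[2], a[4]), c(b[2], b[4]))
  A <- lx[1] * ly[1]; B <- lx[2] * ly[2]; I <- lx[3] * ly[3]
  U <- A + B - I
  if (U <= 0) stop("degenerate raster pair")
  I / U
}

# All-points average precision by explicit threshold sweep: for every
# confidence cut, compute precision/recall, then integrate the monotone
# envelope by scanning recall levels. Independent of the package's
# cumulative-sum implementation.
ap_reference <- function(tp, conf, n_gt) {
  if (n_gt == 0) return(if (length(tp)) 0 else NA_real_)
  if (length(tp) == 0) return(0)
  o <- order(-conf, seq_along(conf))
  tp <- tp[o]
  n <- length(tp)
  prec <- numeric(n); rec <- numeric(n)
  for (k in seq_len(n)) {          # recompute from scratch at each cut
    prec[k] <- sum(tp[seq_len(k)]) / k
    rec[k] <- sum(tp[seq_len(k)]) / n_gt
  }
  area <- 0
  r_prev <- 0
  for (k in seq_len(n)) {
    p_max <- max(prec[k:n])        # best precision at recall >= rec[k]
    area <- area + (rec[k] - r_prev) * p_max
    r_prev <- rec[k]
  }
  area
}

random_box <- function(lim = 4) {
  x <- sort(runif(2, 0, lim)); y <- sort(runif(2, 0, lim))
  if (x[2] - x[1] < 0.3) x[2] <- x[1] + 0.3
  if (y[2] - y[1] < 0.3) y[2] <- y[1] + 0.3
  c(x[1], y[1], x[2], y[2])
}

tiny_dataset <- function(num_classes = 3, num_images = 6, seed = 11, ...) {
  synthetic_dataset(num_classes = num_classes, num_images = num_images,
                    instances_per_image = c(1, 3), gamma = 1,
                    image_size = 64, seed = seed, ...)
}

# Synthetic raw predictions over the 64 px anchor grid, for loss tests that
# need no network.
fake_predictions <- function(num_classes = 4, seed = 3, input_size = 64,
                             reg_max = 16) {
  set.seed(seed)
  an <- make_anchors(input_size)
  L <- nrow(an$anchors)
  bins <- reg_max + 1L
  cls <- matrix(rnorm(L * num_classes, -2), L, num_classes)
  dfl <- matrix(rnorm(L * 4 * bins, 0, 0.5), L, 4 * bins)
  d <- matrix(0, L, 4)
  probs <- vector("list", 4)
  for (s in 1:4) {
    z <- dfl[, (s - 1) * bins + seq_len(bins), drop = FALSE]
    p <- exp(z - apply(z, 1, max))
    p <- p / rowSums(p)
    probs[[s]] <- p
    d[, s] <- p %*% (0:reg_max)
  }
  list(cls_logits = cls, dfl_logits_flat = dfl,
       dfl_logits = aperm(array(dfl, c(L, bins, 4)), c(1, 3, 2)),
       probs = probs, offsets = d,
       boxes = decode_box_offsets(d, an$anchors, an$strides),
       anchors = an$anchors, strides = an$strides)
}
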