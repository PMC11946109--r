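#' Loss configuration
#'
#' Bundles every tunable of the detection objective. The defaults are the
#' settings found optimal for long-tailed fish-species training: gains
#' `alpha1 = 0.5` (classification), `alpha2 = 1.5` (distribution-focal),
#' `alpha3 = 7.5` (box regression), class-aware exponent `eta = 8`, and
#' Wise-IoU hyper-parameters `beta = 1.8`, `tau = 3` with a dynamic
#' outlier degree.
#'
#' The two flags reproduce the ablation grid: `use_class_aware` switches the
#' class-frequency reweighting of all three terms, `use_wiou_v3` selects the
#' Wise-IoU v3 box loss (otherwise the complete-IoU baseline is used).
#'
#' @param alpha1,alpha2,alpha3 positive gains on the classification,
#'   distribution-focal and box terms.
#' @param eta class-aware exponent, `>= 1`; `eta = 1` is the neutral
#'   setting where every class weight is exactly 1.
#' @param use_class_aware apply class-aware weights to all three terms.
#' @param use_wiou_v3 use Wise-IoU v3 for box regression; `FALSE` selects
#'   complete IoU (CIoU).
#' @param reg_max number of distribution bins per box side minus one
#'   (offsets live in `[0, reg_max]` stride units).
#' @param beta,tau Wise-IoU focusing hyper-parameters (`beta > 0`,
#'   `tau != 0`).
#' @param momentum exponential running-mean momentum for the IoU-loss mean
#'   driving the dynamic outlier degree, in `(0, 1)`.
#' @param theta_mode `"dynamic"` (outlier degree = detached IoU loss over
#'   its running mean) or `"fixed"`.
#' @param theta_fixed the constant outlier degree used in `"fixed"` mode.
#' @param wiou_normalizer `"enclosing"` (default): the centre-distance
#'   penalty is normalized by the squared diagonal of the smallest box
#'   enclosing prediction and target; `"pred"`: by the predicted box's own
#'   squared diagonal.
#' @return an object of class `"loss_config"`.
#' @export
loss_config <- function(alpha1 = 0.5, alpha2 = 1.5, alpha3 = 7.5,
                        eta = 8, use_class_aware = TRUE, use_wiou_v3 = TRUE,
                        reg_max = 16, beta = 1.8, tau = 3,
                        momentum = 0.99,
                        theta_mode = c("dynamic", "fixed"), theta_fixed = 2,
                        wiou_normalizer = c("enclosing", "pred")) {
  theta_mode <- match.arg(theta_mode)
  wiou_normalizer <- match.arg(wiou_normalizer)
  if (alpha1 <= 0 || alpha2 <= 0 || alpha3 <= 0)
    stop("alpha1, alpha2, alpha3 must be positive")
  if (eta < 1) stop("eta must be >= 1")
  if (beta <= 0) stop("beta must be positive")
  if (tau == 0) stop("tau must be nonzero")
  if (momentum <= 0 || momentum >= 1) stop("momentum must be in (0, 1)")
  if (reg_max < 1 || reg_max != round(reg_max)) stop("reg_max must be a positive integer")
  structure(list(alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
                 eta = eta, use_class_aware = use_class_aware,
                 use_wiou_v3 = use_wiou_v3, reg_max = as.integer(reg_max),
                 beta = beta, tau = tau, momentum = momentum,
                 theta_mode = theta_mode, theta_fixed = theta_fixed,
                 wiou_normalizer = wiou_normalizer),
            class = "loss_config")
}

#' @export
print.loss_config <- function(x, ...) {
  cat("Detection loss configuration\n")
  cat(sprintf("  gains: alpha1 = %g (cls), alpha2 = %g (dfl), alpha3 = %g (box)\n",
              x$alpha1, x$alpha2, x$alpha3))
  cat(sprintf("  box loss: %s (beta = %g, tau = %g, theta %s)\n",
              if (x$use_wiou_v3) "Wise-IoU v3" else "CIoU",
              x$beta, x$tau, x$theta_mode))
  cat(sprintf("  class-aware: %s (eta = %g)\n",
              if (x$use_class_aware) "on" else "off", x$eta))
  invisible(x)
}

#' Per-class instance counts of a training split
#'
#' A `class_distribution` holds the per-class instance counts `ns` of a
#' training split and their total `n`; it is the sole input of the
#' class-aware weights. Counts are over annotated instances, not images.
#'
#' @param counts nonnegative integer vector, one entry per class.
#' @return an object of class `"class_distribution"` with fields `counts`
#'   and `n = sum(counts)`.
#' @seealso [class_aware_weight()], [class_weight_table()]
#' @export
class_distribution <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 1) stop("need at least one class")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  n <- sum(counts)
  if (n < 1) stop("total instance count must be >= 1")
  structure(list(counts = counts, n = n), class = "class_distribution")
}

#' Class-aware loss weight
#'
#' The weight assigned to a class with `ns` of the `n` training instances is
#' \deqn{w = \frac{1 - n_s/n}{1 - (n_s/n)^\eta},}
#' which equals 1 for every class when `eta = 1`, tends to 1 as
#' `ns/n -> 0`, and decreases towards the limit `1/eta` as `ns/n -> 1`.
#' For `eta > 1` the weight is strictly decreasing in `ns/n`, so rare
#' (tail) species receive larger weights than common (head) species and
#' their loss contributions are amplified relative to the head classes.
#'
#' A single-class dataset (`num_classes = 1`) necessarily has `ns = n`; the
#' weight is defined as 1 there. With more than one class, `ns = n` would
#' mean every other class is empty and is rejected.
#'
#' @param ns instance count(s) of the class(es); vectorized.
#' @param n total instance count, `>= 1`.
#' @param eta exponent `>= 1`.
#' @param num_classes number of classes in the dataset (used only for the
#'   single-class rule); defaults to `length(ns)` when `ns` has length > 1.
#' @return weights in `(1/eta, 1]` (exactly 1 when `eta = 1`).
#' @examples
#' class_aware_weight(500, 1000, eta = 8)  # 0.5 / (1 - 0.5^8)
#' @export
class_aware_weight <- function(ns, n, eta, num_classes = NULL) {
  if (is.null(num_classes)) num_classes <- max(length(ns), 2L)
  if (eta < 1) stop("eta must be >= 1")
  if (n < 1) stop("n must be >= 1")
  if (any(ns < 0)) stop("ns must be nonnegative")
  if (any(ns > n)) stop("ns cannot exceed n")
  if (num_classes > 1 && any(ns == n))
    stop("ns = n with more than one class violates the count invariant")
  r <- ns / n
  if (eta == 1) return(rep(1, length(r)))
  w <- numeric(length(r))
  hi <- 1 - r < 1e-9          # numerically at the single-class limit
  w[hi] <- 1 / eta
  lo <- r < 1e-12
  w[lo] <- 1
  mid <- !hi & !lo
  w[mid] <- (1 - r[mid]) / (1 - r[mid]^eta)
  if (num_classes == 1) w[] <- 1
  w
}

#' Class-aware weight table for a dataset
#'
#' @param dist a [class_distribution()].
#' @param eta class-aware exponent.
#' @param class_names optional character vector of class names.
#' @return a data.frame with columns `class`, `ns`, `frac` (= ns/n) and
#'   `weight`, one row per class.
#' @export
class_weight_table <- function(dist, eta = 8, class_names = NULL) {
  stopifnot(inherits(dist, "class_distribution"))
  C <- length(dist$counts)
  if (is.null(class_names)) class_names <- sprintf("class_%03d", seq_len(C) - 1)
  w <- class_aware_weight(dist$counts, dist$n, eta, num_classes = C)
  data.frame(class = class_names, ns = dist$counts,
             frac = dist$counts / dist$n, weight = w,
             stringsAsFactors = FALSE)
}

#' Wise-IoU running state
#'
#' Training-time state of the Wise-IoU v3 loss: the exponential running mean
#' of the detached IoU loss (`1 - IoU`) over training, which anchors the
#' dynamic outlier degree. The mean starts at `init_mean` and is updated
#' once per batch via [update_wiou_state()]:
#' `mean <- momentum * mean + (1 - momentum) * mean(batch iou losses)`.
#'
#' @param beta,tau,momentum,theta_mode,theta_fixed see [loss_config()].
#' @param init_mean positive initial running mean (default 1, the value of
#'   the IoU loss for a just-missed box).
#' @return an object of class `"wiou_state"`.
#' @export
wiou_state <- function(beta = 1.8, tau = 3, momentum = 0.99,
                       theta_mode = c("dynamic", "fixed"), theta_fixed = 2,
                       init_mean = 1) {
  theta_mode <- match.arg(theta_mode)
  if (beta <= 0) stop("beta must be positive")
  if (tau == 0) stop("tau must be nonzero")
  if (init_mean <= 0) stop("init_mean must be positive")
  if (momentum <= 0 || momentum >= 1) stop("momentum must be in (0, 1)")
  structure(list(mean = init_mean, momentum = momentum, beta = beta,
                 tau = tau, theta_mode = theta_mode,
                 theta_fixed = theta_fixed),
            class = "wiou_state")
}

#' @rdname wiou_state
#' @param state a `"wiou_state"`.
#' @param iou_losses detached IoU-loss values of the batch.
#' @export
update_wiou_state <- function(state, iou_losses) {
  stopifnot(inherits(state, "wiou_state"))
  if (length(iou_losses) == 0) return(state)
  state$mean <- state$momentum * state$mean +
    (1 - state$momentum) * mean(iou_losses)
  state
}

wiou_state_from_config <- function(cfg) {
  wiou_state(beta = cfg$beta, tau = cfg$tau, momentum = cfg$momentum,
             theta_mode = cfg$theta_mode, theta_fixed = cfg$theta_fixed)
}

#' Outlier degree of a prediction box
#'
#' The outlier (abnormality) degree `theta` of a prediction is its detached
#' IoU loss divided by the running mean of IoU losses over training: boxes
#' much worse than the current average are outliers (`theta >> 1`), boxes at
#' the average have `theta = 1`. In `"fixed"` mode the configured constant
#' is returned regardless of the inputs, which reproduces a reported static
#' setting such as `theta = 2` exactly.
#'
#' @param iou_loss detached IoU-loss value(s) (`1 - IoU`), `>= 0`.
#' @param state a [wiou_state()].
#' @return nonnegative outlier degree(s).
#' @export
outlier_degree <- function(iou_loss, state) {
  stopifnot(inherits(state, "wiou_state"))
  if (any(iou_loss < 0)) stop("iou_loss must be nonnegative")
  if (state$theta_mode == "fixed") return(rep(state$theta_fixed, length(iou_loss)))
  if (state$mean <= 0) stop("running IoU-loss mean must be positive")
  iou_loss / state$mean
}

#' Non-monotonic gradient gain of Wise-IoU v3
#'
#' \deqn{\kappa = \frac{\theta}{\tau\,\beta^{\theta-\tau}}.}
#' The gain rises with `theta` up to an interior maximum at
#' `theta = 1/log(beta)` and falls beyond it, so both very easy
#' (`theta ~ 0`) and very hard outlier boxes (`theta` large) receive small
#' gradient gains, focusing training on ordinary-quality anchors. At
#' `theta = tau` the power term vanishes and `kappa = theta / tau = 1`.
#'
#' @param theta outlier degree(s), `>= 0`.
#' @param beta focusing base, `> 0`.
#' @param tau focusing scale, nonzero.
#' @return nonnegative gain(s).
#' @examples
#' gradient_gain(2, beta = 1.8, tau = 3)  # 2 * 1.8 / 3 = 1.2
#' @export
gradient_gain <- function(theta, beta = 1.8, tau = 3) {
  if (inherits(beta, "wiou_state")) { tau <- beta$tau; beta <- beta$beta }
  if (beta <= 0) stop("beta must be positive")
  if (tau == 0) stop("tau must be nonzero")
  theta / (tau * beta^(theta - tau))
}

# Elementwise geometric pieces shared by the box losses. All boxes corner
# form, rows aligned.
box_loss_terms <- function(pred, gt) {
  pred <- as_box_matrix(pred); gt <- as_box_matrix(gt)
  if (nrow(pred) == 1 && nrow(gt) > 1) pred <- pred[rep(1, nrow(gt)), , drop = FALSE]
  if (nrow(gt) == 1 && nrow(pred) > 1) gt <- gt[rep(1, nrow(pred)), , drop = FALSE]
  t <- iou_terms(pred, gt)
  if (any(t$union <= 0)) stop("degenerate box pair: both boxes have zero area")
  cw <- pmax(pred[, 3], gt[, 3]) - pmin(pred[, 1], gt[, 1])  # enclosing box
  ch <- pmax(pred[, 4], gt[, 4]) - pmin(pred[, 2], gt[, 2])
  pc <- cbind((pred[, 1] + pred[, 3]) / 2, (pred[, 2] + pred[, 4]) / 2)
  gc <- cbind((gt[, 1] + gt[, 3]) / 2, (gt[, 2] + gt[, 4]) / 2)
  list(pred = pred, gt = gt, iou = t$inter / t$union,
       d2 = (pc[, 1] - gc[, 1])^2 + (pc[, 2] - gc[, 2])^2,
       cw = cw, ch = ch,
       pw = pred[, 3] - pred[, 1], ph = pred[, 4] - pred[, 2],
       gw = gt[, 3] - gt[, 1], gh = gt[, 4] - gt[, 2])
}

#' Wise-IoU v1 box-regression loss
#'
#' \deqn{L_{WIoUv1} = (1 - IoU)\,
#'   \exp\!\left(\frac{(x_p - x_g)^2 + (y_p - y_g)^2}{(W^2 + H^2)^{*}}\right)}
#' where `(x, y)` are box centres and `(W, H)` are, by default, the width
#' and height of the smallest box enclosing prediction and target (option
#' `"pred"` uses the predicted box's own dimensions). The starred
#' normalizer is *detached*: it is treated as a constant during gradient
#' computation so the exponential distance penalty rescales, but does not
#' redirect, the gradient.
#'
#' @param pred,gt corner-form boxes, rows aligned (a single box recycles).
#' @param normalizer `"enclosing"` or `"pred"`.
#' @return nonnegative loss value(s); 0 exactly when the boxes coincide.
#' @export
wiou_v1 <- function(pred, gt, normalizer = c("enclosing", "pred")) {
  normalizer <- match.arg(normalizer)
  g <- box_loss_terms(pred, gt)
  denom <- if (normalizer == "enclosing") g$cw^2 + g$ch^2 else g$pw^2 + g$ph^2
  if (any(denom <= 0)) stop("degenerate normalizer: zero-diagonal reference box")
  (1 - g$iou) * exp(g$d2 / denom)
}

#' Wise-IoU v3 box-regression loss
#'
#' Wise-IoU v3 multiplies the v1 loss by the non-monotonic gradient gain
#' `kappa` evaluated at the box's outlier degree `theta`:
#' `L_v3 = kappa(theta) * L_v1`. `theta` is computed from the *detached* IoU
#' loss (`1 - IoU`) and the running mean held in `state`; the detached IoU
#' losses are returned so the caller can update the running mean once per
#' batch with [update_wiou_state()].
#'
#' @inheritParams wiou_v1
#' @param state a [wiou_state()].
#' @return a list with components `loss`, `iou_loss` (detached `1 - IoU`),
#'   `theta` and `gain`.
#' @export
wiou_v3 <- function(pred, gt, state, normalizer = c("enclosing", "pred")) {
  stopifnot(inherits(state, "wiou_state"))
  v1 <- wiou_v1(pred, gt, normalizer)
  g <- box_loss_terms(pred, gt)
  iou_loss <- 1 - g$iou
  theta <- outlier_degree(iou_loss, state)
  gain <- gradient_gain(theta, state$beta, state$tau)
  list(loss = gain * v1, iou_loss = iou_loss, theta = theta, gain = gain)
}

#' Complete-IoU (CIoU) box-regression loss
#'
#' The baseline box loss: `1 - IoU + d^2/c^2 + alpha * v`, adding to the IoU
#' term a centre-distance penalty normalized by the squared enclosing-box
#' diagonal and an aspect-ratio consistency term
#' `v = 4/pi^2 (atan(wg/hg) - atan(wp/hp))^2` with trade-off
#' `alpha = v / ((1 - IoU) + v)` (treated as constant in gradients).
#'
#' @inheritParams wiou_v1
#' @return nonnegative loss value(s).
#' @export
ciou_loss <- function(pred, gt) {
  g <- box_loss_terms(pred, gt)
  c2 <- g$cw^2 + g$ch^2
  v <- (4 / pi^2) * (atan(g$gw / pmax(g$gh, 1e-9)) - atan(g$pw / pmax(g$ph, 1e-9)))^2
  alpha <- v / ((1 - g$iou) + v + 1e-9)
  1 - g$iou + g$d2 / pmax(c2, 1e-9) + alpha * v
}

#' Binary cross-entropy classification loss
#'
#' Elementwise binary cross-entropy between per-anchor per-class scores and
#' soft targets in `[0, 1]`. Scores may be probabilities (default) or raw
#' logits (`from_logits = TRUE`, numerically stable form); probabilities are
#' clamped away from 0/1 before taking logs.
#'
#' @param scores numeric vector/matrix of scores.
#' @param targets same shape as `scores`, values in `[0, 1]`.
#' @param from_logits are `scores` raw logits?
#' @param reduction `"mean"`, `"sum"` or `"none"`.
#' @param eps probability clamp.
#' @return scalar loss, or the elementwise matrix for `reduction = "none"`.
#' @export
bce_loss <- function(scores, targets, from_logits = FALSE,
                     reduction = c("mean", "sum", "none"), eps = 1e-12) {
  reduction <- match.arg(reduction)
  if (length(scores) != length(targets)) stop("scores/targets shape mismatch")
  if (any(targets < 0 | targets > 1)) stop("targets must be in [0, 1]")
  if (from_logits) {
    z <- scores
    l <- pmax(z, 0) - z * targets + log1p(exp(-abs(z)))
  } else {
    p <- pmin(pmax(scores, eps), 1 - eps)
    l <- -(targets * log(p) + (1 - targets) * log(1 - p))
  }
  switch(reduction, mean = mean(l), sum = sum(l), none = l)
}

#' Distribution focal loss
#'
#' Each box side is predicted as a discrete distribution over
#' `reg_max + 1` integer bins; a continuous target offset `y` in
#' `[0, reg_max]` is regressed by cross-entropy on the two bracketing bins,
#' weighted by proximity:
#' \deqn{L_{DF} = -\,(y_{hi} - y)\log p_{y_{lo}} - (y - y_{lo})\log p_{y_{hi}}.}
#'
#' @param logits numeric matrix, one row per target, `reg_max + 1` columns
#'   of unnormalized bin scores (a vector is treated as one row).
#' @param target numeric vector of offsets in `[0, reg_max]`.
#' @param reduction `"mean"`, `"sum"` or `"none"`.
#' @return scalar loss or per-target vector.
#' @export
dfl_loss <- function(logits, target, reduction = c("mean", "sum", "none")) {
  reduction <- match.arg(reduction)
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1)
  reg_max <- ncol(logits) - 1L
  if (length(target) != nrow(logits)) stop("one target per logit row required")
  if (any(!is.finite(logits))) stop("logits must be finite")
  if (any(target < 0 | target > reg_max))
    stop("target offsets must lie in [0, reg_max]")
  p <- softmax_rows(logits)
  lo <- pmin(floor(target), reg_max - 1L)
  hi <- lo + 1
  wl <- hi - target
  wr <- target - lo
  i <- seq_along(target)
  l <- -(wl * log(pmax(p[cbind(i, lo + 1)], 1e-12)) +
         wr * log(pmax(p[cbind(i, hi + 1)], 1e-12)))
  switch(reduction, mean = mean(l), sum = sum(l), none = l)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Composite detection objective
#'
#' Assembles the total training loss from already-assigned predictions:
#' \deqn{L = \alpha_1 L_{cls} + \alpha_2 L_{DF} + \alpha_3 L_{box}}
#' where the box term is Wise-IoU v3 (or CIoU when `use_wiou_v3` is off) and
#' each term is optionally reweighted class-awarely. Weights are applied at
#' the granularity of the assigned target's ground-truth class: the
#' classification matrix has each class column of its foreground rows scaled
#' by that class's weight (background rows are unweighted), and each
#' foreground anchor's box and distribution-focal contributions are scaled
#' by its target class's weight.
#'
#' Terms are normalized by the total assigned target-score mass
#' `max(sum(score), 1)`, the standard normalization for this detector
#' family; box and distribution-focal contributions are additionally
#' weighted per anchor by the assignment score.
#'
#' @param pred list with elements `cls_logits` (`L x C` matrix of raw class
#'   logits), `boxes` (`L x 4` decoded corner boxes, pixels),
#'   `dfl_logits` (`L x 4 x (reg_max+1)` array of bin logits, sides ordered
#'   left, top, right, bottom), `anchors` (`L x 2` anchor centres, pixels)
#'   and `strides` (length-`L` stride of each location).
#' @param assigned an assignment as returned by [assign_targets()]: list
#'   with `fg` (logical length `L`), `gt_class` (1-based class index per
#'   location, `NA` on background), `gt_box` (`L x 4` corner boxes),
#'   `score` (alignment score per location, 0 on background) and
#'   `cls_targets` (`L x C` soft classification targets).
#' @param dist a [class_distribution()] covering all `C` classes.
#' @param cfg a [loss_config()].
#' @param state a [wiou_state()]; kept unchanged — update it afterwards with
#'   the returned `iou_loss` values via [update_wiou_state()].
#' @return an object of class `"loss_breakdown"`: list with `l_cls`,
#'   `l_dfl`, `l_box`, `total`, and `iou_loss` (detached per-foreground IoU
#'   losses for the running-mean update).
#' @export
composite_loss <- function(pred, assigned, dist, cfg, state = NULL) {
  stopifnot(inherits(cfg, "loss_config"), inherits(dist, "class_distribution"))
  if (is.null(state)) state <- wiou_state_from_config(cfg)
  C <- ncol(pred$cls_logits)
  if (length(dist$counts) < C) stop("class distribution does not cover all classes")
  fg <- assigned$fg
  score_mass <- max(sum(assigned$score[fg]), 1)

  cw <- if (cfg$use_class_aware)
    class_aware_weight(dist$counts, dist$n, cfg$eta, num_classes = length(dist$counts))
  else rep(1, length(dist$counts))

  # classification: BCE over every location/class; foreground rows get
  # class-column weights, background rows weight 1
  bce <- bce_loss(pred$cls_logits, assigned$cls_targets,
                  from_logits = TRUE, reduction = "none")
  wmat <- matrix(1, nrow(bce), ncol(bce))
  if (any(fg)) wmat[fg, ] <- matrix(cw[seq_len(C)], sum(fg), C, byrow = TRUE)
  l_cls <- sum(bce * wmat) / score_mass

  l_box <- 0; l_dfl <- 0; iou_loss <- numeric(0)
  if (any(fg)) {
    pb <- pred$boxes[fg, , drop = FALSE]
    gb <- assigned$gt_box[fg, , drop = FALSE]
    w_anchor <- assigned$score[fg] * cw[assigned$gt_class[fg]]
    if (cfg$use_wiou_v3) {
      v3 <- wiou_v3(pb, gb, state, normalizer = cfg$wiou_normalizer)
      box_vals <- v3$loss
      iou_loss <- v3$iou_loss
    } else {
      box_vals <- ciou_loss(pb, gb)
      iou_loss <- 1 - box_loss_terms(pb, gb)$iou
    }
    l_box <- sum(box_vals * w_anchor) / score_mass

    tgt <- encode_box_targets(gb, pred$anchors[fg, , drop = FALSE],
                              pred$strides[fg], cfg$reg_max)
    dl <- numeric(sum(fg))
    for (s in 1:4) {
      dl <- dl + dfl_loss(matrix(pred$dfl_logits[fg, s, ], ncol = cfg$reg_max + 1L),
                          tgt[, s], reduction = "none")
    }
    l_dfl <- sum((dl / 4) * w_anchor) / score_mass
  }

  total <- cfg$alpha1 * l_cls + cfg$alpha2 * l_dfl + cfg$alpha3 * l_box
  structure(list(l_cls = l_cls, l_dfl = l_dfl, l_box = l_box,
                 total = total, iou_loss = iou_loss),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("loss: total %.4f (cls %.4f, dfl %.4f, box %.4f)\n",
              x$total, x$l_cls, x$l_dfl, x$l_box))
  invisible(x)
}
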