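# Finite-difference verification of the analytic backward passes and of
# the Wise-IoU detachment contract.

numeric_grad <- function(f, get, set, i, eps = 1e-5) {
  v0 <- get()[i]
  set(i, v0 + eps); lp <- f()
  set(i, v0 - eps); lm <- f()
  set(i, v0)
  (lp - lm) / (2 * eps)
}

test_that("network backward pass matches finite differences", {
  set.seed(11)
  cfg <- detector_preset("micro", num_classes = 2)
  net <- init_detector(build_detector(cfg))
  X <- image_to_fm(array(runif(64 * 64 * 3), c(64, 64, 3)))
  fwd <- forward_detector(net, X, train = TRUE)
  proj <- lapply(fwd$head, function(h)
    list(box = matrix(rnorm(length(h$box$x)), nrow(h$box$x)),
         cls = matrix(rnorm(length(h$cls$x)), nrow(h$cls$x))))
  loss_of <- function() {
    f <- forward_detector(net, X, train = TRUE)
    s <- 0
    for (i in seq_along(f$head))
      s <- s + sum(proj[[i]]$box * f$head[[i]]$box$x) +
        sum(proj[[i]]$cls * f$head[[i]]$cls$x)
    s
  }
  G <- new.env()
  fishdet:::backward_detector(net, fwd$caches, proj, G)
  Ssnap <- as.list(net$S)
  reset <- function() for (n in names(Ssnap)) net$S[[n]] <- Ssnap[[n]]
  # one parameter from several structurally different layers
  picks <- c("n01.W", "n03.cv1.W", "n05.m1.a.g", "n10.cv2.be",
             "n13.cv2.W", "n23.s2.b3.b", "n23.s1.c3.W")
  for (nm in picks) {
    i <- 1 + (abs(sum(utf8ToInt(nm))) %% length(net$P[[nm]]))
    reset()
    num <- numeric_grad(function() { reset(); loss_of() },
                        function() net$P[[nm]],
                        function(j, v) net$P[[nm]][j] <- v, i)
    expect_equal(G[[nm]][i], num, tolerance = 5e-3, label = nm)
  }
})

test_that("transformer backward pass matches finite differences", {
  set.seed(12)
  d <- 8L
  mod <- fishdet:::nn_tstack("t", d, d, n = 2, heads = 2, ffn_ratio = 2)
  P <- new.env(); S <- new.env(); G <- new.env()
  for (sp in mod$pspecs) P[[sp$name]] <- fishdet:::init_param(sp)
  X <- fishdet:::fm(matrix(rnorm(2 * 16 * d), 32, d), 2L, 4L, 4L)
  W <- matrix(rnorm(32 * d), 32, d)
  f <- fishdet:::tstack_fwd(mod, X, P, S, TRUE)
  fishdet:::tstack_bwd(mod, f$cache, W, P, G)
  loss_of <- function() sum(W * fishdet:::tstack_fwd(mod, X, P, S, TRUE)$out$x)
  for (nm in c("t.t1.Wq", "t.t1.Wk", "t.t1.Wv", "t.t1.Wo", "t.t1.pw",
               "t.t2.g1", "t.t2.Wf1", "t.t2.bf2")) {
    i <- 1 + (abs(sum(utf8ToInt(nm))) %% length(P[[nm]]))
    num <- numeric_grad(loss_of, function() P[[nm]],
                        function(j, v) P[[nm]][j] <- v, i)
    expect_equal(G[[nm]][i], num, tolerance = 1e-4, label = nm)
  }
})

test_that("loss gradients match numeric differentiation of composite_loss", {
  pred <- fake_predictions(num_classes = 3, seed = 13)
  gtb <- rbind(c(8, 8, 40, 36), c(30, 30, 62, 58))
  asg <- assign_targets(1 / (1 + exp(-pred$cls_logits)), pred$boxes,
                        gtb, c(1L, 3L), pred$anchors, pred$strides)
  dist <- class_distribution(c(30, 20, 10))
  bins <- 17L
  remake <- function(cls, dfl) {
    d <- matrix(0, nrow(cls), 4); probs <- vector("list", 4)
    for (s in 1:4) {
      p <- fishdet:::softmax_rows(dfl[, (s - 1) * bins + seq_len(bins)])
      probs[[s]] <- p; d[, s] <- p %*% (0:16)
    }
    list(cls_logits = cls, dfl_logits_flat = dfl,
         dfl_logits = aperm(array(dfl, c(nrow(cls), bins, 4)), c(1, 3, 2)),
         probs = probs, offsets = d,
         boxes = decode_box_offsets(d, pred$anchors, pred$strides),
         anchors = pred$anchors, strides = pred$strides)
  }
  # CIoU path: the full objective is differentiable, numeric diff applies
  cfg <- loss_config(use_wiou_v3 = FALSE, use_class_aware = TRUE, eta = 8)
  lg <- fishdet:::detection_loss_grad(pred, asg, dist, cfg, wiou_state())
  f_cls <- function(i, j, v) {
    cl <- pred$cls_logits; cl[i, j] <- v
    composite_loss(remake(cl, pred$dfl_logits_flat), asg, dist, cfg)$total
  }
  fg <- which(asg$fg)
  for (k in 1:4) {
    i <- if (k <= 2) fg[k] else sample(nrow(pred$cls_logits), 1)
    j <- 1 + (k %% 3)
    v0 <- pred$cls_logits[i, j]; eps <- 1e-6
    num <- (f_cls(i, j, v0 + eps) - f_cls(i, j, v0 - eps)) / (2 * eps)
    expect_equal(lg$dcls[i, j], num, tolerance = 1e-4)
  }
  f_dfl <- function(i, j, v) {
    df <- pred$dfl_logits_flat; df[i, j] <- v
    composite_loss(remake(pred$cls_logits, df), asg, dist, cfg)$total
  }
  set.seed(14)
  for (k in 1:5) {
    i <- sample(fg, 1); j <- sample(4 * bins, 1)
    v0 <- pred$dfl_logits_flat[i, j]; eps <- 1e-6
    num <- (f_dfl(i, j, v0 + eps) - f_dfl(i, j, v0 - eps)) / (2 * eps)
    expect_equal(lg$ddfl[i, j], num, tolerance = 1e-3)
  }
})

test_that("gradients do not flow through detached Wise-IoU quantities", {
  pred <- fake_predictions(num_classes = 3, seed = 15)
  gtb <- rbind(c(8, 8, 40, 36))
  asg <- assign_targets(1 / (1 + exp(-pred$cls_logits)), pred$boxes,
                        gtb, 1L, pred$anchors, pred$strides)
  dist <- class_distribution(c(3, 2, 1))
  cfg <- loss_config(use_wiou_v3 = TRUE)
  st <- wiou_state(); st$mean <- 0.7
  lg <- fishdet:::detection_loss_grad(pred, asg, dist, cfg, st)
  fg <- which(asg$fg)
  gb <- asg$gt_box[fg, , drop = FALSE]
  pb <- pred$boxes[fg, , drop = FALSE]
  # frozen-detachment oracle: gain and exponential normalizer fixed at the
  # base point, all remaining dependence differentiated numerically
  bl <- fishdet:::box_loss_grad(pb, gb, cfg, st)
  cw_e <- pmax(pb[, 3], gb[, 3]) - pmin(pb[, 1], gb[, 1])
  ch_e <- pmax(pb[, 4], gb[, 4]) - pmin(pb[, 2], gb[, 2])
  D0 <- cw_e^2 + ch_e^2
  gain0 <- gradient_gain(outlier_degree(bl$iou_loss, st), st$beta, st$tau)
  frozen_loss <- function(pbx) {
    iou <- box_iou(pbx, gb)
    d2 <- ((pbx[, 1] + pbx[, 3]) / 2 - (gb[, 1] + gb[, 3]) / 2)^2 +
          ((pbx[, 2] + pbx[, 4]) / 2 - (gb[, 2] + gb[, 4]) / 2)^2
    sum(gain0 * (1 - iou) * exp(d2 / D0))
  }
  for (k in 1:4) {
    i <- sample(length(fg), 1); j <- sample(4, 1)
    eps <- 1e-5
    up <- pb; up[i, j] <- up[i, j] + eps
    dn <- pb; dn[i, j] <- dn[i, j] - eps
    num <- (frozen_loss(up) - frozen_loss(dn)) / (2 * eps)
    expect_equal(sum(bl$dcorners[i, j]), num, tolerance = 1e-3)
  }
  # full numeric diff (which lets theta, gain and normalizer vary) must
  # DISAGREE with the analytic gradient: the detachment is real
  full_loss <- function(pbx) {
    v3 <- wiou_v3(pbx, gb, st)
    sum(v3$loss)
  }
  diffs <- 0
  for (k in 1:6) {
    i <- sample(length(fg), 1); j <- sample(4, 1)
    eps <- 1e-4
    up <- pb; up[i, j] <- up[i, j] + eps
    dn <- pb; dn[i, j] <- dn[i, j] - eps
    num_full <- (full_loss(up) - full_loss(dn)) / (2 * eps)
    if (abs(num_full - bl$dcorners[i, j]) >
        1e-3 * max(abs(num_full), abs(bl$dcorners[i, j]), 1e-8))
      diffs <- diffs + 1
  }
  expect_gt(diffs, 0)
})
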