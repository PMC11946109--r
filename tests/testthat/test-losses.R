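test_that("wiou_v1 matches componentwise recomputation", {
  # coincident boxes
  expect_equal(wiou_v1(c(1, 1, 3, 3), c(1, 1, 3, 3)), 0)
  # concentric: center distance 0 -> exponential factor 1, loss = 1 - IoU
  inner <- c(1.5, 1.5, 2.5, 2.5)  # area 1 inside area 4 -> IoU 0.25
  outer <- c(1, 1, 3, 3)
  expect_equal(wiou_v1(inner, outer), 0.75)
  # off-center pair: recompute step by step
  p <- c(0, 0, 2, 2); g <- c(1, 0, 3, 2)
  iou <- raster_iou(p, g)            # 2/6
  d2 <- (1 - 2)^2 + (1 - 1)^2             # centres (1,1) vs (2,1)
  denom <- 3^2 + 2^2                      # enclosing box 3 x 2
  expect_equal(wiou_v1(p, g), (1 - iou) * exp(d2 / denom), tolerance = 1e-3)
  # exact arithmetic for the same pair
  expect_equal(wiou_v1(p, g), (1 - 1 / 3) * exp(1 / 13))
  # predicted-box normalizer option
  expect_equal(wiou_v1(p, g, normalizer = "pred"), (1 - 1 / 3) * exp(1 / 8))
  expect_error(wiou_v1(c(1, 1, 1, 1), c(1, 1, 1, 1)), "degenerate")
})

test_that("wiou_v1 always dominates the bare IoU loss", {
  set.seed(3)
  for (i in 1:200) {
    p <- random_box(); g <- random_box()
    v1 <- wiou_v1(p, g)
    il <- 1 - box_iou(p, g)
    expect_gte(v1, il - 1e-12)
  }
  # equality iff centres coincide
  expect_equal(wiou_v1(c(1.5, 1.5, 2.5, 2.5), c(1, 1, 3, 3)), 0.75)
})

test_that("outlier degree is the detached IoU loss over the running mean", {
  st <- wiou_state()
  st$mean <- 0.4
  expect_equal(outlier_degree(0.4, st), 1.0)
  expect_equal(outlier_degree(0, st), 0.0)
  expect_equal(outlier_degree(c(0.2, 0.8), st), c(0.5, 2))
  stf <- wiou_state(theta_mode = "fixed", theta_fixed = 2)
  expect_equal(outlier_degree(c(0, 0.123, 5), stf), c(2, 2, 2))
  st$mean <- -1
  expect_error(outlier_degree(0.1, st), "positive")
})

test_that("gradient gain has the closed form and the documented extremes", {
  # theta = tau makes the power term beta^0 = 1
  expect_equal(gradient_gain(3, beta = 1.8, tau = 3), 1.0)
  expect_equal(gradient_gain(0, beta = 1.8, tau = 3), 0.0)
  # reported operating point: 2 / (3 * 1.8^-1) = 2 * 1.8 / 3 = 1.2 exactly
  expect_identical(gradient_gain(2, beta = 1.8, tau = 3), 2 * 1.8 / 3)
  expect_equal(gradient_gain(2, beta = 1.8, tau = 3), 1.2)
  expect_error(gradient_gain(1, beta = -1, tau = 3), "positive")
  expect_error(gradient_gain(1, beta = 1.8, tau = 0), "nonzero")
})

test_that("gradient gain is non-monotonic with a single interior maximum", {
  th <- seq(0.001, 10, by = 0.001)
  k <- gradient_gain(th, beta = 1.8, tau = 3)
  d <- diff(k)
  sign_changes <- sum(diff(sign(d)) != 0)
  expect_equal(sign_changes, 1)          # rises then falls once
  # the stationary point of theta / beta^theta is 1 / log(beta)
  expect_equal(th[which.max(k)], 1 / log(1.8), tolerance = 1e-2)
})

test_that("wiou_v3 composes gain and v1 loss", {
  stf <- wiou_state(theta_mode = "fixed", theta_fixed = 2)
  # coincident boxes: v1 = 0 regardless of state
  expect_equal(wiou_v3(c(0, 0, 1, 1), c(0, 0, 1, 1), stf)$loss, 0)
  # concentric with IoU 0.5: gain(2) * 0.5 = 1.2 * 0.5
  inner <- c(0, 0.5, 2, 1.5)   # 2x1 inside 2x2, concentric
  outer <- c(0, 0, 2, 2)
  expect_equal(box_iou(inner, outer), 0.5)
  v3 <- wiou_v3(inner, outer, stf)
  expect_equal(v3$loss, 0.6)
  expect_equal(v3$iou_loss, 0.5)
  # dynamic mode at the running mean: theta = 1, kappa = gain(1)
  std <- wiou_state()
  std$mean <- 0.5
  v3d <- wiou_v3(inner, outer, std)
  expect_equal(v3d$theta, 1)
  expect_equal(v3d$loss, gradient_gain(1, 1.8, 3) * 0.5)
})

test_that("running mean converges geometrically under constant input", {
  st <- wiou_state(momentum = 0.9)
  errs <- numeric(30)
  for (i in 1:30) {
    st <- update_wiou_state(st, rep(0.25, 4))
    errs[i] <- abs(st$mean - 0.25)
  }
  expect_true(all(diff(errs) < 0))
  expect_equal(errs[-1] / errs[-30], rep(0.9, 29), tolerance = 1e-9)
  expect_lt(errs[30], 0.05)
  # empty batch leaves the state untouched
  expect_equal(update_wiou_state(st, numeric(0))$mean, st$mean)
})

test_that("class-aware weight identities, limits and bounds hold", {
  # eta = 1 is neutral
  expect_equal(class_aware_weight(c(0, 10, 500, 999), 1000, eta = 1),
               rep(1, 4))
  # vanishing frequency -> weight 1
  expect_equal(class_aware_weight(0, 1000, eta = 8), 1)
  # ns/n = 0.5, eta = 8
  expect_equal(class_aware_weight(500, 1000, eta = 8), 0.5 / (1 - 0.5^8))
  expect_equal(class_aware_weight(500, 1000, eta = 8), 0.501961, tolerance = 1e-6)
  # ns -> n limit is 1/eta
  expect_equal(class_aware_weight(999999999, 1e9, eta = 8), 1 / 8,
               tolerance = 1e-6)
  # single-class degenerate rule and its rejection for C > 1
  expect_equal(class_aware_weight(100, 100, eta = 8, num_classes = 1), 1)
  expect_error(class_aware_weight(100, 100, eta = 8, num_classes = 3),
               "invariant")
  expect_error(class_aware_weight(101, 100, eta = 8), "exceed")
})

test_that("class-aware weight is monotone and bounded on random triples", {
  # strictly decreasing in ns/n for eta > 1
  for (eta in c(2, 4, 8, 16)) {
    w <- class_aware_weight(seq(0, 990, by = 10), 1000, eta = eta)
    expect_true(all(diff(w) < 0))
  }
  set.seed(5)
  for (i in 1:10000) {
    n <- sample(10:100000, 1)
    ns <- sample(0:(n - 1), 1)
    eta <- runif(1, 1, 16)
    w <- class_aware_weight(ns, n, eta)
    expect_gt(w, 1 / eta - 1e-12)
    expect_lte(w, 1 + 1e-12)
  }
})

test_that("class_weight_table amplifies tail classes of a distribution", {
  dist <- class_distribution(c(400, 80, 15, 5))
  tab <- class_weight_table(dist, eta = 8)
  expect_equal(nrow(tab), 4)
  expect_true(all(diff(tab$weight) > 0))  # rarer -> larger weight
  expect_error(class_distribution(c(-1, 2)), "nonnegative")
  expect_error(class_distribution(c(0, 0)), ">= 1")
})

test_that("bce_loss closed forms", {
  # perfect prediction with clamp
  expect_lt(bce_loss(c(1, 0, 0), c(1, 0, 0)), 1e-8)
  # uniform 0.5 scores: every term is -log(0.5)
  expect_equal(bce_loss(rep(0.5, 4), c(1, 0, 0, 0), reduction = "none"),
               rep(-log(0.5), 4))
  # random case vs elementwise hand sum
  set.seed(9)
  p <- runif(20, 0.05, 0.95); t <- runif(20)
  expect_equal(bce_loss(p, t, reduction = "sum"),
               sum(-(t * log(p) + (1 - t) * log(1 - p))))
  # logits path agrees with the probability path
  z <- rnorm(20)
  expect_equal(bce_loss(z, t, from_logits = TRUE, reduction = "sum"),
               bce_loss(1 / (1 + exp(-z)), t, reduction = "sum"),
               tolerance = 1e-9)
  expect_error(bce_loss(1:3 / 4, 1:2 / 3), "mismatch")
  expect_error(bce_loss(0.5, 1.5), "\\[0, 1\\]")
})

test_that("dfl_loss interpolated cross-entropy closed forms", {
  reg_max <- 16
  # concentrated on the target bin -> ~0
  z <- rep(-20, reg_max + 1); z[6] <- 20
  expect_lt(dfl_loss(z, 5), 1e-6)
  # uniform over k bins, integer target inside: contribution log(k)
  k <- 5
  z <- rep(-40, reg_max + 1); z[1:k] <- 0
  expect_equal(dfl_loss(z, 2), log(k), tolerance = 1e-10)
  # mid-bin target vs hand-computed interpolation
  z <- rnorm(reg_max + 1)
  p <- exp(z) / sum(exp(z))
  y <- 7.3
  want <- -(0.7 * log(p[8]) + 0.3 * log(p[9]))
  expect_equal(dfl_loss(z, y), want)
  expect_error(dfl_loss(z, 16.5), "\\[0, reg_max\\]")
  expect_error(dfl_loss(rep(Inf, 17), 3), "finite")
})
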