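# Training: prediction gathering, analytic loss gradients, SGD loop.

# Flatten the head outputs of one image into prediction matrices across the
# three scales, plus decoded boxes. Row order matches make_anchors().
gather_predictions <- function(head, img_idx, cfg, an = NULL) {
  bins <- cfg$reg_max + 1L
  cls <- list(); dfl <- list()
  for (s in seq_along(head)) {
    hm <- head[[s]]$cls
    per <- hm$h * hm$w
    rows <- (img_idx - 1) * per + seq_len(per)
    cls[[s]] <- hm$x[rows, , drop = FALSE]
    dfl[[s]] <- head[[s]]$box$x[rows, , drop = FALSE]
  }
  cls_logits <- do.call(rbind, cls)
  dfl_logits <- do.call(rbind, dfl)   # L x (4 * bins), side-major columns
  if (is.null(an)) an <- make_anchors(cfg$input_size)
  d <- matrix(0, nrow(dfl_logits), 4)
  probs <- vector("list", 4)
  for (side in 1:4) {
    z <- dfl_logits[, (side - 1) * bins + seq_len(bins), drop = FALSE]
    p <- softmax_rows(z)
    probs[[side]] <- p
    d[, side] <- p %*% (0:cfg$reg_max)
  }
  boxes <- decode_box_offsets(d, an$anchors, an$strides)
  list(cls_logits = cls_logits, dfl_logits_flat = dfl_logits,
       dfl_logits = aperm(array(dfl_logits, dim = c(nrow(dfl_logits), bins, 4)),
                          c(1, 3, 2)),
       probs = probs, offsets = d, boxes = boxes,
       anchors = an$anchors, strides = an$strides)
}

# Analytic gradient of the box loss w.r.t. the predicted corner box.
# Returns per-row loss values, detached IoU losses and the n x 4 gradient.
box_loss_grad <- function(pb, gb, cfg, state) {
  n <- nrow(pb)
  x1 <- pb[, 1]; y1 <- pb[, 2]; x2 <- pb[, 3]; y2 <- pb[, 4]
  gx1 <- gb[, 1]; gy1 <- gb[, 2]; gx2 <- gb[, 3]; gy2 <- gb[, 4]
  iw <- pmin(x2, gx2) - pmax(x1, gx1)
  ih <- pmin(y2, gy2) - pmax(y1, gy1)
  pos <- iw > 0 & ih > 0
  iw0 <- pmax(iw, 0); ih0 <- pmax(ih, 0)
  I <- iw0 * ih0
  Ap <- (x2 - x1) * (y2 - y1); Ag <- (gx2 - gx1) * (gy2 - gy1)
  U <- pmax(Ap + Ag - I, 1e-9)
  iou <- I / U
  # intersection gradients (zero when no overlap or the other box binds)
  dI <- cbind(-ih0 * (x1 >= gx1), -iw0 * (y1 >= gy1),
               ih0 * (x2 <= gx2),  iw0 * (y2 <= gy2)) * pos
  dAp <- cbind(-(y2 - y1), -(x2 - x1), y2 - y1, x2 - x1)
  dU <- dAp - dI
  diou <- (dI * U - I * dU) / U^2
  # centre distance and enclosing box
  cx <- (x1 + x2) / 2; cy <- (y1 + y2) / 2
  gcx <- (gx1 + gx2) / 2; gcy <- (gy1 + gy2) / 2
  d2 <- (cx - gcx)^2 + (cy - gcy)^2
  dd2 <- cbind(cx - gcx, cy - gcy, cx - gcx, cy - gcy)
  cw <- pmax(x2, gx2) - pmin(x1, gx1)
  ch <- pmax(y2, gy2) - pmin(y1, gy1)
  c2 <- pmax(cw^2 + ch^2, 1e-9)
  iou_loss <- 1 - iou

  if (cfg$use_wiou_v3) {
    D <- if (cfg$wiou_normalizer == "enclosing") c2
         else pmax((x2 - x1)^2 + (y2 - y1)^2, 1e-9)
    E <- exp(d2 / D)                       # D detached
    theta <- outlier_degree(iou_loss, state)
    gain <- gradient_gain(theta, state$beta, state$tau)   # detached
    loss <- gain * iou_loss * E
    dloss <- gain * (-diou * E + iou_loss * E * dd2 / D)
  } else {
    pw <- x2 - x1; ph <- pmax(y2 - y1, 1e-9)
    gw <- gx2 - gx1; gh <- pmax(gy2 - gy1, 1e-9)
    dlt <- atan(gw / gh) - atan(pw / ph)
    v <- (4 / pi^2) * dlt^2
    alpha <- v / (iou_loss + v + 1e-9)     # detached trade-off
    loss <- iou_loss + d2 / c2 + alpha * v
    dcw <- cbind(-(x1 < gx1), 0, (x2 > gx2), 0)
    dch <- cbind(0, -(y1 < gy1), 0, (y2 > gy2))
    dc2 <- 2 * cw * dcw + 2 * ch * dch
    dvdw <- (8 / pi^2) * dlt * (-ph / (pw^2 + ph^2))
    dvdh <- (8 / pi^2) * dlt * ( pw / (pw^2 + ph^2))
    dv <- cbind(-dvdw, -dvdh, dvdw, dvdh)
    dloss <- -diou + dd2 / c2 - (d2 / c2^2) * dc2 + alpha * dv
  }
  list(loss = loss, iou_loss = iou_loss, dcorners = dloss)
}

# Loss and analytic gradients w.r.t. raw head logits for one image.
# Returns the loss breakdown plus d(cls_logits) and d(dfl_logits_flat).
detection_loss_grad <- function(pred, assigned, dist, cfg, state) {
  C <- ncol(pred$cls_logits)
  bins <- cfg$reg_max + 1L
  fg <- assigned$fg
  score_mass <- max(sum(assigned$score[fg]), 1)
  cw <- if (cfg$use_class_aware)
    class_aware_weight(dist$counts, dist$n, cfg$eta,
                       num_classes = length(dist$counts))
  else rep(1, length(dist$counts))

  z <- pred$cls_logits
  sig <- 1 / (1 + exp(-z))
  bce <- pmax(z, 0) - z * assigned$cls_targets + log1p(exp(-abs(z)))
  wmat <- matrix(1, nrow(z), C)
  if (any(fg)) wmat[fg, ] <- matrix(cw[seq_len(C)], sum(fg), C, byrow = TRUE)
  l_cls <- sum(bce * wmat) / score_mass
  dcls <- (sig - assigned$cls_targets) * wmat * (cfg$alpha1 / score_mass)

  l_box <- 0; l_dfl <- 0
  ddfl <- matrix(0, nrow(z), 4L * bins)
  iou_losses <- numeric(0)
  if (any(fg)) {
    idx <- which(fg)
    pb <- pred$boxes[idx, , drop = FALSE]
    gb <- assigned$gt_box[idx, , drop = FALSE]
    w_anchor <- assigned$score[idx] * cw[assigned$gt_class[idx]]
    bl <- box_loss_grad(pb, gb, cfg, state)
    iou_losses <- bl$iou_loss
    l_box <- sum(bl$loss * w_anchor) / score_mass
    # chain: corners -> side offsets -> bin logits
    strd <- pred$strides[idx]
    dcorn <- bl$dcorners * (w_anchor * cfg$alpha3 / score_mass)
    doff <- cbind(-dcorn[, 1], -dcorn[, 2], dcorn[, 3], dcorn[, 4]) * strd

    tgt <- encode_box_targets(gb, pred$anchors[idx, , drop = FALSE],
                              strd, cfg$reg_max)
    kvec <- 0:cfg$reg_max
    dl_sum <- numeric(length(idx))
    for (side in 1:4) {
      cols <- (side - 1) * bins + seq_len(bins)
      p <- pred$probs[[side]][idx, , drop = FALSE]
      # box-loss chain through the softmax expectation
      dexp <- p * (matrix(kvec, length(idx), bins, byrow = TRUE) -
                     pred$offsets[idx, side])
      ddfl[idx, cols] <- ddfl[idx, cols] + dexp * doff[, side]
      # distribution-focal term
      lo <- pmin(floor(tgt[, side]), cfg$reg_max - 1L); hi <- lo + 1
      wl <- hi - tgt[, side]; wr <- tgt[, side] - lo
      ii <- seq_along(idx)
      dl_sum <- dl_sum - (wl * log(pmax(p[cbind(ii, lo + 1)], 1e-12)) +
                          wr * log(pmax(p[cbind(ii, hi + 1)], 1e-12)))
      tgt_p <- matrix(0, length(idx), bins)
      tgt_p[cbind(ii, lo + 1)] <- wl
      tgt_p[cbind(ii, hi + 1)] <- tgt_p[cbind(ii, hi + 1)] + wr
      ddfl[idx, cols] <- ddfl[idx, cols] +
        (p - tgt_p) * (w_anchor * cfg$alpha2 / (4 * score_mass))
    }
    l_dfl <- sum((dl_sum / 4) * w_anchor) / score_mass
  }
  total <- cfg$alpha1 * l_cls + cfg$alpha2 * l_dfl + cfg$alpha3 * l_box
  list(l_cls = l_cls, l_dfl = l_dfl, l_box = l_box, total = total,
       iou_loss = iou_losses, dcls = dcls, ddfl = ddfl)
}

sgd_step <- function(P, G, V, lr, momentum = 0.937, weight_decay = 5e-4) {
  for (nm in ls(G)) {
    g <- G[[nm]]
    p <- P[[nm]]
    if (!is.null(dim(p)) && weight_decay > 0) g <- g + weight_decay * p
    v <- V[[nm]]
    v <- if (is.null(v)) -lr * g else momentum * v - lr * g
    V[[nm]] <- v
    P[[nm]] <- p + v
  }
}

#' Fit a fish-species detector
#'
#' Trains an anchor-free single-stage detector with stochastic gradient
#' descent on a (typically synthetic) detection dataset. Targets are
#' produced by task-aligned assignment each step; the box objective is
#' Wise-IoU v3 (or CIoU), optionally class-aware reweighted; the Wise-IoU
#' running mean is updated once per batch on detached values. Training is
#' fully reproducible from `seed`, which controls weight initialization
#' and data order.
#'
#' @param data a detection dataset as produced by [synthetic_dataset()]:
#'   list with `images` (list of `H x W x 3` arrays), `labels` (list of
#'   data.frames with columns `class` (0-based), `cx`, `cy`, `w`, `h`,
#'   normalized) and `class_names`.
#' @param model a [model_config()] or preset name (default `"micro"`).
#' @param loss a [loss_config()].
#' @param epochs training epochs.
#' @param batch_size images per SGD step.
#' @param lr0 peak learning rate (linear warmup over `warmup_epochs`
#'   epochs, cosine decay to `lr0 * lrf`).
#' @param lrf final learning-rate fraction.
#' @param warmup_epochs linear warmup length (epochs, may be fractional).
#' @param momentum,weight_decay SGD momentum and L2 penalty (weights only).
#' @param seed integer seed.
#' @param eval_every compute mAP on `data` every this many epochs
#'   (0 = never).
#' @param target_map50 stop early once the evaluated mAP at IoU 0.5
#'   reaches this value (`NULL` = never).
#' @param verbose print per-epoch losses.
#' @return an object of class `"fishdet"` with the trained parameters,
#'   configuration, class distribution and a per-epoch `history`
#'   data.frame (`epoch`, `l_cls`, `l_dfl`, `l_box`, `loss`, `map50`).
#' @export
fit_detector <- function(data, model = "micro", loss = loss_config(),
                         epochs = 100, batch_size = 8, lr0 = 0.01,
                         lrf = 0.01, warmup_epochs = 3,
                         momentum = 0.937, weight_decay = 5e-4,
                         seed = 0, eval_every = 0, target_map50 = NULL,
                         verbose = FALSE) {
  if (is.character(model))
    model <- detector_preset(model, num_classes = length(data$class_names))
  stopifnot(inherits(model, "model_config"), inherits(loss, "loss_config"))
  set.seed(seed)
  graph <- build_detector(model)
  net <- init_detector(graph)
  V <- new.env(parent = emptyenv())
  state <- wiou_state_from_config(loss)
  dist <- class_distribution_from_labels(data$labels,
                                         length(data$class_names))
  n_img <- length(data$images)
  anchors_cache <- make_anchors(model$input_size)
  steps_per_epoch <- ceiling(n_img / batch_size)
  total_steps <- epochs * steps_per_epoch
  warm_steps <- max(warmup_epochs * steps_per_epoch, 1)
  hist <- data.frame(epoch = integer(), l_cls = numeric(), l_dfl = numeric(),
                     l_box = numeric(), loss = numeric(), map50 = numeric())
  step <- 0
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n_img)
    ep_loss <- c(l_cls = 0, l_dfl = 0, l_box = 0, total = 0)
    nb <- 0
    for (bi in seq_len(steps_per_epoch)) {
      step <- step + 1
      lr <- if (step <= warm_steps) lr0 * step / warm_steps
            else {
              prog <- (step - warm_steps) / max(total_steps - warm_steps, 1)
              lr0 * (lrf + (1 - lrf) * 0.5 * (1 + cos(pi * min(prog, 1))))
            }
      ids <- ord[((bi - 1) * batch_size + 1):min(bi * batch_size, n_img)]
      X <- image_to_fm(data$images[ids])
      fwd <- forward_detector(net, X, train = TRUE)
      G <- new.env(parent = emptyenv())
      dHead <- lapply(fwd$head, function(h)
        list(box = matrix(0, nrow(h$box$x), ncol(h$box$x)),
             cls = matrix(0, nrow(h$cls$x), ncol(h$cls$x))))
      batch_iou <- numeric(0)
      bl <- c(l_cls = 0, l_dfl = 0, l_box = 0, total = 0)
      for (ii in seq_along(ids)) {
        pred <- gather_predictions(fwd$head, ii, model, anchors_cache)
        if (any(!is.finite(pred$cls_logits)) || any(!is.finite(pred$boxes)))
          stop(sprintf(paste0("non-finite loss at epoch %d (image %d): the ",
                              "model diverged; lower the learning rate"),
                       ep, ids[ii]))
        lab <- data$labels[[ids[ii]]]
        if (nrow(lab) > 0) {
          gtb <- as_corner(cbind(lab$cx, lab$cy, lab$w, lab$h)) * model$input_size
          gtc <- lab$class + 1L
        } else { gtb <- matrix(0, 0, 4); gtc <- integer(0) }
        asg <- assign_targets(1 / (1 + exp(-pred$cls_logits)), pred$boxes,
                              gtb, gtc, pred$anchors, pred$strides)
        lg <- detection_loss_grad(pred, asg, dist, loss, state)
        if (!is.finite(lg$total))
          stop(sprintf("non-finite loss at epoch %d (image %d): cls %g dfl %g box %g",
                       ep, ids[ii], lg$l_cls, lg$l_dfl, lg$l_box))
        batch_iou <- c(batch_iou, lg$iou_loss)
        bl <- bl + c(lg$l_cls, lg$l_dfl, lg$l_box, lg$total)
        # scatter per-image logit gradients back to the head maps
        off <- 0L
        bins <- model$reg_max + 1L
        for (s in seq_along(dHead)) {
          per <- fwd$head[[s]]$cls$h * fwd$head[[s]]$cls$w
          rows_head <- (ii - 1) * per + seq_len(per)
          rows_pred <- off + seq_len(per)
          dHead[[s]]$cls[rows_head, ] <- lg$dcls[rows_pred, ] / length(ids)
          dHead[[s]]$box[rows_head, ] <- lg$ddfl[rows_pred, ] / length(ids)
          off <- off + per
        }
      }
      backward_detector(net, fwd$caches, dHead, G)
      sgd_step(net$P, G, V, lr, momentum, weight_decay)
      state <- update_wiou_state(state, batch_iou)
      ep_loss <- ep_loss + bl / length(ids)
      nb <- nb + 1
    }
    ep_loss <- ep_loss / nb
    m50 <- NA_real_
    fit_obj <- structure(list(net = net, graph = graph, model = model,
                              loss = loss, dist = dist, state = state,
                              class_names = data$class_names, seed = seed),
                         class = "fishdet")
    if (eval_every > 0 && (ep %% eval_every == 0 || ep == epochs)) {
      dets <- predict(fit_obj, data$images, conf = 0.05)
      m50 <- map_summary(evaluate_detections(dets, data$labels,
                                             length(data$class_names),
                                             model$input_size))$map50
    }
    hist <- rbind(hist, data.frame(epoch = ep, l_cls = ep_loss[1],
                                   l_dfl = ep_loss[2], l_box = ep_loss[3],
                                   loss = ep_loss[4], map50 = m50))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f (cls %.3f dfl %.3f box %.3f)%s",
                      ep, ep_loss[4], ep_loss[1], ep_loss[2], ep_loss[3],
                      if (is.na(m50)) "" else sprintf("  mAP50 %.3f", m50)))
    if (!is.null(target_map50) && !is.na(m50) && m50 >= target_map50) break
  }
  rownames(hist) <- NULL
  structure(list(net = net, graph = graph, model = model, loss = loss,
                 dist = dist, state = state,
                 class_names = data$class_names, history = hist,
                 seed = seed),
            class = "fishdet")
}

#' Detect objects in images
#'
#' Runs the fitted detector in inference mode (batch-norm running
#' statistics), decodes the distribution-bin box predictions, filters by
#' confidence and applies per-class non-maximum suppression.
#'
#' @param object a fitted `"fishdet"` model.
#' @param images a single `H x W x 3` array or list of such arrays (values
#'   in `[0, 1]`, side `object$model$input_size`).
#' @param conf confidence threshold.
#' @param iou_nms NMS IoU threshold.
#' @param max_det maximum detections per image.
#' @param ... unused.
#' @return a list (one element per image) of data.frames with columns
#'   `class` (0-based), `conf`, `x1`, `y1`, `x2`, `y2` (pixels).
#' @export
predict.fishdet <- function(object, images, conf = 0.25, iou_nms = 0.7,
                            max_det = 300, batch_size = 16, ...) {
  if (is.array(images) && length(dim(images)) == 3) images <- list(images)
  out <- vector("list", length(images))
  an <- make_anchors(object$model$input_size)
  for (b0 in seq(1, length(images), by = batch_size)) {
    ids <- b0:min(b0 + batch_size - 1, length(images))
    X <- image_to_fm(images[ids])
    fwd <- forward_detector(object$net, X, train = FALSE)
    for (ii in seq_along(ids)) {
      pred <- gather_predictions(fwd$head, ii, object$model, an)
      sc <- 1 / (1 + exp(-pred$cls_logits))
      best <- max.col(sc, ties.method = "first")
      bconf <- sc[cbind(seq_len(nrow(sc)), best)]
      keep <- which(bconf >= conf)
      df <- data.frame(class = integer(), conf = numeric(), x1 = numeric(),
                       y1 = numeric(), x2 = numeric(), y2 = numeric())
      if (length(keep)) {
        cand <- data.frame(class = best[keep] - 1L, conf = bconf[keep],
                           x1 = pred$boxes[keep, 1], y1 = pred$boxes[keep, 2],
                           x2 = pred$boxes[keep, 3], y2 = pred$boxes[keep, 4])
        df <- nms_per_class(cand, iou_nms, max_det)
      }
      out[[ids[ii]]] <- df
    }
  }
  out
}

nms_per_class <- function(cand, iou_thr = 0.7, max_det = 300) {
  res <- list()
  for (cl in unique(cand$class)) {
    d <- cand[cand$class == cl, , drop = FALSE]
    d <- d[order(-d$conf, seq_len(nrow(d))), , drop = FALSE]
    keep <- logical(nrow(d))
    bx <- as.matrix(d[, c("x1", "y1", "x2", "y2")])
    for (i in seq_len(nrow(d))) {
      if (any(keep)) {
        ious <- box_iou_matrix(bx[i, , drop = FALSE], bx[keep, , drop = FALSE])
        if (any(ious > iou_thr)) next
      }
      keep[i] <- TRUE
    }
    res[[length(res) + 1]] <- d[keep, , drop = FALSE]
  }
  if (!length(res)) return(cand[0, ])
  out <- do.call(rbind, res)
  out <- out[order(-out$conf), , drop = FALSE]
  utils::head(out, max_det)
}

#' @export
print.fishdet <- function(x, ...) {
  cat("Anchor-free fish-species detector\n")
  cat(sprintf("  classes: %d   input: %dpx   parameters: %s (%.2f M)\n",
              x$model$num_classes, x$model$input_size,
              format(count_parameters(x), big.mark = ","),
              count_parameters(x) / 1e6))
  cat(sprintf("  box loss: %s, class-aware: %s (eta = %g)\n",
              if (x$loss$use_wiou_v3) "Wise-IoU v3" else "CIoU",
              if (x$loss$use_class_aware) "on" else "off", x$loss$eta))
  if (!is.null(x$history) && nrow(x$history))
    cat(sprintf("  trained %d epochs, final loss %.4f\n",
                max(x$history$epoch), x$history$loss[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.fishdet <- function(object, ...) {
  print(object)
  cat("\nClass-aware weights (eta =", object$loss$eta, "):\n")
  print(utils::head(class_weight_table(object$dist, object$loss$eta,
                                       object$class_names), 12))
  invisible(object)
}

#' @export
plot.fishdet <- function(x, ...) {
  h <- x$history
  if (is.null(h) || !nrow(h)) stop("no training history to plot")
  graphics::par(mfrow = c(1, 2))
  graphics::matplot(h$epoch, cbind(h$l_cls, h$l_dfl, h$l_box), type = "l",
                    lty = 1, xlab = "epoch", ylab = "loss",
                    main = "loss components")
  graphics::legend("topright", c("cls", "dfl", "box"), col = 1:3, lty = 1,
                   bty = "n")
  if (any(!is.na(h$map50)))
    graphics::plot(h$epoch, h$map50, type = "b", xlab = "epoch",
                   ylab = "mAP@0.5", main = "validation mAP")
  else
    graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                   ylab = "total loss", main = "total loss")
  graphics::par(mfrow = c(1, 1))
  invisible(x)
}

# per-class instance counts from a list of label data.frames
#' Class distribution of a labelled dataset
#'
#' Counts annotated instances (not images) per class over a list of label
#' tables, yielding the [class_distribution()] that drives the class-aware
#' weights.
#'
#' @param labels list of data.frames with a 0-based `class` column.
#' @param num_classes total number of classes.
#' @return a [class_distribution()].
#' @export
class_distribution_from_labels <- function(labels, num_classes) {
  cls <- unlist(lapply(labels, function(l) l$class))
  counts <- tabulate(cls + 1L, nbins = num_classes)
  class_distribution(counts)
}
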