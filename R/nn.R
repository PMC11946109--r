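# Layer engine: forward/backward passes for the small set of layer types
# the detector needs. Feature maps are double matrices with one row per
# spatial location (batch-major, row-major within an image: row index
# b*H*W + i*W + j) and one column per channel, carried around as
# list(x, b, h, w). Parameters live in an environment keyed by
# "<node>.<leaf>"; gradients and batch-norm running statistics live in
# parallel environments with the same keys.

fm <- function(x, b, h, w) list(x = x, b = b, h = h, w = w)

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1   # running-statistics update rate

silu <- function(x) x / (1 + exp(-x))

# ---- parameter specs -------------------------------------------------------

pspec <- function(name, dims, init = "kaiming", const = 0) {
  list(name = name, dims = dims, init = init, const = const)
}

n_params_spec <- function(specs) sum(vapply(specs, function(s) prod(s$dims), 0))

init_param <- function(spec) {
  n <- prod(spec$dims)
  v <- switch(spec$init,
    kaiming = stats::rnorm(n, 0, sqrt(2 / spec$dims[1])),
    linear  = stats::rnorm(n, 0, sqrt(1 / spec$dims[1])),
    zeros   = rep(0, n),
    ones    = rep(1, n),
    const   = rep(spec$const, n),
    # box-branch bias prior: favour small side offsets at initialization so
    # early decoded boxes are anchor-sized and task-aligned assignment has
    # usable IoU signal from the first steps
    dfl_prior = rep(seq(2, -3, length.out = n %/% 4L), 4L),
    stop("unknown init ", spec$init))
  if (length(spec$dims) > 1) dim(v) <- spec$dims
  v
}

# ---- primitive: conv (+ optional BN + SiLU) --------------------------------

nn_conv <- function(id, c1, c2, k = 1, s = 1, bn = TRUE, act = TRUE,
                    bias = !bn, bias_init = 0) {
  specs <- list(pspec(paste0(id, ".W"), c(k * k * c1, c2), "kaiming"))
  if (bias) specs <- c(specs, list(
    if (is.character(bias_init)) pspec(paste0(id, ".b"), c2, bias_init)
    else pspec(paste0(id, ".b"), c2, "const", bias_init)))
  if (bn) specs <- c(specs, list(pspec(paste0(id, ".g"), c2, "ones"),
                                 pspec(paste0(id, ".be"), c2, "zeros")))
  list(type = "conv", id = id, c1 = c1, c2 = c2, k = k, s = s,
       bn = bn, act = act, bias = bias, pspecs = specs)
}

conv_fwd <- function(mod, X, P, S, train) {
  k <- mod$k; s <- mod$s; p <- k %/% 2L
  col <- if (k == 1 && s == 1) X$x else .im2col(X$x, X$b, X$h, X$w, k, s, p)
  oh <- (X$h + 2 * p - k) %/% s + 1L
  ow <- (X$w + 2 * p - k) %/% s + 1L
  Z <- col %*% P[[paste0(mod$id, ".W")]]
  if (mod$bias) Z <- Z + rep(P[[paste0(mod$id, ".b")]], each = nrow(Z))
  cache <- list(col_in = X, oh = oh, ow = ow)
  if (!(k == 1 && s == 1)) cache$col <- col
  if (mod$bn) {
    g <- P[[paste0(mod$id, ".g")]]; be <- P[[paste0(mod$id, ".be")]]
    if (train) {
      mu <- colMeans(Z)
      va <- colMeans(Z * Z) - mu * mu
      rmk <- paste0(mod$id, ".rm"); rvk <- paste0(mod$id, ".rv")
      S[[rmk]] <- (1 - BN_MOMENTUM) * S[[rmk]] + BN_MOMENTUM * mu
      S[[rvk]] <- (1 - BN_MOMENTUM) * S[[rvk]] + BN_MOMENTUM * va
    } else {
      mu <- S[[paste0(mod$id, ".rm")]]
      va <- S[[paste0(mod$id, ".rv")]]
    }
    istd <- 1 / sqrt(va + BN_EPS)
    # fused affine: y = z * (g / sd) + (be - mu * g / sd)
    A <- g * istd
    Y <- Z * rep(A, each = nrow(Z)) + rep(be - mu * A, each = nrow(Z))
    if (train) {
      cache$Z <- Z; cache$mu <- mu; cache$istd <- istd
    }
    cache$train_bn <- train; cache$istd_eval <- istd
  } else {
    Y <- Z
  }
  if (mod$act) {
    sig <- 1 / (1 + exp(-Y))
    cache$pre <- Y; cache$sig <- sig
    Y <- Y * sig
  }
  list(out = fm(Y, X$b, oh, ow), cache = cache)
}

conv_bwd <- function(mod, cache, dY, P, G) {
  N <- nrow(dY)
  if (mod$act) {
    sig <- cache$sig
    dY <- dY * (sig * (1 + cache$pre * (1 - sig)))
  }
  if (mod$bn) {
    g <- P[[paste0(mod$id, ".g")]]
    if (isTRUE(cache$train_bn)) {
      Zh <- (cache$Z - rep(cache$mu, each = N)) * rep(cache$istd, each = N)
      acc_grad(G, paste0(mod$id, ".g"), colSums(dY * Zh))
      acc_grad(G, paste0(mod$id, ".be"), colSums(dY))
      dZh <- dY * rep(g, each = N)
      m1 <- colMeans(dZh)
      m2 <- colMeans(dZh * Zh)
      dZ <- (dZh - rep(m1, each = N) - Zh * rep(m2, each = N)) *
        rep(cache$istd, each = N)
    } else {
      acc_grad(G, paste0(mod$id, ".be"), colSums(dY))
      dZ <- dY * rep(g * cache$istd_eval, each = N)
    }
  } else {
    dZ <- dY
  }
  if (mod$bias) acc_grad(G, paste0(mod$id, ".b"), colSums(dZ))
  W <- P[[paste0(mod$id, ".W")]]
  col <- if (mod$k == 1 && mod$s == 1) cache$col_in$x else cache$col
  acc_grad(G, paste0(mod$id, ".W"), crossprod(col, dZ))
  dcol <- tcrossprod(dZ, W)
  X <- cache$col_in
  if (mod$k == 1 && mod$s == 1) dX <- dcol
  else dX <- .col2im(dcol, X$b, X$h, X$w, mod$c1, mod$k, mod$s, mod$k %/% 2L)
  fm(dX, X$b, X$h, X$w)
}

acc_grad <- function(G, name, val) {
  cur <- G[[name]]
  G[[name]] <- if (is.null(cur)) val else cur + val
}

# ---- C2f: split-transform-concat block with n serial bottlenecks -----------

nn_c2f <- function(id, c1, c2, n, shortcut = TRUE) {
  c <- as.integer(c2 * 0.5)
  cv1 <- nn_conv(paste0(id, ".cv1"), c1, 2L * c, 1)
  bot <- lapply(seq_len(n), function(i) {
    list(a = nn_conv(sprintf("%s.m%d.a", id, i), c, c, 3),
         b = nn_conv(sprintf("%s.m%d.b", id, i), c, c, 3))
  })
  cv2 <- nn_conv(paste0(id, ".cv2"), (2L + n) * c, c2, 1)
  specs <- c(cv1$pspecs, unlist(lapply(bot, function(m) c(m$a$pspecs, m$b$pspecs)),
                                recursive = FALSE), cv2$pspecs)
  list(type = "c2f", id = id, c1 = c1, c2 = c2, c = c, n = n,
       shortcut = shortcut && c1 == c2, cv1 = cv1, bot = bot, cv2 = cv2,
       pspecs = specs)
}

c2f_fwd <- function(mod, X, P, S, train) {
  f1 <- conv_fwd(mod$cv1, X, P, S, train)
  y <- f1$out
  c <- mod$c
  ys <- list(fm(y$x[, seq_len(c), drop = FALSE], y$b, y$h, y$w),
             fm(y$x[, c + seq_len(c), drop = FALSE], y$b, y$h, y$w))
  bcaches <- vector("list", mod$n)
  cur <- ys[[2]]
  for (i in seq_len(mod$n)) {
    fa <- conv_fwd(mod$bot[[i]]$a, cur, P, S, train)
    fb <- conv_fwd(mod$bot[[i]]$b, fa$out, P, S, train)
    out <- if (mod$shortcut) fm(cur$x + fb$out$x, cur$b, cur$h, cur$w) else fb$out
    bcaches[[i]] <- list(a = fa$cache, b = fb$cache)
    ys[[2 + i]] <- out
    cur <- out
  }
  cat_x <- do.call(cbind, lapply(ys, `[[`, "x"))
  f2 <- conv_fwd(mod$cv2, fm(cat_x, y$b, y$h, y$w), P, S, train)
  list(out = f2$out, cache = list(cv1 = f1$cache, bot = bcaches, cv2 = f2$cache))
}

c2f_bwd <- function(mod, cache, dY, P, G) {
  c <- mod$c
  dcat <- conv_bwd(mod$cv2, cache$cv2, dY, P, G)
  # split the concat gradient back into the 2 + n branches
  dys <- vector("list", 2 + mod$n)
  for (i in seq_len(2 + mod$n))
    dys[[i]] <- dcat$x[, (i - 1) * c + seq_len(c), drop = FALSE]
  # walk the serial bottleneck chain backwards; dcur is the gradient wrt
  # branch output o_i, combining its concat contribution and the chain
  dcur <- dys[[2 + mod$n]]
  for (i in rev(seq_len(mod$n))) {
    dfb <- conv_bwd(mod$bot[[i]]$b, cache$bot[[i]]$b, dcur, P, G)
    dfa <- conv_bwd(mod$bot[[i]]$a, cache$bot[[i]]$a, dfb$x, P, G)
    dprev <- dfa$x
    if (mod$shortcut) dprev <- dprev + dcur
    dcur <- if (i > 1) dprev + dys[[1 + i]] else dprev
  }
  dy1 <- cbind(dys[[1]], dcur + dys[[2]])
  conv_bwd(mod$cv1, cache$cv1, dy1, P, G)
}

# ---- SPPF ------------------------------------------------------------------

nn_sppf <- function(id, c1, c2, k = 5) {
  ch <- c1 %/% 2L
  cv1 <- nn_conv(paste0(id, ".cv1"), c1, ch, 1)
  cv2 <- nn_conv(paste0(id, ".cv2"), ch * 4L, c2, 1)
  list(type = "sppf", id = id, c1 = c1, c2 = c2, ch = ch, k = k,
       cv1 = cv1, cv2 = cv2, pspecs = c(cv1$pspecs, cv2$pspecs))
}

sppf_fwd <- function(mod, X, P, S, train) {
  f1 <- conv_fwd(mod$cv1, X, P, S, train)
  y <- f1$out
  p <- mod$k %/% 2L
  m1 <- .maxpool(y$x, y$b, y$h, y$w, mod$k, p)
  m2 <- .maxpool(m1$out, y$b, y$h, y$w, mod$k, p)
  m3 <- .maxpool(m2$out, y$b, y$h, y$w, mod$k, p)
  cat_x <- cbind(y$x, m1$out, m2$out, m3$out)
  f2 <- conv_fwd(mod$cv2, fm(cat_x, y$b, y$h, y$w), P, S, train)
  list(out = f2$out,
       cache = list(cv1 = f1$cache, cv2 = f2$cache,
                    args = list(m1$arg, m2$arg, m3$arg), n = nrow(y$x)))
}

sppf_bwd <- function(mod, cache, dY, P, G) {
  dcat <- conv_bwd(mod$cv2, cache$cv2, dY, P, G)
  ch <- mod$ch
  dy <- dcat$x[, seq_len(ch), drop = FALSE]
  dm1 <- dcat$x[, ch + seq_len(ch), drop = FALSE]
  dm2 <- dcat$x[, 2 * ch + seq_len(ch), drop = FALSE]
  dm3 <- dcat$x[, 3 * ch + seq_len(ch), drop = FALSE]
  dm2 <- dm2 + .maxpool_bwd(dm3, cache$args[[3]], cache$n)
  dm1 <- dm1 + .maxpool_bwd(dm2, cache$args[[2]], cache$n)
  dy <- dy + .maxpool_bwd(dm1, cache$args[[1]], cache$n)
  conv_bwd(mod$cv1, cache$cv1, dy, P, G)
}

# ---- upsample / concat -----------------------------------------------------

nn_upsample <- function(id) list(type = "upsample", id = id, pspecs = list())

nn_concat <- function(id, cs) list(type = "concat", id = id, cs = cs,
                                   pspecs = list())

# ---- transformer stack -----------------------------------------------------

nn_tstack <- function(id, c1, c2, n, heads = 4, ffn_ratio = 1.85) {
  if (c2 %% heads != 0) stop("channel count must be divisible by head count")
  adapter <- if (c1 != c2) nn_conv(paste0(id, ".ad"), c1, c2, 1) else NULL
  hid <- as.integer(c2 * ffn_ratio)
  blocks <- lapply(seq_len(n), function(i) {
    b <- sprintf("%s.t%d", id, i)
    list(id = b,
         pspecs = list(
           pspec(paste0(b, ".pw"), c2, "zeros"),            # positional: weight on index
           pspec(paste0(b, ".pb"), c2, "zeros"),            # positional: bias
           pspec(paste0(b, ".Wq"), c(c2, c2), "linear"), pspec(paste0(b, ".bq"), c2, "zeros"),
           pspec(paste0(b, ".Wk"), c(c2, c2), "linear"), pspec(paste0(b, ".bk"), c2, "zeros"),
           pspec(paste0(b, ".Wv"), c(c2, c2), "linear"), pspec(paste0(b, ".bv"), c2, "zeros"),
           pspec(paste0(b, ".Wo"), c(c2, c2), "linear"), pspec(paste0(b, ".bo"), c2, "zeros"),
           pspec(paste0(b, ".g1"), c2, "ones"), pspec(paste0(b, ".b1"), c2, "zeros"),
           pspec(paste0(b, ".g2"), c2, "ones"), pspec(paste0(b, ".b2"), c2, "zeros"),
           pspec(paste0(b, ".Wf1"), c(c2, hid), "linear"), pspec(paste0(b, ".bf1"), hid, "zeros"),
           pspec(paste0(b, ".Wf2"), c(hid, c2), "linear"), pspec(paste0(b, ".bf2"), c2, "zeros")))
  })
  specs <- c(if (!is.null(adapter)) adapter$pspecs,
             unlist(lapply(blocks, `[[`, "pspecs"), recursive = FALSE))
  list(type = "tstack", id = id, c1 = c1, c2 = c2, n = n, heads = heads,
       hid = hid, adapter = adapter, blocks = blocks, pspecs = specs)
}

layernorm_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  va <- rowMeans(xc * xc)
  istd <- 1 / sqrt(va + 1e-5)
  Xh <- xc * istd
  list(out = Xh * rep(g, each = nrow(X)) + rep(b, each = nrow(X)),
       Xh = Xh, istd = istd)
}

layernorm_bwd <- function(cache, dY, g) {
  N <- nrow(dY); d <- ncol(dY)
  dXh <- dY * rep(g, each = N)
  m1 <- rowMeans(dXh)
  m2 <- rowMeans(dXh * cache$Xh)
  dX <- (dXh - m1 - cache$Xh * m2) * cache$istd
  list(dX = dX, dg = colSums(dY * cache$Xh), db = colSums(dY))
}

# One transformer block on one image's token matrix (n_tok x d):
# learnable linear positional embedding, pre-norm multi-head self-attention
# with residual sum, pre-norm SiLU feed-forward with residual sum.
tblock_fwd <- function(b, Tk, P, pos_scale = 1) {
  n <- nrow(Tk); d <- ncol(Tk); H <- attr(Tk, "heads")
  idx <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0
  T0 <- Tk + pos_scale * (outer(idx, P[[paste0(b, ".pw")]]) +
                            rep(P[[paste0(b, ".pb")]], each = n))
  ln1 <- layernorm_fwd(T0, P[[paste0(b, ".g1")]], P[[paste0(b, ".b1")]])
  q <- ln1$out %*% P[[paste0(b, ".Wq")]] + rep(P[[paste0(b, ".bq")]], each = n)
  k <- ln1$out %*% P[[paste0(b, ".Wk")]] + rep(P[[paste0(b, ".bk")]], each = n)
  v <- ln1$out %*% P[[paste0(b, ".Wv")]] + rep(P[[paste0(b, ".bv")]], each = n)
  dh <- d %/% H
  A <- vector("list", H); O <- matrix(0, n, d)
  for (h in seq_len(H)) {
    cols <- (h - 1) * dh + seq_len(dh)
    Sc <- tcrossprod(q[, cols, drop = FALSE], k[, cols, drop = FALSE]) / sqrt(dh)
    Sc <- Sc - apply(Sc, 1, max)
    E <- exp(Sc)
    Ah <- E / rowSums(E)
    A[[h]] <- Ah
    O[, cols] <- Ah %*% v[, cols, drop = FALSE]
  }
  Op <- O %*% P[[paste0(b, ".Wo")]] + rep(P[[paste0(b, ".bo")]], each = n)
  T1 <- T0 + Op
  ln2 <- layernorm_fwd(T1, P[[paste0(b, ".g2")]], P[[paste0(b, ".b2")]])
  F1pre <- ln2$out %*% P[[paste0(b, ".Wf1")]] + rep(P[[paste0(b, ".bf1")]], each = n)
  sig <- 1 / (1 + exp(-F1pre))
  F1 <- F1pre * sig
  F2 <- F1 %*% P[[paste0(b, ".Wf2")]] + rep(P[[paste0(b, ".bf2")]], each = n)
  out <- T1 + F2
  list(out = out,
       cache = list(idx = idx, ln1 = ln1, ln2 = ln2, q = q, k = k, v = v,
                    A = A, O = O, F1pre = F1pre, sig = sig, F1 = F1,
                    n = n, d = d, H = H, pos_scale = pos_scale))
}

tblock_bwd <- function(b, cache, dOut, P, G) {
  n <- cache$n; d <- cache$d; H <- cache$H; dh <- d %/% H
  # feed-forward branch
  dT1 <- dOut
  dF2 <- dOut
  acc_grad(G, paste0(b, ".bf2"), colSums(dF2))
  acc_grad(G, paste0(b, ".Wf2"), crossprod(cache$F1, dF2))
  dF1 <- tcrossprod(dF2, P[[paste0(b, ".Wf2")]])
  dF1pre <- dF1 * (cache$sig * (1 + cache$F1pre * (1 - cache$sig)))
  acc_grad(G, paste0(b, ".bf1"), colSums(dF1pre))
  acc_grad(G, paste0(b, ".Wf1"), crossprod(cache$ln2$out, dF1pre))
  dln2 <- tcrossprod(dF1pre, P[[paste0(b, ".Wf1")]])
  l2 <- layernorm_bwd(cache$ln2, dln2, P[[paste0(b, ".g2")]])
  acc_grad(G, paste0(b, ".g2"), l2$dg); acc_grad(G, paste0(b, ".b2"), l2$db)
  dT1 <- dT1 + l2$dX
  # attention branch
  dT0 <- dT1
  dOp <- dT1
  acc_grad(G, paste0(b, ".bo"), colSums(dOp))
  acc_grad(G, paste0(b, ".Wo"), crossprod(cache$O, dOp))
  dO <- tcrossprod(dOp, P[[paste0(b, ".Wo")]])
  dq <- matrix(0, n, d); dk <- matrix(0, n, d); dv <- matrix(0, n, d)
  for (h in seq_len(H)) {
    cols <- (h - 1) * dh + seq_len(dh)
    Ah <- cache$A[[h]]
    dOh <- dO[, cols, drop = FALSE]
    dv[, cols] <- crossprod(Ah, dOh)
    dA <- tcrossprod(dOh, cache$v[, cols, drop = FALSE])
    dS <- Ah * (dA - rowSums(dA * Ah))
    dS <- dS / sqrt(dh)
    dq[, cols] <- dS %*% cache$k[, cols, drop = FALSE]
    dk[, cols] <- crossprod(dS, cache$q[, cols, drop = FALSE])
  }
  acc_grad(G, paste0(b, ".bq"), colSums(dq))
  acc_grad(G, paste0(b, ".bk"), colSums(dk))
  acc_grad(G, paste0(b, ".bv"), colSums(dv))
  acc_grad(G, paste0(b, ".Wq"), crossprod(cache$ln1$out, dq))
  acc_grad(G, paste0(b, ".Wk"), crossprod(cache$ln1$out, dk))
  acc_grad(G, paste0(b, ".Wv"), crossprod(cache$ln1$out, dv))
  dln1 <- tcrossprod(dq, P[[paste0(b, ".Wq")]]) +
          tcrossprod(dk, P[[paste0(b, ".Wk")]]) +
          tcrossprod(dv, P[[paste0(b, ".Wv")]])
  l1 <- layernorm_bwd(cache$ln1, dln1, P[[paste0(b, ".g1")]])
  acc_grad(G, paste0(b, ".g1"), l1$dg); acc_grad(G, paste0(b, ".b1"), l1$db)
  dT0 <- dT0 + l1$dX
  # positional embedding
  ps <- cache$pos_scale
  acc_grad(G, paste0(b, ".pw"), ps * as.numeric(crossprod(dT0, cache$idx)))
  acc_grad(G, paste0(b, ".pb"), ps * colSums(dT0))
  dT0
}

tstack_fwd <- function(mod, X, P, S, train) {
  acache <- NULL
  if (!is.null(mod$adapter)) {
    fa <- conv_fwd(mod$adapter, X, P, S, train)
    X <- fa$out; acache <- fa$cache
  }
  bcaches <- vector("list", mod$n)
  per_img <- X$h * X$w
  x <- X$x
  for (i in seq_len(mod$n)) {
    b <- mod$blocks[[i]]$id
    imcaches <- vector("list", X$b)
    newx <- x
    for (im in seq_len(X$b)) {
      rows <- (im - 1) * per_img + seq_len(per_img)
      Tk <- x[rows, , drop = FALSE]
      attr(Tk, "heads") <- mod$heads
      f <- tblock_fwd(b, Tk, P)
      newx[rows, ] <- f$out
      imcaches[[im]] <- f$cache
    }
    x <- newx
    bcaches[[i]] <- imcaches
  }
  list(out = fm(x, X$b, X$h, X$w),
       cache = list(adapter = acache, blocks = bcaches,
                    b = X$b, per_img = per_img))
}

tstack_bwd <- function(mod, cache, dY, P, G) {
  per_img <- cache$per_img
  dx <- dY
  for (i in rev(seq_len(mod$n))) {
    b <- mod$blocks[[i]]$id
    newdx <- dx
    for (im in seq_len(cache$b)) {
      rows <- (im - 1) * per_img + seq_len(per_img)
      newdx[rows, ] <- tblock_bwd(b, cache$blocks[[i]][[im]],
                                  dx[rows, , drop = FALSE], P, G)
    }
    dx <- newdx
  }
  if (!is.null(mod$adapter))
    conv_bwd(mod$adapter, cache$adapter, dx, P, G)
  else
    fm(dx, cache$b, NA, NA)
}

# ---- decoupled detection head ----------------------------------------------

nn_detect <- function(id, chs, nc, reg_max = 16) {
  nb <- 4L * (reg_max + 1L)
  cb <- max(16L, chs[1] %/% 4L, 4L * reg_max)
  cc <- max(chs[1], min(nc, 100L))
  scales <- lapply(seq_along(chs), function(i) {
    sid <- sprintf("%s.s%d", id, i)
    list(b1 = nn_conv(paste0(sid, ".b1"), chs[i], cb, 3),
         b2 = nn_conv(paste0(sid, ".b2"), cb, cb, 3),
         b3 = nn_conv(paste0(sid, ".b3"), cb, nb, 1, bn = FALSE, act = FALSE,
                      bias = TRUE, bias_init = "dfl_prior"),
         c1 = nn_conv(paste0(sid, ".c1"), chs[i], cc, 3),
         c2 = nn_conv(paste0(sid, ".c2"), cc, cc, 3),
         c3 = nn_conv(paste0(sid, ".c3"), cc, nc, 1, bn = FALSE, act = FALSE,
                      bias = TRUE, bias_init = -4.6))  # rare-object prior
  })
  specs <- unlist(lapply(scales, function(s)
    c(s$b1$pspecs, s$b2$pspecs, s$b3$pspecs,
      s$c1$pspecs, s$c2$pspecs, s$c3$pspecs)), recursive = FALSE)
  list(type = "detect", id = id, chs = chs, nc = nc, reg_max = reg_max,
       scales = scales, pspecs = specs)
}

detect_fwd <- function(mod, Xs, P, S, train) {
  outs <- vector("list", length(Xs))
  caches <- vector("list", length(Xs))
  for (i in seq_along(Xs)) {
    sc <- mod$scales[[i]]
    fb1 <- conv_fwd(sc$b1, Xs[[i]], P, S, train)
    fb2 <- conv_fwd(sc$b2, fb1$out, P, S, train)
    fb3 <- conv_fwd(sc$b3, fb2$out, P, S, train)
    fc1 <- conv_fwd(sc$c1, Xs[[i]], P, S, train)
    fc2 <- conv_fwd(sc$c2, fc1$out, P, S, train)
    fc3 <- conv_fwd(sc$c3, fc2$out, P, S, train)
    outs[[i]] <- list(box = fb3$out, cls = fc3$out)
    caches[[i]] <- list(b1 = fb1$cache, b2 = fb2$cache, b3 = fb3$cache,
                        c1 = fc1$cache, c2 = fc2$cache, c3 = fc3$cache)
  }
  list(out = outs, cache = caches)
}

detect_bwd <- function(mod, cache, dOuts, P, G) {
  dXs <- vector("list", length(dOuts))
  for (i in seq_along(dOuts)) {
    sc <- mod$scales[[i]]
    db2 <- conv_bwd(sc$b3, cache[[i]]$b3, dOuts[[i]]$box, P, G)
    db1 <- conv_bwd(sc$b2, cache[[i]]$b2, db2$x, P, G)
    dxb <- conv_bwd(sc$b1, cache[[i]]$b1, db1$x, P, G)
    dc2 <- conv_bwd(sc$c3, cache[[i]]$c3, dOuts[[i]]$cls, P, G)
    dc1 <- conv_bwd(sc$c2, cache[[i]]$c2, dc2$x, P, G)
    dxc <- conv_bwd(sc$c1, cache[[i]]$c1, dc1$x, P, G)
    dXs[[i]] <- fm(dxb$x + dxc$x, dxb$b, dxb$h, dxb$w)
  }
  dXs
}

# ---- generic node dispatch -------------------------------------------------

node_fwd <- function(mod, inputs, P, S, train) {
  switch(mod$type,
    conv = conv_fwd(mod, inputs[[1]], P, S, train),
    c2f = c2f_fwd(mod, inputs[[1]], P, S, train),
    sppf = sppf_fwd(mod, inputs[[1]], P, S, train),
    tstack = tstack_fwd(mod, inputs[[1]], P, S, train),
    upsample = {
      X <- inputs[[1]]
      list(out = fm(.upsample2(X$x, X$b, X$h, X$w), X$b, 2L * X$h, 2L * X$w),
           cache = list(b = X$b, h = X$h, w = X$w))
    },
    concat = {
      list(out = fm(do.call(cbind, lapply(inputs, `[[`, "x")),
                    inputs[[1]]$b, inputs[[1]]$h, inputs[[1]]$w),
           cache = list(cs = vapply(inputs, function(i) ncol(i$x), 0L),
                        b = inputs[[1]]$b, h = inputs[[1]]$h, w = inputs[[1]]$w))
    },
    detect = detect_fwd(mod, inputs, P, S, train),
    stop("unknown node type ", mod$type))
}

node_bwd <- function(mod, cache, dY, P, G) {
  switch(mod$type,
    conv = list(conv_bwd(mod, cache, dY$x, P, G)),
    c2f = list(c2f_bwd(mod, cache, dY$x, P, G)),
    sppf = list(sppf_bwd(mod, cache, dY$x, P, G)),
    tstack = list(tstack_bwd(mod, cache, dY$x, P, G)),
    upsample = list(fm(.upsample2_bwd(dY$x, cache$b, cache$h, cache$w),
                       cache$b, cache$h, cache$w)),
    concat = {
      cs <- cache$cs
      off <- c(0, cumsum(cs))
      lapply(seq_along(cs), function(i)
        fm(dY$x[, off[i] + seq_len(cs[i]), drop = FALSE],
           cache$b, cache$h, cache$w))
    },
    detect = detect_bwd(mod, cache, dY, P, G),
    stop("unknown node type ", mod$type))
}
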