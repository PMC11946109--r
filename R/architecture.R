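#' Detector model configuration
#'
#' Fully determines the detector graph and therefore its exact trainable
#' parameter count. The family follows the usual CSP-style single-stage
#' layout: a strided convolutional stem, four backbone stages of
#' (stride-2 convolution + C2f block), an optional SPPF pooling block,
#' a PAN-FPN neck fusing the stride-8/16/32 feature maps, and a decoupled
#' anchor-free head predicting `num_classes` class logits and
#' `4 * (reg_max + 1)` distribution-bin logits per location.
#'
#' `stage_depths` are the bottleneck counts of the four backbone C2f
#' stages — `c(3, 6, 6, 3)` for the large baseline, `c(6, 12, 12, 6)` for
#' the depth-rescaled variants. With `use_transformer = TRUE` the final
#' backbone stage becomes a stack of `trans_backbone_depth` transformer
#' blocks and every neck fusion block becomes a stack of
#' `trans_neck_depth` transformer blocks.
#'
#' @param num_classes number of object classes `C`.
#' @param stage_depths integer vector of 4 backbone bottleneck counts.
#' @param width_multiple channel scale factor applied to the base widths
#'   (64, 128, 256, 512, 1024), after capping at `max_channels`; results
#'   are rounded to multiples of 8.
#' @param max_channels channel cap applied before scaling.
#' @param neck_depth bottleneck count of each neck C2f fusion block.
#' @param use_transformer replace the final backbone stage and the neck
#'   fusion blocks with transformer stacks.
#' @param trans_backbone_depth,trans_neck_depth transformer blocks per
#'   stack in the backbone final stage / each neck fusion point.
#' @param trans_heads attention heads (must divide every fused channel
#'   count).
#' @param trans_ffn_ratio feed-forward expansion ratio of each transformer
#'   block.
#' @param reg_max upper distribution-bin index; each side is predicted over
#'   `reg_max + 1` bins.
#' @param use_sppf keep the SPPF pooling block at the end of the backbone.
#' @param input_size square input side in pixels (multiple of 32).
#' @return an object of class `"model_config"`.
#' @seealso [detector_preset()], [count_parameters()]
#' @export
model_config <- function(num_classes, stage_depths = c(3, 6, 6, 3),
                         width_multiple = 1, max_channels = 512,
                         neck_depth = 3, use_transformer = FALSE,
                         trans_backbone_depth = 6, trans_neck_depth = 2,
                         trans_heads = 4, trans_ffn_ratio = 1.85,
                         reg_max = 16, use_sppf = TRUE, input_size = 640) {
  if (length(stage_depths) != 4 || any(stage_depths < 1))
    stop("stage_depths must be 4 positive integers")
  if (num_classes < 1) stop("num_classes must be >= 1")
  if (input_size %% 32 != 0) stop("input_size must be a multiple of 32")
  ch <- scaled_channels(width_multiple, max_channels)
  if (any(ch <= 0)) stop("scaled channel counts must be positive")
  if (use_transformer && ch[5] %% trans_heads != 0)
    stop("final-stage channels must be divisible by trans_heads")
  structure(list(num_classes = as.integer(num_classes),
                 stage_depths = as.integer(stage_depths),
                 width_multiple = width_multiple,
                 max_channels = as.integer(max_channels),
                 neck_depth = as.integer(neck_depth),
                 use_transformer = use_transformer,
                 trans_backbone_depth = as.integer(trans_backbone_depth),
                 trans_neck_depth = as.integer(trans_neck_depth),
                 trans_heads = as.integer(trans_heads),
                 trans_ffn_ratio = trans_ffn_ratio,
                 reg_max = as.integer(reg_max),
                 use_sppf = use_sppf,
                 input_size = as.integer(input_size),
                 channels = ch),
            class = "model_config")
}

# base widths 64..1024 capped then scaled, rounded to a multiple of 8
scaled_channels <- function(width, max_channels) {
  base <- c(64, 128, 256, 512, 1024)
  vapply(base, function(c) {
    x <- min(c, max_channels) * width
    max(8L, as.integer(x + 4) %/% 8L * 8L)
  }, integer(1))
}

#' Named detector presets
#'
#' `"v8n"`, `"v8s"`, `"v8m"`, `"v8l"` are the standard nano/small/medium/
#' large baselines. `"tf-depth-only"` is the depth-rescaled variant
#' (backbone 6-12-12-6, conventional C2f neck) and `"tf-full"` additionally
#' replaces the final backbone stage and the neck fusion blocks with
#' transformer stacks; both use the committed calibration constants
#' (width 0.703125, channel cap 512, neck depth 2, 6 backbone / 2-per-fusion
#' transformer blocks, 4 heads, feed-forward ratio 1.85). `"micro"` is a
#' desk-scale preset (width 0.25, depths 1-1-1-1, 64 px input) for tests
#' and small experiments.
#'
#' @param name preset name.
#' @param num_classes number of classes.
#' @param ... overrides passed on to [model_config()].
#' @return a [model_config()].
#' @examples
#' count_parameters(detector_preset("v8s", num_classes = 121)) / 1e6
#' @export
detector_preset <- function(name = c("v8n", "v8s", "v8m", "v8l",
                                     "tf-depth-only", "tf-full", "micro"),
                            num_classes, ...) {
  name <- match.arg(name)
  args <- switch(name,
    "v8n" = list(stage_depths = c(1, 2, 2, 1), width_multiple = 0.25,
                 max_channels = 1024, neck_depth = 1),
    "v8s" = list(stage_depths = c(1, 2, 2, 1), width_multiple = 0.50,
                 max_channels = 1024, neck_depth = 1),
    "v8m" = list(stage_depths = c(2, 4, 4, 2), width_multiple = 0.75,
                 max_channels = 768, neck_depth = 2),
    "v8l" = list(stage_depths = c(3, 6, 6, 3), width_multiple = 1.0,
                 max_channels = 512, neck_depth = 3),
    "tf-depth-only" = list(stage_depths = c(6, 12, 12, 6),
                           width_multiple = 0.703125, max_channels = 512,
                           neck_depth = 2),
    "tf-full" = list(stage_depths = c(6, 12, 12, 6),
                     width_multiple = 0.703125, max_channels = 512,
                     neck_depth = 2, use_transformer = TRUE,
                     trans_backbone_depth = 6, trans_neck_depth = 2,
                     trans_heads = 4, trans_ffn_ratio = 1.85),
    "micro" = list(stage_depths = c(1, 1, 1, 1), width_multiple = 0.25,
                   max_channels = 1024, neck_depth = 1, input_size = 64))
  over <- list(...)
  args[names(over)] <- over
  do.call(model_config, c(list(num_classes = num_classes), args))
}

#' Build the detector graph
#'
#' Constructs the ordered node list of the detector (stem, backbone stages,
#' optional SPPF, top-down + bottom-up neck, decoupled head) without
#' allocating any weights; [init_detector()] attaches initialized
#' parameters.
#'
#' @param cfg a [model_config()].
#' @return an object of class `"fishdet_graph"`: list with `cfg`, `nodes`
#'   (each node a module plus its input ids; id 0 is the image), and the
#'   ids of the three neck outputs and the head.
#' @export
build_detector <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  ch <- cfg$channels
  nodes <- list()
  add <- function(mod, from) {
    nodes[[length(nodes) + 1]] <<- list(mod = mod, f = from)
    length(nodes)
  }
  nid <- function(i) sprintf("n%02d", i)
  d <- cfg$stage_depths
  i1 <- add(nn_conv(nid(1), 3L, ch[1], 3, 2), 0)
  i2 <- add(nn_conv(nid(2), ch[1], ch[2], 3, 2), i1)
  i3 <- add(nn_c2f(nid(3), ch[2], ch[2], d[1], TRUE), i2)
  i4 <- add(nn_conv(nid(4), ch[2], ch[3], 3, 2), i3)
  p3 <- add(nn_c2f(nid(5), ch[3], ch[3], d[2], TRUE), i4)
  i6 <- add(nn_conv(nid(6), ch[3], ch[4], 3, 2), p3)
  p4 <- add(nn_c2f(nid(7), ch[4], ch[4], d[3], TRUE), i6)
  i8 <- add(nn_conv(nid(8), ch[4], ch[5], 3, 2), p4)
  i9 <- if (cfg$use_transformer)
    add(nn_tstack(nid(9), ch[5], ch[5], cfg$trans_backbone_depth,
                  cfg$trans_heads, cfg$trans_ffn_ratio), i8)
  else
    add(nn_c2f(nid(9), ch[5], ch[5], d[4], TRUE), i8)
  p5 <- if (cfg$use_sppf) add(nn_sppf(nid(10), ch[5], ch[5]), i9) else i9

  fuse <- function(i, c1, c2, from) {
    if (cfg$use_transformer)
      add(nn_tstack(nid(i), c1, c2, cfg$trans_neck_depth,
                    cfg$trans_heads, cfg$trans_ffn_ratio), from)
    else
      add(nn_c2f(nid(i), c1, c2, cfg$neck_depth, FALSE), from)
  }
  u1 <- add(nn_upsample(nid(11)), p5)
  k1 <- add(nn_concat(nid(12), c(ch[5], ch[4])), c(u1, p4))
  t1 <- fuse(13, ch[5] + ch[4], ch[4], k1)
  u2 <- add(nn_upsample(nid(14)), t1)
  k2 <- add(nn_concat(nid(15), c(ch[4], ch[3])), c(u2, p3))
  n3 <- fuse(16, ch[4] + ch[3], ch[3], k2)
  dn1 <- add(nn_conv(nid(17), ch[3], ch[3], 3, 2), n3)
  k3 <- add(nn_concat(nid(18), c(ch[3], ch[4])), c(dn1, t1))
  n4 <- fuse(19, ch[3] + ch[4], ch[4], k3)
  dn2 <- add(nn_conv(nid(20), ch[4], ch[4], 3, 2), n4)
  k4 <- add(nn_concat(nid(21), c(ch[4], ch[5])), c(dn2, p5))
  n5 <- fuse(22, ch[4] + ch[5], ch[5], k4)
  hd <- add(nn_detect(nid(23), c(ch[3], ch[4], ch[5]), cfg$num_classes,
                      cfg$reg_max), c(n3, n4, n5))
  structure(list(cfg = cfg, nodes = nodes,
                 p_outs = c(n3, n4, n5), detect_id = hd),
            class = "fishdet_graph")
}

all_pspecs <- function(graph) {
  unlist(lapply(graph$nodes, function(n) n$mod$pspecs), recursive = FALSE)
}

#' Exact trainable parameter count
#'
#' Sums the sizes of every trainable tensor of the detector graph — all
#' convolution kernels and biases, batch-norm scales and shifts, and (when
#' enabled) transformer projection, positional-embedding, layer-norm and
#' feed-forward parameters. The count is a pure function of the
#' configuration: it does not depend on random seeds or input size.
#'
#' @param x a [model_config()], a [build_detector()] graph, a preset name,
#'   or a fitted model.
#' @param num_classes required when `x` is a preset name.
#' @param ... passed to [detector_preset()] when `x` is a name.
#' @return integer-valued numeric: number of trainable scalars.
#' @examples
#' count_parameters("v8s", num_classes = 121)
#' @export
count_parameters <- function(x, num_classes = NULL, ...) {
  if (is.character(x)) {
    if (is.null(num_classes)) stop("num_classes required with a preset name")
    x <- detector_preset(x, num_classes = num_classes, ...)
  }
  if (inherits(x, "fishdet")) return(n_params_spec(all_pspecs(x$graph)))
  if (inherits(x, "model_config")) x <- build_detector(x)
  stopifnot(inherits(x, "fishdet_graph"))
  n_params_spec(all_pspecs(x))
}

#' Structural stage listing of a detector graph
#'
#' @param graph a [build_detector()] graph.
#' @return data.frame with one row per node: id, type, input ids and
#'   parameter count.
#' @export
graph_summary <- function(graph) {
  stopifnot(inherits(graph, "fishdet_graph"))
  data.frame(
    id = seq_along(graph$nodes),
    type = vapply(graph$nodes, function(n) n$mod$type, ""),
    from = vapply(graph$nodes, function(n) paste(n$f, collapse = ","), ""),
    params = vapply(graph$nodes, function(n) n_params_spec(n$mod$pspecs), 0))
}

#' Initialize detector parameters
#'
#' Allocates every parameter tensor of the graph (Kaiming-normal
#' convolution kernels, unit batch-norm scales, zero biases except the
#' head's class-prior and box biases) plus the batch-norm running
#' statistics, reproducibly from the current RNG state.
#'
#' @param graph a [build_detector()] graph (or a [model_config()]).
#' @return list with environments `P` (parameters), `S` (running
#'   statistics) and the `graph`.
#' @export
init_detector <- function(graph) {
  if (inherits(graph, "model_config")) graph <- build_detector(graph)
  P <- new.env(parent = emptyenv())
  S <- new.env(parent = emptyenv())
  for (sp in all_pspecs(graph)) {
    P[[sp$name]] <- init_param(sp)
    if (endsWith(sp$name, ".g")) {  # batch-norm scale implies running stats
      id <- sub("\\.g$", "", sp$name)
      S[[paste0(id, ".rm")]] <- rep(0, sp$dims[1])
      S[[paste0(id, ".rv")]] <- rep(1, sp$dims[1])
    }
  }
  list(graph = graph, P = P, S = S)
}

#' Run the detector forward
#'
#' @param net result of [init_detector()].
#' @param X input feature map: list with `x` (`(B*H*W) x 3` matrix of
#'   RGB values in `[0, 1]`, rows batch-major then row-major), `b`, `h`,
#'   `w` — see [image_to_fm()].
#' @param train training mode (batch statistics; caches kept for the
#'   backward pass).
#' @return list with `head` (per-scale `box`/`cls` feature maps), `caches`
#'   and `outs` (when `train = TRUE`).
#' @export
forward_detector <- function(net, X, train = FALSE) {
  nodes <- net$graph$nodes
  outs <- vector("list", length(nodes))
  caches <- if (train) vector("list", length(nodes)) else NULL
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    inputs <- lapply(nd$f, function(j) if (j == 0) X else outs[[j]])
    r <- node_fwd(nd$mod, inputs, net$P, net$S, train)
    outs[[i]] <- r$out
    if (train) caches[[i]] <- r$cache
  }
  list(head = outs[[net$graph$detect_id]], caches = caches,
       outs = if (train) outs else NULL)
}

# Backward pass: dHead is the gradient w.r.t. the head outputs (per scale,
# list(box =, cls =) matrices). Accumulates parameter gradients into G.
backward_detector <- function(net, caches, dHead, G) {
  nodes <- net$graph$nodes
  douts <- vector("list", length(nodes))
  hd <- net$graph$detect_id
  douts[[hd]] <- dHead
  for (i in rev(seq_along(nodes))) {
    if (is.null(douts[[i]])) next
    nd <- nodes[[i]]
    dins <- node_bwd(nd$mod, caches[[i]], douts[[i]], net$P, G)
    for (j in seq_along(nd$f)) {
      src <- nd$f[j]
      if (src == 0) next
      douts[[src]] <- if (is.null(douts[[src]])) dins[[j]]
                      else fm(douts[[src]]$x + dins[[j]]$x,
                              dins[[j]]$b, dins[[j]]$h, dins[[j]]$w)
    }
    douts[[i]] <- NULL
  }
  invisible(NULL)
}

#' Convert images to the engine's feature-map format
#'
#' @param imgs a single `H x W x 3` array or a list of equally-sized
#'   arrays, values in `[0, 1]`.
#' @return a feature map (list with `x`, `b`, `h`, `w`) with rows ordered
#'   batch-major, then row-major within each image.
#' @export
image_to_fm <- function(imgs) {
  if (is.array(imgs) && length(dim(imgs)) == 3) imgs <- list(imgs)
  h <- dim(imgs[[1]])[1]; w <- dim(imgs[[1]])[2]
  x <- do.call(rbind, lapply(imgs, function(im) {
    # array is (row, col, channel) column-major; want row-major location rows
    matrix(aperm(im, c(2, 1, 3)), nrow = h * w, ncol = 3)
  }))
  fm(x, length(imgs), h, w)
}
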