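# Synthetic long-tailed underwater scenes: procedurally rendered stand-in
# for real reef-fish survey imagery, with controllable class imbalance,
# object scale, low foreground/background contrast, blur and bright
# "marine snow" particles.

#' Sample long-tailed per-class instance counts
#'
#' Draws per-class instance counts from a multinomial with rank-frequency
#' power-law probabilities `p_k` proportional to `k^(-gamma)` (class rank
#' `k = 1..C`), then moves instances from the richest classes so that every
#' class keeps at least one instance. `gamma = 0` is the uniform limit;
#' larger `gamma` yields a heavier head/tail imbalance.
#'
#' @param num_classes number of classes `C >= 1`.
#' @param gamma power-law decay exponent, `>= 0`.
#' @param total total instance count, `>= num_classes`.
#' @return integer vector of length `num_classes` summing to `total`,
#'   non-increasing in class rank on average.
#' @export
sample_class_counts <- function(num_classes, gamma, total) {
  if (num_classes < 1) stop("num_classes must be >= 1")
  if (gamma < 0) stop("gamma must be >= 0")
  if (total < num_classes) stop("total must be >= num_classes")
  p <- seq_len(num_classes)^(-gamma)
  counts <- as.integer(stats::rmultinom(1, total, p / sum(p)))
  while (any(counts == 0)) {
    zero <- which(counts == 0)
    for (z in zero) {
      donor <- which.max(counts)
      counts[donor] <- counts[donor] - 1L
      counts[z] <- 1L
    }
  }
  counts
}

# separable blur with edge-replicated padding
sep_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(2 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_apply <- function(x) {  # x: matrix, blur along columns
    n <- nrow(x)
    xp <- rbind(x[rep(1, r), , drop = FALSE], x, x[rep(n, r), , drop = FALSE])
    out <- stats::filter(xp, k, sides = 2)
    out[(r + 1):(r + n), , drop = FALSE]
  }
  t(pad_apply(t(pad_apply(m))))
}

# deterministic per-class visual style: hue around the colour wheel,
# aspect ratio, striping and tail shape vary with class id
class_style <- function(class_id) {
  k <- class_id
  list(hue = (0.05 + k * 0.6180339887) %% 1,
       sat = 0.45 + 0.25 * ((k * 7) %% 5) / 4,
       val = 0.45 + 0.2 * ((k * 3) %% 4) / 3,
       aspect = 1.6 + 0.25 * (k %% 5),
       stripes = k %% 3 == 1,
       tail_frac = 0.35 + 0.1 * (k %% 4))
}

#' Render one synthetic underwater scene
#'
#' Composites class-distinctive fish-like shapes (rotated ellipse body plus
#' triangular tail, class-specific hue, aspect ratio and striping) onto a
#' procedural low-contrast underwater background: a blue-green vertical
#' gradient with smooth colour noise, optional Gaussian blur, and bright
#' particles emulating suspended matter (marine snow). Instance placement
#' rejects positions whose box IoU with an already-placed instance exceeds
#' `max_occlusion_iou` (bounded retries; unplaceable instances are
#' dropped). Every rendered instance emits a tight box computed from its
#' foreground mask.
#'
#' @param instance_classes integer vector of 0-based class ids to render
#'   (possibly empty).
#' @param image_size square image side in pixels.
#' @param contrast object/background blend factor in `(0, 1]`: 1 = full
#'   object colour, small values sink objects into the background.
#' @param blur Gaussian blur sigma (pixels) applied to the composed scene.
#' @param particle_density particles per pixel (e.g. 0.002).
#' @param scale_range object semi-major axis range, fraction of image side.
#' @param max_occlusion_iou maximum allowed box IoU between instances.
#' @param max_retries placement attempts per instance.
#' @return list with `image` (`H x W x 3` array in `[0, 1]`) and `labels`
#'   (data.frame `class`, `cx`, `cy`, `w`, `h`, normalized center-size),
#'   plus attribute `dropped` (number of unplaceable instances).
#' @export
render_scene <- function(instance_classes, image_size = 64,
                         contrast = 0.35, blur = 0.8,
                         particle_density = 0.002,
                         scale_range = c(0.10, 0.18),
                         max_occlusion_iou = 0.3, max_retries = 30) {
  H <- image_size; W <- image_size
  # background: vertical blue-green gradient + smooth colour noise
  top <- c(0.05, 0.35, 0.45) + stats::runif(3, -0.03, 0.03)
  bot <- c(0.02, 0.18, 0.28) + stats::runif(3, -0.03, 0.03)
  img <- array(0, c(H, W, 3))
  for (c in 1:3) {
    grad <- matrix(seq(top[c], bot[c], length.out = H), H, W)
    noise <- sep_blur(matrix(stats::rnorm(H * W, 0, 1), H, W), H / 12)
    img[, , c] <- grad + 0.08 * noise
  }

  placed <- matrix(0, 0, 4)  # corner boxes, pixels
  labels <- data.frame(class = integer(), cx = numeric(), cy = numeric(),
                       w = numeric(), h = numeric())
  dropped <- 0L
  ix <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)   # pixel centres
  iy <- matrix(rep(seq_len(H) - 0.5, times = W), H, W)
  for (cl in instance_classes) {
    st <- class_style(cl)
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      a <- stats::runif(1, scale_range[1], scale_range[2]) * image_size
      b <- a / st$aspect
      tail_len <- st$tail_frac * a
      cx <- stats::runif(1, a + tail_len + 1, W - a - tail_len - 1)
      cy <- stats::runif(1, b + 2, H - b - 2)
      ang <- stats::runif(1, -0.35, 0.35)
      flip <- sample(c(-1, 1), 1)
      # body-frame coordinates
      u <- ((ix - cx) * cos(ang) + (iy - cy) * sin(ang)) * flip
      v <- -(ix - cx) * sin(ang) + (iy - cy) * cos(ang)
      mask <- (u / a)^2 + (v / b)^2 <= 1
      # triangular tail at the rear (u < -a side)
      tb <- 0.55 * b
      tailm <- u < -a * 0.85 & u > -a * 0.85 - tail_len &
        abs(v) <= tb * (u + a * 0.85 + tail_len) / tail_len
      mask <- mask | tailm
      if (!any(mask)) next
      cols <- range(which(colSums(mask) > 0))
      rows <- range(which(rowSums(mask) > 0))
      bb <- c(cols[1] - 1, rows[1] - 1, cols[2], rows[2])
      if (nrow(placed) &&
          any(box_iou_matrix(matrix(bb, 1), placed) > max_occlusion_iou))
        next
      # paint: class colour, banded value texture, blended with background
      col <- grDevices::col2rgb(grDevices::hsv(st$hue, st$sat, st$val)) / 255
      tex <- if (st$stripes) 0.75 + 0.25 * sin(u[mask] / (0.22 * a) * pi)
             else rep(1, sum(mask))
      for (c in 1:3) {
        ch <- img[, , c]
        ch[mask] <- (1 - contrast) * ch[mask] + contrast * col[c] * tex
        img[, , c] <- ch
      }
      placed <- rbind(placed, bb)
      cs <- as_center(matrix(bb, 1)) / image_size
      labels <- rbind(labels, data.frame(class = cl, cx = cs[1], cy = cs[2],
                                         w = cs[3], h = cs[4]))
      ok <- TRUE
      break
    }
    if (!ok) dropped <- dropped + 1L
  }

  if (blur > 0) for (c in 1:3) img[, , c] <- sep_blur(img[, , c], blur)
  # marine snow: small bright particles on top of the blur
  np <- stats::rpois(1, particle_density * H * W)
  if (np > 0) {
    px <- stats::runif(np, 1, W); py <- stats::runif(np, 1, H)
    pr <- stats::runif(np, 0.5, 1.5); pb <- stats::runif(np, 0.35, 0.8)
    for (i in seq_len(np)) {
      d2 <- (ix - px[i])^2 + (iy - py[i])^2
      spot <- exp(-d2 / (2 * pr[i]^2)) * pb[i]
      sel <- d2 < (3 * pr[i])^2
      for (c in 1:3) {
        ch <- img[, , c]
        ch[sel] <- ch[sel] + spot[sel]
        img[, , c] <- ch
      }
    }
  }
  img[img < 0] <- 0; img[img > 1] <- 1
  structure(list(image = img, labels = labels), dropped = dropped)
}

#' Generate a synthetic long-tailed detection dataset
#'
#' Draws a long-tailed class-instance distribution via
#' [sample_class_counts()], distributes the instances over images, and
#' renders every scene with [render_scene()]. Fully reproducible: the same
#' arguments and seed give bit-identical images and labels.
#'
#' @param num_classes number of species classes.
#' @param num_images number of images.
#' @param instances_per_image integer range (min, max) of instances drawn
#'   uniformly per image.
#' @param gamma power-law imbalance exponent (see [sample_class_counts()]).
#' @param image_size square image side (pixels).
#' @param seed integer seed (sets the R RNG).
#' @param ... rendering options passed to [render_scene()].
#' @return list with `images` (list of arrays), `labels` (list of
#'   data.frames), `class_names`, `counts` (drawn per-class instance
#'   counts) and the generating arguments in `spec`.
#' @export
synthetic_dataset <- function(num_classes = 12, num_images = 32,
                              instances_per_image = c(1, 4), gamma = 1.5,
                              image_size = 64, seed = 0, ...) {
  set.seed(seed)
  per_img <- sample(instances_per_image[1]:instances_per_image[2],
                    num_images, replace = TRUE)
  total <- sum(per_img)
  if (total < num_classes)
    stop("too few instances to cover every class; increase num_images")
  counts <- sample_class_counts(num_classes, gamma, total)
  pool <- sample(rep(seq_len(num_classes) - 1L, counts))
  images <- vector("list", num_images)
  labels <- vector("list", num_images)
  off <- 0
  for (i in seq_len(num_images)) {
    cls <- pool[seq_len(per_img[i]) + off]
    off <- off + per_img[i]
    sc <- render_scene(cls, image_size = image_size, ...)
    images[[i]] <- sc$image
    labels[[i]] <- sc$labels
  }
  list(images = images, labels = labels,
       class_names = sprintf("species_%03d", seq_len(num_classes) - 1L),
       counts = counts,
       spec = list(num_classes = num_classes, num_images = num_images,
                   instances_per_image = instances_per_image, gamma = gamma,
                   image_size = image_size, seed = seed))
}

#' Read and write YOLO-format label files
#'
#' One line per instance: `class cx cy w h` with 0-based integer class and
#' normalized center-size coordinates printed to 6 decimals.
#' `read_yolo_labels()` validates the format and, when a class count is
#' supplied, the class-id range, reporting offending line numbers.
#'
#' @param labels data.frame with columns `class`, `cx`, `cy`, `w`, `h`
#'   (normalized).
#' @param path label file path.
#' @param num_classes optional declared number of classes for validation.
#' @return `read_yolo_labels()` returns the label data.frame.
#' @export
write_yolo_labels <- function(labels, path) {
  if (nrow(labels) &&
      any(labels[, c("cx", "cy", "w", "h")] < -1e-9 |
            labels[, c("cx", "cy", "w", "h")] > 1 + 1e-9))
    stop("normalized coordinates must lie in [0, 1]")
  lines <- if (nrow(labels) == 0) character(0)
  else sprintf("%d %.6f %.6f %.6f %.6f", labels$class,
               labels$cx, labels$cy, labels$w, labels$h)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_yolo_labels
#' @export
read_yolo_labels <- function(path, num_classes = NULL) {
  lines <- readLines(path)
  out <- data.frame(class = integer(), cx = numeric(), cy = numeric(),
                    w = numeric(), h = numeric())
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) next
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(parts) != 5 || any(is.na(vals)) || vals[1] != round(vals[1]))
      stop(sprintf("malformed label line %d in %s: '%s'", i, path, lines[i]))
    if (!is.null(num_classes) && (vals[1] < 0 || vals[1] >= num_classes))
      stop(sprintf("class id %d out of range on line %d in %s",
                   vals[1], i, path))
    out <- rbind(out, data.frame(class = as.integer(vals[1]), cx = vals[2],
                                 cy = vals[3], w = vals[4], h = vals[5]))
  }
  out
}

#' Export a dataset as COCO-format detection JSON
#'
#' @param dataset a [synthetic_dataset()] (or compatible list with
#'   `images`, `labels`, `class_names` and `spec$image_size`).
#' @param path output JSON file.
#' @param file_names optional image file names (defaults to
#'   `img_%05d.png`).
#' @return the path, invisibly.
#' @export
export_coco_json <- function(dataset, path, file_names = NULL) {
  sz <- dataset$spec$image_size
  n <- length(dataset$images)
  if (is.null(file_names)) file_names <- sprintf("img_%05d.png", seq_len(n))
  images <- lapply(seq_len(n), function(i)
    list(id = i, file_name = file_names[i], width = sz, height = sz))
  anns <- list(); aid <- 0
  for (i in seq_len(n)) {
    lab <- dataset$labels[[i]]
    if (!nrow(lab)) next
    corner <- as_corner(cbind(lab$cx, lab$cy, lab$w, lab$h)) * sz
    for (j in seq_len(nrow(lab))) {
      aid <- aid + 1
      bw <- corner[j, 3] - corner[j, 1]; bh <- corner[j, 4] - corner[j, 2]
      anns[[aid]] <- list(id = aid, image_id = i,
                          category_id = lab$class[j] + 1L,
                          bbox = c(corner[j, 1], corner[j, 2], bw, bh),
                          area = bw * bh, iscrowd = 0L)
    }
  }
  cats <- lapply(seq_along(dataset$class_names), function(i)
    list(id = i, name = dataset$class_names[i]))
  jsonlite::write_json(list(images = images, annotations = anns,
                            categories = cats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Import COCO-format detection JSON back into label tables
#'
#' @param path COCO JSON file.
#' @return list with `labels` (per-image normalized label data.frames in
#'   image-id order), `class_names` and `image_size`.
#' @export
import_coco_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  sz <- j$images$width[1]
  n <- nrow(j$images)
  labels <- rep(list(data.frame(class = integer(), cx = numeric(),
                                cy = numeric(), w = numeric(),
                                h = numeric())), n)
  if (NROW(j$annotations)) {
    bb <- do.call(rbind, j$annotations$bbox)
    corner <- cbind(bb[, 1], bb[, 2], bb[, 1] + bb[, 3], bb[, 2] + bb[, 4])
    cs <- as_center(corner) / sz
    for (k in seq_len(nrow(cs))) {
      i <- j$annotations$image_id[k]
      labels[[i]] <- rbind(labels[[i]],
                           data.frame(class = j$annotations$category_id[k] - 1L,
                                      cx = cs[k, 1], cy = cs[k, 2],
                                      w = cs[k, 3], h = cs[k, 4]))
    }
  }
  list(labels = labels, class_names = j$categories$name, image_size = sz)
}

#' Write a dataset to disk in the YOLO directory layout
#'
#' Creates `images/{train,val,test}` (PNG) and `labels/{train,val,test}`
#' (YOLO text labels) under `dir`, plus a `dataset.yaml` naming the class
#' list and split directories. Images are split 70/15/15 by default,
#' stratified so that every class appearing in the dataset occurs in the
#' training split (images containing a missing class are swapped in).
#'
#' @param dataset a [synthetic_dataset()].
#' @param dir output directory.
#' @param split named fractions for train/val/test.
#' @param write_images write PNG images (labels are always written).
#' @return invisibly, a list with the image indices of each split and the
#'   path of the dataset YAML.
#' @export
write_dataset_dir <- function(dataset, dir,
                              split = c(train = 0.7, val = 0.15, test = 0.15),
                              write_images = TRUE) {
  n <- length(dataset$images)
  ntr <- max(1, round(split[["train"]] * n))
  nva <- max(0, round(split[["val"]] * n))
  ord <- sample.int(n)
  idx <- list(train = sort(ord[seq_len(ntr)]),
              val = sort(ord[ntr + seq_len(min(nva, n - ntr))]),
              test = sort(ord[setdiff(seq_len(n), seq_len(ntr + nva))]))
  idx$test <- sort(setdiff(seq_len(n), c(idx$train, idx$val)))
  # stratify: every class present anywhere must appear in train
  cls_of <- function(i) unique(dataset$labels[[i]]$class)
  all_cls <- sort(unique(unlist(lapply(seq_len(n), cls_of))))
  for (cl in all_cls) {
    if (cl %in% unlist(lapply(idx$train, cls_of))) next
    donor_pool <- c(idx$val, idx$test)
    donor <- donor_pool[vapply(donor_pool, function(i) cl %in% cls_of(i), TRUE)][1]
    victim <- idx$train[1]
    idx$val <- sort(c(setdiff(idx$val, donor), victim))
    idx$train <- sort(c(setdiff(idx$train, victim), donor))
  }
  for (sp in names(idx)) {
    dir.create(file.path(dir, "images", sp), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(dir, "labels", sp), recursive = TRUE,
               showWarnings = FALSE)
    for (i in idx[[sp]]) {
      stem <- sprintf("img_%05d", i)
      if (write_images)
        png::writePNG(dataset$images[[i]],
                      file.path(dir, "images", sp, paste0(stem, ".png")))
      write_yolo_labels(dataset$labels[[i]],
                        file.path(dir, "labels", sp, paste0(stem, ".txt")))
    }
  }
  ypath <- file.path(dir, "dataset.yaml")
  yaml::write_yaml(list(path = normalizePath(dir),
                        train = "images/train", val = "images/val",
                        test = "images/test",
                        names = as.list(dataset$class_names)), ypath)
  invisible(list(splits = idx, yaml = ypath))
}
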