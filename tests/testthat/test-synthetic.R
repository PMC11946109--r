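test_that("class counts conserve totals and keep every class populated", {
  set.seed(31)
  for (i in 1:20) {
    C <- sample(2:30, 1)
    total <- C + sample(0:500, 1)
    cnt <- sample_class_counts(C, runif(1, 0, 2.5), total)
    expect_equal(sum(cnt), total)
    expect_true(all(cnt >= 1))
  }
  expect_error(sample_class_counts(10, 1, 5), "total")
  expect_error(sample_class_counts(0, 1, 5), "num_classes")
})

test_that("gamma = 0 gives approximately uniform counts", {
  set.seed(32)
  cnt <- sample_class_counts(10, 0, 10000)
  p <- stats::chisq.test(cnt)$p.value
  expect_gt(p, 0.01)
})

test_that("gamma = 1.5 yields a strong head/tail ratio, deterministically", {
  set.seed(33)
  cnt <- sample_class_counts(12, 1.5, 1000)
  set.seed(33)
  cnt2 <- sample_class_counts(12, 1.5, 1000)
  expect_identical(cnt, cnt2)
  expect_gt(max(cnt) / min(cnt), 10)
})

test_that("rank-frequency slope tracks the requested power law", {
  set.seed(34)
  cnt <- sample_class_counts(50, 1.5, 50000)
  fit <- stats::lm(log(cnt) ~ log(seq_along(cnt)))
  expect_equal(unname(stats::coef(fit)[2]), -1.5, tolerance = 0.2)
})

test_that("rendering emits tight labels on a valid low-contrast scene", {
  set.seed(35)
  sc <- render_scene(c(0L, 1L, 2L), image_size = 64)
  expect_equal(dim(sc$image), c(64, 64, 3))
  expect_true(all(sc$image >= 0 & sc$image <= 1))
  expect_lte(nrow(sc$labels), 3)
  expect_true(all(sc$labels[, c("cx", "cy", "w", "h")] >= 0 &
                    sc$labels[, c("cx", "cy", "w", "h")] <= 1))
  expect_true(all(sc$labels$w > 0 & sc$labels$h > 0))
  # empty scene
  sc0 <- render_scene(integer(0), image_size = 64)
  expect_equal(nrow(sc0$labels), 0)
  expect_equal(dim(sc0$image), c(64, 64, 3))
})

test_that("object/background contrast increases with the contrast setting", {
  box_contrast <- function(sc) {
    img_gray <- (sc$image[, , 1] + sc$image[, , 2] + sc$image[, , 3]) / 3
    bgmed <- stats::median(img_gray)
    vals <- numeric(0)
    for (j in seq_len(nrow(sc$labels))) {
      b <- as_corner(as.matrix(sc$labels[j, 2:5])) * 64
      rows <- max(1, floor(b[2]) + 1):min(64, ceiling(b[4]))
      cols <- max(1, floor(b[1]) + 1):min(64, ceiling(b[3]))
      vals <- c(vals, mean(abs(img_gray[rows, cols] - bgmed)))
    }
    mean(vals)
  }
  set.seed(36)
  hi <- render_scene(c(0L, 1L), image_size = 64, contrast = 0.9,
                     blur = 0, particle_density = 0)
  set.seed(36)
  lo <- render_scene(c(0L, 1L), image_size = 64, contrast = 0.15,
                     blur = 0, particle_density = 0)
  expect_gt(box_contrast(hi), box_contrast(lo))
})

test_that("dataset generation is reproducible and long-tailed end to end", {
  d1 <- tiny_dataset(seed = 37)
  d2 <- tiny_dataset(seed = 37)
  expect_identical(d1$labels, d2$labels)
  expect_identical(d1$images, d2$images)
  d3 <- tiny_dataset(seed = 38)
  expect_false(identical(d1$labels, d3$labels))
  # the generated distribution feeds the class-aware weights directly:
  # tail classes get strictly larger weights at eta > 1
  ds <- synthetic_dataset(num_classes = 8, num_images = 24, gamma = 1.5,
                          seed = 39)
  dist <- class_distribution_from_labels(ds$labels, 8)
  w <- class_aware_weight(dist$counts, dist$n, eta = 8, num_classes = 8)
  expect_gt(w[which.min(dist$counts)], w[which.max(dist$counts)])
})

test_that("YOLO label files round-trip and validate", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  set.seed(40)
  lab <- data.frame(class = sample(0:9, 1000, TRUE),
                    cx = runif(1000), cy = runif(1000),
                    w = runif(1000), h = runif(1000))
  write_yolo_labels(lab, tmp)
  back <- read_yolo_labels(tmp, num_classes = 10)
  expect_equal(nrow(back), 1000)
  expect_lt(max(abs(as.matrix(back[, 2:5]) - as.matrix(lab[, 2:5]))), 1e-6)
  expect_identical(back$class, lab$class)
  # empty list -> empty file -> empty read
  write_yolo_labels(lab[0, ], tmp)
  expect_equal(nrow(read_yolo_labels(tmp)), 0)
  # malformed content reports the line number
  writeLines(c("0 0.5 0.5 0.1 0.1", "1 0.2 oops 0.1 0.1"), tmp)
  expect_error(read_yolo_labels(tmp), "line 2")
  writeLines("12 0.5 0.5 0.1 0.1", tmp)
  expect_error(read_yolo_labels(tmp, num_classes = 10), "out of range")
})

test_that("COCO export round-trips boxes, counts and categories", {
  ds <- tiny_dataset(seed = 41)
  tmp <- withr::local_tempfile(fileext = ".json")
  export_coco_json(ds, tmp)
  j <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(nrow(j$annotations), sum(vapply(ds$labels, nrow, 0L)))
  expect_equal(nrow(j$categories), 3)
  expect_true(all(j$annotations$bbox |> vapply(function(b) b[3] * b[4], 0) > 0))
  back <- import_coco_json(tmp)
  expect_equal(back$class_names, ds$class_names)
  for (i in seq_along(ds$labels)) {
    if (!nrow(ds$labels[[i]])) next
    expect_lt(max(abs(as.matrix(back$labels[[i]][, 2:5]) -
                        as.matrix(ds$labels[[i]][, 2:5]))), 1e-4)
    expect_equal(back$labels[[i]]$class, ds$labels[[i]]$class)
  }
})

test_that("dataset directories carry stratified splits and byte-stable labels", {
  ds <- synthetic_dataset(num_classes = 4, num_images = 12, gamma = 1,
                          seed = 42)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  set.seed(1); write_dataset_dir(ds, dir1)
  set.seed(1); write_dataset_dir(ds, dir2)
  f1 <- list.files(file.path(dir1, "labels"), recursive = TRUE,
                   full.names = TRUE)
  f2 <- list.files(file.path(dir2, "labels"), recursive = TRUE,
                   full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  for (k in seq_along(f1))
    expect_identical(readLines(f1[k]), readLines(f2[k]))
  # every class present in the dataset appears in the training split
  train_labels <- lapply(list.files(file.path(dir1, "labels", "train"),
                                    full.names = TRUE), read_yolo_labels)
  all_cls <- sort(unique(unlist(lapply(ds$labels, function(l) l$class))))
  expect_true(all(all_cls %in% unlist(lapply(train_labels,
                                             function(l) l$class))))
  y <- yaml::read_yaml(file.path(dir1, "dataset.yaml"))
  expect_equal(unlist(y$names), ds$class_names)
})
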