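# Synthetic farmland scenes, augmentation, splitting, image statistics

test_that("scene generation is byte-identical under the same seed", {
  spec <- scene_spec(imgsz = 48L)
  a <- generate_scene(spec, seed = 123L)
  b <- generate_scene(spec, seed = 123L)
  expect_identical(a, b)
  c2 <- generate_scene(spec, seed = 124L)
  expect_false(identical(a$image, c2$image))
})

test_that("every instance has a nonempty in-bounds mask and a closed polygon", {
  for (sc in make_scenes(10L, imgsz = 48L, seed = 5L)) {
    for (a in sc$annotations) {
      expect_gte(sum(a$mask), 4L)
      expect_true(all(a$polygon >= 0 & a$polygon <= 48))
      expect_true(a$class_id %in% 0:7)
      expect_equal(dim(a$mask), c(48L, 48L))
    }
  }
})

test_that("class proportions over many scenes track the configured imbalance", {
  set.seed(31)
  spec <- scene_spec(imgsz = 40L)
  counts <- numeric(8)
  for (i in 1:1000) {
    sc <- generate_scene(spec)
    cl <- vapply(sc$annotations, `[[`, 0, "class_id")
    counts <- counts + tabulate(cl + 1L, 8L)
  }
  props <- counts / sum(counts)
  expect_true(all(abs(props - SYNTH_PROPS) < 0.02))
  expect_lt(props[8], 0.05)  # "people" stay a rare class
})

test_that("augmentation emits the four variants with consistent annotations", {
  sc <- make_scenes(1L, imgsz = 32L, seed = 2L)[[1]]
  out <- augment(sc$image, sc$annotations)
  expect_length(out, 4L)
  expect_equal(vapply(out, `[[`, "", "variant"),
               c("original", "contrast", "noise", "flip"))
  # flip applied twice is the identity on image and annotations
  fl <- out[[4L]]
  back <- augment(fl$image, fl$annotations)[[4L]]
  expect_equal(back$image, sc$image, tolerance = 1e-12)
  for (i in seq_along(sc$annotations)) {
    expect_equal(back$annotations[[i]]$polygon, sc$annotations[[i]]$polygon)
    expect_identical(back$annotations[[i]]$mask, sc$annotations[[i]]$mask)
  }
})

test_that("linear contrast maps 0.4 to 0.35 around an image mean of 0.5", {
  img <- array(0.5, dim = c(8, 8, 3))
  img[1, 1, 1] <- 0.4
  img[1, 2, 1] <- 0.6  # keep the mean at exactly 0.5
  out <- augment(img, list())[[2L]]$image
  expect_equal(out[1, 1, 1], 0.35, tolerance = 1e-12)
  expect_equal(out[1, 2, 1], 0.65, tolerance = 1e-12)
  expect_equal(out[3, 3, 2], 0.5, tolerance = 1e-12)
})

test_that("the noise variant has the folded-normal mean absolute deviation", {
  set.seed(77)
  img <- array(runif(640 * 640 * 3, 0.25, 0.75), dim = c(640, 640, 3))
  out <- augment(img, list())[[3L]]$image
  mad <- mean(abs(out - img))
  expect_equal(mad, 0.1 * sqrt(2 / pi), tolerance = 0.05 * 0.0798)
})

test_that("dataset splitting: exact floor sizes, conservation, leak-free grouping", {
  s <- split_dataset(1:10, c(7, 2, 1), seed = 1L)
  expect_equal(lengths(s), c(train = 7L, val = 2L, test = 1L))
  big <- split_dataset(seq_len(2372), c(7, 2, 1), seed = 2L)
  expect_equal(sum(lengths(big)), 2372L)
  expect_equal(sort(unname(unlist(big))), seq_len(2372))
  # grouped items never straddle a split
  src <- rep(seq_len(40), each = 4L)
  for (seed in 1:100) {
    sp <- split_dataset(seq_len(160), c(7, 2, 1), seed = seed, source = src)
    for (part in sp) {
      touched <- unique(src[part])
      expect_true(all(table(factor(src[part], levels = touched)) == 4L))
    }
  }
  expect_error(split_dataset(1:2, c(7, 2, 1)), "fewer")
  expect_error(split_dataset(1:10, c(7, -1, 1)), "positive")
})

test_that("pixel histograms: point mass, unit area, flip invariance", {
  img <- array(100.4 / 255, dim = c(6, 6, 3))
  h <- pixel_histogram(img)
  expect_equal(which(h$raw > 0), 101L)  # level 100 (0-based)
  expect_equal(sum(h$raw), 1)
  expect_equal(sum(h$density), 1, tolerance = 1e-6)
  set.seed(4)
  img2 <- array(runif(12 * 12 * 3), dim = c(12, 12, 3))
  expect_equal(pixel_histogram(img2)$density,
               pixel_histogram(img2[, 12:1, , drop = FALSE])$density)
})

test_that("gradient magnitudes: zero on constants, flip-invariant, linear in contrast", {
  flat <- array(0.5, dim = c(16, 16, 3))
  expect_true(all(gradient_magnitude_distribution(flat)$magnitudes == 0))
  set.seed(5)
  img <- array(runif(24 * 24 * 3, 0.3, 0.7), dim = c(24, 24, 3))
  g1 <- gradient_magnitude_distribution(img)
  g2 <- gradient_magnitude_distribution(img[, 24:1, , drop = FALSE])
  expect_equal(sort(as.vector(g1$magnitudes)), sort(as.vector(g2$magnitudes)),
               tolerance = 1e-12)
  expect_equal(sum(g1$density), 1)
  # gain 1.5 about the mean without clipping scales every magnitude by 1.5
  mu <- mean(img)
  boosted <- mu + 1.5 * (img - mu)
  g3 <- gradient_magnitude_distribution(boosted)
  expect_equal(g3$magnitudes, 1.5 * g1$magnitudes, tolerance = 1e-12)
})

test_that("PCA embedding matches a dense eigendecomposition up to sign", {
  set.seed(6)
  X <- matrix(rnorm(20 * 8), 20)
  emb <- pca_embedding(X)
  expect_gte(emb$var_share[1], emb$var_share[2])
  ev <- eigen(stats::cov(X))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ref <- Xc %*% ev$vectors[, 1:2]
  for (k in 1:2) {
    same <- max(abs(emb$points[, k] - ref[, k]))
    flip <- max(abs(emb$points[, k] + ref[, k]))
    expect_lt(min(same, flip), 1e-8)
  }
  # duplicated points embed at the same location
  X2 <- rbind(X, X[1, , drop = FALSE])
  e2 <- pca_embedding(X2)
  expect_equal(e2$points[1, ], e2$points[21, ], tolerance = 1e-10)
  expect_error(pca_embedding(matrix(1, 5, 3)), "zero-variance")
})

test_that("feature extraction is deterministic and does not disturb the RNG stream", {
  scenes <- make_scenes(4L, imgsz = 32L, seed = 9L)
  imgs <- lapply(scenes, `[[`, "image")
  set.seed(1); before <- runif(1)
  f1 <- image_features(imgs)
  f2 <- image_features(imgs)
  expect_identical(f1, f2)
  set.seed(1); expect_identical(runif(1), before)
})

test_that("labels round-trip through the polygon text format", {
  sc <- make_scenes(1L, imgsz = 64L, seed = 11L)[[1]]
  tmp <- tempfile(fileext = ".txt")
  write_yolo_labels(sc$annotations, tmp, 64L)
  back <- read_yolo_labels(tmp, 64L)
  expect_length(back, length(sc$annotations))
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$class_id, sc$annotations[[i]]$class_id)
    expect_equal(back[[i]]$polygon, sc$annotations[[i]]$polygon,
                 tolerance = 64 * 1e-6 * 2)
    # re-rasterization reproduces the mask up to coordinate quantization
    m2 <- polygon_to_mask(back[[i]]$polygon, 64L)
    expect_gt(mask_iou(m2, sc$annotations[[i]]$mask), 0.98)
  }
})

test_that("a written dataset reads back with images, labels and manifest splits", {
  scenes <- make_scenes(3L, imgsz = 32L, seed = 12L)
  aug <- augment_dataset(scenes)
  expect_length(aug, 12L)
  sp <- split_dataset(seq_along(aug), seed = 3L,
                      source = vapply(aug, `[[`, 0L, "source"))
  dir <- file.path(tempdir(), "fsdata")
  man <- write_dataset(aug, dir, splits = sp)
  expect_true(file.exists(man))
  tr <- read_dataset(man, "train")
  expect_length(tr, length(sp$train))
  expect_equal(dim(tr[[1]]$image), c(32L, 32L, 3L))
  expect_gte(length(tr[[1]]$annotations), 1L)
  unlink(dir, recursive = TRUE)
})
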