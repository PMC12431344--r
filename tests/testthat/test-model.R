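# Model assembly, forward contract, decoding, NMS, mask composition

fake_raw <- function(H, cls_logits, box_logits = NULL, coef = NULL,
                     proto = NULL, stride = 8L, nc = 2L, npm = 4L) {
  imgsz <- H * stride
  if (is.null(box_logits)) box_logits <- array(0, dim = c(H, H, 64L, 1L))
  if (is.null(coef)) coef <- array(0, dim = c(H, H, npm, 1L))
  if (is.null(proto)) proto <- array(0, dim = c(imgsz / 4L, imgsz / 4L, npm, 1L))
  structure(list(box = list(box_logits), cls = list(cls_logits),
                 coef = list(coef), proto = proto,
                 strides = stride, imgsz = imgsz),
            class = "farmseg_raw")
}

test_that("head count and grid sizes follow variant and input size", {
  for (v in c("baseline", "p2", "p2_cpca", "p2_cpca1", "full")) {
    cfg <- variant_config(v)
    nscale <- if (v == "baseline") 3L else 4L
    expect_length(cfg$strides, nscale)
    for (S in c(160L, 320L, 640L)) {
      g <- grid_sizes(cfg, S)
      expect_equal(g$grids, S / cfg$strides)
    }
  }
  expect_equal(grid_sizes(variant_config("full"), 640L)$grids,
               c(160L, 80L, 40L, 20L))
  expect_error(grid_sizes(variant_config(), 100L), "multiple of 32")
})

test_that("forward emits per-scale grids and prototype maps with the stride contract", {
  set.seed(1)
  m <- build_model(variant_config("full"))
  raw <- forward(m, array(runif(160 * 160 * 3), dim = c(160, 160, 3)))
  expect_equal(vapply(raw$cls, function(x) dim(x)[1], 0L), c(40L, 20L, 10L, 5L))
  expect_equal(vapply(raw$box, function(x) dim(x)[3], 0L), rep(64L, 4L))
  expect_equal(dim(raw$proto)[1:3], c(80L, 80L, 32L))
  mb <- build_model(variant_config("baseline"))
  rb <- forward(mb, array(runif(160 * 160 * 3), dim = c(160, 160, 3)))
  expect_equal(vapply(rb$cls, function(x) dim(x)[1], 0L), c(20L, 10L, 5L))
  expect_equal(dim(rb$proto)[1:3], c(40L, 40L, 32L))
})

test_that("seeded builds are identical and batches are image-independent", {
  set.seed(99); m1 <- build_model(variant_config("baseline"))
  set.seed(99); m2 <- build_model(variant_config("baseline"))
  p1 <- param_list(m1); p2 <- param_list(m2)
  expect_equal(lapply(p1, `[[`, "value"), lapply(p2, `[[`, "value"))
  img <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  two <- array(c(img, img), dim = c(64, 64, 3, 2))
  raw <- forward(m1, two)
  expect_equal(raw$cls[[1]][, , , 1], raw$cls[[1]][, , , 2], tolerance = 1e-12)
})

test_that("decode returns nothing when every class logit is hopeless", {
  raw <- fake_raw(4L, array(-30, dim = c(4, 4, 2, 1)))
  expect_length(decode_and_nms(raw), 0L)
})

test_that("a single dominant cell yields exactly one instance at the decoded box", {
  cls <- array(-30, dim = c(4, 4, 2, 1))
  cls[2, 3, 1, 1] <- 4                       # one confident cell, class 0
  box <- array(0, dim = c(4, 4, 64, 1))
  for (side in 1:4) box[2, 3, (side - 1) * 16 + 2, 1] <- 50  # distance = 1 stride
  proto <- array(10, dim = c(8, 8, 4, 1))
  coef <- array(1, dim = c(4, 4, 4, 1))
  raw <- fake_raw(4L, cls, box, coef, proto)
  det <- decode_and_nms(raw, conf_thresh = 0.25)
  expect_length(det, 1L)
  d <- det[[1]]
  expect_equal(d$class_id, 0L)
  # cell (row 2, col 3): center (20, 12), distances 1 stride each side
  expect_equal(d$box, c(12, 4, 28, 20), tolerance = 1e-6)
  expect_gt(d$score, 0.95)
  expect_true(all(dim(d$mask) == 32L))
  # mask support confined to the box
  on <- which(d$mask == 1L, arr.ind = TRUE)
  expect_true(all(on[, 2] >= 13 & on[, 2] <= 28))
  expect_true(all(on[, 1] >= 5 & on[, 1] <= 20))
})

test_that("class-wise NMS matches the all-pairs suppression oracle", {
  set.seed(42)
  for (case in 1:10) {
    n <- 20L
    x1 <- runif(n, 0, 80); y1 <- runif(n, 0, 80)
    boxes <- cbind(x1, y1, x1 + runif(n, 5, 40), y1 + runif(n, 5, 40))
    scores <- runif(n)
    keep <- farmseg:::nms_class(boxes, scores, 0.5)
    expect_equal(sort(keep), sort(nms_oracle(boxes, scores, 0.5)))
  }
})

test_that("decoded instances are sorted by score and masks stay in bounds", {
  set.seed(3)
  cls <- array(rnorm(6 * 6 * 2) * 2, dim = c(6, 6, 2, 1))
  box <- array(rnorm(6 * 6 * 64), dim = c(6, 6, 64, 1))
  coef <- array(rnorm(6 * 6 * 4), dim = c(6, 6, 4, 1))
  proto <- array(rnorm(12 * 12 * 4), dim = c(12, 12, 4, 1))
  raw <- fake_raw(6L, cls, box, coef, proto)
  det <- decode_and_nms(raw, conf_thresh = 0.1)
  sc <- vapply(det, `[[`, 0, "score")
  expect_true(all(diff(sc) <= 1e-12))
  for (d in det) {
    expect_true(all(d$box >= 0 & d$box <= raw$imgsz))
    expect_equal(dim(d$mask), c(raw$imgsz, raw$imgsz))
  }
})

test_that("mask composition follows the per-pixel prototype arithmetic", {
  set.seed(4)
  proto <- array(rnorm(8 * 8 * 4), dim = c(8, 8, 4))
  co <- rnorm(4)
  full <- c(0, 0, 32, 32)
  m <- compose_masks(proto, co, full, 32L)
  # per-pixel oracle at prototype resolution
  ref <- matrix(0L, 8, 8)
  for (i in 1:8) for (j in 1:8)
    ref[i, j] <- as.integer(plogis(sum(proto[i, j, ] * co)) > 0.5)
  idx <- rep(1:8, each = 4)
  expect_equal(m, ref[idx, idx])
  # all-zero coefficients: sigmoid(0) = 0.5 fails the strict threshold
  expect_equal(sum(compose_masks(proto, rep(0, 4), full, 32L)), 0L)
  # saturated single prototype restricted to the box
  p1 <- array(0, dim = c(8, 8, 1)); p1[3:6, 3:6, 1] <- 1
  mm <- compose_masks(p1, 100, c(8, 8, 24, 24), 32L)
  on <- which(mm == 1L, arr.ind = TRUE)
  expect_true(all(on >= 9 & on <= 24))
  expect_gt(nrow(on), 0)
  expect_error(compose_masks(proto, rnorm(3), full, 32L), "length")
})
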