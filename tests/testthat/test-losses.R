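# Class weighting, task-aligned assignment, composite loss

test_that("inverse-log-frequency weights: symmetry, spot value, monotonicity", {
  w <- class_weights(rep(1 / 8, 8))$weights
  expect_equal(diff(range(w)), 0)
  expect_equal(class_weights(c(0.5, 0.5), alpha = 1)$weights[1],
               1 / log(1.5), tolerance = 1e-12)
  for (a in c(1.02, 1.5, 3)) {
    t2 <- class_weights(c(0.05, 0.25, 0.70), alpha = a)$weights
    expect_gt(t2[1], t2[3])
    expect_true(all(diff(t2) <= 0))
  }
  expect_error(class_weights(c(0.5, 0.5), alpha = 0.3), "alpha")
  expect_error(class_weights(c(0.6, 0.5)), "sum")
})

test_that("weights flatten toward uniform as the smoothing grows", {
  w <- class_weights(SYNTH_PROPS, alpha = 1e6)$weights
  expect_lt(max(w) / min(w) - 1, 0.01)
})

test_that("weighted cross-entropy: perfect prediction, unweighted reduction, spot value", {
  y <- diag(3)
  expect_equal(weighted_class_loss(y, diag(3) * 0.999998 + 1e-6 / 3), 0, tolerance = 1e-5)
  set.seed(1)
  p <- matrix(runif(12), 4); p <- p / rowSums(p)
  yt <- diag(3)[sample(3, 4, replace = TRUE), ]
  expect_equal(weighted_class_loss(yt, p),
               -mean(log(p[yt == 1])), tolerance = 1e-12)
  # single sample, true-class probability 0.25, weight 2
  tab <- structure(list(weights = c(2, 1)), class = "class_weight_table")
  expect_equal(weighted_class_loss(matrix(c(1, 0), 1), matrix(c(0.25, 0.75), 1), tab),
               -2 * log(0.25), tolerance = 1e-12)
  expect_equal(-2 * log(0.25), 2.77259, tolerance = 1e-4)
})

test_that("assignment with no ground truths yields no positives", {
  set.seed(2)
  sc <- matrix(runif(24), 12)
  bx <- cbind(0, 0, runif(12, 5, 10), runif(12, 5, 10))
  an <- cbind(runif(12, 0, 10), runif(12, 0, 10))
  a <- tal_assign(sc, bx, an, NULL, integer(0))
  expect_true(all(a$gt_idx == 0L))
})

test_that("one ground truth covering everything selects exactly top-K positives", {
  set.seed(3)
  n <- 30L
  sc <- matrix(runif(n * 2), n)
  an <- cbind(runif(n, 1, 15), runif(n, 1, 15))
  bx <- cbind(an[, 1] - 2, an[, 2] - 2, an[, 1] + 2, an[, 2] + 2)
  a <- tal_assign(sc, bx, an, matrix(c(0, 0, 16, 16), 1), 0L, topk = 10L)
  expect_equal(sum(a$gt_idx == 1L), 10L)
})

test_that("overlapping ground truths resolve to the exhaustive-ranking oracle", {
  set.seed(4)
  for (case in 1:5) {
    n <- 12L
    an <- cbind(runif(n, 0, 12), runif(n, 0, 12))
    sc <- matrix(runif(n * 3), n)
    bx <- cbind(an[, 1] - runif(n, 1, 3), an[, 2] - runif(n, 1, 3),
                an[, 1] + runif(n, 1, 3), an[, 2] + runif(n, 1, 3))
    gt <- rbind(c(1, 1, 8, 8), c(4, 4, 11, 11))
    gc <- c(0L, 2L)
    got <- tal_assign(sc, bx, an, gt, gc, topk = 4L, alpha_t = 0.5, beta_t = 6.0)
    # oracle: score every (cell, gt) pair explicitly, take top-4 per gt,
    # give contested cells to the larger alignment
    tm <- matrix(0, n, 2)
    for (g in 1:2) for (i in 1:n) {
      inside <- an[i, 1] > gt[g, 1] && an[i, 1] < gt[g, 3] &&
        an[i, 2] > gt[g, 2] && an[i, 2] < gt[g, 4]
      if (!inside) next
      xx1 <- max(bx[i, 1], gt[g, 1]); yy1 <- max(bx[i, 2], gt[g, 2])
      xx2 <- min(bx[i, 3], gt[g, 3]); yy2 <- min(bx[i, 4], gt[g, 4])
      inter <- max(xx2 - xx1, 0) * max(yy2 - yy1, 0)
      un <- (bx[i, 3] - bx[i, 1]) * (bx[i, 4] - bx[i, 2]) +
        (gt[g, 3] - gt[g, 1]) * (gt[g, 4] - gt[g, 2]) - inter
      tm[i, g] <- sc[i, gc[g] + 1]^0.5 * (inter / un)^6
    }
    want <- integer(n)
    pos <- matrix(FALSE, n, 2)
    for (g in 1:2) {
      cand <- which(tm[, g] > 0)
      pos[cand[order(tm[cand, g], decreasing = TRUE)][seq_len(min(4, length(cand)))], g] <- TRUE
    }
    for (i in 1:n) {
      gs <- which(pos[i, ])
      if (length(gs)) want[i] <- gs[which.max(tm[i, gs])]
    }
    expect_equal(got$gt_idx, want)
  }
})

make_toy_raw <- function(cls, box, coef, proto, stride = 8L) {
  structure(list(box = list(box), cls = list(cls), coef = list(coef),
                 proto = proto, strides = stride,
                 imgsz = dim(cls)[1] * stride),
            class = "farmseg_raw")
}

test_that("a batch without ground truths reduces to the classification term", {
  set.seed(5)
  cls <- array(rnorm(4 * 4 * 2), dim = c(4, 4, 2, 1))
  box <- array(rnorm(4 * 4 * 64), dim = c(4, 4, 64, 1))
  coef <- array(rnorm(4 * 4 * 4), dim = c(4, 4, 4, 1))
  proto <- array(rnorm(8 * 8 * 4), dim = c(8, 8, 4, 1))
  raw <- make_toy_raw(cls, box, coef, proto)
  out <- total_loss(raw, list(list(boxes = NULL, classes = integer(0), masks = list())))
  expect_equal(out$components[["box"]], 0)
  expect_equal(out$components[["mask"]], 0)
  expect_equal(out$components[["dfl"]], 0)
  expect_equal(out$total, 0.5 * out$components[["cls"]])
  expect_gte(out$total, 0)
})

test_that("doubling the mask gain doubles its contribution exactly", {
  set.seed(6)
  cls <- array(rnorm(4 * 4 * 2), dim = c(4, 4, 2, 1))
  box <- array(rnorm(4 * 4 * 64), dim = c(4, 4, 64, 1))
  coef <- array(rnorm(4 * 4 * 4), dim = c(4, 4, 4, 1))
  proto <- array(rnorm(8 * 8 * 4), dim = c(8, 8, 4, 1))
  raw <- make_toy_raw(cls, box, coef, proto)
  mk <- matrix(0L, 32, 32); mk[8:24, 8:24] <- 1L
  tg <- list(list(boxes = matrix(c(6, 6, 26, 26), 1), classes = 0L,
                  masks = list(mk)))
  g1 <- c(cls = 0.5, box = 7.5, mask = 2.5, dfl = 1.5)
  g2 <- g1; g2["mask"] <- 5
  l1 <- total_loss(raw, tg, gains = g1)
  l2 <- total_loss(raw, tg, gains = g2)
  expect_gt(l1$npos, 0)
  expect_equal(l2$total - l1$total, 2.5 * l1$components[["mask"]], tolerance = 1e-10)
})

test_that("a single positive cell reproduces hand arithmetic for every term", {
  # 1x1 grid at stride 8: one cell, center (4, 4)
  cls <- array(c(0.3, -0.2), dim = c(1, 1, 2, 1))
  box <- array(0, dim = c(1, 1, 32, 1))   # reg_max 8 here keeps sums small
  coef <- array(c(0.5, -0.5), dim = c(1, 1, 2, 1))
  proto <- array(rep(c(1, -1), each = 4), dim = c(2, 2, 2, 1))
  raw <- make_toy_raw(cls, box, coef, proto)
  mk <- matrix(1L, 8, 8)
  tg <- list(list(boxes = matrix(c(0, 0, 8, 8), 1), classes = 1L, masks = list(mk)))
  out <- loss_core(raw, tg, reg_max = 8L, need_grads = FALSE)
  expect_equal(out$npos, 1L)
  # classification: one-hot at class 2, logits (0.3, -0.2);
  # bce(0.3, 0) + bce(-0.2, 1) = log(1 + e^0.3) + log(1 + e^0.2)
  cls_hand <- log1p(exp(0.3)) + log1p(exp(0.2))
  expect_equal(out$components[["cls"]], cls_hand, tolerance = 1e-10)
  # box: uniform distribution -> expectation 3.5 strides each side;
  # decoded box (-24,-24,32,32) vs gt (0,0,8,8)
  pb <- c(4 - 3.5 * 8, 4 - 3.5 * 8, 4 + 3.5 * 8, 4 + 3.5 * 8)
  expect_equal(out$components[["box"]], 1 - farmseg:::ciou_xyxy(pb, c(0, 0, 8, 8)),
               tolerance = 1e-10)
  # dfl: targets l = t = 0.5, r = b = 0.5 strides; uniform p = 1/8 per bin
  expect_equal(out$components[["dfl"]], -log(1 / 8), tolerance = 1e-10)
  # mask: linear map = 1 * 0.5 + (-1) * (-0.5) = 1 at every prototype pixel,
  # ground truth all ones -> mean bce = log(1 + e^-1)
  expect_equal(out$components[["mask"]], log1p(exp(-1)), tolerance = 1e-10)
})

test_that("training on a few scenes decreases the composite loss", {
  set.seed(10)
  scenes <- make_scenes(8L, imgsz = 64L, seed = 10L)
  samples <- scenes_to_samples(scenes)
  m <- build_model(variant_config("baseline"))
  h <- train_model(m, samples, epochs = 3L, batch_size = 8L, lr0 = 0.01)
  expect_lt(tail(h$total, 1), h$total[1])
  expect_true(all(is.finite(h$total)))
})
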