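# Independent reference implementations used as oracles in the tests.
# These deliberately use naive loops / different algorithms from the package.

# naive dense 2-D convolution for a single image (H, W, C) with weight
# (kh, kw, cin/groups, cout), stride/pad/dilation, optional bias
naive_conv <- function(x, w, bias = NULL, stride = 1L, pad = c(0L, 0L),
                       dil = 1L, groups = 1L) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  wd <- dim(w); kh <- wd[1]; kw <- wd[2]; cg <- wd[3]; Cout <- wd[4]
  og <- Cout %/% groups
  Ho <- (H + 2 * pad[1] - dil * (kh - 1) - 1) %/% stride + 1
  Wo <- (W + 2 * pad[2] - dil * (kw - 1) - 1) %/% stride + 1
  y <- array(0, dim = c(Ho, Wo, Cout))
  for (co in seq_len(Cout)) {
    g <- (co - 1L) %/% og
    for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
      acc <- 0
      for (ci in seq_len(cg)) for (i in seq_len(kh)) for (j in seq_len(kw)) {
        hi <- (ho - 1L) * stride - pad[1] + (i - 1L) * dil + 1L
        wi <- (wo - 1L) * stride - pad[2] + (j - 1L) * dil + 1L
        if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
          acc <- acc + x[hi, wi, g * cg + ci] * w[i, j, ci, co]
      }
      y[ho, wo, co] <- acc + if (is.null(bias)) 0 else bias[co]
    }
  }
  y
}

# O(n^2) all-pairs greedy non-maximum suppression oracle
nms_oracle <- function(boxes, scores, iou_thresh) {
  n <- length(scores)
  suppressed <- logical(n)
  keep <- integer(0)
  repeat {
    best <- -Inf; bi <- 0L
    for (i in seq_len(n)) if (!suppressed[i] && scores[i] > best) {
      best <- scores[i]; bi <- i
    }
    if (bi == 0L) break
    keep <- c(keep, bi)
    suppressed[bi] <- TRUE
    for (j in seq_len(n)) {
      if (suppressed[j]) next
      xx1 <- max(boxes[bi, 1], boxes[j, 1]); yy1 <- max(boxes[bi, 2], boxes[j, 2])
      xx2 <- min(boxes[bi, 3], boxes[j, 3]); yy2 <- min(boxes[bi, 4], boxes[j, 4])
      inter <- max(xx2 - xx1, 0) * max(yy2 - yy1, 0)
      a1 <- (boxes[bi, 3] - boxes[bi, 1]) * (boxes[bi, 4] - boxes[bi, 2])
      a2 <- (boxes[j, 3] - boxes[j, 1]) * (boxes[j, 4] - boxes[j, 2])
      iou <- if (a1 + a2 - inter > 0) inter / (a1 + a2 - inter) else 0
      if (iou > iou_thresh) suppressed[j] <- TRUE
    }
  }
  keep
}

# independent evaluator: per-class greedy matching (explicit loops) and AP by
# fine-grid Riemann integration of the interpolated precision envelope
eval_oracle <- function(predictions, ground_truths, num_classes,
                        thresholds = seq(0.5, 0.95, by = 0.05)) {
  ap_grid <- function(scores, tp, n_gt) {
    if (n_gt == 0L) return(NA_real_)
    if (!length(scores)) return(0)
    o <- order(scores, decreasing = TRUE)
    tp <- tp[o]
    ctp <- cumsum(tp); cfp <- cumsum(!tp)
    rec <- ctp / n_gt; prec <- ctp / (ctp + cfp)
    grid <- seq(0, 1, length.out = 10001L)
    pint <- vapply(grid, function(r) {
      ok <- rec >= r
      if (!any(ok)) 0 else max(prec[ok])
    }, 0)
    mean(pint)
  }
  aps <- matrix(NA_real_, num_classes, length(thresholds))
  for (cl in seq_len(num_classes) - 1L) {
    n_gt <- 0L
    allscore <- numeric(0)
    tp_by_thr <- vector("list", length(thresholds))
    for (ti in seq_along(thresholds)) tp_by_thr[[ti]] <- logical(0)
    for (im in seq_along(predictions)) {
      pr <- Filter(function(p) p$class_id == cl, predictions[[im]])
      gt <- ground_truths[[im]]$masks[ground_truths[[im]]$classes == cl]
      n_gt <- n_gt + length(gt)
      if (!length(pr)) next
      sc <- vapply(pr, `[[`, 0, "score")
      o <- order(sc, decreasing = TRUE)
      for (ti in seq_along(thresholds)) {
        used <- logical(length(gt))
        tps <- logical(length(pr))
        for (i in o) {
          best <- 0; bj <- 0L
          for (j in seq_along(gt)) {
            if (used[j]) next
            a <- pr[[i]]$mask > 0; b <- gt[[j]] > 0
            un <- sum(a | b)
            iou <- if (un == 0) 1 else sum(a & b) / un
            if (iou > best) { best <- iou; bj <- j }
          }
          if (bj > 0L && best >= thresholds[ti]) { tps[i] <- TRUE; used[bj] <- TRUE }
        }
        tp_by_thr[[ti]] <- c(tp_by_thr[[ti]], tps)
      }
      allscore <- c(allscore, sc)
    }
    for (ti in seq_along(thresholds))
      aps[cl + 1L, ti] <- ap_grid(allscore, tp_by_thr[[ti]], n_gt)
  }
  valid <- !is.na(aps[, 1L])
  list(mAP50 = mean(aps[valid, 1L]), mAP50_95 = mean(rowMeans(aps[valid, , drop = FALSE])))
}

# random prediction/ground-truth sets over small mask canvases
random_eval_case <- function(nimg = 3L, sz = 16L, num_classes = 3L) {
  rmask <- function() {
    m <- matrix(0L, sz, sz)
    x1 <- sample(sz - 4L, 1L); y1 <- sample(sz - 4L, 1L)
    w <- sample(3:8, 1L); h <- sample(3:8, 1L)
    m[y1:min(sz, y1 + h), x1:min(sz, x1 + w)] <- 1L
    m
  }
  gts <- lapply(seq_len(nimg), function(i) {
    k <- sample(0:3, 1L)
    list(classes = if (k) sample(num_classes, k, replace = TRUE) - 1L else integer(0),
         masks = replicate(k, rmask(), simplify = FALSE))
  })
  preds <- lapply(seq_len(nimg), function(i) {
    k <- sample(0:5, 1L)
    lapply(seq_len(k), function(j) {
      # half the predictions perturb a ground truth, half are random
      gt <- gts[[i]]
      if (length(gt$classes) && stats::runif(1) < 0.6) {
        g <- sample(length(gt$classes), 1L)
        m <- gt$masks[[g]]
        if (stats::runif(1) < 0.5) {
          sh <- sample(-2:2, 1L)
          m <- matrix(0L, sz, sz)
          src <- gt$masks[[g]]
          ys <- pmax(1L, 1L + sh):pmin(sz, sz + sh)
          m[ys - sh, ] <- src[ys, ]
        }
        list(score = stats::runif(1), class_id = gt$classes[g], mask = m)
      } else {
        list(score = stats::runif(1), class_id = sample(num_classes, 1L) - 1L,
             mask = rmask())
      }
    })
  })
  list(preds = preds, gts = gts)
}

# small random scenes shared across tests
make_scenes <- function(n, imgsz = 48L, seed = 1L) {
  set.seed(seed)
  spec <- scene_spec(imgsz = imgsz, n_instances = c(3L, 5L))
  lapply(seq_len(n), function(i) generate_scene(spec))
}
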