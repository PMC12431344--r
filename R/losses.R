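# Target assignment and the composite training loss.
#
# Classification uses binary cross-entropy with inverse-log-frequency class
# weights, box regression uses 1 - CIoU plus a distribution focal term on the
# discretized distances, and the mask term is a per-instance binary
# cross-entropy of the composed prototype mask against the ground-truth mask
# inside its box. Loss gains follow the training recipe:
# total = 0.5 * cls + 7.5 * box + 2.5 * mask + 1.5 * dfl.

#' Inverse-log-frequency class weights
#'
#' `w_c = 1 / log(frequency_c + alpha)` (natural log). Rarer classes get
#' larger weights; as `alpha` grows the weights flatten toward uniform.
#'
#' @param frequencies per-class relative frequencies; positive, summing to 1.
#' @param alpha smoothing hyperparameter; every `frequency_c + alpha` must
#'   exceed 1 so all weights stay positive (default 1.02).
#' @return object of class `class_weight_table` with `$weights`.
#' @examples
#' class_weights(c(0.5, 0.5), alpha = 1)$weights  # both 1/log(1.5)
#' @export
class_weights <- function(frequencies, alpha = 1.02) {
  if (any(frequencies <= 0)) stop("frequencies must be positive")
  if (abs(sum(frequencies) - 1) > 1e-6) stop("frequencies must sum to 1")
  if (any(frequencies + alpha <= 1))
    stop("alpha too small: frequency + alpha must exceed 1 for every class")
  w <- 1 / log(frequencies + alpha)
  structure(list(weights = w, alpha = alpha, frequencies = frequencies),
            class = "class_weight_table")
}

#' Class-weighted cross-entropy
#'
#' `-mean_i sum_c w_c * y_true[i, c] * log y_pred[i, c]` over rows.
#'
#' @param y_true one-hot matrix (n x C).
#' @param y_pred predicted probability matrix (n x C), rows summing to 1.
#' @param table a [class_weights()] table (or NULL for unweighted).
#' @export
weighted_class_loss <- function(y_true, y_pred, table = NULL) {
  if (!all(abs(rowSums(y_pred) - 1) < 1e-6))
    stop("predicted probabilities must sum to 1 per row")
  w <- if (is.null(table)) rep(1, ncol(y_pred)) else table$weights
  if (any(y_pred[y_true > 0] == 0)) {
    warning("zero predicted probability at a true class; clamping")
    y_pred <- pmax(y_pred, 1e-12)
  }
  -mean(rowSums(sweep(y_true * log(y_pred), 2L, w, `*`)))
}

# ---- geometric helpers ------------------------------------------------------

ciou_xyxy <- function(a, b) {
  # complete IoU between two xyxy boxes
  iw <- pmax(pmin(a[3], b[3]) - pmax(a[1], b[1]), 0)
  ih <- pmax(pmin(a[4], b[4]) - pmax(a[2], b[2]), 0)
  inter <- iw * ih
  aa <- (a[3] - a[1]) * (a[4] - a[2]); ab <- (b[3] - b[1]) * (b[4] - b[2])
  un <- aa + ab - inter
  iou <- if (un > 0) inter / un else 0
  cw <- max(a[3], b[3]) - min(a[1], b[1])
  chh <- max(a[4], b[4]) - min(a[2], b[2])
  c2 <- cw^2 + chh^2 + 1e-9
  rho2 <- ((a[1] + a[3]) - (b[1] + b[3]))^2 / 4 + ((a[2] + a[4]) - (b[2] + b[4]))^2 / 4
  wa <- a[3] - a[1] + 1e-9; ha <- a[4] - a[2] + 1e-9
  wb <- b[3] - b[1] + 1e-9; hb <- b[4] - b[2] + 1e-9
  v <- 4 / pi^2 * (atan(wb / hb) - atan(wa / ha))^2
  al <- v / (1 - iou + v + 1e-9)
  iou - rho2 / c2 - al * v
}

#' Task-aligned assignment of cells to ground truths
#'
#' Candidate cells are those whose center lies inside a ground-truth box.
#' Each candidate is scored `t = score^alpha_t * IoU^beta_t` with `score` the
#' predicted probability of the ground truth's class and IoU between the
#' decoded cell box and the ground-truth box; the top-K candidates per ground
#' truth become positives and a cell claimed by several ground truths goes to
#' the one with the higher alignment.
#'
#' @param class_scores n x C matrix of predicted class probabilities.
#' @param predicted_boxes n x 4 decoded boxes (xyxy pixels).
#' @param anchors n x 2 matrix of cell centers (cx, cy).
#' @param gt_boxes G x 4 ground-truth boxes (xyxy); G may be 0.
#' @param gt_classes integer vector (0-based class ids).
#' @param topk positives kept per ground truth.
#' @param alpha_t,beta_t alignment exponents.
#' @return list with `gt_idx` (length n; 0 = negative, else ground-truth
#'   index), `align` (alignment score per cell, 0 for negatives), `iou`
#'   (box IoU with the assigned ground truth) and `target` (quality-aware
#'   soft classification target: `align / max_align(gt) * max_iou(gt)`).
#' @export
tal_assign <- function(class_scores, predicted_boxes, anchors, gt_boxes,
                       gt_classes, topk = 10L, alpha_t = 0.5, beta_t = 6.0) {
  n <- nrow(class_scores)
  gt_idx <- integer(n); align <- numeric(n); iou_out <- numeric(n)
  target <- numeric(n)
  G <- if (is.null(gt_boxes)) 0L else nrow(gt_boxes)
  if (G == 0L)
    return(list(gt_idx = gt_idx, align = align, iou = iou_out, target = target))
  tmat <- matrix(0, n, G)
  imat <- matrix(0, n, G)
  for (g in seq_len(G)) {
    b <- gt_boxes[g, ]
    inside <- anchors[, 1L] > b[1] & anchors[, 1L] < b[3] &
      anchors[, 2L] > b[2] & anchors[, 2L] < b[4]
    if (!any(inside)) next
    iou <- box_iou_xyxy(predicted_boxes[inside, , drop = FALSE],
                        matrix(b, 1L))[, 1L]
    s <- class_scores[inside, gt_classes[g] + 1L]
    imat[inside, g] <- iou
    tmat[inside, g] <- pmax(s, 0)^alpha_t * pmax(iou, 0)^beta_t
  }
  pos <- matrix(FALSE, n, G)
  for (g in seq_len(G)) {
    cand <- which(tmat[, g] > 0)
    if (!length(cand)) next
    kk <- cand[order(tmat[cand, g], decreasing = TRUE)][seq_len(min(topk, length(cand)))]
    pos[kk, g] <- TRUE
  }
  for (i in seq_len(n)) {
    gs <- which(pos[i, ])
    if (!length(gs)) next
    g <- gs[which.max(tmat[i, gs])]
    gt_idx[i] <- g
    align[i] <- tmat[i, g]
    iou_out[i] <- imat[i, g]
  }
  # quality-aware soft targets: rescale each ground truth's alignments so its
  # best cell targets its best achieved IoU
  for (g in seq_len(G)) {
    cells <- which(gt_idx == g)
    if (!length(cells)) next
    tmax <- max(align[cells]); imax <- max(iou_out[cells])
    target[cells] <- if (tmax > 0) align[cells] / tmax * imax else 0
  }
  list(gt_idx = gt_idx, align = align, iou = iou_out, target = target)
}

# ---- flattening raw predictions --------------------------------------------

flatten_raw <- function(raw, n, reg_max) {
  cls <- list(); box <- list(); coef <- list(); cx <- list(); cy <- list()
  stride <- list(); scale <- list()
  for (s in seq_along(raw$strides)) {
    H <- dim(raw$cls[[s]])[1]; W <- dim(raw$cls[[s]])[2]
    nb <- H * W
    cls[[s]] <- matrix(raw$cls[[s]][, , , n], nb)
    box[[s]] <- matrix(raw$box[[s]][, , , n], nb)
    coef[[s]] <- matrix(raw$coef[[s]][, , , n], nb)
    ij <- arrayInd(seq_len(nb), c(H, W))
    cy[[s]] <- (ij[, 1L] - 0.5) * raw$strides[s]
    cx[[s]] <- (ij[, 2L] - 0.5) * raw$strides[s]
    stride[[s]] <- rep(raw$strides[s], nb)
    scale[[s]] <- rep(s, nb)
  }
  list(cls = do.call(rbind, cls), box = do.call(rbind, box),
       coef = do.call(rbind, coef),
       cx = unlist(cx), cy = unlist(cy), stride = unlist(stride),
       scale = unlist(scale),
       ncell_per_scale = vapply(seq_along(raw$strides),
                                function(s) length(cx[[s]]), 0))
}

decode_flat <- function(fl, reg_max) {
  nb <- nrow(fl$box)
  bins <- 0:(reg_max - 1L)
  e <- matrix(0, nb, 4L); p <- vector("list", 4L)
  for (side in 1:4) {
    logits <- fl$box[, (side - 1L) * reg_max + seq_len(reg_max), drop = FALSE]
    ps <- softmax_rows(logits)
    p[[side]] <- ps
    e[, side] <- ps %*% bins
  }
  boxes <- cbind(fl$cx - e[, 1L] * fl$stride, fl$cy - e[, 2L] * fl$stride,
                 fl$cx + e[, 3L] * fl$stride, fl$cy + e[, 4L] * fl$stride)
  list(boxes = boxes, e = e, p = p)
}

bce <- function(z, y) {
  # numerically stable binary cross-entropy from logits
  pmax(z, 0) - z * y + log1p(exp(-abs(z)))
}

# Composite loss + gradients w.r.t. the raw head outputs for one batch.
# targets: list per image with $boxes (G x 4 xyxy), $classes (0-based),
# $masks (list of imgsz x imgsz binary matrices, rows = y).
loss_core <- function(raw, targets, weights = NULL,
                      gains = c(cls = 0.5, box = 7.5, mask = 2.5, dfl = 1.5),
                      reg_max = 16L, topk = 10L, alpha_t = 0.5, beta_t = 6.0,
                      need_grads = TRUE) {
  nimg <- dim(raw$cls[[1L]])[4]
  nc <- dim(raw$cls[[1L]])[3]
  npm <- dim(raw$proto)[3]
  wvec <- if (is.null(weights)) rep(1, nc) else weights$weights
  bins <- 0:(reg_max - 1L)
  pd <- dim(raw$proto)

  # pass 1: flatten, decode and assign every image; count positives
  per <- vector("list", nimg)
  npos_total <- 0L
  for (n in seq_len(nimg)) {
    fl <- flatten_raw(raw, n, reg_max)
    dec <- decode_flat(fl, reg_max)
    tg <- targets[[n]]
    scores <- 1 / (1 + exp(-fl$cls))
    asg <- tal_assign(scores, dec$boxes, cbind(fl$cx, fl$cy),
                      tg$boxes, tg$classes, topk, alpha_t, beta_t)
    per[[n]] <- list(fl = fl, dec = dec, scores = scores, asg = asg)
    npos_total <- npos_total + sum(asg$gt_idx > 0L)
  }
  npz <- max(npos_total, 1L)

  comp <- c(cls = 0, box = 0, mask = 0, dfl = 0)
  dhead <- NULL
  if (need_grads) {
    zero_like <- function(xs) lapply(xs, function(x) array(0, dim = dim(x)))
    dhead <- list(box = zero_like(raw$box), cls = zero_like(raw$cls),
                  coef = zero_like(raw$coef),
                  proto = array(0, dim = dim(raw$proto)))
  }

  for (n in seq_len(nimg)) {
    fl <- per[[n]]$fl; dec <- per[[n]]$dec
    scores <- per[[n]]$scores; asg <- per[[n]]$asg
    tg <- targets[[n]]
    nb <- nrow(fl$cls)
    pos <- which(asg$gt_idx > 0L)
    y <- matrix(0, nb, nc)
    wmat <- matrix(1, nb, nc)
    if (length(pos)) {
      cls_pos <- tg$classes[asg$gt_idx[pos]] + 1L
      y[cbind(pos, cls_pos)] <- 1
      wmat[cbind(pos, cls_pos)] <- wvec[cls_pos]
    }
    comp["cls"] <- comp["cls"] + sum(wmat * bce(fl$cls, y)) / npz
    dcls_flat <- if (need_grads) gains[["cls"]] * wmat * (scores - y) / npz
    dbox_flat <- if (need_grads) matrix(0, nb, 4L * reg_max)
    dcoef_flat <- if (need_grads) matrix(0, nb, npm)
    if (length(pos)) {
      proto_mat <- matrix(raw$proto[, , , n], pd[1] * pd[2], npm)
      scp <- pd[1] / raw$imgsz
      pys <- (rep(seq_len(pd[1]), pd[2]) - 0.5) / scp
      pxs <- (rep(seq_len(pd[2]), each = pd[1]) - 0.5) / scp
      dproto_mat <- if (need_grads) matrix(0, pd[1] * pd[2], npm)
      for (i in pos) {
        g <- asg$gt_idx[i]
        gb <- tg$boxes[g, ]
        cl <- tg$classes[g] + 1L
        # --- box: 1 - CIoU, gradient by central differences on the distances
        pb <- dec$boxes[i, ]
        comp["box"] <- comp["box"] + (1 - ciou_xyxy(pb, gb)) / npz
        if (need_grads) {
          h <- 1e-3
          for (side in 1:4) {
            shift <- c(-1, -1, 1, 1)[side] * fl$stride[i]
            bp <- pb; bp[side] <- bp[side] + h * shift
            bm <- pb; bm[side] <- bm[side] - h * shift
            de <- (ciou_xyxy(bm, gb) - ciou_xyxy(bp, gb)) / (2 * h)  # d(1-ciou)/de
            ps <- dec$p[[side]][i, ]
            dz <- ps * (bins - dec$e[i, side]) * de
            cols <- (side - 1L) * reg_max + seq_len(reg_max)
            dbox_flat[i, cols] <- dbox_flat[i, cols] + gains[["box"]] * dz / npz
          }
        }
        # --- distribution focal term on the discretized distances
        tdist <- c(fl$cx[i] - gb[1], fl$cy[i] - gb[2],
                   gb[3] - fl$cx[i], gb[4] - fl$cy[i]) / fl$stride[i]
        tdist <- pmin(pmax(tdist, 0), reg_max - 1 - 1e-3)
        for (side in 1:4) {
          lo <- floor(tdist[side]); hi <- lo + 1
          wl <- hi - tdist[side]; wh <- 1 - wl
          ps <- dec$p[[side]][i, ]
          comp["dfl"] <- comp["dfl"] -
            (wl * log(ps[lo + 1] + 1e-12) + wh * log(ps[hi + 1] + 1e-12)) / (4 * npz)
          if (need_grads) {
            tvec <- numeric(reg_max); tvec[lo + 1] <- wl; tvec[hi + 1] <- wh
            cols <- (side - 1L) * reg_max + seq_len(reg_max)
            dbox_flat[i, cols] <- dbox_flat[i, cols] +
              gains[["dfl"]] * (ps - tvec) / (4 * npz)
          }
        }
        # --- mask BCE inside the ground-truth box, class-weighted
        inb <- pys >= gb[2] & pys < gb[4] & pxs >= gb[1] & pxs < gb[3]
        if (any(inb)) {
          lin <- proto_mat[inb, , drop = FALSE] %*% fl$coef[i, ]
          gm <- tg$masks[[g]]
          giy <- pmin(nrow(gm), pmax(1L, ceiling(pys[inb] * nrow(gm) / raw$imgsz)))
          gix <- pmin(ncol(gm), pmax(1L, ceiling(pxs[inb] * ncol(gm) / raw$imgsz)))
          ym <- gm[cbind(giy, gix)]
          area <- sum(inb)
          comp["mask"] <- comp["mask"] + wvec[cl] * sum(bce(lin, ym)) / area / npz
          if (need_grads) {
            sig <- 1 / (1 + exp(-lin))
            dlin <- gains[["mask"]] * wvec[cl] * (sig - ym) / area / npz
            dcoef_flat[i, ] <- dcoef_flat[i, ] +
              as.vector(crossprod(proto_mat[inb, , drop = FALSE], dlin))
            dproto_mat[inb, ] <- dproto_mat[inb, ] +
              outer(as.vector(dlin), fl$coef[i, ])
          }
        }
      }
      if (need_grads)
        dhead$proto[, , , n] <- dhead$proto[, , , n] + array(dproto_mat, dim = pd[1:3])
    }
    if (need_grads) {
      at <- 0L
      for (s in seq_along(raw$strides)) {
        ncs <- fl$ncell_per_scale[s]
        idx <- at + seq_len(ncs)
        dhead$cls[[s]][, , , n] <- array(dcls_flat[idx, ], dim = dim(raw$cls[[s]])[1:3])
        dhead$box[[s]][, , , n] <- array(dbox_flat[idx, ], dim = dim(raw$box[[s]])[1:3])
        dhead$coef[[s]][, , , n] <- array(dcoef_flat[idx, ], dim = dim(raw$coef[[s]])[1:3])
        at <- at + ncs
      }
    }
  }
  total <- sum(gains[c("cls", "box", "mask", "dfl")] * comp[c("cls", "box", "mask", "dfl")])
  list(total = unname(total), components = comp, dhead = dhead,
       npos = npos_total)
}

#' Composite training loss
#'
#' Runs task-aligned assignment on the raw prediction and evaluates the
#' composite loss `0.5 * cls + 7.5 * box + 2.5 * mask + 1.5 * dfl`, where the
#' box term is `1 - CIoU` over positives, the classification and mask terms
#' are class-weighted binary cross-entropies, and the dfl term is the
#' distribution focal loss of the discretized box distances.
#'
#' @param raw raw prediction from [forward()].
#' @param targets list (one element per image) with `$boxes` (G x 4 xyxy
#'   pixel boxes), `$classes` (0-based ids) and `$masks` (list of binary
#'   matrices at image resolution).
#' @param weights optional [class_weights()] table.
#' @param gains named loss gains (cls, box, mask, dfl).
#' @return list with `total` and `components` (per-term unweighted means).
#' @export
total_loss <- function(raw, targets, weights = NULL,
                       gains = c(cls = 0.5, box = 7.5, mask = 2.5, dfl = 1.5)) {
  out <- loss_core(raw, targets, weights, gains, need_grads = FALSE)
  if (!is.finite(out$total))
    stop("non-finite loss; components: ",
         paste(names(out$components), round(out$components, 4), collapse = ", "))
  out[c("total", "components", "npos")]
}
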