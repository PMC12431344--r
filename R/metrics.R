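# Mask-level evaluation: precision, recall, average precision and mAP.
#
# Matching is greedy in descending score order against the ground truths of
# the same image and class: a prediction is a true positive at threshold T if
# its best mask IoU over still-unmatched ground truths reaches T. AP is the
# area under the precision-recall curve with all-point interpolation (the
# precision envelope integrated over every achieved recall level); mAP is the
# arithmetic mean over classes. P and R are additionally reported at the
# per-class confidence that maximizes F1.

#' Mask intersection-over-union
#'
#' @param a,b binary matrices (0/1 or logical) of identical shape.
#' @return `|a & b| / |a | b|`; defined as 1 when both masks are empty
#'   (vacuous agreement).
#' @export
mask_iou <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  a <- a > 0; b <- b > 0
  un <- sum(a | b)
  if (un == 0L) return(1)
  sum(a & b) / un
}

ap_from_pr <- function(tp, fp, n_gt) {
  # tp/fp: flags in descending score order
  if (n_gt == 0L) return(NA_real_)
  if (!length(tp)) return(0)
  ctp <- cumsum(tp); cfp <- cumsum(fp)
  recall <- ctp / n_gt
  precision <- ctp / (ctp + cfp)
  # precision envelope (all-point interpolation)
  mpre <- c(1, precision, 0)
  mrec <- c(0, recall, 1)
  for (i in rev(seq_len(length(mpre) - 1L)))
    mpre[i] <- max(mpre[i], mpre[i + 1L])
  idx <- which(mrec[-1L] != mrec[-length(mrec)])
  sum((mrec[idx + 1L] - mrec[idx]) * mpre[idx + 1L])
}

match_class <- function(preds, gts, thr) {
  # preds: list sorted by descending score; gts: list of masks
  used <- logical(length(gts))
  tp <- logical(length(preds))
  for (i in seq_along(preds)) {
    best <- 0; bj <- 0L
    for (j in seq_along(gts)) {
      if (used[j]) next
      iou <- mask_iou(preds[[i]]$mask, gts[[j]])
      if (iou > best) { best <- iou; bj <- j }
    }
    if (bj > 0L && best >= thr) { tp[i] <- TRUE; used[bj] <- TRUE }
  }
  tp
}

#' Evaluate instance segmentation predictions
#'
#' @param predictions list per image; each element a list of instances
#'   `list(score, class_id, mask)` (as produced by [decode_and_nms()]).
#' @param ground_truths list per image; each element
#'   `list(classes = 0-based ids, masks = list of binary matrices)`.
#' @param num_classes number of classes in the label space.
#' @param thresholds IoU thresholds; default `seq(0.5, 0.95, 0.05)`.
#' @return an `eval_report`: per-class data.frame (`precision`, `recall`,
#'   `ap50`, `ap`), plus `mAP50` and `mAP50_95` (means over classes with at
#'   least one ground truth).
#' @export
evaluate <- function(predictions, ground_truths, num_classes = 8L,
                     thresholds = seq(0.5, 0.95, by = 0.05)) {
  stopifnot(length(predictions) == length(ground_truths))
  for (ps in predictions)
    for (p in ps)
      if (p$class_id < 0L || p$class_id >= num_classes)
        stop("prediction class id outside configured label space")
  nthr <- length(thresholds)
  per_class <- vector("list", num_classes)
  for (cl in seq_len(num_classes) - 1L) {
    # gather predictions/gt of this class across images
    recs <- list()  # per image: preds (sorted later globally), gts
    n_gt <- 0L
    for (im in seq_along(predictions)) {
      pr <- Filter(function(p) p$class_id == cl, predictions[[im]])
      gt_idx <- which(ground_truths[[im]]$classes == cl)
      recs[[im]] <- list(preds = pr,
                         gts = ground_truths[[im]]$masks[gt_idx])
      n_gt <- n_gt + length(gt_idx)
    }
    scores <- unlist(lapply(recs, function(r)
      vapply(r$preds, `[[`, 0, "score")))
    img_of <- unlist(lapply(seq_along(recs), function(im)
      rep(im, length(recs[[im]]$preds))))
    ord <- order(scores, decreasing = TRUE)
    tp_mat <- matrix(FALSE, length(ord), nthr)
    for (ti in seq_len(nthr)) {
      # greedy matching must respect global score order within each image;
      # match_class on each image's (already score-sorted) predictions
      for (im in seq_along(recs)) {
        r <- recs[[im]]
        if (!length(r$preds)) next
        o <- order(vapply(r$preds, `[[`, 0, "score"), decreasing = TRUE)
        tps <- match_class(r$preds[o], r$gts, thresholds[ti])
        # map back to global positions
        rows <- which(img_of == im)[o]
        tp_mat[match(rows, ord), ti] <- tps
      }
    }
    aps <- vapply(seq_len(nthr), function(ti)
      ap_from_pr(tp_mat[, ti], !tp_mat[, ti], n_gt), 0)
    # operating point: confidence maximizing F1 at IoU 0.5
    s_sorted <- scores[ord]
    tp50 <- tp_mat[, 1L]
    if (length(ord) && n_gt > 0L) {
      ctp <- cumsum(tp50); cfp <- cumsum(!tp50)
      prec <- ctp / (ctp + cfp); rec <- ctp / n_gt
      f1 <- 2 * prec * rec / pmax(prec + rec, 1e-12)
      k <- which.max(f1)
      p_at <- prec[k]; r_at <- rec[k]
    } else { p_at <- if (n_gt == 0L) NA_real_ else 0; r_at <- p_at }
    per_class[[cl + 1L]] <- data.frame(
      class_id = cl, n_gt = n_gt,
      precision = p_at, recall = r_at,
      ap50 = aps[1L], ap = mean(aps))
  }
  tab <- do.call(rbind, per_class)
  valid <- tab$n_gt > 0L
  structure(list(per_class = tab,
                 mAP50 = mean(tab$ap50[valid]),
                 mAP50_95 = mean(tab$ap[valid]),
                 thresholds = thresholds),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Instance segmentation evaluation (mask IoU)\n")
  print(x$per_class, row.names = FALSE)
  cat(sprintf("mAP@0.5 = %.4f   mAP@0.5:0.95 = %.4f\n", x$mAP50, x$mAP50_95))
  invisible(x)
}
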