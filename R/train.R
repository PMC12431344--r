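# Training loop: AdamW with cosine-annealed learning rate, gradient-norm
# clipping and the composite segmentation loss.

adamw_step <- function(model, lr, betas = c(0.9, 0.999), eps = 1e-8,
                       weight_decay = 5e-4, t = 1L) {
  b1 <- betas[1]; b2 <- betas[2]
  walk_params(model, function(e, nm, path) {
    g <- get0(paste0("g_", nm), envir = e, ifnotfound = NULL)
    if (is.null(g)) return(invisible(NULL))
    p <- get(nm, envir = e)
    ms <- paste0("opt_m_", nm); vs <- paste0("opt_v_", nm)
    m <- get0(ms, envir = e, ifnotfound = NULL)
    v <- get0(vs, envir = e, ifnotfound = NULL)
    if (is.null(m)) { m <- p * 0; v <- p * 0 }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    mh <- m / (1 - b1^t); vh <- v / (1 - b2^t)
    wd <- if (nm %in% c("w", "w1", "w2")) weight_decay else 0
    p <- p - lr * (mh / (sqrt(vh) + eps) + wd * p)
    assign(nm, p, envir = e)
    assign(ms, m, envir = e); assign(vs, v, envir = e)
  })
  invisible(NULL)
}

clip_grads <- function(model, max_norm = 10) {
  gn <- grad_global_norm(model)
  if (is.finite(gn) && gn > max_norm) {
    sc <- max_norm / (gn + 1e-12)
    walk_params(model, function(e, nm, path) {
      slot <- paste0("g_", nm)
      g <- get0(slot, envir = e, ifnotfound = NULL)
      if (!is.null(g)) assign(slot, g * sc, envir = e)
    })
  }
  gn
}

#' Train a segmentation model on an in-memory dataset
#'
#' AdamW (beta1 = 0.9, beta2 = 0.999, weight decay 5e-4), initial learning
#' rate 1e-3 with cosine annealing to 1% of the initial value, gradient-norm
#' clipping at 10, batch size 8 by default.
#'
#' @param model a [build_model()] result (modified in place).
#' @param dataset list of samples, each `list(image, boxes, classes, masks)`
#'   with `image` an (S, S, 3) array in `[0, 1]`.
#' @param epochs,batch_size,lr0,weight_decay,clip training hyperparameters.
#' @param schedule `"cosine"` (anneal to 1% over the run), `"cosine_restarts"`
#'   (5-epoch warm-restart cycles, useful for short runs) or `"constant"`.
#' @param weights optional [class_weights()] table for the loss.
#' @param verbose print a line per epoch.
#' @return data.frame with per-epoch mean loss components (the training log).
#' @export
train_model <- function(model, dataset, epochs = 20L, batch_size = 8L,
                        lr0 = 1e-3, weight_decay = 5e-4, clip = 10,
                        weights = NULL, schedule = c("cosine", "cosine_restarts",
                                                     "constant"),
                        verbose = FALSE) {
  schedule <- match.arg(schedule)
  nimg <- length(dataset)
  steps_per_epoch <- ceiling(nimg / batch_size)
  total_steps <- epochs * steps_per_epoch
  history <- vector("list", epochs)
  step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(nimg)
    ep_loss <- c(total = 0, cls = 0, box = 0, mask = 0, dfl = 0)
    nb <- 0L
    for (bs in seq_len(steps_per_epoch)) {
      idx <- ord[((bs - 1L) * batch_size + 1L):min(bs * batch_size, nimg)]
      batch <- dataset[idx]
      imgs <- array(0, dim = c(dim(batch[[1L]]$image), length(batch)))
      for (i in seq_along(batch)) imgs[, , , i] <- batch[[i]]$image
      raw <- forward(model, imgs, train = TRUE)
      out <- loss_core(raw, lapply(batch, function(b)
        list(boxes = b$boxes, classes = b$classes, masks = b$masks)),
        weights = weights, need_grads = TRUE)
      if (!is.finite(out$total))
        stop("non-finite training loss at epoch ", ep, "; components: ",
             paste(names(out$components), round(out$components, 4), collapse = ", "))
      zero_grads(model)
      backward_model(model, raw, out$dhead)
      clip_grads(model, clip)
      step <- step + 1L
      lr <- switch(schedule,
        cosine = lr0 * (0.01 + 0.99 * 0.5 * (1 + cos(pi * (step - 1L) / total_steps))),
        cosine_restarts = {
          cycle <- 5L * steps_per_epoch
          lr0 * (0.01 + 0.99 * 0.5 * (1 + cos(pi * ((step - 1L) %% cycle) / cycle)))
        },
        constant = lr0)
      adamw_step(model, lr, weight_decay = weight_decay, t = step)
      zero_grads(model)
      ep_loss <- ep_loss + c(out$total, out$components[c("cls", "box", "mask", "dfl")])
      nb <- nb + 1L
    }
    history[[ep]] <- data.frame(epoch = ep, t(ep_loss / nb))
    if (verbose)
      message(sprintf("epoch %d  loss %.4f (cls %.3f box %.3f mask %.3f dfl %.3f)",
                      ep, ep_loss[1] / nb, ep_loss[2] / nb, ep_loss[3] / nb,
                      ep_loss[4] / nb, ep_loss[5] / nb))
  }
  do.call(rbind, history)
}

#' Run a model over a dataset and collect detections
#'
#' @param model trained model.
#' @param dataset list of samples as in [train_model()].
#' @param conf_thresh,iou_thresh decoding thresholds.
#' @return list of per-image instance lists (see [decode_and_nms()]).
#' @export
predict_dataset <- function(model, dataset, conf_thresh = 0.25, iou_thresh = 0.7) {
  lapply(dataset, function(smp) {
    raw <- forward(model, smp$image, train = FALSE)
    decode_and_nms(raw, conf_thresh, iou_thresh)
  })
}
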