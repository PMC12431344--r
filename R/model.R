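# Model assembly for the five architecture variants, forward execution and
# decoding of raw predictions into instances.
#
# Variants:
#   baseline : three detection scales (strides 8/16/32)
#   p2       : adds the stride-4 high-resolution scale and a fourth head
#   p2_cpca  : p2 with every neck C2f replaced by C2f_CPCA
#   p2_cpca1 : p2 with only the four head-adjacent C2f replaced
#   full     : p2_cpca plus a C3RFEM block inserted after SPPF

VARIANTS <- c("baseline", "p2", "p2_cpca", "p2_cpca1", "full")

FARM_CLASSES <- c("unharvested area", "having harvested areas", "farm",
                  "ridge between fields", "slight lodging area", "harvester",
                  "obstacle", "people")

make_div <- function(x, d = 8L) as.integer(max(d, round(x / d) * d))

#' Configuration of one architecture variant
#'
#' @param variant one of `"baseline"`, `"p2"`, `"p2_cpca"`, `"p2_cpca1"`,
#'   `"full"`.
#' @param num_classes number of object classes (default 8, the farmland set).
#' @param depth_multiple,width_multiple nano-scale compound multipliers.
#' @param reg_max number of bins of the discretized box-distance distribution.
#' @param num_prototypes number of shared prototype masks.
#' @param cpca_preset CPCA geometry for the attention variants.
#' @param class_names optional character vector of class names.
#' @return a `farmseg_config` list with derived channel widths and strides.
#' @export
variant_config <- function(variant = "baseline", num_classes = 8L,
                           depth_multiple = 0.33, width_multiple = 0.25,
                           reg_max = 16L, num_prototypes = 32L,
                           cpca_preset = "light",
                           class_names = NULL) {
  variant <- match.arg(variant, VARIANTS)
  if (is.null(class_names))
    class_names <- if (num_classes == 8L) FARM_CLASSES else paste0("class", seq_len(num_classes))
  wch <- function(x) make_div(min(x, 1024) * width_multiple)
  nrep <- function(n) max(1L, round(n * depth_multiple))
  structure(list(
    variant = variant,
    num_classes = as.integer(num_classes),
    depth_multiple = depth_multiple, width_multiple = width_multiple,
    reg_max = as.integer(reg_max),
    num_prototypes = as.integer(num_prototypes),
    proto_channels = wch(256),
    strides = if (variant == "baseline") c(8L, 16L, 32L) else c(4L, 8L, 16L, 32L),
    cpca_preset = cpca_preset,
    class_names = class_names,
    w = vapply(c(64, 128, 256, 512, 1024), wch, 0L),
    n3 = nrep(3L), n6 = nrep(6L)
  ), class = "farmseg_config")
}

# Segmentation head: per-scale decoupled towers + shared prototype head.
nn_seghead <- function(ch, cfg) {
  nc <- cfg$num_classes; reg <- cfg$reg_max
  npm <- cfg$num_prototypes; npr <- cfg$proto_channels
  c2h <- max(16L, ch[1L] %/% 4L, 4L * reg)
  c3h <- max(ch[1L], min(nc, 100L))
  c4h <- max(ch[1L] %/% 4L, npm)
  scales <- lapply(ch, function(c1) {
    sc <- list(
      box = list(nn_convbn(c1, c2h, 3L), nn_convbn(c2h, c2h, 3L),
                 nn_conv(c2h, 4L * reg, 1L, bias = TRUE)),
      cls = list(nn_convbn(c1, c3h, 3L), nn_convbn(c3h, c3h, 3L),
                 nn_conv(c3h, nc, 1L, bias = TRUE)),
      coef = list(nn_convbn(c1, c4h, 3L), nn_convbn(c4h, c4h, 3L),
                  nn_conv(c4h, npm, 1L, bias = TRUE)))
    sc
  })
  proto <- list(nn_convbn(ch[1L], npr, 3L), nn_convT2(npr, npr),
                nn_convbn(npr, npr, 3L), nn_convbn(npr, npm, 1L))
  m <- new_mod("seghead", nscale = length(ch),
               mods = list(scales = scales, proto = proto))
  m$dfl_bins <- 0:(reg - 1L)  # fixed expectation weights, not learnable
  m
}

tower_fwd <- function(tower, x, train) {
  caches <- vector("list", length(tower))
  for (i in seq_along(tower)) {
    f <- blk_fwd(tower[[i]], x, train)
    x <- f$y
    caches[[i]] <- f$cache
  }
  list(y = x, cache = caches)
}

tower_bwd <- function(tower, caches, dy) {
  for (i in rev(seq_along(tower)))
    dy <- blk_bwd(tower[[i]], caches[[i]], dy)
  dy
}

seghead_fwd <- function(m, xs, train = TRUE) {
  out <- list(box = list(), cls = list(), coef = list())
  caches <- list(scales = list())
  for (s in seq_len(m$nscale)) {
    sc <- m$mods$scales[[s]]
    fb <- tower_fwd(sc$box, xs[[s]], train)
    fc <- tower_fwd(sc$cls, xs[[s]], train)
    fm <- tower_fwd(sc$coef, xs[[s]], train)
    out$box[[s]] <- fb$y; out$cls[[s]] <- fc$y; out$coef[[s]] <- fm$y
    caches$scales[[s]] <- list(box = fb$cache, cls = fc$cache, coef = fm$cache)
  }
  fp <- tower_fwd(m$mods$proto, xs[[1L]], train)
  out$proto <- fp$y
  caches$proto <- fp$cache
  list(y = out, cache = caches)
}

# dy: list(box=, cls=, coef= per scale, proto=) -> list of dx per scale input
seghead_bwd <- function(m, cache, dy) {
  dxs <- vector("list", m$nscale)
  for (s in seq_len(m$nscale)) {
    sc <- m$mods$scales[[s]]
    dxs[[s]] <- tower_bwd(sc$box, cache$scales[[s]]$box, dy$box[[s]]) +
      tower_bwd(sc$cls, cache$scales[[s]]$cls, dy$cls[[s]]) +
      tower_bwd(sc$coef, cache$scales[[s]]$coef, dy$coef[[s]])
  }
  dxs[[1L]] <- dxs[[1L]] + tower_bwd(m$mods$proto, cache$proto, dy$proto)
  dxs
}

# ---- graph assembly ---------------------------------------------------------

node <- function(mod, from, tag = "") list(mod = mod, from = from, tag = tag)

#' Build a segmentation model
#'
#' Assembles the layer graph of the requested variant: CSP backbone with SPPF
#' (plus C3RFEM for `full`), PAN-FPN neck (three or four scales, plain C2f or
#' C2f_CPCA per variant) and decoupled segmentation heads with a shared
#' prototype branch. Parameter initialization draws from the R RNG, so
#' `set.seed()` before building gives reproducible weights.
#'
#' @param cfg a [variant_config()].
#' @return a `farmseg_model` environment holding the node graph.
#' @export
build_model <- function(cfg) {
  if (!inherits(cfg, "farmseg_config")) stop("cfg must come from variant_config()")
  w <- cfg$w  # channel widths at 64/128/256/512/1024 base
  n3 <- cfg$n3; n6 <- cfg$n6
  neck_block <- function(c1, c2, role) {
    use_att <- switch(cfg$variant,
                      p2_cpca = , full = TRUE,
                      p2_cpca1 = role == "head",
                      FALSE)
    if (use_att) nn_c2f_cpca(c1, c2, n3, FALSE, preset = cfg$cpca_preset)
    else nn_c2f(c1, c2, n3, FALSE)
  }
  nodes <- list(
    node(nn_convbn(3L, w[1], 3L, 2L), 0L, "stem/P1"),
    node(nn_convbn(w[1], w[2], 3L, 2L), 1L, "down/P2"),
    node(nn_c2f(w[2], w[2], n3, TRUE), 2L, "backbone C2f P2"),
    node(nn_convbn(w[2], w[3], 3L, 2L), 3L, "down/P3"),
    node(nn_c2f(w[3], w[3], n6, TRUE), 4L, "backbone C2f P3"),
    node(nn_convbn(w[3], w[4], 3L, 2L), 5L, "down/P4"),
    node(nn_c2f(w[4], w[4], n6, TRUE), 6L, "backbone C2f P4"),
    node(nn_convbn(w[4], w[5], 3L, 2L), 7L, "down/P5"),
    node(nn_c2f(w[5], w[5], n3, TRUE), 8L, "backbone C2f P5"),
    node(nn_sppf(w[5], w[5], 5L), 9L, "SPPF"))
  b <- 10L  # index (1-based) of the backbone output node
  if (cfg$variant == "full") {
    nodes <- c(nodes, list(node(nn_c3rfem(w[5], w[5]), 10L, "C3RFEM")))
    b <- 11L
  }
  up <- function() new_mod("upsample")
  cat_ <- function() new_mod("concat")
  if (cfg$variant == "baseline") {
    nodes <- c(nodes, list(
      node(up(), b, "up x2"),
      node(cat_(), c(b + 1L, 7L), "cat P4"),
      node(neck_block(w[4] + w[5], w[4], "mid"), b + 2L, "neck C2f P4-td"),
      node(up(), b + 3L, "up x2"),
      node(cat_(), c(b + 4L, 5L), "cat P3"),
      node(neck_block(w[3] + w[4], w[3], "head"), b + 5L, "neck C2f P3"),
      node(nn_convbn(w[3], w[3], 3L, 2L), b + 6L, "down"),
      node(cat_(), c(b + 7L, b + 3L), "cat"),
      node(neck_block(w[3] + w[4], w[4], "head"), b + 8L, "neck C2f P4"),
      node(nn_convbn(w[4], w[4], 3L, 2L), b + 9L, "down"),
      node(cat_(), c(b + 10L, b), "cat"),
      node(neck_block(w[4] + w[5], w[5], "head"), b + 11L, "neck C2f P5")))
    head_from <- b + c(5L, 8L, 11L) + 1L
    head_ch <- c(w[3], w[4], w[5])
  } else {
    nodes <- c(nodes, list(
      node(up(), b, "up x2"),
      node(cat_(), c(b + 1L, 7L), "cat P4"),
      node(neck_block(w[4] + w[5], w[4], "mid"), b + 2L, "neck C2f P4-td"),
      node(up(), b + 3L, "up x2"),
      node(cat_(), c(b + 4L, 5L), "cat P3"),
      node(neck_block(w[3] + w[4], w[3], "mid"), b + 5L, "neck C2f P3-td"),
      node(up(), b + 6L, "up x2"),
      node(cat_(), c(b + 7L, 3L), "cat P2"),
      node(neck_block(w[2] + w[3], w[2], "head"), b + 8L, "neck C2f P2"),
      node(nn_convbn(w[2], w[2], 3L, 2L), b + 9L, "down"),
      node(cat_(), c(b + 10L, b + 6L), "cat"),
      node(neck_block(w[2] + w[3], w[3], "head"), b + 11L, "neck C2f P3"),
      node(nn_convbn(w[3], w[3], 3L, 2L), b + 12L, "down"),
      node(cat_(), c(b + 13L, b + 3L), "cat"),
      node(neck_block(w[3] + w[4], w[4], "head"), b + 14L, "neck C2f P4"),
      node(nn_convbn(w[4], w[4], 3L, 2L), b + 15L, "down"),
      node(cat_(), c(b + 16L, b), "cat"),
      node(neck_block(w[4] + w[5], w[5], "head"), b + 17L, "neck C2f P5")))
    head_from <- b + c(8L, 11L, 14L, 17L) + 1L
    head_ch <- c(w[2], w[3], w[4], w[5])
  }
  head <- nn_seghead(head_ch, cfg)
  model <- new_mod("model", cfg = cfg, nodes = nodes, head = head,
                   head_from = head_from)
  model$mods <- list(nodes = lapply(nodes, `[[`, "mod"), head = head)
  class(model) <- c("farmseg_model", "fs_module")
  model
}

#' Grid sizes and head count of a variant at a given input size
#' @param cfg a [variant_config()].
#' @param imgsz input side length (multiple of 32).
#' @return list with `strides` and integer `grids` (side length per scale).
#' @export
grid_sizes <- function(cfg, imgsz) {
  if (imgsz %% 32L != 0L) stop("input size must be a multiple of 32")
  list(strides = cfg$strides, grids = as.integer(imgsz / cfg$strides))
}

#' Forward pass
#'
#' @param model a [build_model()] result.
#' @param images array (H, W, 3) or (H, W, 3, N) of intensities in `[0, 1]`;
#'   H = W and divisible by 32.
#' @param train logical; training mode uses batch statistics in the
#'   normalization layers and retains caches for the backward pass.
#' @return a raw prediction: per-scale lists `box` (4*reg_max channels),
#'   `cls`, `coef`, plus shared `proto` maps; with `train = TRUE` also the
#'   node caches under `attr(, "caches")`.
#' @export
forward <- function(model, images, train = FALSE) {
  tensor_check(images, "image batch")
  x <- as_batch(images)
  if (dim(x)[1] != dim(x)[2] || dim(x)[1] %% 32L != 0L)
    stop("images must be square with side a multiple of 32")
  if (dim(x)[3] != 3L) stop("images must have 3 channels")
  outs <- vector("list", length(model$nodes))
  caches <- if (train) vector("list", length(model$nodes))
  for (i in seq_along(model$nodes)) {
    nd <- model$nodes[[i]]
    if (nd$mod$type == "concat") {
      y <- concat_c(outs[nd$from])
      if (train) caches[[i]] <- dim(outs[[nd$from[1L]]])[3]
    } else {
      inp <- if (nd$from == 0L) x else outs[[nd$from]]
      f <- blk_fwd(nd$mod, inp, train)
      y <- f$y
      if (train) caches[[i]] <- f$cache
    }
    outs[[i]] <- y
  }
  fh <- seghead_fwd(model$head, outs[model$head_from], train)
  raw <- fh$y
  raw$strides <- model$cfg$strides
  raw$imgsz <- dim(x)[1]
  if (train) {
    attr(raw, "caches") <- list(nodes = caches, head = fh$cache,
                                outs = outs, x = x)
  }
  class(raw) <- "farmseg_raw"
  raw
}

# Backward through the whole graph given gradients on the raw head outputs.
backward_model <- function(model, raw, dhead) {
  caches <- attr(raw, "caches")
  if (is.null(caches)) stop("forward() must be run with train = TRUE")
  douts <- vector("list", length(model$nodes))
  addg <- function(i, g) {
    douts[[i]] <<- if (is.null(douts[[i]])) g else douts[[i]] + g
  }
  dxs <- seghead_bwd(model$head, caches$head, dhead)
  for (s in seq_along(model$head_from)) addg(model$head_from[s], dxs[[s]])
  for (i in rev(seq_along(model$nodes))) {
    if (is.null(douts[[i]])) next
    nd <- model$nodes[[i]]
    if (nd$mod$type == "concat") {
      at <- 0L
      for (j in nd$from) {
        cj <- dim(caches$outs[[j]])[3]
        addg(j, slice_c(douts[[i]], at + seq_len(cj)))
        at <- at + cj
      }
    } else if (nd$from > 0L) {
      addg(nd$from, blk_bwd(nd$mod, caches$nodes[[i]], douts[[i]]))
    } else {
      blk_bwd(nd$mod, caches$nodes[[i]], douts[[i]])
    }
  }
  invisible(NULL)
}

# ---- decoding ---------------------------------------------------------------

softmax_rows <- function(z) {
  z <- exp(z - apply(z, 1L, max))
  z / rowSums(z)
}

# decode one scale of one image into candidate boxes/scores
decode_scale <- function(box, cls, stride, reg_max) {
  H <- dim(box)[1]; W <- dim(box)[2]
  nb <- H * W
  # box channels are side-major: reg_max bins for l, then t, r, b
  bm <- matrix(box, nb, 4L * reg_max)
  lt <- matrix(0, nb, 4L)
  bins <- 0:(reg_max - 1L)
  for (side in 1:4) {
    logits <- bm[, (side - 1L) * reg_max + seq_len(reg_max), drop = FALSE]
    p <- softmax_rows(logits)
    lt[, side] <- p %*% bins
  }
  ij <- arrayInd(seq_len(nb), c(H, W))
  cy <- (ij[, 1L] - 0.5) * stride
  cx <- (ij[, 2L] - 0.5) * stride
  boxes <- cbind(cx - lt[, 1L] * stride, cy - lt[, 2L] * stride,
                 cx + lt[, 3L] * stride, cy + lt[, 4L] * stride)
  colnames(boxes) <- c("x1", "y1", "x2", "y2")
  scores <- 1 / (1 + exp(-matrix(cls, nb, dim(cls)[3])))
  list(boxes = boxes, scores = scores, cy = cy, cx = cx)
}

box_iou_xyxy <- function(a, b) {
  # a: n x 4, b: m x 4
  n <- nrow(a); m <- nrow(b)
  ix1 <- outer(a[, 1L], b[, 1L], pmax); iy1 <- outer(a[, 2L], b[, 2L], pmax)
  ix2 <- outer(a[, 3L], b[, 3L], pmin); iy2 <- outer(a[, 4L], b[, 4L], pmin)
  iw <- pmax(ix2 - ix1, 0); ih <- pmax(iy2 - iy1, 0)
  inter <- iw * ih
  aa <- (a[, 3L] - a[, 1L]) * (a[, 4L] - a[, 2L])
  ab <- (b[, 3L] - b[, 1L]) * (b[, 4L] - b[, 2L])
  un <- outer(aa, ab, `+`) - inter
  ifelse(un > 0, inter / un, 0)
}

nms_class <- function(boxes, scores, iou_thresh) {
  ord <- order(scores, decreasing = TRUE)
  keep <- integer(0)
  while (length(ord)) {
    i <- ord[1L]
    keep <- c(keep, i)
    if (length(ord) == 1L) break
    ious <- box_iou_xyxy(boxes[i, , drop = FALSE], boxes[ord[-1L], , drop = FALSE])
    ord <- ord[-1L][ious[1L, ] <= iou_thresh]
  }
  keep
}

#' Compose an instance mask from prototypes and coefficients
#'
#' `mask = sigmoid(sum_k coeff_k * proto_k)` thresholded strictly above 0.5,
#' cropped to the detection box and upsampled (nearest) to the image size.
#'
#' @param prototypes array (Hp, Wp, K) of prototype maps.
#' @param coeffs numeric vector of length K.
#' @param box numeric (x1, y1, x2, y2) in image pixels; clipped to the image.
#' @param imgsz image side length in pixels.
#' @return binary (0/1) matrix `imgsz x imgsz` (rows = y).
#' @export
compose_masks <- function(prototypes, coeffs, box, imgsz) {
  d <- dim(prototypes)
  if (length(coeffs) != d[3]) stop("coefficient length must equal prototype count")
  lin <- matrix(prototypes, d[1] * d[2], d[3]) %*% coeffs
  m <- matrix(1 / (1 + exp(-lin)) > 0.5, d[1], d[2])
  # crop in prototype coordinates (pixel centers), half-open box
  sc <- d[1] / imgsz
  box <- pmin(pmax(box, 0), imgsz)
  ys <- (seq_len(d[1]) - 0.5) / sc
  xs <- (seq_len(d[2]) - 0.5) / sc
  m[ys < box[2] | ys >= box[4], ] <- FALSE
  m[, xs < box[1] | xs >= box[3]] <- FALSE
  # nearest-neighbour upsample to image size
  idx <- pmin(d[1], floor((seq_len(imgsz) - 0.5) * sc) + 1L)
  storage.mode(m) <- "integer"
  m[idx, idx, drop = FALSE]
}

#' Decode raw predictions into instances
#'
#' Applies the distribution-expectation box decode at every cell, filters by
#' confidence, composes candidate masks from the prototypes, and runs
#' class-wise non-maximum suppression on mask overlap (duplicates of one
#' instance share pixels even when their boxes disagree); detections whose
#' composed mask is empty are dropped.
#'
#' @param raw a raw prediction from [forward()].
#' @param conf_thresh,iou_thresh confidence and NMS IoU thresholds in `[0, 1]`.
#' @param max_det maximum detections kept per image.
#' @param reg_max bins of the distance distribution (16 unless reconfigured).
#' @return for a single-image batch, a list of instances (box, score,
#'   class_id, mask); for larger batches a list per image. Instances are
#'   sorted by decreasing score.
#' @export
decode_and_nms <- function(raw, conf_thresh = 0.25, iou_thresh = 0.7,
                           max_det = 300L, reg_max = 16L) {
  stopifnot(conf_thresh >= 0, conf_thresh <= 1, iou_thresh >= 0, iou_thresh <= 1)
  nimg <- dim(raw$box[[1L]])[4]
  imgsz <- raw$imgsz
  res <- vector("list", nimg)
  for (n in seq_len(nimg)) {
    cand <- list()
    for (s in seq_along(raw$strides)) {
      dec <- decode_scale(raw$box[[s]][, , , n, drop = FALSE],
                          raw$cls[[s]][, , , n, drop = FALSE],
                          raw$strides[s], reg_max)
      conf <- apply(dec$scores, 1L, max)
      keep <- which(conf >= conf_thresh)
      if (!length(keep)) next
      co <- matrix(raw$coef[[s]][, , , n], ncol = dim(raw$coef[[s]])[3])
      cand[[length(cand) + 1L]] <- list(
        boxes = dec$boxes[keep, , drop = FALSE],
        score = conf[keep],
        class_id = max.col(dec$scores[keep, , drop = FALSE], "first") - 1L,
        coef = co[keep, , drop = FALSE])
    }
    if (!length(cand)) { res[[n]] <- list(); next }
    boxes <- do.call(rbind, lapply(cand, `[[`, "boxes"))
    score <- unlist(lapply(cand, `[[`, "score"))
    clsid <- unlist(lapply(cand, `[[`, "class_id"))
    coef <- do.call(rbind, lapply(cand, `[[`, "coef"))
    # cap the candidate pool before mask composition
    if (length(score) > 4L * max_det) {
      top <- order(score, decreasing = TRUE)[seq_len(4L * max_det)]
      boxes <- boxes[top, , drop = FALSE]; score <- score[top]
      clsid <- clsid[top]; coef <- coef[top, , drop = FALSE]
    }
    proto <- array(raw$proto[, , , n], dim = dim(raw$proto)[1:3])
    pdim <- dim(proto)
    # compose all candidate masks at prototype resolution in one product
    lin <- matrix(proto, pdim[1] * pdim[2], pdim[3]) %*% t(coef)
    mm <- lin > 0                       # sigmoid(z) > 0.5  <=>  z > 0
    sc <- pdim[1] / imgsz
    pys <- (rep(seq_len(pdim[1]), pdim[2]) - 0.5) / sc
    pxs <- (rep(seq_len(pdim[2]), each = pdim[1]) - 0.5) / sc
    for (i in seq_along(score)) {
      b <- pmin(pmax(boxes[i, ], 0), imgsz)
      mm[pys < b[2] | pys >= b[4] | pxs < b[1] | pxs >= b[3], i] <- FALSE
    }
    areas <- colSums(mm)
    ok <- which(areas > 0)              # drop detections with empty masks
    # greedy class-wise suppression on mask overlap: duplicates of one
    # instance share pixels even when their boxes are sloppy
    keep <- integer(0)
    for (cl in unique(clsid[ok])) {
      idx <- ok[clsid[ok] == cl]
      idx <- idx[order(score[idx], decreasing = TRUE)]
      while (length(idx)) {
        i <- idx[1L]
        keep <- c(keep, i)
        if (length(idx) == 1L) break
        rest <- idx[-1L]
        inter <- colSums(mm[, rest, drop = FALSE] & mm[, i])
        iou <- inter / (areas[rest] + areas[i] - inter)
        idx <- rest[iou <= iou_thresh]
      }
    }
    keep <- keep[order(score[keep], decreasing = TRUE)]
    if (length(keep) > max_det) keep <- keep[seq_len(max_det)]
    idxup <- pmin(pdim[1], floor((seq_len(imgsz) - 0.5) * sc) + 1L)
    res[[n]] <- lapply(keep, function(i) {
      b <- pmin(pmax(boxes[i, ], 0), imgsz)
      mi <- matrix(mm[, i], pdim[1], pdim[2])
      storage.mode(mi) <- "integer"
      list(box = unname(b), score = unname(score[i]), class_id = clsid[i],
           mask = mi[idxup, idxup, drop = FALSE])
    })
  }
  if (nimg == 1L) res[[1L]] else res
}

#' @export
print.farmseg_model <- function(x, ...) {
  cat("<farmseg model>", x$cfg$variant, "-", length(x$cfg$strides),
      "detection scales, strides", paste(x$cfg$strides, collapse = "/"),
      "-", x$cfg$num_classes, "classes\n")
  invisible(x)
}
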