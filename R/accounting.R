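# Architecture bookkeeping: learnable-parameter counts and FLOP estimates.
#
# Parameter counts are reported, by default, in the deploy-time ("fused")
# convention: every Conv-BN unit is counted as its convolution weights plus
# one bias per output channel, i.e. with the batch-norm affine pair folded
# into the convolution. The raw training-time sum (BN scale and shift counted
# separately) is available with fused = FALSE. The 16 fixed expectation
# weights of the box-distribution decode layer are included, matching the
# reporting convention of mainstream detection frameworks.

count_mod <- function(m, fused) {
  n <- 0
  if (is.environment(m)) {
    for (nm in PARAM_NAMES) {
      v <- get0(nm, envir = m, ifnotfound = NULL)
      if (is.null(v)) next
      n <- n + if (fused && m$type == "convbn" && nm == "gamma") length(v)
        else if (fused && m$type == "convbn" && nm == "beta") 0L
        else length(v)
    }
    sub <- get0("mods", envir = m, ifnotfound = NULL)
    if (!is.null(sub)) n <- n + count_mod(sub, fused)
  } else if (is.list(m)) {
    for (x in m) n <- n + count_mod(x, fused)
  }
  n
}

#' Count learnable parameters
#'
#' Sums every learnable scalar of a module or model: convolution kernels and
#' biases, normalization scale/shift, MLP weights. For a full model the fixed
#' box-distribution expectation weights (reg_max scalars) are included.
#'
#' @param m a model from [build_model()] or any single block/module.
#' @param fused count Conv-BN units in the folded deploy convention
#'   (default TRUE); `FALSE` counts BN scale and shift separately.
#' @return integer parameter count.
#' @export
count_params <- function(m, fused = TRUE) {
  n <- count_mod(m, fused)
  if (inherits(m, "farmseg_model")) n <- n + m$cfg$reg_max
  as.integer(n)
}

# ---- FLOPs ------------------------------------------------------------------

# MACs of one primitive conv at output side 'ho'
conv_macs <- function(m, ho) {
  wd <- dim(m$w)
  if (m$type == "convT2") return(4 * wd[4] * wd[3] * (2 * ho)^2)
  wd[1] * wd[2] * wd[3] * wd[4] * ho * ho
}

# Recursive MAC count of a block given input side length h.
# convention "profile": standard Conv / Conv-BN / head conv / convT layers
# only (the profiler-parity convention the headline GFLOPs use).
# convention "all": additionally counts attention and RFEM internals,
# pooling, and one op per activation output.
block_macs <- function(m, h, convention) {
  all_ops <- convention == "all"
  act <- function(cout, ho) if (all_ops) cout * ho * ho / 2 else 0
  switch(m$type,
    conv = , convbn = {
      ho <- h %/% m$stride
      conv_macs(m, ho) + act(dim(m$w)[4], ho)
    },
    convT2 = conv_macs(m, h),
    bottleneck = block_macs(m$mods$cv1, h, convention) +
      block_macs(m$mods$cv2, h, convention),
    c2f = , c2f_cpca = {
      n <- m$n
      s <- block_macs(m$mods$cv1, h, convention) +
        block_macs(m$mods$cv2, h, convention)
      for (i in seq_len(n)) s <- s + block_macs(m$mods[[paste0("m", i)]], h, convention)
      if (m$type == "c2f_cpca" && all_ops) s <- s + block_macs(m$mods$att, h, convention)
      s
    },
    cpca = {
      if (!all_ops) return(0)
      s <- 0
      for (sm in m$mods) s <- s + block_macs(sm, h, convention)
      s + 2 * m$channels * h * h  # two elementwise attention products
    },
    sppf = {
      ch <- dim(m$mods$cv1$w)[4]
      block_macs(m$mods$cv1, h, convention) +
        block_macs(m$mods$cv2, h, convention) +
        (if (all_ops) 3 * ch * h * h else 0)
    },
    rfem = {
      if (!all_ops) return(0)
      s <- 0
      for (sm in m$mods) s <- s + block_macs(sm, h, convention)
      s + 3 * 9 * m$channels * h * h + m$channels * h * h
    },
    c3 = , c3rfem = {
      s <- block_macs(m$mods$cv1, h, convention) +
        block_macs(m$mods$cv2, h, convention) +
        block_macs(m$mods$cv3, h, convention)
      if (m$type == "c3rfem") s + block_macs(m$mods$rfem, h, convention)
      else {
        for (i in seq_len(m$n)) s <- s + block_macs(m$mods[[paste0("m", i)]], h, convention)
        s
      }
    },
    upsample = 0,
    concat = 0,
    stop("block_macs: unknown type ", m$type))
}

#' Estimate FLOPs of a model at a given input size
#'
#' Sums multiply-accumulates layer by layer over the graph at the spatial
#' resolution each layer sees, doubles them (1 MAC = 2 FLOPs) and reports
#' GFLOPs. The default `"profile"` convention counts the standard
#' convolution/linear layers of the graph -- the convention under which the
#' canonical nano-scale baseline measures 12.0 GFLOPs at 640 x 640;
#' `"all"` additionally counts attention/RFEM internals, pooling and
#' activations.
#'
#' @param model a [build_model()] result.
#' @param imgsz input side length (multiple of 32).
#' @param convention `"profile"` (default) or `"all"`.
#' @param digits decimal places of the returned value (default 1); `NA` for
#'   the unrounded value.
#' @return GFLOPs (numeric scalar).
#' @export
count_flops <- function(model, imgsz = 640L, convention = c("profile", "all"),
                        digits = 1L) {
  convention <- match.arg(convention)
  if (imgsz %% 32L != 0L) stop("input size must be a multiple of 32")
  macs <- 0
  hs <- numeric(length(model$nodes))  # output side per node
  for (i in seq_along(model$nodes)) {
    nd <- model$nodes[[i]]
    hin <- if (identical(nd$from[1L], 0L)) imgsz else hs[nd$from[1L]]
    m <- nd$mod
    hs[i] <- switch(m$type,
                    conv = , convbn = hin %/% m$stride,
                    upsample = 2L * hin,
                    hin)
    if (m$type != "concat") macs <- macs + block_macs(m, hin, convention)
  }
  # segmentation head
  cfg <- model$cfg
  head <- model$head
  anchors <- 0
  for (s in seq_len(head$nscale)) {
    hsc <- hs[model$head_from[s]]
    anchors <- anchors + hsc^2
    for (tw in model$head$mods$scales[[s]])
      for (mm in tw) macs <- macs + block_macs(mm, hsc, convention)
  }
  h0 <- hs[model$head_from[1L]]
  pr <- head$mods$proto
  macs <- macs + block_macs(pr[[1L]], h0, convention) +
    block_macs(pr[[2L]], h0, convention) +
    block_macs(pr[[3L]], 2 * h0, convention) +
    block_macs(pr[[4L]], 2 * h0, convention)
  macs <- macs + cfg$reg_max * 4 * anchors  # distribution expectation decode
  g <- 2 * macs / 1e9
  if (is.na(digits)) g else round(g, digits)
}

#' Architecture accounting table for the five variants
#'
#' Builds each requested variant and reports its parameter count and GFLOPs,
#' with a per-layer parameter breakdown attached for diagnosing mismatches.
#'
#' @param variants character vector of variant ids (default: all five).
#' @param imgsz input side for the FLOP estimate.
#' @param num_classes classes configured in the heads.
#' @return data.frame with columns `variant`, `parameters`, `gflops`;
#'   attribute `"breakdown"` holds a per-layer data.frame per variant.
#' @export
report_table <- function(variants = VARIANTS, imgsz = 640L, num_classes = 8L) {
  rows <- list(); breakdown <- list()
  for (v in variants) {
    cfg <- variant_config(v, num_classes = num_classes)
    model <- build_model(cfg)
    rows[[v]] <- data.frame(variant = v,
                            parameters = count_params(model),
                            gflops = count_flops(model, imgsz))
    per <- data.frame(
      layer = c(vapply(model$nodes, `[[`, "", "tag"), "head"),
      params = c(vapply(model$nodes, function(nd) count_mod(nd$mod, TRUE), 0),
                 count_mod(model$head, TRUE) + cfg$reg_max))
    breakdown[[v]] <- per
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "breakdown") <- breakdown
  out
}
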