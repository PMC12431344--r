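# Convolutional building blocks of the segmentation networks.
#
# All blocks preserve spatial size (stride-1 internals); downsampling happens
# only through explicit stride-2 Conv units in the backbone/neck. Blocks are
# composites of the primitive modules in nn.R and carry their own
# forward/backward so the whole graph is trainable.

concat_c <- function(xs) {
  d <- dim(xs[[1L]])
  cs <- vapply(xs, function(x) dim(x)[3], 0L)
  out <- array(0, dim = c(d[1], d[2], sum(cs), d[4]))
  at <- 0L
  for (x in xs) {
    out[, , at + seq_len(dim(x)[3]), ] <- x
    at <- at + dim(x)[3]
  }
  out
}

slice_c <- function(x, idx) x[, , idx, , drop = FALSE]

#' Standard bottleneck: two 3x3 Conv units with optional residual
#' @keywords internal
nn_bottleneck <- function(c1, c2, shortcut = TRUE, k = c(3L, 3L), e = 1.0) {
  ch <- as.integer(c2 * e)
  new_mod("bottleneck", shortcut = shortcut && c1 == c2,
          mods = list(cv1 = nn_convbn(c1, ch, k[1]),
                      cv2 = nn_convbn(ch, c2, k[2])))
}

#' Split-bottleneck-concatenate block (C2f)
#'
#' `cv1` projects to two hidden-width halves; one half runs through `n`
#' chained bottlenecks, each intermediate map is kept, and the (2 + n)
#' hidden-width chunks are concatenated and fused by a 1x1 Conv unit.
#'
#' @param c1,c2 input/output channels.
#' @param n bottleneck repeat count.
#' @param shortcut residual connections inside the bottlenecks.
#' @param e hidden-width expansion ratio (hidden = c2 * e).
#' @export
nn_c2f <- function(c1, c2, n = 1L, shortcut = FALSE, e = 0.5) {
  ch <- as.integer(c2 * e)
  if (2L * ch != as.integer(2 * c2 * e)) stop("odd hidden width in C2f config")
  mods <- list(cv1 = nn_convbn(c1, 2L * ch, 1L),
               cv2 = nn_convbn((2L + n) * ch, c2, 1L))
  for (i in seq_len(n))
    mods[[paste0("m", i)]] <- nn_bottleneck(ch, ch, shortcut, e = 1.0)
  new_mod("c2f", n = as.integer(n), hidden = ch, mods = mods)
}

#' C2f with a channel-prior-attention direct branch (C2f_CPCA)
#'
#' The direct-pass half of C2f is no longer retained as-is: it is refined by a
#' CPCA block, and the plain copy of the second half is dropped, so the
#' concatenation has (1 + n) hidden-width chunks before the 1x1 fuse.
#'
#' @inheritParams nn_c2f
#' @param preset CPCA geometry passed to [nn_cpca()].
#' @export
nn_c2f_cpca <- function(c1, c2, n = 1L, shortcut = FALSE, e = 0.5,
                        preset = "light") {
  ch <- as.integer(c2 * e)
  mods <- list(cv1 = nn_convbn(c1, 2L * ch, 1L),
               att = nn_cpca(ch, preset = preset),
               cv2 = nn_convbn((1L + n) * ch, c2, 1L))
  for (i in seq_len(n))
    mods[[paste0("m", i)]] <- nn_bottleneck(ch, ch, shortcut, e = 1.0)
  new_mod("c2f_cpca", n = as.integer(n), hidden = ch, mods = mods)
}

#' Spatial pyramid pooling (fast) block
#' @param c1,c2 input/output channels.
#' @param k pooling kernel (odd, stride 1, same padding).
#' @export
nn_sppf <- function(c1, c2, k = 5L) {
  if (k %% 2L == 0L) stop("SPPF pool kernel must be odd")
  ch <- c1 %/% 2L
  new_mod("sppf", k = as.integer(k),
          mods = list(cv1 = nn_convbn(c1, ch, 1L),
                      cv2 = nn_convbn(4L * ch, c2, 1L)))
}

#' Receptive-field enhancement block (RFEM)
#'
#' Four parallel branches on the same input: an identity-path 1x1 convolution,
#' and for each dilation d in `rates` a parameter-free depthwise 3x3 mean
#' aggregation at dilation d followed by a 1x1 convolution. Branch outputs are
#' summed, fused by a 1x1 weighted layer with SiLU, and added back to the
#' input (residual). The dilated aggregation gives the d = 3 branch a 7x7
#' composite receptive field while all learnable weights stay pointwise, so
#' the block costs exactly 5 (C^2 + C) parameters.
#'
#' @param channels in = out channel count (required by the residual).
#' @param rates dilation rates of the aggregation branches.
#' @export
nn_rfem <- function(channels, rates = c(1L, 2L, 3L)) {
  C <- as.integer(channels)
  mods <- list(pw0 = nn_conv(C, C, 1L, bias = TRUE))
  for (d in rates) mods[[paste0("pw", d)]] <- nn_conv(C, C, 1L, bias = TRUE)
  mods$mix <- nn_conv(C, C, 1L, bias = TRUE)
  m <- new_mod("rfem", rates = as.integer(rates), channels = C, mods = mods)
  m$smooth <- array(1 / 9, dim = c(3L, 3L, 1L, C))  # fixed, not learnable
  m
}

#' Cross-stage-partial block with three Conv units (C3)
#' @export
nn_c3 <- function(c1, c2, n = 1L, shortcut = TRUE, e = 0.5) {
  ch <- as.integer(c2 * e)
  mods <- list(cv1 = nn_convbn(c1, ch, 1L),
               cv2 = nn_convbn(c1, ch, 1L),
               cv3 = nn_convbn(2L * ch, c2, 1L))
  for (i in seq_len(n))
    mods[[paste0("m", i)]] <- nn_bottleneck(ch, ch, shortcut, k = c(1L, 3L), e = 1.0)
  new_mod("c3", n = as.integer(n), hidden = ch, mods = mods)
}

#' C3 block with the bottleneck stack replaced by RFEM (C3RFEM)
#' @export
nn_c3rfem <- function(c1, c2, e = 0.5) {
  ch <- as.integer(c2 * e)
  new_mod("c3rfem", hidden = ch,
          mods = list(cv1 = nn_convbn(c1, ch, 1L),
                      cv2 = nn_convbn(c1, ch, 1L),
                      cv3 = nn_convbn(2L * ch, c2, 1L),
                      rfem = nn_rfem(ch)))
}

# ---- block forward/backward -------------------------------------------------

blk_fwd <- function(m, x, train = TRUE) {
  switch(m$type,
    conv = , convbn = , convT2 = mod_fwd(m, x, train),
    cpca = cpca_fwd(m, x, train),
    upsample = list(y = upsample2_fwd(x), cache = NULL),
    bottleneck = {
      f1 <- blk_fwd(m$mods$cv1, x, train)
      f2 <- blk_fwd(m$mods$cv2, f1$y, train)
      y <- if (m$shortcut) f2$y + x else f2$y
      list(y = y, cache = list(c1 = f1$cache, c2 = f2$cache))
    },
    c2f = {
      f1 <- blk_fwd(m$mods$cv1, x, train)
      ch <- m$hidden
      chunks <- list(slice_c(f1$y, seq_len(ch)),
                     slice_c(f1$y, ch + seq_len(ch)))
      bcaches <- list()
      cur <- chunks[[2L]]
      for (i in seq_len(m$n)) {
        fb <- blk_fwd(m$mods[[paste0("m", i)]], cur, train)
        cur <- fb$y
        chunks[[2L + i]] <- cur
        bcaches[[i]] <- fb$cache
      }
      f2 <- blk_fwd(m$mods$cv2, concat_c(chunks), train)
      list(y = f2$y, cache = list(c1 = f1$cache, c2 = f2$cache, b = bcaches))
    },
    c2f_cpca = {
      f1 <- blk_fwd(m$mods$cv1, x, train)
      ch <- m$hidden
      y1 <- slice_c(f1$y, seq_len(ch))
      y2 <- slice_c(f1$y, ch + seq_len(ch))
      fa <- blk_fwd(m$mods$att, y1, train)
      chunks <- list(fa$y)
      bcaches <- list()
      cur <- y2
      for (i in seq_len(m$n)) {
        fb <- blk_fwd(m$mods[[paste0("m", i)]], cur, train)
        cur <- fb$y
        chunks[[1L + i]] <- cur
        bcaches[[i]] <- fb$cache
      }
      f2 <- blk_fwd(m$mods$cv2, concat_c(chunks), train)
      list(y = f2$y, cache = list(c1 = f1$cache, att = fa$cache,
                                  c2 = f2$cache, b = bcaches))
    },
    sppf = {
      f1 <- blk_fwd(m$mods$cv1, x, train)
      p1 <- maxpool_fwd(f1$y, m$k)
      p2 <- maxpool_fwd(p1$y, m$k)
      p3 <- maxpool_fwd(p2$y, m$k)
      f2 <- blk_fwd(m$mods$cv2, concat_c(list(f1$y, p1$y, p2$y, p3$y)), train)
      list(y = f2$y, cache = list(c1 = f1$cache, c2 = f2$cache,
                                  a1 = p1$arg, a2 = p2$arg, a3 = p3$arg))
    },
    rfem = {
      f0 <- blk_fwd(m$mods$pw0, x, train)
      s <- f0$y
      caches <- list(pw0 = f0$cache)
      for (d in m$rates) {
        sm <- conv2d_fwd(x, m$smooth, NULL, 1L, d, d, d, m$channels)
        fd <- blk_fwd(m$mods[[paste0("pw", d)]], sm, train)
        s <- s + fd$y
        caches[[paste0("pw", d)]] <- fd$cache
      }
      fm <- blk_fwd(m$mods$mix, s, train)
      a <- silu_fwd(fm$y)
      list(y = x + a, cache = c(caches, list(mix = fm$cache, pre = fm$y)))
    },
    c3 = , c3rfem = {
      f1 <- blk_fwd(m$mods$cv1, x, train)
      cur <- f1$y
      inner <- list()
      if (m$type == "c3rfem") {
        fi <- blk_fwd(m$mods$rfem, cur, train)
        cur <- fi$y
        inner[[1L]] <- fi$cache
      } else {
        for (i in seq_len(m$n)) {
          fi <- blk_fwd(m$mods[[paste0("m", i)]], cur, train)
          cur <- fi$y
          inner[[i]] <- fi$cache
        }
      }
      f2 <- blk_fwd(m$mods$cv2, x, train)
      f3 <- blk_fwd(m$mods$cv3, concat_c(list(cur, f2$y)), train)
      list(y = f3$y, cache = list(c1 = f1$cache, c2 = f2$cache, c3 = f3$cache,
                                  inner = inner))
    },
    stop("blk_fwd: unknown block type ", m$type))
}

blk_bwd <- function(m, cache, dy) {
  switch(m$type,
    conv = , convbn = , convT2 = mod_bwd(m, cache, dy),
    cpca = cpca_bwd(m, cache, dy),
    upsample = upsample2_bwd(dy),
    bottleneck = {
      d2 <- blk_bwd(m$mods$cv2, cache$c2, dy)
      d1 <- blk_bwd(m$mods$cv1, cache$c1, d2)
      if (m$shortcut) d1 + dy else d1
    },
    c2f = {
      dcat <- blk_bwd(m$mods$cv2, cache$c2, dy)
      ch <- m$hidden
      dchunks <- lapply(seq_len(2L + m$n),
                        function(i) slice_c(dcat, (i - 1L) * ch + seq_len(ch)))
      dcur <- dchunks[[2L + m$n]]
      for (i in rev(seq_len(m$n))) {
        dprev <- blk_bwd(m$mods[[paste0("m", i)]], cache$b[[i]], dcur)
        dcur <- dprev + (if (i > 1L) dchunks[[1L + i]] else dchunks[[2L]])
      }
      dy0 <- concat_c(list(dchunks[[1L]], dcur))
      blk_bwd(m$mods$cv1, cache$c1, dy0)
    },
    c2f_cpca = {
      dcat <- blk_bwd(m$mods$cv2, cache$c2, dy)
      ch <- m$hidden
      dchunks <- lapply(seq_len(1L + m$n),
                        function(i) slice_c(dcat, (i - 1L) * ch + seq_len(ch)))
      dcur <- if (m$n > 0L) dchunks[[1L + m$n]] else NULL
      for (i in rev(seq_len(m$n))) {
        dprev <- blk_bwd(m$mods[[paste0("m", i)]], cache$b[[i]], dcur)
        dcur <- if (i > 1L) dprev + dchunks[[i]] else dprev
      }
      dy1 <- blk_bwd(m$mods$att, cache$att, dchunks[[1L]])
      dy0 <- concat_c(list(dy1, dcur))
      blk_bwd(m$mods$cv1, cache$c1, dy0)
    },
    sppf = {
      dcat <- blk_bwd(m$mods$cv2, cache$c2, dy)
      ch <- dim(dcat)[3] %/% 4L
      d0 <- slice_c(dcat, seq_len(ch))
      d1 <- slice_c(dcat, ch + seq_len(ch))
      d2 <- slice_c(dcat, 2L * ch + seq_len(ch))
      d3 <- slice_c(dcat, 3L * ch + seq_len(ch))
      d2 <- d2 + maxpool_bwd(d3, cache$a3)
      d1 <- d1 + maxpool_bwd(d2, cache$a2)
      d0 <- d0 + maxpool_bwd(d1, cache$a1)
      blk_bwd(m$mods$cv1, cache$c1, d0)
    },
    rfem = {
      da <- silu_bwd(dy, cache$pre)
      ds <- blk_bwd(m$mods$mix, cache$mix, da)
      dx <- dy + blk_bwd(m$mods$pw0, cache$pw0, ds)
      for (d in m$rates) {
        dsm <- blk_bwd(m$mods[[paste0("pw", d)]], cache[[paste0("pw", d)]], ds)
        g <- conv2d_bwd(cache$pw0$x, m$smooth, dsm, 1L, d, d, d, m$channels,
                        FALSE, TRUE)
        dx <- dx + g$dx
      }
      dx
    },
    c3 = , c3rfem = {
      dcat <- blk_bwd(m$mods$cv3, cache$c3, dy)
      ch <- m$hidden
      dcur <- slice_c(dcat, seq_len(ch))
      db <- slice_c(dcat, ch + seq_len(ch))
      dx <- blk_bwd(m$mods$cv2, cache$c2, db)
      if (m$type == "c3rfem") {
        dcur <- blk_bwd(m$mods$rfem, cache$inner[[1L]], dcur)
      } else {
        for (i in rev(seq_len(m$n)))
          dcur <- blk_bwd(m$mods[[paste0("m", i)]], cache$inner[[i]], dcur)
      }
      dx + blk_bwd(m$mods$cv1, cache$c1, dcur)
    },
    stop("blk_bwd: unknown block type ", m$type))
}
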