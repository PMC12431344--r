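# Channel-prior convolutional attention (CPCA).
#
# The block refines a feature map in two sequential stages:
#   Fc = CA(F) (x) F     -- channel attention, weights C x 1 x 1 in (0,1)
#   Fb = SA(Fc) (x) Fc   -- per-channel spatial attention, same shape as Fc
# CA pools the map globally (average and max), pushes both descriptors through
# a shared MLP and squashes the summed outputs with a sigmoid.  SA applies a
# depthwise 5x5 convolution, adds multi-scale depthwise strip branches on top
# of an identity branch, and finishes with a 1x1 mixing step.  The raw mixing
# output multiplies Fc directly (no extra squashing).
#
# Two geometries are provided:
#  * "light" (default): the shared MLP is a channel-shared scalar bottleneck
#    (8 hidden units, no bias), one strip pair of length 3, and the 1x1 mix is
#    per-channel.  Costs exactly 33*C + 16 learnable scalars, so swapping it
#    into a C2f block always reduces the block's parameter count.
#  * "reference": dense channel MLP with reduction 16 (hidden floor 8), strip
#    pairs of lengths 7/11/21 and a dense 1x1 channel-mixing convolution, the
#    geometry of the original CPCA design.

#' Create CPCA attention parameters
#'
#' @param channels number of input channels C.
#' @param preset `"light"` (default) or `"reference"`; see Details.
#' @param mlp_hidden hidden width of the shared MLP. Defaults to 8 for
#'   `"light"` and `max(channels %/% 16, 8)` for `"reference"`.
#' @param strip_kernels integer vector of strip-convolution lengths for the
#'   multi-scale spatial branches (each length k adds a depthwise 1xk followed
#'   by kx1 pair). Defaults to 3 for `"light"`, c(7, 11, 21) for `"reference"`.
#' @return a CPCA module usable with [channel_attention()], [spatial_attention()]
#'   and [cpca()].
#' @details The `"light"` geometry keeps the attention cost linear in the
#'   channel count (33 C + 16 parameters), which is what makes the C2f_CPCA
#'   neck lighter than the plain C2f neck it replaces. The `"reference"`
#'   geometry is the heavier published CPCA design and is retained for
#'   comparison studies.
#' @export
nn_cpca <- function(channels, preset = c("light", "reference"),
                    mlp_hidden = NULL, strip_kernels = NULL) {
  preset <- match.arg(preset)
  C <- as.integer(channels)
  if (C < 1L) stop("channels must be >= 1")
  if (is.null(mlp_hidden))
    mlp_hidden <- if (preset == "light") 8L else max(C %/% 16L, 8L)
  if (is.null(strip_kernels))
    strip_kernels <- if (preset == "light") 3L else c(7L, 11L, 21L)
  h <- as.integer(mlp_hidden)
  m <- new_mod("cpca", preset = preset, channels = C, hidden = h,
               strip_kernels = as.integer(strip_kernels))
  if (preset == "light") {
    # channel-shared scalar bottleneck MLP, no bias
    m$w1 <- init_w(c(h, 1L), 1)          # scalar -> hidden
    m$w2 <- init_w(c(1L, h), h)          # hidden -> scalar
  } else {
    m$w1 <- init_w(c(h, C), C); m$b1 <- rep(0, h)
    m$w2 <- init_w(c(C, h), h); m$b2 <- rep(0, C)
  }
  mods <- list(dw = nn_conv(C, C, 5L, groups = C, bias = TRUE))
  for (k in m$strip_kernels) {
    sh <- nn_conv(C, C, 1L, groups = C, bias = FALSE)
    sh$w <- init_w(c(1L, k, 1L, C), k); sh$pad <- c(0L, k %/% 2L)
    sv <- nn_conv(C, C, 1L, groups = C, bias = FALSE)
    sv$w <- init_w(c(k, 1L, 1L, C), k); sv$pad <- c(k %/% 2L, 0L)
    mods[[paste0("sh", k)]] <- sh
    mods[[paste0("sv", k)]] <- sv
  }
  mods$mix <- if (preset == "light")
    nn_conv(C, C, 1L, groups = C, bias = FALSE)
  else
    nn_conv(C, C, 1L, bias = TRUE)
  m$mods <- mods
  m
}

# extra parameter slots used by the CPCA MLP
CPCA_PARAMS <- c("w1", "b1", "w2", "b2")

# shared-MLP forward on a C x N matrix of pooled descriptors
cpca_mlp_fwd <- function(m, v) {
  if (m$preset == "light") {
    z <- outer(as.vector(m$w1), as.vector(v))        # h x (C*N)
    r <- pmax(z, 0)
    o <- as.vector(matrix(m$w2, 1L) %*% r)
    dim(o) <- dim(v)
    list(o = o, mask = z > 0, v = v)
  } else {
    z <- m$w1 %*% v + m$b1                           # h x N
    r <- pmax(z, 0)
    o <- m$w2 %*% r + m$b2
    list(o = o, mask = z > 0, v = v)
  }
}

# returns dv and accumulates MLP parameter grads
cpca_mlp_bwd <- function(m, cache, do) {
  if (m$preset == "light") {
    dr <- outer(as.vector(m$w2), as.vector(do))      # h x (C*N)
    r <- pmax(outer(as.vector(m$w1), as.vector(cache$v)), 0)
    acc_grad(m, "w2", matrix(r %*% as.vector(do), 1L, m$hidden))
    dz <- dr * cache$mask
    acc_grad(m, "w1", matrix(dz %*% as.vector(cache$v), m$hidden, 1L))
    dv <- as.vector(as.vector(m$w1) %*% dz)
    dim(dv) <- dim(cache$v)
    dv
  } else {
    z <- m$w1 %*% cache$v + m$b1
    r <- pmax(z, 0)
    acc_grad(m, "w2", do %*% t(r))
    acc_grad(m, "b2", rowSums(do))
    dr <- t(m$w2) %*% do
    dz <- dr * cache$mask
    acc_grad(m, "w1", dz %*% t(cache$v))
    acc_grad(m, "b1", rowSums(dz))
    t(m$w1) %*% dz
  }
}

cpca_ca_fwd <- function(m, x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  xm <- matrix(x, H * W, C * N)
  avg <- matrix(colMeans(xm), C, N)
  arg <- max.col(t(xm), ties.method = "first")       # index of max per (c,n)
  mx <- matrix(xm[cbind(arg, seq_len(C * N))], C, N)
  fa <- cpca_mlp_fwd(m, avg)
  fm <- cpca_mlp_fwd(m, mx)
  ca <- 1 / (1 + exp(-(fa$o + fm$o)))
  list(ca = ca, fa = fa, fm = fm, arg = arg)
}

cpca_ca_bwd <- function(m, cache, x, dca) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  dpre <- dca * cache$ca * (1 - cache$ca)
  davg <- cpca_mlp_bwd(m, cache$fa, dpre)
  dmx <- cpca_mlp_bwd(m, cache$fm, dpre)
  dx <- array(rep(as.vector(davg) / (H * W), each = H * W), dim = d)
  dxm <- matrix(dx, H * W, C * N)
  idx <- cbind(cache$arg, seq_len(C * N))
  dxm[idx] <- dxm[idx] + as.vector(dmx)
  array(dxm, dim = d)
}

cpca_sa_fwd <- function(m, fc, train = TRUE) {
  f1 <- mod_fwd(m$mods$dw, fc, train)
  s <- f1$y
  branch_caches <- list()
  for (k in m$strip_kernels) {
    fh <- mod_fwd(m$mods[[paste0("sh", k)]], f1$y, train)
    fv <- mod_fwd(m$mods[[paste0("sv", k)]], fh$y, train)
    s <- s + fv$y
    branch_caches[[as.character(k)]] <- list(h = fh$cache, v = fv$cache)
  }
  fm <- mod_fwd(m$mods$mix, s, train)
  list(sa = fm$y, dw = f1$cache, branches = branch_caches, mix = fm$cache)
}

cpca_sa_bwd <- function(m, cache, dsa) {
  ds <- mod_bwd(m$mods$mix, cache$mix, dsa)
  dd <- ds
  for (k in m$strip_kernels) {
    bc <- cache$branches[[as.character(k)]]
    dh <- mod_bwd(m$mods[[paste0("sv", k)]], bc$v, ds)
    dd <- dd + mod_bwd(m$mods[[paste0("sh", k)]], bc$h, dh)
  }
  mod_bwd(m$mods$dw, cache$dw, dd)
}

cpca_fwd <- function(m, x, train = TRUE) {
  d <- dim(x)
  ca <- cpca_ca_fwd(m, x)
  fc <- x * rep(as.vector(ca$ca), each = d[1] * d[2])
  sa <- cpca_sa_fwd(m, fc, train)
  y <- sa$sa * fc
  list(y = y, cache = list(x = x, ca = ca, fc = fc, sa = sa))
}

cpca_bwd <- function(m, cache, dy) {
  d <- dim(cache$x)
  dfc <- dy * cache$sa$sa
  dsa <- dy * cache$fc
  dfc <- dfc + cpca_sa_bwd(m, cache$sa, dsa)
  dca <- matrix(colSums(matrix(dfc * cache$x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
  dx <- dfc * rep(as.vector(cache$ca$ca), each = d[1] * d[2])
  dx + cpca_ca_bwd(m, cache$ca, cache$x, dca)
}

#' Channel attention map
#'
#' Computes the C x 1 x 1 channel attention weights
#' `sigmoid(MLP(avgpool(f)) + MLP(maxpool(f)))` where both pooling operations
#' are global over the spatial extent and the MLP is shared between the two
#' descriptors.
#'
#' @param f numeric array of dim (H, W, C): the input feature map.
#' @param params a CPCA module from [nn_cpca()].
#' @return array of dim (C, 1, 1) with every entry strictly in (0, 1).
#' @export
channel_attention <- function(f, params) {
  tensor_check(f)
  x <- as_batch(f)
  if (dim(x)[3] != params$channels)
    stop("feature map has ", dim(x)[3], " channels; attention expects ", params$channels)
  ca <- cpca_ca_fwd(params, x)$ca
  array(ca[, 1L], dim = c(params$channels, 1L, 1L))
}

#' Per-channel spatial attention map
#'
#' Applies the depthwise 5x5 convolution, sums the identity branch with the
#' multi-scale depthwise strip branches and mixes with a 1x1 step:
#' `SA(Fc) = Mix( sum_i Branch_i( DwConv(Fc) ) )` with Branch_0 the identity.
#' The output keeps the full C x H x W shape (channel-prior form), one spatial
#' weight map per channel.
#'
#' @param fc numeric array of dim (H, W, C): the channel-refined feature map.
#' @param params a CPCA module from [nn_cpca()].
#' @return array of the same dim as `fc`.
#' @export
spatial_attention <- function(fc, params) {
  tensor_check(fc)
  x <- as_batch(fc)
  if (dim(x)[3] != params$channels)
    stop("feature map has ", dim(x)[3], " channels; attention expects ", params$channels)
  y <- cpca_sa_fwd(params, x, train = FALSE)$sa
  array(y, dim = dim(fc))
}

#' Channel-prior convolutional attention
#'
#' Sequentially applies channel then spatial attention:
#' `Fc = CA(F) * F`, `Fb = SA(Fc) * Fc`, with the channel weights broadcast
#' over space. Output shape equals input shape.
#'
#' @inheritParams channel_attention
#' @return refined feature map, same dim as `f`.
#' @export
cpca <- function(f, params) {
  tensor_check(f)
  x <- as_batch(f)
  y <- cpca_fwd(params, x, train = FALSE)$y
  array(y, dim = dim(f))
}
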