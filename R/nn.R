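#' @useDynLib farmseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- tensor helpers ---------------------------------------------------------
# Feature maps are arrays dim c(H, W, C, N). Single images (H, W, C) are
# promoted to N = 1 at the model boundary.

as_batch <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

tensor_check <- function(x, what = "feature map") {
  if (!is.numeric(x) || is.null(dim(x)) || !length(dim(x)) %in% c(3L, 4L))
    stop(what, " must be a numeric array of dim (H, W, C) or (H, W, C, N)")
  if (!all(is.finite(x))) stop(what, " contains non-finite values")
  invisible(x)
}

# ---- primitive modules ------------------------------------------------------
# A module is an environment with $type, parameter arrays, matching $g_<name>
# gradient slots, and optimizer state created lazily. Composites hold $mods.

new_mod <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(paste0("fs_", type), "fs_module")
  e
}

init_w <- function(dims, fan_in) {
  b <- 1 / sqrt(fan_in)
  array(stats::runif(prod(dims), -b, b), dim = dims)
}

#' @keywords internal
nn_conv <- function(c1, c2, k = 1L, stride = 1L, pad = NULL, dil = 1L,
                    groups = 1L, bias = TRUE) {
  if (c1 %% groups != 0L || c2 %% groups != 0L) stop("channels not divisible by groups")
  if (is.null(pad)) pad <- dil * (k %/% 2L)
  if (length(pad) == 1L) pad <- c(pad, pad)
  fan <- k * k * c1 / groups
  new_mod("conv",
          w = init_w(c(k, k, c1 %/% groups, c2), fan),
          b = if (bias) stats::runif(c2, -1 / sqrt(fan), 1 / sqrt(fan)) else NULL,
          stride = as.integer(stride), pad = as.integer(pad),
          dil = as.integer(dil), groups = as.integer(groups))
}

# Conv-BN-SiLU unit (the basic convolution block of the architecture family)
#' @keywords internal
nn_convbn <- function(c1, c2, k = 1L, stride = 1L, act = TRUE) {
  m <- nn_conv(c1, c2, k, stride, bias = FALSE)
  m$type <- "convbn"
  class(m) <- c("fs_convbn", "fs_module")
  m$gamma <- rep(1, c2); m$beta <- rep(0, c2)
  m$rmean <- rep(0, c2); m$rvar <- rep(1, c2)
  m$momentum <- 0.03; m$eps <- 1e-3
  m$act <- act
  m
}

nn_convT2 <- function(c1, c2) {
  fan <- 4 * c1
  new_mod("convT2",
          w = init_w(c(2L, 2L, c2, c1), fan),
          b = stats::runif(c2, -1 / sqrt(fan), 1 / sqrt(fan)))
}

acc_grad <- function(m, name, g) {
  slot <- paste0("g_", name)
  cur <- get0(slot, envir = m, ifnotfound = NULL)
  assign(slot, if (is.null(cur)) g else cur + g, envir = m)
}

mod_fwd <- function(m, x, train = TRUE) {
  switch(m$type,
    conv = {
      y <- conv2d_fwd(x, m$w, m$b, m$stride, m$pad[1], m$pad[2], m$dil, m$groups)
      list(y = y, cache = list(x = x))
    },
    convbn = {
      z <- conv2d_fwd(x, m$w, NULL, m$stride, m$pad[1], m$pad[2], m$dil, m$groups)
      if (train) {
        bn <- bnsilu_fwd(z, m$gamma, m$beta, m$eps, m$act)
        m$rmean <- (1 - m$momentum) * m$rmean + m$momentum * bn$mean
        m$rvar  <- (1 - m$momentum) * m$rvar  + m$momentum * bn$var
        list(y = bn$y, cache = list(x = x, xhat = bn$xhat, var = bn$var))
      } else {
        a <- bn_infer(z, m$gamma, m$beta, m$rmean, m$rvar, m$eps)
        list(y = if (m$act) silu_fwd(a) else a, cache = list(x = x))
      }
    },
    convT2 = {
      list(y = convT2_fwd(x, m$w, m$b), cache = list(x = x))
    },
    stop("unknown primitive module type ", m$type))
}

mod_bwd <- function(m, cache, dy) {
  switch(m$type,
    conv = {
      g <- conv2d_bwd(cache$x, m$w, dy, m$stride, m$pad[1], m$pad[2], m$dil, m$groups,
                      !is.null(m$b), TRUE)
      acc_grad(m, "w", g$dw)
      if (!is.null(m$b)) acc_grad(m, "b", g$db)
      g$dx
    },
    convbn = {
      bn <- bnsilu_bwd(dy, cache$xhat, m$gamma, m$beta, cache$var, m$eps, m$act)
      acc_grad(m, "gamma", bn$dgamma)
      acc_grad(m, "beta", bn$dbeta)
      g <- conv2d_bwd(cache$x, m$w, bn$dx, m$stride, m$pad[1], m$pad[2], m$dil, m$groups,
                      FALSE, TRUE)
      acc_grad(m, "w", g$dw)
      g$dx
    },
    convT2 = {
      g <- convT2_bwd(cache$x, m$w, dy)
      acc_grad(m, "w", g$dw)
      acc_grad(m, "b", g$db)
      g$dx
    },
    stop("unknown primitive module type ", m$type))
}

# ---- parameter traversal ----------------------------------------------------

PARAM_NAMES <- c("w", "b", "gamma", "beta", "w1", "b1", "w2", "b2")

#' Walk a module tree collecting parameter slots
#' @keywords internal
walk_params <- function(m, fun, prefix = "") {
  if (is.environment(m)) {
    for (nm in PARAM_NAMES) {
      v <- get0(nm, envir = m, ifnotfound = NULL)
      if (!is.null(v)) fun(m, nm, paste0(prefix, m$type, ".", nm))
    }
    sub <- get0("mods", envir = m, ifnotfound = NULL)
    if (!is.null(sub))
      for (i in seq_along(sub))
        walk_params(sub[[i]], fun,
                    paste0(prefix, if (!is.null(names(sub))) names(sub)[i] else i, "/"))
  } else if (is.list(m)) {
    for (i in seq_along(m))
      walk_params(m[[i]], fun,
                  paste0(prefix, if (!is.null(names(m))) names(m)[i] else i, "/"))
  }
  invisible(NULL)
}

zero_grads <- function(m) {
  walk_params(m, function(e, nm, path) {
    slot <- paste0("g_", nm)
    if (exists(slot, envir = e, inherits = FALSE)) rm(list = slot, envir = e)
  })
}

#' Flat list of every parameter array in a module tree
#' @keywords internal
param_list <- function(m) {
  out <- list()
  walk_params(m, function(e, nm, path) {
    out[[length(out) + 1L]] <<- list(env = e, name = nm, path = path,
                                     value = get(nm, envir = e))
  })
  out
}

set_all_params <- function(m, value) {
  walk_params(m, function(e, nm, path) {
    v <- get(nm, envir = e)
    v[] <- value
    assign(nm, v, envir = e)
  })
}

grad_global_norm <- function(m) {
  s <- 0
  walk_params(m, function(e, nm, path) {
    g <- get0(paste0("g_", nm), envir = e, ifnotfound = NULL)
    if (!is.null(g)) s <<- s + sum(g * g)
  })
  sqrt(s)
}
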