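# Convolutional building blocks

test_that("C2f concatenates 2+n hidden chunks and C2f_CPCA 1+n before the fuse", {
  m <- nn_c2f(64L, 64L, n = 1L)          # hidden 32
  expect_equal(dim(m$mods$cv2$w)[3], 3L * 32L)
  m3 <- nn_c2f(64L, 64L, n = 3L)
  expect_equal(dim(m3$mods$cv2$w)[3], 5L * 32L)
  a <- nn_c2f_cpca(64L, 64L, n = 1L)
  expect_equal(dim(a$mods$cv2$w)[3], 2L * 32L)
})

test_that("C2f and C2f_CPCA keep the output-channel and spatial contract", {
  set.seed(1)
  x <- array(rnorm(10 * 10 * 48), dim = c(10, 10, 48, 1))
  for (blk in list(nn_c2f(48L, 64L, 2L), nn_c2f_cpca(48L, 64L, 2L))) {
    y <- blk_fwd(blk, x, train = FALSE)$y
    expect_equal(dim(y), c(10L, 10L, 64L, 1L))
  }
})

test_that("zeroed shortcut bottlenecks make the C2f concat a tiling of the split half", {
  set.seed(2)
  m <- nn_c2f(16L, 16L, n = 2L, shortcut = TRUE)
  for (i in 1:2) set_all_params(m$mods[[paste0("m", i)]], 0)
  x <- array(rnorm(6 * 6 * 16), dim = c(6, 6, 16, 1))
  y0 <- blk_fwd(m$mods$cv1, x, train = FALSE)$y
  y1 <- y0[, , 1:8, , drop = FALSE]
  y2 <- y0[, , 9:16, , drop = FALSE]
  # bottlenecks with zero weights and residual act as the identity,
  # so the fused output equals cv2 applied to [y1, y2, y2, y2]
  manual <- blk_fwd(m$mods$cv2, farmseg:::concat_c(list(y1, y2, y2, y2)),
                    train = FALSE)$y
  expect_equal(blk_fwd(m, x, train = FALSE)$y, manual, tolerance = 1e-12)
})

test_that("C2f_CPCA is lighter in parameters than C2f at matched config", {
  expect_lt(count_params(nn_c2f_cpca(64L, 64L, 1L)),
            count_params(nn_c2f(64L, 64L, 1L)))
})

test_that("with attention forced to unity C2f_CPCA reduces to C2f minus the direct chunk", {
  set.seed(3)
  m <- nn_c2f_cpca(16L, 16L, n = 1L)
  att <- m$mods$att
  # saturate the channel MLP so CA ~ 1 and make SA exactly all-ones
  att$w1 <- matrix(c(1e4, -1e4, rep(0, att$hidden - 2L)), att$hidden, 1L)
  att$w2 <- matrix(c(1e4, 1e4, rep(0, att$hidden - 2L)), 1L, att$hidden)
  set_all_params(att$mods$dw, 0); att$mods$dw$b[] <- 1
  for (k in att$strip_kernels) {
    set_all_params(att$mods[[paste0("sh", k)]], 0)
    set_all_params(att$mods[[paste0("sv", k)]], 0)
  }
  att$mods$mix$w[] <- 1
  x <- array(rnorm(6 * 6 * 16), dim = c(6, 6, 16, 1))
  y0 <- blk_fwd(m$mods$cv1, x, train = FALSE)$y
  y1 <- y0[, , 1:8, , drop = FALSE]
  y2 <- y0[, , 9:16, , drop = FALSE]
  b1 <- blk_fwd(m$mods$m1, y2, train = FALSE)$y
  manual <- blk_fwd(m$mods$cv2, farmseg:::concat_c(list(y1, b1)), train = FALSE)$y
  expect_equal(blk_fwd(m, x, train = FALSE)$y, manual, tolerance = 1e-6)
})

test_that("RFEM with zero branch weights is the identity residual", {
  set.seed(4)
  for (dims in list(c(16, 16, 32), c(7, 7, 8))) {
    m <- nn_rfem(dims[3])
    set_all_params(m, 0)
    x <- array(rnorm(prod(dims)), dim = c(dims, 1))
    expect_equal(blk_fwd(m, x, train = FALSE)$y, x, tolerance = 1e-12)
  }
})

test_that("the dilation-3 RFEM branch has a 7x7 composite receptive field", {
  m <- nn_rfem(1L)
  set_all_params(m, 0)
  m$mods$pw3$w[] <- 1          # only the dilation-3 branch active
  m$mods$mix$w[] <- 1
  x <- array(0, dim = c(15, 15, 1, 1))
  x[8, 8, 1, 1] <- 1           # unit impulse at the center
  y <- blk_fwd(m, x, train = FALSE)$y - x
  nz <- which(abs(y[, , 1, 1]) > 1e-12, arr.ind = TRUE)
  expect_equal(max(nz[, 1]) - min(nz[, 1]) + 1L, 7L)
  expect_equal(max(nz[, 2]) - min(nz[, 2]) + 1L, 7L)
})

test_that("SPPF matches a brute-force chained-window pooling oracle", {
  set.seed(5)
  m <- nn_sppf(8L, 8L, k = 5L)
  x <- array(rnorm(7 * 7 * 8), dim = c(7, 7, 8, 1))
  f1 <- blk_fwd(m$mods$cv1, x, train = FALSE)$y
  pool1 <- function(a) {
    d <- dim(a); out <- a
    for (c in seq_len(d[3])) for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      ys <- max(1, i - 2):min(d[1], i + 2)
      xs <- max(1, j - 2):min(d[2], j + 2)
      out[i, j, c, 1] <- max(a[ys, xs, c, 1])
    }
    out
  }
  p1 <- pool1(f1); p2 <- pool1(p1); p3 <- pool1(p2)
  manual <- blk_fwd(m$mods$cv2, farmseg:::concat_c(list(f1, p1, p2, p3)),
                    train = FALSE)$y
  expect_equal(blk_fwd(m, x, train = FALSE)$y, manual, tolerance = 1e-12)
  # constant input propagates as a constant
  xc <- array(0.3, dim = c(6, 6, 8, 1))
  yc <- blk_fwd(m, xc, train = FALSE)$y
  expect_lt(max(apply(yc, 3, function(p) diff(range(p)))), 1e-12)
})

test_that("SPPF concat width is four hidden chunks", {
  m <- nn_sppf(256L, 256L)
  expect_equal(dim(m$mods$cv2$w)[3], 512L)
  expect_error(nn_sppf(16L, 16L, k = 4L), "odd")
})

test_that("C3RFEM keeps the C3 shape contract and reduces to C3 with identity inner path", {
  set.seed(6)
  m <- nn_c3rfem(32L, 32L)
  x <- array(rnorm(9 * 9 * 32), dim = c(9, 9, 32, 1))
  y <- blk_fwd(m, x, train = FALSE)$y
  expect_equal(dim(y), dim(x))
  set_all_params(m$mods$rfem, 0)
  a <- blk_fwd(m$mods$cv1, x, train = FALSE)$y
  b <- blk_fwd(m$mods$cv2, x, train = FALSE)$y
  manual <- blk_fwd(m$mods$cv3, farmseg:::concat_c(list(a, b)), train = FALSE)$y
  expect_equal(blk_fwd(m, x, train = FALSE)$y, manual, tolerance = 1e-12)
})

test_that("stride-1 blocks preserve spatial size; stride-2 Conv halves it", {
  set.seed(7)
  x <- array(rnorm(8 * 8 * 16), dim = c(8, 8, 16, 1))
  for (blk in list(nn_c2f(16L, 16L), nn_c2f_cpca(16L, 16L), nn_sppf(16L, 16L),
                   nn_rfem(16L), nn_c3(16L, 16L), nn_c3rfem(16L, 16L)))
    expect_equal(dim(blk_fwd(blk, x, train = FALSE)$y)[1:2], c(8L, 8L))
  down <- nn_convbn(16L, 32L, 3L, 2L)
  expect_equal(dim(blk_fwd(down, x, train = FALSE)$y)[1:2], c(4L, 4L))
})

test_that("block parameter counts match closed-form per-layer sums", {
  # Conv-BN unit: k^2 c1 c2 weights + 2 c2 (scale, shift)
  expect_equal(count_params(nn_convbn(16L, 32L, 3L), fused = FALSE),
               9L * 16L * 32L + 2L * 32L)
  # C2f: cv1 + cv2 + n bottlenecks of two 3x3 units, hidden width c
  c1 <- 64L; c2 <- 64L; n <- 2L; ch <- 32L
  expected <- (c1 * 2 * ch + 4 * ch) + ((2 + n) * ch * c2 + 2 * c2) +
    n * 2 * (9 * ch * ch + 2 * ch)
  expect_equal(count_params(nn_c2f(c1, c2, n), fused = FALSE), expected)
  # RFEM: five pointwise convs with bias
  expect_equal(count_params(nn_rfem(128L)), 5L * (128L * 128L + 128L))
})

test_that("block gradients agree with finite differences", {
  set.seed(8)
  for (make in list(function() nn_c2f(4L, 4L, 1L, TRUE),
                    function() nn_c2f_cpca(4L, 4L, 1L),
                    function() nn_rfem(4L),
                    function() nn_c3rfem(4L, 4L),
                    function() nn_sppf(4L, 4L))) {
    m <- make()
    x <- array(rnorm(5 * 5 * 4 * 2), dim = c(5, 5, 4, 2))
    f <- blk_fwd(m, x, train = TRUE)
    R <- array(rnorm(length(f$y)), dim = dim(f$y))
    zero_grads(m)
    dx <- blk_bwd(m, f$cache, R)
    h <- 1e-6
    for (i in sample(length(x), 4L)) {
      xp <- x; xp[i] <- xp[i] + h
      xm <- x; xm[i] <- xm[i] - h
      fd <- (sum(blk_fwd(m, xp, TRUE)$y * R) - sum(blk_fwd(m, xm, TRUE)$y * R)) / (2 * h)
      expect_equal(dx[i], fd, tolerance = 1e-4)
    }
  }
})
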