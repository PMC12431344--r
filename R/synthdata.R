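# Seeded synthetic farmland scenes with instance polygons and masks.
#
# The generator emulates the structure of 8-class harvest-season imagery:
# large irregular regions (unharvested / harvested / farm / lodging patches),
# thin elongated strips (ridges between fields), compact mid-size blobs
# (harvester, obstacle) and rare small blobs (people, kept below 5% of
# instances). Class identity is carried mainly by colour and shape, which is
# what makes the scenes learnable at small sample sizes; they do not attempt
# photorealism.

# per-class instance proportions mirroring the harvest-scene class imbalance
SYNTH_COUNTS <- c(7420, 4692, 3068, 2628, 1900, 1004, 806, 690)
SYNTH_PROPS <- SYNTH_COUNTS / sum(SYNTH_COUNTS)

SYNTH_COLORS <- matrix(c(
  0.45, 0.62, 0.20,   # unharvested area: green crop
  0.78, 0.68, 0.45,   # having harvested areas: pale stubble
  0.52, 0.40, 0.28,   # farm: brown soil
  0.30, 0.26, 0.18,   # ridge between fields: dark earth strip
  0.62, 0.58, 0.30,   # slight lodging area: olive flattened crop
  0.85, 0.20, 0.15,   # harvester: red machine
  0.45, 0.45, 0.50,   # obstacle: grey block
  0.15, 0.25, 0.75),  # people: blue figure
  nrow = 8L, byrow = TRUE)

#' Specification of a synthetic farmland scene
#'
#' @param imgsz image side length in pixels.
#' @param proportions per-class target instance proportions (sum to 1); the
#'   default mirrors the instance-count imbalance of the study's farmland
#'   dataset, with "people" under 5%.
#' @param n_instances integer range (min, max) of instances per scene.
#' @param noise_sd pixel texture noise standard deviation.
#' @export
scene_spec <- function(imgsz = 640L, proportions = SYNTH_PROPS,
                       n_instances = c(4L, 9L), noise_sd = 0.03) {
  if (abs(sum(proportions) - 1) > 1e-6) stop("proportions must sum to 1")
  if (proportions[8L] >= 0.05) stop("'people' proportion must stay below 5%")
  if (imgsz < 32L) stop("image too small for the configured size ranges")
  structure(list(imgsz = as.integer(imgsz), proportions = proportions,
                 n_instances = as.integer(n_instances), noise_sd = noise_sd),
            class = "scene_spec")
}

# even-odd rule point-in-polygon, vectorized over query points
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi + 1e-12) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Rasterize a polygon to a binary mask
#'
#' Pixel centers (x - 0.5, y - 0.5) falling inside the polygon (even-odd
#' rule) are set. Rows index y, columns x.
#'
#' @param poly matrix (V x 2) of vertices in pixel coordinates.
#' @param imgsz image side length.
#' @export
polygon_to_mask <- function(poly, imgsz) {
  px <- rep(seq_len(imgsz) - 0.5, each = imgsz)   # column-major: y fastest
  py <- rep(seq_len(imgsz) - 0.5, imgsz)
  m <- matrix(points_in_polygon(px, py, poly), imgsz, imgsz)
  m * 1L
}

# irregular star-convex blob polygon around (cx, cy)
blob_polygon <- function(cx, cy, radius, nvert = 10L, wobble = 0.35) {
  ang <- sort(stats::runif(nvert, 0, 2 * pi))
  r <- radius * (1 - wobble + 2 * wobble * stats::runif(nvert))
  cbind(cx + r * cos(ang), cy + r * sin(ang))
}

# thin elongated strip across the image (ridge between fields)
strip_polygon <- function(imgsz) {
  horiz <- stats::runif(1) < 0.5
  t0 <- stats::runif(1, 0.15, 0.85) * imgsz
  t1 <- t0 + stats::runif(1, -0.2, 0.2) * imgsz
  hw <- stats::runif(1, 0.006, 0.015) * imgsz + 1.5
  if (horiz)
    cbind(c(0, imgsz, imgsz, 0), c(t0 - hw, t1 - hw, t1 + hw, t0 + hw))
  else
    cbind(c(t0 - hw, t1 - hw, t1 + hw, t0 + hw), c(0, imgsz, imgsz, 0))
}

sample_instance_polygon <- function(class_id, imgsz) {
  s <- imgsz
  switch(as.character(class_id),
    "3" = strip_polygon(s),
    "5" = {  # harvester: boxy polygon
      cx <- stats::runif(1, 0.15, 0.85) * s; cy <- stats::runif(1, 0.15, 0.85) * s
      w <- stats::runif(1, 0.06, 0.14) * s; h <- stats::runif(1, 0.05, 0.10) * s
      jit <- matrix(stats::runif(8, -0.1, 0.1) * min(w, h), 4L)
      cbind(c(cx - w, cx + w, cx + w, cx - w), c(cy - h, cy - h, cy + h, cy + h)) + jit
    },
    "6" = {  # obstacle: compact blob
      blob_polygon(stats::runif(1, 0.1, 0.9) * s, stats::runif(1, 0.1, 0.9) * s,
                   stats::runif(1, 0.03, 0.07) * s, nvert = 8L)
    },
    "7" = {  # people: small blob, at least a few pixels across
      blob_polygon(stats::runif(1, 0.1, 0.9) * s, stats::runif(1, 0.1, 0.9) * s,
                   max(3, stats::runif(1, 0.012, 0.03) * s), nvert = 7L, wobble = 0.25)
    },
    {     # area classes 0, 1, 2, 4: large irregular regions
      blob_polygon(stats::runif(1, 0.2, 0.8) * s, stats::runif(1, 0.2, 0.8) * s,
                   stats::runif(1, 0.16, 0.32) * s, nvert = 12L)
    })
}

clip_poly <- function(poly, imgsz) {
  poly[, 1L] <- pmin(pmax(poly[, 1L], 0), imgsz)
  poly[, 2L] <- pmin(pmax(poly[, 2L], 0), imgsz)
  poly
}

#' Generate one synthetic farmland scene
#'
#' Layered polygonal instances over a textured soil background; every
#' instance carries a closed polygon and its rasterized binary mask (full
#' polygon support, independent of occlusion by later layers). Deterministic
#' given `seed`.
#'
#' @param spec a [scene_spec()].
#' @param seed integer seed; if `NULL` the current RNG stream is used.
#' @return list with `image` (imgsz x imgsz x 3, values in `[0, 1]`) and
#'   `annotations`: list of `list(class_id, polygon, mask)`.
#' @export
generate_scene <- function(spec = scene_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- spec$imgsz
  n <- sample(spec$n_instances[1L]:spec$n_instances[2L], 1L)
  classes <- sample(0:7, n, replace = TRUE, prob = spec$proportions)
  # paint large region classes first, then strips, then compact objects
  layer_rank <- c(0, 0, 0, 1, 0, 2, 2, 3)
  classes <- classes[order(layer_rank[classes + 1L])]
  img <- array(stats::rnorm(s * s * 3, 0, spec$noise_sd), dim = c(s, s, 3L))
  base <- c(0.58, 0.50, 0.36)  # bare field background
  for (ch in 1:3) img[, , ch] <- img[, , ch] + base[ch]
  anns <- vector("list", n)
  occupied <- matrix(0L, s, s)
  for (i in seq_len(n)) {
    cl <- classes[i]
    # fields, ridges and machines do not overlap in real scenes: retry
    # placements that would cover already-claimed ground
    best <- NULL; best_frac <- Inf
    for (try in 1:8) {
      poly <- clip_poly(sample_instance_polygon(cl, s), s)
      mask <- polygon_to_mask(poly, s)
      a <- sum(mask)
      if (a < 4L) next
      frac <- sum(mask & occupied) / a
      if (frac < best_frac) { best <- list(poly = poly, mask = mask); best_frac <- frac }
      if (frac <= 0.05) break
    }
    poly <- best$poly; mask <- best$mask
    occupied <- occupied | mask
    shade <- stats::runif(1, 0.85, 1.15)
    idx <- mask == 1L
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[idx] <- SYNTH_COLORS[cl + 1L, ch] * shade +
        stats::rnorm(sum(idx), 0, spec$noise_sd)
      img[, , ch] <- plane
    }
    anns[[i]] <- list(class_id = cl, polygon = poly, mask = mask)
  }
  img <- pmin(pmax(img, 0), 1)
  list(image = img, annotations = anns)
}

#' Augmentation recipe
#'
#' @param contrast_gain linear contrast gain about the per-image mean.
#' @param noise_sd standard deviation of additive Gaussian noise on the
#'   `[0, 1]` intensity scale.
#' @param flip include the horizontally flipped variant.
#' @export
augmentation_recipe <- function(contrast_gain = 1.5, noise_sd = 0.1,
                                flip = TRUE) {
  structure(list(contrast_gain = contrast_gain, noise_sd = noise_sd,
                 flip = flip), class = "augmentation_recipe")
}

flip_h <- function(scene_img) scene_img[, dim(scene_img)[2]:1, , drop = FALSE]

flip_annotations <- function(anns, imgsz) {
  lapply(anns, function(a) {
    a$polygon[, 1L] <- imgsz - a$polygon[, 1L]
    a$mask <- a$mask[, ncol(a$mask):1, drop = FALSE]
    a
  })
}

#' Augment one scene into its four variants
#'
#' Emits the original, a linear-contrast variant
#' (`clip(mu + gain * (x - mu))` about the per-image mean `mu`), an additive
#' Gaussian-noise variant, and a horizontally flipped variant with
#' consistently transformed annotations.
#'
#' @param image (S, S, 3) array in `[0, 1]`.
#' @param annotations annotation list as from [generate_scene()].
#' @param recipe an [augmentation_recipe()].
#' @return list of 4 `list(image, annotations, variant)` entries.
#' @export
augment <- function(image, annotations, recipe = augmentation_recipe()) {
  if (min(image) < 0 || max(image) > 1) stop("image intensities must be in [0, 1]")
  s <- dim(image)[1]
  mu <- mean(image)
  contrast <- pmin(pmax(mu + recipe$contrast_gain * (image - mu), 0), 1)
  noisy <- pmin(pmax(image + array(stats::rnorm(length(image), 0, recipe$noise_sd),
                                   dim = dim(image)), 0), 1)
  out <- list(
    list(image = image, annotations = annotations, variant = "original"),
    list(image = contrast, annotations = annotations, variant = "contrast"),
    list(image = noisy, annotations = annotations, variant = "noise"))
  if (recipe$flip)
    out[[4L]] <- list(image = flip_h(image),
                      annotations = flip_annotations(annotations, s),
                      variant = "flip")
  out
}

#' Expand a list of scenes through the augmentation pipeline
#'
#' @param scenes list of `list(image, annotations)`.
#' @param recipe an [augmentation_recipe()].
#' @return flat list of augmented scenes; each carries `source` (index of its
#'   source scene) and `variant`.
#' @export
augment_dataset <- function(scenes, recipe = augmentation_recipe()) {
  out <- list()
  for (i in seq_along(scenes)) {
    vs <- augment(scenes[[i]]$image, scenes[[i]]$annotations, recipe)
    for (v in vs) {
      v$source <- i
      out[[length(out) + 1L]] <- v
    }
  }
  out
}

#' Split items into train/validation/test manifests
#'
#' Seeded shuffle; split sizes are floor proportions of the item count with
#' the remainder going to the training split. When `source` groups are given
#' (augmented variants of one source image), whole groups are assigned to a
#' single split to prevent leakage, filling the test and validation quotas
#' greedily; group sizes that do not divide the quotas leave the remainder in
#' training.
#'
#' @param items vector (or list) of items to split.
#' @param ratios positive split ratios (train, val, test).
#' @param seed RNG seed for the shuffle.
#' @param source optional grouping vector (same length as `items`).
#' @return list with integer index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(items, ratios = c(7, 2, 1), seed = 0L, source = NULL) {
  n <- length(items)
  if (any(ratios <= 0)) stop("ratios must be positive")
  if (n < 3L) stop("fewer items than splits")
  r <- ratios / sum(ratios)
  n_val <- floor(n * r[2L]); n_test <- floor(n * r[3L])
  if (is.null(source)) source <- seq_len(n)
  groups <- split(seq_len(n), source)
  set.seed(seed)
  groups <- groups[sample.int(length(groups))]
  val <- integer(0); test <- integer(0); train <- integer(0)
  for (g in groups) {
    if (length(test) + length(g) <= n_test) test <- c(test, g)
    else if (length(val) + length(g) <= n_val) val <- c(val, g)
    else train <- c(train, g)
  }
  list(train = sort(train), val = sort(val), test = sort(test))
}

# ---- image statistics -------------------------------------------------------

#' Smoothed brightness histogram over 0-255
#'
#' @param images a single (S, S, 3) array or a list of them.
#' @param bw Gaussian smoothing bandwidth in brightness levels.
#' @return list with `levels` (0:255), `raw` (unsmoothed normalized counts)
#'   and `density` (kernel-smoothed, summing to 1).
#' @export
pixel_histogram <- function(images, bw = 3) {
  if (!is.list(images)) images <- list(images)
  counts <- numeric(256L)
  for (im in images) {
    v <- pmin(pmax(round(as.vector(im) * 255), 0), 255)
    counts <- counts + tabulate(v + 1L, nbins = 256L)
  }
  raw <- counts / sum(counts)
  k <- stats::dnorm(-25:25, sd = bw)
  sm <- stats::filter(c(rep(0, 25), raw, rep(0, 25)), k, sides = 2L)
  sm <- as.numeric(sm)[26:281]
  density <- sm / sum(sm)
  list(levels = 0:255, raw = raw, density = density)
}

luma <- function(image) {
  0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L]
}

#' Sobel gradient-magnitude distribution
#'
#' Converts to luma, applies the 3x3 Sobel operators over the image interior
#' and returns the per-pixel gradient magnitudes with their normalized
#' frequency distribution.
#'
#' @param image (S, S, 3) array in `[0, 1]`.
#' @param nbins histogram bins.
#' @return list with `magnitudes` (matrix), `breaks`, `density` (sums to 1).
#' @export
gradient_magnitude_distribution <- function(image, nbins = 64L) {
  g <- luma(image)
  H <- nrow(g); W <- ncol(g)
  ry <- 2:(H - 1L); rx <- 2:(W - 1L)
  gx <- (g[ry - 1L, rx + 1L] + 2 * g[ry, rx + 1L] + g[ry + 1L, rx + 1L]) -
        (g[ry - 1L, rx - 1L] + 2 * g[ry, rx - 1L] + g[ry + 1L, rx - 1L])
  gy <- (g[ry + 1L, rx - 1L] + 2 * g[ry + 1L, rx] + g[ry + 1L, rx + 1L]) -
        (g[ry - 1L, rx - 1L] + 2 * g[ry - 1L, rx] + g[ry - 1L, rx + 1L])
  mag <- sqrt(gx^2 + gy^2)
  breaks <- seq(0, max(mag) + 1e-9, length.out = nbins + 1L)
  h <- hist(mag, breaks = breaks, plot = FALSE)
  list(magnitudes = mag, breaks = breaks, density = h$counts / sum(h$counts))
}

#' Two-dimensional PCA embedding of image feature vectors
#'
#' Mean-centered projection onto the top two principal components.
#'
#' @param feature_vectors matrix (n x d), one row per image; n >= 3.
#' @return list with `points` (n x 2 scores) and `var_share` (explained
#'   variance shares of PC1 and PC2).
#' @export
pca_embedding <- function(feature_vectors) {
  X <- as.matrix(feature_vectors)
  if (nrow(X) < 3L) stop("need at least 3 feature vectors")
  if (all(apply(X, 2L, stats::sd) < 1e-12)) stop("zero-variance input")
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  share <- p$sdev^2 / sum(p$sdev^2)
  list(points = p$x[, 1:2, drop = FALSE], var_share = share[1:2])
}

#' Seeded random-projection image features
#'
#' A fixed, seeded random projection bank applied to the downsampled image;
#' a dependency-free stand-in for deep features in the PCA analysis, and
#' pluggable (any function image -> numeric vector can be used instead).
#'
#' @param images list of (S, S, 3) arrays.
#' @param dim output feature dimension.
#' @param grid downsampling grid side.
#' @param seed seed of the projection bank (fixed by default so features are
#'   comparable across calls).
#' @export
image_features <- function(images, dim = 16L, grid = 16L, seed = 777L) {
  if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  P <- matrix(stats::rnorm(grid * grid * 3L * dim), ncol = dim)
  t(vapply(images, function(im) {
    s <- base::dim(im)[1]
    idx <- pmin(s, floor((seq_len(grid) - 0.5) * s / grid) + 1L)
    v <- as.vector(im[idx, idx, , drop = FALSE])
    as.vector(v %*% P)
  }, numeric(dim)))
}
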