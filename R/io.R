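# Dataset serialization: polygon segmentation labels (one text file per
# image, one instance per line: class_id followed by the polygon vertices
# normalized to [0, 1]), PNG images, and a YAML manifest listing the splits
# and class names.

#' Write polygon segmentation labels
#'
#' One line per instance: `class_id x1 y1 x2 y2 ...` with coordinates
#' normalized by the image size.
#'
#' @param annotations list of `list(class_id, polygon)` in pixel coordinates.
#' @param path output text file.
#' @param imgsz image side length used for normalization.
#' @export
write_yolo_labels <- function(annotations, path, imgsz) {
  lines <- vapply(annotations, function(a) {
    xy <- t(a$polygon / imgsz)
    paste(a$class_id, paste(sprintf("%.6f", as.vector(xy)), collapse = " "))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read polygon segmentation labels
#'
#' @param path label text file.
#' @param imgsz image side length to scale back to pixels.
#' @return list of `list(class_id, polygon)`.
#' @export
read_yolo_labels <- function(path, imgsz) {
  lines <- readLines(path)
  lapply(lines[nzchar(lines)], function(ln) {
    v <- as.numeric(strsplit(trimws(ln), "\\s+")[[1L]])
    list(class_id = as.integer(v[1L]),
         polygon = matrix(v[-1L] * imgsz, ncol = 2L, byrow = TRUE))
  })
}

#' Write a synthetic dataset to disk
#'
#' Images as PNG, labels in the polygon text format, and a YAML manifest
#' with per-split file lists and the class names.
#'
#' @param scenes flat list of scenes (image + annotations), e.g. from
#'   [augment_dataset()].
#' @param dir output directory.
#' @param splits optional [split_dataset()] result (index vectors).
#' @param class_names class names for the manifest.
#' @return the manifest path.
#' @export
write_dataset <- function(scenes, dir, splits = NULL,
                          class_names = FARM_CLASSES) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "labels"), recursive = TRUE, showWarnings = FALSE)
  files <- character(length(scenes))
  for (i in seq_along(scenes)) {
    stem <- sprintf("scene_%05d", i)
    img <- scenes[[i]]$image
    png::writePNG(aperm(img, c(1L, 2L, 3L)), file.path(dir, "images", paste0(stem, ".png")))
    write_yolo_labels(scenes[[i]]$annotations,
                      file.path(dir, "labels", paste0(stem, ".txt")),
                      dim(img)[1L])
    files[i] <- paste0("images/", stem, ".png")
  }
  manifest <- list(names = as.list(class_names), nc = length(class_names))
  if (is.null(splits)) manifest$images <- as.list(files)
  else for (sp in names(splits)) manifest[[sp]] <- as.list(files[splits[[sp]]])
  mp <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, mp)
  mp
}

#' Read a dataset written by [write_dataset()]
#'
#' @param manifest path to the manifest YAML.
#' @param split which file list to read (`"images"` if the manifest was
#'   written without splits).
#' @param rasterize also rasterize each polygon to a mask.
#' @return list of `list(image, annotations)`.
#' @export
read_dataset <- function(manifest, split = "images", rasterize = TRUE) {
  man <- yaml::read_yaml(manifest)
  root <- dirname(manifest)
  lapply(unlist(man[[split]]), function(f) {
    img <- png::readPNG(file.path(root, f))
    s <- dim(img)[1L]
    lab <- file.path(root, sub("^images/", "labels/", sub("\\.png$", ".txt", f)))
    anns <- read_yolo_labels(lab, s)
    if (rasterize)
      anns <- lapply(anns, function(a) {
        a$mask <- polygon_to_mask(a$polygon, s)
        a
      })
    list(image = img, annotations = anns)
  })
}

# convert annotation list into the target structure used by the loss
annotations_to_targets <- function(anns, imgsz) {
  if (!length(anns))
    return(list(boxes = NULL, classes = integer(0), masks = list()))
  boxes <- t(vapply(anns, function(a)
    c(min(a$polygon[, 1L]), min(a$polygon[, 2L]),
      max(a$polygon[, 1L]), max(a$polygon[, 2L])), numeric(4L)))
  list(boxes = boxes,
       classes = vapply(anns, function(a) as.integer(a$class_id), 0L),
       masks = lapply(anns, `[[`, "mask"))
}

#' Turn scenes into training samples
#'
#' @param scenes list of `list(image, annotations)`.
#' @return list of `list(image, boxes, classes, masks)` for [train_model()].
#' @export
scenes_to_samples <- function(scenes) {
  lapply(scenes, function(sc) {
    tg <- annotations_to_targets(sc$annotations, dim(sc$image)[1L])
    list(image = sc$image, boxes = tg$boxes, classes = tg$classes,
         masks = tg$masks)
  })
}
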