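#' Read a fundus photograph from disk
#'
#' Loads a PNG as an H x W x 3 array in `[0, 1]`. Grayscale images are
#' channel-replicated with a warning; an alpha channel is dropped.
#'
#' @param path image file.
#' @return H x W x 3 numeric array.
#' @export
read_fundus_png <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("image file not found: %s", path), call. = FALSE)
  }
  img <- png::readPNG(path)
  if (is.matrix(img)) {
    warning(sprintf("grayscale image %s: replicating channels", basename(path)),
            call. = FALSE)
    img <- array(rep(img, 3L), c(dim(img), 3L))
  } else if (dim(img)[3] == 4L) {
    img <- img[, , 1:3, drop = FALSE]
  } else if (dim(img)[3] == 2L) {
    warning(sprintf("grayscale image %s: replicating channels", basename(path)),
            call. = FALSE)
    img <- array(rep(img[, , 1], 3L), c(dim(img)[1:2], 3L))
  }
  img
}

#' Load and validate a labeled dataset index
#'
#' Reads a labels CSV with columns `image,label` (and optionally `split`),
#' checks every referenced image exists and every label is in range, and
#' returns the validated index. In 5-class mode, rows labeled 5
#' (ungradable) are dropped when `drop_ungradable = TRUE` and rejected
#' otherwise.
#'
#' @param root_dir dataset directory; image paths in the CSV are relative
#'   to it.
#' @param labels_csv path to the CSV (default `<root_dir>/labels.csv`).
#' @param class_count 2, 5 or 6.
#' @param drop_ungradable silently drop label-5 rows in 5-class mode.
#' @return data.frame of class `dataset_index` with columns `image`
#'   (absolute path), `label`, `split`; attribute `class_count`.
#' @export
load_labeled_dataset <- function(root_dir,
                                 labels_csv = file.path(root_dir, "labels.csv"),
                                 class_count = 6L,
                                 drop_ungradable = FALSE) {
  if (!class_count %in% c(2L, 5L, 6L)) {
    stop("class_count must be 2, 5, or 6", call. = FALSE)
  }
  if (!file.exists(labels_csv)) {
    stop(sprintf("labels file not found: %s", labels_csv), call. = FALSE)
  }
  df <- utils::read.csv(labels_csv, stringsAsFactors = FALSE)
  if (!all(c("image", "label") %in% names(df))) {
    stop("labels CSV must have columns image,label", call. = FALSE)
  }
  if (is.null(df$split)) df$split <- "train"
  df$label <- suppressWarnings(as.integer(df$label))
  bad <- which(is.na(df$label) | df$label < 0L |
                 (class_count == 6L & df$label > 5L) |
                 (class_count == 2L & df$label > 5L) |
                 (class_count == 5L & df$label > 5L))
  if (length(bad)) {
    stop(sprintf("bad label at CSV row %d (image %s)", bad[1],
                 df$image[bad[1]]), call. = FALSE)
  }
  if (class_count == 5L) {
    five <- df$label == 5L
    if (any(five)) {
      if (drop_ungradable) {
        df <- df[!five, , drop = FALSE]
      } else {
        stop(sprintf(
          "label 5 (ungradable) at CSV row %d but class_count=5; use drop_ungradable=TRUE",
          which(five)[1]), call. = FALSE)
      }
    }
  }
  if (class_count == 2L) df$label <- binarize_labels(df$label)
  if (nrow(df) == 0L) stop("dataset index is empty", call. = FALSE)
  df$image <- file.path(root_dir, df$image)
  missing <- !file.exists(df$image)
  if (any(missing)) {
    stop(sprintf("missing image file at CSV row %d: %s",
                 which(missing)[1], df$image[which(missing)[1]]),
         call. = FALSE)
  }
  attr(df, "class_count") <- class_count
  class(df) <- c("dataset_index", class(df))
  df
}

#' Load one split of an indexed dataset into memory
#'
#' @param index `dataset_index`.
#' @param split one of "train", "val", "test", or "all".
#' @param size optional side length; images are resized when it differs
#'   from their stored resolution.
#' @return list with `images` (list of arrays) and `labels`.
#' @export
load_split <- function(index, split = "train", size = NULL) {
  sel <- if (identical(split, "all")) rep(TRUE, nrow(index)) else index$split == split
  sub <- index[sel, , drop = FALSE]
  imgs <- lapply(sub$image, function(p) {
    img <- read_fundus_png(p)
    if (!is.null(size)) img <- resize_image(img, size) else img
  })
  list(images = imgs, labels = sub$label)
}
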