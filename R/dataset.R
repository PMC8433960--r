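#' Labeled image dataset
#'
#' An `image_dataset` holds a collection of same-shape images as a single
#' numeric array of dimension `H x W x C x N` with pixel values in `[0, 1]`,
#' integer class labels in `0..n_classes-1`, and a unique string id per image.
#' All pipeline stages (prototype clustering, Siamese training, dissimilarity
#' spaces) consume this container.
#'
#' @param images numeric array `H x W x C x N` (or `H x W x C` for a single
#'   image), values in `[0, 1]`.
#' @param labels integer vector of length `N`; classes `0..n_classes-1`,
#'   every class present at least once.
#' @param ids character vector of unique ids, length `N`; generated as
#'   `img_00001, ...` when omitted.
#' @return An object of class `image_dataset` with elements `images`,
#'   `labels`, `ids`, `n_classes`.
#' @export
image_dataset <- function(images, labels, ids = NULL) {
  if (length(dim(images)) == 3L) dim(images) <- c(dim(images), 1L)
  if (length(dim(images)) != 4L)
    stop("`images` must be an H x W x C x N array")
  n <- dim(images)[4L]
  labels <- as.integer(labels)
  if (length(labels) != n)
    stop("length(labels) must equal the number of images")
  if (any(labels < 0L))
    stop("labels must be non-negative integers (0-based classes)")
  n_classes <- max(labels) + 1L
  if (!setequal(unique(labels), 0:(n_classes - 1L)))
    stop("every class in 0..n_classes-1 must appear at least once")
  if (is.null(ids)) ids <- sprintf("img_%05d", seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n || anyDuplicated(ids))
    stop("`ids` must be unique and match the number of images")
  structure(
    list(images = images, labels = labels, ids = ids, n_classes = n_classes),
    class = "image_dataset"
  )
}

#' @export
print.image_dataset <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<image_dataset> %d images, %d x %d x %d, %d classes\n",
              d[4L], d[1L], d[2L], d[3L], x$n_classes))
  invisible(x)
}

#' @export
length.image_dataset <- function(x) dim(x$images)[4L]

#' Subset an image dataset by image index
#'
#' Keeps the stored 0-based labels; the subset must still contain every class
#' if it is to be used for training, but partial subsets (e.g. one class) are
#' permitted for inspection, so validation is not re-run here beyond bounds.
#'
#' @param dataset an [image_dataset()].
#' @param idx integer indices of images to keep (1-based).
#' @return A new `image_dataset`-classed object with the selected images.
#' @export
subset_dataset <- function(dataset, idx) {
  idx <- as.integer(idx)
  n <- length(dataset)
  if (any(idx < 1L | idx > n)) stop("index out of range")
  structure(
    list(images = dataset$images[, , , idx, drop = FALSE],
         labels = dataset$labels[idx],
         ids = dataset$ids[idx],
         n_classes = dataset$n_classes),
    class = "image_dataset"
  )
}

#' Deterministic per-class stratified train/test split
#'
#' @param dataset an [image_dataset()].
#' @param n_train_per_class images per class assigned to the training split.
#' @param seed integer seed controlling the shuffle within each class.
#' @return `list(train = , test = )` of `image_dataset` objects.
#' @export
split_dataset <- function(dataset, n_train_per_class, seed = 0L) {
  train_idx <- integer(0)
  test_idx <- integer(0)
  rng <- local_rng(seed)
  for (cl in 0:(dataset$n_classes - 1L)) {
    members <- which(dataset$labels == cl)
    if (length(members) <= n_train_per_class)
      stop("class ", cl, " has too few members for the requested split")
    members <- sample(members)
    train_idx <- c(train_idx, members[seq_len(n_train_per_class)])
    test_idx <- c(test_idx, members[-seq_len(n_train_per_class)])
  }
  list(train = subset_dataset(dataset, sort(train_idx)),
       test = subset_dataset(dataset, sort(test_idx)))
}

# Seed the session RNG for the calling frame only, restoring any prior state
# when that frame exits. All randomness in the package flows through this
# helper, so a top-level seed fixes the whole pipeline (R's default
# Mersenne-Twister RNG).
local_rng <- function(seed, env = parent.frame()) {
  withr::local_seed(as.integer(seed), .local_envir = env)
  invisible(seed)
}

#' Generate a synthetic class-structured toy image dataset
#'
#' Each class is a distinct deterministic texture: an oriented sinusoidal
#' grating whose orientation and spatial frequency depend on the class index,
#' plus a Gaussian intensity blob at a class-specific position. i.i.d.
#' Gaussian pixel noise (`noise_sd`) is added and values are clipped to
#' `[0, 1]`. The single-channel pattern is replicated to three channels, so
#' all downstream code can assume `C = 3`. The class patterns are functions
#' of `(class index, seed)` only, so regeneration is bit-reproducible for a
#' given seed on any platform using R's default Mersenne-Twister RNG.
#'
#' @param n_classes number of classes (>= 2).
#' @param n_per_class images per class (>= 2).
#' @param image_size side of the square images in pixels (>= 8).
#' @param noise_sd standard deviation of the additive Gaussian pixel noise,
#'   on the `[0, 1]` intensity scale (>= 0); 0 makes all images of a class
#'   identical.
#' @param seed integer seed; the same seed always yields the same dataset.
#' @return An [image_dataset()] of `n_classes * n_per_class` images of shape
#'   `image_size x image_size x 3`, labels grouped by class.
#' @examples
#' ds <- generate_toy_dataset(3, 5, 32, 0.05, seed = 7)
#' dim(ds$images)
#' @export
generate_toy_dataset <- function(n_classes, n_per_class, image_size,
                                 noise_sd = 0.05, seed = 0L) {
  if (n_classes < 2L) stop("n_classes must be >= 2")
  if (n_per_class < 2L) stop("n_per_class must be >= 2")
  if (image_size < 8L) stop("image_size must be >= 8")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  local_rng(seed)
  s <- image_size
  n <- n_classes * n_per_class
  xs <- matrix(seq(0, 1, length.out = s), s, s, byrow = TRUE)  # column coord
  ys <- matrix(seq(0, 1, length.out = s), s, s)                # row coord
  images <- array(0, c(s, s, 3L, n))
  labels <- integer(n)
  i <- 0L
  for (cl in 0:(n_classes - 1L)) {
    # class pattern: grating angle/frequency and blob center vary with class
    ang <- pi * cl / n_classes
    freq <- 3 + 2 * (cl %% 3L)
    proj <- cos(ang) * xs + sin(ang) * ys
    grating <- 0.5 + 0.35 * sin(2 * pi * freq * proj)
    cx <- 0.2 + 0.6 * ((cl * 2L + 1L) %% n_classes) / n_classes
    cy <- 0.2 + 0.6 * ((cl * 3L + 2L) %% n_classes) / n_classes
    blob <- 0.4 * exp(-(((xs - cx)^2 + (ys - cy)^2) / 0.02))
    base <- pmin(pmax(grating + blob - 0.2, 0), 1)
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      img <- base
      if (noise_sd > 0) img <- img + matrix(stats::rnorm(s * s, 0, noise_sd), s, s)
      img <- pmin(pmax(img, 0), 1)
      images[, , 1L, i] <- img
      images[, , 2L, i] <- img
      images[, , 3L, i] <- img
      labels[i] <- cl
    }
  }
  image_dataset(images, labels)
}

#' Read a directory-of-class-folders image dataset
#'
#' Expects one subdirectory per class, each containing PNG images. Images are
#' resized to `size x size` by nearest-neighbour sampling, grayscale images
#' are replicated to three channels, and any alpha channel is dropped.
#' Classes are numbered `0..n_classes-1` in the lexical order of the folder
#' names. Only PNG files are supported.
#'
#' `preprocess` is a pluggable per-image hook (e.g. a handcrafted-descriptor
#' transform) applied to each `size x size x 3` array after resizing; the
#' default is the identity, and the hook must return an array of the same
#' shape with values in `[0, 1]`.
#'
#' @param path root directory.
#' @param size target square image side in pixels.
#' @param preprocess function applied to each image array (identity default).
#' @return An [image_dataset()].
#' @seealso [write_image_dir()]
#' @export
read_image_dir <- function(path, size = 32L, preprocess = identity) {
  classes <- sort(list.dirs(path, recursive = FALSE, full.names = FALSE))
  if (length(classes) < 1L) stop("no class subdirectories under ", path)
  imgs <- list(); labels <- integer(0); ids <- character(0)
  for (ci in seq_along(classes)) {
    files <- sort(list.files(file.path(path, classes[ci]),
                             pattern = "\\.png$", ignore.case = TRUE,
                             full.names = TRUE))
    for (f in files) {
      raw <- png::readPNG(f)
      if (length(dim(raw)) == 2L) dim(raw) <- c(dim(raw), 1L)
      if (dim(raw)[3L] >= 3L) raw <- raw[, , 1:3, drop = FALSE]
      else raw <- raw[, , rep(1L, 3L), drop = FALSE]
      ri <- round(seq(1, dim(raw)[1L], length.out = size))
      cj <- round(seq(1, dim(raw)[2L], length.out = size))
      img <- preprocess(raw[ri, cj, , drop = FALSE])
      if (!all(dim(img) == c(size, size, 3L)))
        stop("preprocess hook must preserve the size x size x 3 shape")
      imgs[[length(imgs) + 1L]] <- img
      labels <- c(labels, ci - 1L)
      ids <- c(ids, paste0(classes[ci], "/", basename(f)))
    }
  }
  if (length(imgs) == 0L) stop("no PNG images found under ", path)
  images <- array(unlist(imgs), c(size, size, 3L, length(imgs)))
  image_dataset(images, labels, ids)
}

#' Write a dataset as a directory of class folders of PNG images
#'
#' @param dataset an [image_dataset()].
#' @param path output root directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_image_dir <- function(dataset, path) {
  for (cl in 0:(dataset$n_classes - 1L)) {
    dir.create(file.path(path, sprintf("class_%02d", cl)),
               recursive = TRUE, showWarnings = FALSE)
  }
  for (i in seq_len(length(dataset))) {
    cl <- dataset$labels[i]
    f <- file.path(path, sprintf("class_%02d", cl),
                   paste0(gsub("[^A-Za-z0-9_.-]", "_", dataset$ids[i]), ".png"))
    png::writePNG(dataset$images[, , , i], f)
  }
  invisible(path)
}
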