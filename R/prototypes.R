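#' k-means prototypes of an image dataset
#'
#' Prototypes are the k centroids of a k-means clustering of the flattened
#' pixel vectors (`H*W*C` per image), reshaped back to image shape. They are
#' the reference points of a dissimilarity space: a sample is later described
#' by its k distances to these prototypes. Clustering runs in raw pixel space
#' by default so that prototypes are themselves images and can be fed through
#' the Siamese network (required by the FULLY construction); pass a feature
#' `matrix` to cluster in an embedding space instead (prototypes are then
#' returned as feature rows, usable only by feature-space consumers).
#'
#' k-means uses k-means++ seeding with `restarts` independent restarts (best
#' within-cluster sum of squares kept) and Lloyd iterations from
#' [stats::kmeans()]. With `per_class = TRUE` the clustering is run
#' separately inside each class with `k / n_classes` centroids per class
#' (rounded, remainder assigned to the largest classes), a supervised
#' variant.
#'
#' @param dataset an [image_dataset()].
#' @param k number of prototypes, `1 <= k <= n images`.
#' @param seed integer seed (controls seeding of all restarts).
#' @param restarts independent k-means++ restarts (default 5).
#' @param max_iter Lloyd iteration cap (default 300).
#' @param per_class supervised per-class mode (default `FALSE`).
#' @param features optional `n x d` matrix to cluster instead of pixels.
#' @return An object of class `prototype_set`: `prototypes` (array
#'   `H x W x C x k`, or `k x d` matrix in feature mode), `k`, `inertia`
#'   (within-cluster sum of squares), `seed`, `space` ("pixel" or "feature").
#' @export
compute_prototypes <- function(dataset, k, seed = 0L, restarts = 5L,
                               max_iter = 300L, per_class = FALSE,
                               features = NULL) {
  n <- length(dataset)
  if (k < 1L) stop("k must be >= 1")
  if (k > n) stop("k = ", k, " exceeds the number of images (", n, ")")
  d <- dim(dataset$images)
  x <- if (is.null(features)) {
    t(matrix(dataset$images, nrow = prod(d[1:3]), ncol = n))
  } else {
    if (nrow(features) != n) stop("features must have one row per image")
    features
  }
  local_rng(seed)
  if (per_class) {
    ks <- per_class_k(dataset, k)
    cent <- NULL; inertia <- 0
    for (cl in 0:(dataset$n_classes - 1L)) {
      kc <- ks[cl + 1L]
      if (kc == 0L) next
      fit <- best_kmeans(x[dataset$labels == cl, , drop = FALSE], kc,
                         restarts, max_iter)
      cent <- rbind(cent, fit$centers)
      inertia <- inertia + fit$tot.withinss
    }
  } else {
    fit <- best_kmeans(x, k, restarts, max_iter)
    cent <- fit$centers
    inertia <- fit$tot.withinss
  }
  prototypes <- if (is.null(features)) {
    array(t(cent), c(d[1:3], k))
  } else cent
  structure(
    list(prototypes = prototypes, k = as.integer(k), inertia = inertia,
         seed = as.integer(seed),
         space = if (is.null(features)) "pixel" else "feature"),
    class = "prototype_set"
  )
}

#' @export
print.prototype_set <- function(x, ...) {
  cat(sprintf("<prototype_set> k = %d (%s space), inertia = %.4g\n",
              x$k, x$space, x$inertia))
  invisible(x)
}

# Split k centroids across classes: floor(k / n_classes) each, remainder to
# the largest classes (ties by class index).
per_class_k <- function(dataset, k) {
  nc <- dataset$n_classes
  sizes <- tabulate(dataset$labels + 1L, nbins = nc)
  ks <- rep(k %/% nc, nc)
  extra <- k - sum(ks)
  if (extra > 0L) {
    ord <- order(-sizes, seq_len(nc))
    ks[ord[seq_len(extra)]] <- ks[ord[seq_len(extra)]] + 1L
  }
  if (any(ks > sizes))
    stop("per-class mode: a class has fewer members than its centroid share")
  ks
}

# Best-of-`restarts` k-means with k-means++ seeding; Lloyd iterations via
# stats::kmeans. Degenerate cases (k >= number of distinct rows) return the
# distinct rows themselves as centroids.
best_kmeans <- function(x, k, restarts, max_iter) {
  ux <- unique(x)
  if (k >= nrow(ux)) {
    cent <- ux[seq_len(min(k, nrow(ux))), , drop = FALSE]
    if (nrow(cent) < k)  # cannot happen for valid inputs; guard anyway
      cent <- cent[rep(seq_len(nrow(cent)), length.out = k), , drop = FALSE]
    assign_ <- apply_assign(x, cent)
    return(list(centers = cent, tot.withinss = assign_$wss))
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- kmeanspp_init(x, k)
    fit <- suppressWarnings(
      stats::kmeans(x, centers = init, iter.max = max_iter,
                    algorithm = "Lloyd")
    )
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

# k-means++ seeding: first center uniform, subsequent centers sampled with
# probability proportional to squared distance from the nearest chosen center.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- x[sample.int(n, 1L, prob = prob), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
  }
  centers
}

# Assign rows of x to nearest centroid; returns total within-cluster SS.
apply_assign <- function(x, cent) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(cent))) -
    2 * x %*% t(cent) + outer(rep(1, nrow(x)), rowSums(cent^2))
  list(cluster = max.col(-d2, ties.method = "first"),
       wss = sum(apply(d2, 1L, min)))
}

#' Prototype sets for a sweep of k values
#'
#' One [compute_prototypes()] call per requested k, with per-k seeds derived
#' deterministically from the base seed (`seed + index`).
#'
#' @param dataset an [image_dataset()].
#' @param ks integer vector of prototype counts (default the pipeline's
#'   standard sweep `c(15, 30, 45, 60)`).
#' @param seed base integer seed.
#' @param ... passed on to [compute_prototypes()].
#' @return A list of `prototype_set` objects, one per element of `ks`.
#' @export
prototype_sweep <- function(dataset, ks = c(15L, 30L, 45L, 60L), seed = 0L,
                            ...) {
  if (length(ks) == 0L) stop("ks must be non-empty")
  lapply(seq_along(ks), function(i) {
    compute_prototypes(dataset, ks[i], seed = as.integer(seed) + i - 1L, ...)
  })
}

#' Persist / load a prototype set as PNG images plus a JSON sidecar
#'
#' @param pset a `prototype_set` in pixel space.
#' @param path output directory.
#' @return `path` invisibly; `read_prototypes()` returns a `prototype_set`.
#' @export
write_prototypes <- function(pset, path) {
  if (pset$space != "pixel") stop("only pixel-space prototype sets are image-persistable")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (j in seq_len(pset$k)) {
    img <- pmin(pmax(pset$prototypes[, , , j], 0), 1)
    png::writePNG(img, file.path(path, sprintf("prototype_%03d.png", j)))
  }
  jsonlite::write_json(
    list(k = pset$k, seed = pset$seed, inertia = pset$inertia),
    file.path(path, "prototypes.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_prototypes
#' @export
read_prototypes <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "prototypes.json"))
  files <- sort(list.files(path, pattern = "^prototype_\\d+\\.png$",
                           full.names = TRUE))
  if (length(files) != meta$k) stop("prototype files do not match sidecar k")
  imgs <- lapply(files, function(f) {
    raw <- png::readPNG(f)
    if (length(dim(raw)) == 2L) raw <- array(raw, c(dim(raw), 1L))[, , c(1L, 1L, 1L)]
    raw[, , 1:3]
  })
  d <- dim(imgs[[1L]])
  structure(
    list(prototypes = array(unlist(imgs), c(d, length(imgs))),
         k = meta$k, inertia = meta$inertia, seed = meta$seed,
         space = "pixel"),
    class = "prototype_set"
  )
}
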