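#' Orthonormal 2-D type-II discrete cosine transform
#'
#' `dct2(X) = C X C^T` with the orthonormal DCT-II basis matrix
#' `C[u, x] = c(u) cos((2x + 1) u pi / (2N))` (0-based indices,
#' `c(0) = sqrt(1/N)`, `c(u>0) = sqrt(2/N)`). The transform is orthogonal,
#' so it preserves Frobenius norm and [idct2()] inverts it exactly; energy
#' concentrates in the low-frequency (top-left) coefficients, which is what
#' the 9 x 9 channel reduction of the DEEPER construction exploits.
#'
#' @param x square numeric matrix.
#' @return matrix of DCT coefficients, same size as `x`.
#' @export
dct2 <- function(x) {
  if (!is.matrix(x) || nrow(x) != ncol(x))
    stop("dct2 expects a square matrix")
  cm <- dct_matrix(nrow(x))
  cm %*% x %*% t(cm)
}

#' @rdname dct2
#' @export
idct2 <- function(x) {
  if (!is.matrix(x) || nrow(x) != ncol(x))
    stop("idct2 expects a square matrix")
  cm <- dct_matrix(nrow(x))
  t(cm) %*% x %*% cm
}

dct_matrix <- local({
  cache <- new.env(parent = emptyenv())
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    u <- 0:(n - 1)
    cm <- sqrt(2 / n) * cos(outer(u, 2 * u + 1) * pi / (2 * n))
    cm[1L, ] <- sqrt(1 / n)
    cache[[key]] <- cm
    cm
  }
})

#' Reduce an activation channel to 81 low-frequency DCT coefficients
#'
#' Non-square channels are center-cropped to `min(H, W)` square, transformed
#' with [dct2()], and the top-left `9 x 9` low-frequency block is kept and
#' flattened row-major. Channels smaller than 9 on a side contribute their
#' full coefficient block, zero-padded to 81 entries.
#'
#' @param channel numeric matrix `H' x W'`.
#' @return numeric vector of length 81.
#' @export
reduce_channel <- function(channel) {
  if (!is.matrix(channel)) channel <- as.matrix(channel)
  h <- nrow(channel); w <- ncol(channel)
  n <- min(h, w)
  r0 <- (h - n) %/% 2L
  c0 <- (w - n) %/% 2L
  sq <- channel[r0 + seq_len(n), c0 + seq_len(n), drop = FALSE]
  coef <- dct2(sq)
  m <- min(9L, n)
  block <- matrix(0, 9L, 9L)
  block[seq_len(m), seq_len(m)] <- coef[seq_len(m), seq_len(m)]
  as.vector(t(block))
}

#' DEEPER descriptor of images
#'
#' Runs the backbone to the tap layer and reduces each of the C' channels
#' with [reduce_channel()], concatenating in channel order into a vector of
#' length `81 * C'` per image.
#'
#' @param model a [build_model()] result.
#' @param images batch array or [image_dataset()].
#' @return `N x (81 * C')` numeric matrix, one descriptor per row.
#' @export
deeper_descriptor <- function(model, images) {
  feats <- deep_features(model, images)   # H' x W' x C' x N
  d <- dim(feats)
  out <- matrix(0, d[4L], 81L * d[3L])
  for (i in seq_len(d[4L])) {
    for (ch in seq_len(d[3L])) {
      out[i, (ch - 1L) * 81L + 1:81] <- reduce_channel(feats[, , ch, i])
    }
  }
  out
}

#' Cosine distance
#'
#' `1 - a.b / (|a||b|)`, in `[0, 2]`; defined as 1 (maximal ignorance) when
#' either vector is all-zero.
#'
#' @param a,b numeric vectors of equal length.
#' @return scalar in `[0, 2]`.
#' @export
cosine_distance <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(1)
  min(max(1 - sum(a * b) / (na * nb), 0), 2)
}

new_dissimilarity_matrix <- function(values, method, k, sample_ids,
                                     prototype_ids = NULL) {
  if (is.null(prototype_ids)) prototype_ids <- sprintf("p%03d", seq_len(k))
  dimnames(values) <- list(sample_ids, prototype_ids)
  structure(list(values = values, method = method, k = k),
            class = "dissimilarity_matrix")
}

#' @export
print.dissimilarity_matrix <- function(x, ...) {
  cat(sprintf("<dissimilarity_matrix> %s, %d samples x %d prototypes\n",
              x$method, nrow(x$values), x$k))
  invisible(x)
}

#' FULLY dissimilarity space
#'
#' Entry `(i, j)` is the Siamese head's predicted dissimilarity between
#' sample i and prototype j, i.e. `pair_dissimilarity(model, x_i, p_j)`;
#' the prototypes must therefore be pixel-space images. All entries lie in
#' (0, 1); larger means more dissimilar under the training convention.
#'
#' @param model a trained (or untrained) [build_model()] result.
#' @param dataset an [image_dataset()].
#' @param prototypes a pixel-space `prototype_set`.
#' @return A `dissimilarity_matrix` (`n_samples x k`).
#' @export
build_space_fully <- function(model, dataset, prototypes) {
  if (prototypes$space != "pixel")
    stop("FULLY requires pixel-space prototypes (images)")
  if (!all(dim(prototypes$prototypes)[1:3] == model$input_shape))
    stop("prototype shape does not match the model input shape")
  f <- embed(model, dataset)                     # n x E
  p <- embed(model, prototypes$prototypes)       # k x E
  w <- model$params[["head.w"]]; b <- model$params[["head.b"]]
  vals <- matrix(0, nrow(f), nrow(p))
  for (j in seq_len(nrow(p))) {
    z <- abs(sweep(f, 2L, p[j, ]))
    vals[, j] <- sigmoid(drop(z %*% w) + b)
  }
  new_dissimilarity_matrix(vals, "FULLY", prototypes$k, dataset$ids)
}

#' DEEPER dissimilarity space
#'
#' Entry `(i, j)` is the cosine distance between the DEEPER descriptors of
#' sample i and prototype j; prototype descriptors are computed once.
#' Entries lie in `[0, 2]`.
#'
#' @inheritParams build_space_fully
#' @return A `dissimilarity_matrix` (`n_samples x k`).
#' @export
build_space_deeper <- function(model, dataset, prototypes) {
  if (prototypes$space != "pixel")
    stop("DEEPER (as configured here) requires pixel-space prototypes")
  ds <- deeper_descriptor(model, dataset)
  dp <- deeper_descriptor(model, prototypes$prototypes)
  vals <- matrix(0, nrow(ds), nrow(dp))
  for (j in seq_len(nrow(dp))) {
    for (i in seq_len(nrow(ds))) {
      vals[i, j] <- cosine_distance(ds[i, ], dp[j, ])
    }
  }
  new_dissimilarity_matrix(vals, "DEEPER", prototypes$k, dataset$ids)
}

#' Write / read a dissimilarity matrix as CSV
#'
#' One row per sample (id in the first column), one column per prototype.
#'
#' @param dmat a `dissimilarity_matrix`.
#' @param path CSV file path.
#' @export
write_dissimilarity_csv <- function(dmat, path) {
  df <- data.frame(sample_id = rownames(dmat$values),
                   dmat$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
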