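#' Sample a balanced batch of image pairs
#'
#' Draws `n_pairs` index pairs from a dataset, a stated fraction of them
#' same-class. Pair targets follow the package's dissimilarity convention:
#' **target 1 means the two images come from different classes**, so the
#' Siamese head learns to output the dissimilarity directly (larger = more
#' dissimilar). Exhaustive pairing over the whole training set is quadratic
#' and is replaced by this balanced sampler; set `exhaustive = TRUE` to
#' enumerate every unordered pair of a small dataset instead (targets then
#' follow from the labels and `positive_fraction` is ignored).
#'
#' @param dataset an [image_dataset()] with at least two classes.
#' @param n_pairs number of pairs to draw (>= 2).
#' @param positive_fraction fraction of same-class pairs, strictly in (0, 1).
#' @param seed integer seed.
#' @param exhaustive enumerate all unordered pairs instead of sampling.
#' @return A list of class `pair_batch`: `first`, `second` (1-based image
#'   indices), `target` (1 = different class, 0 = same class).
#' @export
sample_pairs <- function(dataset, n_pairs, positive_fraction = 0.5,
                         seed = 0L, exhaustive = FALSE) {
  if (dataset$n_classes < 2L)
    stop("need at least two classes to form cross-class pairs")
  n <- length(dataset)
  if (exhaustive) {
    cmb <- utils::combn(n, 2L)
    first <- cmb[1L, ]; second <- cmb[2L, ]
    target <- as.integer(dataset$labels[first] != dataset$labels[second])
    return(structure(list(first = first, second = second, target = target),
                     class = "pair_batch"))
  }
  if (n_pairs < 2L) stop("n_pairs must be >= 2")
  if (positive_fraction <= 0 || positive_fraction >= 1)
    stop("positive_fraction must lie strictly in (0, 1)")
  local_rng(seed)
  n_same <- round(n_pairs * positive_fraction)
  n_same <- max(1L, min(n_pairs - 1L, as.integer(n_same)))
  by_class <- split(seq_len(n), dataset$labels)
  multi <- names(by_class)[lengths(by_class) >= 2L]
  first <- integer(n_pairs); second <- integer(n_pairs)
  target <- integer(n_pairs)
  for (i in seq_len(n_same)) {
    cl <- sample(multi, 1L)
    pick <- sample(by_class[[cl]], 2L, replace = FALSE)
    first[i] <- pick[1L]; second[i] <- pick[2L]; target[i] <- 0L
  }
  for (i in seq.int(n_same + 1L, n_pairs)) {
    a <- sample.int(n, 1L)
    b <- resample(which(dataset$labels != dataset$labels[a]), 1L)
    first[i] <- a; second[i] <- b; target[i] <- 1L
  }
  structure(list(first = first, second = second, target = target),
            class = "pair_batch")
}

# sample() treats a length-1 numeric x as 1:x; this keeps index semantics.
resample <- function(x, size) x[sample.int(length(x), size)]

#' Sample anchor/positive/negative triplets
#'
#' Every row satisfies `label(anchor) == label(positive)` and
#' `label(anchor) != label(negative)`; anchors are only drawn from classes
#' with at least two members so a distinct positive always exists.
#'
#' @param dataset an [image_dataset()] with at least two classes.
#' @param n_triplets number of triplets to draw (>= 1).
#' @param seed integer seed.
#' @return A list of class `triplet_batch`: `anchor`, `positive`, `negative`
#'   (1-based image indices).
#' @export
sample_triplets <- function(dataset, n_triplets, seed = 0L) {
  if (dataset$n_classes < 2L)
    stop("need at least two classes to form triplets")
  if (n_triplets < 1L) stop("n_triplets must be >= 1")
  n <- length(dataset)
  by_class <- split(seq_len(n), dataset$labels)
  multi <- names(by_class)[lengths(by_class) >= 2L]
  if (length(multi) == 0L)
    stop("no class has two or more members; cannot form positives")
  local_rng(seed)
  anchor <- integer(n_triplets); positive <- integer(n_triplets)
  negative <- integer(n_triplets)
  for (i in seq_len(n_triplets)) {
    cl <- sample(multi, 1L)
    pick <- sample(by_class[[cl]], 2L, replace = FALSE)
    anchor[i] <- pick[1L]; positive[i] <- pick[2L]
    negative[i] <- resample(which(dataset$labels != dataset$labels[anchor[i]]), 1L)
  }
  structure(list(anchor = anchor, positive = positive, negative = negative),
            class = "triplet_batch")
}
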