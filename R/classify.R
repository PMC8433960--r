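#' Class-score matrix
#'
#' `n_samples x n_classes` real-valued classifier outputs: the unit of
#' score-level fusion. Row order is fixed by `sample_ids`, column order by
#' `class_labels`; the predicted label of a row is its argmax (ties broken
#' by the lowest class index).
#'
#' @param scores numeric matrix `n_samples x n_classes`, no missing values.
#' @param class_labels ordered class labels (one per column).
#' @param sample_ids unique sample ids (one per row).
#' @return An object of class `score_matrix`.
#' @export
score_matrix <- function(scores, class_labels, sample_ids) {
  scores <- as.matrix(scores)
  if (anyNA(scores)) stop("scores contain missing values")
  if (ncol(scores) != length(class_labels))
    stop("one column per class label required")
  if (nrow(scores) != length(sample_ids))
    stop("one row per sample id required")
  dimnames(scores) <- list(sample_ids, as.character(class_labels))
  structure(list(scores = scores,
                 class_labels = as.character(class_labels),
                 sample_ids = as.character(sample_ids)),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %d samples x %d classes\n",
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Train an RBF support vector machine on dissimilarity features
#'
#' A fixed generic setting is used deliberately — radial basis kernel,
#' `C = 1000`, `gamma = 0.1`, no hyperparameter search — so that
#' differences between ensemble members reflect their dissimilarity spaces,
#' not per-member tuning. Multiclass handling is libsvm's one-vs-one;
#' [predict_scores()] aggregates the pairwise decision values into
#' per-class scores.
#'
#' @param features numeric matrix `n x k` of dissimilarity vectors (or a
#'   `dissimilarity_matrix`).
#' @param labels class labels (coerced to factor; at least two classes).
#' @param cost,gamma SVM hyperparameters (defaults 1000 and 0.1).
#' @return A fitted classifier of class `svm_classifier`.
#' @export
train_svm <- function(features, labels, cost = 1000, gamma = 0.1) {
  if (inherits(features, "dissimilarity_matrix")) features <- features$values
  features <- as.matrix(features)
  if (any(!is.finite(features))) stop("features must be finite")
  y <- factor(labels)
  if (nlevels(y) < 2L) stop("need at least two classes to train an SVM")
  if (nrow(features) < nlevels(y)) stop("fewer samples than classes")
  fit <- e1071::svm(features, y, kernel = "radial", cost = cost,
                    gamma = gamma, scale = FALSE)
  structure(list(fit = fit, classes = levels(y), width = ncol(features)),
            class = "svm_classifier")
}

#' Per-class scores from a trained SVM
#'
#' Aggregates libsvm's one-vs-one decision values into per-class scores:
#' each pairwise value is added to its favoured class and subtracted from
#' the other, a signed-vote total whose argmax is the predicted class.
#'
#' @param classifier a [train_svm()] result.
#' @param features matrix with the training feature width (or a
#'   `dissimilarity_matrix`).
#' @param sample_ids optional ids for the rows (default from row names or
#'   generated).
#' @return A [score_matrix()].
#' @export
predict_scores <- function(classifier, features, sample_ids = NULL) {
  if (inherits(features, "dissimilarity_matrix")) {
    if (is.null(sample_ids)) sample_ids <- rownames(features$values)
    features <- features$values
  }
  features <- as.matrix(features)
  if (ncol(features) != classifier$width)
    stop("feature width ", ncol(features), " does not match training width ",
         classifier$width)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(features)
    if (is.null(sample_ids)) sample_ids <- sprintf("s%05d", seq_len(nrow(features)))
  }
  pred <- stats::predict(classifier$fit, features, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  classes <- classifier$classes
  scores <- matrix(0, nrow(features), length(classes),
                   dimnames = list(NULL, classes))
  for (cn in colnames(dv)) {
    pair <- strsplit(cn, "/", fixed = TRUE)[[1L]]
    scores[, pair[1L]] <- scores[, pair[1L]] + dv[, cn]
    scores[, pair[2L]] <- scores[, pair[2L]] - dv[, cn]
  }
  score_matrix(scores, classes, sample_ids)
}

#' Standardize a score matrix to global mean 0 and standard deviation 1
#'
#' One affine map over all entries (not per column), matching the
#' score-normalization step applied before fusing with external classifier
#' scores. Strictly increasing and uniform, so per-row argmax (and hence
#' accuracy) is unchanged; idempotent.
#'
#' @param s a [score_matrix()].
#' @return A [score_matrix()] with standardized entries.
#' @export
normalize_scores <- function(s) {
  v <- as.vector(s$scores)
  sd_ <- stats::sd(v)
  if (!is.finite(sd_) || sd_ == 0)
    stop("cannot standardize a constant score matrix")
  score_matrix((s$scores - mean(v)) / sd_, s$class_labels, s$sample_ids)
}

check_aligned <- function(members) {
  ref <- members[[1L]]
  for (m in members[-1L]) {
    if (!identical(m$sample_ids, ref$sample_ids))
      stop("score matrices disagree on sample ids/order")
    if (!identical(m$class_labels, ref$class_labels))
      stop("score matrices disagree on class labels/order")
  }
  invisible(ref)
}

#' Fuse score matrices by the average (or sum) rule
#'
#' Element-wise mean over aligned members; the sum rule is the same up to a
#' positive scale and yields identical argmax decisions.
#'
#' @param members list of aligned [score_matrix()] objects.
#' @return A fused [score_matrix()].
#' @export
fuse_average <- function(members) {
  if (length(members) == 0L) stop("no members to fuse")
  ref <- check_aligned(members)
  acc <- Reduce(`+`, lapply(members, `[[`, "scores"))
  score_matrix(acc / length(members), ref$class_labels, ref$sample_ids)
}

#' @rdname fuse_average
#' @export
fuse_sum <- function(members) {
  if (length(members) == 0L) stop("no members to fuse")
  ref <- check_aligned(members)
  acc <- Reduce(`+`, lapply(members, `[[`, "scores"))
  score_matrix(acc, ref$class_labels, ref$sample_ids)
}

#' Classification accuracy of a score matrix
#'
#' Fraction of rows whose argmax column matches the true label; argmax ties
#' are broken by the lowest class index (stable and documented).
#'
#' @param s a [score_matrix()].
#' @param truth true labels, one per row, as values of `s$class_labels`;
#'   may be named by sample id (then checked against `s$sample_ids`).
#' @return scalar accuracy in `[0, 1]`.
#' @export
evaluate_accuracy <- function(s, truth) {
  if (length(truth) != nrow(s$scores))
    stop("truth length does not match the score matrix")
  if (!is.null(names(truth)) && !identical(names(truth), s$sample_ids))
    stop("truth ids do not match the score matrix sample ids")
  pred <- s$class_labels[max.col(s$scores, ties.method = "first")]
  mean(pred == as.character(truth))
}

#' Predicted labels of a score matrix
#'
#' @param s a [score_matrix()].
#' @return character vector of per-row argmax class labels.
#' @export
predicted_labels <- function(s) {
  s$class_labels[max.col(s$scores, ties.method = "first")]
}

#' Write / read a score matrix as CSV
#'
#' First column `sample_id`, then one column per class — the interchange
#' format for fusing with externally produced classifier scores.
#'
#' @param s a [score_matrix()].
#' @param path CSV file path.
#' @export
write_scores_csv <- function(s, path) {
  df <- data.frame(sample_id = s$sample_ids, s$scores, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores_csv
#' @export
read_scores_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  score_matrix(as.matrix(df[, -1L, drop = FALSE]),
               colnames(df)[-1L], df$sample_id)
}
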