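#' Train a Siamese model on a labeled dataset
#'
#' One "iteration" is one optimizer update on one freshly sampled minibatch
#' of pairs (cross-entropy objective) or triplets (triplet objective).
#' Sampling, initialization and the optimizer are all driven by `seed`, so
#' a run is bit-reproducible on one platform.
#'
#' @param model a [build_model()] result.
#' @param dataset training [image_dataset()] (>= 2 classes).
#' @param loss `"cross"` (binary cross-entropy on pair dissimilarity) or
#'   `"triplet"` (clipped triplet objective, margin 1).
#' @param optimizer `"adam"`, `"dgrad"` or `"decaydgrad"`, or a ready
#'   [optimizer_state()].
#' @param iterations optimizer updates (default 3000).
#' @param batch_size pairs/triplets per minibatch (default 32).
#' @param lr learning rate (default 1e-4).
#' @param margin triplet margin (default 1).
#' @param seed integer seed.
#' @return The trained model, with a numeric `loss_trace` attached.
#' @export
train_siamese <- function(model, dataset, loss = c("cross", "triplet"),
                          optimizer = "adam", iterations = 3000L,
                          batch_size = 32L, lr = 1e-4, margin = 1,
                          seed = 0L) {
  loss <- match.arg(loss)
  if (iterations < 1L) stop("iterations must be >= 1")
  if (dataset$n_classes < 2L) stop("training needs at least two classes")
  state <- if (inherits(optimizer, "optimizer_state")) optimizer
           else optimizer_state(optimizer, lr = lr, niter = iterations)
  local_rng(seed)
  n <- length(dataset)
  by_class <- split(seq_len(n), dataset$labels)
  multi <- names(by_class)[lengths(by_class) >= 2L]
  trace <- numeric(iterations)
  for (it in seq_len(iterations)) {
    if (loss == "cross") {
      b <- draw_pair_batch(dataset$labels, by_class, multi, n, batch_size)
      lg <- pair_loss_grads(
        model,
        dataset$images[, , , b$first, drop = FALSE],
        dataset$images[, , , b$second, drop = FALSE],
        b$target)
    } else {
      b <- draw_triplet_batch(dataset$labels, by_class, multi, n, batch_size)
      lg <- triplet_loss_grads(
        model,
        dataset$images[, , , b$anchor, drop = FALSE],
        dataset$images[, , , b$positive, drop = FALSE],
        dataset$images[, , , b$negative, drop = FALSE],
        margin = margin)
    }
    upd <- optimizer_step(state, lg$grads, model$params)
    model$params <- upd$params
    state <- upd$state
    trace[it] <- lg$loss
  }
  attr(model, "loss_trace") <- trace
  model
}

# In-loop balanced pair draw (half same-class target 0, half different
# target 1), consuming the caller's RNG stream.
draw_pair_batch <- function(labels, by_class, multi, n, batch_size) {
  n_same <- batch_size %/% 2L
  first <- integer(batch_size); second <- integer(batch_size)
  target <- integer(batch_size)
  for (i in seq_len(batch_size)) {
    if (i <= n_same) {
      cl <- if (length(multi) == 1L) multi else sample(multi, 1L)
      pick <- sample(by_class[[cl]], 2L)
      first[i] <- pick[1L]; second[i] <- pick[2L]; target[i] <- 0L
    } else {
      a <- sample.int(n, 1L)
      cand <- which(labels != labels[a])
      first[i] <- a
      second[i] <- if (length(cand) == 1L) cand else sample(cand, 1L)
      target[i] <- 1L
    }
  }
  list(first = first, second = second, target = target)
}

draw_triplet_batch <- function(labels, by_class, multi, n, batch_size) {
  anchor <- integer(batch_size); positive <- integer(batch_size)
  negative <- integer(batch_size)
  for (i in seq_len(batch_size)) {
    cl <- if (length(multi) == 1L) multi else sample(multi, 1L)
    pick <- sample(by_class[[cl]], 2L)
    anchor[i] <- pick[1L]; positive[i] <- pick[2L]
    cand <- which(labels != labels[anchor[i]])
    negative[i] <- if (length(cand) == 1L) cand else sample(cand, 1L)
  }
  list(anchor = anchor, positive = positive, negative = negative)
}

#' Run configuration for a training grid
#'
#' Bundles every tunable of a train/evaluate run. The defaults mirror the
#' pipeline's standard conditions: prototype sweep `c(15, 30, 45, 60)`,
#' 3000 iterations, batch size 32, learning rate 1e-4.
#'
#' @param loss `"cross"` or `"triplet"`.
#' @param optimizer `"adam"`, `"dgrad"` or `"decaydgrad"`.
#' @param space_methods subset of `c("FULLY", "DEEPER")`.
#' @param ks prototype counts.
#' @param iterations,batch_size,lr training hyperparameters.
#' @param backbone a [backbone_spec()] (default [default_backbone_spec()]).
#' @param seed base integer seed.
#' @param out_dir optional directory; when given, training score matrices,
#'   the config (with hash) and the backbone spec are persisted there as
#'   CSV/JSON; stage progress is logged to stderr either way.
#' @return An object of class `run_config`.
#' @export
run_config <- function(loss = "cross", optimizer = "adam",
                       space_methods = c("FULLY", "DEEPER"),
                       ks = c(15L, 30L, 45L, 60L), iterations = 3000L,
                       batch_size = 32L, lr = 1e-4,
                       backbone = default_backbone_spec(), seed = 0L,
                       out_dir = NULL) {
  loss <- match.arg(loss, c("cross", "triplet"))
  optimizer <- match.arg(optimizer, c("adam", "dgrad", "decaydgrad"))
  space_methods <- match.arg(space_methods, c("FULLY", "DEEPER"),
                             several.ok = TRUE)
  if (length(ks) == 0L) stop("ks must be non-empty")
  if (iterations < 1L) stop("iterations must be >= 1")
  structure(
    list(loss = loss, optimizer = optimizer, space_methods = space_methods,
         ks = as.integer(ks), iterations = as.integer(iterations),
         batch_size = as.integer(batch_size), lr = lr, backbone = backbone,
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

config_hash <- function(config) {
  key <- paste(config$loss, config$optimizer,
               paste(config$space_methods, collapse = "+"),
               paste(config$ks, collapse = ","), config$iterations,
               config$batch_size, format(config$lr), config$seed, sep = "|")
  # small stable polynomial rolling hash over the config string
  h <- 17
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

run_log <- function(config, stage, t0) {
  message(sprintf("[siamdiss %s] %s (%.1fs)", config_hash(config), stage,
                  as.numeric(Sys.time()) - t0))
}

#' Train the ensemble members of a run configuration
#'
#' For each k in `config$ks`: computes k pixel-space prototypes, trains one
#' Siamese model (loss and optimizer from the config, per-k seed derived as
#' `seed + index`), and builds one ensemble member per requested space
#' method (members of the same k share the trained model). SVMs are trained
#' on the resulting dissimilarity vectors.
#'
#' @param config a [run_config()].
#' @param train_dataset training [image_dataset()].
#' @return List of members; each has `loss`, `space_method`, `k`, `model`,
#'   `prototypes`, `svm`, `train_scores`, plus the config hash and seed.
#' @export
run_training <- function(config, train_dataset) {
  t0 <- as.numeric(Sys.time())
  members <- list()
  for (i in seq_along(config$ks)) {
    k <- config$ks[i]
    seed_k <- config$seed + i
    protos <- compute_prototypes(train_dataset, k, seed = seed_k)
    run_log(config, sprintf("prototypes k=%d", k), t0)
    model <- build_model(config$backbone, seed = seed_k,
                         input_shape = dim(train_dataset$images)[1:3])
    model <- train_siamese(model, train_dataset, loss = config$loss,
                           optimizer = config$optimizer,
                           iterations = config$iterations,
                           batch_size = config$batch_size, lr = config$lr,
                           seed = seed_k)
    run_log(config, sprintf("trained model k=%d (%s/%s)", k, config$loss,
                            config$optimizer), t0)
    for (method in config$space_methods) {
      dmat <- switch(method,
        FULLY = build_space_fully(model, train_dataset, protos),
        DEEPER = build_space_deeper(model, train_dataset, protos))
      svm_fit <- train_svm(dmat, train_dataset$labels)
      scores <- predict_scores(svm_fit, dmat)
      members[[length(members) + 1L]] <- list(
        loss = config$loss, space_method = method, k = k,
        model = model, prototypes = protos, svm = svm_fit,
        train_scores = scores, config_hash = config_hash(config),
        seed = seed_k)
      run_log(config, sprintf("member %s k=%d", method, k), t0)
    }
  }
  if (!is.null(config$out_dir)) persist_run(config, members)
  members
}

persist_run <- function(config, members) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config
  cfg$backbone <- NULL
  jsonlite::write_json(c(unclass(cfg), list(hash = config_hash(config))),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  write_backbone_spec(config$backbone,
                      file.path(config$out_dir, "backbone.json"))
  for (m in members) {
    write_scores_csv(m$train_scores, file.path(
      config$out_dir,
      sprintf("train_scores_%s_%s_k%02d.csv", m$loss, m$space_method, m$k)))
  }
  invisible(config$out_dir)
}

#' Evaluate ensemble members on a held-out dataset
#'
#' Builds each member's dissimilarity space on the test images, scores it
#' with the member's SVM, and fuses all members by the average rule.
#' Sample-id alignment is verified at the fusion step.
#'
#' @param members a [run_training()] result (or any list of members).
#' @param test_dataset held-out [image_dataset()] with the same image shape
#'   and class set as the training data.
#' @return `list(member_accuracy, fused_accuracy, member_scores,
#'   fused_scores)`.
#' @export
run_evaluation <- function(members, test_dataset) {
  if (length(members) == 0L) stop("no members to evaluate")
  truth <- as.character(test_dataset$labels)
  member_scores <- lapply(members, function(m) {
    if (!setequal(m$svm$classes, unique(truth)))
      stop("test dataset class set does not match the trained members")
    dmat <- switch(m$space_method,
      FULLY = build_space_fully(m$model, test_dataset, m$prototypes),
      DEEPER = build_space_deeper(m$model, test_dataset, m$prototypes))
    predict_scores(m$svm, dmat)
  })
  member_accuracy <- vapply(member_scores, evaluate_accuracy, 0, truth = truth)
  names(member_accuracy) <- vapply(
    members, function(m) sprintf("%s_%s_k%d", m$loss, m$space_method, m$k), "")
  fused <- fuse_average(member_scores)
  list(member_accuracy = member_accuracy,
       fused_accuracy = evaluate_accuracy(fused, truth),
       member_scores = member_scores, fused_scores = fused)
}

#' Fuse ensemble scores with an external classifier's scores
#'
#' Both score matrices are standardized to global mean 0 / sd 1 with
#' [normalize_scores()] and then summed element-wise — the sum-rule fusion
#' used to combine the dissimilarity ensemble with, e.g., an ensemble of
#' conventional CNN classifiers whose scores arrive as CSV
#' ([read_scores_csv()]).
#'
#' @param fused the ensemble [score_matrix()].
#' @param external an aligned external [score_matrix()].
#' @return A fused [score_matrix()].
#' @export
fuse_with_external <- function(fused, external) {
  check_aligned(list(fused, external))
  a <- normalize_scores(fused)
  b <- normalize_scores(external)
  score_matrix(a$scores + b$scores, fused$class_labels, fused$sample_ids)
}
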