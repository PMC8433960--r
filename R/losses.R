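#' Binary cross-entropy pair loss
#'
#' Mean of `-(t*log(y) + (1-t)*log(1-y))` over a batch of head outputs.
#' Under the package's pair convention, target 1 marks a different-class
#' pair, so the head output y is the predicted dissimilarity. Predictions
#' are clamped `1e-7` away from 0 and 1 to keep the loss finite.
#'
#' @param predicted numeric vector of head outputs in (0, 1).
#' @param targets binary vector of the same length.
#' @return non-negative scalar loss.
#' @export
bce_pair_loss <- function(predicted, targets) {
  if (length(predicted) != length(targets))
    stop("predicted and targets differ in length")
  y <- pmin(pmax(predicted, 1e-7), 1 - 1e-7)
  t <- as.numeric(targets)
  -mean(t * log(y) + (1 - t) * log(1 - y))
}

#' Clipped triplet loss
#'
#' For sigmoid-squashed embeddings `YA, YP, YN` of an anchor, a same-class
#' positive and a different-class negative, the per-triplet loss is
#' `max(||YA - YP||^2 - ||YA - YN||^2, -margin)` with Euclidean norms; the
#' batch loss is the mean. Note the clip at `-margin`: unlike the
#' conventional hinge `max(d_ap - d_an + margin, 0)`, this objective can go
#' negative (down to `-margin`) and keeps pushing `d_an` above `d_ap` until
#' the gap reaches the margin. The conventional hinge is available as
#' `variant = "hinge"` for comparison but is not the default.
#'
#' @param ya,yp,yn numeric matrices `n_triplets x d` (or vectors for a
#'   single triplet) with entries in (0, 1).
#' @param margin positive clipping margin (default 1).
#' @param variant `"clip"` (default) or `"hinge"`.
#' @return scalar batch loss, `>= -margin` for `"clip"`.
#' @export
triplet_loss <- function(ya, yp, yn, margin = 1, variant = c("clip", "hinge")) {
  variant <- match.arg(variant)
  if (margin <= 0) stop("margin must be positive")
  if (is.null(dim(ya))) { ya <- rbind(ya); yp <- rbind(yp); yn <- rbind(yn) }
  if (!all(dim(ya) == dim(yp)) || !all(dim(ya) == dim(yn)))
    stop("ya, yp, yn must have identical dimensions")
  d_ap <- rowSums((ya - yp)^2)
  d_an <- rowSums((ya - yn)^2)
  per <- switch(variant,
    clip = pmax(d_ap - d_an, -margin),
    hinge = pmax(d_ap - d_an + margin, 0))
  mean(per)
}

# Loss + parameter gradients for one minibatch of image pairs through the
# shared backbone and head. Gradients of the two branches are summed into
# the single tied parameter set. Returns list(loss, grads).
pair_loss_grads <- function(model, x1, x2, targets) {
  f1 <- backbone_forward(model, x1, keep_cache = TRUE)
  f2 <- backbone_forward(model, x2, keep_cache = TRUE)
  z <- abs(f1$out - f2$out)                       # N x E
  logits <- drop(z %*% model$params[["head.w"]] + model$params[["head.b"]])
  y <- sigmoid(logits)
  loss <- bce_pair_loss(y, targets)
  n <- length(targets)
  dlogit <- (y - as.numeric(targets)) / n          # d loss / d logits
  dw <- crossprod(z, dlogit)
  db <- sum(dlogit)
  dz <- matrix(dlogit, n, 1L) %*% t(model$params[["head.w"]])  # N x E
  s <- sign(f1$out - f2$out)
  g1 <- backbone_backward(model, f1$caches, dz * s)
  g2 <- backbone_backward(model, f2$caches, -dz * s)
  grads <- sum_grads(g1, g2)
  grads[["head.w"]] <- dw
  grads[["head.b"]] <- db
  list(loss = loss, grads = grads)
}

# Loss + parameter gradients for a minibatch of triplets (clipped objective).
# Clipped rows contribute zero gradient.
triplet_loss_grads <- function(model, xa, xp, xn, margin = 1) {
  fa <- backbone_forward(model, xa, keep_cache = TRUE)
  fp <- backbone_forward(model, xp, keep_cache = TRUE)
  fn_ <- backbone_forward(model, xn, keep_cache = TRUE)
  ya <- sigmoid(fa$out); yp <- sigmoid(fp$out); yn <- sigmoid(fn_$out)
  d_ap <- rowSums((ya - yp)^2)
  d_an <- rowSums((ya - yn)^2)
  diff <- d_ap - d_an
  loss <- mean(pmax(diff, -margin))
  n <- nrow(ya)
  active <- as.numeric(diff > -margin) / n
  dya <- 2 * (yn - yp) * active
  dyp <- -2 * (ya - yp) * active
  dyn <- 2 * (ya - yn) * active
  ga <- backbone_backward(model, fa$caches, dya * ya * (1 - ya))
  gp <- backbone_backward(model, fp$caches, dyp * yp * (1 - yp))
  gn <- backbone_backward(model, fn_$caches, dyn * yn * (1 - yn))
  grads <- sum_grads(sum_grads(ga, gp), gn)
  grads[["head.w"]] <- matrix(0, model$spec$embedding_dim, 1L)
  grads[["head.b"]] <- 0
  list(loss = loss, grads = grads)
}

sum_grads <- function(a, b) {
  nms <- union(names(a), names(b))
  nms <- setdiff(nms, "dx")
  out <- list()
  for (nm in nms) {
    if (is.null(a[[nm]])) out[[nm]] <- b[[nm]]
    else if (is.null(b[[nm]])) out[[nm]] <- a[[nm]]
    else out[[nm]] <- a[[nm]] + b[[nm]]
  }
  out
}
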