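# Minimal CNN layer primitives with explicit forward/backward pairs.
# Spatial activations use an internal H x W x N x C layout (channel last)
# and are manipulated as flattened (H*W) x (N*C) matrices with precomputed
# row indices: each convolution offset is then a single fast 2-D subscript
# plus one BLAS matrix product, with no array permutations in the hot path.
# The public API converts from/to the user-facing H x W x C x N layout at
# the boundaries. Backward passes are exact gradients, verified against
# central differences in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

# user layout H x W x C x N  ->  internal H x W x N x C (and back)
to_internal <- function(x) aperm(x, c(1L, 2L, 4L, 3L))
to_user <- function(x) aperm(x, c(1L, 2L, 4L, 3L))

pad_batch <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1L] + 2L * p, d[2L] + 2L * p, d[3L], d[4L]))
  out[p + seq_len(d[1L]), p + seq_len(d[2L]), , ] <- x
  out
}

conv_out_hw <- function(h, w, kernel, stride, padding) {
  c((h + 2L * padding - kernel) %/% stride + 1L,
    (w + 2L * padding - kernel) %/% stride + 1L)
}

# Row indices (into an (H*W)-row matrix) of the output window anchored at
# kernel offset (a, bb); ordered row-fastest to match column-major reshape.
offset_rows <- function(a, bb, hp, ho, wo, stride) {
  ridx <- seq.int(a, by = stride, length.out = ho)
  cidx <- seq.int(bb, by = stride, length.out = wo)
  as.vector(outer(ridx, (cidx - 1L) * hp, "+"))
}

# x: H x W x N x Cin; w: kh x kw x Cin x Cout; b: length Cout
conv_fwd <- function(x, w, b, stride, padding) {
  dw <- dim(w); kh <- dw[1L]; kw <- dw[2L]; cin <- dw[3L]; cout <- dw[4L]
  xp <- pad_batch(x, padding)
  dp <- dim(xp); hp <- dp[1L]; n <- dp[3L]
  ho <- (dp[1L] - kh) %/% stride + 1L
  wo <- (dp[2L] - kw) %/% stride + 1L
  in_dim <- dim(x)
  dim(xp) <- c(hp * dp[2L], n * cin)
  rows <- ho * wo * n
  out_mat <- matrix(rep(b, each = rows), rows, cout)
  for (a in seq_len(kh)) {
    for (bb in seq_len(kw)) {
      idx <- offset_rows(a, bb, hp, ho, wo, stride)
      xs <- xp[idx, , drop = FALSE]
      dim(xs) <- c(rows, cin)
      wab <- w[a, bb, , , drop = FALSE]
      dim(wab) <- c(cin, cout)
      out_mat <- out_mat + xs %*% wab
    }
  }
  list(out = array(out_mat, c(ho, wo, n, cout)),
       cache = list(xp = xp, pad_dim = dp, w = w, stride = stride,
                    padding = padding, in_dim = in_dim))
}

conv_bwd <- function(d_out, cache) {
  w <- cache$w; xp <- cache$xp
  stride <- cache$stride; padding <- cache$padding
  dw_dims <- dim(w); kh <- dw_dims[1L]; kw <- dw_dims[2L]
  cin <- dw_dims[3L]; cout <- dw_dims[4L]
  do_d <- dim(d_out); ho <- do_d[1L]; wo <- do_d[2L]; n <- do_d[3L]
  hp <- cache$pad_dim[1L]
  rows <- ho * wo * n
  dout_mat <- d_out
  dim(dout_mat) <- c(rows, cout)
  db <- colSums(dout_mat)
  dw <- array(0, dw_dims)
  dxp <- matrix(0, nrow(xp), ncol(xp))
  for (a in seq_len(kh)) {
    for (bb in seq_len(kw)) {
      idx <- offset_rows(a, bb, hp, ho, wo, stride)
      xs <- xp[idx, , drop = FALSE]
      dim(xs) <- c(rows, cin)
      dw[a, bb, , ] <- crossprod(xs, dout_mat)
      wab <- w[a, bb, , , drop = FALSE]
      dim(wab) <- c(cin, cout)
      dxs <- tcrossprod(dout_mat, wab)          # rows x cin
      dim(dxs) <- c(ho * wo, n * cin)
      dxp[idx, ] <- dxp[idx, , drop = FALSE] + dxs
    }
  }
  dim(dxp) <- cache$pad_dim
  id <- cache$in_dim
  dx <- dxp[padding + seq_len(id[1L]), padding + seq_len(id[2L]), , ,
            drop = FALSE]
  list(dx = dx, dw = dw, db = db)
}

# Max pooling; ties broken by the first window position (row-major order).
pool_fwd <- function(x, kernel, stride) {
  d <- dim(x)
  ho <- (d[1L] - kernel) %/% stride + 1L
  wo <- (d[2L] - kernel) %/% stride + 1L
  xf <- x
  dim(xf) <- c(d[1L] * d[2L], d[3L] * d[4L])
  out <- NULL; arg <- NULL
  pos <- 0L
  for (a in seq_len(kernel)) {
    for (bb in seq_len(kernel)) {
      pos <- pos + 1L
      idx <- offset_rows(a, bb, d[1L], ho, wo, stride)
      xs <- xf[idx, , drop = FALSE]
      if (is.null(out)) {
        out <- xs
        arg <- matrix(pos, nrow(xs), ncol(xs))
      } else {
        m <- xs > out
        out[m] <- xs[m]
        arg[m] <- pos
      }
    }
  }
  dim(out) <- c(ho, wo, d[3L], d[4L])
  list(out = out,
       cache = list(arg = arg, kernel = kernel, stride = stride,
                    in_dim = d, out_hw = c(ho, wo)))
}

pool_bwd <- function(d_out, cache) {
  d <- cache$in_dim
  kernel <- cache$kernel; stride <- cache$stride
  ho <- cache$out_hw[1L]; wo <- cache$out_hw[2L]
  dof <- d_out
  dim(dof) <- c(ho * wo, d[3L] * d[4L])
  dx <- matrix(0, d[1L] * d[2L], d[3L] * d[4L])
  pos <- 0L
  for (a in seq_len(kernel)) {
    for (bb in seq_len(kernel)) {
      pos <- pos + 1L
      idx <- offset_rows(a, bb, d[1L], ho, wo, stride)
      dx[idx, ] <- dx[idx, , drop = FALSE] + dof * (cache$arg == pos)
    }
  }
  dim(dx) <- d
  list(dx = dx)
}

relu_fwd <- function(x) list(out = pmax(x, 0), cache = list(mask = x > 0))

relu_bwd <- function(d_out, cache) list(dx = d_out * cache$mask)

# Fully connected layer. 4-D input arrives in the internal H x W x N x C
# layout and is flattened per image in H x W x C (user) order, so the
# feature layout of the weight matrix is independent of the batch.
fc_fwd <- function(x, w, b) {
  was_array <- is.array(x) && length(dim(x)) == 4L
  in_dim <- dim(x)
  if (was_array) {
    n <- in_dim[3L]
    xm <- to_user(x)                       # H x W x C x N
    xm <- t(matrix(xm, prod(in_dim[c(1L, 2L, 4L)]), n))
  } else xm <- x
  out <- sweep(xm %*% w, 2L, b, "+")
  list(out = out,
       cache = list(xm = xm, w = w, was_array = was_array, in_dim = in_dim))
}

fc_bwd <- function(d_out, cache) {
  dw <- crossprod(cache$xm, d_out)
  db <- colSums(d_out)
  dxm <- tcrossprod(d_out, cache$w)
  dx <- if (cache$was_array) {
    to_internal(array(t(dxm), cache$in_dim[c(1L, 2L, 4L, 3L)]))
  } else dxm
  list(dx = dx, dw = dw, db = db)
}
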