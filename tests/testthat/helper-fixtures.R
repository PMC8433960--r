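# Shared tiny fixtures, built in code at load time so every test file can
# reuse them without regeneration cost.

tiny_dataset <- function(n_classes = 3L, n_per_class = 20L, size = 32L,
                         noise_sd = 0.05, seed = 7L) {
  generate_toy_dataset(n_classes, n_per_class, size, noise_sd, seed)
}

# A small backbone for fast structural tests on 8x8 inputs.
tiny_spec <- function() {
  backbone_spec(list(
    conv_layer(2L), relu_layer(), pool_layer(),
    conv_layer(3L), relu_layer(), fc_layer(5L)
  ), tap_layer = "conv2")
}

tiny_model <- function(seed = 3L, input_shape = c(8L, 8L, 3L)) {
  build_model(tiny_spec(), seed = seed, input_shape = input_shape)
}

random_batch <- function(n = 4L, shape = c(8L, 8L, 3L), seed = 42L) {
  withr::with_seed(seed, array(stats::runif(prod(shape) * n), c(shape, n)))
}

# Independent brute-force O(N^4) oracle for the orthonormal type-II 2-D DCT
# (0-based standard form), kept free of the package's matrix implementation.
dct2_bruteforce <- function(x) {
  n <- nrow(x)
  cc <- function(u) if (u == 0) sqrt(1 / n) else sqrt(2 / n)
  out <- matrix(0, n, n)
  for (u in 0:(n - 1)) for (v in 0:(n - 1)) {
    acc <- 0
    for (p in 0:(n - 1)) for (q in 0:(n - 1)) {
      acc <- acc + x[p + 1, q + 1] *
        cos((2 * p + 1) * u * pi / (2 * n)) *
        cos((2 * q + 1) * v * pi / (2 * n))
    }
    out[u + 1, v + 1] <- cc(u) * cc(v) * acc
  }
  out
}

# Reference Adam recurrence written independently of the package (plain
# scalar/vector arithmetic, no shared helpers).
reference_adam <- function(grad_seq, theta0, lr, rho1 = 0.9, rho2 = 0.99,
                           eps = 1e-8) {
  m <- theta0 * 0; u <- theta0 * 0; theta <- theta0
  path <- vector("list", length(grad_seq))
  for (t in seq_along(grad_seq)) {
    g <- grad_seq[[t]]
    m <- rho1 * m + (1 - rho1) * g
    u <- rho2 * u + (1 - rho2) * g^2
    mhat <- m / (1 - rho1^t)
    uhat <- u / (1 - rho2^t)
    theta <- theta - lr * mhat / (sqrt(uhat) + eps)
    path[[t]] <- theta
  }
  path
}
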