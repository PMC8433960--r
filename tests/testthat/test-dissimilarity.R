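test_that("dct2 agrees with the brute-force double-sum oracle", {
  withr::with_seed(1, {
    for (n in 1:8) {
      for (rep in 1:3) {
        x <- matrix(stats::rnorm(n * n), n, n)
        expect_lt(max(abs(dct2(x) - dct2_bruteforce(x))), 1e-9)
      }
    }
  })
})

test_that("dct2 is orthonormal: energy conservation and exact inversion", {
  withr::with_seed(2, {
    for (n in c(1, 4, 9, 16)) {
      x <- matrix(stats::rnorm(n * n), n, n)
      y <- dct2(x)
      expect_equal(norm(y, "F"), norm(x, "F"), tolerance = 1e-10)
      expect_lt(max(abs(idct2(y) - x)), 1e-9)
    }
  })
  expect_error(dct2(matrix(0, 2, 3)), "square")
})

test_that("a constant matrix concentrates in the DC coefficient c*N", {
  for (n in c(3, 9)) {
    y <- dct2(matrix(2.5, n, n))
    expect_equal(y[1, 1], 2.5 * n, tolerance = 1e-10)
    expect_lt(max(abs(y[-1])), 1e-10)
  }
})

test_that("channel reduction yields 81 coefficients under all geometries", {
  withr::with_seed(3, {
    r16 <- reduce_channel(matrix(stats::rnorm(256), 16, 16))
    expect_length(r16, 81L)
    # constant channel: DC only
    rc <- reduce_channel(matrix(1.5, 16, 16))
    expect_equal(rc[1], 1.5 * 16)
    expect_lt(max(abs(rc[-1])), 1e-10)
    # small channel: 16 true coefficients, 65 structural zeros
    r4 <- reduce_channel(matrix(stats::rnorm(16), 4, 4))
    expect_length(r4, 81L)
    expect_identical(sum(r4 != 0), 16L)
    # non-square input is center-cropped to square, not an error
    expect_length(reduce_channel(matrix(stats::rnorm(60), 6, 10)), 81L)
  })
})

test_that("deeper descriptor has length 81 * channels and is pure", {
  m <- build_model(default_backbone_spec(), seed = 0,
                   input_shape = c(32L, 32L, 3L))
  x <- random_batch(2, c(32L, 32L, 3L))
  d <- deeper_descriptor(m, x[, , , c(1, 1), drop = FALSE])
  expect_identical(dim(d), c(2L, 2592L))   # 32 channels * 81
  expect_identical(d[1, ], d[2, ])
  # zero image, zero biases: zero activations hence zero descriptor
  z <- array(0, c(32, 32, 3, 1))
  expect_true(all(deeper_descriptor(m, z) == 0))
})

test_that("cosine distance hits its geometric anchors", {
  a <- c(1, 2, 3)
  expect_equal(cosine_distance(a, a), 0)
  expect_equal(cosine_distance(a, -a), 2)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(c(0, 0), c(1, 1)), 1)  # zero-vector rule
  expect_error(cosine_distance(c(1, 2), c(1, 2, 3)), "length")
})

test_that("FULLY space has the right shape, range and coincidence value", {
  ds <- tiny_dataset(2, 5, 16, 0.05, seed = 1)
  spec <- backbone_spec(list(conv_layer(4L), relu_layer(), pool_layer(),
                             conv_layer(8L), relu_layer(), pool_layer(),
                             fc_layer(16L)), tap_layer = "conv2")
  m <- build_model(spec, seed = 2, input_shape = c(16L, 16L, 3L))
  p <- compute_prototypes(ds, 4, seed = 0)
  dm <- build_space_fully(m, ds, p)
  expect_s3_class(dm, "dissimilarity_matrix")
  expect_identical(dim(dm$values), c(10L, 4L))
  expect_true(all(dm$values > 0 & dm$values < 1))

  # a sample identical to a prototype scores sigmoid(head bias)
  fake <- ds
  fake$images[, , , 1] <- p$prototypes[, , , 2]
  dm2 <- build_space_fully(m, fake, p)
  expect_equal(dm2$values[1, 2],
               1 / (1 + exp(-m$params[["head.b"]])), tolerance = 1e-12)

  # matrix agrees with pair_dissimilarity entry by entry
  expect_equal(dm$values[3, 1],
               pair_dissimilarity(m, ds$images[, , , 3, drop = FALSE],
                                  p$prototypes[, , , 1, drop = FALSE]),
               tolerance = 1e-12)
})

test_that("FULLY rows permute with the dataset order", {
  ds <- tiny_dataset(2, 4, 16, 0.05, seed = 5)
  spec <- backbone_spec(list(conv_layer(2L), relu_layer(), pool_layer(),
                             fc_layer(8L)), tap_layer = "conv1")
  m <- build_model(spec, seed = 1, input_shape = c(16L, 16L, 3L))
  p <- compute_prototypes(ds, 2, seed = 0)
  dm <- build_space_fully(m, ds, p)
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  dmp <- build_space_fully(m, subset_dataset(ds, perm), p)
  expect_equal(unname(dmp$values), unname(dm$values[perm, ]),
               tolerance = 1e-12)
})

test_that("DEEPER space is a cosine-distance matrix with zero self-distance", {
  ds <- tiny_dataset(2, 5, 16, 0.05, seed = 3)
  spec <- backbone_spec(list(conv_layer(4L), relu_layer(), pool_layer(),
                             fc_layer(8L)), tap_layer = "conv1")
  m <- build_model(spec, seed = 4, input_shape = c(16L, 16L, 3L))
  p <- compute_prototypes(ds, 3, seed = 0)
  dm <- build_space_deeper(m, ds, p)
  expect_identical(dim(dm$values), c(10L, 3L))
  expect_true(all(dm$values >= 0 & dm$values <= 2))

  fake <- ds
  fake$images[, , , 4] <- p$prototypes[, , , 3]
  dm2 <- build_space_deeper(m, fake, p)
  expect_lt(dm2$values[4, 3], 1e-10)

  # entries match direct descriptor cosine distances
  d_s <- deeper_descriptor(m, ds)
  d_p <- deeper_descriptor(m, p$prototypes)
  expect_equal(dm$values[2, 1], cosine_distance(d_s[2, ], d_p[1, ]),
               tolerance = 1e-12)
})

test_that("dissimilarity CSV export keeps ids and values", {
  ds <- tiny_dataset(2, 3, 16, 0.05, seed = 6)
  spec <- backbone_spec(list(conv_layer(2L), relu_layer(), pool_layer(),
                             fc_layer(4L)), tap_layer = "conv1")
  m <- build_model(spec, seed = 1, input_shape = c(16L, 16L, 3L))
  p <- compute_prototypes(ds, 2, seed = 0)
  dm <- build_space_fully(m, ds, p)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dissimilarity_csv(dm, path)
  back <- utils::read.csv(path)
  expect_identical(back$sample_id, ds$ids)
  expect_equal(as.matrix(back[, -1]), unname(dm$values), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("trained DEEPER spaces separate noise-free classes", {
  # weak separation: most samples are closer (cosine) to their own class
  # prototype than to the other after brief training
  ds <- generate_toy_dataset(2, 12, 16, 0.0, seed = 9)
  spec <- backbone_spec(list(conv_layer(4L), relu_layer(), pool_layer(),
                             conv_layer(8L), relu_layer(), pool_layer(),
                             fc_layer(16L)), tap_layer = "conv2")
  m <- build_model(spec, seed = 3, input_shape = c(16L, 16L, 3L))
  m <- train_siamese(m, ds, "cross", "adam", iterations = 30,
                     batch_size = 8, lr = 1e-3, seed = 1)
  p <- compute_prototypes(ds, 2, seed = 0)
  # map prototype -> class via pixel distance (noise-free: exact)
  proto_class <- sapply(1:2, function(j) {
    d0 <- sum((p$prototypes[, , , j] - ds$images[, , , 1])^2)
    d1 <- sum((p$prototypes[, , , j] - ds$images[, , , 24])^2)
    if (d0 < d1) 0L else 1L
  })
  expect_setequal(proto_class, 0:1)
  dm <- build_space_deeper(m, ds, p)
  own <- dm$values[cbind(seq_len(24), match(ds$labels, proto_class))]
  other <- dm$values[cbind(seq_len(24), match(1L - ds$labels, proto_class))]
  expect_gte(mean(own <= other), 0.95)
})
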