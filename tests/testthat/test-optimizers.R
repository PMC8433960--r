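test_that("first Adam step matches the hand-evaluated recurrence", {
  st <- optimizer_state("adam", lr = 0.1)
  res <- adam_step(st, list(p = 1), list(p = 0))
  # m1 = 0.1, u1 = 0.01, mhat = 1, uhat = 1, theta = -0.1/(1 + 1e-8)
  expect_equal(res$state$m$p, 0.1, tolerance = 1e-15)
  expect_equal(res$state$u$p, 0.01, tolerance = 1e-15)
  expect_equal(res$params$p, -0.1 / (1 + 1e-8), tolerance = 1e-15)
  # bias correction makes the first-step size ~lr regardless of |g|
  # exact first-step size is lr * |g| / (|g| + eps) ~ lr for |g| >> eps
  for (g in c(1e-4, 1, 250)) {
    r <- adam_step(optimizer_state("adam", lr = 0.1), list(p = g), list(p = 0))
    expect_equal(abs(r$params$p), 0.1 * g / (g + 1e-8), tolerance = 1e-12)
    expect_equal(abs(r$params$p), 0.1, tolerance = 1e-3)
  }
})

test_that("zero gradients never move parameters", {
  st <- optimizer_state("adam", lr = 0.1)
  par <- list(p = c(1, -2, 3))
  for (i in 1:5) {
    res <- adam_step(st, list(p = c(0, 0, 0)), par)
    st <- res$state; par <- res$params
  }
  expect_identical(par$p, c(1, -2, 3))
})

test_that("Adam matches an independent reference over 100 random steps", {
  withr::with_seed(8, {
    grads <- lapply(1:100, function(i) stats::rnorm(7))
    theta0 <- stats::rnorm(7)
  })
  ref <- reference_adam(grads, theta0, lr = 0.01)
  st <- optimizer_state("adam", lr = 0.01)
  par <- list(p = theta0)
  for (t in 1:100) {
    res <- adam_step(st, list(p = grads[[t]]), par)
    st <- res$state; par <- res$params
    expect_equal(par$p, ref[[t]], tolerance = 1e-12)
  }
})

test_that("DGrad modulation obeys its bounds and degenerate rules", {
  st <- optimizer_state("dgrad")
  # with avg_0 = 0 and g in {0,1}, g^2 tracking keeps avg below g, so the
  # maximal component reaches Sig(4); zero components sit at exactly 0.5
  g <- c(0, 1, 0.3)
  md <- dgrad_modulation(st, list(p = g))
  expect_true(all(md$xi$p >= 0.5 & md$xi$p <= 1 / (1 + exp(-4))))
  expect_equal(md$xi$p[1], 0.5)                      # dag = 0 there
  expect_equal(md$xi$p[2], 1 / (1 + exp(-4)), tolerance = 1e-12)
  # all-zero deviation tensor: 0/0 defined as 0 -> Sig(0) = 0.5 everywhere
  md0 <- dgrad_modulation(optimizer_state("dgrad"), list(p = c(0, 0)))
  expect_identical(md0$xi$p, c(0.5, 0.5))
})

test_that("DGrad reduces to half or all of the Adam step", {
  withr::with_seed(2, g <- stats::rnorm(5))
  par <- list(p = rep(0, 5))
  # force xi = 1: identical to Adam bit for bit over 100 random steps
  st_a <- optimizer_state("adam", lr = 0.01)
  st_d <- optimizer_state("dgrad", lr = 0.01)
  pa <- par; pd <- par
  withr::with_seed(4, gs <- lapply(1:100, function(i) stats::rnorm(5)))
  for (t in 1:100) {
    ra <- adam_step(st_a, list(p = gs[[t]]), pa)
    rd <- dgrad_step(st_d, list(p = gs[[t]]), pd,
                     xi_override = list(p = rep(1, 5)))
    st_a <- ra$state; pa <- ra$params
    st_d <- rd$state; pd <- rd$params
    expect_identical(pa$p, pd$p)
  }
  # g == avg exactly: xi = 0.5, step is exactly half the Adam step.
  # With g = 1 and avg seeded at 1, the squared-gradient average stays 1.
  st1 <- optimizer_state("adam", lr = 0.01)
  st2 <- optimizer_state("dgrad", lr = 0.01)
  st2$avg$p <- rep(1, 3)
  g1 <- list(p = rep(1, 3))
  ra <- adam_step(st1, g1, list(p = rep(0, 3)))
  rd <- dgrad_step(st2, g1, list(p = rep(0, 3)))
  expect_equal(rd$params$p, ra$params$p / 2, tolerance = 1e-15)
})

test_that("DGrad steps never exceed Adam steps component-wise", {
  m <- tiny_model(seed = 1)
  ds <- generate_toy_dataset(2, 4, 8, 0.1, seed = 1)
  b <- sample_pairs(ds, 8, 0.5, seed = 0)
  lg <- siamdiss:::pair_loss_grads(
    m, ds$images[, , , b$first, drop = FALSE],
    ds$images[, , , b$second, drop = FALSE], b$target)
  adam <- adam_step(optimizer_state("adam", lr = 0.01), lg$grads, m$params)
  dgrad <- dgrad_step(optimizer_state("dgrad", lr = 0.01), lg$grads, m$params)
  for (nm in names(lg$grads)) {
    da <- abs(adam$params[[nm]] - m$params[[nm]])
    dd <- abs(dgrad$params[[nm]] - m$params[[nm]])
    expect_true(all(dd <= da + 1e-15))
  }
})

test_that("impulse and global decay evaluate to their printed values", {
  expect_equal(impulse(0, 10), 1)
  expect_equal(impulse(10, 10), 1)
  expect_equal(impulse(30, 10), 1)
  expect_equal(impulse(5, 10), exp(-1), tolerance = 1e-12)
  expect_equal(impulse(9, 10), exp(-3.24), tolerance = 1e-12)
  expect_error(impulse(5, 0), "s must be")

  expect_equal(global_decay(750, 0.25, 3000), 1)
  expect_equal(global_decay(0, 0.25, 3000), exp(-0.125), tolerance = 1e-12)
  expect_equal(global_decay(3000, 0.25, 3000), exp(-1.125), tolerance = 1e-12)
  expect_error(global_decay(5, 0.25, 0), "niter")
})

test_that("impulse has period exactly s over a 100-step scan", {
  t <- 0:100
  expect_equal(impulse(t, 10), impulse(t + 10, 10), tolerance = 1e-15)
  expect_true(all(impulse(t, 10) > 0 & impulse(t, 10) <= 1))
})

test_that("DecayDGrad equals DGrad at the schedule peak and never exceeds it", {
  g <- list(p = c(0.5, -1, 2))
  par <- list(p = rep(0, 3))
  # schedule peak: t multiple of s AND t = c*niter -> imp*d = 1
  st_dd <- optimizer_state("decaydgrad", lr = 0.01, s = 10L, c = 0.25,
                           niter = 40L)
  st_d <- optimizer_state("dgrad", lr = 0.01)
  # advance both to t = 9 with identical gradients, compare step 10
  gs <- lapply(1:9, function(i) list(p = c(0.1, 0.2, -0.1) * i))
  pdd <- par; pd <- par
  for (t in 1:9) {
    rdd <- decaydgrad_step(st_dd, gs[[t]], pdd); st_dd <- rdd$state; pdd <- rdd$params
    rd <- dgrad_step(st_d, gs[[t]], pd); st_d <- rd$state; pd <- rd$params
  }
  rdd <- decaydgrad_step(st_dd, g, pdd)
  rd <- dgrad_step(st_d, g, pd)
  # at t = 10 = 0.25*40: imp = d = 1, so the parameter *changes* agree
  expect_equal(rdd$params$p - pdd$p, rd$params$p - pd$p, tolerance = 1e-12)

  # at any t the DecayDGrad change is <= the DGrad change component-wise
  st1 <- optimizer_state("decaydgrad", lr = 0.01, niter = 3000L)
  st2 <- optimizer_state("dgrad", lr = 0.01)
  p1 <- par; p2 <- par
  withr::with_seed(6, gs <- lapply(1:25, function(i) list(p = stats::rnorm(3))))
  for (t in 1:25) {
    r1 <- decaydgrad_step(st1, gs[[t]], p1)
    r2 <- dgrad_step(st2, gs[[t]], p2)
    expect_true(all(abs(r1$params$p - p1$p) <= abs(r2$params$p - p2$p) + 1e-15))
    st1 <- r1$state; p1 <- r1$params
    st2 <- r2$state; p2 <- r2$params
  }
})

test_that("the combined scale multiplies the three evaluated factors", {
  # direct evaluation at t = 5, s = 10, c = 0.25, niter = 3000 for the
  # maximal-deviation component: Sig(4) * e^-1 * e^(-2*745^2/3000^2)
  expected <- (1 / (1 + exp(-4))) * exp(-1) * exp(-2 * 745^2 / 3000^2)
  got <- (1 / (1 + exp(-4))) * impulse(5, 10) * global_decay(5, 0.25, 3000)
  expect_equal(got, expected, tolerance = 1e-12)
  expect_equal(expected, 0.319, tolerance = 2e-3)
})

test_that("non-finite gradients are rejected with the parameter name", {
  st <- optimizer_state("adam")
  expect_error(adam_step(st, list(conv1.W = c(1, NaN)), list(conv1.W = c(0, 0))),
               "conv1.W")
})
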