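test_that("divergence closed forms: identity and constant denoisers", {
  set.seed(1)
  y <- matrix(runif(64, 0, 1), 8, 8)
  sig2 <- matrix(runif(64, 0.01, 0.1), 8, 8)
  # identity with Rademacher probes: b_d^2 = 1, so the estimate is sum(sigma^2)
  d <- mc_divergence(identity, y, sig2, sure_config(probe_seed = 3L))
  expect_equal(d, sum(sig2), tolerance = 1e-10)
  # constant denoiser: f(y + eps b) = f(y)
  d <- mc_divergence(function(z) matrix(0.5, 8, 8), y, sig2,
                     sure_config(probe_seed = 3L))
  expect_equal(d, 0)
})

test_that("analytic linear-denoiser divergence matches coordinate-wise finite differences", {
  expect_equal(analytic_divergence_linear(diag(5), rep(1, 5)), 5)
  expect_equal(analytic_divergence_linear(matrix(0, 4, 4), runif(4)), 0)
  expect_error(analytic_divergence_linear(matrix(0, 3, 4), rep(1, 3)),
               "square")
  expect_error(analytic_divergence_linear(diag(3), rep(1, 4)), "length")

  set.seed(7)
  D <- 64
  A <- matrix(rnorm(D * D), D, D) / D
  sig2 <- runif(D, 0.01, 0.2)
  y <- rnorm(D)
  h <- 1e-6
  fd <- vapply(seq_len(D), function(d) {
    e <- numeric(D); e[d] <- h
    g <- sig2 * (A %*% (y + e) - A %*% (y - e)) / (2 * h)
    g[d]
  }, numeric(1))
  expect_equal(analytic_divergence_linear(A, sig2), sum(fd),
               tolerance = 1e-6)
})

test_that("Monte-Carlo divergence is unbiased for a random linear operator", {
  set.seed(11)
  D <- 16 * 16
  A <- matrix(rnorm(D * D), D, D) / D
  sig2m <- matrix(runif(D, 0.02, 0.2), 16, 16)
  y <- matrix(rnorm(D), 16, 16)
  f <- function(z) matrix(A %*% c(z), 16, 16)
  n <- 3000
  ests <- vapply(seq_len(n), function(k)
    mc_divergence(f, y, sig2m, sure_config()), numeric(1))
  exact <- analytic_divergence_linear(A, c(sig2m))
  se <- sd(ests) / sqrt(n)
  expect_lt(abs(mean(ests) - exact), 3 * se)
})

test_that("Gaussian and Rademacher probes agree in expectation", {
  set.seed(13)
  D <- 100
  A <- matrix(rnorm(D * D), D, D) / D
  sig2m <- matrix(runif(D, 0.02, 0.2), 10, 10)
  y <- matrix(rnorm(D), 10, 10)
  f <- function(z) matrix(A %*% c(z), 10, 10)
  n <- 3000
  er <- vapply(seq_len(n), function(k)
    mc_divergence(f, y, sig2m, sure_config(probe = "rademacher")), numeric(1))
  eg <- vapply(seq_len(n), function(k)
    mc_divergence(f, y, sig2m, sure_config(probe = "gaussian")), numeric(1))
  se <- sqrt(var(er) / n + var(eg) / n)
  expect_lt(abs(mean(er) - mean(eg)), 3 * se)
})

test_that("the estimator is epsilon-independent for linear denoisers", {
  set.seed(17)
  D <- 36
  A <- matrix(rnorm(D * D), D, D) / D
  sig2m <- matrix(runif(D, 0.05, 0.1), 6, 6)
  y <- matrix(rnorm(D), 6, 6)
  f <- function(z) matrix(A %*% c(z), 6, 6)
  d1 <- mc_divergence(f, y, sig2m, sure_config(epsilon = 1e-2,
                                               probe_seed = 5L))
  d2 <- mc_divergence(f, y, sig2m, sure_config(epsilon = 5e-3,
                                               probe_seed = 5L))
  expect_equal(d1, d2, tolerance = 1e-6)
})

test_that("SURE closed forms for identity and constant denoisers", {
  set.seed(19)
  y <- matrix(runif(144, 0.1, 1), 12, 12)
  nm <- matrix(runif(144, 0.05, 0.2), 12, 12)
  s <- sure_loss(identity, y, nm, sure_config(include_constant = TRUE))
  expect_equal(s, mean(nm^2), tolerance = 1e-10)

  x <- matrix(runif(144), 12, 12)  # noise-free "observation"
  cden <- function(z) matrix(0.3, 12, 12)
  s <- sure_loss(cden, x, nm, sure_config(include_constant = TRUE,
                                          probe_seed = 2L))
  expect_equal(s, mean((0.3 - x)^2) - mean(nm^2), tolerance = 1e-12)
})

test_that("dropping the constant term shifts SURE by exactly mean(sigma^2)", {
  set.seed(23)
  y <- matrix(runif(64), 8, 8)
  nm <- matrix(runif(64, 0.05, 0.2), 8, 8)
  f <- function(z) 0.8 * z
  a <- sure_loss(f, y, nm, sure_config(include_constant = TRUE,
                                       probe_seed = 9L))
  b <- sure_loss(f, y, nm, sure_config(include_constant = FALSE,
                                       probe_seed = 9L))
  expect_equal(b - a, mean(nm^2), tolerance = 1e-12)
})

test_that("SURE estimates the true MSE without bias (Monte-Carlo)", {
  set.seed(29)
  H <- 24
  x <- matrix(0, H, H)
  x[6:18, 6:18] <- 1  # piecewise-constant scene
  nm <- matrix(runif(H * H, 0.05, 0.15), H, H)
  denoisers <- list(identity = identity,
                    shrink = function(z) 0.7 * z,
                    boxcar = function(z) boxcar_filter(z, 3))
  n <- 400
  for (nmf in names(denoisers)) {
    f <- denoisers[[nmf]]
    diffs <- vapply(seq_len(n), function(k) {
      y <- x + matrix(rnorm(H * H), H, H) * nm
      s <- sure_loss(f, y, nm, sure_config(include_constant = TRUE))
      m <- mean((f(y) - x)^2)
      s - m
    }, numeric(1))
    se <- sd(diffs) / sqrt(n)
    expect_lt(abs(mean(diffs)), 3 * se, label = paste("bias z,", nmf))
  }
})

test_that("degenerate noise maps are flagged", {
  y <- matrix(1, 4, 4)
  expect_warning(sure_loss(identity, y, matrix(0, 4, 4)), "all-zero")
  expect_error(sure_loss(identity, y, matrix(-1, 4, 4)), "non-negative")
})
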