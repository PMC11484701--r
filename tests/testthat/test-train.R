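make_preps <- function(n_slices = 2, grid = 16, seed = 1, reps = c(2L, 4L)) {
  lapply(seq_len(n_slices), function(s) {
    p <- generate_phantom(phantom_config(grid_size = grid,
                                         b_values = c(50, 1000),
                                         n_directions = 3L,
                                         n_repetitions = reps,
                                         seed = seed * 100 + s))
    preprocess_stack(p$stack, kernel = 5, blur_sigma = 2)
  })
}

test_that("SURE dataset construction counts, scales and passes channels through", {
  preps <- make_preps(n_slices = 10)
  ds <- make_sure_dataset(preps, repetition_fraction = 1)
  expect_length(ds, 30)  # 3 directions x 10 slices

  # guidance is the preprocessed low-b average, bit for bit
  expect_identical(ds[[1]]$guidance, preps[[1]]$by_b[[1]][[1]]$avg)
  expect_equal(ds[[1]]$target, preps[[1]]$by_b[[2]][[1]]$avg,
               ignore_attr = TRUE)

  # fraction = 0.5 with N = 12: average of 6 repetitions, sigma / sqrt(6)
  preps12 <- make_preps(n_slices = 1, reps = c(2L, 12L))
  ds6 <- make_sure_dataset(preps12, repetition_fraction = 0.5)
  expect_identical(ds6[[1]]$n_used, 6)
  el <- preps12[[1]]$by_b[[2]][[1]]
  expect_equal(ds6[[1]]$target,
               average_repetitions(el$reps[, , 1:6]), ignore_attr = TRUE)
  expect_equal(ds6[[1]]$sigma, el$sigma_rep / sqrt(6))
  # halving the repetitions doubles the noise variance of the average
  ds12 <- make_sure_dataset(preps12, repetition_fraction = 1)
  expect_equal(mean(ds6[[1]]$sigma^2) / mean(ds12[[1]]$sigma^2), 2,
               tolerance = 1e-12)
})

test_that("Noise2Noise and Half2Full splits follow the parity protocol", {
  preps12 <- make_preps(n_slices = 1, reps = c(2L, 12L))
  el <- preps12[[1]]$by_b[[2]][[1]]
  n2n <- dwisure:::make_split_dataset(preps12, "noise2noise")
  expect_equal(n2n[[1]]$target,
               average_repetitions(el$reps[, , seq(1, 11, 2)]),
               ignore_attr = TRUE)
  expect_equal(n2n[[1]]$reference,
               average_repetitions(el$reps[, , seq(2, 12, 2)]),
               ignore_attr = TRUE)
  h2f <- dwisure:::make_split_dataset(preps12, "half2full")
  expect_equal(h2f[[1]]$reference, el$avg, ignore_attr = TRUE)
  expect_identical(h2f[[1]]$n_used, 6L)
})

test_that("training is reproducible given the seed", {
  preps <- make_preps(n_slices = 2)
  ctrl <- train_control(learning_rate = 1e-3, batch_size = 2, max_epochs = 3,
                        patience = 3, seed = 5)
  cfg <- denoiser_config("dncnn", depth = 3, width = 4)
  f1 <- fit_denoiser(preps, "sure", cfg, ctrl)
  f2 <- fit_denoiser(preps, "sure", cfg, ctrl)
  expect_identical(f1$history, f2$history)
  expect_identical(coef(f1), coef(f2))
  f3 <- fit_denoiser(preps, "sure", cfg,
                     train_control(learning_rate = 1e-3, batch_size = 2,
                                   max_epochs = 3, patience = 3, seed = 6))
  expect_false(identical(f1$history$train, f3$history$train))
})

test_that("with a near-zero noise map SURE training keeps outputs close to inputs", {
  slices <- lapply(1:2, function(s)
    generate_phantom(phantom_config(grid_size = 16L, b_values = c(50, 1000),
                                    n_directions = 2L,
                                    n_repetitions = c(2L, 3L),
                                    sigma_profile = list(type = "radial",
                                                         min = 1e-7,
                                                         max = 2e-7),
                                    seed = 70 + s)))
  preps <- lapply(slices, function(sl)
    preprocess_stack(sl$stack, kernel = 5, blur_sigma = 0))
  fit <- fit_denoiser(preps, "sure", denoiser_config("dncnn", depth = 3,
                                                     width = 4),
                      train_control(learning_rate = 1e-3, batch_size = 2,
                                    max_epochs = 8, patience = 8, seed = 1))
  den <- denoise(fit, preps)
  for (s in 1:2) for (d in 1:2) {
    rel <- mean(abs(den[[s]]$directions[[d]] - den[[s]]$noisy[[d]])) /
      mean(abs(den[[s]]$noisy[[d]]))
    expect_lt(rel, 0.05)
  }
})

test_that("denoising is equivariant under direction permutation and supports identity weights", {
  preps <- make_preps(n_slices = 1)
  fit <- fit_denoiser(preps, "sure", denoiser_config("dncnn", depth = 3,
                                                     width = 4),
                      train_control(learning_rate = 1e-3, batch_size = 2,
                                    max_epochs = 2, patience = 2, seed = 3))
  den <- denoise(fit, preps)[[1]]
  # permute directions in the prep; outputs permute identically
  perm <- preps[[1]]
  perm$by_b <- lapply(perm$by_b, function(bb) bb[c(2, 3, 1)])
  perm$directions <- perm$directions[c(2, 3, 1)]
  denp <- denoise(fit, list(perm))[[1]]
  expect_equal(denp$directions[[1]], den$directions[[2]])
  expect_equal(denp$trace, den$trace)

  # zero weights + residual connection: denoise() is the identity
  fit$net$params <- unflatten_params(numeric(count_parameters(fit$net)),
                                     fit$net$params)
  deni <- denoise(fit, preps)[[1]]
  expect_equal(deni$directions[[1]], deni$noisy[[1]], tolerance = 1e-12)
})

test_that("fitted objects expose the standard modelling methods", {
  preps <- make_preps(n_slices = 2)
  fit <- fit_denoiser(preps, "sure", denoiser_config("dncnn", depth = 3,
                                                     width = 4),
                      train_control(learning_rate = 1e-3, batch_size = 2,
                                    max_epochs = 2, patience = 2, seed = 2))
  expect_s3_class(fit, "dwi_denoiser")
  expect_output(print(fit), "strategy: sure")
  expect_type(coef(fit), "double")
  expect_length(coef(fit), count_parameters(fit$net))
  r <- residuals(fit)
  expect_true(all(is.finite(r)))
  pr <- predict(fit)
  expect_length(pr, length(fit$samples))
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
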