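test_that("combined_field is the channel-weighted sum and linear in b", {
  sl <- random_slice(n_channels = 3L, nr = 3L, nc = 3L, seed = 2)
  expect_true(all(combined_field(sl$fields, rep(0 + 0i, 3)) == 0))
  one <- combined_field(sl$fields[1, , , drop = FALSE] |>
                          array(dim = c(1, 3, 3)), 1 + 0i)
  expect_equal(one, matrix(sl$fields[1, , ], 3, 3))
  set.seed(4)
  b1 <- complex(real = rnorm(3), imaginary = rnorm(3))
  b2 <- complex(real = rnorm(3), imaginary = rnorm(3))
  expect_equal(combined_field(sl$fields, b1 + b2),
               combined_field(sl$fields, b1) + combined_field(sl$fields, b2),
               tolerance = 1e-14)
  expect_error(combined_field(sl$fields, b1[1:2]), "channels")
})

test_that("mls_objective matches trivial cases and a plain-R evaluation", {
  sl <- perfect_recovery_slice(n_channels = 4L, nr = 5L, nc = 4L, seed = 3)
  expect_lt(mls_objective(sl$fields, sl$b_star, sl$mask, lambda_reg = 0),
            1e-18)
  # zero weights, unit target: each in-mask voxel contributes exactly 1
  expect_equal(mls_objective(sl$fields, rep(0 + 0i, 4), sl$mask,
                             lambda_reg = 0), sum(sl$mask))
  rnd <- random_slice(3L, 3L, 4L, seed = 6)
  set.seed(8)
  b <- complex(real = rnorm(3), imaginary = rnorm(3))
  m <- matrix(runif(12, 0.5, 1.5), 3, 4)
  expect_equal(mls_objective(rnd$fields, b, rnd$mask, m, lambda_reg = 0.3),
               objective_by_hand(rnd$fields, b, rnd$mask, m, 0.3),
               tolerance = 1e-12)
  expect_error(mls_objective(rnd$fields, b, matrix(FALSE, 3, 4)),
               "no in-region")
})

test_that("rmse_percent has the right anchors and a hand-computed value", {
  sl <- perfect_recovery_slice(seed = 5)
  expect_equal(rmse_percent(sl$fields, sl$b_star, sl$mask), 0,
               tolerance = 1e-9)
  expect_equal(rmse_percent(sl$fields, rep(0 + 0i, 8), sl$mask), 100)
  # 1 channel, 3 voxels with magnitudes 0.5 / 1.0 / 1.5 against target 1:
  # RMSE = 100 * sqrt((0.25 + 0 + 0.25)/3) = 100 * sqrt(1/6)
  fields <- array(c(0.5 + 0i, 1 + 0i, 1.5 + 0i), c(1, 3, 1))
  expect_equal(rmse_percent(fields, 1 + 0i, matrix(TRUE, 3, 1)),
               100 * sqrt(1 / 6))
})

test_that("quadrature weights step by -360/n degrees with unit magnitude", {
  q <- quadrature_weights(8)
  expect_equal(Mod(q), rep(1, 8))
  expect_equal(Arg(q)[1:3], c(0, -pi / 4, -pi / 2))
  expect_equal(quadrature_weights(1), 1 + 0i)
  expect_equal(sum(Mod(q)^2), 8)
})

test_that("random initial weights are reproducible, bounded and phase-uniform", {
  set.seed(11); w1 <- random_init_weights(8)
  set.seed(11); w2 <- random_init_weights(8)
  expect_identical(w1, w2)
  set.seed(12)
  draws <- replicate(1250, random_init_weights(8))
  mags <- Mod(draws)
  expect_true(all(mags > 0 & mags <= 1))
  phases <- (Arg(draws) %% (2 * pi))
  counts <- table(cut(phases, breaks = seq(0, 2 * pi, length.out = 37)))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("objective and RMSE are invariant under a global weight phase", {
  sl <- random_slice(4L, 3L, 5L, seed = 13)
  set.seed(14)
  b <- complex(real = rnorm(4), imaginary = rnorm(4))
  for (theta in c(0.3, 1.7, 4.4)) {
    rot <- b * exp(1i * theta)
    expect_equal(mls_objective(sl$fields, rot, sl$mask, lambda_reg = 0.2),
                 mls_objective(sl$fields, b, sl$mask, lambda_reg = 0.2),
                 tolerance = 1e-12)
    expect_equal(rmse_percent(sl$fields, rot, sl$mask),
                 rmse_percent(sl$fields, b, sl$mask), tolerance = 1e-12)
  }
})

test_that("adam_shim recovers an exactly achievable target", {
  sl <- perfect_recovery_slice(seed = 21)
  res <- adam_shim(sl$fields, sl$mask,
                   config = shim_config(lambda_reg = 0, n_restarts = 20,
                                        max_iters = 1500, seed = 22,
                                        include_quadrature_start = FALSE))
  expect_lt(res$rmse_percent, 0.5)
  # stored RMSE is consistent with recomputation from the weights
  expect_equal(res$rmse_percent,
               rmse_percent(sl$fields, res$weights, sl$mask),
               tolerance = 1e-9)
})

test_that("both optimizers match the exhaustive 2-channel oracle", {
  sl <- random_slice(2L, 2L, 3L, seed = 31)
  oracle <- grid_search_shim(sl$fields, sl$mask, lambda_reg = 0)
  adam <- adam_shim(sl$fields, sl$mask,
                    config = shim_config(lambda_reg = 0, n_restarts = 30,
                                         seed = 32))
  ve <- mls_variable_exchange(sl$fields, sl$mask, lambda_reg = 0,
                              max_outer = 100, n_restarts = 10, seed = 33)
  expect_lt(abs(adam$objective - oracle$objective) / oracle$objective, 0.01)
  expect_lt(abs(ve$objective - oracle$objective) / oracle$objective, 0.02)
  # multi-start never does worse than the deterministic single start
  single <- mls_variable_exchange(sl$fields, sl$mask, lambda_reg = 0)
  expect_lte(ve$objective, single$objective + 1e-12)
})

test_that("one-channel magnitude fitting reaches the closed-form optimum", {
  sl <- random_slice(1L, 2L, 3L, seed = 41)
  a <- Mod(as.vector(sl$fields[1, , ]))
  s_opt <- sum(a) / sum(a^2)          # argmin_s sum (s*a - 1)^2
  ve <- mls_variable_exchange(sl$fields, sl$mask, lambda_reg = 0)
  expect_equal(Mod(ve$weights), s_opt, tolerance = 1e-8)
  expect_lte(ve$iterations_used, 2L)
  oracle <- grid_search_shim(sl$fields, sl$mask, lambda_reg = 0,
                             mag_max = 2, mag_step = 0.001)
  expect_lt(abs(ve$objective - oracle$objective) / oracle$objective, 1e-3)
})

test_that("variable exchange decreases the objective monotonically", {
  sl <- random_slice(4L, 4L, 4L, seed = 51)
  objs <- numeric(0)
  b <- quadrature_weights(4)
  for (k in 1:8) {
    res <- mls_variable_exchange(sl$fields, sl$mask, lambda_reg = 0.1,
                                 max_outer = k, tolerance = 0,
                                 b_init = b)
    objs <- c(objs, res$objective)
  }
  expect_true(all(diff(objs) <= 1e-10))
})

test_that("best-of-k restart objective is non-increasing in k", {
  sl <- random_slice(3L, 3L, 4L, seed = 61)
  objs <- vapply(1:6, function(k) {
    adam_shim(sl$fields, sl$mask,
              config = shim_config(lambda_reg = 0, n_restarts = k,
                                   max_iters = 120, seed = 62,
                                   include_quadrature_start = FALSE))$objective
  }, numeric(1))
  expect_true(all(diff(objs) <= 1e-12))
})

test_that("the residual error term grows with the regularization weight", {
  sl <- random_slice(3L, 4L, 4L, seed = 71)
  err_term <- vapply(c(0, 0.3, 1, 5, 20), function(lam) {
    res <- mls_variable_exchange(sl$fields, sl$mask, lambda_reg = lam)
    mls_objective(sl$fields, res$weights, sl$mask, lambda_reg = 0)
  }, numeric(1))
  expect_true(all(diff(err_term) >= -1e-9))
})

test_that("optimal RMSE is invariant to a joint field/target rescaling", {
  sl <- random_slice(3L, 3L, 4L, seed = 81)
  s <- 3.7
  r1 <- mls_variable_exchange(sl$fields, sl$mask, m = 1, lambda_reg = 0)
  r2 <- mls_variable_exchange(sl$fields * s, sl$mask,
                              m = matrix(s, 3, 4), lambda_reg = 0)
  expect_equal(r1$rmse_percent, r2$rmse_percent, tolerance = 1e-8)
})

test_that("adam result never falls behind the quadrature baseline", {
  vol <- small_volume(grid = 32, n_slices = 2, seed = 91)
  for (i in 1:2) {
    sl <- get_slice(vol, i)
    res <- adam_shim(sl$fields, sl$mask,
                     config = shim_config(n_restarts = 3, max_iters = 150,
                                          seed = 92))
    quad <- rmse_percent(sl$fields, quadrature_weights(8), sl$mask)
    expect_lte(res$rmse_percent, quad)
  }
})

test_that("shim_volume flags failing slices instead of aborting", {
  vol <- small_volume(grid = 32, n_slices = 2, seed = 95)
  vol$mask[, , 2] <- FALSE
  tab <- shim_volume(vol, method = "quadrature")
  expect_equal(nrow(tab), 2L)
  expect_true(tab$ok[1])
  expect_false(tab$ok[2])
  expect_match(tab$message[2], "no in-region")
  expect_s3_class(attr(tab, "results")[[1]], "shim_result")
})
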