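make_examples_fixture <- function(n_volumes = 2L, n_slices = 3L,
                                  n_rotations = 2L, grid = 32L,
                                  seed = 17L, restarts = 2L) {
  fs <- asNamespace("fastshim")
  vols <- fs$simulate_volumes(n_volumes, n_slices, n_rotations,
                              c(grid, grid), 8L, 0.02, 0.1, seed)
  cfg <- shim_config(n_restarts = restarts, max_iters = 100, seed = seed)
  refs <- lapply(vols, shim_volume, method = "adam", config = cfg)
  build_examples(vols, refs)
}

test_that("input encoding produces the documented planes and round-trips", {
  sl <- random_slice(8L, 6L, 5L, seed = 2)
  e16 <- encode_input(sl$fields, "realimag16")
  expect_equal(dim(e16), c(16L, 6L, 5L))
  e32 <- encode_input(sl$fields, "magphase32")
  expect_equal(dim(e32), c(32L, 6L, 5L))
  # lossless: the real/imag planes reconstruct the complex field exactly
  rebuilt <- array(complex(real = e16[1:8, , ], imaginary = e16[9:16, , ]),
                   c(8, 6, 5))
  expect_identical(rebuilt, sl$fields)
  # phase planes are wrapped to (-pi, pi]
  expect_true(all(e32[25:32, , ] > -pi & e32[25:32, , ] <= pi))
  expect_error(encode_input(sl$fields, "other"), "arg")
})

test_that("weight decoding pairs entries and ignores surplus dimensions", {
  expect_equal(decode_weights(rep(c(1, 0), 8), 8), rep(1 + 0i, 8))
  expect_equal(decode_weights(rep(0, 16), 8), rep(0 + 0i, 8))
  set.seed(3)
  b <- complex(real = rnorm(8), imaginary = rnorm(8))
  vec <- as.vector(rbind(Re(b), Im(b)))
  expect_equal(decode_weights(vec, 8), b)
  expect_equal(decode_weights(c(vec, rnorm(16)), 8), b)  # 32-wide head
  expect_error(decode_weights(rep(0, 7), 8), "decode")
})

test_that("source-slice splitting is exhaustive, disjoint and leak-free", {
  ex <- make_examples_fixture(n_volumes = 2L, n_slices = 5L, n_rotations = 4L)
  expect_length(ex, 40L)
  sp <- split_dataset(ex, c(0.8, 0.1, 0.1), seed = 9)
  all_idx <- sort(c(sp$train, sp$val, sp$test))
  expect_identical(all_idx, seq_along(ex))
  expect_length(intersect(sp$train, sp$test), 0L)
  # 10 source slices at 8:1:1 -> 8/1/1 sources -> 32/4/4 examples
  expect_equal(lengths(sp), c(train = 32L, val = 4L, test = 4L))
  # all rotated copies of one source stay together
  src <- vapply(ex, function(e) e$source_id, character(1))
  for (part in sp)
    expect_length(intersect(unique(src[part]),
                            unique(src[setdiff(seq_along(ex), part)])), 0L)
  expect_identical(split_dataset(ex, c(0.8, 0.1, 0.1), seed = 9), sp)
  expect_error(split_dataset(ex[1:5], seed = 1), "too small")
  expect_error(split_dataset(ex, c(0.5, 0.4, 0.05), seed = 1), "sum to 1")
})

test_that("physics loss matches its arithmetic definition", {
  ex <- make_examples_fixture(n_volumes = 1L, n_slices = 2L,
                              n_rotations = 1L)
  refw <- lapply(ex, `[[`, "weights_ref")
  # predicting the reference weights gives zero loss in both forms
  expect_equal(physics_loss(refw, ex, "eq3_plain"), 0, tolerance = 1e-9)
  expect_equal(physics_loss(refw, ex, "mse"), 0, tolerance = 1e-12)
  # a single slice with RMSE_pred = RMSE_ref + delta
  one <- ex[1]
  worse <- refw[[1]] * 0   # zero weights: RMSE_pred = 100 %
  delta <- 100 - one[[1]]$rmse_ref
  expect_equal(physics_loss(list(worse), one, "eq3_plain"), delta,
               tolerance = 1e-9)
  expect_equal(physics_loss(list(worse), one, "mse"), delta^2,
               tolerance = 1e-6)
})

test_that("physics-loss gradients agree with finite differences", {
  fs <- asNamespace("fastshim")
  ex <- make_examples_fixture(n_volumes = 1L, n_slices = 2L,
                              n_rotations = 1L)
  set.seed(5)
  out <- matrix(rnorm(16 * 2, sd = 0.5), 16, 2)
  terms <- fs$physics_terms(out, ex, 8L)
  eps <- 1e-6
  for (trial in 1:5) {
    i <- sample(16, 1); j <- sample(2, 1)
    op <- out; op[i, j] <- op[i, j] + eps
    om <- out; om[i, j] <- om[i, j] - eps
    fd <- (fs$physics_terms(op, ex, 8L, want_grad = FALSE)$rmse[j] -
             fs$physics_terms(om, ex, 8L, want_grad = FALSE)$rmse[j]) /
      (2 * eps)
    expect_equal(terms$dout[i, j], fd, tolerance = 1e-4)
  }
})

test_that("short training reduces the physics loss on a small fixture", {
  ex <- make_examples_fixture(n_volumes = 2L, n_slices = 4L,
                              n_rotations = 2L, restarts = 3L)
  cfg <- predictor_config(stage_widths = c(4L, 8L), blocks_per_stage = 1L,
                          epochs = 6L, batch_size = 8L, seed = 23)
  model <- train_predictor(ex, cfg)
  expect_s3_class(model, "shim_net")
  expect_equal(nrow(model$history), 6L)
  expect_lt(mean(tail(model$history$train_loss, 2)),
            model$history$train_loss[1])
  # validation RMSE is tracked and the checkpointed epoch is recorded
  expect_true(all(is.finite(model$history$val_rmse)))
  expect_gte(model$best_epoch, 1L)
})

test_that("training and prediction are reproducible from the seed", {
  ex <- make_examples_fixture(n_volumes = 1L, n_slices = 5L,
                              n_rotations = 2L)
  cfg <- predictor_config(stage_widths = c(4L), blocks_per_stage = 1L,
                          epochs = 2L, batch_size = 8L, seed = 31)
  m1 <- train_predictor(ex, cfg)
  m2 <- train_predictor(ex, cfg)
  expect_identical(m1$history, m2$history)
  sl <- get_slice(small_volume(grid = 32, n_slices = 1, seed = 40), 1)
  p1 <- predict(m1, sl$fields, sl$mask)
  p2 <- predict(m1, sl$fields, sl$mask)
  expect_identical(p1$weights, p2$weights)
  expect_s3_class(p1, "shim_result")
  expect_equal(p1$method, "resnet")
  # channel-count mismatch is a shape error
  bad <- array(0i, c(4, 32, 32))
  expect_error(predict(m1, bad, sl$mask), "channels")
})

test_that("the learning-rate schedule decays by steps", {
  ex <- make_examples_fixture(n_volumes = 1L, n_slices = 5L,
                              n_rotations = 2L)
  cfg <- predictor_config(stage_widths = c(4L), blocks_per_stage = 1L,
                          epochs = 4L, lr_period = 2L, lr_decay = 0.5,
                          learning_rate = 1e-3, batch_size = 8L, seed = 3)
  model <- train_predictor(ex, cfg)
  expect_equal(model$history$lr, c(1e-3, 1e-3, 5e-4, 5e-4))
})
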