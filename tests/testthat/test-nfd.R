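fs <- asNamespace("fastshim")

nfd_fixture <- function(grid = 32L, n_slices = 2L, n_rotations = 8L,
                        n_per_class = 10L, seed = 3L,
                        radius_frac = c(0.08, 0.2),
                        depth_range = c(0.5, 1)) {
  vol <- small_volume(grid = grid, n_slices = n_slices, seed = seed,
                      n_rotations = n_rotations)
  tab <- shim_volume(vol, method = "adam",
                     config = shim_config(n_restarts = 3, max_iters = 150,
                                          seed = seed))
  list(volume = vol, table = tab,
       examples = make_nfd_dataset(vol, tab, n_per_class = n_per_class,
                                   rmse_cut = 30, radius_frac = radius_frac,
                                   depth_range = depth_range,
                                   seed = seed + 1))
}

test_that("NFD datasets are balanced and voids strictly raise the error", {
  fx <- nfd_fixture()
  labels <- vapply(fx$examples, function(e) e$label, character(1))
  expect_equal(sum(labels == "uniform"), 10L)
  expect_equal(sum(labels == "nonuniform"), 10L)
  # each non-uniform example pairs with the uniform one built from the
  # same slice; its masked RMSE against the unit target must be larger
  uniform <- fx$examples[labels == "uniform"]
  nonuniform <- fx$examples[labels == "nonuniform"]
  for (j in seq_along(uniform)) {
    u <- uniform[[j]]; v <- nonuniform[[j]]
    expect_identical(u$slice, v$slice)
    rmse_u <- sqrt(mean((u$map[u$mask] - 1)^2))
    rmse_v <- sqrt(mean((v$map[v$mask] - 1)^2))
    expect_gt(rmse_v, rmse_u)
  }
  expect_error(make_nfd_dataset(fx$volume, fx$table, n_per_class = 1000L),
               "need")
})

test_that("a briefly trained NFD separates voids from uniform maps", {
  # pronounced voids: this is a smoke test of the training mechanics,
  # not of borderline sensitivity (that is exercised at larger scale)
  fx <- nfd_fixture(n_slices = 3L, n_rotations = 10L, n_per_class = 24L,
                    radius_frac = c(0.15, 0.3), depth_range = c(0.8, 1))
  cfg <- nfd_config(widths = c(8L, 16L, 32L), epochs = 30L, batch_size = 8L,
                    learning_rate = 2e-3, seed = 5)
  model <- train_nfd(fx$examples, cfg)
  expect_s3_class(model, "nfd_model")
  ev <- evaluate_nfd(model, fx$examples)
  # confusion-matrix conservation and row consistency
  expect_equal(sum(ev$confusion), length(fx$examples))
  expect_equal(as.vector(rowSums(ev$confusion)), c(24, 24))
  expect_equal(as.vector(diag(ev$confusion) / rowSums(ev$confusion)),
               as.vector(ev$accuracy))
  expect_gt(ev$balanced_accuracy, 0.7)
  expect_gt(ev$mean_confidence[["uniform"]],
            ev$mean_confidence[["nonuniform"]])
})

test_that("classification is deterministic and honours the threshold", {
  fx <- nfd_fixture(n_per_class = 8L)
  cfg <- nfd_config(widths = c(4L, 8L), epochs = 2L, batch_size = 8L,
                    seed = 7)
  model <- train_nfd(fx$examples, cfg)
  map <- fx$examples[[1]]$map
  r1 <- nfd_classify(model, map)
  r2 <- nfd_classify(model, map)
  expect_identical(r1$confidence, r2$confidence)
  expect_true(r1$confidence >= 0 && r1$confidence <= 1)
  # threshold 1.0 labels everything non-uniform (confidence < 1 always)
  expect_equal(nfd_classify(model, map, threshold = 1.0 + 1e-9)$predicted_label,
               "nonuniform")
  expect_equal(nfd_classify(model, map, threshold = 0)$predicted_label,
               "uniform")
  expect_error(nfd_classify(model, map[1:10, 1:10]), "shape")
})

test_that("NFD gradients agree with finite differences", {
  set.seed(11)
  model <- build_nfd(nfd_config(widths = c(4L, 8L), local_contrast = FALSE,
                                seed = 11),
                     input_shape = c(16L, 16L))
  x <- array(rnorm(1 * 16 * 16 * 3), c(1, 16, 16, 3))
  fw <- fs$nfd_fwd(model$layers, x, training = TRUE)
  R <- matrix(rnorm(3), 1)
  grads <- fs$nfd_bwd(fw$layers, fw$caches, R)
  flat <- fs$flatten_pars(list(layers = model$layers))
  expect_setequal(names(grads), names(flat))
  loss_at <- function(flat2) {
    ly <- fs$set_pars(list(layers = model$layers), flat2)$layers
    sum(fs$nfd_fwd(ly, x, training = TRUE)$out * R)
  }
  eps <- 1e-5
  set.seed(12)
  for (trial in 1:4) {
    nm <- sample(names(flat), 1)
    j <- sample(length(flat[[nm]]), 1)
    fp <- flat; fp[[nm]][j] <- fp[[nm]][j] + eps
    fm <- flat; fm[[nm]][j] <- fm[[nm]][j] - eps
    fd <- (loss_at(fp) - loss_at(fm)) / (2 * eps)
    expect_equal(grads[[nm]][j], fd, tolerance = 1e-5)
  }
})
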