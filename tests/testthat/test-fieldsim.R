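test_that("single-loop field matches the closed-form on-axis expression", {
  # one coil at 0 degrees; voxels on the row through the grid center lie
  # on the loop axis, so the magnitude must follow a^2/(a^2 + d^2)^(3/2)
  coils <- coil_array_spec(n_channels = 1L, radius = 30, element_size = 8,
                           element_angles = 0, quadrature_phases = 0,
                           wavelength = 50, amplitude = 2.5)
  phantom <- phantom_spec(grid_shape = c(41L, 41L), semi_axes = c(15, 15),
                          noise_level = 0)
  vol <- simulate_channel_fields(coils, phantom, n_slices = 1, seed = 1,
                                 normalize = FALSE)
  sl <- get_slice(vol, 1)
  center_row <- 21L
  cols <- 1:41
  dist <- abs((21 + 30) - cols)          # coil center sits at column cc + radius
  expected <- 2.5 * 8^2 / (8^2 + dist^2)^1.5
  got <- Mod(sl$fields[1, center_row, ])
  expect_equal(got, expected, tolerance = 1e-6)
})

test_that("opposed coils driven out of phase cancel at the center voxel", {
  coils <- coil_array_spec(n_channels = 2L, radius = 20, element_size = 8,
                           element_angles = c(0, 180),
                           quadrature_phases = c(0, 180), wavelength = 50)
  phantom <- phantom_spec(grid_shape = c(41L, 41L), semi_axes = c(15, 15),
                          noise_level = 0)
  vol <- simulate_channel_fields(coils, phantom, 1, seed = 1,
                                 normalize = FALSE)
  comb <- combined_field(get_slice(vol, 1)$fields, c(1 + 0i, 1 + 0i))
  expect_lt(Mod(comb[21, 21]), 1e-12)
})

test_that("simulation is bit-reproducible for identical specs and seed", {
  sp <- default_specs(c(32L, 32L))
  v1 <- simulate_channel_fields(sp$coils, sp$phantom, 3, seed = 42)
  v2 <- simulate_channel_fields(sp$coils, sp$phantom, 3, seed = 42)
  expect_identical(v1$b1, v2$b1)
  expect_identical(v1$mask, v2$mask)
  v3 <- simulate_channel_fields(sp$coils, sp$phantom, 3, seed = 43)
  expect_false(identical(v1$b1, v3$b1))
})

test_that("invalid specs are rejected", {
  expect_error(coil_array_spec(radius = -1), "radius")
  expect_error(coil_array_spec(n_channels = 3, element_angles = c(0, 90)),
               "element_angles")
  expect_error(phantom_spec(grid_shape = c(21, 21), semi_axes = c(50, 10)),
               "fit within")
  expect_error(phantom_spec(density_inside = 0, density_outside = 0),
               "density")
})

test_that("build_mask thresholds density and flags empty masks", {
  expect_true(all(build_mask(matrix(1, 5, 5), 0.5)))
  expect_warning(m <- build_mask(matrix(0, 5, 5), 0.5), "no in-region")
  expect_false(any(m))
  # elliptical phantom: mask area equals the discrete ellipse voxel count
  phantom <- phantom_spec(grid_shape = c(51L, 51L), semi_axes = c(20, 14),
                          noise_level = 0)
  sp <- coil_array_spec(radius = 40, element_size = 10)
  vol <- simulate_channel_fields(sp, phantom, 1, seed = 1)
  expected <- 0L
  for (r in 1:51) for (c in 1:51)
    if (((r - 26) / 20)^2 + ((c - 26) / 14)^2 <= 1)
      expected <- expected + 1L
  expect_identical(sum(vol$mask[, , 1]), expected)
})

test_that("rotation augmentation obeys identity, count and group structure", {
  vol <- small_volume(grid = 32, n_slices = 2, seed = 5)
  expect_identical(augment_rotations(vol, 1L), vol)
  aug <- augment_rotations(vol, 4L)
  expect_equal(n_slices(aug), 8L)
  expect_equal(aug$metadata$rotation_deg, rep(c(0, 90, 180, 270), 2))
  expect_equal(aug$metadata$source_slice, rep(1:2, each = 4))
  # slice 1 at rotation 0 is the original
  expect_identical(aug$b1[, , , 1], vol$b1[, , , 1])

  # rotation group property: a then b equals a + b within interpolation
  g <- Mod(combined_field(get_slice(vol, 1)$fields, quadrature_weights(8)))
  two_step <- rotate_grid(rotate_grid(g, 40), 50)
  one_step <- rotate_grid(g, 90)
  interior <- rotate_grid(vol$mask[, , 1] * 1, 90, "nearest") > 0.5
  interior[c(1:3, 30:32), ] <- FALSE; interior[, c(1:3, 30:32)] <- FALSE
  expect_lt(max(abs(two_step - one_step)[interior]), 0.05)

  # full turn composed in steps returns the original within tolerance
  full <- g
  for (k in 1:4) full <- rotate_grid(full, 90)
  expect_lt(max(abs(full - g)[interior]), 1e-10)
})

test_that("quadrature magnitude of a circular phantom is 45-degree symmetric", {
  coils <- coil_array_spec(radius = 22, element_size = 7, wavelength = 22)
  phantom <- phantom_spec(grid_shape = c(33L, 33L), semi_axes = c(12, 12),
                          noise_level = 0)
  vol <- simulate_channel_fields(coils, phantom, 1, seed = 1)
  sl <- get_slice(vol, 1)
  g <- Mod(combined_field(sl$fields, quadrature_weights(8)))
  rot <- rotate_grid(g, 45)
  interior <- sl$mask
  interior[c(1:4, 29:33), ] <- FALSE; interior[, c(1:4, 29:33)] <- FALSE
  rel <- abs(rot - g)[interior] / mean(g[interior])
  expect_lt(stats::median(rel), 0.02)
  expect_lt(max(rel), 0.2)
})

test_that("void injection suppresses magnitude as specified", {
  vol <- small_volume(grid = 32, n_slices = 1, seed = 9)
  sl <- get_slice(vol, 1)
  map <- Mod(combined_field(sl$fields, quadrature_weights(8)))
  center <- c(16L, 16L)
  expect_identical(inject_nonuniformity(map, sl$mask, radius = 5, depth = 0,
                                        center = center), map)
  one_voxel <- inject_nonuniformity(map, sl$mask, radius = 1, depth = 1,
                                    center = center)
  expect_equal(one_voxel[16, 16], 0)
  changed <- one_voxel != map
  expect_equal(sum(changed), 1)
  expect_true(changed[16, 16])
  expect_error(inject_nonuniformity(map, sl$mask, radius = -2, depth = 1),
               "radius")
  expect_error(inject_nonuniformity(map, sl$mask, radius = 3, depth = 0.5,
                                    center = c(1L, 1L)), "inside the mask")

  # injected map is strictly less uniform than its source
  injected <- inject_nonuniformity(map, sl$mask, radius = 6, depth = 0.8,
                                   center = center)
  rmse_of <- function(g) sqrt(mean((g[sl$mask] - 1)^2)) * 100
  expect_gt(rmse_of(injected), rmse_of(map))
})

test_that("every stored slice keeps a non-empty mask after augmentation", {
  vol <- small_volume(grid = 32, n_slices = 3, seed = 7, n_rotations = 6)
  counts <- apply(vol$mask, 3, sum)
  expect_true(all(counts > 0))
})
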