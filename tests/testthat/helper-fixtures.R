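# Fixture builders shared across the suite.  Everything is generated in
# code; no stored data.

# Random n-channel complex field slice on a small full-mask grid.
random_slice <- function(n_channels = 2L, nr = 2L, nc = 4L, seed = 1L) {
  set.seed(seed)
  v <- n_channels * nr * nc
  fields <- array(complex(real = rnorm(v), imaginary = rnorm(v)),
                  c(n_channels, nr, nc))
  list(fields = fields, mask = matrix(TRUE, nr, nc))
}

# Fields constructed so that a known weight vector b_star reproduces the
# unit target magnitude exactly: channel 1 is solved for so that
# A %*% b_star equals a random unit-modulus complex map.
perfect_recovery_slice <- function(n_channels = 8L, nr = 12L, nc = 12L,
                                   seed = 1L) {
  set.seed(seed)
  V <- nr * nc
  b_star <- complex(modulus = runif(n_channels, 0.5, 1.5),
                    argument = runif(n_channels, 0, 2 * pi))
  target_field <- complex(modulus = 1, argument = runif(V, 0, 2 * pi))
  A <- matrix(complex(real = rnorm(V * n_channels),
                      imaginary = rnorm(V * n_channels)), V, n_channels)
  A[, 1] <- (target_field - A[, -1, drop = FALSE] %*% b_star[-1]) / b_star[1]
  fields <- array(0i, c(n_channels, nr, nc))
  for (ch in seq_len(n_channels)) fields[ch, , ] <- A[, ch]
  list(fields = fields, mask = matrix(TRUE, nr, nc), b_star = b_star)
}

# Small simulated head-like volume for integration-style tests.
small_volume <- function(grid = 48L, n_slices = 2L, seed = 3L,
                         n_rotations = 1L, noise_level = 0.02) {
  sp <- default_specs(c(grid, grid), noise_level = noise_level)
  vol <- simulate_channel_fields(sp$coils, sp$phantom, n_slices, seed = seed)
  if (n_rotations > 1L) vol <- augment_rotations(vol, n_rotations)
  vol
}

# Deterministic brute-force MLS objective evaluation used as a slow
# cross-check of the C++ objective (plain R arithmetic).
objective_by_hand <- function(fields, b, mask, m = 1, lambda = 0) {
  d <- dim(fields)
  total <- lambda * sum(Mod(b)^2)
  for (r in seq_len(d[2])) for (c in seq_len(d[3])) {
    if (!mask[r, c]) next
    f <- sum(fields[, r, c] * b)
    mv <- if (length(m) == 1) m else m[r, c]
    total <- total + (Mod(f) - mv)^2
  }
  total
}
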