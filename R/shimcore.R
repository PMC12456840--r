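# Magnitude least-squares (MLS) RF shimming.
#
# For an in-mask field matrix A (voxels x channels), target magnitude m
# and complex weights b, the shim objective is
#     J(b) = || |A b| - m ||^2_w  +  lambda * ||b||^2 ,
# minimized over b.  Because only |A b| enters, J is invariant under a
# global phase of b; optimization runs over the 2C real parameters
# (Re b, Im b), which is smooth everywhere unlike magnitude/phase.

# Coerce a (C, R, Co) complex field array to the (voxels x channels)
# matrix A, optionally restricted to in-mask voxels.
field_matrix <- function(fields, mask = NULL) {
  d <- dim(fields)
  if (length(d) == 4L && d[4] == 1L) {
    fields <- array(fields, dim = d[1:3]); d <- d[1:3]
  }
  if (length(d) != 3L) stopf("fields must be a (channels, rows, cols) array")
  A <- t(matrix(fields, d[1], d[2] * d[3]))
  if (!is.null(mask)) {
    if (!identical(dim(mask), d[2:3])) stopf("mask shape does not match fields")
    A <- A[as.vector(mask), , drop = FALSE]
  }
  A
}

target_vector <- function(m, mask) {
  n <- sum(mask)
  if (length(m) == 1L) return(rep(as.numeric(m), n))
  if (!identical(dim(m), dim(mask))) stopf("target map shape does not match mask")
  as.numeric(m[mask])
}

check_mask <- function(mask) {
  if (!any(mask)) stopf("region mask has no in-region voxels")
  invisible(TRUE)
}

#' Combined transmit field under a set of shim weights
#'
#' The aggregate B1+ field is the per-voxel sum over channels of
#' `b[c] * field[c]`; linear in the weights.
#'
#' @param fields complex array `(channels, rows, cols)`.
#' @param b complex weight vector, one entry per channel.
#' @return complex matrix `(rows, cols)`.
#' @export
combined_field <- function(fields, b) {
  d <- dim(fields)
  if (length(d) == 4L && d[4] == 1L) {
    fields <- array(fields, dim = d[1:3]); d <- d[1:3]
  }
  if (length(b) != d[1]) stopf("weight length %d does not match %d channels",
                               length(b), d[1])
  v <- as.vector(t(matrix(fields, d[1], d[2] * d[3])) %*% as.complex(b))
  matrix(v, d[2], d[3])
}

#' Magnitude least-squares shim objective
#'
#' `sum_w (| (A b)_v | - m_v)^2 + lambda * sum_c |b_c|^2` over in-mask
#' voxels; non-negative, and exactly invariant under a global phase of
#' `b`.
#'
#' @param fields complex array `(channels, rows, cols)`.
#' @param b complex weight vector.
#' @param mask logical region-of-interest mask.
#' @param m target magnitude: scalar or `(rows, cols)` map. Default 1.
#' @param lambda_reg regularization weight balancing RF power against
#'   excitation error.
#' @return scalar objective value.
#' @export
mls_objective <- function(fields, b, mask, m = 1, lambda_reg = 0) {
  check_mask(mask)
  A <- field_matrix(fields, mask)
  cpp_mls_objective(A, target_vector(m, mask), as.complex(b), lambda_reg)
}

#' Root-mean-square excitation error in percent of target flip angle
#'
#' `100 * sqrt(sum_w (| (A b)_v | - m_v)^2 / N_voxel) / mean_w(m)`,
#' where `N_voxel` is the in-mask voxel count.  With the default unit
#' target this is the RMS deviation of the combined field magnitude
#' from 1, in percent; a zero weight vector scores exactly 100.
#'
#' @inheritParams mls_objective
#' @return RMSE as a percentage of the target flip angle.
#' @export
rmse_percent <- function(fields, b, mask, m = 1) {
  check_mask(mask)
  A <- field_matrix(fields, mask)
  mv <- target_vector(m, mask)
  err <- abs(as.vector(A %*% as.complex(b))) - mv
  100 * sqrt(mean(err^2)) / mean(mv)
}

#' Quadrature (circularly polarized) mode weights
#'
#' Unit-magnitude weights with phases `-k * 360 / n` degrees for
#' channel k, the default drive of an n-channel azimuthal array (45
#' degree steps for 8 channels).
#'
#' @param n_channels number of channels.
#' @return complex weight vector.
#' @export
quadrature_weights <- function(n_channels) {
  n_channels <- as.integer(n_channels)
  if (n_channels < 1L) stopf("n_channels must be >= 1")
  exp(-2i * pi * (seq_len(n_channels) - 1) / n_channels)
}

#' Random initial shim weights
#'
#' Magnitudes uniform on (0, 1], phases uniform on [0, 360) degrees;
#' consumes the current R RNG stream, so results are reproducible under
#' `set.seed()`.
#'
#' @param n_channels number of channels.
#' @return complex weight vector.
#' @export
random_init_weights <- function(n_channels) {
  mag <- 1 - runif(n_channels)           # uniform on (0, 1]
  ph <- runif(n_channels, 0, 2 * pi)
  complex(modulus = mag, argument = ph)
}

#' Shim optimizer configuration
#'
#' @param lambda_reg regularization weight; `NULL` (default) resolves at
#'   call time to `1e-3 * N_voxel / n_channels`, which puts the power
#'   penalty on the same scale as the per-voxel error sum.
#' @param n_restarts number of random Adam restarts.
#' @param max_iters Adam iterations per restart.
#' @param learning_rate Adam step size.
#' @param tolerance stop when the absolute objective change per
#'   iteration falls below this.
#' @param seed seed for the random initializations.
#' @param include_quadrature_start also run one deterministic restart
#'   warm-started at the magnitude-scaled quadrature mode, and keep the
#'   scaled quadrature itself as a candidate; guarantees the result is
#'   never worse than the quadrature baseline.
#' @return a `shim_config` list.
#' @export
shim_config <- function(lambda_reg = NULL, n_restarts = 300L,
                        max_iters = 500L, learning_rate = 0.05,
                        tolerance = 1e-8, seed = 1L,
                        include_quadrature_start = TRUE) {
  if (n_restarts < 1L) stopf("n_restarts must be >= 1")
  if (max_iters < 1L) stopf("max_iters must be >= 1")
  if (learning_rate <= 0) stopf("learning_rate must be positive")
  structure(list(lambda_reg = lambda_reg, n_restarts = as.integer(n_restarts),
                 max_iters = as.integer(max_iters),
                 learning_rate = learning_rate, tolerance = tolerance,
                 seed = as.integer(seed),
                 include_quadrature_start = isTRUE(include_quadrature_start)),
            class = "shim_config")
}

resolve_lambda <- function(lambda_reg, n_voxel, n_channels) {
  if (is.null(lambda_reg)) 1e-3 * n_voxel / n_channels else lambda_reg
}

# Optimal real magnitude scaling of a fixed weight direction q:
#   min_s sum (s |A q| - m)^2 + lambda s^2 |q|^2.
scaled_candidate <- function(A, mv, q, lambda) {
  f <- abs(as.vector(A %*% q))
  s <- sum(mv * f) / (sum(f^2) + lambda * sum(Mod(q)^2))
  s * q
}

make_shim_result <- function(fields, mask, m, b, lambda, method,
                             restart_index = NA_integer_,
                             iterations_used = NA_integer_,
                             seconds = NA_real_) {
  comb <- combined_field(fields, b)
  structure(list(weights = b,
                 combined_magnitude = abs(comb),
                 rmse_percent = rmse_percent(fields, b, mask, m),
                 objective = mls_objective(fields, b, mask, m, lambda),
                 lambda_reg = lambda, method = method,
                 restart_index = restart_index,
                 iterations_used = iterations_used,
                 seconds = seconds),
            class = "shim_result")
}

#' @export
print.shim_result <- function(x, ...) {
  cat(sprintf("<shim_result> method=%s  RMSE = %.3f %% of target FA\n",
              x$method, x$rmse_percent))
  cat(sprintf("  objective %.6g (lambda %.3g)", x$objective, x$lambda_reg))
  if (!is.na(x$restart_index))
    cat(sprintf("  restart %d, %d iterations", x$restart_index,
                x$iterations_used))
  cat("\n")
  invisible(x)
}

#' @export
coef.shim_result <- function(object, ...) object$weights

#' Multi-restart Adam magnitude least-squares shimming
#'
#' Runs `n_restarts` independent first-order minimizations of the MLS
#' objective over the real and imaginary parts of the weight vector,
#' each started from [random_init_weights()], using the Adam update
#' rule (beta1 = 0.9, beta2 = 0.999, eps = 1e-8).  The restart with the
#' lowest final objective wins; ties break to the lowest restart index.
#' Restarts that diverge to a non-finite objective are discarded with a
#' warning.  With `include_quadrature_start` (default) the
#' magnitude-scaled quadrature mode is also optimized and kept as a
#' candidate, so the result is never worse than the quadrature
#' baseline.
#'
#' @param fields complex array `(channels, rows, cols)`.
#' @param mask logical region-of-interest mask (non-empty).
#' @param m target magnitude map or scalar; default 1.
#' @param config a [shim_config()].
#' @return a `shim_result`: weights, combined magnitude map,
#'   `rmse_percent`, final objective, winning restart index and
#'   iteration count.
#' @export
adam_shim <- function(fields, mask, m = 1, config = shim_config()) {
  check_mask(mask)
  A <- field_matrix(fields, mask)
  mv <- target_vector(m, mask)
  C <- ncol(A)
  lambda <- resolve_lambda(config$lambda_reg, nrow(A), C)

  t0 <- proc.time()[["elapsed"]]
  inits <- with_seed(config$seed,
                     vapply(seq_len(config$n_restarts),
                            function(k) random_init_weights(C),
                            complex(C)))
  inits <- matrix(inits, nrow = C)
  restart_ids <- seq_len(config$n_restarts)
  if (config$include_quadrature_start) {
    q <- scaled_candidate(A, mv, quadrature_weights(C), lambda)
    inits <- cbind(q, inits)
    restart_ids <- c(0L, restart_ids)
  }
  fit <- cpp_adam_shim(A, mv, inits, lambda, config$learning_rate,
                       0.9, 0.999, 1e-8, config$max_iters, config$tolerance)
  obj <- fit$objective
  ok <- is.finite(obj)
  if (!all(ok))
    warning(sprintf("%d restart(s) diverged and were discarded", sum(!ok)),
            call. = FALSE)
  if (!any(ok)) stopf("all shim restarts failed with non-finite objectives")

  cand_w <- lapply(which(ok), function(j) fit$weights[, j])
  cand_obj <- obj[ok]
  cand_id <- restart_ids[ok]
  cand_it <- fit$iterations[ok]
  if (config$include_quadrature_start) {
    # raw scaled-quadrature candidate (un-optimized baseline guard)
    cand_w <- c(cand_w, list(as.vector(q)))
    cand_obj <- c(cand_obj, cpp_mls_objective(A, mv, as.complex(q), lambda))
    cand_id <- c(cand_id, 0L)
    cand_it <- c(cand_it, 0L)
  }
  best <- which.min(cand_obj)   # which.min takes the first minimum: lowest index
  make_shim_result(fields, mask, m, cand_w[[best]], lambda, "adam",
                   restart_index = cand_id[best],
                   iterations_used = cand_it[best],
                   seconds = proc.time()[["elapsed"]] - t0)
}

#' Variable-exchange magnitude least-squares shimming
#'
#' The classic alternating scheme for magnitude-only fitting (the
#' phase-retrieval analogue): (i) adopt the current combined field's
#' per-voxel phase onto the target to form a complex target `z = m *
#' exp(i * arg(A b))`; (ii) solve the regularized linear least squares
#' `min_b ||A b - z||^2 + lambda ||b||^2` in closed form.  The MLS
#' objective is non-increasing across outer iterations.  Serves as the
#' conventional comparison arm for [adam_shim()].
#'
#' @inheritParams adam_shim
#' @param lambda_reg regularization weight; `NULL` resolves as in
#'   [shim_config()].
#' @param max_outer maximum outer iterations.
#' @param tolerance stop when the objective decrease falls below this.
#' @param b_init optional starting weights; default is the
#'   magnitude-scaled quadrature mode.
#' @param n_restarts total number of starts.  The first is `b_init`;
#'   additional starts adopt random per-voxel target phases (the
#'   variable being exchanged), which samples distinct fixed-point
#'   basins.  The default of 1 keeps the classic deterministic
#'   single-start behavior.
#' @param seed seed for the random-phase restarts (unused when
#'   `n_restarts` is 1).
#' @return a `shim_result`.
#' @export
mls_variable_exchange <- function(fields, mask, m = 1, lambda_reg = NULL,
                                  max_outer = 50L, tolerance = 1e-10,
                                  b_init = NULL, n_restarts = 1L,
                                  seed = 1L) {
  check_mask(mask)
  A <- field_matrix(fields, mask)
  mv <- target_vector(m, mask)
  C <- ncol(A)
  lambda <- resolve_lambda(lambda_reg, nrow(A), C)
  t0 <- proc.time()[["elapsed"]]

  AtA <- Conj(t(A)) %*% A
  normal <- AtA + diag(lambda, C)
  solver <- tryCatch({
    inv <- solve(normal)
    function(rhs) inv %*% rhs
  }, error = function(e) {
    warning("singular normal equations; using pseudo-inverse", call. = FALSE)
    sv <- svd(normal)
    keep <- sv$d > max(sv$d) * 1e-12
    function(rhs) sv$v[, keep, drop = FALSE] %*%
      ((Conj(t(sv$u[, keep, drop = FALSE])) %*% rhs) / sv$d[keep])
  })

  run_exchange <- function(b) {
    obj <- cpp_mls_objective(A, mv, as.complex(b), lambda)
    used <- 0L
    for (it in seq_len(max_outer)) {
      f <- as.vector(A %*% b)
      phase <- ifelse(Mod(f) > 0, f / Mod(f), 1 + 0i)
      z <- mv * phase
      b_new <- as.vector(solver(Conj(t(A)) %*% z))
      obj_new <- cpp_mls_objective(A, mv, as.complex(b_new), lambda)
      used <- it
      if (obj_new > obj) break      # numerical safeguard; theory says non-increasing
      b <- b_new
      if (obj - obj_new < tolerance) { obj <- obj_new; break }
      obj <- obj_new
    }
    list(b = b, obj = obj, used = used)
  }

  b0 <- if (is.null(b_init))
    scaled_candidate(A, mv, quadrature_weights(C), lambda)
  else as.complex(b_init)
  best <- run_exchange(b0)
  if (n_restarts > 1L) {
    phases <- with_seed(seed,
                        matrix(runif(nrow(A) * (n_restarts - 1L), 0, 2 * pi),
                               nrow(A)))
    for (k in seq_len(n_restarts - 1L)) {
      z <- mv * exp(1i * phases[, k])
      bk <- as.vector(solver(Conj(t(A)) %*% z))
      res <- run_exchange(bk)
      if (res$obj < best$obj) best <- res
    }
  }
  make_shim_result(fields, mask, m, best$b, lambda, "mls",
                   restart_index = NA_integer_, iterations_used = best$used,
                   seconds = proc.time()[["elapsed"]] - t0)
}

#' Exhaustive grid-search shim oracle
#'
#' Brute-force minimization of the MLS objective over a magnitude x
#' phase grid per channel, with the global phase removed by pinning
#' channel 1 to phase 0.  Supports 1 or 2 channels; intended as an
#' independent reference for the iterative optimizers on tiny fixtures,
#' not for production use.
#'
#' @inheritParams adam_shim
#' @param lambda_reg regularization weight (default 0).
#' @param mag_max,mag_step magnitude grid: `0, mag_step, ..., mag_max`.
#' @param phase_step_deg phase grid step in degrees.
#' @return list with `weights` and `objective`.
#' @export
grid_search_shim <- function(fields, mask, m = 1, lambda_reg = 0,
                             mag_max = 2, mag_step = 0.01,
                             phase_step_deg = 1) {
  check_mask(mask)
  A <- field_matrix(fields, mask)
  cpp_grid_search(A, target_vector(m, mask), lambda_reg,
                  mag_max, mag_step, phase_step_deg)
}

#' Shim every slice of a field volume
#'
#' Batch driver: applies one shimming method independently to each
#' slice and collects a tidy results table.  Per-slice failures are
#' recorded as flagged rows rather than aborting the run.
#'
#' @param volume a `field_volume`.
#' @param method `"adam"`, `"mls"` or `"quadrature"`.
#' @param config a [shim_config()] (used by `"adam"`; its `lambda_reg`
#'   and seed also apply to `"mls"`).
#' @param m target magnitude; default 1.
#' @return data frame with columns `slice`, `source_slice`,
#'   `rotation_deg`, `method`, `rmse_percent`, `objective`,
#'   `restarts`, `iterations`, `seconds`, `ok`, `message`, plus a
#'   `results` attribute holding the `shim_result` objects.
#' @export
shim_volume <- function(volume, method = c("adam", "mls", "quadrature"),
                        config = shim_config(), m = 1) {
  stopifnot(inherits(volume, "field_volume"))
  method <- match.arg(method)
  S <- n_slices(volume)
  rows <- vector("list", S)
  results <- vector("list", S)
  for (i in seq_len(S)) {
    sl <- get_slice(volume, i)
    res <- tryCatch({
      cfg <- config
      cfg$seed <- derive_seed(config$seed, i)
      switch(method,
        adam = adam_shim(sl$fields, sl$mask, m, cfg),
        mls = mls_variable_exchange(sl$fields, sl$mask, m,
                                    lambda_reg = config$lambda_reg),
        quadrature = {
          t0 <- proc.time()[["elapsed"]]
          C <- dim(sl$fields)[1]
          lam <- resolve_lambda(config$lambda_reg, sum(sl$mask), C)
          make_shim_result(sl$fields, sl$mask, m, quadrature_weights(C),
                           lam, "quadrature",
                           seconds = proc.time()[["elapsed"]] - t0)
        })
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(slice = i, source_slice = sl$source_slice,
                              rotation_deg = sl$rotation_deg, method = method,
                              rmse_percent = NA_real_, objective = NA_real_,
                              restarts = NA_integer_, iterations = NA_integer_,
                              seconds = NA_real_, ok = FALSE,
                              message = conditionMessage(res))
    } else {
      results[[i]] <- res
      rows[[i]] <- data.frame(slice = i, source_slice = sl$source_slice,
                              rotation_deg = sl$rotation_deg, method = method,
                              rmse_percent = res$rmse_percent,
                              objective = res$objective,
                              restarts = if (method == "adam")
                                config$n_restarts else NA_integer_,
                              iterations = res$iterations_used,
                              seconds = res$seconds, ok = TRUE,
                              message = "")
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "results") <- results
  out
}
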