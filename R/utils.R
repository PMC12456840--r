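# Shared helpers: grid rotation, smooth random surfaces, seed handling.

#' Rotate a 2-D grid about its geometric center
#'
#' Inverse-mapping rotation with bilinear (default) or nearest-neighbor
#' interpolation.  Points mapped from outside the grid are filled with
#' `fill`.  The rotation center is the geometric center of the grid,
#' `((nrow+1)/2, (ncol+1)/2)` in 1-based voxel coordinates.
#'
#' @param mat numeric matrix.
#' @param angle_deg rotation angle in degrees, counter-clockwise.
#' @param method `"bilinear"` or `"nearest"`.
#' @param fill value for points rotated in from outside the grid.
#' @return a matrix of the same shape.
#' @export
rotate_grid <- function(mat, angle_deg, method = c("bilinear", "nearest"),
                        fill = 0) {
  method <- match.arg(method)
  nr <- nrow(mat); nc <- ncol(mat)
  ang <- angle_deg %% 360
  if (ang == 0) return(mat)
  th <- -ang * pi / 180  # inverse mapping
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  r <- rep(seq_len(nr), times = nc) - cr
  c <- rep(seq_len(nc), each = nr) - cc
  # source coordinates in the unrotated grid
  rs <- cos(th) * r - sin(th) * c + cr
  cs <- sin(th) * r + cos(th) * c + cc
  out <- rep(fill, nr * nc)
  if (method == "nearest") {
    ri <- round(rs); ci <- round(cs)
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    out[ok] <- mat[cbind(ri[ok], ci[ok])]
  } else {
    r0 <- floor(rs); c0 <- floor(cs)
    fr <- rs - r0; fc <- cs - c0
    ok <- r0 >= 1 & r0 + 1 <= nr & c0 >= 1 & c0 + 1 <= nc
    i00 <- cbind(r0[ok], c0[ok]);     i10 <- cbind(r0[ok] + 1, c0[ok])
    i01 <- cbind(r0[ok], c0[ok] + 1); i11 <- cbind(r0[ok] + 1, c0[ok] + 1)
    out[ok] <- (1 - fr[ok]) * (1 - fc[ok]) * mat[i00] +
      fr[ok] * (1 - fc[ok]) * mat[i10] +
      (1 - fr[ok]) * fc[ok] * mat[i01] +
      fr[ok] * fc[ok] * mat[i11]
  }
  matrix(out, nr, nc)
}

# Low-frequency random surface on a grid: a short sum of random-phase
# sinusoids, scaled to roughly unit amplitude.  Consumes the R RNG stream.
smooth_noise_surface <- function(grid_shape, n_terms = 3L) {
  nr <- grid_shape[1]; nc <- grid_shape[2]
  r <- matrix(rep(seq_len(nr), times = nc), nr, nc) / nr
  c <- matrix(rep(seq_len(nc), each = nr), nr, nc) / nc
  out <- matrix(0, nr, nc)
  for (j in seq_len(n_terms)) {
    fr <- runif(1, 0.5, 2.5); fc <- runif(1, 0.5, 2.5)
    ph <- runif(1, 0, 2 * pi); amp <- runif(1, 0.5, 1)
    out <- out + amp * cos(2 * pi * (fr * r + fc * c) + ph)
  }
  out / n_terms
}

# Evaluate an expression with a locally-seeded RNG, restoring the caller's
# RNG state afterwards so library code does not disturb user streams.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a per-stage seed from a global seed; stays below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(offset) %% 1000L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Separable box mean with edge renormalization: each output voxel is the
# mean of the input over a (2k+1)^2 window clipped to the grid.
box_blur <- function(m, k = 4L) {
  ones <- matrix(1, nrow(m), ncol(m))
  run1 <- function(x) {
    apply(x, 2, function(col) {
      cs <- cumsum(col)
      n <- length(cs)
      c(cs[(k + 1):n], rep(cs[n], k)) -
        c(rep(0, k + 1), cs[1:(n - k - 1)])
    })
  }
  run <- function(x) t(run1(t(run1(x))))
  run(m) / pmax(run(ones), 1)
}
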