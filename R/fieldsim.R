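# Synthetic multi-channel B1+ field generation.
#
# The transmit array is modeled quasi-statically: each channel is a
# circular current loop whose field magnitude follows the on-axis
# Biot-Savart law evaluated at the 3-D distance from the loop center,
# with a phase ramp proportional to that distance emulating the RF
# wavelength effects that drive B1+ interference at 7 T (298 MHz).

#' Transmit coil array specification
#'
#' Describes an n-channel loop array placed around the phantom, plus the
#' quasi-static field-model parameters.  Defaults describe an 8-loop
#' single-row head array with elements every 45 degrees, driven in
#' circularly-polarized (quadrature) mode, sized for a 101 x 101 grid.
#'
#' @param n_channels number of transmit channels.
#' @param radius distance (in voxels) of each loop center from the grid
#'   center.  Loops may sit outside the imaged grid.
#' @param element_size effective loop radius in voxels; sets how quickly
#'   each channel's field falls off.
#' @param element_angles azimuthal loop positions in degrees; default
#'   `k * 360 / n_channels`.
#' @param quadrature_phases per-channel drive phases in degrees; default
#'   `-k * 360 / n_channels` (circularly polarized mode).
#' @param wavelength RF wavelength in voxels controlling the phase ramp;
#'   roughly the in-tissue wavelength at 298 MHz on this grid scale.
#' @param amplitude overall field scale before normalization.
#' @return an object of class `coil_array_spec`.
#' @export
coil_array_spec <- function(n_channels = 8L, radius = 70, element_size = 20,
                            element_angles = NULL, quadrature_phases = NULL,
                            wavelength = 70, amplitude = 1) {
  n_channels <- as.integer(n_channels)
  if (n_channels < 1L) stopf("n_channels must be >= 1")
  if (!is.finite(radius) || radius <= 0) stopf("coil radius must be positive")
  if (!is.finite(element_size) || element_size <= 0)
    stopf("element_size must be positive")
  if (is.null(element_angles))
    element_angles <- (seq_len(n_channels) - 1L) * 360 / n_channels
  if (length(element_angles) != n_channels)
    stopf("element_angles must have exactly n_channels entries")
  if (is.null(quadrature_phases))
    quadrature_phases <- -(seq_len(n_channels) - 1L) * 360 / n_channels
  if (length(quadrature_phases) != n_channels)
    stopf("quadrature_phases must have exactly n_channels entries")
  structure(list(n_channels = n_channels, radius = radius,
                 element_size = element_size,
                 element_angles = element_angles,
                 quadrature_phases = quadrature_phases,
                 wavelength = wavelength, amplitude = amplitude),
            class = "coil_array_spec")
}

#' Head-like phantom specification
#'
#' An elliptical phantom on a rectangular voxel grid, carrying a uniform
#' mass-density surrogate inside and zero (air) outside.  The
#' region-of-interest mask is derived by thresholding the density map.
#'
#' @param grid_shape `(rows, cols)` voxel counts.
#' @param semi_axes ellipse semi-axes in voxels, `(row, col)`.
#' @param density_inside density value inside the phantom.
#' @param density_outside density outside (air); must be below the
#'   mask threshold.
#' @param noise_level relative amplitude of the smooth multiplicative
#'   magnitude/phase perturbations added per channel and slice.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(101L, 101L), semi_axes = c(45, 38),
                         density_inside = 1, density_outside = 0,
                         noise_level = 0.02) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 1L))
    stopf("grid_shape must be two positive integers")
  if (any(!is.finite(semi_axes)) || any(semi_axes <= 0))
    stopf("phantom semi-axes must be positive")
  if (any(semi_axes > grid_shape / 2))
    stopf("phantom semi-axes must fit within the grid")
  if (density_outside >= density_inside)
    stopf("density_outside must be below density_inside")
  if (noise_level < 0) stopf("noise_level must be non-negative")
  structure(list(grid_shape = grid_shape, semi_axes = semi_axes,
                 density_inside = density_inside,
                 density_outside = density_outside,
                 noise_level = noise_level),
            class = "phantom_spec")
}

#' Coil and phantom specifications scaled to a grid
#'
#' Convenience constructor returning a matched `coil_array_spec` /
#' `phantom_spec` pair with all geometric parameters scaled
#' proportionally from the 101 x 101 reference grid, so smaller grids
#' keep the same interference structure at lower cost.
#'
#' @param grid_shape `(rows, cols)` voxel counts.
#' @param n_channels number of transmit channels.
#' @param noise_level passed to [phantom_spec()].
#' @return list with elements `coils` and `phantom`.
#' @export
default_specs <- function(grid_shape = c(101L, 101L), n_channels = 8L,
                          noise_level = 0.02) {
  s <- max(grid_shape) / 101
  list(coils = coil_array_spec(n_channels = n_channels, radius = 70 * s,
                               element_size = 20 * s, wavelength = 70 * s),
       phantom = phantom_spec(grid_shape = grid_shape,
                              semi_axes = c(45, 38) * s,
                              noise_level = noise_level))
}

#' On-axis field magnitude of a circular current loop
#'
#' Biot-Savart magnitude of a loop of radius `a` at axial distance
#' `dist`, `amplitude * a^2 / (a^2 + dist^2)^(3/2)`, with `amplitude`
#' absorbing the mu0*I/2 prefactor.  This is the radial profile the
#' simulator assigns to each channel.
#'
#' @param a loop radius.
#' @param dist distance from the loop center.
#' @param amplitude field scale.
#' @return field magnitude, same shape as `dist`.
#' @export
loop_field_magnitude <- function(a, dist, amplitude = 1) {
  amplitude * a^2 / (a^2 + dist^2)^1.5
}

# Complex per-channel field on one slice at axial offset dz.
channel_field_grid <- function(coils, grid_shape, channel, dz = 0) {
  nr <- grid_shape[1]; nc <- grid_shape[2]
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  th <- coils$element_angles[channel] * pi / 180
  # loop center in voxel coordinates (rows ~ y, cols ~ x)
  pr <- cr + coils$radius * sin(th)
  pc <- cc + coils$radius * cos(th)
  r <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  c <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  d <- sqrt((r - pr)^2 + (c - pc)^2 + dz^2)
  mag <- loop_field_magnitude(coils$element_size, d, coils$amplitude)
  ph <- -2 * pi * d / coils$wavelength +
    coils$quadrature_phases[channel] * pi / 180
  mag * exp(1i * ph)
}

#' Simulate a multi-channel B1+ field volume
#'
#' Generates `n_slices` axial slices of complex per-channel transmit
#' fields over a head-like phantom, together with the density map and
#' region-of-interest mask per slice.  Slices differ by the axial offset
#' of the loop plane and by a mild head-like shrinkage of the phantom
#' away from the central slice.  A smooth random magnitude/phase
#' perturbation (per channel and slice) emulates residual
#' subject-dependent field structure.  With `normalize = TRUE` each
#' slice is scaled so the quadrature-mode mean in-mask magnitude is 1,
#' which makes the percent-of-target-flip-angle error metric comparable
#' across slices.
#'
#' @param coils a [coil_array_spec()].
#' @param phantom a [phantom_spec()].
#' @param n_slices number of slices to generate.
#' @param seed integer seed; the volume is bit-reproducible given
#'   `(coils, phantom, n_slices, seed)`.
#' @param slice_spacing axial distance between slices in voxels.
#' @param normalize logical; per-slice quadrature-mode normalization.
#' @return an object of class `field_volume`: a list with complex array
#'   `b1` of dimension `(channels, rows, cols, slices)`, numeric array
#'   `density`, logical array `mask` (both `(rows, cols, slices)`), the
#'   input specs, and a `metadata` record (seed, per-slice axial
#'   offsets, source-slice ids, rotation tags).
#' @export
simulate_channel_fields <- function(coils, phantom, n_slices = 1L,
                                    seed = 1L, slice_spacing = 3,
                                    normalize = TRUE) {
  stopifnot(inherits(coils, "coil_array_spec"),
            inherits(phantom, "phantom_spec"))
  n_slices <- as.integer(n_slices)
  if (n_slices < 1L) stopf("n_slices must be >= 1")
  gs <- phantom$grid_shape
  C <- coils$n_channels
  b1 <- array(0i, dim = c(C, gs[1], gs[2], n_slices))
  density <- array(0, dim = c(gs[1], gs[2], n_slices))
  offsets <- (seq_len(n_slices) - (n_slices + 1) / 2) * slice_spacing

  with_seed(seed, {
    for (s in seq_len(n_slices)) {
      # head-like shrink of the ellipse away from the central slice
      u <- if (n_slices > 1) 2 * (s - 1) / (n_slices - 1) - 1 else 0
      shrink <- sqrt(1 - 0.4 * u^2)
      density[, , s] <- ellipse_density(gs, phantom$semi_axes * shrink,
                                        phantom$density_inside,
                                        phantom$density_outside)
      for (ch in seq_len(C)) {
        f <- channel_field_grid(coils, gs, ch, dz = offsets[s])
        if (phantom$noise_level > 0) {
          gm <- smooth_noise_surface(gs)
          gp <- smooth_noise_surface(gs)
          f <- f * (1 + phantom$noise_level * gm) *
            exp(1i * phantom$noise_level * pi * gp)
        }
        b1[ch, , , s] <- f
      }
    }
  })

  mask <- density > 0.5 * phantom$density_inside
  if (normalize) {
    qw <- quadrature_weights(C)
    for (s in seq_len(n_slices)) {
      msk <- mask[, , s]
      if (!any(msk)) next
      comb <- combined_field(b1[, , , s, drop = FALSE], qw)
      scale <- mean(abs(comb)[msk])
      if (scale > 0) b1[, , , s] <- b1[, , , s] / scale
    }
  }

  structure(list(b1 = b1, density = density, mask = mask,
                 coils = coils, phantom = phantom,
                 metadata = list(seed = as.integer(seed),
                                 slice_offsets = offsets,
                                 slice_spacing = slice_spacing,
                                 normalize = normalize,
                                 source_slice = seq_len(n_slices),
                                 rotation_deg = rep(0, n_slices))),
            class = "field_volume")
}

ellipse_density <- function(grid_shape, semi_axes, inside, outside) {
  nr <- grid_shape[1]; nc <- grid_shape[2]
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  r <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  c <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  ins <- ((r - cr) / semi_axes[1])^2 + ((c - cc) / semi_axes[2])^2 <= 1
  ifelse(ins, inside, outside)
}

#' @export
print.field_volume <- function(x, ...) {
  d <- dim(x$b1)
  cat(sprintf("<field_volume> %d channels, %d x %d grid, %d slice(s)\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  in-mask voxels per slice: %s\n",
              paste(apply(x$mask, 3, sum), collapse = ", ")))
  invisible(x)
}

#' Number of slices in a field volume
#' @param volume a `field_volume`.
#' @return integer slice count.
#' @export
n_slices <- function(volume) dim(volume$b1)[4]

#' Extract one slice from a field volume
#'
#' @param volume a `field_volume`.
#' @param i slice index.
#' @return list with complex array `fields` `(channels, rows, cols)`,
#'   logical matrix `mask`, numeric matrix `density`, and slice
#'   metadata (`source_slice`, `rotation_deg`).
#' @export
get_slice <- function(volume, i) {
  stopifnot(inherits(volume, "field_volume"))
  i <- as.integer(i)
  if (i < 1L || i > n_slices(volume)) stopf("slice index out of range")
  d <- dim(volume$b1)
  list(fields = array(volume$b1[, , , i], dim = d[1:3]),
       mask = volume$mask[, , i],
       density = volume$density[, , i],
       source_slice = volume$metadata$source_slice[i],
       rotation_deg = volume$metadata$rotation_deg[i])
}

#' Build a region-of-interest mask from a density map
#'
#' Thresholds a mass-density surrogate: voxels with `density >
#' threshold` are inside the region of interest, excluding surrounding
#' air.  An all-false mask is allowed but flagged with a warning, since
#' shimming on it is rejected downstream.
#'
#' @param density numeric matrix (or array) of densities.
#' @param threshold scalar threshold; default 0.5.
#' @return logical mask of the same shape.
#' @export
build_mask <- function(density, threshold = 0.5) {
  if (!is.finite(threshold)) stopf("threshold must be finite")
  mask <- density > threshold
  if (!any(mask))
    warning("mask has no in-region voxels; shimming on it will be rejected",
            call. = FALSE)
  mask
}

#' Augment a field volume with in-plane rotations
#'
#' Replaces each slice with `n_rotations` copies rotated by
#' `k * 360 / n_rotations` degrees (k = 0, ..., n_rotations - 1) about
#' the grid center.  Channel fields are rotated with bilinear
#' interpolation on real and imaginary parts; the density map is
#' rotated bilinearly and the mask is re-derived by nearest-neighbor
#' rotation followed by re-binarization.  Slice metadata records the
#' source slice and rotation angle so dataset splits can group rotated
#' copies.
#'
#' @param volume a `field_volume`.
#' @param n_rotations number of rotated copies per slice (1 = identity).
#' @return a `field_volume` with `n_slices * n_rotations` slices,
#'   ordered source-slice-major.
#' @export
augment_rotations <- function(volume, n_rotations = 12L) {
  stopifnot(inherits(volume, "field_volume"))
  n_rotations <- as.integer(n_rotations)
  if (n_rotations < 1L) stopf("n_rotations must be >= 1")
  if (n_rotations == 1L) return(volume)
  d <- dim(volume$b1)
  S <- d[4]; C <- d[1]
  angles <- (seq_len(n_rotations) - 1L) * 360 / n_rotations
  b1 <- array(0i, dim = c(C, d[2], d[3], S * n_rotations))
  density <- array(0, dim = c(d[2], d[3], S * n_rotations))
  mask <- array(FALSE, dim = c(d[2], d[3], S * n_rotations))
  src <- integer(S * n_rotations); rot <- numeric(S * n_rotations)
  out_i <- 0L
  for (s in seq_len(S)) {
    for (k in seq_len(n_rotations)) {
      out_i <- out_i + 1L
      a <- angles[k]
      if (a == 0) {
        b1[, , , out_i] <- volume$b1[, , , s]
        density[, , out_i] <- volume$density[, , s]
        mask[, , out_i] <- volume$mask[, , s]
      } else {
        for (ch in seq_len(C)) {
          re <- rotate_grid(Re(volume$b1[ch, , , s]), a)
          im <- rotate_grid(Im(volume$b1[ch, , , s]), a)
          b1[ch, , , out_i] <- complex(real = re, imaginary = im)
        }
        density[, , out_i] <- rotate_grid(volume$density[, , s], a)
        mask[, , out_i] <-
          rotate_grid(volume$mask[, , s] * 1, a, method = "nearest") > 0.5
      }
      src[out_i] <- volume$metadata$source_slice[s]
      rot[out_i] <- (volume$metadata$rotation_deg[s] + a) %% 360
    }
  }
  meta <- volume$metadata
  meta$source_slice <- src
  meta$rotation_deg <- rot
  meta$slice_offsets <- rep(volume$metadata$slice_offsets, each = n_rotations)
  meta$n_rotations <- n_rotations
  structure(list(b1 = b1, density = density, mask = mask,
                 coils = volume$coils, phantom = volume$phantom,
                 metadata = meta),
            class = "field_volume")
}

#' Inject smooth non-uniformity voids into a magnitude map
#'
#' Multiplies the map by compact smooth suppression profiles
#' `1 - depth * (1 - (d/radius)^2)^2` (for `d < radius`), emulating the
#' local B1+ voids and artifacts that a non-uniformity detector is
#' trained to flag.  Void centers default to random in-mask voxels.
#'
#' @param magnitude_map non-negative numeric matrix.
#' @param mask logical region-of-interest mask.
#' @param radius void radius in voxels (scalar or length-`n_voids`).
#' @param depth suppression depth in `[0, 1]`; 1 drives the center to 0.
#' @param center optional `(row, col)` void center (single void); must
#'   lie inside the mask.
#' @param n_voids number of voids when centers are drawn at random.
#' @param seed seed for random void placement.
#' @return the modified magnitude map.
#' @export
inject_nonuniformity <- function(magnitude_map, mask, radius, depth,
                                 center = NULL, n_voids = 1L, seed = NULL) {
  if (any(radius <= 0)) stopf("void radius must be positive")
  if (any(depth < 0 | depth > 1)) stopf("void depth must be in [0, 1]")
  nr <- nrow(magnitude_map); nc <- ncol(magnitude_map)
  if (!is.null(center)) {
    centers <- matrix(center, ncol = 2)
    if (!mask[center[1], center[2]]) stopf("void center must lie inside the mask")
  } else {
    idx <- which(mask, arr.ind = TRUE)
    if (nrow(idx) == 0L) stopf("mask has no in-region voxels")
    pick <- if (is.null(seed)) sample.int(nrow(idx), n_voids, replace = TRUE)
            else with_seed(seed, sample.int(nrow(idx), n_voids, replace = TRUE))
    centers <- idx[pick, , drop = FALSE]
  }
  radius <- rep_len(radius, nrow(centers))
  depth <- rep_len(depth, nrow(centers))
  r <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  c <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  out <- magnitude_map
  for (j in seq_len(nrow(centers))) {
    d2 <- (r - centers[j, 1])^2 + (c - centers[j, 2])^2
    prof <- pmax(0, 1 - d2 / radius[j]^2)
    out <- out * (1 - depth[j] * prof^2)
  }
  out
}

#' Generate and write a complete synthetic dataset
#'
#' Simulates `n_volumes` field volumes (with per-volume phantom size
#' jitter emulating different head sizes), applies rotation
#' augmentation, and writes them to a versioned dataset container (see
#' [write_dataset()]).  Fully reproducible from `(config, seed)`.
#'
#' @param path output file path.
#' @param n_volumes,slices_per_volume,n_rotations dataset dimensions.
#' @param grid_shape voxel grid; specs are scaled via [default_specs()].
#' @param n_channels number of transmit channels.
#' @param noise_level phantom noise level.
#' @param size_jitter relative half-range of per-volume phantom scaling.
#' @param seed integer seed.
#' @return the list of `field_volume` objects, invisibly; the dataset
#'   is written to `path`.
#' @export
make_dataset <- function(path, n_volumes = 4L, slices_per_volume = 8L,
                         n_rotations = 12L, grid_shape = c(101L, 101L),
                         n_channels = 8L, noise_level = 0.02,
                         size_jitter = 0.1, seed = 1L) {
  volumes <- simulate_volumes(n_volumes, slices_per_volume, n_rotations,
                              grid_shape, n_channels, noise_level,
                              size_jitter, seed)
  write_dataset(volumes, path)
  invisible(volumes)
}

# In-memory dataset generation shared by make_dataset() and the pipeline.
simulate_volumes <- function(n_volumes, slices_per_volume, n_rotations,
                             grid_shape, n_channels, noise_level,
                             size_jitter, seed) {
  base <- default_specs(grid_shape, n_channels, noise_level)
  scales <- with_seed(derive_seed(seed, 1L),
                      runif(n_volumes, 1 - size_jitter, 1 + size_jitter))
  lapply(seq_len(n_volumes), function(v) {
    ph <- base$phantom
    sa <- pmin(ph$semi_axes * scales[v], ph$grid_shape / 2)
    ph <- phantom_spec(grid_shape = ph$grid_shape, semi_axes = sa,
                       density_inside = ph$density_inside,
                       density_outside = ph$density_outside,
                       noise_level = ph$noise_level)
    vol <- simulate_channel_fields(base$coils, ph, slices_per_volume,
                                   seed = derive_seed(seed, 10L + v))
    vol <- augment_rotations(vol, n_rotations)
    vol$metadata$volume_id <- v
    vol
  })
}
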