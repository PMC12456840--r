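# Dataset container and exports.
#
# Datasets are stored in a single versioned container file written with
# R serialization (uncompressed, format version 3) so that write/read
# round trips are bit-exact.  Layout (layout_version 1):
#
#   $layout_version  integer
#   $provenance      list(tool_version, created, seed, config_hash)
#   $volumes         list of field_volume objects, each with
#                    $b1 (complex [C, rows, cols, slices]), $density,
#                    $mask, $coils, $phantom, $metadata
#   $reference       optional list of per-volume shim tables (weights
#                    and RMSEs cached for training)
#   $nfd             optional list(maps, labels)

CONTAINER_VERSION <- 1L

#' Write a dataset container
#'
#' @param volumes a `field_volume` or list of them.
#' @param path output file path.
#' @param reference optional cached per-volume reference shim tables.
#' @param nfd optional NFD example set.
#' @param provenance optional extra provenance fields (seed, config
#'   hash); tool version and creation time are recorded automatically.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(volumes, path, reference = NULL, nfd = NULL,
                          provenance = list()) {
  if (inherits(volumes, "field_volume")) volumes <- list(volumes)
  stopifnot(all(vapply(volumes, inherits, TRUE, "field_volume")))
  obj <- list(layout_version = CONTAINER_VERSION,
              provenance = c(list(
                tool_version = as.character(utils::packageVersion("fastshim")),
                created = format(Sys.time(), tz = "UTC")), provenance),
              volumes = volumes, reference = reference, nfd = nfd)
  ok <- tryCatch({
    saveRDS(obj, path, version = 3L, compress = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stopf("failed to write dataset to '%s': %s", path, conditionMessage(ok))
  invisible(path)
}

#' Read a dataset container
#'
#' Lossless inverse of [write_dataset()]: the returned volumes are
#' bit-identical to the ones written.  Corrupt files and unsupported
#' layout versions raise explicit format errors.
#'
#' @param path container file path.
#' @return list with `volumes`, `reference`, `nfd`, `provenance` and
#'   `layout_version`.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stopf("dataset file '%s' does not exist", path)
  obj <- tryCatch(readRDS(path), error = function(e)
    stopf("'%s' is not a readable dataset container: %s", path,
          conditionMessage(e)))
  if (!is.list(obj) || is.null(obj$layout_version))
    stopf("'%s' has no layout_version attribute; unsupported container", path)
  if (obj$layout_version != CONTAINER_VERSION)
    stopf("unsupported layout_version %s (expected %d)",
          obj$layout_version, CONTAINER_VERSION)
  if (is.null(obj$volumes))
    stopf("dataset container is missing the 'volumes' group")
  obj
}

#' Export per-slice magnitude maps as NIfTI
#'
#' Writes the quadrature-mode combined magnitude of a volume as a 3-D
#' NIfTI image for visual inspection.  Requires the RNifti package.
#'
#' @param volume a `field_volume`.
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
export_magnitude_nifti <- function(volume, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stopf("RNifti is required for NIfTI export")
  stopifnot(inherits(volume, "field_volume"))
  S <- n_slices(volume)
  qw <- quadrature_weights(dim(volume$b1)[1])
  mag <- vapply(seq_len(S),
                function(s) abs(combined_field(get_slice(volume, s)$fields,
                                               qw)),
                matrix(0, dim(volume$b1)[2], dim(volume$b1)[3]))
  RNifti::writeNifti(RNifti::asNifti(mag), path)
  invisible(path)
}
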