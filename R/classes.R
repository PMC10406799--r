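#' Volumetric intensity stack
#'
#' A `volume_stack` is the unit of compression and PSNR computation: a 3D
#' grid of unsigned integer intensities with a bit depth and per-axis voxel
#' spacing. Arrays are stored `[y, x, z]` (rows, columns, slices), so the
#' slice index is the third dimension.
#'
#' @param data 3D numeric array of integral intensities in
#'   `[0, 2^bit_depth - 1]`.
#' @param bit_depth Bits per voxel (default 16).
#' @param spacing Voxel spacing in micrometres per axis, `c(y, x, z)`.
#' @return An object of class `volume_stack` with fields `data`,
#'   `bit_depth`, `spacing`.
#' @examples
#' v <- volume_stack(array(0L, c(8, 8, 4)))
#' dim(v$data)
#' @export
volume_stack <- function(data, bit_depth = 16L, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  bit_depth <- as.integer(bit_depth)
  if (bit_depth < 1L || bit_depth > 32L)
    stop("`bit_depth` must be between 1 and 32")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values")
  peak <- 2^bit_depth - 1
  rng <- range(data)
  if (rng[1] < 0 || rng[2] > peak)
    stop("intensities outside [0, 2^bit_depth - 1]")
  structure(
    list(data = data, bit_depth = bit_depth, spacing = as.numeric(spacing)),
    class = "volume_stack"
  )
}

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<volume_stack> %d x %d x %d voxels, %d-bit, spacing %s um\n",
    d[1], d[2], d[3], x$bit_depth,
    paste(signif(x$spacing, 4), collapse = " x ")
  ))
  invisible(x)
}

#' Binary segmentation mask stack
#'
#' A `mask_stack` is the unit of segmentation comparison: a logical 3D grid
#' aligned to a parent [volume_stack()], carrying provenance (which
#' observer / timepoint / encoder / quality, or `"auto"` for the automated
#' branch) so agreement reports can identify the pair compared.
#'
#' @param data 3D logical array, same shape as the parent volume.
#' @param spacing Voxel spacing in micrometres per axis, `c(y, x, z)`.
#' @param provenance Character label; must be non-empty.
#' @return An object of class `mask_stack`.
#' @examples
#' m <- mask_stack(array(FALSE, c(8, 8, 4)), provenance = "truth")
#' @export
mask_stack <- function(data, spacing = c(1, 1, 1), provenance = "unspecified") {
  if (is.numeric(data)) data <- array(data != 0, dim(data))
  if (!is.array(data) || length(dim(data)) != 3L || !is.logical(data))
    stop("`data` must be a 3D logical array")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values")
  if (!is.character(provenance) || length(provenance) != 1L ||
      !nzchar(provenance))
    stop("`provenance` must be a non-empty string")
  structure(
    list(data = data, spacing = as.numeric(spacing), provenance = provenance),
    class = "mask_stack"
  )
}

#' @export
print.mask_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<mask_stack> %d x %d x %d, %d foreground voxels, provenance '%s'\n",
    d[1], d[2], d[3], sum(x$data), x$provenance
  ))
  invisible(x)
}

#' Two-timepoint record of one observer's segmentations
#'
#' Bundles the two masks one observer drew on the same dataset version at
#' timepoints t = 0 and t = 1; the input to valid-slice selection and the
#' intra-observer variability baseline.
#'
#' @param observer_id Label for the observer.
#' @param s_t0,s_t1 [mask_stack()] objects, aligned to the same volume.
#' @return An object of class `observer_record`.
#' @export
observer_record <- function(observer_id, s_t0, s_t1) {
  stopifnot(inherits(s_t0, "mask_stack"), inherits(s_t1, "mask_stack"))
  if (!identical(dim(s_t0$data), dim(s_t1$data)))
    stop("timepoint masks must be aligned (same shape)")
  structure(
    list(observer_id = as.character(observer_id), s_t0 = s_t0, s_t1 = s_t1),
    class = "observer_record"
  )
}

n_slices <- function(x) {
  if (inherits(x, c("volume_stack", "mask_stack"))) dim(x$data)[3]
  else dim(x)[3]
}

check_aligned <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("stacks are not aligned: shapes differ")
  invisible(TRUE)
}
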