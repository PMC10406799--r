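#' Read and write volumes and masks
#'
#' Volumes are stored as multi-page TIFF (one page per slice, 16-bit
#' grayscale) or NIfTI; masks as 8-bit multi-page TIFF with values
#' `{0, 255}`. A JSON sidecar can record the generating configuration and
#' seed next to the image file.
#'
#' @param vs A [volume_stack()] (bit depth at most 16 for TIFF).
#' @param mask A [mask_stack()].
#' @param path Output path.
#' @param spacing,bit_depth,provenance Metadata to attach when reading
#'   (TIFF carries neither spacing nor provenance).
#' @return Writers return `path` invisibly; readers return the
#'   reconstructed object.
#' @name volume_io
NULL

#' @rdname volume_io
#' @export
write_volume_tiff <- function(vs, path) {
  stopifnot(inherits(vs, "volume_stack"))
  if (vs$bit_depth > 16L) stop("TIFF writer supports up to 16 bits")
  scale <- 2^16 - 1
  pages <- lapply(seq_len(n_slices(vs)), function(s)
    vs$data[, , s] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname volume_io
#' @export
read_volume_tiff <- function(path, bit_depth = 16L, spacing = c(1, 1, 1)) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (s in seq_along(pages)) arr[, , s] <- pages[[s]]
  volume_stack(arr, bit_depth = bit_depth, spacing = spacing)
}

#' @rdname volume_io
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(inherits(mask, "mask_stack"))
  pages <- lapply(seq_len(n_slices(mask)), function(s)
    (mask$data[, , s] * 255) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname volume_io
#' @export
read_mask_tiff <- function(path, spacing = c(1, 1, 1),
                           provenance = "file") {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(FALSE, c(dim(pages[[1]]), length(pages)))
  for (s in seq_along(pages)) arr[, , s] <- pages[[s]] > 0
  mask_stack(arr, spacing = spacing, provenance = provenance)
}

#' @rdname volume_io
#' @export
write_volume_nifti <- function(vs, path) {
  stopifnot(inherits(vs, "volume_stack"))
  img <- RNifti::asNifti(vs$data)
  RNifti::pixdim(img) <- vs$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname volume_io
#' @export
read_volume_nifti <- function(path, bit_depth = 16L) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  volume_stack(array(as.numeric(img), dim(img)[1:3]),
               bit_depth = bit_depth, spacing = spacing)
}

#' Write / read a JSON sidecar recording configuration and seed
#'
#' @param config Any JSON-serializable list (e.g., a [phantom_config()]).
#' @param path Path of the sidecar file.
#' @return `write_sidecar_json()` returns `path` invisibly;
#'   `read_sidecar_json()` the parsed list.
#' @export
write_sidecar_json <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_sidecar_json
#' @export
read_sidecar_json <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Serialize an agreement report
#'
#' Writes the per-slice table as flat CSV (one row per slice) and the full
#' report as JSON.
#'
#' @param report An `agreement_report` from [jaccard_stack()].
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, a list of the paths written.
#' @export
write_agreement_report <- function(report, csv_path = NULL,
                                   json_path = NULL) {
  stopifnot(inherits(report, "agreement_report"))
  if (!is.null(csv_path)) {
    df <- data.frame(slice = as.integer(names(report$per_slice_ji)),
                     ji = report$per_slice_ji, row.names = NULL)
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(per_slice_ji = report$per_slice_ji,
           stack_ji = report$stack_ji, avg_hd = report$avg_hd,
           n_slices_used = report$n_slices_used,
           pair_provenance = report$pair_provenance),
      json_path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(list(csv = csv_path, json = json_path))
}
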