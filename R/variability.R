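#' Valid-slice selection from a two-timepoint record
#'
#' A slice is valid when the observer's two timepoint annotations agree:
#' the per-slice Jaccard index between `s_t0` and `s_t1` is defined and at
#' least the threshold `t` (default 0.7). Slices where the index is
#' undefined (both annotations empty) are never valid. Comparisons of
#' compressed data are restricted to this set so that observer
#' inconsistency is not mistaken for compression damage.
#'
#' @param rec An [observer_record()].
#' @param t Jaccard threshold in `[0, 1]`.
#' @return A `validity_set`: `slice_indices` (integer vector, possibly
#'   empty), `threshold_t`, `per_slice_ji`.
#' @export
valid_slices <- function(rec, t = 0.7) {
  stopifnot(inherits(rec, "observer_record"))
  if (!is_scalar_number(t) || t < 0 || t > 1)
    stop("`t` must be in [0, 1]")
  nz <- n_slices(rec$s_t0)
  ji <- vapply(seq_len(nz), function(s)
    jaccard_slice(rec$s_t0$data[, , s], rec$s_t1$data[, , s]), numeric(1))
  idx <- which(!is.na(ji) & ji >= t)
  structure(
    list(slice_indices = as.integer(idx), threshold_t = t,
         per_slice_ji = ji),
    class = "validity_set"
  )
}

#' Retained-slice percentage versus agreement threshold
#'
#' For each threshold in `t_grid`, the percentage of the stack's slices
#' whose two-timepoint Jaccard index is defined and at least the
#' threshold. The curve is monotone non-increasing in `t`.
#'
#' @param rec An [observer_record()].
#' @param t_grid Thresholds in `[0, 1]`.
#' @return A data frame with columns `t` and `pct_kept`.
#' @export
threshold_sweep <- function(rec, t_grid = seq(0, 1, by = 0.05)) {
  stopifnot(inherits(rec, "observer_record"))
  if (any(t_grid < 0 | t_grid > 1)) stop("`t_grid` must lie in [0, 1]")
  nz <- n_slices(rec$s_t0)
  ji <- valid_slices(rec, 0)$per_slice_ji
  pct <- vapply(t_grid, function(t)
    100 * sum(!is.na(ji) & ji >= t) / nz, numeric(1))
  data.frame(t = t_grid, pct_kept = pct)
}

#' Intra-observer variability baseline
#'
#' The reproducibility of one observer on uncompressed data: the mean
#' per-slice Jaccard index between the two timepoint masks over the valid
#' slices, and the average Hausdorff distance between the two masks with
#' all annotated voxels outside the valid set ignored.
#'
#' @param rec An [observer_record()].
#' @param t Validity threshold (default 0.7).
#' @param use_spacing Scale Hausdorff coordinates by voxel spacing.
#' @return A list: `ji`, `hd`, `validity` (the [valid_slices()] result).
#' @export
iaov <- function(rec, t = 0.7, use_spacing = FALSE) {
  vs <- valid_slices(rec, t)
  if (length(vs$slice_indices) == 0L)
    stop(sprintf("no valid slices at threshold t = %g", t))
  ji <- mean(vs$per_slice_ji[vs$slice_indices])
  m0 <- restrict_slices(rec$s_t0, vs$slice_indices)
  m1 <- restrict_slices(rec$s_t1, vs$slice_indices)
  hd <- average_hausdorff(extract_points(m0, use_spacing),
                          extract_points(m1, use_spacing))
  list(ji = ji, hd = hd, validity = vs)
}

#' Merge an observer's two timepoint masks
#'
#' Voxel-wise logical intersection of `s_t0` and `s_t1`, keeping only the
#' annotations preserved between the two timepoints; the conservative
#' single mask used for inter-observer comparison.
#'
#' @param rec An [observer_record()].
#' @return A [mask_stack()] with provenance `"merge(<id>)"`.
#' @export
merge_timepoints <- function(rec) {
  stopifnot(inherits(rec, "observer_record"))
  mask_stack(rec$s_t0$data & rec$s_t1$data, rec$s_t0$spacing,
             provenance = sprintf("merge(%s)", rec$observer_id))
}

#' Inter-observer variability baseline
#'
#' Agreement between two observers on uncompressed data, computed on the
#' conjunction of their valid-slice sets: each observer's timepoints are
#' merged by intersection, then the mean per-slice Jaccard index of the
#' two merged masks over `V_AB = V_A` \eqn{\cap} `V_B` (slices where the
#' merged-mask index is undefined are excluded from the mean), and the
#' average Hausdorff distance between the merged masks restricted to
#' `V_AB`.
#'
#' @param recA,recB [observer_record()]s aligned to the same volume.
#' @param t Validity threshold (default 0.7).
#' @param use_spacing Scale Hausdorff coordinates by voxel spacing.
#' @return A list: `ji`, `hd`, `validity` (a `validity_set` over `V_AB`),
#'   `n_slices_used`.
#' @export
ieov <- function(recA, recB, t = 0.7, use_spacing = FALSE) {
  stopifnot(inherits(recA, "observer_record"),
            inherits(recB, "observer_record"))
  check_aligned(recA$s_t0, recB$s_t0)
  vA <- valid_slices(recA, t)
  vB <- valid_slices(recB, t)
  v_ab <- intersect(vA$slice_indices, vB$slice_indices)
  if (length(v_ab) == 0L)
    stop(sprintf("V_AB empty at threshold t = %g", t))
  SA <- merge_timepoints(recA)
  SB <- merge_timepoints(recB)
  ji_slices <- vapply(v_ab, function(s)
    jaccard_slice(SA$data[, , s], SB$data[, , s]), numeric(1))
  defined <- !is.na(ji_slices)
  if (!any(defined))
    stop("merged masks empty on every slice of V_AB")
  mA <- restrict_slices(SA, v_ab)
  mB <- restrict_slices(SB, v_ab)
  hd <- if (any(mA$data) && any(mB$data))
    average_hausdorff(extract_points(mA, use_spacing),
                      extract_points(mB, use_spacing))
  else NA_real_
  vs <- structure(
    list(slice_indices = as.integer(sort(v_ab)), threshold_t = t,
         per_slice_ji = NULL),
    class = "validity_set"
  )
  list(ji = mean(ji_slices[defined]), hd = hd, validity = vs,
       n_slices_used = sum(defined))
}

#' Serialize variability baselines as JSON
#'
#' Writes the machine twin of a baseline-variability table:
#' `{IaOV: {JI, HD}, IeOV: {JI, HD}, V sizes, t}`.
#'
#' @param iaov_res Result of [iaov()] (one observer, or a list of them).
#' @param ieov_res Result of [ieov()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_variability_json <- function(iaov_res, ieov_res, path) {
  obj <- list(
    IaOV = list(JI = iaov_res$ji, HD = iaov_res$hd,
                n_valid = length(iaov_res$validity$slice_indices)),
    IeOV = list(JI = ieov_res$ji, HD = ieov_res$hd,
                n_valid = length(ieov_res$validity$slice_indices)),
    t = iaov_res$validity$threshold_t
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
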