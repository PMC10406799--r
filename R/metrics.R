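#' Per-slice Jaccard index
#'
#' `|x & y| / |x | y|` for two aligned 2D binary masks. When both masks are
#' empty the union is zero and the index is undefined; the sentinel
#' `NA_real_` is returned (and such slices are excluded from stack
#' averages).
#'
#' @param x,y 2D logical matrices of equal shape.
#' @return The Jaccard index in `[0, 1]`, or `NA_real_` if undefined.
#' @examples
#' truth <- matrix(FALSE, 1, 2); truth[1, 1:2] <- TRUE
#' ann <- matrix(FALSE, 1, 2); ann[1, 1] <- TRUE
#' jaccard_slice(truth, ann)  # 0.5
#' @export
jaccard_slice <- function(x, y) {
  if (is.numeric(x)) x <- x != 0
  if (is.numeric(y)) y <- y != 0
  if (!identical(dim(x), dim(y)))
    stop("mask shapes differ")
  uni <- sum(x | y)
  if (uni == 0L) return(NA_real_)
  sum(x & y) / uni
}

#' Stack-level agreement report (Jaccard + average Hausdorff)
#'
#' Computes the Jaccard index per slice and averages it arithmetically over
#' the slices where it is defined (union nonempty), optionally restricted
#' to a slice filter. The average Hausdorff distance between the two
#' foreground point sets (restricted to the same slices) is reported
#' alongside, in voxel units, or `NA` when either restricted mask is empty.
#'
#' @param X,Y Aligned [mask_stack()] objects.
#' @param slice_filter Optional integer vector of slice indices to use.
#' @param use_spacing If `TRUE`, Hausdorff distances are computed on
#'   spacing-scaled coordinates (micrometres) instead of voxel indices.
#' @return An `agreement_report`: `per_slice_ji` (named numeric, `NA` for
#'   undefined slices), `stack_ji`, `avg_hd`, `n_slices_used`,
#'   `pair_provenance`.
#' @export
jaccard_stack <- function(X, Y, slice_filter = NULL, use_spacing = FALSE) {
  stopifnot(inherits(X, "mask_stack"), inherits(Y, "mask_stack"))
  check_aligned(X, Y)
  nz <- n_slices(X)
  slices <- if (is.null(slice_filter)) seq_len(nz) else {
    sf <- sort(unique(as.integer(slice_filter)))
    if (any(sf < 1L | sf > nz)) stop("slice_filter outside stack range")
    sf
  }
  ji <- vapply(slices, function(s)
    jaccard_slice(X$data[, , s], Y$data[, , s]), numeric(1))
  names(ji) <- as.character(slices)
  defined <- !is.na(ji)
  if (!any(defined))
    stop("Jaccard index undefined on every selected slice")

  Xr <- restrict_slices(X, slices)
  Yr <- restrict_slices(Y, slices)
  avg_hd <- if (any(Xr$data) && any(Yr$data)) {
    average_hausdorff(extract_points(Xr, use_spacing),
                      extract_points(Yr, use_spacing))
  } else NA_real_

  structure(
    list(per_slice_ji = ji,
         stack_ji = mean(ji[defined]),
         avg_hd = avg_hd,
         n_slices_used = sum(defined),
         pair_provenance = c(X$provenance, Y$provenance)),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "<agreement_report> %s vs %s: stack JI %.4f, avg HD %s (%d slices)\n",
    x$pair_provenance[1], x$pair_provenance[2], x$stack_ji,
    if (is.na(x$avg_hd)) "NA" else sprintf("%.4f", x$avg_hd),
    x$n_slices_used
  ))
  invisible(x)
}

# Zero the foreground outside the given slice indices.
restrict_slices <- function(mask, slices) {
  d <- dim(mask$data)
  keep <- array(FALSE, d)
  keep[, , slices] <- TRUE
  mask_stack(mask$data & keep, mask$spacing, mask$provenance)
}

#' Extract the annotated point set of a mask
#'
#' One point per foreground voxel, at voxel-index coordinates `(y, x, z)`;
#' with `use_spacing = TRUE`, coordinates are multiplied per axis by the
#' voxel spacing, giving micrometre positions (relevant for anisotropic
#' stacks).
#'
#' @param mask A nonempty [mask_stack()].
#' @param use_spacing Scale coordinates by voxel spacing.
#' @return A `point_set`: numeric matrix with columns y, x, z and attribute
#'   `count`.
#' @export
extract_points <- function(mask, use_spacing = FALSE) {
  stopifnot(inherits(mask, "mask_stack"))
  idx <- which(mask$data, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("empty mask: point set (and Hausdorff distance) undefined")
  pts <- matrix(as.numeric(idx), ncol = 3L,
                dimnames = list(NULL, c("y", "x", "z")))
  if (use_spacing)
    pts <- sweep(pts, 2L, mask$spacing, "*")
  structure(pts, count = nrow(pts), class = c("point_set", "matrix"))
}

#' Average Hausdorff distance between two point sets
#'
#' The symmetric mean of directed nearest-neighbour Euclidean distances:
#' `(mean_x min_y d(x, y) + mean_y min_x d(y, x)) / 2`. Distances are exact
#' (kd-tree search); units follow the coordinates of the point sets (voxel
#' indices by default, micrometres if extracted with spacing).
#'
#' @param X,Y Nonempty point matrices (columns y, x, z), as returned by
#'   [extract_points()].
#' @return Non-negative distance; 0 iff the sets coincide.
#' @examples
#' X <- matrix(c(0, 0, 0), 1); Y <- matrix(c(0, 0, 3), 1)
#' average_hausdorff(X, Y)  # 3
#' @export
average_hausdorff <- function(X, Y) {
  X <- unclass(X); Y <- unclass(Y)
  if (!is.matrix(X) || !is.matrix(Y) || nrow(X) == 0L || nrow(Y) == 0L)
    stop("both point sets must be nonempty matrices")
  (mean(nn_dists(X, Y)) + mean(nn_dists(Y, X))) / 2
}

# ---- MS-SSIM ----------------------------------------------------------------

# Standard 5-scale exponent weights of the multi-scale SSIM construction.
MSSSIM_WEIGHTS <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)

gaussian_window <- function(size = 11L, sigma = 1.5) {
  half <- (size - 1L) / 2
  g <- exp(-((-half:half)^2) / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

local_stats <- function(img, w) {
  mu <- EBImage::filter2(img, w, boundary = "replicate")
  mu2 <- EBImage::filter2(img^2, w, boundary = "replicate")
  list(mu = mu, var = mu2 - mu^2)
}

ssim_maps <- function(x, y, w, L, K1 = 0.01, K2 = 0.03) {
  C1 <- (K1 * L)^2
  C2 <- (K2 * L)^2
  sx <- local_stats(x, w)
  sy <- local_stats(y, w)
  mxy <- EBImage::filter2(x * y, w, boundary = "replicate")
  cov <- mxy - sx$mu * sy$mu
  l <- (2 * sx$mu * sy$mu + C1) / (sx$mu^2 + sy$mu^2 + C1)
  cs <- (2 * cov + C2) / (sx$var + sy$var + C2)
  list(l = l, cs = cs)
}

downsample2 <- function(img) {
  d <- dim(img)
  m <- d[1] %/% 2L; n <- d[2] %/% 2L
  img <- img[seq_len(2L * m), seq_len(2L * n), drop = FALSE]
  (img[seq(1L, 2L * m, 2L), seq(1L, 2L * n, 2L)] +
     img[seq(2L, 2L * m, 2L), seq(1L, 2L * n, 2L)] +
     img[seq(1L, 2L * m, 2L), seq(2L, 2L * n, 2L)] +
     img[seq(2L, 2L * m, 2L), seq(2L, 2L * n, 2L)]) / 4
}

upsample_to <- function(img, target_dim) {
  yi <- clip(ceiling(seq_len(target_dim[1]) / (target_dim[1] / nrow(img))),
             1, nrow(img))
  xi <- clip(ceiling(seq_len(target_dim[2]) / (target_dim[2] / ncol(img))),
             1, ncol(img))
  img[yi, xi, drop = FALSE]
}

# Sign-preserving fractional power (the contrast-structure term can be
# slightly negative).
signed_pow <- function(x, p) sign(x) * abs(x)^p

#' Per-pixel multi-scale structural similarity map
#'
#' Local MS-SSIM following the standard multi-scale construction: SSIM
#' contrast-structure maps computed at dyadic scales (2x2 mean
#' downsampling between scales), the luminance term at the coarsest scale
#' only, combined with the standard exponent weights (renormalized when
#' fewer than 5 scales are requested). Coarse-scale maps are upsampled to
#' the original resolution, so the result is a full-resolution map in
#' `(-1, 1]`, together with its mean and standard deviation (the
#' "dispersion" statistic of map-based quality inspection).
#'
#' @param raw_slice,recon_slice 2D numeric matrices of equal shape.
#' @param scales Number of dyadic scales (default 5); the image at the
#'   coarsest scale must still accommodate the 11x11 analysis window.
#' @param bit_depth Bit depth defining the dynamic range `L = 2^bit - 1`.
#' @return A list: `map` (matrix), `mean`, `sd`, `scales`, `weights`,
#'   `window` (description string).
#' @export
ms_ssim_map <- function(raw_slice, recon_slice, scales = 5L,
                        bit_depth = 16L) {
  if (!identical(dim(raw_slice), dim(recon_slice)))
    stop("slice shapes differ")
  scales <- as.integer(scales)
  if (scales < 1L || scales > 5L) stop("`scales` must be between 1 and 5")
  d0 <- dim(raw_slice)
  if (min(d0) %/% 2^(scales - 1L) < 11L)
    stop(sprintf("image too small for %d scales (needs >= %d px per side)",
                 scales, 11L * 2^(scales - 1L)))
  L <- 2^as.integer(bit_depth) - 1
  w <- gaussian_window()
  weights <- MSSSIM_WEIGHTS[seq_len(scales)]
  weights <- weights / sum(weights)

  x <- raw_slice; y <- recon_slice
  map <- matrix(1, d0[1], d0[2])
  for (j in seq_len(scales)) {
    s <- ssim_maps(x, y, w, L)
    term <- if (j == scales) s$l * s$cs else s$cs
    map <- map * upsample_to(signed_pow(term, weights[j]), d0)
    if (j < scales) {
      x <- downsample2(x)
      y <- downsample2(y)
    }
  }
  map <- pmin(map, 1)
  list(map = map, mean = mean(map), sd = stats::sd(map),
       scales = scales, weights = weights,
       window = "gaussian 11x11 sigma 1.5, K1=0.01 K2=0.03, replicate pad")
}
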