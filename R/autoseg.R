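#' Otsu threshold of a volume
#'
#' Computes the global Otsu threshold on the full-volume histogram with
#' `2^bit_depth` bins: the cut maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` over all candidate thresholds. Ties are broken
#' toward the lower threshold (more inclusive foreground). Voxels strictly
#' above the returned threshold are foreground.
#'
#' @param volume A [volume_stack()] with at least two distinct intensities.
#' @return The integer threshold `T`; foreground is `intensity > T`.
#' @export
otsu_threshold <- function(volume) {
  stopifnot(inherits(volume, "volume_stack"))
  nbins <- 2^volume$bit_depth
  v <- as.integer(volume$data)
  if (min(v) == max(v))
    stop("constant volume: no Otsu threshold exists")
  counts <- tabulate(v + 1L, nbins = nbins)
  n <- length(v)
  p <- counts / n
  lv <- 0:(nbins - 1L)
  w0 <- cumsum(p)
  mu_cum <- cumsum(p * lv)
  mu_tot <- mu_cum[nbins]
  # candidate cuts t = 0 .. nbins-2: class0 = {<= t}, class1 = {> t}
  w0 <- w0[-nbins]
  mu_cum <- mu_cum[-nbins]
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, nbins - 1L)
  sigma_b[valid] <- (mu_tot * w0[valid] - mu_cum[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  # which.max returns the first (lowest-threshold) maximizer
  as.integer(which.max(sigma_b) - 1L)
}

#' Automated Otsu segmentation of a volume
#'
#' The automated segmentation branch used for CT-like modalities: labels
#' voxels strictly above the global Otsu threshold as foreground. Fully
#' deterministic; the output provenance is `"auto"`.
#'
#' @param volume A [volume_stack()] with at least two distinct intensities.
#' @return A [mask_stack()] with provenance `"auto"`.
#' @examples
#' ph <- generate_phantom(phantom_config(shape = c(32, 32, 8), seed = 3))
#' m <- otsu_segment(ph$volume)
#' @export
otsu_segment <- function(volume) {
  thr <- otsu_threshold(volume)
  mask_stack(array(volume$data > thr, dim(volume$data)),
             spacing = volume$spacing, provenance = "auto")
}
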