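#' Configuration for a synthetic vascular phantom
#'
#' The phantom emulates the regime of micrometre-resolution preclinical
#' stacks: sparse bright tubular vessels over a low-frequency textured
#' background with additive Gaussian noise, stored as unsigned integers at
#' a given bit depth. Defaults describe a 16-bit, isotropically spaced
#' stack whose vessels are separable from background by Otsu thresholding
#' on the raw data (required by the automated segmentation branch).
#'
#' @param shape Voxels per axis as `c(y, x, z)`; every dimension must be at
#'   least 8.
#' @param voxel_spacing Micrometres per axis, `c(y, x, z)`.
#' @param n_vessels Number of vessels to draw.
#' @param radius_range Tube radius range in voxels (minimum at least 1).
#' @param vessel_intensity_range Vessel intensity as a fraction of the
#'   dynamic range, `c(lo, hi)` in (0, 1].
#' @param background_mean Mean background intensity, intensity units.
#' @param background_texture_amp Standard deviation of the low-frequency
#'   background texture field, intensity units.
#' @param noise_sd Additive Gaussian noise standard deviation, intensity
#'   units.
#' @param bit_depth Bits per voxel (default 16).
#' @param seed Integer seed; identical (config, seed) pairs produce
#'   bit-identical phantoms.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(shape = c(64, 64, 32),
                           voxel_spacing = c(3, 3, 3),
                           n_vessels = 6L,
                           radius_range = c(1.5, 3),
                           vessel_intensity_range = c(0.30, 0.45),
                           background_mean = 12000,
                           background_texture_amp = 1500,
                           noise_sd = 300,
                           bit_depth = 16L,
                           seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop("all phantom dimensions must be >= 8 voxels")
  if (length(radius_range) != 2L || radius_range[1] < 1)
    stop("`radius_range` minimum must be >= 1 voxel")
  if (diff(radius_range) < 0) stop("`radius_range` must be non-decreasing")
  peak <- 2^as.integer(bit_depth) - 1
  if (any(vessel_intensity_range <= 0) || any(vessel_intensity_range > 1))
    stop("`vessel_intensity_range` must lie in (0, 1]")
  if (background_mean < 0 || background_mean > peak)
    stop("`background_mean` outside the dynamic range")
  if (background_texture_amp < 0 || noise_sd < 0)
    stop("texture amplitude and noise sd must be non-negative")
  n_vessels <- as.integer(n_vessels)
  if (n_vessels < 0L) stop("`n_vessels` must be >= 0")
  # a tube of minimum radius must fit inside the volume
  if (any(shape < 2 * ceiling(radius_range[1]) + 1L))
    stop("volume too small to fit a tube of the minimum radius")
  structure(
    list(shape = shape, voxel_spacing = as.numeric(voxel_spacing),
         n_vessels = n_vessels, radius_range = as.numeric(radius_range),
         vessel_intensity_range = as.numeric(vessel_intensity_range),
         background_mean = background_mean,
         background_texture_amp = background_texture_amp,
         noise_sd = noise_sd, bit_depth = as.integer(bit_depth),
         seed = as.integer(seed)),
    class = "phantom_config"
  )
}

#' Rasterize a tube around a 3D centerline
#'
#' Marks every voxel whose centre lies within `radius` (Euclidean, voxel
#' units) of any centerline sample. With sample spacing at most 1 voxel
#' along the path, the union of spheres is a faithful discrete tube.
#'
#' @param centerline Numeric matrix with columns (y, x, z), one row per
#'   sample point, in voxel coordinates.
#' @param radius Tube radius in voxels.
#' @param shape Volume dimensions `c(y, x, z)`.
#' @return 3D logical array of the voxelized tube.
#' @export
rasterize_tube <- function(centerline, radius, shape) {
  stopifnot(is.matrix(centerline), ncol(centerline) == 3L, radius >= 0)
  mask <- array(FALSE, shape)
  r_ceil <- ceiling(radius)
  off <- as.matrix(expand.grid(dy = -r_ceil:r_ceil,
                               dx = -r_ceil:r_ceil,
                               dz = -r_ceil:r_ceil))
  for (i in seq_len(nrow(centerline))) {
    p <- centerline[i, ]
    vox <- cbind(round(p[1]) + off[, 1], round(p[2]) + off[, 2],
                 round(p[3]) + off[, 3])
    keep <- vox[, 1] >= 1 & vox[, 1] <= shape[1] &
      vox[, 2] >= 1 & vox[, 2] <= shape[2] &
      vox[, 3] >= 1 & vox[, 3] <= shape[3]
    vox <- vox[keep, , drop = FALSE]
    if (nrow(vox) == 0L) next
    d2 <- (vox[, 1] - p[1])^2 + (vox[, 2] - p[2])^2 + (vox[, 3] - p[3])^2
    vox <- vox[d2 <= radius^2, , drop = FALSE]
    if (nrow(vox) > 0L) mask[vox] <- TRUE
  }
  mask
}

# A smoothed 3D random walk confined to the volume (reflecting at a margin
# of one tube radius), sampled at unit step length.
random_centerline <- function(shape, radius, n_steps) {
  margin <- pmin(ceiling(radius) + 1, floor(shape / 2))
  lo <- 1 + margin
  hi <- shape - margin
  pos <- lo + stats::runif(3) * pmax(hi - lo, 0)
  dir <- stats::rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  path <- matrix(0, n_steps, 3)
  for (i in seq_len(n_steps)) {
    dir <- dir + 0.25 * stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    pos_new <- pos + dir
    # reflect components that would leave the confined box
    for (a in 1:3) {
      if (pos_new[a] < lo[a] || pos_new[a] > hi[a]) {
        dir[a] <- -dir[a]
        pos_new[a] <- pos[a] + dir[a]
      }
    }
    pos <- clip(pos_new, lo, hi)
    path[i, ] <- pos
  }
  path
}

# Low-frequency 3D texture field with unit sd: white noise smoothed
# slice-wise with a wide Gaussian, then a running mean along z.
texture_field <- function(shape, sigma_xy = 8, z_span = 5L) {
  # gblur's brush must fit inside the slice
  sigma_xy <- min(sigma_xy, max(1, (min(shape[1:2]) - 1) %/% 8))
  field <- array(stats::rnorm(prod(shape)), shape)
  for (s in seq_len(shape[3]))
    field[, , s] <- EBImage::gblur(field[, , s], sigma = sigma_xy)
  if (shape[3] >= z_span) {
    k <- rep(1 / z_span, z_span)
    flat <- matrix(field, nrow = shape[1] * shape[2])
    sm <- t(apply(flat, 1, function(v)
      stats::filter(v, k, sides = 2, circular = TRUE)))
    field <- array(as.numeric(sm), shape)
  }
  field / stats::sd(field)
}

#' Generate a synthetic vascular phantom
#'
#' Draws `n_vessels` curved tubes (smoothed random-walk centerlines with a
#' per-vessel radius and intensity) brighter than a textured background,
#' adds Gaussian noise, and clips/rounds to the configured bit depth. The
#' returned mask is the exact voxelized tube set, before any noise.
#'
#' @param config A [phantom_config()].
#' @return A list with elements `volume` (a [volume_stack()]) and `mask`
#'   (a [mask_stack()] with provenance `"truth"`).
#' @examples
#' ph <- generate_phantom(phantom_config(shape = c(32, 32, 8), seed = 7))
#' sum(ph$mask$data)
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  shape <- config$shape
  peak <- 2^config$bit_depth - 1

  with_local_seed(config$seed, {
    mask <- array(FALSE, shape)
    intensity <- array(0, shape)
    if (config$n_vessels > 0L) {
      n_steps <- max(16L, round(1.5 * max(shape)))
      for (v in seq_len(config$n_vessels)) {
        r <- stats::runif(1, config$radius_range[1], config$radius_range[2])
        val <- peak * stats::runif(1, config$vessel_intensity_range[1],
                                   config$vessel_intensity_range[2])
        cl <- random_centerline(shape, r, n_steps)
        tube <- rasterize_tube(cl, r, shape)
        mask <- mask | tube
        intensity[tube] <- pmax(intensity[tube], val)
      }
    }
    bg <- config$background_mean +
      (if (config$background_texture_amp > 0)
        config$background_texture_amp * texture_field(shape)
       else 0)
    vol <- ifelse(mask, intensity, bg)
    if (config$noise_sd > 0)
      vol <- vol + stats::rnorm(length(vol), sd = config$noise_sd)
    vol <- array(clip(round(vol), 0, peak), shape)

    list(
      volume = volume_stack(vol, config$bit_depth, config$voxel_spacing),
      mask = mask_stack(mask, config$voxel_spacing, provenance = "truth")
    )
  })
}

#' Observer model for simulated manual segmentations
#'
#' Describes how an imperfect human annotator deviates from ground truth:
#' per 2D-slice connected component, a random boundary dilation/erosion
#' whose amplitude is drawn with standard deviation `boundary_jitter_sd`
#' voxels, and dropout of small components (area below `area_threshold`)
#' with probability `dropout_prob_small`. The second timepoint adds
#' `timepoint_drift` extra jitter, so the two timepoint masks of one
#' simulated observer differ in general. With all parameters zero the
#' simulated mask equals ground truth.
#'
#' @param boundary_jitter_sd Jitter amplitude sd, voxels (>= 0).
#' @param dropout_prob_small Probability in `[0, 1]` of omitting a small
#'   component.
#' @param area_threshold Component area (pixels) below which dropout may
#'   apply.
#' @param timepoint_drift Extra jitter sd applied at timepoint 1, voxels.
#' @param seed Integer seed for the observer's random stream.
#' @return An `observer_model` list.
#' @export
observer_model <- function(boundary_jitter_sd = 0.4,
                           dropout_prob_small = 0.3,
                           area_threshold = 5,
                           timepoint_drift = 0.2,
                           seed = 1L) {
  if (boundary_jitter_sd < 0 || timepoint_drift < 0)
    stop("jitter parameters must be >= 0")
  if (dropout_prob_small < 0 || dropout_prob_small > 1)
    stop("`dropout_prob_small` must be in [0, 1]")
  if (area_threshold < 0) stop("`area_threshold` must be >= 0")
  structure(
    list(boundary_jitter_sd = boundary_jitter_sd,
         dropout_prob_small = dropout_prob_small,
         area_threshold = area_threshold,
         timepoint_drift = timepoint_drift,
         seed = as.integer(seed)),
    class = "observer_model"
  )
}

disc_brush <- function(r) {
  EBImage::makeBrush(2L * r + 1L, shape = "disc")
}

#' Simulate one observer's segmentation of a ground-truth mask
#'
#' Applies the observer model per 2D-slice connected component (manual
#' tracing is slice-wise): random boundary dilation (positive jitter draw)
#' or erosion (negative draw) with a disc structuring element of the
#' rounded amplitude, and dropout of small components. Timepoint 1 uses a
#' distinct random substream and adds the drift term to the jitter sd.
#'
#' @param truth A [mask_stack()] aligned to a generated phantom.
#' @param model An [observer_model()].
#' @param timepoint 0 or 1.
#' @param observer_id Label recorded in the output provenance.
#' @return A [mask_stack()] of the simulated annotation.
#' @export
simulate_observer <- function(truth, model, timepoint = 0L,
                              observer_id = "sim") {
  stopifnot(inherits(truth, "mask_stack"), inherits(model, "observer_model"))
  timepoint <- as.integer(timepoint)
  if (!timepoint %in% c(0L, 1L)) stop("`timepoint` must be 0 or 1")
  sd_eff <- model$boundary_jitter_sd +
    if (timepoint == 1L) model$timepoint_drift else 0
  d <- dim(truth$data)

  with_local_seed(model$seed + 97L * timepoint, {
    out <- array(FALSE, d)
    for (s in seq_len(d[3])) {
      sl <- truth$data[, , s]
      if (!any(sl)) next
      lbl <- label_components_8(sl)
      acc <- matrix(FALSE, d[1], d[2])
      for (k in seq_len(max(lbl))) {
        comp <- lbl == k
        area <- sum(comp)
        if (area < model$area_threshold &&
            stats::runif(1) < model$dropout_prob_small) next
        amp <- if (sd_eff > 0) stats::rnorm(1, 0, sd_eff) else 0
        r <- as.integer(round(abs(amp)))
        if (r >= 1L) {
          comp_img <- EBImage::Image(comp * 1)
          comp <- if (amp > 0)
            as.matrix(EBImage::dilate(comp_img, disc_brush(r))) > 0
          else
            as.matrix(EBImage::erode(comp_img, disc_brush(r))) > 0
        }
        acc <- acc | comp
      }
      out[, , s] <- acc
    }
    mask_stack(out, truth$spacing,
               provenance = sprintf("%s/t%d", observer_id, timepoint))
  })
}

#' Build a ladder of compressed copies at controlled PSNR
#'
#' Degrades a volume to each requested global PSNR target using the
#' codec module's slice-independent rate control ([encode_target_psnr()]),
#' achieving each target within ±0.5 dB; an infinite target requests
#' lossless coding. The ladder is returned sorted by decreasing PSNR.
#'
#' @param volume A [volume_stack()].
#' @param target_psnrs Numeric vector of target PSNRs in dB, each within
#'   `range` (infinite entries allowed for lossless rungs).
#' @param range Sanity range for finite targets (default 30-70 dB).
#' @return A list of `compression_result` objects, sorted by decreasing
#'   target PSNR; reconstructed stacks are at `$reconstructed`.
#' @export
make_fixture_ladder <- function(volume, target_psnrs, range = c(30, 70)) {
  stopifnot(inherits(volume, "volume_stack"))
  finite <- is.finite(target_psnrs)
  if (any(target_psnrs[finite] < range[1] | target_psnrs[finite] > range[2]))
    stop(sprintf("finite targets must lie in [%g, %g] dB",
                 range[1], range[2]))
  ord <- order(target_psnrs, decreasing = TRUE)
  lapply(target_psnrs[ord], function(t) encode_target_psnr(volume, t))
}
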