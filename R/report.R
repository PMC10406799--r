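#' Condition group of per-slice agreement values
#'
#' One experimental condition to compare: the per-slice Jaccard index
#' distribution of a (encoder, compression-ratio) condition or of an
#' observer baseline (`"raw-intra"`, `"raw-inter"`), with its summary mean
#' Jaccard index and mean Hausdorff distance.
#'
#' @param label Condition label.
#' @param ji_values Nonempty numeric vector of per-slice Jaccard indices in
#'   `[0, 1]`.
#' @param mean_hd Mean average-Hausdorff distance of the condition
#'   (optional, `NA` allowed).
#' @return A `condition_group`.
#' @export
condition_group <- function(label, ji_values, mean_hd = NA_real_) {
  ji_values <- ji_values[!is.na(ji_values)]
  if (length(ji_values) == 0L) stop("`ji_values` must be nonempty")
  if (any(ji_values < 0 | ji_values > 1))
    stop("Jaccard values must lie in [0, 1]")
  structure(
    list(label = as.character(label), ji_values = as.numeric(ji_values),
         mean_ji = mean(ji_values), mean_hd = mean_hd),
    class = "condition_group"
  )
}

#' Tukey multiple comparison of condition groups
#'
#' All-pairs Tukey honest-significant-difference test (studentized range)
#' on the per-slice Jaccard distributions at the stated confidence level,
#' plus, for every non-baseline group, flags for whether it differs
#' significantly from the intra-observer and the inter-observer baseline
#' distribution. Per-slice values are treated as the statistical units;
#' the returned object carries an explicit caveat that slices are assumed
#' exchangeable/independent.
#'
#' @param groups List of [condition_group()]s (at least 2, each with at
#'   least 2 values).
#' @param confidence Family-wise confidence level (default 0.95).
#' @param intra_label,inter_label Labels identifying the baseline groups
#'   (flags are `NA` when a baseline is absent).
#' @return A list: `table` (data frame of all pairs: `group1`, `group2`,
#'   `diff`, `lwr`, `upr`, `p_adj`, `significant`), `flags` (per
#'   non-baseline group: `differs_from_intra`, `differs_from_inter`),
#'   `confidence`, `caveat`.
#' @export
tukey_compare <- function(groups, confidence = 0.95,
                          intra_label = "raw-intra",
                          inter_label = "raw-inter") {
  if (length(groups) < 2L) stop("need at least 2 groups")
  labels <- vapply(groups, function(g) g$label, character(1))
  if (anyDuplicated(labels)) stop("group labels must be unique")
  sizes <- vapply(groups, function(g) length(g$ji_values), integer(1))
  if (any(sizes < 2L)) stop("every group needs at least 2 values")
  df <- data.frame(
    value = unlist(lapply(groups, function(g) g$ji_values)),
    group = factor(rep(labels, sizes), levels = labels)
  )
  if (stats::var(df$value) == 0 ||
      all(tapply(df$value, df$group, stats::var) == 0 &
            length(unique(df$value)) == 1L))
    stop("degenerate groups: zero variance everywhere")
  fit <- stats::aov(value ~ group, data = df)
  tk <- stats::TukeyHSD(fit, conf.level = confidence)$group
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  # labels themselves may contain "-": recover by matching against the
  # known label set
  split_pair <- function(rn) {
    for (l1 in labels) {
      pre <- paste0(l1, "-")
      rest <- substring(rn, nchar(pre) + 1L)
      if (startsWith(rn, pre) && rest %in% labels) return(c(l1, rest))
    }
    stop("could not parse Tukey pair label: ", rn)
  }
  pm <- t(vapply(rownames(tk), split_pair, character(2)))
  alpha <- 1 - confidence
  table <- data.frame(
    group1 = pm[, 1], group2 = pm[, 2],
    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    p_adj = tk[, "p adj"],
    significant = tk[, "p adj"] < alpha,
    row.names = NULL
  )
  flag_vs <- function(g, baseline) {
    if (!baseline %in% labels || g == baseline) return(NA)
    hit <- (table$group1 == g & table$group2 == baseline) |
      (table$group2 == g & table$group1 == baseline)
    any(table$significant[hit])
  }
  others <- setdiff(labels, c(intra_label, inter_label))
  flags <- data.frame(
    group = others,
    differs_from_intra = vapply(others, flag_vs, logical(1),
                                baseline = intra_label),
    differs_from_inter = vapply(others, flag_vs, logical(1),
                                baseline = inter_label),
    row.names = NULL
  )
  list(table = table, flags = flags, confidence = confidence,
       caveat = paste("per-slice Jaccard values treated as independent",
                      "statistical units"))
}

#' Compression-validity decision for one condition
#'
#' A compressed condition is a *valid compression* when its average
#' performance meets or beats the inter-observer baseline on both metrics:
#' mean Jaccard index at least the baseline's, and mean Hausdorff distance
#' at most the baseline's (smaller distance = better performance). Ties at
#' the baseline count as meeting it and are flagged. The Tukey
#' significance flag versus the inter-observer distribution is reported
#' alongside, not folded into the verdict.
#'
#' @param group A [condition_group()] with a finite `mean_hd`.
#' @param inter_baseline The inter-observer baseline [condition_group()]
#'   (same modality), with finite `mean_hd`.
#' @param tukey_flag Logical (or `NA`): does the group differ significantly
#'   from the inter-observer distribution.
#' @return A list: `decision` (`"valid"` / `"invalid"`), `ji_pass`,
#'   `hd_pass`, `tie` (at either baseline), `tukey_differs_from_inter`.
#' @export
validity_decision <- function(group, inter_baseline, tukey_flag = NA) {
  stopifnot(inherits(group, "condition_group"),
            inherits(inter_baseline, "condition_group"))
  if (!is.finite(inter_baseline$mean_ji) || !is.finite(inter_baseline$mean_hd))
    stop("inter-observer baseline must provide finite mean JI and mean HD")
  if (!is.finite(group$mean_hd))
    stop("group must provide a finite mean HD")
  ji_pass <- group$mean_ji >= inter_baseline$mean_ji
  hd_pass <- group$mean_hd <= inter_baseline$mean_hd
  tie <- (group$mean_ji == inter_baseline$mean_ji) ||
    (group$mean_hd == inter_baseline$mean_hd)
  list(
    decision = if (ji_pass && hd_pass) "valid" else "invalid",
    ji_pass = ji_pass, hd_pass = hd_pass, tie = tie,
    tukey_differs_from_inter = tukey_flag
  )
}

#' Rate-distortion (CR-quality) curve
#'
#' Collects `(compression ratio, achieved PSNR)` points per encoder,
#' sorted by increasing CR, and checks the rate-distortion trade-off
#' (PSNR non-increasing in CR within each encoder).
#'
#' @param results List of `compression_result` objects (at least 2 per
#'   encoder).
#' @return A data frame `encoder`, `control_param`, `cr`, `psnr`, sorted
#'   within encoder by CR, with attribute `monotone` (named logical per
#'   encoder).
#' @export
cr_quality_curve <- function(results) {
  df <- do.call(rbind, lapply(results, function(r) {
    stopifnot(inherits(r, "compression_result"))
    data.frame(encoder = r$encoder_id,
               control_param = as.numeric(r$control_param),
               cr = r$compression_ratio, psnr = r$global_psnr)
  }))
  df <- df[order(df$encoder, df$cr), , drop = FALSE]
  rownames(df) <- NULL
  mono <- tapply(seq_len(nrow(df)), df$encoder, function(ix) {
    if (length(ix) < 2L) return(TRUE)
    all(diff(df$psnr[ix]) <= 0)
  })
  attr(df, "monotone") <- mono
  df
}

#' Segmentation complexity profile of a record
#'
#' Relates per-slice intra-observer agreement to the complexity of the
#' slice content: the number of annotated structures per slice, and the
#' mean annotation area normalized by the slice area (in `[0, 1]`). Fewer
#' but larger structures are easier to segment reproducibly; the binned
#' trends make that visible.
#'
#' @param rec An [observer_record()] (agreement measured between its two
#'   timepoints; covariates from `s_t0`).
#' @param n_bins Number of bins for the trend curves (default 5).
#' @return A list: `per_slice` (data frame `slice`, `ji`, `n_annotations`,
#'   `norm_area`), `trend_n` and `trend_area` (binned mean JI curves).
#' @export
complexity_profile <- function(rec, n_bins = 5L) {
  stopifnot(inherits(rec, "observer_record"))
  d <- dim(rec$s_t0$data)
  slice_area <- d[1] * d[2]
  ji <- valid_slices(rec, 0)$per_slice_ji
  rows <- lapply(seq_len(d[3]), function(s) {
    if (is.na(ji[s])) return(NULL)
    sl <- rec$s_t0$data[, , s]
    lbl <- label_components_8(sl)
    k <- max(lbl)
    mean_area <- if (k > 0) sum(sl) / k else 0
    data.frame(slice = s, ji = ji[s], n_annotations = k,
               norm_area = mean_area / slice_area)
  })
  per_slice <- do.call(rbind, rows)
  if (is.null(per_slice) || nrow(per_slice) == 0L)
    stop("no slices with a defined Jaccard index")
  binned <- function(x) {
    if (length(unique(x)) < 2L)
      return(data.frame(bin_center = mean(x), mean_ji = mean(per_slice$ji)))
    brk <- unique(stats::quantile(x, seq(0, 1, length.out = n_bins + 1L)))
    b <- cut(x, brk, include.lowest = TRUE)
    data.frame(
      bin_center = as.numeric(tapply(x, b, mean)),
      mean_ji = as.numeric(tapply(per_slice$ji, b, mean))
    )
  }
  list(per_slice = per_slice,
       trend_n = binned(per_slice$n_annotations),
       trend_area = binned(per_slice$norm_area))
}

#' Study-level storage-reduction arithmetic
#'
#' For each modality plan, the reduced size is
#' `n_datasets * raw_size_mb / chosen_cr`; the total fold-reduction is the
#' ratio of summed raw to summed reduced sizes (the size-weighted harmonic
#' composition of the per-modality ratios). Display strings round to 2
#' significant figures for GB-scale values and to the nearest integer for
#' MB-scale values; unrounded values are always retained.
#'
#' @param plans A data frame (or list of lists) with columns `modality`,
#'   `n_datasets`, `raw_size_mb` (per dataset), `chosen_cr` (>= 1).
#' @return A list: `per_modality` (data frame with `raw_total_mb`,
#'   `reduced_mb`, `display`), `total_raw_mb`, `total_reduced_mb`,
#'   `fold_reduction`, `display_total`.
#' @examples
#' plans <- data.frame(
#'   modality = c("HREM", "MRI", "CT"),
#'   n_datasets = 10, raw_size_mb = c(51000, 36, 300),
#'   chosen_cr = c(274, 52, 34))
#' storage_reduction(plans)$per_modality
#' @export
storage_reduction <- function(plans) {
  plans <- as.data.frame(plans)
  need <- c("modality", "n_datasets", "raw_size_mb", "chosen_cr")
  if (!all(need %in% names(plans)))
    stop("plans must provide: ", paste(need, collapse = ", "))
  if (any(plans$n_datasets <= 0 | plans$raw_size_mb <= 0))
    stop("sizes and counts must be positive")
  if (any(plans$chosen_cr < 1))
    stop("chosen_cr must be >= 1")
  fmt_size <- function(mb) {
    if (mb >= 1000) sprintf("%s GB", format(signif(mb / 1000, 2)))
    else sprintf("%d MB", round(mb))
  }
  raw_total <- plans$n_datasets * plans$raw_size_mb
  reduced <- raw_total / plans$chosen_cr
  per_modality <- data.frame(
    modality = plans$modality,
    raw_total_mb = raw_total,
    chosen_cr = plans$chosen_cr,
    reduced_mb = reduced,
    display = vapply(reduced, fmt_size, character(1))
  )
  total_raw <- sum(raw_total)
  total_reduced <- sum(reduced)
  list(
    per_modality = per_modality,
    total_raw_mb = total_raw,
    total_reduced_mb = total_reduced,
    fold_reduction = total_raw / total_reduced,
    display_total = sprintf("%s -> %s (%.0f-fold)",
                            fmt_size(total_raw), fmt_size(total_reduced),
                            total_raw / total_reduced)
  )
}

#' Run the full compression audit on a synthetic study
#'
#' Orchestrates the pipeline end to end on a phantom: generate volume and
#' ground truth, simulate two observers at two timepoints, build the
#' compressed ladder, segment every version (Otsu automated branch),
#' compute agreement against the reference mask on the valid slices,
#' observer-variability baselines, the texture audit, the Tukey
#' comparison, and the per-rung validity decisions.
#'
#' @param config A list with optional elements `phantom` (a
#'   [phantom_config()]), `observer_a`, `observer_b` ([observer_model()]s),
#'   `targets` (PSNR ladder, dB), `t` (validity threshold),
#'   `reference` (`"merged"` or `"t0"`: which mask of observer A anchors
#'   compressed comparisons).
#' @return A list bundling every stage's outputs (see element names).
#' @export
run_audit <- function(config = list()) {
  cfg <- utils::modifyList(
    list(phantom = phantom_config(),
         observer_a = observer_model(seed = 11L),
         observer_b = observer_model(seed = 23L),
         targets = c(60, 55, 50, 45),
         t = 0.7,
         reference = "merged"),
    config)

  ph <- generate_phantom(cfg$phantom)
  rec_a <- observer_record(
    "A",
    simulate_observer(ph$mask, cfg$observer_a, 0L, "A"),
    simulate_observer(ph$mask, cfg$observer_a, 1L, "A"))
  rec_b <- observer_record(
    "B",
    simulate_observer(ph$mask, cfg$observer_b, 0L, "B"),
    simulate_observer(ph$mask, cfg$observer_b, 1L, "B"))

  ia <- iaov(rec_a, cfg$t)
  ie <- ieov(rec_a, rec_b, cfg$t)
  vset <- ia$validity$slice_indices

  reference_mask <- if (identical(cfg$reference, "t0")) rec_a$s_t0
  else merge_timepoints(rec_a)

  ladder <- make_fixture_ladder(ph$volume, cfg$targets)
  per_rung <- lapply(ladder, function(res) {
    seg <- otsu_segment(res$reconstructed)
    rep_ <- jaccard_stack(seg, reference_mask, slice_filter = vset)
    list(result = res, segmentation = seg, agreement = rep_)
  })

  groups <- c(
    list(condition_group("raw-intra",
                         ia$validity$per_slice_ji[vset], ia$hd),
         condition_group("raw-inter", {
           sa <- merge_timepoints(rec_a); sb <- merge_timepoints(rec_b)
           v <- ie$validity$slice_indices
           ji <- vapply(v, function(s)
             jaccard_slice(sa$data[, , s], sb$data[, , s]), numeric(1))
           ji[!is.na(ji)]
         }, ie$hd)),
    lapply(per_rung, function(r)
      condition_group(
        sprintf("%s-%gdB-CR%.1f", r$result$encoder_id,
                r$result$control_param, r$result$compression_ratio),
        r$agreement$per_slice_ji[!is.na(r$agreement$per_slice_ji)],
        r$agreement$avg_hd))
  )
  # small studies can leave a group with a single valid slice; such groups
  # cannot enter the Tukey comparison but still get a mean-based decision
  eligible <- vapply(groups, function(g) length(g$ji_values) >= 2L,
                     logical(1))
  tukey <- if (sum(eligible) >= 2L) tukey_compare(groups[eligible]) else NULL
  inter_bl <- groups[[2]]
  decisions <- lapply(seq_along(per_rung), function(i) {
    g <- groups[[i + 2L]]
    fl <- if (!is.null(tukey))
      tukey$flags$differs_from_inter[tukey$flags$group == g$label]
    else logical(0)
    validity_decision(g, inter_bl, if (length(fl)) fl else NA)
  })

  list(
    phantom = ph, records = list(A = rec_a, B = rec_b),
    iaov = ia, ieov = ie,
    ladder = ladder, per_rung = per_rung,
    texture = delta_wtv(ph$volume, ladder, reference_mask),
    cr_curve = cr_quality_curve(ladder),
    tukey = tukey, decisions = decisions,
    config = cfg
  )
}
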