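#' Voxel-wise Spearman correlation between two images
#'
#' Spearman rank correlation of the two images over the voxels of the
#' (intersection) mask, with average ranks for ties. Undefined cases (< 3
#' voxels, or zero variance in either image) return `NA` with a warning.
#'
#' @param a,b grid-compatible `sv_volume`s.
#' @param mask `sv_mask` over which to correlate.
#' @return numeric scalar in `[-1, 1]`, or `NA`.
#' @export
spearman_voxelwise <- function(a, b, mask) {
  stop_if_grid_mismatch(a, b, "images")
  stop_if_grid_mismatch(a, mask, "image and mask")
  sel <- mask$data > 0
  x <- as.numeric(a$data[sel])
  y <- as.numeric(b$data[sel])
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("Spearman correlation undefined (<3 voxels or zero variance)")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Split a ventilation image at a percentile into high/low function masks
#'
#' Computes the percentile (default 66th) of the ventilation values over the
#' mask by linear interpolation between order statistics, then labels voxels
#' strictly above the threshold "high-functioning" and the remainder of the
#' mask "low-functioning". The two outputs always partition the mask.
#'
#' @param v `sv_ventilation` (or `sv_volume`).
#' @param mask nonempty `sv_mask`.
#' @param pct percentile in `[0, 100)` (default 66).
#' @return list with `sv_mask` elements `high` and `low`, plus attributes
#'   `threshold` and `n_boundary` (voxels exactly at the threshold, which go
#'   to `low`).
#' @export
percentile_split <- function(v, mask, pct = 66) {
  stop_if_grid_mismatch(v, mask, "image and mask")
  sel <- mask$data > 0
  if (!any(sel)) stop("mask is empty (no foreground voxel)")
  vals <- as.numeric(v$data[sel])
  thr <- as.numeric(stats::quantile(vals, pct / 100, type = 7, names = FALSE))
  hi <- array(0, dim(v$data))
  hi[sel] <- as.numeric(v$data[sel] > thr)
  lo <- array(0, dim(v$data))
  lo[sel] <- 1 - hi[sel]
  if (sum(hi) == 0) warning("high-function split is empty (constant image?)")
  out <- list(high = binary_mask(hi, v$spacing, v$origin),
              low = binary_mask(lo, v$spacing, v$origin))
  attr(out, "threshold") <- thr
  attr(out, "n_boundary") <- sum(vals == thr)
  out
}

#' Dice similarity coefficient
#'
#' `DSC = 2 |a & b| / (|a| + |b|)`; two empty masks give 1 by convention
#' (message logged).
#'
#' @param a,b grid-compatible `sv_mask`s.
#' @return numeric in `[0, 1]`.
#' @export
dsc <- function(a, b) {
  stop_if_grid_mismatch(a, b, "masks")
  na <- sum(a$data > 0)
  nb <- sum(b$data > 0)
  if (na + nb == 0) {
    message("both masks empty: DSC = 1 by convention")
    return(1.0)
  }
  2 * sum(a$data > 0 & b$data > 0) / (na + nb)
}

#' Evaluate one case against a reference ventilation image
#'
#' Restricts the analysis to the intersection of the CT and reference lung
#' masks, computes the voxel-wise Spearman correlation, splits both images at
#' the 66th percentile of their values over the intersection, and reports the
#' Dice overlap of the high-functioning (`dsc_h`) and low-functioning
#' (`dsc_l`) regions.
#'
#' @param ctvi `sv_ventilation` under evaluation.
#' @param reference reference `sv_ventilation` (e.g. SPECT-like).
#' @param ct_mask,ref_mask `sv_mask`s of the two modalities.
#' @param pct percentile for the function split (default 66).
#' @return one-row data.frame: `spearman`, `dsc_h`, `dsc_l`, `n_voxels`; all
#'   `NA` (with a warning) if the intersection is empty.
#' @export
evaluate_case <- function(ctvi, reference, ct_mask, ref_mask, pct = 66) {
  inter <- suppressWarnings(intersect_masks(ct_mask, ref_mask))
  n <- sum(inter$data)
  if (n == 0) {
    warning("empty mask intersection: case not evaluable")
    return(data.frame(spearman = NA_real_, dsc_h = NA_real_,
                      dsc_l = NA_real_, n_voxels = 0L))
  }
  rho <- spearman_voxelwise(ctvi, reference, inter)
  sa <- percentile_split(ctvi, inter, pct)
  sb <- percentile_split(reference, inter, pct)
  data.frame(spearman = rho,
             dsc_h = dsc(sa$high, sb$high),
             dsc_l = dsc(sa$low, sb$low),
             n_voxels = as.integer(n))
}

#' Cohort summary of per-case metrics
#'
#' @param report data.frame of per-case rows from [evaluate_case()].
#' @return data.frame with mean and SD per metric.
#' @export
summarize_cohort <- function(report) {
  metrics <- intersect(c("spearman", "spearman_supervoxel", "dsc_h", "dsc_l"),
                       names(report))
  data.frame(metric = metrics,
             mean = vapply(metrics, function(m)
               mean(report[[m]], na.rm = TRUE), numeric(1)),
             sd = vapply(metrics, function(m)
               stats::sd(report[[m]], na.rm = TRUE), numeric(1)),
             row.names = NULL)
}

#' Super-voxel-number sweep
#'
#' Re-runs the super-voxel pipeline on each case at several requested
#' super-voxel counts `K_init` and reports, per `K_init`: the mean extracted
#' count `K_final`, the mean super-voxel-level Spearman correlation between
#' mean density and mean reference ventilation (`corr_dmean_vent`), the mean
#' voxel-wise correlation of the resulting ventilation image with the
#' reference (`corr_ctvi_ref`), and two-sided paired t-test p-values of the
#' per-case correlations at each `K_init` against the reference `K_init`
#' (`NA` on the reference row; 1 when all paired differences are zero).
#'
#' @param cases list of cases; each a list with elements `ct` (`sv_volume`,
#'   already preprocessed or raw HU), `mask` (`sv_mask`) and `reference`
#'   (`sv_volume` ventilation reference on the same grid).
#' @param k_values integer vector of `K_init` values.
#' @param reference_k the comparison `K_init` (default 1500).
#' @param slic base [slic_params()]; `k_init` is overridden per sweep point.
#' @param ... further arguments passed to [run_ctvi_svd()] (e.g.
#'   `target_spacing_mm = NULL` when cases are pre-resampled).
#' @return data.frame of class `sv_sweep` with one row per `K_init`.
#' @export
sweep_k <- function(cases, k_values = c(300L, 500L, 800L, 1000L, 1500L,
                                        2000L, 2500L, 3000L, 4000L, 8000L,
                                        12000L, 15000L),
                    reference_k = 1500L, slic = slic_params(), ...) {
  if (length(cases) < 1) stop("need at least one case")
  k_values <- as.integer(k_values)
  if (!reference_k %in% k_values)
    stop("reference_k must be among k_values")
  per_case <- function(k) {
    rows <- lapply(cases, function(cs) {
      p <- slic
      p$k_init <- as.integer(k)
      p$min_size_voxels <- NULL
      vi <- run_ctvi_svd(cs$ct, cs$mask, slic = p, ...)
      svm <- attr(vi, "svm")
      svm <- compute_label_stats(svm, cs$reference, "Vent_mean")
      corr_sv <- if (svm$k_final >= 3 &&
                     stats::sd(svm$stats$D_mean) > 0 &&
                     stats::sd(svm$stats$Vent_mean) > 0)
        stats::cor(svm$stats$D_mean, svm$stats$Vent_mean,
                   method = "spearman") else NA_real_
      corr_vox <- spearman_voxelwise(vi, cs$reference, cs$mask)
      data.frame(k_final = svm$k_final, corr_sv = corr_sv,
                 corr_vox = corr_vox)
    })
    do.call(rbind, rows)
  }
  by_k <- lapply(k_values, per_case)
  names(by_k) <- as.character(k_values)
  ref <- by_k[[as.character(reference_k)]]
  paired_p <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 2) return(NA_real_)
    d <- x[ok] - y[ok]
    # zero-variance differences (e.g. duplicated cases): test uninformative
    if (stats::sd(d) == 0) return(1.0)
    stats::t.test(x[ok], y[ok], paired = TRUE)$p.value
  }
  rows <- lapply(seq_along(k_values), function(t) {
    b <- by_k[[t]]
    is_ref <- k_values[t] == reference_k
    data.frame(
      k_init = k_values[t],
      k_final = mean(b$k_final),
      corr_dmean_vent = mean(b$corr_sv, na.rm = TRUE),
      p_dmean_vent = if (is_ref) NA_real_ else paired_p(b$corr_sv,
                                                        ref$corr_sv),
      corr_ctvi_ref = mean(b$corr_vox, na.rm = TRUE),
      p_ctvi_ref = if (is_ref) NA_real_ else paired_p(b$corr_vox,
                                                      ref$corr_vox))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sv_sweep", "data.frame")
  attr(out, "reference_k") <- reference_k
  attr(out, "per_case") <- by_k
  out
}
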