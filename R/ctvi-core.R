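#' Convert Hounsfield units to tissue density
#'
#' Voxelwise affine conversion `density = (HU + 1000) / 1000`, so air
#' (-1000 HU) maps to 0 and water (0 HU) to 1. The super-voxel density gate
#' of 0.6 corresponds to -400 HU, the conventional upper bound of the lung
#' parenchyma window.
#'
#' @param v `sv_volume` of HU values.
#' @return `sv_volume` of densities.
#' @export
hu_to_density <- function(v) {
  volume((v$data + 1000) / 1000, v$spacing, v$origin)
}

#' Gate high-density super-voxels
#'
#' Super-voxels whose mean density `D_mean` exceeds the threshold (strictly
#' greater than 0.6 by default, i.e. denser than -400 HU) are consolidation,
#' tumour or other abnormal tissue: dense regions that cannot ventilate.
#' Their source ventilation value is set to 0 but they remain interpolation
#' sources, so neighbouring super-voxels cannot bleed high values into the
#' gated region. All other super-voxels keep `D_mean` as their source value.
#'
#' @param svm `sv_supervoxel_map` with `D_mean` computed on the
#'   density-converted CT (see [compute_label_stats()]).
#' @param threshold density gate (default 0.6); values strictly above are
#'   zeroed.
#' @return `svm` with `source_value` and logical `gated` columns in `stats`.
#' @export
gate_supervoxels <- function(svm, threshold = 0.6) {
  if (is.null(svm$stats$D_mean))
    stop("D_mean not computed; call compute_label_stats() first")
  gated <- svm$stats$D_mean > threshold
  svm$stats$gated <- gated
  svm$stats$source_value <- ifelse(gated, 0, svm$stats$D_mean)
  svm
}

#' Ventilation image constructor
#'
#' An `sv_volume` tagged with the method that produced it. Values are finite
#' inside the lung mask and 0 outside.
#'
#' @param v `sv_volume`.
#' @param provenance one of `"SVD"`, `"HU"`, `"Jac"`, `"SVHU"`, `"SVJac"`,
#'   `"VI_SV"`, `"reference"`.
#' @return `sv_ventilation` object.
#' @export
ventilation_image <- function(v, provenance = "SVD") {
  provenance <- match.arg(provenance,
                          c("SVD", "HU", "Jac", "SVHU", "SVJac", "VI_SV",
                            "reference"))
  structure(list(data = v$data, spacing = v$spacing, origin = v$origin,
                 provenance = provenance),
            class = c("sv_ventilation", "sv_volume"))
}

#' Split a lung mask into left and right lungs
#'
#' Takes the two largest 26-connected components as the lungs, assigning
#' laterality by centroid position along the x (laterality) axis; any smaller
#' extra components are attached to the nearer lung. A fused single-component
#' mask is split by the sagittal plane through its centroid (logged via
#' `message`).
#'
#' @param mask nonempty `sv_mask`.
#' @return list with `sv_mask` elements `left` and `right`.
#' @export
split_lungs <- function(mask) {
  if (sum(mask$data) == 0) stop("mask is empty (no foreground voxel)")
  dm <- dim(mask$data)
  comp <- array(cpp_label_components(as.integer(mask$data > 0), dm), dm)
  ncomp <- max(comp)
  sel <- which(comp > 0)
  ijk <- flat_to_ijk(sel, dm)
  world <- index_to_world(mask, ijk)
  cid <- comp[sel]
  sizes <- tabulate(cid, nbins = ncomp)
  if (ncomp == 1L) {
    message("single lung component: splitting at the sagittal centroid plane")
    cx <- mean(world[, 1])
    left_sel <- world[, 1] <= cx
    assign_side <- ifelse(left_sel, 1L, 2L)
    if (all(left_sel) || !any(left_sel)) {
      # degenerate mask thinner than one voxel column: split on median index
      med <- stats::median(ijk[, 1])
      assign_side <- ifelse(ijk[, 1] <= med, 1L, 2L)
    }
  } else {
    main <- order(sizes, decreasing = TRUE)[1:2]
    cx <- vapply(main, function(c) mean(world[cid == c, 1]), numeric(1))
    left_comp <- main[which.min(cx)]   # smaller x = left by convention
    right_comp <- main[which.max(cx)]
    ctr <- rbind(colMeans(world[cid == left_comp, , drop = FALSE]),
                 colMeans(world[cid == right_comp, , drop = FALSE]))
    assign_side <- integer(length(sel))
    assign_side[cid == left_comp] <- 1L
    assign_side[cid == right_comp] <- 2L
    rest <- assign_side == 0L
    if (any(rest)) {
      d1 <- rowSums(sweep(world[rest, , drop = FALSE], 2, ctr[1, ])^2)
      d2 <- rowSums(sweep(world[rest, , drop = FALSE], 2, ctr[2, ])^2)
      assign_side[rest] <- ifelse(d1 <= d2, 1L, 2L)
    }
  }
  mk <- function(side) {
    a <- array(0, dm)
    a[sel[assign_side == side]] <- 1
    binary_mask(a, mask$spacing, mask$origin)
  }
  list(left = mk(1L), right = mk(2L))
}

# Assign each super-voxel to the lung side holding the majority of its
# voxels; returns integer side id per label (1 = first side, 2 = second).
label_sides <- function(svm, sides) {
  sel <- which(svm$labels > 0)
  lab <- as.integer(svm$labels[sel])
  k <- svm$k_final
  in1 <- rowsum(as.numeric(sides[[1]]$data[sel]), lab, reorder = TRUE)
  cnt <- tabulate(lab, nbins = k)
  ifelse(as.numeric(in1) / cnt >= 0.5, 1L, 2L)
}

#' Build Gaussian interpolation weights for one lung side
#'
#' For every voxel `i` of the side mask and every ipsilateral super-voxel
#' centre `j`, the raw weight is `w_ij = exp(-(r_ij / r_mean)^2)` with
#' `r_ij` the voxel-to-centre distance in mm and `r_mean` the mean
#' nearest-neighbour centre distance among the side's super-voxels. Rows are
#' normalised to sum to 1, which makes the interpolation exact on constant
#' fields and independent of the super-voxel count.
#'
#' @param svm `sv_supervoxel_map` with centres computed
#'   ([compute_label_stats()]).
#' @param mask_side `sv_mask` for one lung.
#' @param labels integer ids of the side's super-voxels; defaults to every
#'   label whose centre lies inside `mask_side`'s voxels by majority.
#' @return object of class `sv_weights`: normalised weight matrix `W`
#'   (voxels x labels), flat voxel indices, label ids and the side `r_mean`.
#' @export
build_weights <- function(svm, mask_side, labels = NULL) {
  if (is.null(svm$stats$cx))
    stop("geometric centres not computed; call compute_label_stats() first")
  if (is.null(labels)) {
    labels <- which(label_sides(svm, list(mask_side, mask_side)) == 1L)
  }
  if (length(labels) == 0L) {
    warning("no ipsilateral super-voxels on this side: using all labels")
    labels <- svm$stats$label
  }
  vox <- which(mask_side$data > 0)
  ijk <- flat_to_ijk(vox, dim(mask_side$data))
  world <- index_to_world(mask_side, ijk)
  ctr <- as.matrix(svm$stats[labels, c("cx", "cy", "cz"), drop = FALSE])
  if (length(labels) < 2L) {
    warning("single super-voxel on this lung side: constant interpolation")
    W <- matrix(1, nrow = length(vox), ncol = 1)
    return(structure(list(W = W, voxels = vox, labels = labels,
                          r_mean = NA_real_), class = "sv_weights"))
  }
  r_mean <- mean_nn_distance(ctr)
  d2 <- outer(rowSums(world^2), rep(1, nrow(ctr))) +
    outer(rep(1, nrow(world)), rowSums(ctr^2)) -
    2 * world %*% t(ctr)
  d2[d2 < 0] <- 0
  W <- exp(-d2 / r_mean^2)
  W <- W / rowSums(W)
  structure(list(W = W, voxels = vox, labels = labels, r_mean = r_mean),
            class = "sv_weights")
}

#' Interpolate super-voxel values to a whole-lung ventilation image
#'
#' Evaluates `V = W V_sup` per lung side: each voxel's ventilation is the
#' normalised Gaussian-weighted combination of the ipsilateral super-voxel
#' source values. Voxels outside the mask are 0.
#'
#' @param svm `sv_supervoxel_map` whose `stats` carry the source values.
#' @param weights list of `sv_weights`, one per lung side.
#' @param mask full lung `sv_mask` (grid reference).
#' @param values per-label source values; defaults to `stats$source_value`
#'   (gated mean density, see [gate_supervoxels()]).
#' @param provenance tag for the output image.
#' @return `sv_ventilation`.
#' @export
interpolate_ventilation <- function(svm, weights, mask, values = NULL,
                                    provenance = "SVD") {
  if (!identical(dim(svm$labels), dim(mask$data)))
    stop("mask is not grid-compatible with the label map")
  if (is.null(values)) values <- svm$stats$source_value
  if (is.null(values))
    stop("no source values; call gate_supervoxels() or pass `values`")
  out <- array(0, dim(mask$data))
  for (w in weights) {
    out[w$voxels] <- as.numeric(w$W %*% values[w$labels])
  }
  ventilation_image(volume(out, mask$spacing, mask$origin), provenance)
}

#' Mask-aware Gaussian smoothing
#'
#' Final smoothing of a ventilation image with a 3D Gaussian kernel of
#' half-width `kernel_voxels` (default 3) and standard deviation
#' `sigma_voxels` (default 1). Smoothing is renormalised by the smoothed mask
#' (`smooth(v * m) / smooth(m)` inside the mask) so lung-border values are
#' not diluted by the zeros outside; constant fields are preserved exactly.
#'
#' @param v `sv_ventilation` (or any `sv_volume`).
#' @param mask `sv_mask`; smoothing support and output support.
#' @param kernel_voxels positive integer kernel half-width (voxels).
#' @param sigma_voxels Gaussian standard deviation (voxels).
#' @return smoothed `sv_ventilation`.
#' @export
smooth_ventilation <- function(v, mask, kernel_voxels = 3L,
                               sigma_voxels = 1.0) {
  kernel_voxels <- as.integer(kernel_voxels)
  if (is.na(kernel_voxels) || kernel_voxels < 1L)
    stop("kernel size must be a positive integer")
  if (!is.numeric(sigma_voxels) || sigma_voxels <= 0)
    stop("sigma must be positive")
  stop_if_grid_mismatch(v, mask, "image and mask")
  dm <- dim(v$data)
  m <- as.numeric(mask$data > 0)
  num <- cpp_gauss_smooth(as.numeric(v$data) * m, dm, sigma_voxels,
                          kernel_voxels)
  den <- cpp_gauss_smooth(m, dm, sigma_voxels, kernel_voxels)
  out <- array(0, dm)
  sel <- m > 0 & den > 0
  out[sel] <- num[sel] / den[sel]
  prov <- if (inherits(v, "sv_ventilation")) v$provenance else "SVD"
  ventilation_image(volume(out, v$spacing, v$origin), prov)
}

#' Manual defect correction
#'
#' Overrides the ventilation values inside a manually contoured defect mask
#' with a fixed low value (default 0). Intended to be applied to the
#' pre-smoothing interpolation result, after which smoothing is re-run (the
#' [run_ctvi_svd()] pipeline does this when given a `defect_mask`).
#'
#' @param v `sv_ventilation`.
#' @param defect_mask grid-compatible `sv_mask` of the defect region.
#' @param value replacement value (default 0).
#' @return corrected `sv_ventilation`.
#' @export
manual_defect_correction <- function(v, defect_mask, value = 0) {
  stop_if_grid_mismatch(v, defect_mask, "image and defect mask")
  out <- v$data
  out[defect_mask$data > 0] <- value
  ventilation_image(volume(out, v$spacing, v$origin),
                    if (inherits(v, "sv_ventilation")) v$provenance else "SVD")
}

#' CTVI_SVD pipeline: ventilation image from a single exhale CT
#'
#' Composes the full single-CT ventilation pipeline: isotropic resampling
#' (2 mm), 5-voxel median denoising, SLIC super-voxel segmentation inside the
#' lung mask, per-super-voxel mean density (`D_mean`) on the HU-to-density
#' converted CT, density gating at 0.6, per-lung Gaussian-distance
#' interpolation of the gated values from the super-voxel geometric centres,
#' optional manual defect correction, and mask-aware Gaussian smoothing. The
#' pipeline is deterministic: identical inputs give bit-identical output.
#'
#' @param ct_ex exhale-phase CT `sv_volume` (HU).
#' @param mask lung `sv_mask` on the same grid.
#' @param slic [slic_params()].
#' @param target_spacing_mm isotropic working spacing (mm); `NULL` skips
#'   resampling.
#' @param median_window median filter window (voxels); `NULL` or 1 skips
#'   denoising.
#' @param gate density gate threshold (default 0.6).
#' @param kernel_voxels,sigma_voxels final Gaussian smoothing parameters.
#' @param defect_mask optional `sv_mask` (on the working grid) of manually
#'   contoured defects set to `defect_value` before smoothing.
#' @param defect_value value assigned inside `defect_mask`.
#' @return `sv_ventilation` with attributes `svm` (the super-voxel map,
#'   gated), `weights` (per-side `sv_weights`) and `log` (run parameters,
#'   `k_final`, per-side `r_mean`).
#' @export
run_ctvi_svd <- function(ct_ex, mask, slic = slic_params(),
                         target_spacing_mm = 2.0, median_window = 5L,
                         gate = 0.6, kernel_voxels = 3L, sigma_voxels = 1.0,
                         defect_mask = NULL, defect_value = 0) {
  stop_if_grid_mismatch(ct_ex, mask, "ct and mask")
  if (sum(mask$data) == 0) stop("mask is empty (no foreground voxel)")
  if (!is.null(target_spacing_mm)) {
    ct_ex <- resample_isotropic(ct_ex, target_spacing_mm)
    mask <- resample_isotropic(mask, target_spacing_mm)
    if (!is.null(defect_mask))
      defect_mask <- resample_isotropic(defect_mask, target_spacing_mm)
  }
  if (!is.null(median_window) && median_window > 1L)
    ct_ex <- median_denoise(ct_ex, median_window, mask = mask)
  svm <- slic_supervoxels(ct_ex, mask, slic)
  svm <- compute_label_stats(svm, hu_to_density(ct_ex), "D_mean")
  svm <- gate_supervoxels(svm, gate)
  sides <- split_lungs(mask)
  side_of <- label_sides(svm, sides)
  weights <- list(
    left = build_weights(svm, sides$left, labels = which(side_of == 1L)),
    right = build_weights(svm, sides$right, labels = which(side_of == 2L)))
  weights <- Filter(function(w) length(w$voxels) > 0, weights)
  vi <- interpolate_ventilation(svm, weights, mask, provenance = "SVD")
  if (!is.null(defect_mask))
    vi <- manual_defect_correction(vi, defect_mask, defect_value)
  vi <- smooth_ventilation(vi, mask, kernel_voxels, sigma_voxels)
  attr(vi, "svm") <- svm
  attr(vi, "weights") <- weights
  attr(vi, "log") <- list(k_init = slic$k_init, k_final = svm$k_final,
                          gate = gate,
                          r_mean = vapply(weights, function(w) w$r_mean,
                                          numeric(1)),
                          target_spacing_mm = target_spacing_mm,
                          median_window = median_window,
                          kernel_voxels = kernel_voxels,
                          sigma_voxels = sigma_voxels)
  vi
}
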