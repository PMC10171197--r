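#' Deformation field constructor
#'
#' Per-voxel displacement vectors in mm on the exhale grid, 4D array
#' `[x, y, z, component]` with the convention `x' = x + u(x)` in world mm:
#' the field maps each exhale voxel to its inhale position, and the inhale
#' volume is sampled there (pull-back).
#'
#' @param u numeric 4D array, last dimension 3 (mm displacements).
#' @param spacing,origin grid geometry as in [volume()].
#' @return `sv_dvf` object.
#' @export
deformation_field <- function(u, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(u) || length(dim(u)) != 4L || dim(u)[4] != 3L)
    stop("deformation field must be a 4D array with 3 components")
  if (anyNA(u) || any(!is.finite(u)))
    stop("all displacement components must be finite")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (mm)")
  structure(list(u = u, spacing = spacing, origin = origin,
                 convention = "x' = x + u(x), mm, pull-back"),
            class = "sv_dvf")
}

#' @export
print.sv_dvf <- function(x, ...) {
  d <- dim(x$u)
  cat(sprintf("<sv_dvf> %d x %d x %d, |u| in [%.3g, %.3g] mm (%s)\n",
              d[1], d[2], d[3],
              sqrt(min(rowSums(matrix(x$u, ncol = 3)^2))),
              sqrt(max(rowSums(matrix(x$u, ncol = 3)^2))), x$convention))
  invisible(x)
}

#' HU density-change ventilation (CTVI_HU)
#'
#' For each exhale voxel `x`, samples the inhale CT at the deformed position
#' `x' = x + u(x)` (trilinear) and computes the specific air-volume change
#' `Vent(x) = -1000 (HU_ex(x) - HU_in(x')) / (HU_ex(x) (HU_in(x') + 1000))`.
#' Voxels whose denominator magnitude falls below `eps` (air-like inhale
#' values or zero exhale HU) are set to 0 and counted; positions mapped
#' outside the inhale volume use the nearest border value and are counted as
#' out-of-volume.
#'
#' @param ct_ex,ct_in exhale / inhale CT `sv_volume`s (HU).
#' @param dvf `sv_dvf` on the exhale grid.
#' @param mask exhale lung `sv_mask`.
#' @param eps denominator guard in HU^2 units (default 1e-6).
#' @return `sv_ventilation` (provenance `"HU"`) with attribute `counts`
#'   (`n_guarded`, `n_out_of_volume`).
#' @export
ctvi_hu <- function(ct_ex, ct_in, dvf, mask, eps = 1e-6) {
  stop_if_grid_mismatch(ct_ex, mask, "exhale ct and mask")
  if (!identical(dim(ct_ex$data), dim(dvf$u)[1:3]))
    stop("deformation field is not on the exhale grid")
  sel <- which(mask$data > 0)
  ijk <- flat_to_ijk(sel, dim(ct_ex$data))
  world <- index_to_world(ct_ex, ijk)
  u <- matrix(c(dvf$u[, , , 1][sel], dvf$u[, , , 2][sel], dvf$u[, , , 3][sel]),
              ncol = 3)
  pts0 <- world_to_index0(ct_in, world + u)
  smp <- cpp_sample_trilinear(as.numeric(ct_in$data), dim(ct_in$data), pts0)
  hu_ex <- as.numeric(ct_ex$data[sel])
  hu_in <- smp$values
  den <- hu_ex * (hu_in + 1000)
  guarded <- abs(den) < eps
  vent <- numeric(length(sel))
  ok <- !guarded
  vent[ok] <- -1000 * (hu_ex[ok] - hu_in[ok]) / den[ok]
  out <- array(0, dim(ct_ex$data))
  out[sel] <- vent
  vi <- ventilation_image(volume(out, ct_ex$spacing, ct_ex$origin), "HU")
  attr(vi, "counts") <- list(n_guarded = sum(guarded),
                             n_out_of_volume = sum(smp$oob))
  vi
}

#' Jacobian-determinant ventilation (CTVI_Jac)
#'
#' Local volume change of the transform `x + u(x)`:
#' `Vent(x) = det(I + grad u(x)) - 1`, with displacement gradients from
#' central differences in mm (one-sided at the volume boundary). A zero field
#' or pure translation gives 0 everywhere; a uniform 10% one-axis stretch
#' gives 0.1 in the interior.
#'
#' @param dvf `sv_dvf` on the exhale grid.
#' @param mask exhale lung `sv_mask`.
#' @return `sv_ventilation` (provenance `"Jac"`).
#' @export
ctvi_jac <- function(dvf, mask) {
  if (!identical(dim(mask$data), dim(dvf$u)[1:3]))
    stop("deformation field is not on the mask grid")
  dm <- dim(mask$data)
  det1 <- cpp_jacobian_det(as.numeric(dvf$u[, , , 1]),
                           as.numeric(dvf$u[, , , 2]),
                           as.numeric(dvf$u[, , , 3]),
                           dm, dvf$spacing)
  out <- array(det1, dm)
  out[mask$data == 0] <- 0
  ventilation_image(volume(out, mask$spacing, mask$origin), "Jac")
}

#' Super-voxel averaging of a ventilation image
#'
#' Replaces a voxelwise ventilation image by its super-voxel reconstruction:
#' the per-super-voxel mean (`Vent_mean`) is interpolated back to every lung
#' voxel from the super-voxel geometric centres with the same per-lung
#' Gaussian-distance interpolation and mask-aware smoothing as the CTVI_SVD
#' pipeline. No density gate is applied — the inputs are already ventilation
#' values. Applied to the deformation-based images this yields the SVHU and
#' SVJac variants; applied to a reference (SPECT-like) image it yields
#' VI_SV, the super-voxel-level upper bound.
#'
#' @param v `sv_ventilation` (or any grid-compatible `sv_volume`).
#' @param svm `sv_supervoxel_map` on the same grid.
#' @param mask lung `sv_mask`.
#' @param provenance tag for the output (`"SVHU"`, `"SVJac"`, `"VI_SV"`);
#'   default derives from `v$provenance`.
#' @param kernel_voxels,sigma_voxels smoothing parameters as in
#'   [smooth_ventilation()].
#' @return `sv_ventilation`.
#' @export
supervoxel_average <- function(v, svm, mask, provenance = NULL,
                               kernel_voxels = 3L, sigma_voxels = 1.0) {
  if (!identical(dim(svm$labels), dim(v$data)))
    stop("image is not grid-compatible with the label map")
  if (is.null(provenance)) {
    pv <- if (inherits(v, "sv_ventilation")) v$provenance else "reference"
    provenance <- switch(pv, HU = "SVHU", Jac = "SVJac", "VI_SV")
  }
  svm <- compute_label_stats(svm, v, "Vent_mean")
  sides <- split_lungs(mask)
  side_of <- label_sides(svm, sides)
  weights <- list(
    left = build_weights(svm, sides$left, labels = which(side_of == 1L)),
    right = build_weights(svm, sides$right, labels = which(side_of == 2L)))
  weights <- Filter(function(w) length(w$voxels) > 0, weights)
  vi <- interpolate_ventilation(svm, weights, mask,
                                values = svm$stats$Vent_mean,
                                provenance = provenance)
  smooth_ventilation(vi, mask, kernel_voxels, sigma_voxels)
}
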