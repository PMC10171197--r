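#' Resample a volume to isotropic spacing
#'
#' Resamples onto an isotropic grid (default 2 mm) sharing the input origin.
#' Intensity volumes are interpolated trilinearly; masks use nearest-neighbour
#' sampling and are re-binarized, so mask values stay in {0, 1}. The world
#' extent is preserved to within one voxel. A volume already at the target
#' spacing is returned unchanged.
#'
#' @param v an `sv_volume` or `sv_mask`.
#' @param target_spacing_mm target isotropic spacing in mm (default 2).
#' @param is_mask force mask (nearest-neighbour) semantics; defaults to the
#'   class of `v`.
#' @return resampled volume of the same class.
#' @export
resample_isotropic <- function(v, target_spacing_mm = 2.0,
                               is_mask = inherits(v, "sv_mask")) {
  if (!is.numeric(target_spacing_mm) || length(target_spacing_mm) != 1L ||
      !is.finite(target_spacing_mm) || target_spacing_mm <= 0)
    stop("target spacing must be a single positive number (mm)")
  if (all(abs(v$spacing - target_spacing_mm) < 1e-9)) return(v)
  dm <- dim(v$data)
  n_new <- pmax(1L, as.integer(ceiling((dm - 1L) * v$spacing /
                                         target_spacing_mm)) + 1L)
  grid <- expand.grid(i = seq_len(n_new[1]), j = seq_len(n_new[2]),
                      k = seq_len(n_new[3]))
  world <- sweep(sweep(as.matrix(grid) - 1, 2,
                       rep(target_spacing_mm, 3), "*"), 2, v$origin, "+")
  pts0 <- world_to_index0(v, world)
  if (is_mask) {
    vals <- cpp_sample_nearest(as.numeric(v$data), dim(v$data), pts0)
    binary_mask(array(vals, n_new), spacing = rep(target_spacing_mm, 3),
                origin = v$origin)
  } else {
    res <- cpp_sample_trilinear(as.numeric(v$data), dim(v$data), pts0)
    volume(array(res$values, n_new), spacing = rep(target_spacing_mm, 3),
           origin = v$origin)
  }
}

#' 3D median denoising
#'
#' Applies a cubic 3D median filter (default 5x5x5 voxels) with
#' nearest-replication at the volume edges, the standard pre-step before
#' super-voxel segmentation of lung CT. The filter is idempotent on constant
#' volumes and a window of 1 is the identity.
#'
#' When a `mask` is given, windows centred on in-mask voxels pool only
#' in-mask values, so the background cannot bleed across the lung border into
#' the density statistics; out-of-mask centres use the plain window.
#'
#' @param v an `sv_volume`.
#' @param window_voxels odd window side length in voxels (default 5).
#' @param mask optional grid-compatible `sv_mask` restricting the window
#'   support at the mask border.
#' @return denoised volume.
#' @export
median_denoise <- function(v, window_voxels = 5L, mask = NULL) {
  window_voxels <- as.integer(window_voxels)
  if (is.na(window_voxels) || window_voxels < 1L ||
      window_voxels %% 2L == 0L)
    stop("median window must be an odd integer >= 1")
  if (window_voxels == 1L) return(v)
  if (!is.null(mask)) stop_if_grid_mismatch(v, mask, "volume and mask")
  mk <- if (is.null(mask)) integer(length(v$data))
        else as.integer(mask$data > 0)
  out <- cpp_median_filter(as.numeric(v$data), dim(v$data), window_voxels,
                           mk, !is.null(mask))
  volume(array(out, dim(v$data)), v$spacing, v$origin)
}

#' Intersect two binary masks
#'
#' Voxelwise AND of two grid-compatible masks, used to restrict evaluation to
#' the region covered by both the CT and the reference lung masks.
#'
#' @param a,b `sv_mask` objects on the same grid.
#' @return `sv_mask` of the intersection; a warning is raised if it is empty.
#' @export
intersect_masks <- function(a, b) {
  stop_if_grid_mismatch(a, b, "masks")
  out <- binary_mask(a$data * b$data, a$spacing, a$origin)
  if (sum(out$data) == 0) warning("mask intersection is empty")
  out
}
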