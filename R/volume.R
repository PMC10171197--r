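#' Construct a Volume
#'
#' A `Volume` is a scalar 3D grid with physical geometry: a numeric array
#' indexed `[x, y, z]` plus voxel spacing and world origin in millimetres.
#' The axis convention used throughout the package is: axis 1 = x
#' (left-right, the laterality axis), axis 2 = y (anterior-posterior),
#' axis 3 = z (superior-inferior, the gravity axis). The world coordinate of
#' voxel `(1,1,1)` is `origin`; voxel `(i,j,k)` sits at
#' `origin + (c(i,j,k) - 1) * spacing`. All geometric computation in the
#' package (distances, centres, interpolation radii) is carried out in mm,
#' never in voxel indices, so results are invariant to resampling.
#'
#' @param data numeric 3D array of voxel values; all values must be finite.
#' @param spacing numeric length-3, mm per voxel along each axis; strictly
#'   positive.
#' @param origin numeric length-3, world mm coordinate of voxel `(1,1,1)`.
#' @return an object of class `sv_volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume must be 3D")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values (mm)")
  if (anyNA(data) || any(!is.finite(data)))
    stop("all voxel values must be finite")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "sv_volume")
}

#' Construct a BinaryMask
#'
#' A binary lung (or region) mask on the same geometric grid as [volume()].
#' Values are coerced to 0/1 by thresholding at 0.5.
#'
#' @inheritParams volume
#' @param require_nonempty error if the mask has no foreground voxel.
#' @return an object of class `sv_mask` (also `sv_volume`).
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        require_nonempty = FALSE) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume must be 3D")
  storage.mode(data) <- "double"
  data[] <- as.numeric(data > 0.5)
  v <- volume(data, spacing, origin)
  if (require_nonempty && sum(v$data) == 0)
    stop("mask is empty (no foreground voxel)")
  class(v) <- c("sv_mask", "sv_volume")
  v
}

#' @export
print.sv_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d, spacing %.3g x %.3g x %.3g mm",
              class(x)[1], d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  if (inherits(x, "sv_mask")) {
    cat(sprintf(", %d foreground voxels\n", sum(x$data > 0)))
  } else {
    cat(sprintf(", range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  }
  invisible(x)
}

is_mask <- function(x) inherits(x, "sv_mask")

#' Test grid compatibility of two volumes
#'
#' Two volumes share a grid iff they have the same array dimensions, the same
#' spacing within 1e-6 mm, and the same origin within 1e-3 mm.
#'
#' @param a,b `sv_volume` objects.
#' @return logical scalar.
#' @export
grid_compatible <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < 1e-6) &&
    all(abs(a$origin - b$origin) < 1e-3)
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!grid_compatible(a, b))
    stop(sprintf("%s are not grid-compatible (shape/spacing/origin differ)",
                 what))
  invisible(TRUE)
}

# World mm coordinates of voxels given 1-based index matrix (n x 3).
index_to_world <- function(v, idx) {
  sweep(sweep(idx - 1, 2, v$spacing, "*"), 2, v$origin, "+")
}

# Continuous 0-based voxel index for world mm coordinates (n x 3).
world_to_index0 <- function(v, world) {
  sweep(sweep(world, 2, v$origin, "-"), 2, v$spacing, "/")
}

# n x 3 matrix of 1-based voxel indices for flattened positions.
flat_to_ijk <- function(flat, dm) {
  flat0 <- flat - 1L
  cbind(flat0 %% dm[1] + 1L,
        (flat0 %/% dm[1]) %% dm[2] + 1L,
        flat0 %/% (dm[1] * dm[2]) + 1L)
}
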