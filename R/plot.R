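#' Display scaling for ventilation images
#'
#' Visualization-only rescaling used for figure panels: the 99th percentile
#' of the in-mask values (and everything above it) maps to 100 and the
#' in-mask minimum to 0, suppressing hot-spot artifacts. Never applied before
#' computing metrics.
#'
#' @param v `sv_ventilation`.
#' @param mask `sv_mask`.
#' @return rescaled `sv_ventilation` (values 0-100 inside the mask).
#' @export
scale_for_display <- function(v, mask) {
  stop_if_grid_mismatch(v, mask, "image and mask")
  sel <- mask$data > 0
  vals <- v$data[sel]
  hi <- as.numeric(stats::quantile(vals, 0.99, type = 7, names = FALSE))
  lo <- min(vals)
  out <- array(0, dim(v$data))
  if (hi > lo) out[sel] <- pmin((vals - lo) / (hi - lo), 1) * 100
  ventilation_image(volume(out, v$spacing, v$origin),
                    if (inherits(v, "sv_ventilation")) v$provenance else "SVD")
}

#' Plot an axial slice of a volume
#'
#' Quick-look axial (xy) slice display with physical aspect ratio, optionally
#' with a mask contour overlaid.
#'
#' @param v `sv_volume`.
#' @param k axial slice index (default: middle slice).
#' @param mask optional `sv_mask` drawn as a contour.
#' @param ... passed to [graphics::image()].
#' @return invisibly, the slice matrix.
#' @export
plot_slice <- function(v, k = NULL, mask = NULL, ...) {
  dm <- dim(v$data)
  if (is.null(k)) k <- ceiling(dm[3] / 2)
  sl <- v$data[, , k]
  x <- (seq_len(dm[1]) - 1) * v$spacing[1]
  y <- (seq_len(dm[2]) - 1) * v$spacing[2]
  graphics::image(x, y, sl, asp = 1, col = grDevices::hcl.colors(64, "Grays"),
                  xlab = "x (mm)", ylab = "y (mm)", useRaster = TRUE, ...)
  if (!is.null(mask))
    graphics::contour(x, y, mask$data[, , k], levels = 0.5, add = TRUE,
                      drawlabels = FALSE, col = "red")
  invisible(sl)
}
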