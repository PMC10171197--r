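# Small in-code fixtures and independent oracles shared across tests.

toy_volume <- function(a, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.null(dim(a))) a <- array(a, c(length(a), 1, 1))
  volume(a, spacing, origin)
}

# constant-valued cube volume
cube_volume <- function(n, value = 0, spacing = c(1, 1, 1)) {
  volume(array(value, c(n, n, n)), spacing)
}

full_mask <- function(v) binary_mask(array(1, dim(v$data)), v$spacing, v$origin)

# Brute-force 3D median with nearest-replication edges (the oracle for
# cpp_median_filter); only sane for small volumes.
median_oracle <- function(a, window) {
  dm <- dim(a)
  h <- window %/% 2
  out <- array(0, dm)
  for (k in seq_len(dm[3])) for (j in seq_len(dm[2])) for (i in seq_len(dm[1])) {
    ii <- pmin(pmax(i + (-h:h), 1), dm[1])
    jj <- pmin(pmax(j + (-h:h), 1), dm[2])
    kk <- pmin(pmax(k + (-h:h), 1), dm[3])
    out[i, j, k] <- stats::median(a[ii, jj, kk])
  }
  out
}

# Independent Spearman: average ranks computed by hand, then the Pearson
# product-moment formula written out.
spearman_oracle <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- (sum(v < v[i]) + 1 + sum(v <= v[i])) / 2
    r
  }
  rx <- avg_rank(x)
  ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Direct evaluation of the Gaussian-distance interpolation for one voxel:
# normalised exp(-(r/r_mean)^2) weights over the given centres.
interp_oracle <- function(voxel_mm, centers_mm, values, r_mean) {
  r <- sqrt(rowSums(sweep(centers_mm, 2, voxel_mm)^2))
  w <- exp(-(r / r_mean)^2)
  sum(w * values) / sum(w)
}

# Two-ellipsoid lung phantom at reduced size for fast pipeline tests.
small_phantom <- function(...) {
  make_phantom(phantom_spec(shape = c(48L, 48L, 48L), spacing_mm = 4,
                            lung_semiaxes_mm = c(26, 36, 56),
                            defects = list(), texture_hu = 6, ...))
}

# Hand-built supervoxel map: labels array partitioning `mask_arr`.
toy_svm <- function(labels_arr, spacing = c(1, 1, 1), value_arr = NULL) {
  svm <- supervent:::new_supervoxel_map(labels_arr, spacing, c(0, 0, 0))
  if (!is.null(value_arr))
    svm <- compute_label_stats(svm, volume(value_arr, spacing), "D_mean")
  svm
}
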