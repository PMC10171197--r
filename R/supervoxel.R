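#' SLIC parameters
#'
#' Parameters of the spacing-aware 3D SLIC clustering. `k_init` is the
#' requested number of super-voxels (the number actually extracted,
#' `K_final`, is smaller after connectivity enforcement and depends on lung
#' anatomy). `compactness_m` weighs spatial distance against HU difference in
#' the SLIC distance `D = sqrt(d_c^2 + (d_s/S)^2 m^2)`; the default
#' `"adaptive"` re-estimates a per-cluster `m` each iteration as the largest
#' HU deviation observed in that cluster (SLIC0-style), removing the free
#' parameter.
#'
#' @param k_init requested number of super-voxels (default 1500).
#' @param max_iters maximum assign/update iterations (default 10).
#' @param compactness_m `"adaptive"` or a positive number (HU units).
#' @param convergence_tol stop when the mean seed-centre displacement falls
#'   below this value (mm, default 0.1).
#' @param min_size_voxels minimum super-voxel size kept by connectivity
#'   enforcement; default `S^3 / 4` voxels (`NULL` selects the default).
#' @return a list of class `sv_slic_params`.
#' @export
slic_params <- function(k_init = 1500L, max_iters = 10L,
                        compactness_m = "adaptive", convergence_tol = 0.1,
                        min_size_voxels = NULL) {
  k_init <- as.integer(k_init)
  max_iters <- as.integer(max_iters)
  if (is.na(k_init) || k_init < 1L) stop("k_init must be >= 1")
  if (is.na(max_iters) || max_iters < 1L) stop("max_iters must be >= 1")
  if (!identical(compactness_m, "adaptive")) {
    compactness_m <- as.numeric(compactness_m)
    if (!is.finite(compactness_m) || compactness_m <= 0)
      stop("compactness_m must be 'adaptive' or a positive number")
  }
  if (!is.numeric(convergence_tol) || convergence_tol < 0)
    stop("convergence_tol must be >= 0")
  structure(list(k_init = k_init, max_iters = max_iters,
                 compactness_m = compactness_m,
                 convergence_tol = convergence_tol,
                 min_size_voxels = min_size_voxels),
            class = "sv_slic_params")
}

# Seed sampling interval in voxel units: cube root of voxels-per-seed.
slic_interval <- function(n_mask_voxels, k_init) {
  (n_mask_voxels / k_init)^(1 / 3)
}

#' Initialize SLIC seeds
#'
#' Places seeds on a regular grid with interval `S = (N/K_init)^(1/3)` voxels
#' over the lung-mask bounding box (`N` = mask voxel count), drops seeds
#' falling outside the mask, then moves each retained seed to the
#' minimum-gradient voxel in its 3x3x3 neighbourhood so seeds avoid edges and
#' noisy voxels. The gradient is the sum over axes of absolute central HU
#' differences; on a tie (e.g. uniform HU) the original grid position is
#' kept.
#'
#' @param ct `sv_volume` of HU values.
#' @param mask `sv_mask` lung mask (nonempty).
#' @param p [slic_params()].
#' @return data.frame with 1-based voxel indices `i, j, k` and seed `hu`.
#' @export
initialize_seeds <- function(ct, mask, p = slic_params()) {
  stop_if_grid_mismatch(ct, mask, "ct and mask")
  n_mask <- sum(mask$data > 0)
  if (n_mask < 1) stop("mask is empty (no foreground voxel)")
  S <- slic_interval(n_mask, p$k_init)
  idx <- which(mask$data > 0)
  ijk <- flat_to_ijk(idx, dim(mask$data))
  bb_lo <- apply(ijk, 2, min)
  bb_hi <- apply(ijk, 2, max)
  ax <- lapply(1:3, function(a) {
    g <- if (bb_lo[a] + S / 2 > bb_hi[a]) (bb_lo[a] + bb_hi[a]) / 2
         else seq(bb_lo[a] + S / 2, bb_hi[a], by = S)
    unique(pmin(pmax(round(g), bb_lo[a]), bb_hi[a]))
  })
  grid <- as.matrix(expand.grid(i = ax[[1]], j = ax[[2]], k = ax[[3]]))
  inside <- mask$data[grid] > 0
  grid <- grid[inside, , drop = FALSE]
  if (nrow(grid) == 0) stop("mask too small to host a seed")
  G <- gradient_magnitude(ct$data)
  dm <- dim(ct$data)
  for (s in seq_len(nrow(grid))) {
    ctr <- grid[s, ]
    best <- ctr
    best_g <- G[ctr[1], ctr[2], ctr[3]]
    for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
      cand <- ctr + c(di, dj, dk)
      if (any(cand < 1L) || any(cand > dm)) next
      g <- G[cand[1], cand[2], cand[3]]
      if (g < best_g - 1e-12) {  # strict improvement only: ties keep original
        best_g <- g
        best <- cand
      }
    }
    grid[s, ] <- best
  }
  data.frame(i = grid[, 1], j = grid[, 2], k = grid[, 3],
             hu = ct$data[grid])
}

# Sum over axes of |central difference| of HU (replicate edges).
gradient_magnitude <- function(a) {
  dm <- dim(a)
  G <- array(0, dm)
  for (ax in 1:3) {
    n <- dm[ax]
    hi <- pmin(seq_len(n) + 1L, n)
    lo <- pmax(seq_len(n) - 1L, 1L)
    if (ax == 1) G <- G + abs(a[hi, , , drop = FALSE] - a[lo, , , drop = FALSE])
    if (ax == 2) G <- G + abs(a[, hi, , drop = FALSE] - a[, lo, , drop = FALSE])
    if (ax == 3) G <- G + abs(a[, , hi, drop = FALSE] - a[, , lo, drop = FALSE])
  }
  G
}

#' Run SLIC super-voxel segmentation
#'
#' Iteratively assigns every mask voxel within a `2S` search window of a seed
#' to the seed minimising `D = sqrt(d_c^2 + (d_s/S)^2 m^2)` (`d_c` HU
#' difference, `d_s` Euclidean distance in mm), updates seed centres to the
#' cluster means, and stops at convergence or `max_iters`. Mask voxels
#' covered by no window are attached to the nearest seed by `d_s` alone (and
#' counted). Connectivity is then enforced and labels are renumbered
#' `1..K_final`.
#'
#' @inheritParams initialize_seeds
#' @param seeds optional seed data.frame from [initialize_seeds()];
#'   recomputed when `NULL`.
#' @return a `sv_supervoxel_map`: integer label array (0 outside the mask)
#'   plus per-label statistics and run metadata.
#' @export
slic_supervoxels <- function(ct, mask, p = slic_params(), seeds = NULL) {
  stop_if_grid_mismatch(ct, mask, "ct and mask")
  if (is.null(seeds)) seeds <- initialize_seeds(ct, mask, p)
  if (nrow(seeds) < 1) stop("need at least one seed")
  n_mask <- sum(mask$data > 0)
  S_vox <- slic_interval(n_mask, p$k_init)
  S_mm <- S_vox * exp(mean(log(ct$spacing)))  # geometric-mean voxel pitch
  m_fixed <- if (identical(p$compactness_m, "adaptive")) -1 else p$compactness_m
  res <- cpp_slic(as.numeric(ct$data), dim(ct$data), ct$spacing,
                  as.integer(mask$data > 0),
                  as.matrix(seeds[, c("i", "j", "k")]) - 1, seeds$hu,
                  S_mm, S_vox, m_fixed, 10.0, p$max_iters, p$convergence_tol)
  labels <- array(res$labels, dim(ct$data))
  min_size <- p$min_size_voxels
  if (is.null(min_size)) min_size <- max(1L, as.integer(S_vox^3 / 4))
  svm <- new_supervoxel_map(labels, ct$spacing, ct$origin, params = p,
                            S_vox = S_vox, S_mm = S_mm,
                            objective = res$objective,
                            iterations = res$iterations,
                            n_uncovered = res$n_uncovered)
  svm <- enforce_connectivity(svm, min_size_voxels = min_size)
  if (svm$n_uncovered > 0)
    message(sprintf("%d mask voxels outside all search windows attached by distance",
                    svm$n_uncovered))
  svm
}

new_supervoxel_map <- function(labels, spacing, origin, ...) {
  svm <- structure(list(labels = labels, spacing = spacing, origin = origin),
                   class = "sv_supervoxel_map")
  extra <- list(...)
  svm[names(extra)] <- extra
  svm <- relabel_contiguous(svm)
  svm
}

relabel_contiguous <- function(svm) {
  present <- sort(unique(as.integer(svm$labels[svm$labels > 0])))
  map <- integer(if (length(present)) max(present) else 0)
  map[present] <- seq_along(present)
  lab <- svm$labels
  sel <- lab > 0
  lab[sel] <- map[lab[sel]]
  svm$labels <- lab
  svm$k_final <- length(present)
  svm$stats <- data.frame(label = seq_len(svm$k_final),
                          voxel_count = as.integer(
                            tabulate(lab[sel], nbins = svm$k_final)))
  svm
}

#' @export
print.sv_supervoxel_map <- function(x, ...) {
  cat(sprintf("<sv_supervoxel_map> %d super-voxels over %d voxels, grid %s\n",
              x$k_final, sum(x$labels > 0),
              paste(dim(x$labels), collapse = " x ")))
  invisible(x)
}

#' Enforce super-voxel connectivity
#'
#' SLIC assignment can leave labels split into several 26-connected pieces.
#' Each piece that is not the largest component of its label, or is smaller
#' than `min_size_voxels`, is merged into the neighbouring label sharing the
#' longest face boundary; passes repeat until every label is one connected
#' component. Labels are then renumbered contiguously.
#'
#' @param svm `sv_supervoxel_map`.
#' @param min_size_voxels smallest super-voxel size retained.
#' @return `sv_supervoxel_map` with connected, contiguously numbered labels.
#' @export
enforce_connectivity <- function(svm, min_size_voxels = 1L) {
  lab <- as.integer(svm$labels)
  dm <- dim(svm$labels)
  for (pass in 1:100) {
    res <- cpp_merge_components(lab, dm, as.integer(min_size_voxels))
    lab <- res$labels
    if (res$n_merged == 0) break
    # after the first pass only true disconnections remain to be fixed
    min_size_voxels <- 1L
  }
  svm$labels <- array(lab, dm)
  relabel_contiguous(svm)
}

#' Per-label statistics over a value volume
#'
#' Computes the arithmetic mean of `value_volume` over each super-voxel's
#' member voxels, stored as `D_mean` (mean density) or `Vent_mean` (mean
#' reference ventilation). Also fills in each label's geometric centre (mean
#' world mm coordinate of member voxels) and `r_mean`, the mean over labels
#' of the distance from each centre to its nearest other centre — the length
#' scale of the Gaussian interpolation kernel.
#'
#' @param svm `sv_supervoxel_map`.
#' @param value_volume grid-compatible `sv_volume`.
#' @param which statistic name: `"D_mean"` or `"Vent_mean"`.
#' @return `svm` with updated `stats` (and `r_mean`).
#' @export
compute_label_stats <- function(svm, value_volume,
                                which = c("D_mean", "Vent_mean")) {
  which <- match.arg(which)
  if (!identical(dim(svm$labels), dim(value_volume$data)))
    stop("value volume is not grid-compatible with the label map")
  sel <- which(svm$labels > 0)
  lab <- as.integer(svm$labels[sel])
  k <- svm$k_final
  means <- as.numeric(rowsum(as.numeric(value_volume$data[sel]), lab,
                             reorder = TRUE)) /
    tabulate(lab, nbins = k)
  svm$stats[[which]] <- means
  if (is.null(svm$stats$cx)) {
    ijk <- flat_to_ijk(sel, dim(svm$labels))
    world <- index_to_world(svm, ijk)
    cnt <- tabulate(lab, nbins = k)
    ctr <- rowsum(world, lab, reorder = TRUE) / cnt
    svm$stats$cx <- ctr[, 1]
    svm$stats$cy <- ctr[, 2]
    svm$stats$cz <- ctr[, 3]
    svm$r_mean <- mean_nn_distance(ctr)
  }
  svm
}

# Mean nearest-neighbour distance among centre rows (mm); NA for < 2 rows.
mean_nn_distance <- function(centers) {
  n <- nrow(centers)
  if (n < 2) return(NA_real_)
  d <- as.matrix(stats::dist(centers))
  diag(d) <- Inf
  mean(apply(d, 1, min))
}

# Total mask coverage check used by tests: labels partition the mask.
labels_partition_mask <- function(svm, mask) {
  all((svm$labels > 0) == (mask$data > 0)) &&
    sum(svm$stats$voxel_count) == sum(mask$data > 0)
}
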