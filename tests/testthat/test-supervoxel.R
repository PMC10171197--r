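test_that("seed initialization covers the stated cases", {
  # one-voxel mask hosts exactly one seed at that voxel
  m1 <- array(0, c(5, 5, 5)); m1[3, 2, 4] <- 1
  ct <- cube_volume(5, value = -800)
  s <- initialize_seeds(ct, binary_mask(m1), slic_params(k_init = 1))
  expect_equal(nrow(s), 1)
  expect_equal(unlist(s[1, c("i", "j", "k")], use.names = FALSE), c(3, 2, 4))
  # uniform HU: tie rule keeps seeds on the grid
  cube <- binary_mask(array(1, c(16, 16, 16)))
  ctu <- cube_volume(16, value = -850)
  p8 <- slic_params(k_init = 8)
  s8 <- initialize_seeds(ctu, cube, p8)
  S <- (16^3 / 8)^(1 / 3)  # 8 voxels
  expected <- unique(pmin(pmax(round(seq(1 + S / 2, 16, by = S)), 1), 16))
  expect_true(all(s8$i %in% expected))
  expect_equal(nrow(s8), length(expected)^3)
  # 64^3 mask at K_init 512: S = 8, at most 512 seeds (all inside the cube)
  big <- binary_mask(array(1, c(64, 64, 64)))
  ctb <- cube_volume(64, value = -850)
  sb <- initialize_seeds(ctb, big, slic_params(k_init = 512))
  expect_lte(nrow(sb), 512)
  expect_equal(nrow(sb), 512)  # cubic mask hosts the full grid
  expect_error(initialize_seeds(ct, binary_mask(array(0, c(5, 5, 5)))),
               "empty")
})

test_that("seeds move to the lowest-gradient voxel in their neighbourhood", {
  # V-shaped HU valley along x with its floor at x = 5: the central-grid
  # seed (x = 5 or 6) must end on the zero-gradient valley floor
  a <- array(0, c(9, 9, 9))
  for (x in 1:9) a[x, , ] <- abs(x - 5) * 100
  m <- binary_mask(array(1, c(9, 9, 9)))
  s <- initialize_seeds(volume(a), m, slic_params(k_init = 1))
  expect_equal(s$i, 5)  # G(5) = 0, G(4) = G(6) = 200
  G <- supervent:::gradient_magnitude(a)
  expect_equal(G[5, 5, 5], 0)
  expect_gt(G[6, 5, 5], 0)
})

test_that("two homogeneous HU blocks with one seed each are recovered exactly", {
  a <- array(-900, c(8, 4, 4))
  a[5:8, , ] <- -500
  ct <- volume(a)
  mask <- full_mask(ct)
  seeds <- data.frame(i = c(2, 7), j = c(2, 2), k = c(2, 2),
                      hu = c(-900, -500))
  svm <- slic_supervoxels(ct, mask, slic_params(k_init = 2, compactness_m = 10),
                          seeds = seeds)
  expect_equal(svm$k_final, 2)
  expect_true(all(svm$labels[1:4, , ] == svm$labels[1, 1, 1]))
  expect_true(all(svm$labels[5:8, , ] == svm$labels[5, 1, 1]))
  expect_true(svm$labels[1, 1, 1] != svm$labels[5, 1, 1])
})

test_that("a single seed labels every mask voxel 1", {
  ph <- small_phantom()
  seeds <- data.frame(i = 24, j = 24, k = 24, hu = -880)
  svm <- slic_supervoxels(ph$ct_ex, ph$lung_mask,
                          slic_params(k_init = 1), seeds = seeds)
  expect_equal(svm$k_final, 1)
  expect_true(supervent:::labels_partition_mask(svm, ph$lung_mask))
})

test_that("very large compactness on a uniform volume yields Voronoi cells", {
  ct <- cube_volume(12, value = -850)
  mask <- full_mask(ct)
  p <- slic_params(k_init = 8, compactness_m = 1e6, max_iters = 1)
  seeds <- initialize_seeds(ct, mask, p)
  svm <- slic_supervoxels(ct, mask, p, seeds = seeds)
  # oracle: nearest seed by Euclidean distance, lowest id on ties
  ctr <- as.matrix(seeds[, c("i", "j", "k")])
  idx <- which(mask$data > 0)
  ijk <- supervent:::flat_to_ijk(idx, dim(mask$data))
  oracle <- apply(ijk, 1, function(v) {
    which.min(colSums((t(ctr) - v)^2))
  })
  # map oracle seed ids to the contiguous relabeling
  expect_equal(as.integer(as.factor(as.integer(svm$labels[idx]))),
               as.integer(as.factor(oracle)))
})

test_that("labels partition the mask and runs are deterministic", {
  ph <- small_phantom()
  p <- slic_params(k_init = 150)
  svm1 <- slic_supervoxels(ph$ct_ex, ph$lung_mask, p)
  svm2 <- slic_supervoxels(ph$ct_ex, ph$lung_mask, p)
  expect_identical(svm1$labels, svm2$labels)
  expect_true(supervent:::labels_partition_mask(svm1, ph$lung_mask))
  expect_lte(svm1$k_final, 150)
  expect_equal(sort(unique(as.integer(svm1$labels[svm1$labels > 0]))),
               seq_len(svm1$k_final))
})

test_that("every final label is one 26-connected component", {
  ph <- small_phantom()
  svm <- slic_supervoxels(ph$ct_ex, ph$lung_mask, slic_params(k_init = 120))
  comp <- supervent:::cpp_label_components(as.integer(svm$labels),
                                           dim(svm$labels))
  per_label <- tapply(comp[svm$labels > 0], svm$labels[svm$labels > 0],
                      function(x) length(unique(x)))
  expect_true(all(per_label == 1))
})

test_that("the SLIC objective is non-increasing with fixed compactness", {
  for (seed in 1:3) {
    ph <- make_phantom(phantom_spec(shape = c(32L, 32L, 32L), spacing_mm = 6,
                                    lung_semiaxes_mm = c(26, 36, 56),
                                    defects = list(), seed = seed))
    p <- slic_params(k_init = 40, compactness_m = 20, max_iters = 8,
                     convergence_tol = 0)
    seeds <- initialize_seeds(ph$ct_ex, ph$lung_mask, p)
    n_mask <- sum(ph$lung_mask$data > 0)
    S_vox <- supervent:::slic_interval(n_mask, p$k_init)
    res <- supervent:::cpp_slic(as.numeric(ph$ct_ex$data), dim(ph$ct_ex$data),
                                ph$ct_ex$spacing,
                                as.integer(ph$lung_mask$data > 0),
                                as.matrix(seeds[, c("i", "j", "k")]) - 1,
                                seeds$hu, S_vox * 6, S_vox, 20, 10, 8, 0)
    expect_true(all(diff(res$objective) <= 1e-6 * res$objective[1]))
  }
})

test_that("connectivity enforcement resolves islands and split labels", {
  # already-connected labels pass through unchanged
  lab <- array(1L, c(4, 4, 4)); lab[3:4, , ] <- 2L
  svm <- toy_svm(lab)
  out <- enforce_connectivity(svm, 1)
  expect_equal(out$labels, lab)
  # a one-voxel island inside another label is absorbed
  lab2 <- array(5L, c(5, 5, 5)); lab2[3, 3, 3] <- 3L
  out2 <- enforce_connectivity(toy_svm(lab2), 2)
  expect_true(all(out2$labels == 1L))
  # two labels each split in two components end up as connected labels
  row <- array(0L, c(8, 1, 1))
  row[, 1, 1] <- c(1L, 1L, 2L, 2L, 1L, 1L, 2L, 2L)
  out3 <- enforce_connectivity(toy_svm(row), 1)
  expect_equal(out3$k_final, 2)
  comp <- supervent:::cpp_label_components(as.integer(out3$labels),
                                           dim(out3$labels))
  per_label <- tapply(comp[out3$labels > 0], out3$labels[out3$labels > 0],
                      function(x) length(unique(x)))
  expect_true(all(per_label == 1))
})

test_that("label statistics: means, centres, and r_mean", {
  lab <- array(0L, c(4, 2, 2))
  lab[1:2, , ] <- 1L
  lab[3:4, , ] <- 2L
  vals <- array(0, c(4, 2, 2))
  vals[1, , ] <- 0.2; vals[2, , ] <- 0.4
  vals[3:4, , ] <- 7
  svm <- supervent:::new_supervoxel_map(lab, c(5, 5, 5), c(0, 0, 0))
  svm <- compute_label_stats(svm, volume(vals, c(5, 5, 5)), "D_mean")
  expect_equal(svm$stats$D_mean, c(0.3, 7))
  # centres: label 1 spans x-index 1..2 -> mm mean 2.5; label 2 -> 12.5
  expect_equal(svm$stats$cx, c(2.5, 12.5))
  expect_equal(svm$r_mean, 10)  # two centres 10 mm apart
  # constant volume: every mean equals the constant
  cst <- compute_label_stats(svm, volume(array(1.5, c(4, 2, 2)), c(5, 5, 5)),
                             "Vent_mean")
  expect_equal(cst$stats$Vent_mean, c(1.5, 1.5))
})

test_that("K_final grows with K_init", {
  ph <- small_phantom()
  kf <- vapply(c(40, 150, 400), function(k) {
    slic_supervoxels(ph$ct_ex, ph$lung_mask, slic_params(k_init = k))$k_final
  }, numeric(1))
  expect_true(all(diff(kf) > 0))
})
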