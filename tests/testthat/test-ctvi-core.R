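test_that("HU to density conversion pins air, water and the parenchyma bound", {
  v <- toy_volume(c(-1000, 0, -400, -880))
  d <- hu_to_density(v)
  expect_equal(as.numeric(d$data), c(0, 1, 0.6, 0.12))
})

test_that("density gating zeroes only super-voxels strictly above 0.6", {
  lab <- array(rep(1:4, each = 2), c(8, 1, 1))
  dens <- array(rep(c(0.61, 0.6, 0.12, 0.95), each = 2), c(8, 1, 1))
  svm <- toy_svm(lab, value_arr = dens)
  svm <- gate_supervoxels(svm)
  expect_equal(svm$stats$gated, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(svm$stats$source_value, c(0, 0.6, 0.12, 0))
})

test_that("interpolation weights follow the Gaussian distance law", {
  # raw weight at r = r_mean is exp(-1)
  expect_equal(exp(-(1)^2), 0.3678794, tolerance = 1e-6)
  # two labels, both centres equidistant from the middle voxel: 0.5/0.5
  lab <- array(0L, c(5, 1, 1))
  lab[c(1, 2), 1, 1] <- 1L
  lab[c(4, 5), 1, 1] <- 2L
  svm <- supervent:::new_supervoxel_map(lab, c(1, 1, 1), c(0, 0, 0))
  svm <- compute_label_stats(svm, toy_volume(rep(1, 5)), "D_mean")
  m <- binary_mask(array(1, dim(lab)))  # interpolate over all five voxels
  w <- build_weights(svm, m, labels = 1:2)
  mid <- which(w$voxels == 3L)  # x = 2 mm, centres at 0.5 and 3.5 mm
  expect_equal(as.numeric(w$W[mid, ]), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(rowSums(w$W), rep(1, nrow(w$W)), tolerance = 1e-9)
  # a voxel at an isolated centre, all other centres >= 5 r_mean away,
  # carries essentially all the weight after normalization
  lab2 <- array(0L, c(106, 1, 1))
  lab2[1, 1, 1] <- 1L
  for (j in 2:7) lab2[99 + j, 1, 1] <- j  # tight cluster at x = 100..105 mm
  svm2 <- supervent:::new_supervoxel_map(lab2, c(1, 1, 1), c(0, 0, 0))
  svm2 <- compute_label_stats(svm2, toy_volume(rep(1, 106)), "D_mean")
  m2 <- binary_mask(array(1, dim(lab2)))
  w2 <- build_weights(svm2, m2, labels = 1:7)
  expect_equal(w2$r_mean, (100 + 6 * 1) / 7)
  at1 <- as.numeric(w2$W[which(w2$voxels == 1L), ])
  expect_equal(at1[1], 1, tolerance = 1e-6)
})

test_that("interpolated image matches a brute-force 3-label oracle", {
  dm <- c(6, 5, 4)
  lab <- array(0L, dm)
  lab[1:2, , ] <- 1L
  lab[3:4, , ] <- 2L
  lab[5:6, , ] <- 3L
  sp <- c(2, 2, 2)
  svm <- supervent:::new_supervoxel_map(lab, sp, c(0, 0, 0))
  dens <- array(0, dm)
  dens[lab == 1] <- 0.10
  dens[lab == 2] <- 0.25
  dens[lab == 3] <- 0.70
  svm <- compute_label_stats(svm, volume(array(dens, dm), sp), "D_mean")
  svm <- gate_supervoxels(svm)
  expect_equal(svm$stats$source_value, c(0.10, 0.25, 0))  # label 3 gated
  mask <- binary_mask(array(1, dm), sp)
  w <- build_weights(svm, mask, labels = 1:3)
  vi <- interpolate_ventilation(svm, list(w), mask)
  centers <- as.matrix(svm$stats[, c("cx", "cy", "cz")])
  vals <- svm$stats$source_value
  idx <- which(mask$data > 0)
  ijk <- supervent:::flat_to_ijk(idx, dm)
  world <- supervent:::index_to_world(mask, ijk)
  oracle <- vapply(seq_along(idx), function(t) {
    interp_oracle(world[t, ], centers, vals, w$r_mean)
  }, numeric(1))
  expect_equal(as.numeric(vi$data[idx]), oracle, tolerance = 1e-12)
})

test_that("constant sources interpolate to the constant", {
  dm <- c(6, 6, 6)
  lab <- array(rep(1:3, each = 72), dm)
  svm <- supervent:::new_supervoxel_map(lab, c(2, 2, 2), c(0, 0, 0))
  svm <- compute_label_stats(svm, volume(array(0.12, dm), c(2, 2, 2)),
                             "D_mean")
  svm <- gate_supervoxels(svm)
  mask <- binary_mask(array(1, dm), c(2, 2, 2))
  w <- build_weights(svm, mask, labels = 1:3)
  vi <- interpolate_ventilation(svm, list(w), mask)
  expect_equal(as.numeric(vi$data), rep(0.12, prod(dm)), tolerance = 1e-12)
})

test_that("mask-aware smoothing preserves constants and impulse mass", {
  dm <- c(15, 15, 15)
  mask <- binary_mask(array(1, dm))
  cst <- ventilation_image(volume(array(0.4, dm)))
  sm <- smooth_ventilation(cst, mask)
  expect_equal(sm$data, cst$data, tolerance = 1e-12)
  imp <- array(0, dm); imp[8, 8, 8] <- 5
  smi <- smooth_ventilation(ventilation_image(volume(imp)), mask)
  expect_equal(sum(smi$data), 5, tolerance = 5 * 1e-6)
  expect_lt(max(smi$data), 5)
  expect_error(smooth_ventilation(cst, mask, kernel_voxels = 0), "positive")
})

test_that("lung splitting handles separate, fused and fragmented masks", {
  dm <- c(10, 6, 6)
  two <- array(0, dm)
  two[2:4, 2:5, 2:5] <- 1
  two[7:9, 2:5, 2:5] <- 1
  s <- split_lungs(binary_mask(two))
  expect_equal(sum(s$left$data), 3 * 4 * 4)
  expect_equal(sum(s$right$data), 3 * 4 * 4)
  expect_lt(mean(which(s$left$data > 0) %% dm[1]),
            mean(which(s$right$data > 0) %% dm[1]))
  # fused mask: sagittal plane split, both halves nonempty
  one <- array(0, dm); one[2:9, 2:5, 2:5] <- 1
  expect_message(sf <- split_lungs(binary_mask(one)), "sagittal")
  expect_gt(sum(sf$left$data), 0)
  expect_gt(sum(sf$right$data), 0)
  expect_equal(sf$left$data + sf$right$data, one)
  # three components: the small extra one goes to the nearer lung
  three <- two
  three[6, 2, 2] <- 1  # single voxel near the right block
  st <- split_lungs(binary_mask(three))
  expect_equal(sum(st$left$data) + sum(st$right$data), sum(three))
  expect_equal(st$right$data[6, 2, 2], 1)
})

test_that("manual defect correction rewrites only the defect region", {
  dm <- c(12, 12, 12)
  mask <- binary_mask(array(1, dm))
  base <- ventilation_image(volume(array(0.9, dm)))
  empty <- binary_mask(array(0, dm))
  expect_equal(manual_defect_correction(base, empty)$data, base$data)
  whole <- binary_mask(array(1, dm))
  expect_true(all(manual_defect_correction(base, whole, 0)$data == 0))
  defect <- array(0, dm); defect[3:9, 3:9, 3:9] <- 1
  corr <- manual_defect_correction(base, binary_mask(defect), 0)
  sm <- smooth_ventilation(corr, mask)
  expect_lt(sm$data[6, 6, 6], 0.05)            # defect core near 0
  expect_equal(sm$data[12, 12, 12], 0.9, tolerance = 1e-6)  # far field intact
})

test_that("a homogeneous -880 HU lung yields a constant 0.12 image", {
  ph <- small_phantom()
  ct <- volume(array(-880, dim(ph$ct_ex$data)), ph$ct_ex$spacing)
  vi <- run_ctvi_svd(ct, ph$lung_mask, slic_params(k_init = 60),
                     target_spacing_mm = NULL)
  inmask <- vi$data[ph$lung_mask$data > 0]
  expect_equal(inmask, rep(0.12, length(inmask)), tolerance = 1e-9)
  expect_true(all(vi$data[ph$lung_mask$data == 0] == 0))
})

test_that("the full pipeline is deterministic and errors on an empty mask", {
  ph <- small_phantom()
  v1 <- run_ctvi_svd(ph$ct_ex, ph$lung_mask, slic_params(k_init = 80),
                     target_spacing_mm = NULL)
  v2 <- run_ctvi_svd(ph$ct_ex, ph$lung_mask, slic_params(k_init = 80),
                     target_spacing_mm = NULL)
  expect_identical(v1$data, v2$data)
  empty <- binary_mask(array(0, dim(ph$ct_ex$data)), ph$ct_ex$spacing)
  expect_error(run_ctvi_svd(ph$ct_ex, empty), "empty")
})

test_that("left-lung values are invariant to right-lung perturbations", {
  ph <- small_phantom()
  v1 <- run_ctvi_svd(ph$ct_ex, ph$lung_mask, slic_params(k_init = 80),
                     target_spacing_mm = NULL)
  sides <- split_lungs(ph$lung_mask)
  ct2 <- ph$ct_ex
  ct2$data[sides$right$data > 0] <- ct2$data[sides$right$data > 0] + 40
  v2 <- run_ctvi_svd(ct2, ph$lung_mask, slic_params(k_init = 80),
                     target_spacing_mm = NULL)
  lsel <- sides$left$data > 0
  expect_identical(v1$data[lsel], v2$data[lsel])
  expect_false(identical(v1$data[sides$right$data > 0],
                         v2$data[sides$right$data > 0]))
})

test_that("gated super-voxels contribute exactly zero to the sources", {
  ph <- small_phantom()
  ct <- ph$ct_ex
  # implant a dense nodule so at least one super-voxel crosses the gate
  sides <- split_lungs(ph$lung_mask)
  rsel <- which(sides$right$data > 0)
  nod <- rsel[seq_len(min(600, length(rsel)))]
  ct$data[nod] <- -100
  vi <- run_ctvi_svd(ct, ph$lung_mask, slic_params(k_init = 80),
                     target_spacing_mm = NULL)
  svm <- attr(vi, "svm")
  expect_gt(sum(svm$stats$gated), 0)
  expect_true(all(svm$stats$source_value[svm$stats$gated] == 0))
})
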