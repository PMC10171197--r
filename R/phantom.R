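#' Synthetic thorax phantom specification
#'
#' Describes a reproducible exhale/inhale phantom with density-ventilation
#' coupling: two ellipsoidal lungs in a tissue background, a smooth positive
#' ventilation field with a gravity-direction (z) ramp, optional spherical
#' defects (emphysema: low HU and low ventilation; consolidation: high HU and
#' low ventilation), band-limited HU texture, an analytic expansion
#' deformation field whose Jacobian reproduces the ventilation field, and a
#' blurred noisy SPECT-like reference. Defaults emulate a 2 mm resampled
#' clinical thorax at desk scale; see the methods vignette for the rationale
#' behind each value.
#'
#' @param shape grid dimensions (voxels), default `c(96, 96, 96)`.
#' @param spacing_mm isotropic voxel spacing, default 2 mm.
#' @param lung_centers_frac 2x3 matrix of lung centres as fractions of the
#'   grid extent (rows: left, right lung).
#' @param lung_semiaxes_mm ellipsoid semi-axes in mm.
#' @param base_hu exhale lung HU at the ventilation baseline (default -880).
#' @param texture_hu SD of the band-limited HU texture (default 12).
#' @param texture_smooth_mm Gaussian smoothing length of the texture.
#' @param vent_base,vent_ramp ventilation baseline and z-ramp amplitude
#'   (fractional volume change; defaults 0.15 and 0.15 give a 0.075-0.225
#'   range, about the 3:1 gravity-dependent ratio seen clinically).
#' @param coupling_hu HU increase per unit ventilation (positive: denser
#'   lung ventilates more, the empirical direction; default 800).
#' @param defects list of defects, each
#'   `list(center_frac, radius_mm, vent_multiplier, hu_offset)` with
#'   `center_frac` the centre as fractions of the grid extent; must fall
#'   inside a lung.
#' @param spect_fwhm_mm Gaussian blur FWHM of the SPECT-like reference
#'   (default 8 mm, the nominal SPECT resolution).
#' @param spect_noise_sd SD of the multiplicative SPECT-like noise
#'   (default 0.10).
#' @param seed RNG seed; the phantom is bit-reproducible given the spec.
#' @return list of class `sv_phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96L, 96L, 96L), spacing_mm = 2.0,
                         lung_centers_frac = rbind(c(0.30, 0.50, 0.50),
                                                   c(0.70, 0.50, 0.50)),
                         lung_semiaxes_mm = c(28, 38, 60),
                         base_hu = -880, texture_hu = 12,
                         texture_smooth_mm = 6,
                         vent_base = 0.15, vent_ramp = 0.15,
                         coupling_hu = 800,
                         defects = list(
                           list(center_frac = c(0.70, 0.50, 0.65),
                                radius_mm = 12, vent_multiplier = 0.3,
                                hu_offset = -80),
                           list(center_frac = c(0.30, 0.50, 0.38),
                                radius_mm = 10, vent_multiplier = 0.2,
                                hu_offset = 600)),
                         spect_fwhm_mm = 8, spect_noise_sd = 0.10,
                         seed = 1L) {
  structure(list(shape = as.integer(shape), spacing_mm = spacing_mm,
                 lung_centers_frac = lung_centers_frac,
                 lung_semiaxes_mm = lung_semiaxes_mm, base_hu = base_hu,
                 texture_hu = texture_hu,
                 texture_smooth_mm = texture_smooth_mm,
                 vent_base = vent_base, vent_ramp = vent_ramp,
                 coupling_hu = coupling_hu, defects = defects,
                 spect_fwhm_mm = spect_fwhm_mm,
                 spect_noise_sd = spect_noise_sd, seed = as.integer(seed)),
            class = "sv_phantom_spec")
}

# mm coordinate arrays for a spec grid.
phantom_coords <- function(spec) {
  dm <- spec$shape
  sp <- spec$spacing_mm
  x <- (seq_len(dm[1]) - 1) * sp
  y <- (seq_len(dm[2]) - 1) * sp
  z <- (seq_len(dm[3]) - 1) * sp
  list(x = array(rep(x, times = dm[2] * dm[3]), dm),
       y = array(rep(rep(y, each = dm[1]), times = dm[3]), dm),
       z = array(rep(z, each = dm[1] * dm[2]), dm),
       extent = (dm - 1) * sp)
}

#' Generate a synthetic thorax phantom
#'
#' Builds, in order: the ventilation truth (smooth ramp plus cosine-tapered
#' defect multipliers, masked to the lungs), the exhale CT (base HU +
#' coupling x ventilation + band-limited texture + defect HU offsets inside
#' the lungs; 0 HU tissue outside), the deformation field
#' `u = (0, 0, integral of ventilation dz)` whose Jacobian determinant
#' reproduces the ventilation field, the inhale CT obtained by inverting that
#' z-displacement per column with mass-conserving density reduction
#' `HU_in + 1000 = (HU_ex + 1000) / (1 + vent)`, and the SPECT-like
#' reference (Gaussian blur at the nominal SPECT resolution plus
#' multiplicative noise). Same spec, same seed: bit-identical outputs.
#'
#' @param spec [phantom_spec()].
#' @return list with `ct_ex`, `ct_in` (`sv_volume`, HU), `lung_mask`
#'   (`sv_mask`), `dvf` (`sv_dvf`), `vent_truth`, `spect_like`
#'   (`sv_ventilation`, provenance `"reference"`), and `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "sv_phantom_spec"))
  set.seed(spec$seed)
  dm <- spec$shape
  sp <- rep(spec$spacing_mm, 3)
  co <- phantom_coords(spec)
  # lungs
  mask_arr <- array(0, dm)
  for (l in 1:2) {
    ctr <- spec$lung_centers_frac[l, ] * co$extent
    e <- ((co$x - ctr[1]) / spec$lung_semiaxes_mm[1])^2 +
      ((co$y - ctr[2]) / spec$lung_semiaxes_mm[2])^2 +
      ((co$z - ctr[3]) / spec$lung_semiaxes_mm[3])^2
    mask_arr[e <= 1] <- 1
  }
  lung_mask <- binary_mask(mask_arr, sp, c(0, 0, 0), require_nonempty = TRUE)
  # ventilation field: gravity ramp, defect multipliers with cosine taper
  zfrac <- co$z / co$extent[3]
  vent <- spec$vent_base + spec$vent_ramp * (zfrac - 0.5)
  hu_off <- array(0, dm)
  for (d in spec$defects) {
    ctr <- d$center_frac * co$extent
    ci <- pmin(pmax(round(ctr / spec$spacing_mm) + 1, 1), dm)
    if (mask_arr[ci[1], ci[2], ci[3]] == 0)
      stop("defect centre falls outside the lungs")
    r <- sqrt((co$x - ctr[1])^2 + (co$y - ctr[2])^2 + (co$z - ctr[3])^2)
    w <- ifelse(r < d$radius_mm, 0.5 * (1 + cos(pi * r / d$radius_mm)), 0)
    vent <- vent * (1 - (1 - d$vent_multiplier) * w)
    hu_off <- hu_off + d$hu_offset * w
  }
  vent_truth_arr <- vent * mask_arr
  # exhale CT: tissue background at 0 HU, coupled lung HU + texture
  sigma_vox <- spec$texture_smooth_mm / spec$spacing_mm
  tex <- array(stats::rnorm(prod(dm)), dm)
  tex <- array(cpp_gauss_smooth(as.numeric(tex), dm, sigma_vox,
                                as.integer(ceiling(3 * sigma_vox))), dm)
  if (stats::sd(tex) > 0) tex <- tex / stats::sd(tex) * spec$texture_hu
  hu_lung <- spec$base_hu +
    spec$coupling_hu * (vent - spec$vent_base) + tex + hu_off
  ct_ex_arr <- hu_lung * mask_arr
  ct_ex_arr <- pmin(pmax(ct_ex_arr, -1024), 200)
  ct_ex <- volume(ct_ex_arr, sp, c(0, 0, 0))
  # deformation field: u_z = cumulative trapezoid of (masked) vent along z
  vmask <- vent * mask_arr
  dz <- spec$spacing_mm
  uz <- array(0, dm)
  for (k in 2:dm[3]) {
    uz[, , k] <- uz[, , k - 1] + dz * 0.5 * (vmask[, , k - 1] + vmask[, , k])
  }
  u <- array(0, c(dm, 3))
  u[, , , 3] <- uz
  dvf <- deformation_field(u, sp, c(0, 0, 0))
  # inhale CT: invert the monotone z-map per column; density reduced 1/(1+v)
  target <- (ct_ex_arr + 1000) / (1 + vmask) - 1000
  z_mm <- (seq_len(dm[3]) - 1) * dz
  ct_in_arr <- ct_ex_arr
  for (j in seq_len(dm[2])) for (i in seq_len(dm[1])) {
    col_u <- uz[i, j, ]
    if (col_u[dm[3]] == 0) next  # no lung in this column: identity
    ct_in_arr[i, j, ] <- stats::approx(z_mm + col_u, target[i, j, ],
                                       xout = z_mm, rule = 2)$y
  }
  ct_in <- volume(ct_in_arr, sp, c(0, 0, 0))
  # SPECT-like reference: blur to the nominal resolution + multiplicative noise
  sig_spect <- spec$spect_fwhm_mm / (2 * sqrt(2 * log(2))) / spec$spacing_mm
  blur <- array(cpp_gauss_smooth(as.numeric(vent_truth_arr), dm, sig_spect,
                                 as.integer(ceiling(3 * sig_spect))), dm)
  noise <- 1 + spec$spect_noise_sd * array(stats::rnorm(prod(dm)), dm)
  spect_arr <- pmax(blur * noise, 0) * mask_arr
  list(ct_ex = ct_ex, ct_in = ct_in, lung_mask = lung_mask, dvf = dvf,
       vent_truth = ventilation_image(volume(vent_truth_arr, sp, c(0, 0, 0)),
                                      "reference"),
       spect_like = ventilation_image(volume(spect_arr, sp, c(0, 0, 0)),
                                      "reference"),
       spec = spec)
}

#' Generate a phantom cohort
#'
#' `n` phantoms with per-case jittered geometry and ventilation so cohort
#' statistics (means, SDs, paired tests) are non-degenerate. Per-case seeds
#' are derived from the master seed, so the cohort is reproducible as a
#' whole.
#'
#' @param n number of cases (>= 1).
#' @param base_spec [phantom_spec()] to perturb.
#' @param jitter list of relative jitter ranges: `geometry` (lung semi-axes,
#'   default 0.10), `vent` (ramp amplitude, default 0.20), `defect_mm`
#'   (defect centre displacement in mm, default 4).
#' @param seed master seed; case `i` uses `seed + i - 1`, so `n = 1` with
#'   zero jitter reproduces `make_phantom(base_spec)` when
#'   `seed = base_spec$seed`.
#' @return list of `n` phantom cases (each as [make_phantom()]).
#' @export
make_cohort <- function(n, base_spec = phantom_spec(),
                        jitter = list(geometry = 0.10, vent = 0.20,
                                      defect_mm = 4), seed = base_spec$seed) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1")
  jitter <- utils::modifyList(list(geometry = 0.10, vent = 0.20,
                                   defect_mm = 4), jitter)
  set.seed(seed)
  specs <- lapply(seq_len(n), function(i) {
    s <- base_spec
    s$lung_semiaxes_mm <- s$lung_semiaxes_mm *
      (1 + stats::runif(3, -jitter$geometry, jitter$geometry))
    s$vent_ramp <- s$vent_ramp *
      (1 + stats::runif(1, -jitter$vent, jitter$vent))
    s$defects <- lapply(s$defects, function(d) {
      shift_frac <- stats::runif(3, -jitter$defect_mm, jitter$defect_mm) /
        ((s$shape - 1) * s$spacing_mm)
      d$center_frac <- d$center_frac + shift_frac
      d
    })
    s$seed <- as.integer(seed + i - 1)
    s
  })
  lapply(specs, make_phantom)
}
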