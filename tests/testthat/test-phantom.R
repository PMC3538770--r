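test_that("source and spec validation enforce the susceptibility sign rules", {
  expect_error(susceptibility_source(c(5, 5, 5), 3, -0.5, "hemorrhage"),
               "delta_chi > 0")
  expect_error(susceptibility_source(c(5, 5, 5), 3, +0.5, "calcification"),
               "delta_chi < 0")
  expect_error(susceptibility_source(c(5, 5, 5), -1, 0.5, "hemorrhage"),
               "radius")
  expect_error(phantom_spec(grid_shape = c(8, 8, 8)), ">= 16")
  expect_error(
    phantom_spec(sources = list(
      susceptibility_source(c(200, 5, 5), 3, 0.5, "hemorrhage"))),
    "outside the grid")
})

test_that("susceptibility map rasterisation matches a brute-force oracle", {
  # empty phantom
  empty <- build_susceptibility_map(phantom_spec(
    grid_shape = c(16, 16, 16), voxel_size = c(1, 1, 1), sources = list()))
  expect_true(all(empty$chi == 0))
  expect_true(all(empty$truth$label_volume == 0L))

  # one hemorrhage sphere: exact value inside, zero outside
  spec1 <- phantom_spec(grid_shape = c(24, 24, 24), voxel_size = c(1, 1, 1),
                        sources = list(susceptibility_source(
                          c(12, 12, 12), 3, 0.5, "hemorrhage")))
  m1 <- build_susceptibility_map(spec1)
  inside <- m1$truth$label_volume == 1L
  expect_true(all(m1$chi[inside] == 0.5))
  expect_true(all(m1$chi[!inside] == 0))

  # two disjoint opposite-sign sources: per-label voxel counts equal the
  # brute-force per-voxel distance check
  spec2 <- phantom_spec(
    grid_shape = c(24, 24, 16), voxel_size = c(1, 1, 2),
    sources = list(
      susceptibility_source(c(7.3, 8.1, 6.2), 3.5, 0.4, "hemorrhage"),
      susceptibility_source(c(17.6, 16.2, 10.8), 2.8, -0.3, "calcification")
    ))
  m2 <- build_susceptibility_map(spec2)
  n_hem <- brute_count_inside(c(24, 24, 16), c(1, 1, 2), c(7.3, 8.1, 6.2), 3.5)
  n_cal <- brute_count_inside(c(24, 24, 16), c(1, 1, 2), c(17.6, 16.2, 10.8), 2.8)
  expect_identical(sum(m2$truth$label_volume == 1L), n_hem)
  expect_identical(sum(m2$truth$label_volume == 2L), n_cal)
  expect_identical(sum(m2$chi > 0), n_hem)
  expect_identical(sum(m2$chi < 0), n_cal)
})

test_that("overlapping sources are rejected naming the pair", {
  spec <- phantom_spec(
    grid_shape = c(24, 24, 24), voxel_size = c(1, 1, 1),
    sources = list(
      susceptibility_source(c(12, 12, 12), 4, 0.5, "hemorrhage"),
      susceptibility_source(c(14, 12, 12), 4, -0.5, "calcification")
    ))
  expect_error(build_susceptibility_map(spec), "sources 1 and 2 overlap")
})

test_that("dipole field is linear, zero-mean, and matches the real-space dipole sum", {
  dims <- c(32, 32, 32)
  expect_true(all(dipole_field(array(0, dims)) == 0))
  expect_error(dipole_field(array(NaN, dims)), "non-finite")

  set.seed(11)
  chi1 <- array(rnorm(prod(dims)), dims)
  chi2 <- array(rnorm(prod(dims)), dims)
  f1 <- dipole_field(chi1); f2 <- dipole_field(chi2)
  f12 <- dipole_field(2 * chi1 - 3 * chi2)
  expect_lt(max(abs(f12 - (2 * f1 - 3 * f2))), 1e-9)
  expect_lt(abs(mean(f1)), 1e-9)
  expect_lt(abs(mean(f12)), 1e-9)

  # single voxel source: z vs x lobes have opposite signs with ratio -2,
  # as the point-dipole angular factor (3 cos^2 theta - 1) dictates
  chi <- array(0, dims); chi[16, 16, 16] <- 1
  f <- dipole_field(chi, c(1, 1, 1))
  expect_equal(f[16, 16, 23] / f[23, 16, 16], -2, tolerance = 0.05)
  expect_gt(f[16, 16, 23], 0)
  expect_lt(f[23, 16, 16], 0)

  # analytic slab oracle: a uniform slab normal to the field axis sees
  # -2/3 * (chi - mean chi) inside (demagnetisation), one normal to x sees
  # +1/3 * (chi - mean chi); exact for the Lorentz-corrected kernel
  slab_z <- array(0, dims); slab_z[, , 12:20] <- 1
  fz <- dipole_field(slab_z, c(1, 1, 1))
  expect_lt(max(abs(fz - (-2 / 3) * (slab_z - mean(slab_z)))), 1e-10)
  slab_x <- array(0, dims); slab_x[12:20, , ] <- 1
  fx <- dipole_field(slab_x, c(1, 1, 1))
  expect_lt(max(abs(fx - (1 / 3) * (slab_x - mean(slab_x)))), 1e-10)

  # uniform sphere: interior mean field vanishes under the Lorentz-corrected
  # kernel
  chi_s <- array(0, dims)
  inside <- swiprost:::sphere_voxels(dims, c(1, 1, 1), c(16.5, 16.5, 16.5), 6)
  chi_s[inside] <- 0.5
  fs <- dipole_field(chi_s, c(1, 1, 1))
  expect_lt(abs(mean(fs[inside])), 0.02 * 0.5)
})

test_that("signal synthesis honours wrapping, handedness and noiselessness", {
  # no sources, zero background, no noise: phase 0, magnitude 1
  spec0 <- phantom_spec(grid_shape = c(16, 16, 16), voxel_size = c(1, 1, 1),
                        background_phase_coeffs = numeric(0), noise_sd = 0)
  sim0 <- simulate_phantom(spec0)
  expect_true(all(sim0$volume$phase == 0))
  expect_true(all(sim0$volume$magnitude == 1))

  # injected background of 3*pi/2 wraps to -pi/2
  spec_w <- phantom_spec(grid_shape = c(16, 16, 16), voxel_size = c(1, 1, 1),
                         background_phase_coeffs = c("1" = 3 * pi / 2),
                         noise_sd = 0)
  sim_w <- simulate_phantom(spec_w)
  expect_equal(sim_w$volume$phase[1, 1, 1], -pi / 2, tolerance = 1e-12)
  expect_true(all(sim_w$volume$phase > -pi & sim_w$volume$phase <= pi))

  # noiseless synthesis is bit-reproducible and seed-independent
  a <- simulate_phantom(two_source_spec(seed = 1L))$volume
  b <- simulate_phantom(two_source_spec(seed = 99L))$volume
  expect_identical(a$phase, b$phase)
  expect_identical(a$magnitude, b$magnitude)

  # flipping the sign of every delta_chi flips the phase perturbation exactly
  flip <- phantom_spec(
    grid_shape = c(96L, 96L, 32L), voxel_size = c(1, 1, 3),
    background_phase_coeffs = numeric(0), noise_sd = 0,
    sources = list(
      susceptibility_source(c(30, 48, 16), 4, -0.5, "calcification"),
      susceptibility_source(c(66, 48, 16), 4, +0.5, "hemorrhage")
    ))
  orig <- two_source_spec(); orig$background_phase_coeffs <- numeric(0)
  expect_equal(simulate_phantom(flip)$volume$phase,
               -simulate_phantom(orig)$volume$phase, tolerance = 1e-12)

  # magnitude attenuation applies inside sources only (tolerance: magnitude
  # is re-extracted as Mod(m * exp(i*phi)))
  sim <- simulate_phantom(orig)
  src <- sim$truth$label_volume > 0L
  expect_lt(max(abs(sim$volume$magnitude[src] - 0.5)), 1e-12)
  expect_lt(max(abs(sim$volume$magnitude[!src] - 1)), 1e-12)
})

test_that("hemorrhage phase sign follows handedness end to end", {
  for (h in c("left", "right")) {
    spec <- two_source_spec(handedness = h)
    sim <- simulate_phantom(spec)
    fp <- highpass_filter_phase(sim$volume)
    hem <- sim$truth$label_volume == 1L
    cal <- sim$truth$label_volume == 2L
    s <- if (h == "left") 1 else -1
    expect_lt(s * mean(fp$phase_hp[hem]), 0)   # blood dark on filtered phase
    expect_gt(s * mean(fp$phase_hp[cal]), 0)   # calcification bright
  }
})

test_that("cohort simulation is reproducible and converges to its rates", {
  a <- simulate_cohort(seed = 5L)
  b <- simulate_cohort(seed = 5L)
  expect_identical(a, b)
  expect_identical(nrow(a), 2L * 76L)

  all_on <- simulate_cohort(
    detect_probs = list(hemorrhage = c(swi = 1, conv_mri = 1, ct = 1),
                        calcification = c(swi = 1, conv_mri = 1, ct = 1)),
    seed = 2L)
  expect_true(all(all_on$swi_detected == all_on$present))
  expect_true(all(all_on$ct_detected == all_on$present))

  none <- simulate_cohort(
    detect_probs = list(hemorrhage = c(swi = 0, conv_mri = 0, ct = 0),
                        calcification = c(swi = 0, conv_mri = 0, ct = 0)),
    seed = 2L)
  expect_true(!any(none$swi_detected))

  # binomial convergence of the SWI-positive fraction among cancer patients
  big <- simulate_cohort(n_cancer = 10000L, n_bph = 0L, seed = 3L)
  hem <- big[big$lesion_kind == "hemorrhage", ]
  p <- 19 / 23
  frac <- mean(hem$swi_detected)
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 10000))
})
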