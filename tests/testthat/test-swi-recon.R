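make_vol <- function(mag, phase, ...) {
  complex_gre_volume(mag, phase, voxel_size = c(1, 1, 1), ...)
}

test_that("homodyne filter suppresses uniform and smooth phase, keeps impulses", {
  dims <- c(96, 96, 2)
  mag <- array(1, dims)

  # uniform phase is removed entirely
  vol <- make_vol(mag, array(0.8, dims))
  fp <- highpass_filter_phase(vol, recon_params(filter_size = c(64, 64)))
  interior <- fp$phase_hp[17:80, 17:80, ]
  expect_lt(max(abs(interior)), 1e-6)

  # smooth quadratic background spanning 2*pi: max |filtered| drops >= 10x
  x <- 2 * (seq_len(96) - 48.5) / 95
  quad <- outer(x^2, x^2, `+`) * pi   # range ~ [0, 2*pi]
  ph <- wrap_phase(array(rep(quad, dims[3]), dims))
  fpq <- highpass_filter_phase(make_vol(mag, ph),
                               recon_params(filter_size = c(64, 64)))
  expect_lt(max(abs(fpq$phase_hp)), max(abs(quad)) / 10)

  # a single-voxel impulse of 0.5 rad survives mostly intact
  imp <- array(0, dims); imp[48, 48, 1] <- 0.5
  fpi <- highpass_filter_phase(make_vol(mag, imp), recon_params())
  expect_gte(abs(fpi$phase_hp[48, 48, 1]), 0.4)
})

test_that("homodyne filter agrees with a DFT-matrix oracle", {
  dims <- c(24, 24, 1)
  set.seed(4)
  mag <- array(runif(prod(dims), 0.5, 1.5), dims)
  ph <- array(wrap_phase(rnorm(prod(dims), sd = 1.2)), dims)
  for (win in c("hann", "boxcar")) {
    params <- recon_params(filter_size = c(16, 16), window = win)
    fp <- highpass_filter_phase(make_vol(mag, ph), params)
    oracle <- homodyne_oracle_slice(mag[, , 1], ph[, , 1], c(16, 16), win)
    expect_equal(fp$phase_hp[, , 1], oracle, tolerance = 1e-10)
  }
})

test_that("filter size must fit inside the in-plane matrix", {
  vol <- make_vol(array(1, c(32, 32, 2)), array(0, c(32, 32, 2)))
  expect_error(highpass_filter_phase(vol, recon_params(filter_size = c(64, 64))),
               "smaller than the in-plane matrix")
})

test_that("negative-phase mask follows the stated linear ramp", {
  deg <- function(d) d * pi / 180
  m <- make_phase_mask(c(deg(90), deg(0), deg(-90), -pi + 1e-15, deg(45),
                         deg(-45)))
  expect_equal(m$mask[1], 1)
  expect_equal(m$mask[2], 1)
  expect_equal(m$mask[3], 0.5)
  expect_equal(m$mask[4], 0, tolerance = 1e-12)
  expect_equal(m$mask[5], 1)
  expect_equal(m$mask[6], 0.75)

  # mask in [0,1] and non-decreasing on (-pi, 0], constant at 1 on [0, pi]
  ph <- sort(wrap_phase(runif(1e4, -pi + 1e-9, pi)))
  mk <- make_phase_mask(ph)$mask
  expect_true(all(mk >= 0 & mk <= 1))
  expect_true(all(diff(mk[ph <= 0]) >= 0))
  expect_true(all(mk[ph >= 0] == 1))
})

test_that("mask multiplication and its exponent behave as stated", {
  mag <- array(16, c(4, 4, 2))
  mk <- array(0.5, c(4, 4, 2))
  expect_equal(apply_mask(mag, mk, 4), array(1.0, c(4, 4, 2)))
  expect_identical(apply_mask(mag, array(1, c(4, 4, 2)), 4), mag)
  expect_error(apply_mask(mag, array(1, c(4, 4, 3)), 4), "shapes differ")

  # higher exponent gives strictly more contrast wherever mask < 1
  set.seed(2)
  mag <- array(runif(64, 0.5, 2), c(4, 4, 4))
  mk <- array(runif(64, 0.05, 0.95), c(4, 4, 4))
  c1 <- 1 - apply_mask(mag, mk, 1) / mag
  c4 <- 1 - apply_mask(mag, mk, 4) / mag
  expect_true(all(c4 > c1))
})

test_that("minimum-intensity projection equals brute-force slab minima", {
  set.seed(9)
  swi <- array(runif(6 * 5 * 8), c(6, 5, 8))

  # depth 1 is the identity
  p1 <- min_intensity_projection(swi, 1L)
  expect_equal(p1$mip, swi)

  # two slices, one voxel: min wins
  two <- array(c(5, 3), c(1, 1, 2))
  expect_equal(min_intensity_projection(two, 2L)$mip[1, 1, 1], 3)

  # random volume, depth 2, against triple-loop brute force
  p2 <- min_intensity_projection(swi, 2L)
  expect_identical(dim(p2$mip)[3], 4L)
  for (s in 1:4) for (i in 1:6) for (j in 1:5) {
    zr <- (2 * s - 1):(2 * s)
    expect_identical(p2$mip[i, j, s], min(swi[i, j, zr]))
  }

  # trailing partial slab: 8 slices, depth 3 -> sections of 3, 3, 2 slices
  p3 <- min_intensity_projection(swi, 3L)
  expect_identical(dim(p3$mip)[3], 3L)
  expect_equal(p3$slabs$last_slice, c(3L, 6L, 8L))
  expect_equal(p3$mip[2, 2, 3], min(swi[2, 2, 7:8]))

  expect_error(min_intensity_projection(swi, 0L), ">= 1")
  expect_error(min_intensity_projection(swi, 9L), "exceeds")
})

test_that("full reconstruction honours its invariants on a phantom", {
  sim <- simulate_phantom(two_source_spec(noise_sd = 0.05))
  rec <- reconstruct_swi(sim$volume)

  expect_true(all(rec$mask$mask >= 0 & rec$mask$mask <= 1))
  expect_true(all(rec$swi <= sim$volume$magnitude + 1e-15))
  expect_true(all(rec$filtered_phase$phase_hp > -pi &
                  rec$filtered_phase$phase_hp <= pi))

  # mIP never exceeds any slice of its slab and equals the argmin slice
  for (s in seq_len(nrow(rec$slabs))) {
    zr <- rec$slabs$first_slice[s]:rec$slabs$last_slice[s]
    for (z in zr) expect_true(all(rec$mip[, , s] <= rec$swi[, , z]))
    expect_equal(rec$mip[, , s],
                 apply(rec$swi[, , zr, drop = FALSE], c(1, 2), min))
  }

  # bit-reproducible
  rec2 <- reconstruct_swi(sim$volume)
  expect_identical(rec$swi, rec2$swi)
  expect_identical(rec$filtered_phase$phase_hp, rec2$filtered_phase$phase_hp)
})

test_that("all-zero phase yields mask one and swi equal to magnitude", {
  set.seed(3)
  mag <- array(runif(16 * 16 * 4, 0.5, 2), c(16, 16, 4))
  rec <- reconstruct_swi(make_vol(mag, array(0, c(16, 16, 4))),
                         recon_params(filter_size = c(8, 8)))
  expect_true(all(rec$mask$mask == 1))
  expect_identical(rec$swi, mag)
})

test_that("handedness flip negates the noiseless filtered phase", {
  # background polynomial off: it does not flip with handedness
  ls <- two_source_spec(handedness = "left")
  ls$background_phase_coeffs <- numeric(0)
  rs <- two_source_spec(handedness = "right")
  rs$background_phase_coeffs <- numeric(0)
  left <- simulate_phantom(ls)
  right <- simulate_phantom(rs)
  fl <- highpass_filter_phase(left$volume)
  fr <- highpass_filter_phase(right$volume)
  # compare away from the wrap boundary
  ok <- abs(fl$phase_hp) < 3
  expect_lt(max(abs(fl$phase_hp[ok] + fr$phase_hp[ok])), 1e-8)
})

test_that("paramagnetic vs diamagnetic sources separate on SWI as expected", {
  sim <- simulate_phantom(two_source_spec())
  rec <- reconstruct_swi(sim$volume)
  hem <- sim$truth$label_volume == 1L
  cal <- sim$truth$label_volume == 2L
  # blood: mask-attributable darkening on top of magnitude attenuation
  expect_lt(mean(rec$swi[hem]), mean(sim$volume$magnitude[hem]))
  expect_lt(mean(rec$mask$mask[hem]), 0.95)
  # calcification: mask ~ 1, darkening from magnitude attenuation only
  expect_gt(mean(rec$mask$mask[cal]), 0.98)
  expect_equal(mean(rec$swi[cal]) / mean(sim$volume$magnitude[cal]), 1,
               tolerance = 0.03)
})
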