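test_that("cylindrical Gaussian mask has the right profile", {
  mk <- cylindrical_gaussian_mask(c(48, 48, 16), apix = 11.81, diameter = 280)
  ctr <- (48 - 1) / 2
  # on-axis value 1 (sample the voxel nearest the axis)
  expect_equal(mk$grid[24, 24, 1], 1)
  expect_equal(max(mk$grid), 1)
  expect_true(min(mk$grid) >= 0)
  # at r0 + 4 sigma the falloff is below exp(-8) (wider box so the 4-sigma
  # point lies inside it)
  mk64 <- cylindrical_gaussian_mask(c(64, 64, 16), apix = 11.81,
                                    diameter = 280)
  r0 <- 140; sg <- r0 / 4
  far_vox <- ceiling((64 - 1) / 2 + (r0 + 4 * sg) / 11.81)
  expect_lt(mk64$grid[far_vox + 1, 32, 1], exp(-8) + 1e-6)
  # mask mass is monotonic in diameter
  mass <- vapply(c(150, 280, 400), function(d)
    sum(cylindrical_gaussian_mask(c(48, 48, 16), 11.81, d)$grid), 0)
  expect_true(all(diff(mass) > 0))
  expect_error(cylindrical_gaussian_mask(c(48, 48, 16), 11.81, 1e4),
               "exceeds")
})

test_that("layer-line cross-over matches the closed-form oracle", {
  m <- measure_crossover(cof_filament_bin4())
  oracle <- crossover_from_symmetry(cofilactin_sym()) / 10  # nm
  expect_equal(m$crossover_nm, oracle, tolerance = 1.0 / oracle)
  expect_equal(m$crossover_nm, m$box * m$pixel_nm / m$L_pixels)
  volf <- render_helical_filament(factin_sym(), box = c(48, 48, 512),
                                  apix = 11.81, morphology = "factin")
  mf <- measure_crossover(volf)
  oracle_f <- crossover_from_symmetry(factin_sym()) / 10   # 38.08 nm
  expect_lt(abs(mf$crossover_nm - oracle_f), 1.5)
  # cofilin decoration shortens the measured cross-over too
  expect_lt(m$crossover_nm, mf$crossover_nm)
})

test_that("cross-over measurement is invariant to a polarity flip", {
  vol <- cof_filament_bin4()
  flipped <- density_volume(vol$grid[, dim(vol$grid)[2]:1, dim(vol$grid)[3]:1],
                            vol$apix)
  expect_equal(measure_crossover(flipped)$crossover_nm,
               measure_crossover(vol)$crossover_nm, tolerance = 0.2 / 27)
})

test_that("doubling the Fourier box doubles L and leaves c unchanged", {
  vol <- cof_filament_bin4()
  m1 <- measure_crossover(vol, fft_box = 512L, bin_to = 256L)
  m2 <- measure_crossover(vol, fft_box = 1024L, bin_to = 512L,
                          search_band = c(6L, 80L))
  expect_equal(m2$L_pixels, 2L * m1$L_pixels, tolerance = 0.1)
  expect_lt(abs(m2$crossover_nm - m1$crossover_nm), 1.5)
})

test_that("pure noise has no layer line", {
  set.seed(41)
  noise <- density_volume(array(rnorm(48 * 48 * 512), c(48, 48, 512)), 11.81)
  expect_error(measure_crossover(noise), "no layer line")
})

test_that("symmetry scoring peaks at the generating parameters", {
  map <- cof_map64()
  truth <- symmetry_score(map, cofilactin_sym())
  expect_gt(truth, 0.99)
  # identity transform scores exactly 1
  expect_equal(symmetry_score(map, list(twist_deg = 0, rise_ang = 0)), 1,
               tolerance = 1e-9)
  # off-grid probes on a (-150..-170) x (20..35) grid never beat the truth
  for (tw in seq(-150, -170, by = -5)) for (ri in seq(20, 35, by = 5)) {
    if (abs(tw + 161.8) < 1 && abs(ri - 28.5) < 1) next
    expect_lt(symmetry_score(map, list(twist_deg = tw, rise_ang = ri)), truth)
  }
  # chirality: the mirrored twist scores strictly lower on a chiral map
  mirror <- symmetry_score(map, list(twist_deg = 161.8, rise_ang = 28.5))
  expect_lt(mirror, truth)
})

test_that("a uniform cylinder degenerates the search surface", {
  cyl <- cylindrical_gaussian_mask(c(32, 32, 32), apix = 5.9, diameter = 100)
  res <- symmetry_grid_search(cyl, twist_range = c(-170, -150),
                              rise_range = c(20, 30), coarse_step = c(5, 2.5))
  expect_true(res$degenerate)
  expect_gt(min(res$surface, na.rm = TRUE), 0.95)
})

test_that("grid search tolerates additive noise", {
  # a single 13-subunit filament carries limited twist information, so the
  # usable noise level for sub-degree recovery is modest (see the methods
  # vignette); at 5% of peak the optimum stays within half a degree
  vol <- cof_map64()
  set.seed(42)
  noisy <- add_noise(vol, 0.05)
  res <- symmetry_grid_search(noisy, twist_range = c(-170, -150),
                              rise_range = c(24, 33))
  expect_equal(res$best$twist_deg, -161.8, tolerance = 0.5 / 161.8)
  expect_equal(res$best$rise_ang, 28.5, tolerance = 0.3 / 28.5)
  expect_false(res$degenerate)
})

test_that("FSC behaves on identical, independent and constructed half-maps", {
  vol <- render_helical_filament(cofilactin_sym(), box = 32, apix = 5.9)
  f_self <- fsc_curve(vol, vol)
  expect_true(all(abs(f_self$fsc - 1) < 1e-9))
  expect_true(is.na(fsc_resolution(vol, vol)$resolution_ang))
  # FSC is symmetric in its arguments
  set.seed(43)
  n1 <- density_volume(array(rnorm(32^3), c(32, 32, 32)), 5.9)
  n2 <- density_volume(array(rnorm(32^3), c(32, 32, 32)), 5.9)
  f12 <- fsc_curve(n1, n2); f21 <- fsc_curve(n2, n1)
  expect_equal(f12$fsc, f21$fsc, tolerance = 1e-9)
  # independent noise: |FSC| ~ 0 beyond the 3rd shell, within 3/sqrt(n)
  tailsh <- f12[f12$shell > 3, ]
  expect_true(all(abs(tailsh$fsc) < 3 / sqrt(tailsh$n_voxels / 2)))
  # half-maps sharing a 20 A lowpassed signal resolve at 20 +- 2 A
  d <- dim(vol$grid)
  fi <- function(n) { k <- 0:(n - 1); ifelse(k > n / 2, k - n, k) / n }
  kr <- sqrt(outer(outer(fi(d[1])^2, fi(d[2])^2, "+"), fi(d[3])^2, "+")) /
    vol$apix
  sig <- Re(stats::fft(stats::fft(vol$grid) * (kr <= 1 / 20),
                       inverse = TRUE)) / prod(d)
  set.seed(44)
  mk_half <- function() density_volume(
    sig + array(rnorm(prod(d), sd = 0.02 * max(sig)), d), vol$apix)
  res <- fsc_resolution(mk_half(), mk_half())
  expect_equal(res$resolution_ang, 20, tolerance = 2 / 20)
  tall <- density_volume(array(0, c(32, 32, 64)), 5.9)
  expect_error(fsc_curve(vol, tall), "differ")
})
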