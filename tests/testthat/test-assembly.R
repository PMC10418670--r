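test_that("missing-angle correction matches closed forms to 6 figures", {
  sigma <- 50
  iso <- function(th) rep(sigma / (4 * pi), length(th))
  # half the solid angle for an isotropic DCS
  expect_equal(missing_angle_correction(iso, acceptance_geometry(89.9999999)),
               sigma / 2, tolerance = 1e-6)
  expect_identical(missing_angle_correction(iso, acceptance_geometry(0)), 0)
  # c cos^2(theta) on [0, 90]: 2 pi c (1 - cos^3 acc) / 3
  cc <- function(th) ifelse(th <= 90, 3.7 * cos(th * pi / 180)^2, 0)
  expect_equal(missing_angle_correction(cc, acceptance_geometry(60)),
               2 * pi * 3.7 * (1 - cos(pi / 3)^3) / 3, tolerance = 1e-6)
  expect_equal(missing_angle_correction(cc, acceptance_geometry(60)),
               2 * pi * 3.7 * 7 / 24, tolerance = 1e-6)
  # backward cone adds the analogous integral
  both <- missing_angle_correction(iso, acceptance_geometry(30, 150))
  expect_equal(both, sigma / 2 * (1 - cos(pi / 6)) * 2, tolerance = 1e-6)
  expect_error(
    missing_angle_correction(function(th) -iso(th), acceptance_geometry(10)),
    "negative DCS")
})

test_that("total inelastic subtraction matches the printed tables and clamps", {
  tcs <- load_xs_set("1m5ni_tcs_reference")
  rec <- load_xs_set("1m5ni_recommended")
  inel <- derive_total_inelastic(tcs$tables$tcs_reference,
                                 rec$tables$elastic, grid = 20)
  expect_equal(inel$values, 73.18 - 54.9, tolerance = 1e-12)
  ref <- channel_table("tcs_reference", c(1, 10, 100), c(50, 40, 30))
  expect_identical(
    derive_total_inelastic(ref, channel_table("elastic", c(1, 10, 100),
                                              c(50, 40, 30)))$values,
    c(0, 0, 0))
  bigger <- channel_table("elastic", c(1, 10, 100), c(55, 40, 30))
  expect_warning(out <- derive_total_inelastic(ref, bigger), "clamped")
  expect_identical(out$values[1], 0)
  disjoint <- channel_table("elastic", c(500, 900), c(10, 8))
  expect_error(derive_total_inelastic(ref, disjoint), "disjoint")
})

test_that("resonance extraction recovers a synthetic peak to 5% in area", {
  g <- fine_log_grid()
  cur <- make_resonance_curve(g, peaks = data.frame(center = 2, width = 0.4,
                                                    area = 8))
  truth <- attr(cur, "truth")
  dec <- extract_resonances(cur)
  expect_equal(nrow(dec$peaks), 1)
  expect_false(dec$peaks$flagged_pseudo)
  # center within one grid spacing of 2 eV
  i <- which.min(abs(g - 2))
  expect_lt(abs(dec$peaks$center_eV - 2), diff(g)[i])
  expect_equal(trapz(g, dec$attachment$values), trapz(g, truth$resonant),
               tolerance = 0.05)
  # background + attachment reproduces the input off the clamped floor
  expect_true(all(dec$background$values + dec$attachment$values >=
                  cur$values * (1 - 0.05)))
  expect_true(all(dec$attachment$values >= 0))
})

test_that("resonance extraction: smooth input, coarse grids, pseudo-peaks", {
  g <- fine_log_grid()
  smooth <- make_resonance_curve(g)
  dec <- extract_resonances(smooth)
  expect_identical(max(dec$attachment$values), 0)
  expect_identical(nrow(dec$peaks), 0L)
  # idempotent on its own background
  peaked <- make_resonance_curve(g, peaks = data.frame(center = 2,
                                                       width = 0.4, area = 8))
  dec1 <- extract_resonances(peaked)
  expect_identical(max(extract_resonances(dec1$background)$attachment$values),
                   0)
  # peak above the cutoff is flagged and zeroed in the attachment
  hi <- make_resonance_curve(g, peaks = data.frame(center = 12, width = 0.8,
                                                   area = 5))
  dec2 <- extract_resonances(hi)
  expect_true(any(dec2$peaks$flagged_pseudo))
  expect_identical(max(dec2$attachment$values[g > 10]), 0)
  # coarse printed grid still locates the peak within one grid spacing
  crs <- make_resonance_curve(coarse_low_grid,
                              peaks = data.frame(center = 2, width = 0.4,
                                                 area = 8))
  dec3 <- extract_resonances(crs)
  expect_lt(abs(dec3$peaks$center_eV[which.max(dec3$peaks$height)] - 2), 1)
  expect_error(extract_resonances(
    channel_table("elastic", 1:5, rep(1, 5))), "insufficient data")
})

test_that("inelastic partition conserves the residual and obeys thresholds", {
  rec <- load_xs_set("1m5ni_recommended")
  spec <- calibrate_partition(rec)
  E <- c(2, 20)
  resid <- channel_table(
    "electronic", E,
    interpolate_xs(rec$tables$vibrational, E) +
      interpolate_xs(rec$tables$electronic, E))
  parts <- partition_inelastic(resid, spec)
  # printed rows: all-vibrational at 2 eV, all-electronic at 20 eV
  expect_equal(parts$vibrational$values, c(20.3, 0), tolerance = 1e-9)
  expect_equal(parts$electronic$values, c(0, 15.2), tolerance = 1e-9)
  # conservation on a dense grid
  g <- exp(seq(log(0.7), log(900), length.out = 120))
  r2 <- channel_table("electronic", g, 5 + 10 / g)
  p2 <- partition_inelastic(r2, spec)
  expect_equal(p2$vibrational$values + p2$electronic$values, r2$values,
               tolerance = 1e-12)
  expect_true(all(p2$vibrational$values >= 0))
  expect_true(all(p2$electronic$values >= 0))
  expect_true(all(p2$electronic$values[g < spec$elec_threshold] == 0))
  zero <- channel_table("electronic", g, rep(0, length(g)))
  p0 <- partition_inelastic(zero, spec)
  expect_identical(max(p0$vibrational$values, p0$electronic$values), 0)
  expect_error(partition_spec(0.7, 4, anchor_E = c(5, 10),
                              anchor_w = c(0.5, 1.2)), "spec error")
})

test_that("assembly pipeline reproduces the recommended vibrational and electronic columns", {
  # feed the reference TCS, the recommended elastic/ionization/attachment and
  # the data-calibrated partition back through the assembly chain
  tcs <- load_xs_set("1m5ni_tcs_reference")
  rec <- load_xs_set("1m5ni_recommended")
  spec <- calibrate_partition(rec)
  grid <- rec$tables$tcs_reference$energies
  grid <- grid[grid >= 1 & grid <= 300 & grid != 70]  # reference span, anomaly out
  suppressWarnings({
    inel <- derive_total_inelastic(tcs$tables$tcs_reference,
                                   rec$tables$elastic, grid = grid)
  })
  resid <- pmax(inel$values - interpolate_xs(rec$tables$ionization, grid) -
                  interpolate_xs(rec$tables$attachment, grid), 0)
  parts <- partition_inelastic(channel_table("electronic", grid, resid), spec)
  vib_ref <- interpolate_xs(rec$tables$vibrational, grid)
  ele_ref <- interpolate_xs(rec$tables$electronic, grid)
  dev <- pmax(abs(parts$vibrational$values - vib_ref),
              abs(parts$electronic$values - ele_ref))
  # at 15, 200 and 300 eV the printed reference TCS and the recommended SUM
  # column themselves disagree by 0.16-0.42, so the rebuilt split inherits
  # that gap; everywhere else the chain closes within 0.15
  loose <- grid %in% c(15, 200, 300)
  expect_lt(max(dev[!loose]), 0.15)
  expect_lt(max(dev[loose]), 0.5)
})
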