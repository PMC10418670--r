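test_that("channel tables reject invalid inputs instead of repairing them", {
  expect_error(channel_table("elastic", c(2, 1), c(1, 1)),
               "not strictly increasing")
  expect_error(channel_table("elastic", c(1, 2), c(1, -1)), "negative")
  expect_error(channel_table("elastic", c(0, 1), c(1, 1)), "> 0")
  expect_error(channel_table("elastic", c(1, 2), c(1, 1, 1)), "length")
  expect_error(channel_table("elastic", numeric(), numeric()), "empty")
  expect_error(channel_table("ionization", c(1, 20), c(0.5, 3),
                             threshold = 15),
               "below threshold")
})

test_that("interpolation is exact on grid points and log-log between them", {
  set <- load_xs_set("1m5ni_recommended")
  el <- set$tables$elastic
  # bit-level equality at every grid node
  expect_identical(interpolate_xs(el, el$energies), el$values)
  expect_identical(interpolate_xs(el, 20), 54.9)
  # log-log midpoint between the 20 and 30 eV nodes
  expect_equal(interpolate_xs(el, sqrt(20 * 30)),
               exp((log(54.9) + log(46.8)) / 2), tolerance = 1e-12)
  # interpolated values stay between the bracketing nodes
  E <- exp(seq(log(0.11), log(990), length.out = 400))
  v <- interpolate_xs(el, E)
  i <- findInterval(E, el$energies)
  inner <- E != el$energies[pmax(i, 1)]
  expect_true(all(v[inner] >= pmin(el$values[i], el$values[i + 1])[inner]))
  expect_true(all(v[inner] <= pmax(el$values[i], el$values[i + 1])[inner]))
})

test_that("closed channels interpolate to zero below threshold, error off-span", {
  set <- load_xs_set("1m5ni_recommended")
  expect_identical(interpolate_xs(set$tables$ionization, 10), 0)
  expect_identical(interpolate_xs(set$tables$electronic, c(0.5, 2)), c(0, 0))
  expect_error(interpolate_xs(set$tables$elastic, 1001), "outside tabulated")
  expect_error(interpolate_xs(set$tables$elastic, 0.05), "outside tabulated")
  # linear fallback across a zero cell stays within the bracketing values
  vib <- set$tables$vibrational
  v8 <- interpolate_xs(vib, 8)
  expect_gt(v8, 0)
  expect_lt(v8, 14.2)
})

test_that("channel CSV schema round-trips bit-exactly and rejects bad files", {
  tab <- channel_table("attachment", c(1.5, 2, 3), c(2.39, 14.5, 4.12),
                       threshold = 1.5, provenance = "round-trip check")
  path <- withr::local_tempfile(fileext = ".csv")
  write_channel_csv(tab, path, molecule = "test")
  back <- read_channel_csv(path)
  expect_identical(back$energies, tab$energies)
  expect_identical(back$values, tab$values)
  expect_identical(back$threshold, tab$threshold)
  expect_identical(attr(back, "molecule"), "test")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# channel: elastic", "# units: 1e-20 m2",
               "energy_eV,sigma_1e-20_m2", "2,5", "1,5"), bad)
  expect_error(read_channel_csv(bad), "not strictly increasing")
  writeLines(c("# channel: elastic", "energy_eV,sigma_1e-20_m2"), bad)
  expect_error(read_channel_csv(bad), "no data rows")
  writeLines(c("energy_eV,sigma_1e-20_m2", "1,5"), bad)
  expect_error(read_channel_csv(bad), "channel")
})

test_that("open-channel sums reproduce the recommended SUM column", {
  set <- load_xs_set("1m5ni_recommended")
  expect_equal(sum_channels(set, 20), 73.2, tolerance = 0.15 / 73.2)
  expect_equal(sum_channels(set, 1000), 13.8, tolerance = 0.15 / 13.8)
  only_el <- xs_set("toy", list(set$tables$elastic))
  expect_identical(sum_channels(only_el, 0.1), 390)
})

test_that("closure validation flags only the known anomalous row", {
  set <- load_xs_set("1m5ni_recommended")
  rep <- validate_consistency(set, tol = 0.15, known_anomalies = 70)
  expect_s3_class(rep, "xs_closure_report")
  expect_identical(attr(rep, "n_fail"), 0L)
  expect_identical(rep$energy_eV[!rep$pass], 70)
  expect_true(rep$flagged[rep$energy_eV == 70])
  # exact fractions of the reference close to machine precision
  ref <- set$tables$tcs_reference
  frac <- xs_set("frac", list(
    channel_table("elastic", ref$energies, 0.6 * ref$values),
    channel_table("electronic", ref$energies, 0.4 * ref$values),
    ref))
  rep2 <- validate_consistency(frac, tol = 1e-9)
  expect_identical(attr(rep2, "n_fail"), 0L)
  # degenerate tolerance flags essentially everything with floating data
  rep3 <- validate_consistency(set, tol = 0)
  expect_gt(attr(rep3, "n_fail"), nrow(rep3) / 2)
})

test_that("missing-angle-corrected TCS dominates the measured TCS everywhere", {
  tcs <- load_xs_set("1m5ni_tcs_reference")
  expect_true(all(tcs$tables$tcs_reference$values >=
                  tcs$tables$tcs_experimental$values))
  expect_identical(interpolate_xs(tcs$tables$tcs_experimental, 300), 27.6)
  expect_identical(interpolate_xs(tcs$tables$tcs_reference, 300), 28.78)
})

test_that("a set rejects duplicate channels and records span mismatches", {
  el <- channel_table("elastic", c(1, 10), c(80, 70))
  expect_error(xs_set("m", list(el, el)), "duplicate channel")
  ref <- channel_table("tcs_reference", c(2, 8), c(90, 75))
  s <- xs_set("m", list(el, ref))
  expect_identical(s$outside_reference_span, "elastic")
})
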