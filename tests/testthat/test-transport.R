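rec_set <- load_xs_set("1m5ni_recommended")

test_that("free paths are exponential with mean 1/(n sigma)", {
  cfg <- transport_config(density_m3 = 1e25, E0_eV = 100)
  set.seed(41)
  s <- step_free_path(20, rec_set, cfg, n = 1e5)
  lambda <- 1 / (1e25 * sum_channels(rec_set, 20) * 1e-20)
  expect_lt(abs(mean(s) - lambda), 3 * lambda / sqrt(1e5))
  # doubling the density halves the mean free path
  cfg2 <- transport_config(density_m3 = 2e25, E0_eV = 100)
  set.seed(42)
  s2 <- step_free_path(20, rec_set, cfg2, n = 1e5)
  expect_equal(mean(s2) / mean(s), 0.5, tolerance = 0.02)
  # seed reproducibility
  set.seed(43); a <- step_free_path(20, rec_set, cfg, n = 100)
  set.seed(43); b <- step_free_path(20, rec_set, cfg, n = 100)
  expect_identical(a, b)
  expect_error(step_free_path(2000, rec_set, cfg), "outside tabulated")
})

test_that("single-collision channel frequencies match the table ratios", {
  n <- 1e5
  # at 0.1 eV only the elastic channel is open
  expect_identical(unique(choose_channel(0.1, rec_set, 100)), "elastic")
  for (E in c(2, 20)) {
    probs <- vapply(c("elastic", "attachment", "vibrational", "electronic",
                      "ionization"),
                    function(ch) interpolate_xs(rec_set$tables[[ch]], E),
                    numeric(1))
    probs <- probs / sum(probs)
    set.seed(44 + E)
    draws <- choose_channel(E, rec_set, n)
    counts <- table(factor(draws, levels = names(probs)))
    keep <- probs > 0
    expect_gt(stats::chisq.test(counts[keep], p = probs[keep])$p.value, 0.01)
  }
  # spot checks against printed-row ratios
  set.seed(46)
  d2 <- choose_channel(2, rec_set, n)
  p_att <- 14.5 / (63.3 + 14.5 + 20.3)
  expect_lt(abs(mean(d2 == "attachment") - p_att),
            3 * sqrt(p_att * (1 - p_att) / n))
  set.seed(47)
  d20 <- choose_channel(20, rec_set, n)
  p_ion <- 3.11 / (54.9 + 15.2 + 3.11)
  expect_lt(abs(mean(d20 == "ionization") - p_ion),
            3 * sqrt(p_ion * (1 - p_ion) / n))
})

test_that("collision semantics follow the channel contracts", {
  cfg <- transport_config(E0_eV = 67)
  models <- transport_models(rec_set)
  st <- list(E = 67, dir = c(0, 0, 1), pos = c(0, 0, 0))
  set.seed(48)
  el <- apply_collision(st, "elastic", models, cfg)
  expect_identical(el$event$E_after, el$event$E_before)
  expect_null(el$secondary)
  expect_equal(sum(el$electron$dir^2), 1, tolerance = 1e-12)
  vib <- apply_collision(st, "vibrational", models, cfg)
  expect_equal(vib$electron$E, 67 - cfg$vibrational_loss_eV)
  expect_equal(vib$event$deposit, cfg$vibrational_loss_eV)
  ion <- apply_collision(st, "ionization", models, cfg)
  expect_false(is.null(ion$secondary))
  expect_gte(ion$secondary$E, 0)
  # loss = deposit + secondary KE; deposit includes the binding energy
  expect_equal(ion$event$E_before - ion$event$E_after,
               ion$event$deposit + ion$secondary$E, tolerance = 1e-12)
  expect_gte(ion$event$deposit, cfg$ionization_eV - 1e-12)
  expect_true(ion$event$product %in% models$cation$species)
  att <- apply_collision(list(E = 3.1, dir = c(0, 0, 1), pos = c(0, 0, 0)),
                         "attachment", models, cfg)
  expect_null(att$electron)              # the electron is captured
  expect_true(att$event$product %in% models$anion_br$species)
  expect_equal(att$event$deposit, 3.1)
  expect_gte(att$event$product_ke, 0)
})

test_that("ionization at 67 eV reproduces the cation inventory", {
  cfg <- transport_config(E0_eV = 67)
  models <- transport_models(rec_set)
  n <- 2e4
  set.seed(49)
  prods <- sample_cation(models$cation, n)   # apply_collision delegates here
  counts <- table(factor(prods, levels = models$cation$species))
  p <- models$cation$intensity / sum(models$cation$intensity)
  expect_gt(stats::chisq.test(counts, p = p)$p.value, 0.01)
})

test_that("cascades conserve energy and reproduce with a fixed seed", {
  cfg <- transport_config(E0_eV = 500, cutoff_eV = 1, max_events = 20000,
                          collect_events = FALSE)
  set.seed(51)
  run <- simulate_tracks(rec_set, cfg, n_primaries = 25)
  expect_true(all(run$summary$closure_rel < 1e-6))
  expect_false(any(run$summary$truncated))
  expect_true(all(run$summary$n_ionization >= 1))
  expect_gt(sum(run$summary$n_secondaries), 0)
  # event stream is bitwise reproducible under the same seed
  cfg2 <- transport_config(E0_eV = 150, cutoff_eV = 1, collect_events = TRUE)
  set.seed(52); r1 <- simulate_tracks(rec_set, cfg2, n_primaries = 3)
  set.seed(52); r2 <- simulate_tracks(rec_set, cfg2, n_primaries = 3)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$summary, r2$summary)
  # energy never increases along an electron's event sequence
  expect_true(all(r1$events$E_after <= r1$events$E_before + 1e-12))
})

test_that("sub-threshold transport reduces to a capped elastic random walk", {
  cfg <- transport_config(E0_eV = 0.5, cutoff_eV = 0.1, max_events = 300,
                          channels = "elastic", collect_events = TRUE)
  set.seed(53)
  run <- simulate_tracks(rec_set, cfg, n_primaries = 2)
  expect_identical(unique(run$events$channel), "elastic")
  expect_true(all(run$summary$truncated))       # nothing can stop it but the cap
  expect_identical(unique(run$summary$n_events), 300L)
  expect_equal(run$summary$residual_eV, c(0.5, 0.5))   # no energy lost
  # step lengths are exponential with the elastic-only mean free path
  lam <- 1 / (cfg$density_m3 * interpolate_xs(rec_set$tables$elastic, 0.5) *
              1e-20)
  d <- run$events[run$events$track == 1, c("x", "y", "z")]
  seg <- sqrt(diff(d$x)^2 + diff(d$y)^2 + diff(d$z)^2)
  expect_lt(abs(mean(seg) - lam), 4 * lam / sqrt(length(seg)))
})

test_that("JSONL event stream round-trips through jsonlite", {
  cfg <- transport_config(E0_eV = 30, cutoff_eV = 1, collect_events = TRUE)
  set.seed(54)
  run <- simulate_tracks(rec_set, cfg, n_primaries = 2)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_events_jsonl(run, path)
  lines <- readLines(path)
  expect_identical(length(lines), nrow(run$events))
  first <- jsonlite::fromJSON(lines[1])
  expect_identical(first$track, 1L)
  expect_equal(first$E_before, cfg$E0_eV)
})

test_that("configuration guards reject unusable setups", {
  expect_error(transport_config(density_m3 = 0), "density")
  expect_error(
    simulate_tracks(rec_set, transport_config(E0_eV = 100, cutoff_eV = 0.01)),
    "data floor")
  expect_error(
    simulate_tracks(rec_set, transport_config(E0_eV = 5000)),
    "tabulated span")
})
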