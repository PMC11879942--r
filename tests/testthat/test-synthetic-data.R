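test_that("config invariants are enforced", {
  expect_error(sim_config(eprime = c(mean = 5.5, sd = -1)), "SD")
  expect_error(sim_config(group_sizes = list(
    "Sham" = c(fusion = 0L, half = 7L, sep = 19L),
    "HTN-CM" = c(fusion = 15L, half = 25L, sep = 26L))), ">= 1")
  expect_error(sim_config(preload_coupling = c(e = 0.5, eprime = 0.4)),
               "strictly greater")
  expect_error(sim_config(la_loading = 1.2), "la_loading")
})

test_that("cycle length and diastasis follow heart rate", {
  cfg <- sim_config()
  hrs <- seq(250, 420, by = 10)
  truths <- lapply(hrs, function(h) animal_truth("Sham", h, cfg, 0.9, 0.6, 5.5))
  cyc <- vapply(truths, `[[`, numeric(1), "cycle_length")
  expect_equal(cyc, 60000 / hrs)
  dia <- vapply(truths, `[[`, numeric(1), "diastasis")
  expect_true(all(diff(dia) < 0))
  expect_error(animal_truth("Sham", 1500, cfg, 0.9, 0.6, 5.5),
               "shorter than the cycle")
})

test_that("generated cycles have the documented morphology", {
  cfg <- sim_config()
  # slow heart: diastasis > 0, two separated lobes at the annulus
  slow <- animal_truth("Sham", 260, cfg, 0.9, 0.6, 5.5)
  expect_gt(slow$diastasis, 0)
  map <- generate_cycle(slow, ds = 0.05, dt = 1, n_cycles = 2)
  tr <- base_trace(map)[cmmeivpg:::cycle_windows(map)[[1]]]
  f <- extract_wave_features(tr, dt = 1)
  expect_equal(nrow(f$peaks), 2)
  expect_identical(f$inter_peak_min, 0)
  expect_gt(f$diastasis_estimate, 0)
  # E pulse starts at end of systole, A pulse ends at cycle end
  expect_true(all(tr[1:cfg$systolic_interval_ms] == 0))
  expect_gt(tr[cfg$systolic_interval_ms + 25], 0)
  expect_gt(tr[length(tr) - 5], 0)

  # fast heart: single-lobed merged wave (brute-force scan of the trace)
  fast <- animal_truth("Sham", 410, cfg, 0.9, 0.6, 5.5)
  expect_lt(fast$diastasis, 0)
  trf <- base_trace(generate_cycle(fast, 0.05, 1, 2))
  w <- cmmeivpg:::cycle_windows(generate_cycle(fast, 0.05, 1, 2))[[1]]
  pk <- cmmeivpg:::find_local_maxima(trf[w])
  pk <- pk[trf[w][pk] >= 0.1 * max(trf[w])]
  expect_length(pk, 1)

  # zero A amplitude: the base trace is the E pulse alone
  e_only <- animal_truth("Sham", 300, cfg, 0.9, 0, 5.5)
  tre <- base_trace(generate_cycle(e_only, 0.05, 1, 2))
  expect_equal(max(tre), e_only$e$amp, tolerance = 1e-3)
  win <- seq_len(round(e_only$cycle_length))
  expect_equal(tre[win],
               hann_pulse((win - 1), cfg$systolic_interval_ms,
                          cfg$e_wave$duration_ms, e_only$e$amp),
               tolerance = 1e-12)
})

test_that("maps propagate apically with exponential decay", {
  cfg <- sim_config()
  truth <- animal_truth("Sham", 300, cfg, 0.9, 0, 5.5)
  map <- generate_cycle(truth, ds = 0.05, dt = 1, n_cycles = 2)
  s <- (seq_len(nrow(map$values)) - 1) * map$ds
  rowmax <- apply(map$values[, cmmeivpg:::cycle_windows(map)[[1]]], 1, max)
  # sampled maxima undershoot the continuous peak by O((dt/duration)^2)
  expect_equal(rowmax, truth$e$amp * exp(-s / truth$e$decay_cm),
               tolerance = 2e-3)
  # onset delay at depth s is s / vp
  onset <- apply(map$values, 1, function(r) which(r > 1e-9)[1])
  expect_equal((onset - onset[1]) * map$dt, 1000 * s / truth$e$vp_cms,
               tolerance = map$dt + 1e-9)
})

test_that("generation is deterministic and schemas are seed-stable", {
  cfg <- small_cfg(seed = 7L)
  s1 <- generate_cohort(cfg, keep_maps = FALSE)
  s2 <- generate_cohort(cfg, keep_maps = FALSE)
  expect_identical(s1$cohort, s2$cohort)
  s3 <- generate_cohort(small_cfg(seed = 8L), keep_maps = FALSE)
  expect_identical(names(s3$cohort), names(s1$cohort))
  expect_false(identical(s3$cohort$hr, s1$cohort$hr))
})

test_that("cell-size-one configs give one row per cell", {
  cfg <- small_cfg(n = 1L)
  sim <- generate_cohort(cfg, keep_maps = FALSE)
  expect_equal(nrow(sim$cohort), 6)
  expect_equal(unname(table(sim$cohort$group)), c(3L, 3L),
               ignore_attr = TRUE)
})

test_that("pattern counts are exact and labels match the classifier", {
  sim <- generate_cohort(small_cfg(n = 3L))
  counts <- table(sim$cohort$group, sim$cohort$pattern)
  expect_true(all(counts == 3))
  relabeled <- vapply(sim$maps, function(m) classify_map(m)$code, integer(1))
  expect_equal(relabeled, sim$cohort$pattern_code)
})

test_that("an unrealizable cell fails with a clear message", {
  cfg <- small_cfg(n = 1L)
  cfg$attempt_budget <- 3L
  hd <- cfg$hr_distribution
  hd$mean[hd$pattern == "fusion"] <- 200   # far below the fusion boundary
  hd$sd[hd$pattern == "fusion"] <- 1
  cfg$hr_distribution <- hd
  expect_error(generate_cohort(cfg, keep_maps = FALSE), "hr_distribution")
})
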