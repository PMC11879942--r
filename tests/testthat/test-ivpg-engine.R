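test_that("constant velocity gives an identically zero field and result", {
  m <- velocity_map(matrix(0.8, 21, 50), ds = 0.1, dt = 1, lv_length = 2)
  expect_lt(max(abs(pressure_gradient_field(m))), 1e-8)
  tr <- ivpd_trace(m)
  expect_lt(max(abs(tr$total)), 1e-9)
  expect_lt(max(abs(tr$basal)), 1e-9)
  expect_lt(max(abs(tr$mid_apical)), 1e-9)
  expect_lt(abs(ivpg_from_trace(tr)$total_ivpg), 1e-9)
})

test_that("uniform acceleration matches the closed form rho*a and rho*a*L", {
  a <- 5
  m <- uniform_accel_map(a = a, nr = 61, nt = 128)
  f <- pressure_gradient_field(m)
  # v = a t is linear in t and flat in s: the O(h^2) scheme is exact
  expect_equal(max(abs(f - (-RHO * a))), 0, tolerance = 1e-9)
  tr <- ivpd_trace(m)
  expect_equal(unname(tr$total), rep(RHO * a * 0.02 / MMHG, 128),
               tolerance = 1e-12)
  # 61 nodes put L/3 on the grid: basal is exactly one third of total
  expect_equal(tr$basal, tr$total / 3, tolerance = 1e-12)
})

test_that("traveling sine matches its closed form with second-order convergence", {
  errs <- vapply(c(32, 64, 128), function(n) {
    sf <- sine_field(nr = n, nt = 4 * n)
    tr <- suppressMessages(ivpd_trace(sf$map))
    max(abs(tr$total - sf$exact_ivpd)) / max(abs(sf$exact_ivpd))
  }, numeric(1))
  expect_lt(errs[2], 0.01)
  orders <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(orders > 1.6 & orders < 2.6))
})

test_that("adding a constant to v changes only the convective term as predicted", {
  sf <- sine_field(nr = 41, nt = 120)
  m <- sf$map
  m2 <- m
  m2$values <- m$values + 0.3
  f1 <- pressure_gradient_field(m)
  f2 <- pressure_gradient_field(m2)
  # (v + c) dv/ds - v dv/ds = c dv/ds, under the same difference operator
  dvds <- cmmeivpg:::fd_derivative(m$values, m$ds / 100, dim = 1)
  expect_equal(f2 - f1, -RHO * 0.3 * dvds, tolerance = 1e-9)
})

test_that("basal and mid-apical IVPD sum to the total at every sample", {
  cfg <- sim_config()
  truth <- animal_truth("Sham", 320, cfg, 0.9, 0.6, 5.5)
  map <- generate_cycle(truth, ds = cfg$ds, dt = cfg$dt, n_cycles = 2)
  tr <- suppressMessages(ivpd_trace(map))
  expect_lt(max(abs(tr$total - (tr$basal + tr$mid_apical))), 1e-9)
  res <- suppressMessages(ivpg(map))
  expect_equal(res$total_ivpg, res$basal_ivpg + res$mid_apical_ivpg,
               tolerance = 1e-12)
})

test_that("ivpg_from_trace divides the peak IVPD by the LV length", {
  tms <- 0:99
  tr <- make_ivpd_trace(tms, basal = rep(2.5, 100), mid_apical = rep(1.5, 100),
                        lv_length = 2)
  res <- ivpg_from_trace(tr)
  expect_equal(res$total_ivpg, 2.0)
  expect_equal(res$basal_ivpg, 1.25)
  expect_error(ivpg_from_trace(tr, window = c(500, 600)), "empty")
})

test_that("total IVPG grows with wave amplitude at fixed shape", {
  cfg <- sim_config()
  tots <- vapply(c(0.6, 0.9, 1.2), function(amp) {
    truth <- animal_truth("Sham", 300, cfg, amp, 0, 5.5)
    suppressMessages(ivpg(generate_cycle(truth, 0.05, 1, 2)))$total_ivpg
  }, numeric(1))
  expect_true(all(diff(tots) > 0))
})

test_that("degenerate inputs are rejected with informative errors", {
  v <- matrix(1, 21, 50)
  v[3, 7] <- NA
  expect_error(velocity_map(v, 0.1, 1, 2), "\\[3, 7\\]")
  m <- velocity_map(matrix(1, 2, 50), ds = 1, dt = 1, lv_length = 2)
  expect_error(ivpd_trace(m), "at least 3")
})

test_that("multi-cycle maps average per-cycle gradients", {
  cfg <- sim_config()
  truth <- animal_truth("HTN-CM", 350, cfg, 0.95, 0.6, 5.5)
  map <- generate_cycle(truth, ds = cfg$ds, dt = cfg$dt, n_cycles = 3)
  res <- suppressMessages(ivpg(map))
  expect_equal(res$n_cycles, 3)
  per <- vapply(res$per_cycle, `[[`, numeric(1), "total_ivpg")
  expect_equal(res$total_ivpg, mean(per))
  # periodic input: interior cycles agree closely
  expect_equal(per[2], per[3], tolerance = 0.05)
})
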