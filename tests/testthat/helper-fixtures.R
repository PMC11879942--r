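# Analytic velocity fields with closed-form IVPD, and small simulation
# configs, built in code at test time.

RHO <- 1060
MMHG <- 133.322

# v(s, t) = a * t  (uniform acceleration, no spatial structure);
# closed form: IVPD = rho * a * L at every instant
uniform_accel_map <- function(a = 5, L = 2, nr = 61, nt = 128, Ttot = 100) {
  ds <- L / (nr - 1)
  dt <- Ttot / (nt - 1)
  tt <- (0:(nt - 1)) * dt / 1000
  V <- matrix(rep(a * tt, each = nr), nr, nt)
  velocity_map(V, ds = ds, dt = dt, lv_length = L)
}

# v(s, t) = Vamp * sin(omega t - k s), one temporal period over the map;
# closed-form IVPD from integrating -dP/ds = rho (dv/dt + v dv/ds):
#   IVPD(t) = rho [ Vamp*omega*(sin(th0) - sin(thL))/k
#                   - (Vamp^2/4) * (cos(2 thL) - cos(2 th0)) ]
# with th0 = omega t, thL = omega t - k L.
sine_field <- function(nr, nt, L = 2, Ttot = 100, Vamp = 0.5,
                       wavelength_cm = 4) {
  ds <- L / (nr - 1)
  dt <- Ttot / (nt - 1)
  om <- 2 * pi / (Ttot / 1000)
  k <- 2 * pi / (wavelength_cm / 100)
  s_m <- (0:(nr - 1)) * ds / 100
  t_s <- (0:(nt - 1)) * dt / 1000
  V <- Vamp * sin(outer(-k * s_m, om * t_s, `+`))
  th0 <- om * t_s
  thL <- om * t_s - k * (L / 100)
  exact <- RHO * (Vamp * om * (sin(th0) - sin(thL)) / k -
                    (Vamp^2 / 4) * (cos(2 * thL) - cos(2 * th0))) / MMHG
  list(map = velocity_map(V, ds = ds, dt = dt, lv_length = L),
       exact_ivpd = exact)
}

# tiny cohort config for fast structural tests
small_cfg <- function(seed = 42L, n = 2L) {
  sim_config(seed = seed,
             group_sizes = list(
               "Sham" = c(fusion = n, half = n, sep = n),
               "HTN-CM" = c(fusion = n, half = n, sep = n)))
}

# textbook Pearson r and its t-transform p-value, as an independent oracle
r_brute <- function(x, y) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}
p_brute <- function(r, n) {
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tstat), n - 2)
}
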