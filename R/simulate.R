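# Synthetic velocity-field and cohort generator.
#
# The generator emulates the measurement situation the pipeline is built
# for: transmitral inflow recorded along the LV long axis in anesthetized
# rats, two surgical groups (Sham, HTN-CM by aortic coarctation), and an
# inflow morphology (EA-separation / half-separation / fusion) driven
# causally by heart rate through loss of diastasis. Each cardiac cycle is
# a systolic no-flow interval followed by an E wave and an A wave, both
# raised-cosine pulses that propagate from the mitral annulus toward the
# apex with exponential amplitude decay and sum where they overlap. The
# A wave is anchored to the end of the cycle (atrial contraction precedes
# the next systole), so
#
#   diastasis = cycle length - systole - E duration - A duration,
#
# which shrinks and goes negative (overlap) as HR rises. Preload coupling:
# the filling-time loss fraction scales latent E and E' amplitudes up,
# with a strictly larger coefficient on E' than on E, which is what makes
# E/E' fall as patterns merge. Left-atrial loading: as filling becomes
# atrial-driven (merging), early inflow concentrates toward the base, so
# the E-wave penetration depth shrinks with the merging fraction; this is
# what loads basal IVPG with the inflow pattern while leaving mid-to-apical
# IVPG (active relaxation) nearly independent of it.

default_hr_distribution <- function() {
  data.frame(
    group = rep(c("Sham", "HTN-CM"), each = 3),
    pattern = rep(c("fusion", "half", "sep"), 2),
    mean = c(359.72, 315.77, 304.14, 350.32, 348.48, 306.22),
    sd = c(42.30, 54.10, 43.97, 40.39, 36.11, 39.68),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' All tunable parameters of the synthetic cohort generator, with
#' defaults matching the emulated study design: group sizes 7/7/19
#' (Sham fusion/half/sep) and 15/25/26 (HTN-CM), per-cell heart-rate
#' distributions in bpm, wave geometry, preload coupling, hypertension
#' effects and measurement-noise SDs. Wave durations and propagation
#' velocities for rats are stated assumptions (see the methods
#' vignette), not literature measurements.
#'
#' @param seed integer RNG seed.
#' @param group_sizes named list `list(Sham = c(fusion=, half=, sep=),
#'   "HTN-CM" = ...)` of cell sizes (each >= 1).
#' @param hr_distribution data.frame with columns `group`, `pattern`
#'   (`"fusion"/"half"/"sep"`), `mean`, `sd` (bpm).
#' @param systolic_interval_ms duration of the non-filling part of each
#'   cycle, ms.
#' @param e_wave,a_wave named lists: `amp_mean`/`amp_sd` (m/s),
#'   `duration_ms`, `vp_cms` (propagation velocity, cm/s), `decay_cm`
#'   (apical e-folding length, cm) and `decay_sd`.
#' @param eprime latent annular E' amplitude `c(mean=, sd=)`, cm/s.
#' @param preload_coupling `c(e=, eprime=)` — relative amplitude gain at
#'   full merging; the E' coefficient must be strictly greater than the
#'   E coefficient (preload acts more strongly on E' than on E).
#' @param la_loading fractional reduction of the E-wave penetration
#'   depth at full merging (atrial-driven filling concentrates basally);
#'   in `[0, 1)`.
#' @param atrial_attenuation fractional reduction of the A-wave
#'   amplitude at full merging (the atrium has not refilled when
#'   diastasis is lost, so the atrial kick shrinks); in `[0, 1]`.
#' @param htn_effects additive shifts for the HTN-CM group:
#'   `c(sap=, wall=, lvidd=)` (mmHg, cm, cm).
#' @param lv_length LV long-axis length `c(mean=, sd=)`, cm.
#' @param dims named list of `c(mean, sd)` for `lvidd`, `ivsd`, `lvfwd`,
#'   `lvids`, cm.
#' @param sap Sham systolic arterial pressure `c(mean=, sd=)`, mmHg.
#' @param noise_sd measurement noise SDs: `c(e=, eprime=, sap=)`
#'   (m/s, cm/s, mmHg).
#' @param ds,dt velocity-map grid steps (cm, ms).
#' @param n_cycles cardiac cycles per generated map (>= 2).
#' @param attempt_budget rejection-sampling attempts allowed per animal.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       group_sizes = list(
                         "Sham" = c(fusion = 7L, half = 7L, sep = 19L),
                         "HTN-CM" = c(fusion = 15L, half = 25L, sep = 26L)),
                       hr_distribution = default_hr_distribution(),
                       systolic_interval_ms = 85,
                       e_wave = list(amp_mean = 0.90, amp_sd = 0.10,
                                     duration_ms = 50, vp_cms = 150,
                                     decay_cm = 1.50, decay_sd = 0.15),
                       a_wave = list(amp_mean = 0.60, amp_sd = 0.07,
                                     duration_ms = 45, vp_cms = 130,
                                     decay_cm = 0.50, decay_sd = 0.05),
                       eprime = c(mean = 5.5, sd = 0.8),
                       preload_coupling = c(e = 0.20, eprime = 0.65),
                       la_loading = 0.10,
                       atrial_attenuation = 0.75,
                       htn_effects = c(sap = 69, wall = 0.045, lvidd = 0),
                       lv_length = c(mean = 2.0, sd = 0.10),
                       dims = list(lvidd = c(0.60, 0.05),
                                   ivsd = c(0.105, 0.012),
                                   lvfwd = c(0.105, 0.012),
                                   lvids = c(0.33, 0.04)),
                       sap = c(mean = 91, sd = 11),
                       noise_sd = c(e = 0.02, eprime = 0.30, sap = 4),
                       ds = 0.05, dt = 1, n_cycles = 2L,
                       attempt_budget = 2000L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  sizes <- unlist(cfg$group_sizes)
  if (any(sizes < 1) || any(sizes != round(sizes)))
    stop("group sizes must be integers >= 1")
  if (!all(c("Sham", "HTN-CM") %in% names(cfg$group_sizes)))
    stop("group_sizes must name groups Sham and HTN-CM")
  hd <- cfg$hr_distribution
  if (!all(c("group", "pattern", "mean", "sd") %in% names(hd)))
    stop("hr_distribution needs columns group, pattern, mean, sd")
  sds <- c(hd$sd, cfg$e_wave$amp_sd, cfg$e_wave$decay_sd,
           cfg$a_wave$amp_sd, cfg$a_wave$decay_sd, cfg$eprime["sd"],
           cfg$lv_length["sd"], cfg$sap["sd"], cfg$noise_sd,
           vapply(cfg$dims, `[`, numeric(1), 2))
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("all SDs must be finite and >= 0")
  if (!(cfg$preload_coupling[["eprime"]] > cfg$preload_coupling[["e"]]))
    stop("preload coupling on E' must be strictly greater than on E")
  if (cfg$la_loading < 0 || cfg$la_loading >= 1)
    stop("`la_loading` must be in [0, 1)")
  if (cfg$atrial_attenuation < 0 || cfg$atrial_attenuation > 1)
    stop("`atrial_attenuation` must be in [0, 1]")
  for (w in list(cfg$e_wave, cfg$a_wave))
    if (w$duration_ms <= 0 || w$vp_cms <= 0 || w$decay_cm <= 0)
      stop("wave duration, propagation velocity and decay must be positive")
  if (cfg$systolic_interval_ms <= 0) stop("systolic interval must be positive")
  if (cfg$ds <= 0 || cfg$dt <= 0) stop("grid steps must be positive")
  if (cfg$n_cycles < 2) stop("need at least 2 cycles per map")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  sizes <- vapply(x$group_sizes, sum, numeric(1))
  cat("<sim_config> seed", x$seed, "-", sum(sizes), "animals (",
      paste(sprintf("%s: %d", names(sizes), sizes), collapse = ", "), ")\n")
  cat(sprintf("  systole %g ms; E %g ms @ %g cm/s; A %g ms @ %g cm/s\n",
              x$systolic_interval_ms, x$e_wave$duration_ms, x$e_wave$vp_cms,
              x$a_wave$duration_ms, x$a_wave$vp_cms))
  cat(sprintf("  preload coupling: E %.2f < E' %.2f\n",
              x$preload_coupling[["e"]], x$preload_coupling[["eprime"]]))
  invisible(x)
}

#' Latent per-animal ground truth
#'
#' Bundles the quantities the generator draws per animal before any
#' measurement noise: group, heart rate (hence cycle length and
#' diastasis), wave geometry and latent E/A/E' amplitudes. The merging
#' fraction `merge_frac` (overlap as a fraction of the A-wave duration,
#' clamped to `[0, 1]`) drives the preload coupling: the effective E
#' amplitude in the velocity field is `e_amp * (1 + c_e * merge_frac)`
#' and the latent E' is `eprime_base * (1 + c_eprime * merge_frac)`.
#'
#' @param group `"Sham"` or `"HTN-CM"`.
#' @param hr heart rate, bpm.
#' @param config a [sim_config()] supplying timing/coupling constants.
#' @param e_amp,a_amp latent wave amplitudes, m/s.
#' @param eprime_base latent annular E', cm/s.
#' @param lv_length LV length, cm.
#' @param e_decay,a_decay apical decay lengths, cm.
#' @return an object of class `animal_truth`.
#' @export
animal_truth <- function(group, hr, config, e_amp, a_amp, eprime_base,
                         lv_length = config$lv_length[["mean"]],
                         e_decay = config$e_wave$decay_cm,
                         a_decay = config$a_wave$decay_cm) {
  stopifnot(group %in% c("Sham", "HTN-CM"), hr > 0, lv_length > 0)
  cyc <- 60000 / hr
  de <- config$e_wave$duration_ms
  da <- config$a_wave$duration_ms
  if (de >= cyc || da >= cyc)
    stop(sprintf("wave duration (%g/%g ms) must be shorter than the cycle (%g ms at %g bpm)",
                 de, da, cyc, hr))
  diastasis <- cyc - config$systolic_interval_ms - de - da
  merge_frac <- min(max(-diastasis, 0) / da, 1)
  ce <- config$preload_coupling[["e"]]
  cep <- config$preload_coupling[["eprime"]]
  e_decay_eff <- max(e_decay * (1 - config$la_loading * merge_frac), 0.3)
  a_amp_eff <- a_amp * (1 - config$atrial_attenuation * merge_frac)
  structure(
    list(group = group, hr = hr, cycle_length = cyc,
         systole_ms = config$systolic_interval_ms,
         diastasis = diastasis, merge_frac = merge_frac,
         e = list(amp = e_amp * (1 + ce * merge_frac), duration_ms = de,
                  vp_cms = config$e_wave$vp_cms, decay_cm = e_decay_eff),
         a = list(amp = a_amp_eff, duration_ms = da,
                  vp_cms = config$a_wave$vp_cms, decay_cm = a_decay),
         eprime_latent = eprime_base * (1 + cep * merge_frac),
         lv_length = lv_length, pattern = NULL),
    class = "animal_truth")
}

# mitral-annulus (s = 0) inflow trace for one cycle; A-wave support of the
# previous cycle ends exactly at t = 0, so one cycle is self-contained
base_trace_one_cycle <- function(truth, dt) {
  cyc_n <- round(truth$cycle_length / dt)
  cyc_eff <- cyc_n * dt
  t <- (seq_len(cyc_n) - 1) * dt
  hann_pulse(t, truth$systole_ms, truth$e$duration_ms, truth$e$amp) +
    hann_pulse(t, cyc_eff - truth$a$duration_ms, truth$a$duration_ms,
               truth$a$amp)
}

#' Generate a synthetic velocity map for one animal
#'
#' Builds a [velocity_map()] of `n_cycles` cardiac cycles from a ground
#' truth: per cycle, an E pulse starting at the end of the systolic
#' interval and an A pulse ending at the cycle end, each propagating
#' apically at its configured velocity with exponential amplitude decay;
#' overlapping pulses sum. The cycle length is quantized to the time step
#' (`round(cycle/dt)` samples). Deterministic given truth and grid.
#'
#' @param truth an [animal_truth()].
#' @param ds,dt grid steps (cm, ms), both > 0.
#' @param n_cycles number of full cycles to generate (>= 2).
#' @return a [velocity_map()] with `cycle_starts` set.
#' @export
generate_cycle <- function(truth, ds = 0.05, dt = 1, n_cycles = 2L) {
  stopifnot(inherits(truth, "animal_truth"))
  if (ds <= 0 || dt <= 0) stop("grid steps must be positive")
  if (truth$lv_length <= 0) stop("LV length must be positive")
  n_cycles <- as.integer(n_cycles)
  if (n_cycles < 2) stop("need at least 2 cycles")
  cyc_n <- round(truth$cycle_length / dt)
  cyc_eff <- cyc_n * dt
  for (w in list(truth$e, truth$a))
    if (w$duration_ms >= cyc_eff)
      stop("wave duration must be shorter than the cycle length")
  nt <- cyc_n * n_cycles
  t <- (seq_len(nt) - 1) * dt
  nr <- as.integer(floor(truth$lv_length / ds + 1e-9)) + 1L
  s <- (seq_len(nr) - 1) * ds
  V <- matrix(0, nr, nt)
  add_wave <- function(V, wave, onset) {
    delay <- 1000 * s / wave$vp_cms                    # ms to reach depth s
    amp_s <- wave$amp * exp(-s / wave$decay_cm)
    # phase[i, j] = t[j] - delay[i] - onset
    phase <- outer(-delay - onset, t, `+`)
    P <- 0.5 * (1 - cos(2 * pi * phase / wave$duration_ms))
    P[phase < 0 | phase > wave$duration_ms] <- 0
    V + amp_s * P
  }
  for (k in -1:(n_cycles)) {
    V <- add_wave(V, truth$e, k * cyc_eff + truth$systole_ms)
    V <- add_wave(V, truth$a, (k + 1) * cyc_eff - truth$a$duration_ms)
  }
  velocity_map(V, ds = ds, dt = dt, lv_length = truth$lv_length,
               hr = truth$hr,
               cycle_starts = 1L + (0:(n_cycles - 1L)) * cyc_n)
}

rnorm_floor <- function(n, mean, sd, floor) pmax(stats::rnorm(n, mean, sd), floor)

#' Generate a synthetic cohort
#'
#' Draws one animal at a time: heart rate and latent amplitudes are
#' sampled from the cell's configured distributions, the mitral-annulus
#' trace is classified, and draws are rejected until the classifier
#' output matches the cell's target pattern (the HR -> diastasis ->
#' pattern mechanism stays causal; the cell counts are exact by
#' construction). For each accepted animal a full velocity map is
#' generated, the Euler engine computes its IVPGs, wave features give the
#' measured E (and A for EA-separation animals), configured measurement
#' noise is added, and the derived indices are appended. Fully
#' reproducible for a fixed seed.
#'
#' @param config a [sim_config()].
#' @param keep_maps keep the per-animal velocity maps and truths in the
#'   result (`TRUE`, default) or drop them to save memory on large
#'   cohorts.
#' @return an object of class `cohort_sim`: `cohort` (data.frame, one
#'   row per animal), `maps` (list of [velocity_map()] or `NULL`),
#'   `truths` (list of [animal_truth()] or `NULL`), `config`.
#' @export
generate_cohort <- function(config = sim_config(), keep_maps = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  target_code <- c(fusion = 3L, half = 2L, sep = 1L)
  rows <- list()
  maps <- list()
  truths <- list()
  for (g in names(config$group_sizes)) {
    for (p in c("fusion", "half", "sep")) {
      n_cell <- config$group_sizes[[g]][[p]]
      hd <- config$hr_distribution
      cell <- hd[hd$group == g & hd$pattern == p, ]
      if (nrow(cell) != 1)
        stop("hr_distribution lacks a row for ", g, "/", p)
      for (i in seq_len(n_cell)) {
        attempts <- 0L
        repeat {
          attempts <- attempts + 1L
          if (attempts > config$attempt_budget)
            stop(sprintf(
              "could not realize pattern `%s` for group `%s` within %d attempts; hr_distribution is inconsistent with the wave durations",
              p, g, config$attempt_budget))
          hr <- stats::rnorm(1, cell$mean, cell$sd)
          if (hr < 150 || hr > 599) next
          e_amp <- rnorm_floor(1, config$e_wave$amp_mean,
                               config$e_wave$amp_sd, 0.3)
          a_amp <- rnorm_floor(1, config$a_wave$amp_mean,
                               config$a_wave$amp_sd, 0.15)
          ep_base <- rnorm_floor(1, config$eprime[["mean"]],
                                 config$eprime[["sd"]], 2)
          lv_len <- rnorm_floor(1, config$lv_length[["mean"]],
                                config$lv_length[["sd"]], 1.2)
          e_dec <- rnorm_floor(1, config$e_wave$decay_cm,
                               config$e_wave$decay_sd, 0.3)
          a_dec <- rnorm_floor(1, config$a_wave$decay_cm,
                               config$a_wave$decay_sd, 0.15)
          truth <- animal_truth(g, hr, config, e_amp, a_amp, ep_base,
                                lv_length = lv_len, e_decay = e_dec,
                                a_decay = a_dec)
          code <- tryCatch({
            f <- extract_wave_features(base_trace_one_cycle(truth, config$dt),
                                       dt = config$dt)
            classify_pattern(f)$code
          }, error = function(e) NA_integer_)
          if (!is.na(code) && code == target_code[[p]]) break
        }
        map <- generate_cycle(truth, ds = config$ds, dt = config$dt,
                              n_cycles = config$n_cycles)
        lab <- classify_map(map)
        truth$pattern <- lab
        res <- ivpg(map)
        win <- cycle_windows(map)[[1]]
        feats <- extract_wave_features(base_trace(map)[win], dt = config$dt)
        e_meas <- max(rnorm_floor(1, 0, config$noise_sd[["e"]], -0.05) +
                        max(feats$peaks$velocity), 0.05)
        a_meas <- if (lab$code == 1L)
          feats$a_peak + stats::rnorm(1, 0, config$noise_sd[["e"]])
        else NA_real_
        ep_ivs <- rnorm_floor(1, truth$eprime_latent,
                              config$noise_sd[["eprime"]], 0.5)
        ep_lvfw <- rnorm_floor(1, truth$eprime_latent,
                               config$noise_sd[["eprime"]], 0.5)
        wall_shift <- if (g == "HTN-CM") config$htn_effects[["wall"]] else 0
        lvidd_shift <- if (g == "HTN-CM") config$htn_effects[["lvidd"]] else 0
        sap_shift <- if (g == "HTN-CM") config$htn_effects[["sap"]] else 0
        lvidd <- rnorm_floor(1, config$dims$lvidd[1] + lvidd_shift,
                             config$dims$lvidd[2], 0.3)
        ivsd <- rnorm_floor(1, config$dims$ivsd[1] + wall_shift,
                            config$dims$ivsd[2], 0.03)
        lvfwd <- rnorm_floor(1, config$dims$lvfwd[1] + wall_shift,
                             config$dims$lvfwd[2], 0.03)
        lvids <- rnorm_floor(1, config$dims$lvids[1], config$dims$lvids[2], 0.15)
        sap <- rnorm_floor(1, config$sap[["mean"]] + sap_shift,
                           max(config$sap[["sd"]], config$noise_sd[["sap"]]),
                           50)
        dap <- sap - rnorm_floor(1, 28, 4, 10)
        mabp <- dap + (sap - dap) / 3
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("%s_%s_%02d", gsub("-", "", g), p, i),
          group = g, pattern = lab$label, pattern_code = lab$code,
          hr = hr, e = e_meas, a = a_meas,
          eprime_ivs = ep_ivs, eprime_lvfw = ep_lvfw,
          lvidd = lvidd, lvids = lvids, ivsd = ivsd, lvfwd = lvfwd,
          sap = sap, dap = dap, mabp = mabp, lv_length = lv_len,
          total_ivpg = res$total_ivpg, basal_ivpg = res$basal_ivpg,
          mid_apical_ivpg = res$mid_apical_ivpg,
          stringsAsFactors = FALSE)
        if (keep_maps) {
          maps[[length(maps) + 1L]] <- map
          truths[[length(truths) + 1L]] <- truth
        }
      }
    }
  }
  cohort <- derive_indices(do.call(rbind, rows))
  cohort <- cohort[, COHORT_REQUIRED_COLS]
  validate_cohort(cohort)
  structure(list(cohort = cohort,
                 maps = if (keep_maps) maps else NULL,
                 truths = if (keep_maps) truths else NULL,
                 config = config),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat("<cohort_sim>", nrow(x$cohort), "animals\n")
  print(table(x$cohort$group, x$cohort$pattern))
  invisible(x)
}
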