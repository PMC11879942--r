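# Derived echocardiographic indices.
#
# LV mass by the cube formula from M-mode dimensions; E/E' as the mean of
# the septal and free-wall ratios; LVEDP and pre-A LVDP by affine
# regressions on E/E' calibrated against invasive catheterization.

#' Left-ventricular mass (cube formula)
#'
#' `LVM [g] = 0.8 * 1.04 * ((LVIDd + IVSd + LVFWd)^3 - LVIDd^3) + 0.6`
#' with all dimensions in cm. Wall thicknesses of zero are admitted (the
#' cube terms cancel and the formula returns its 0.6 g offset).
#'
#' @param lvidd LV internal diameter at end-diastole, cm (> 0).
#' @param ivsd interventricular septal thickness at end-diastole, cm
#'   (>= 0).
#' @param lvfwd LV free-wall thickness at end-diastole, cm (>= 0).
#' @return LV mass in grams; vectorized.
#' @export
lv_mass <- function(lvidd, ivsd, lvfwd) {
  if (any(!is.finite(lvidd)) || any(lvidd <= 0))
    stop("`lvidd` must be positive")
  if (any(!is.finite(ivsd)) || any(ivsd < 0) ||
      any(!is.finite(lvfwd)) || any(lvfwd < 0))
    stop("wall thicknesses must be non-negative")
  0.8 * 1.04 * ((lvidd + ivsd + lvfwd)^3 - lvidd^3) + 0.6
}

#' E/E' ratio
#'
#' Mean of the transmitral E velocity over the early-diastolic annular
#' tissue velocity at the septum and at the free wall:
#' `E/E' = (E/E'_IVS + E/E'_LVFW) / 2`. E is measured in m/s and E' in
#' cm/s; E is converted to cm/s internally so the ratio is dimensionless
#' (set `e_in_cm_s = TRUE` if E is already in cm/s).
#'
#' @param e transmitral E velocity, m/s.
#' @param eprime_ivs,eprime_lvfw annular E' at the septum / free wall,
#'   cm/s (> 0).
#' @param e_in_cm_s set to `TRUE` to skip the m/s -> cm/s conversion.
#' @return dimensionless E/E'; vectorized.
#' @export
e_over_eprime <- function(e, eprime_ivs, eprime_lvfw, e_in_cm_s = FALSE) {
  if (any(!is.finite(eprime_ivs)) || any(eprime_ivs <= 0) ||
      any(!is.finite(eprime_lvfw)) || any(eprime_lvfw <= 0))
    stop("E' values must be positive")
  e_cms <- if (e_in_cm_s) e else 100 * e
  (e_cms / eprime_ivs + e_cms / eprime_lvfw) / 2
}

#' Estimated LV filling pressures from E/E'
#'
#' Affine regression estimates: `LVEDP = 17.1 + 0.19 * E/E'` and
#' `Pre-A LVDP = 6.97 + 0.3 * E/E'` (mmHg). Exact affine maps; rounding
#' is left to presentation.
#'
#' @param ee dimensionless E/E'.
#' @return pressure in mmHg; vectorized.
#' @export
lvedp <- function(ee) {
  stopifnot(is.numeric(ee))
  17.1 + 0.19 * ee
}

#' @rdname lvedp
#' @export
pre_a_lvdp <- function(ee) {
  stopifnot(is.numeric(ee))
  6.97 + 0.3 * ee
}

#' Append derived indices to a cohort table
#'
#' Computes `lvm`, `eprime_avg`, `e_over_eprime`, `lvedp`, `prea_lvdp`
#' and `e_over_a` (NA where the A wave is not separately measurable)
#' from the per-animal measurement columns.
#'
#' @param tab data.frame with columns `e`, `a`, `eprime_ivs`,
#'   `eprime_lvfw`, `lvidd`, `ivsd`, `lvfwd`.
#' @return `tab` with the derived columns added/overwritten.
#' @export
derive_indices <- function(tab) {
  stopifnot(is.data.frame(tab))
  need <- c("e", "a", "eprime_ivs", "eprime_lvfw", "lvidd", "ivsd", "lvfwd")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  tab$lvm <- lv_mass(tab$lvidd, tab$ivsd, tab$lvfwd)
  tab$eprime_avg <- (tab$eprime_ivs + tab$eprime_lvfw) / 2
  tab$e_over_eprime <- e_over_eprime(tab$e, tab$eprime_ivs, tab$eprime_lvfw)
  tab$lvedp <- lvedp(tab$e_over_eprime)
  tab$prea_lvdp <- pre_a_lvdp(tab$e_over_eprime)
  tab$e_over_a <- ifelse(is.na(tab$a), NA_real_, tab$e / tab$a)
  tab
}
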