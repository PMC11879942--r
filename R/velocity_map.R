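#' Color M-mode velocity map
#'
#' Container for a spatiotemporal grid of inflow velocities sampled along
#' the left-ventricular long axis, as recorded by color M-mode
#' echocardiography (CMME). Coordinate convention: `s = 0` at the mitral
#' annulus, increasing toward the apex; velocity is positive toward the
#' apex, so inflow is positive during filling and the early-filling IVPD
#' derived from it is positive.
#'
#' @param values numeric matrix, space x time, velocities in m/s
#'   (rows = positions from the mitral annulus toward the apex).
#' @param ds spatial step, cm; must satisfy
#'   `ds * (nrow - 1) <= lv_length <= ds * nrow`.
#' @param dt temporal step, ms.
#' @param lv_length left-ventricular long-axis length, cm.
#' @param s_origin label of the spatial origin; only `"mitral_annulus"`
#'   is defined.
#' @param hr optional heart rate, bpm.
#' @param cycle_starts integer vector of 1-based time indices at which
#'   cardiac cycles start; strictly increasing, within the time range.
#'   Stored explicitly rather than re-detected so that I/O and analysis
#'   stay decoupled.
#' @return an object of class `velocity_map`.
#' @seealso [read_velocity_map()], [write_velocity_map()], [ivpg()]
#' @export
velocity_map <- function(values, ds, dt, lv_length,
                         s_origin = "mitral_annulus",
                         hr = NULL, cycle_starts = integer(0)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (space x time)")
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-finite velocity at cell [%d, %d]", bad[1, 1], bad[1, 2]))
  for (nm in c("ds", "dt", "lv_length")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop(sprintf("`%s` must be a single positive number", nm))
  }
  if (!identical(s_origin, "mitral_annulus"))
    stop("`s_origin` must be \"mitral_annulus\"")
  nr <- nrow(values)
  if (!(ds * (nr - 1) <= lv_length + 1e-9 && lv_length <= ds * nr + 1e-9))
    stop(sprintf(
      "grid extent inconsistent with `lv_length`: need ds*(rows-1) <= lv_length <= ds*rows, got %g*(%d-1)=%g, lv_length=%g",
      ds, nr, ds * (nr - 1), lv_length))
  if (!is.null(hr)) {
    if (!is.numeric(hr) || length(hr) != 1 || hr <= 0)
      stop("`hr` must be a single positive number (bpm)")
    hr <- as.numeric(hr)
  }
  cycle_starts <- as.integer(cycle_starts)
  if (length(cycle_starts)) {
    if (any(diff(cycle_starts) <= 0))
      stop("`cycle_starts` must be strictly increasing")
    if (min(cycle_starts) < 1L || max(cycle_starts) > ncol(values))
      stop("`cycle_starts` out of the map's time range")
  }
  structure(
    list(values = values, ds = ds, dt = dt, lv_length = lv_length,
         s_origin = s_origin, hr = hr, cycle_starts = cycle_starts),
    class = "velocity_map")
}

#' Velocity trace at the mitral annulus
#'
#' The base row (`s = 0`) of a velocity map: the transmitral inflow trace
#' used for E/A wave detection, matching where pulsed-wave Doppler samples
#' the inflow.
#'
#' @param map a [velocity_map()].
#' @return numeric vector of velocities (m/s), one per time sample.
#' @export
base_trace <- function(map) {
  stopifnot(inherits(map, "velocity_map"))
  map$values[1, ]
}

# time-index windows (list of integer ranges), one per cardiac cycle;
# a map without recorded cycle starts is treated as a single window
cycle_windows <- function(map) {
  nt <- ncol(map$values)
  cs <- map$cycle_starts
  if (length(cs) == 0L) return(list(seq_len(nt)))
  bounds <- c(cs, nt + 1L)
  lapply(seq_along(cs), function(k) seq.int(bounds[k], bounds[k + 1L] - 1L))
}

#' @export
print.velocity_map <- function(x, ...) {
  cat("<velocity_map> ", nrow(x$values), " positions x ", ncol(x$values),
      " samples\n", sep = "")
  cat(sprintf("  ds = %g cm, dt = %g ms, LV length = %g cm, origin = %s\n",
              x$ds, x$dt, x$lv_length, x$s_origin))
  if (!is.null(x$hr)) cat(sprintf("  hr = %g bpm\n", x$hr))
  if (length(x$cycle_starts))
    cat("  cycle starts (index):", paste(x$cycle_starts, collapse = ", "), "\n")
  cat(sprintf("  velocity range: [%.3g, %.3g] m/s\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.velocity_map <- function(x, ...) {
  tt <- (seq_len(ncol(x$values)) - 1) * x$dt
  ss <- (seq_len(nrow(x$values)) - 1) * x$ds
  graphics::image(tt, ss, t(x$values), xlab = "time (ms)",
                  ylab = "distance from mitral annulus (cm)",
                  main = "CMME velocity map (m/s)", ...)
  if (length(x$cycle_starts))
    graphics::abline(v = (x$cycle_starts - 1) * x$dt, lty = 3)
  invisible(x)
}
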