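# On-disk formats
#
# Velocity map: a dense numeric CSV matrix (<base>.ivm.csv, rows = positions,
# columns = time samples, no header) plus a JSON sidecar (<base>.ivm.json)
# holding the geometry/timing metadata and a format-version field. Values are
# written with 17 significant digits so the write -> read round trip is
# bit-exact for doubles.
#
# Cohort table: a plain CSV with one row per animal and documented units
# (E in m/s, E' in cm/s, HR in bpm, dimensions in cm, pressures in mmHg,
# IVPG in mmHg/cm).

IVM_FORMAT_VERSION <- "1.0"

ivm_paths <- function(path) {
  base <- sub("\\.ivm\\.(csv|json)$", "", path)
  list(csv = paste0(base, ".ivm.csv"), json = paste0(base, ".ivm.json"))
}

#' Write / read a velocity map
#'
#' `write_velocity_map()` stores a [velocity_map()] as a dense CSV matrix
#' plus a JSON metadata sidecar; `read_velocity_map()` restores it,
#' validating the sidecar schema (missing, unknown or malformed keys are
#' reported by name, non-rectangular matrices and non-finite cells by
#' position).
#'
#' @param map a [velocity_map()].
#' @param path file path; the `.ivm.csv` / `.ivm.json` pair is derived
#'   from it (any `.ivm.csv` or `.ivm.json` suffix is stripped first).
#' @return `write_velocity_map()` returns `path` invisibly;
#'   `read_velocity_map()` returns a [velocity_map()].
#' @export
write_velocity_map <- function(map, path) {
  stopifnot(inherits(map, "velocity_map"))
  p <- ivm_paths(path)
  lines <- apply(map$values, 1, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  writeLines(lines, p$csv)
  meta <- list(
    format_version = IVM_FORMAT_VERSION,
    ds = map$ds, dt = map$dt, lv_length = map$lv_length,
    s_origin = map$s_origin,
    hr = map$hr,
    cycle_starts = I(map$cycle_starts))
  jsonlite::write_json(meta, p$json, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_velocity_map
#' @export
read_velocity_map <- function(path) {
  p <- ivm_paths(path)
  for (f in c(p$csv, p$json))
    if (!file.exists(f)) stop("file not found: ", f)
  meta <- jsonlite::read_json(p$json, simplifyVector = TRUE)
  required <- c("format_version", "ds", "dt", "lv_length", "s_origin",
                "cycle_starts")
  optional <- "hr"
  missing_keys <- setdiff(required, names(meta))
  if (length(missing_keys))
    stop("sidecar missing required key(s): ",
         paste0("`", missing_keys, "`", collapse = ", "))
  extra <- setdiff(names(meta), c(required, optional))
  if (length(extra))
    stop("sidecar has unknown key(s): ",
         paste0("`", extra, "`", collapse = ", "))
  if (!identical(meta$format_version, IVM_FORMAT_VERSION))
    stop("unknown velocity-map format_version: ", meta$format_version)
  rows <- strsplit(readLines(p$csv), ",", fixed = TRUE)
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1)
    stop(sprintf("non-rectangular matrix: row %d has %d cells, row 1 has %d",
                 which(ncols != ncols[1])[1], ncols[ncols != ncols[1]][1],
                 ncols[1]))
  values <- do.call(rbind, lapply(rows, function(r)
    suppressWarnings(as.numeric(r))))
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-finite or unparseable value at cell [%d, %d]",
                 bad[1, 1], bad[1, 2]))
  velocity_map(values, ds = as.numeric(meta$ds), dt = as.numeric(meta$dt),
               lv_length = as.numeric(meta$lv_length),
               s_origin = meta$s_origin,
               hr = if (is.null(meta$hr)) NULL else as.numeric(meta$hr),
               cycle_starts = as.integer(unlist(meta$cycle_starts)))
}

# columns every cohort table must carry; `a` and `e_over_a` may be NA
# (only EA-separation animals have a measurable A wave)
COHORT_REQUIRED_COLS <- c(
  "id", "group", "pattern", "pattern_code", "hr",
  "e", "a", "eprime_ivs", "eprime_lvfw", "eprime_avg",
  "lvidd", "lvids", "ivsd", "lvfwd", "sap", "dap", "mabp", "lv_length",
  "total_ivpg", "basal_ivpg", "mid_apical_ivpg",
  "lvm", "e_over_eprime", "lvedp", "prea_lvdp", "e_over_a")

COHORT_NA_OK <- c("a", "e_over_a")

validate_cohort <- function(tab) {
  if (!is.data.frame(tab)) stop("cohort must be a data.frame")
  missing_cols <- setdiff(COHORT_REQUIRED_COLS, names(tab))
  if (length(missing_cols))
    stop("cohort missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!all(tab$group %in% c("Sham", "HTN-CM")))
    stop("`group` must be \"Sham\" or \"HTN-CM\"")
  if (!all(tab$pattern_code %in% 1:3))
    stop("unknown pattern code: ",
         paste(unique(setdiff(tab$pattern_code, 1:3)), collapse = ", "))
  if (!all(tab$pattern %in% PATTERN_LEVELS))
    stop("unknown pattern label")
  if (any(pattern_code_of(tab$pattern) != tab$pattern_code))
    stop("`pattern` and `pattern_code` disagree")
  if (any(!is.finite(tab$hr)) || any(tab$hr <= 0))
    stop("`hr` must be positive and finite (bpm)")
  num_cols <- setdiff(COHORT_REQUIRED_COLS, c("id", "group", "pattern", COHORT_NA_OK))
  for (nm in setdiff(num_cols, "pattern_code")) {
    if (any(!is.finite(tab[[nm]])))
      stop("missing or non-finite values in column `", nm, "`")
  }
  invisible(tab)
}

#' Write / read a cohort table
#'
#' Per-animal measurement and derived-index table as plain CSV. Units:
#' E and A in m/s, E' in cm/s, HR in bpm, linear dimensions and LV length
#' in cm, pressures in mmHg, IVPG in mmHg/cm. Both directions validate the
#' schema (required columns, pattern code in 1..3, positive HR, group
#' labels, no missing values in the columns the statistics stage uses).
#'
#' @param tab cohort `data.frame` with the documented columns.
#' @param path CSV file path.
#' @return `read_cohort()` returns the validated `data.frame`;
#'   `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(tab, path) {
  validate_cohort(tab)
  out <- tab
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && nm != "pattern_code")
      out[[nm]] <- ifelse(is.na(out[[nm]]), "NA", sprintf("%.17g", out[[nm]]))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(COHORT_REQUIRED_COLS, names(tab))
  if (length(missing_cols))
    stop("cohort missing column(s): ", paste(missing_cols, collapse = ", "))
  tab$pattern_code <- as.integer(tab$pattern_code)
  for (nm in setdiff(COHORT_REQUIRED_COLS,
                     c("id", "group", "pattern", "pattern_code")))
    tab[[nm]] <- as.numeric(tab[[nm]])
  validate_cohort(tab)
  tab
}
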