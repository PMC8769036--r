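#' Calibration-protocol flow grid
#'
#' The calibration protocol samples the reference flow in steps of about
#' 1 L/min from 1 up to 40 L/min, then in steps of 5 L/min until the sensor
#' saturates (about 80 L/min), giving 48 points for the default sensor range.
#'
#' @param fine_max_lpm last flow of the 1 L/min section.
#' @param coarse_step_lpm step of the coarse section.
#' @param max_lpm sensor saturation flow, L/min.
#' @return Numeric vector of reference flows, L/min.
#' @export
#' @examples
#' length(protocol_flow_grid())  # 48
protocol_flow_grid <- function(fine_max_lpm = 40, coarse_step_lpm = 5,
                               max_lpm = 80) {
  stopifnot(fine_max_lpm >= 1, coarse_step_lpm > 0, max_lpm > fine_max_lpm)
  c(seq(1, fine_max_lpm, by = 1),
    seq(fine_max_lpm + coarse_step_lpm, max_lpm, by = coarse_step_lpm))
}

.new_calibration_table <- function(dps_pa, dp_model_pa, flow_ref_lpm,
                                   created_density = NA_real_,
                                   geometry = NULL) {
  structure(data.frame(dps_pa = dps_pa, dp_model_pa = dp_model_pa,
                       flow_ref_lpm = flow_ref_lpm),
            class = c("calibration_table", "data.frame"),
            created_density = created_density,
            geometry = geometry)
}

#' Build the calibration lookup table
#'
#' For each paired observation of reference flow (from a gas analyzer) and raw
#' differential-pressure-sensor (DPS) reading, the model-consistent
#' differential pressure is computed from the inverse Venturi relation with
#' the assumed geometry and the density of air at the calibration site
#' (calibration is performed with air only, open circuit, so atmospheric
#' pressure alone enters the density). The stored two-column array — measured
#' DPS against model differential pressure — is what the runtime estimator
#' searches.
#'
#' Near-duplicate DPS readings (within `dedup_tol_pa`, the offset-stability
#' scale of the sensor) are merged by averaging, because the binary search
#' requires strictly increasing keys.
#'
#' @param pairs data.frame with columns `flow_lpm` (reference flow, L/min,
#'   non-negative) and `dps_pa` (raw DPS reading, Pa).
#' @param amb `ambient_conditions` at the calibration site.
#' @param geom assumed `venturi_geometry` (cd = 0.7, ac = 58 mm^2 by default).
#' @param constants `gas_constants` for the air density.
#' @param dedup_tol_pa DPS readings closer than this are collapsed, Pa.
#' @return A `calibration_table`: data.frame with columns `dps_pa`,
#'   `dp_model_pa`, `flow_ref_lpm`, sorted by strictly increasing `dps_pa`,
#'   with the calibration air density and geometry kept as attributes.
#' @export
#' @examples
#' amb <- ambient_conditions(101325, 293.15)
#' rho <- gas_density(fio2_to_fractions(21), amb)
#' grid <- protocol_flow_grid()
#' # an ideal sensor whose true transfer matches the assumed model exactly:
#' pairs <- data.frame(flow_lpm = grid, dps_pa = dp_from_flow(grid, rho))
#' tab <- build_table(pairs, amb)
#' nrow(tab)  # 48
build_table <- function(pairs, amb, geom = venturi_geometry(),
                        constants = gas_constants(), dedup_tol_pa = 0.01) {
  stopifnot(is.data.frame(pairs),
            all(c("flow_lpm", "dps_pa") %in% names(pairs)),
            inherits(amb, "ambient_conditions"))
  if (nrow(pairs) < 2)
    stop("calibration needs at least 2 (flow, DPS) pairs", call. = FALSE)
  if (any(!is.finite(pairs$flow_lpm)) || any(!is.finite(pairs$dps_pa)))
    stop("non-finite values in calibration pairs", call. = FALSE)
  if (any(pairs$flow_lpm < 0))
    stop("calibration flows must be non-negative (air-only protocol)",
         call. = FALSE)

  rho <- gas_density(fio2_to_fractions(21), amb, constants,
                     include_airway_pressure = FALSE)
  dp_model <- dp_from_flow(pairs$flow_lpm, rho, geom)

  ord <- order(pairs$dps_pa)
  d <- pairs$dps_pa[ord]
  p <- dp_model[ord]
  f <- pairs$flow_lpm[ord]

  # collapse runs of near-identical DPS keys by averaging
  grp <- cumsum(c(TRUE, diff(d) > dedup_tol_pa))
  d <- as.numeric(tapply(d, grp, mean))
  p <- as.numeric(tapply(p, grp, mean))
  f <- as.numeric(tapply(f, grp, mean))

  if (length(d) < 2)
    stop("fewer than 2 distinct DPS readings after merging duplicates",
         call. = FALSE)
  if (any(diff(p) < 0))
    warning("dp_model not non-decreasing after sorting by DPS: ",
            "possible sensor fault in the calibration data")

  .new_calibration_table(d, p, f, created_density = rho, geometry = geom)
}

#' Validate a calibration table
#'
#' Report-only structural checks: row count, monotonicity of both columns,
#' DPS coverage range, and the per-row intrinsic adjustment factor
#' `dp_model / dps` — the proportional correction the lookup applies at each
#' stored point (1.0 everywhere when the sensor's true transfer matches the
#' assumed model).
#'
#' @param table a `calibration_table`.
#' @return An object of class `calibration_report` (a list).
#' @export
validate_table <- function(table) {
  stopifnot(inherits(table, "calibration_table"))
  d <- table$dps_pa
  p <- table$dp_model_pa
  viol_dps <- which(diff(d) <= 0)
  viol_dp <- which(diff(p) < 0)
  structure(list(
    n = nrow(table),
    dps_strictly_increasing = length(viol_dps) == 0L,
    dp_model_non_decreasing = length(viol_dp) == 0L,
    n_monotonicity_violations = length(viol_dps) + length(viol_dp),
    dps_range_pa = range(d),
    adjustment_factor = ifelse(d != 0, p / d, NA_real_)
  ), class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("Calibration table report: %d rows, DPS %.4g to %.4g Pa\n",
              x$n, x$dps_range_pa[1], x$dps_range_pa[2]))
  cat(sprintf("  DPS strictly increasing: %s; dp_model non-decreasing: %s (%d violation(s))\n",
              x$dps_strictly_increasing, x$dp_model_non_decreasing,
              x$n_monotonicity_violations))
  af <- x$adjustment_factor[is.finite(x$adjustment_factor)]
  if (length(af))
    cat(sprintf("  adjustment factor dp_model/DPS: %.4g to %.4g (median %.4g)\n",
                min(af), max(af), stats::median(af)))
  invisible(x)
}

#' Persist and reload a calibration table
#'
#' The on-disk format is a plain CSV with header
#' `dps_pa,dp_model_pa,flow_ref_lpm`, rows sorted by the first column, and
#' `#`-prefixed comment lines carrying metadata (geometry, calibration
#' density, date). `read_calibration_table()` re-checks all structural
#' invariants and rejects files whose first column is not strictly increasing.
#'
#' @param table a `calibration_table`.
#' @param path file path.
#' @return `read_calibration_table()` returns a `calibration_table`;
#'   `write_calibration_table()` returns `path` invisibly.
#' @export
write_calibration_table <- function(table, path) {
  stopifnot(inherits(table, "calibration_table"))
  geom <- attr(table, "geometry")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# dliteflow calibration table",
    sprintf("# created: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    if (!is.null(geom))
      sprintf("# cd: %.10g", geom$cd),
    if (!is.null(geom))
      sprintf("# ac_mm2: %.10g", geom$ac_mm2),
    sprintf("# density_kg_m3: %.10g", attr(table, "created_density"))
  ), con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration_table
#' @export
read_calibration_table <- function(path) {
  if (!file.exists(path))
    stop("calibration table file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    m <- grep(paste0("^# ", key, ":"), meta, value = TRUE)
    if (length(m)) as.numeric(sub(paste0("^# ", key, ":\\s*"), "", m[1]))
    else NA_real_
  }
  df <- tryCatch(
    utils::read.csv(text = lines[!grepl("^#", lines)]),
    error = function(e) stop("malformed calibration table file: ", path,
                             " (", conditionMessage(e), ")", call. = FALSE))
  req <- c("dps_pa", "dp_model_pa", "flow_ref_lpm")
  if (!all(req %in% names(df)) || nrow(df) < 2)
    stop("malformed calibration table file: ", path,
         " (need columns ", paste(req, collapse = ", "),
         " and at least 2 rows)", call. = FALSE)
  if (any(diff(df$dps_pa) <= 0))
    stop("calibration table file rejected: dps_pa column not strictly ",
         "increasing in ", path, call. = FALSE)

  cd <- get_meta("cd")
  ac <- get_meta("ac_mm2")
  geom <- if (is.finite(cd) && is.finite(ac)) venturi_geometry(cd, ac) else NULL
  .new_calibration_table(df$dps_pa, df$dp_model_pa, df$flow_ref_lpm,
                         created_density = get_meta("density_kg_m3"),
                         geometry = geom)
}

#' @export
print.calibration_table <- function(x, ...) {
  cat(sprintf("Calibration table: %d rows, DPS %.4g to %.4g Pa", nrow(x),
              min(x$dps_pa), max(x$dps_pa)))
  rho <- attr(x, "created_density")
  if (is.finite(rho)) cat(sprintf(", built at air density %.4g kg/m^3", rho))
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("  ...\n")
  invisible(x)
}
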