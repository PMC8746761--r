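## Unit whitelist: multiplier to SI and physical quantity class.
.units <- list(
  V = c(1, "V"), mV = c(1e-3, "V"),
  A = c(1, "A"), nA = c(1e-9, "A"), pA = c(1e-12, "A"),
  S = c(1, "S"), nS = c(1e-9, "S"),
  F = c(1, "F"), nF = c(1e-9, "F"), pF = c(1e-12, "F"),
  Ohm = c(1, "Ohm"), MOhm = c(1e6, "Ohm"),
  s = c(1, "s"), ms = c(1e-3, "s"))

unit_factor <- function(unit) {
  u <- .units[[unit]]
  if (is.null(u)) stop("unit not in whitelist: ", unit)
  as.numeric(u[1])
}

unit_class <- function(unit) {
  u <- .units[[unit]]
  if (is.null(u)) stop("unit not in whitelist: ", unit)
  u[2]
}

#' Write a trace as two-column delimited text
#'
#' Tab-separated file with a header declaring the units
#' (`time_s<TAB>value_<unit>`); times start at 0.
#'
#' @param values numeric trace, in `unit`.
#' @param dt sample interval, seconds.
#' @param path output file.
#' @param unit value unit (whitelisted; e.g. `"mV"`, `"nA"`, `"nS"`).
#' @export
write_trace <- function(values, dt, path, unit) {
  unit_class(unit)
  tt <- (seq_along(values) - 1) * dt
  utils::write.table(
    data.frame(a = tt, b = values),
    path, sep = "\t", row.names = FALSE, quote = FALSE,
    col.names = c("time_s", paste0("value_", unit)))
  invisible(path)
}

#' Read a two-column trace file into SI units
#'
#' Expects the header written by [write_trace]. The time column must be
#' uniform to 1 ppm of `dt`; values are converted to SI using the declared
#' unit, which must belong to the expected physical quantity.
#'
#' @param path input file.
#' @param expected_unit an SI unit naming the expected quantity
#'   (`"V"`, `"A"`, `"S"`, `"F"`, `"Ohm"`).
#' @return list with `values` (SI), `dt` (seconds) and `unit` (as read).
#' @export
read_trace <- function(path, expected_unit) {
  header <- strsplit(readLines(path, n = 1), "\t")[[1]]
  if (length(header) != 2 || !startsWith(header[2], "value_"))
    stop("not a trace file (expected 'time_s<TAB>value_<unit>' header)")
  unit <- sub("^value_", "", header[2])
  if (unit_class(unit) != unit_class(expected_unit))
    stop("unit ", unit, " is not convertible to ", expected_unit)
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  tt <- d[[1]]
  dts <- diff(tt)
  dt <- stats::median(dts)
  dev <- max(abs(dts - dt))
  if (dev > 1e-6 * dt)
    stop(sprintf("non-uniform sampling: max deviation %.3g s from dt %.3g s",
                 dev, dt))
  list(values = d[[2]] * unit_factor(unit), dt = dt, unit = unit)
}

## Tiny polynomial rolling hash over a deparsed object (configuration
## fingerprint; modulus kept small so the arithmetic stays exact in
## double precision).
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 1000000007
  sprintf("%08x", h)
}

#' Write an extraction result to CSV plus a JSON sidecar
#'
#' The CSV holds the per-sample traces (time, cleaned voltage, impedance
#' magnitudes, total conductance, series resistance, E/I conductances,
#' and the dynamic leak when cable mode was on); the JSON sidecar records
#' the scalar estimates, diagnostics, the full effective configuration,
#' a configuration hash, and the package version.
#'
#' @param fit an `ei_fit`.
#' @param path output prefix; writes `<path>.csv` and `<path>.json`.
#' @param seed optional seed to record for provenance.
#' @return the prefix, invisibly.
#' @export
write_result <- function(fit, path, seed = NULL) {
  stopifnot(inherits(fit, "ei_fit"))
  utils::write.csv(as.data.frame(fit), paste0(path, ".csv"),
                   row.names = FALSE)
  cfg <- fit$config
  sidecar <- list(
    C_est = fit$C_est, Cp_est = fit$Cp_est, g_l_est = fit$g_l_est,
    V_l_est = fit$V_l_est, Rs_coarse = fit$Rs_coarse, theta = fit$theta,
    edge_trim_s = fit$trim, dt = fit$dt, n = fit$n,
    eq_dynamic_leak = isTRUE(cfg$cable_correction),
    cp_compensation = isTRUE(cfg$cp_compensation),
    diagnostics = fit$diagnostics,
    config = cfg[setdiff(names(cfg), "I_slow")],
    config_hash = config_hash(cfg),
    package_version = as.character(utils::packageVersion("dualsine")),
    seed = seed)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read back the scalar sidecar of a written result
#'
#' @param path prefix used in [write_result].
#' @return named list of scalars and configuration echo.
#' @export
read_result_sidecar <- function(path) {
  jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
}
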