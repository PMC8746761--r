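#' Extraction-pipeline configuration
#'
#' Collects every tunable of the single-trial extraction. Defaults are the
#' reference recording condition: tones at 210 and 315 Hz, 6 Hz Gaussian
#' impedance half-bandwidth (the accuracy optimum on the reference
#' fixture; envelope temporal resolution is `sigma_t = sqrt(log 2)/(2 pi
#' half_bandwidth)`, about 22 ms), 5 Hz notch half-width for voltage cleaning,
#' leak from the lowest 5th percentile of the total conductance, reversal
#' potentials 0 / -70 mV, and a 1 s synaptically silent calibration window
#' at the start of the trace.
#'
#' @param f1,f2 stimulus frequencies, hertz (distinct; must be separated
#'   by at least 5 half-bandwidths).
#' @param half_bandwidth impedance filter half-bandwidth, hertz.
#' @param notch_half_width voltage-cleaning stop-band half-width, hertz.
#' @param lowpass optional lowpass cutoff for the cleaned voltage, hertz
#'   (recommended with broadband recording noise, e.g. 180 Hz); `NULL`
#'   for none.
#' @param calib_window synaptically silent window `c(t0, t1)`, seconds,
#'   used for the capacitance (and stray-capacitance) estimates.
#' @param percentile leak percentile (see [leak_and_rest]).
#' @param V_e,V_i assumed reversal potentials, volts.
#' @param C known cell capacitance, farads, or `NULL` to estimate it.
#' @param cap_freq which tone the capacitance estimator uses: `"f2"`
#'   (default; the higher tone better satisfies the high-frequency
#'   approximation), `"f1"`, or `"both"` (average).
#' @param solve_method circuit-inversion path: `"complex"` (default) or
#'   `"magnitude"` (see [solve_circuit]).
#' @param cp_compensation logical: estimate and subtract pipette stray
#'   capacitance from the impedance traces.
#' @param cable_correction logical: apply the dynamic leak correction
#'   ([dendritic_leak_correction]) before the E/I decomposition
#'   (recommended only for spatially extended cells).
#' @param I_slow non-sinusoidal injected current, amperes (scalar 0 or a
#'   per-sample trace). Its ohmic drop across the estimated `R_s(t)` is
#'   removed from the cleaned voltage.
#' @param trim_extra additional edge trim, seconds.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(f1 = 210, f2 = 315, half_bandwidth = 6,
                            notch_half_width = 5, lowpass = NULL,
                            calib_window = c(0.15, 1), percentile = 5,
                            V_e = 0, V_i = -70e-3, C = NULL,
                            cap_freq = c("f2", "f1", "both"),
                            solve_method = c("complex", "magnitude"),
                            cp_compensation = FALSE,
                            cable_correction = FALSE, I_slow = 0,
                            trim_extra = 0) {
  cap_freq <- match.arg(cap_freq)
  solve_method <- match.arg(solve_method)
  if (f1 == f2) stop("f1 and f2 must be distinct")
  if (abs(f1 - f2) < 5 * half_bandwidth)
    stop("stimulus tones must be separated by at least 5 half-bandwidths")
  if (abs(f1 - f2) <= 2 * notch_half_width)
    stop("notch bands overlap")
  structure(list(f1 = f1, f2 = f2, half_bandwidth = half_bandwidth,
                 notch_half_width = notch_half_width, lowpass = lowpass,
                 calib_window = calib_window, percentile = percentile,
                 V_e = V_e, V_i = V_i, C = C, cap_freq = cap_freq,
                 solve_method = solve_method,
                 cp_compensation = cp_compensation,
                 cable_correction = cable_correction, I_slow = I_slow,
                 trim_extra = trim_extra),
            class = "pipeline_config")
}

#' Single-trial E/I conductance estimation from a dual-sine recording
#'
#' The full extraction pipeline, from the raw recorded voltage and
#' injected current to time-resolved excitatory and inhibitory
#' conductances:
#' 1. narrow-band impedance traces at the two stimulus frequencies
#'    (analytic-signal ratio of band-passed voltage and current);
#' 2. phase-based capacitance estimate on the silent calibration window
#'    (unless `config$C` supplies a known value);
#' 3. optional estimation and subtraction of pipette stray capacitance;
#' 4. per-sample closed-form inversion for the series resistance
#'    `R_s(t)` and total conductance `g(t)`;
#' 5. removal of the stimulus tones from the voltage;
#' 6. leak conductance / resting potential from the lowest-percentile
#'    conductance samples; `g_s(t) = g(t) - g_l`;
#' 7. optional dynamic leak correction (cable mode);
#' 8. E/I decomposition through the passive membrane equation.
#'
#' @param V_p recorded (pipette) voltage trace, volts.
#' @param I_m injected current trace, amperes.
#' @param dt sample interval, seconds.
#' @param config a [pipeline_config].
#' @return object of class `ei_fit`; see [summary.ei_fit]. Key elements:
#'   `g_e`, `g_i`, `g_s` (siemens traces), `Rs_t` (ohms), `V_clean`
#'   (volts), scalars `C_est`, `Cp_est`, `g_l_est`, `V_l_est`,
#'   `Rs_coarse`, `theta`, edge trim `trim` (seconds), `diagnostics`.
#' @export
estimate_conductances <- function(V_p, I_m, dt,
                                  config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"), length(V_p) == length(I_m),
            dt > 0)
  n <- length(V_p)
  f1 <- config$f1
  f2 <- config$f2

  stage <- "impedance"
  Z1 <- impedance_trace(V_p, I_m, dt, f1, config$half_bandwidth)
  Z2 <- impedance_trace(V_p, I_m, dt, f2, config$half_bandwidth)

  stage <- "capacitance"
  cap_one <- function(f) {
    FV <- narrowband_filter(V_p, dt, f, config$half_bandwidth)
    FI <- narrowband_filter(I_m, dt, f, config$half_bandwidth)
    rs <- coarse_rs(FV, FI, dt, f, config$calib_window)
    th <- phase_estimate(FV, FI, dt, f, config$calib_window)
    list(rs = rs, theta = th, C = capacitance_estimate(rs, th, f))
  }
  cap <- switch(config$cap_freq,
                f1 = cap_one(f1),
                f2 = cap_one(f2),
                both = {
                  a <- cap_one(f1); b <- cap_one(f2)
                  list(rs = (a$rs + b$rs) / 2,
                       theta = (a$theta + b$theta) / 2,
                       C = (a$C + b$C) / 2)
                })
  C_est <- config$C %||% cap$C

  stage <- "cp-compensation"
  Cp_est <- 0
  if (isTRUE(config$cp_compensation)) {
    # Stray capacitance biases the phase-based C estimate, so calibrate
    # the full circuit jointly on the silent window; a user-supplied C
    # only needs the Cp fit.
    if (!is.null(config$C)) {
      Cp_est <- pipette_capacitance_estimate(Z1, Z2, dt,
                                             config$calib_window, C = C_est)
    } else {
      cal <- calibrate_circuit(Z1, Z2, dt, config$calib_window)
      Cp_est <- cal$Cp
      C_est <- cal$C
    }
    if (Cp_est > 0) {
      Z1 <- compensate_cp(Z1, Cp_est)
      Z2 <- compensate_cp(Z2, Cp_est)
    }
  }

  stage <- "circuit-inversion"
  sol <- solve_circuit(Z1, Z2, C_est, method = config$solve_method)

  stage <- "voltage-cleaning"
  V_clean <- clean_voltage(V_p, dt, f1, f2, config$notch_half_width,
                           config$lowpass)
  I_slow <- config$I_slow
  if (any(I_slow != 0)) {
    rs_fill <- sol$Rs_t
    rs_fill[!is.finite(rs_fill)] <- stats::median(rs_fill, na.rm = TRUE)
    V_clean <- V_clean - I_slow * rs_fill
  }

  trim_samp <- max(attr(V_clean, "edge_trim"), sol$edge_trim) +
    round(config$trim_extra / dt)
  inner <- (trim_samp + 1):(n - trim_samp)

  stage <- "leak"
  leak <- leak_and_rest(as.numeric(V_clean)[inner], sol$g_t[inner],
                        config$percentile)
  g_s <- sol$g_t - leak$g_l

  stage <- "decomposition"
  g_l_use <- leak$g_l
  g_l_dyn <- NULL
  if (isTRUE(config$cable_correction)) {
    g_l_dyn <- dendritic_leak_correction(g_s, leak$g_l)
    g_l_use <- g_l_dyn
  }
  dec <- decompose_ei(as.numeric(V_clean), g_s, g_l_use, leak$V_l,
                      config$V_e, config$V_i, C_est, dt, I_slow)

  # count meaningfully negative excursions (below -0.1 nS), not the
  # numerical jitter around zero at rest; traces themselves are never
  # clipped
  neg_frac <- mean(dec$g_e[inner] < -1e-10 | dec$g_i[inner] < -1e-10,
                   na.rm = TRUE)
  diagnostics <- list(
    imag_resid = mean(sol$imag_resid[inner][is.finite(sol$imag_resid[inner])]),
    n_masked = sum(sol$masked[inner]),
    negative_fraction = neg_frac)

  structure(list(
    g_e = dec$g_e, g_i = dec$g_i, g_s = g_s, g_t = sol$g_t,
    Rs_t = sol$Rs_t, V_clean = as.numeric(V_clean),
    Z1 = Z1, Z2 = Z2, g_l_dyn = g_l_dyn,
    C_est = C_est, Cp_est = Cp_est, Rs_coarse = cap$rs, theta = cap$theta,
    g_l_est = leak$g_l, V_l_est = leak$V_l,
    dt = dt, n = n, trim = trim_samp * dt, trim_samples = trim_samp,
    config = config, diagnostics = diagnostics),
    class = "ei_fit")
}

#' Score a fit against ground-truth conductances
#'
#' Pearson correlation between estimated and imposed excitatory and
#' inhibitory conductances over the edge-trimmed trace.
#'
#' @param fit an `ei_fit`.
#' @param g_e_true,g_i_true imposed conductance traces, siemens.
#' @return list with `r_e` and `r_i`.
#' @export
score_fit <- function(fit, g_e_true, g_i_true) {
  stopifnot(inherits(fit, "ei_fit"))
  list(r_e = pearson_score(fit$g_e, g_e_true, trim = fit$trim, dt = fit$dt),
       r_i = pearson_score(fit$g_i, g_i_true, trim = fit$trim, dt = fit$dt))
}

#' @export
print.ei_fit <- function(x, ...) {
  cat("Single-trial E/I conductance fit (dual-sine current clamp)\n")
  cat(sprintf("  trace: %d samples at dt = %g ms (%.3g s); edge trim %.3g s\n",
              x$n, x$dt * 1e3, x$n * x$dt, x$trim))
  cat(sprintf("  C_est   = %.4g nF%s\n", x$C_est * 1e9,
              if (is.null(x$config$C)) "" else " (supplied)"))
  if (isTRUE(x$config$cp_compensation))
    cat(sprintf("  Cp_est  = %.4g pF (compensated)\n", x$Cp_est * 1e12))
  cat(sprintf("  g_l_est = %.4g nS,  V_l_est = %.4g mV\n",
              x$g_l_est * 1e9, x$V_l_est * 1e3))
  cat(sprintf("  R_s(t)  = %.4g MOhm (median)\n",
              stats::median(x$Rs_t, na.rm = TRUE) / 1e6))
  invisible(x)
}

#' Summarise a single-trial conductance fit
#'
#' @param object an `ei_fit`.
#' @param ... unused.
#' @return the fit, invisibly; prints scalar estimates and diagnostics.
#' @export
summary.ei_fit <- function(object, ...) {
  print(object)
  k <- object$trim_samples
  inner <- (k + 1):(object$n - k)
  ge <- object$g_e[inner]; gi <- object$g_i[inner]
  cat(sprintf("  g_e: mean %.3g nS, max %.3g nS;  g_i: mean %.3g nS, max %.3g nS\n",
              mean(ge, na.rm = TRUE) * 1e9, max(ge, na.rm = TRUE) * 1e9,
              mean(gi, na.rm = TRUE) * 1e9, max(gi, na.rm = TRUE) * 1e9))
  d <- object$diagnostics
  cat(sprintf("  diagnostics: mean imag residual %.2g; %d masked samples; %.1f%% samples below -0.1 nS\n",
              d$imag_resid, d$n_masked, 100 * d$negative_fraction))
  invisible(object)
}

#' @export
coef.ei_fit <- function(object, ...) {
  c(C = object$C_est, Cp = object$Cp_est, g_l = object$g_l_est,
    V_l = object$V_l_est, Rs = stats::median(object$Rs_t, na.rm = TRUE))
}

#' @export
as.data.frame.ei_fit <- function(x, ...) {
  d <- data.frame(time = (seq_len(x$n) - 1) * x$dt, V_clean = x$V_clean,
                  g_t = x$g_t, Rs_t = x$Rs_t, g_s = x$g_s, g_e = x$g_e,
                  g_i = x$g_i, absZ1 = Mod(x$Z1), absZ2 = Mod(x$Z2))
  if (!is.null(x$g_l_dyn)) d$g_l_dyn <- x$g_l_dyn
  d
}

#' Diagnostic plot of a single-trial conductance fit
#'
#' Four stacked panels over time: cleaned membrane potential, impedance
#' magnitudes at the two tones, total conductance with the series
#' resistance, and the estimated E/I conductances. Edge-trim margins are
#' shaded.
#'
#' @param x an `ei_fit`.
#' @param ... passed to [graphics::plot].
#' @export
plot.ei_fit <- function(x, ...) {
  tvec <- (seq_len(x$n) - 1) * x$dt
  op <- graphics::par(mfrow = c(4, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  shade <- function() {
    usr <- graphics::par("usr")
    graphics::rect(usr[1], usr[3], x$trim, usr[4],
                   col = grDevices::adjustcolor("grey", 0.4), border = NA)
    graphics::rect(max(tvec) - x$trim, usr[3], usr[2], usr[4],
                   col = grDevices::adjustcolor("grey", 0.4), border = NA)
  }
  graphics::plot(tvec, x$V_clean * 1e3, type = "l", xlab = "",
                 ylab = "V_clean (mV)", ...)
  shade()
  graphics::plot(tvec, Mod(x$Z1) / 1e6, type = "l", col = "blue", xlab = "",
                 ylab = "|Z| (MOhm)")
  graphics::lines(tvec, Mod(x$Z2) / 1e6, col = "red")
  shade()
  graphics::plot(tvec, x$g_t * 1e9, type = "l", xlab = "",
                 ylab = "g (nS) / Rs (10 MOhm)")
  graphics::lines(tvec, x$Rs_t / 1e7, col = "grey40")
  shade()
  graphics::plot(tvec, x$g_e * 1e9, type = "l", col = "darkgreen",
                 xlab = "time (s)", ylab = "g_e, g_i (nS)")
  graphics::lines(tvec, x$g_i * 1e9, col = "red")
  shade()
  invisible(x)
}
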