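#' Passive point-neuron parameters
#'
#' The default preset is the standard in-silico recording condition: total
#' capacitance 0.15 nF, resting input resistance 150 MOhm (leak conductance
#' `1/150e6` S), resting/leak reversal -70 mV, excitatory reversal 0 mV and
#' inhibitory reversal -70 mV (at the resting potential, the regime in which
#' shunting inhibition is invisible in the voltage). A 300 MOhm variant of
#' the input resistance is available via `preset = "R300"`; the two values
#' coexist in the reference experiments and neither supersedes the other.
#'
#' @param C total membrane capacitance, farads (> 0).
#' @param g_l leak conductance, siemens (> 0).
#' @param V_l leak (resting) reversal potential, volts.
#' @param V_e,V_i excitatory / inhibitory reversal potentials, volts
#'   (`V_i < V_e`).
#' @param preset `"R150"` (default) or `"R300"`, selecting the input
#'   resistance when `g_l` is not given.
#' @return object of class `cell_params`.
#' @export
cell_params <- function(C = 0.15e-9, g_l = NULL, V_l = -70e-3, V_e = 0,
                        V_i = -70e-3, preset = c("R150", "R300")) {
  preset <- match.arg(preset)
  if (is.null(g_l)) g_l <- if (preset == "R150") 1 / 150e6 else 1 / 300e6
  stopifnot(C > 0, g_l > 0)
  if (V_i >= V_e) stop("V_i must be below V_e")
  structure(list(C = C, g_l = g_l, V_l = V_l, V_e = V_e, V_i = V_i),
            class = "cell_params")
}

#' Electrode (pipette) model
#'
#' @param R_s series/access resistance, ohms; a scalar or a per-sample trace
#'   (all values > 0).
#' @param C_p pipette stray capacitance, farads (>= 0).
#' @param k stray-capacitance flag: 0 ignores `C_p` (recorded voltage is
#'   `V_m + I_m * R_s`), 1 integrates the pipette node explicitly
#'   (requires `C_p > 0`).
#' @return object of class `electrode_model`.
#' @export
electrode_model <- function(R_s = 30e6, C_p = 0, k = 0) {
  if (any(R_s <= 0)) stop("R_s must be > 0 everywhere")
  if (C_p < 0) stop("C_p must be >= 0")
  if (!k %in% c(0, 1)) stop("k must be 0 or 1")
  if (k == 1 && C_p <= 0) stop("k = 1 requires C_p > 0")
  structure(list(R_s = R_s, C_p = C_p, k = as.integer(k)),
            class = "electrode_model")
}

#' Dual-sinusoid stimulus specification
#'
#' The injected current is `I(t) = I_1 sin(2 pi f_1 t) + I_2 sin(2 pi f_2 t)`
#' plus any extra pulse/step currents. The reference condition uses 0.375 nA
#' per tone at 210 and 315 Hz.
#'
#' @param I_1,I_2 sinusoid amplitudes, amperes.
#' @param f_1,f_2 sinusoid frequencies, hertz (distinct, > 0).
#' @param extras optional list of pulses, each a list with `onset`,
#'   `duration` (seconds) and `amplitude` (amperes).
#' @return object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(I_1 = 0.375e-9, I_2 = 0.375e-9, f_1 = 210,
                          f_2 = 315, extras = list()) {
  if (f_1 == f_2) stop("f_1 and f_2 must be distinct")
  stopifnot(f_1 > 0, f_2 > 0)
  structure(list(I_1 = I_1, I_2 = I_2, f_1 = f_1, f_2 = f_2,
                 extras = extras),
            class = "stimulus_spec")
}

#' Dual-sinusoid injected-current trace
#'
#' @param spec a [stimulus_spec].
#' @param duration trace duration, seconds.
#' @param dt sample interval, seconds; both frequencies must lie below the
#'   Nyquist frequency `1/(2 dt)`.
#' @return numeric current trace (amperes) starting at `t = 0`.
#' @export
dual_sine_current <- function(spec, duration, dt) {
  stopifnot(inherits(spec, "stimulus_spec"), duration > 0, dt > 0)
  nyq <- 1 / (2 * dt)
  if (spec$f_1 >= nyq || spec$f_2 >= nyq)
    stop("stimulus frequency at or above Nyquist for this dt")
  n <- round(duration / dt)
  tvec <- (seq_len(n) - 1) * dt
  I <- spec$I_1 * sin(2 * pi * spec$f_1 * tvec) +
    spec$I_2 * sin(2 * pi * spec$f_2 * tvec)
  for (p in spec$extras) {
    on <- tvec >= p$onset & tvec < p$onset + p$duration
    I[on] <- I[on] + p$amplitude
  }
  I
}

#' Simulate a passive point neuron recorded through an electrode
#'
#' Forward-Euler integration of the passive membrane equation with imposed
#' excitatory/inhibitory conductances and injected current, including the
#' electrode: for `k = 0` the recorded (pipette) voltage is
#' `V_p = V_m + I_m R_s`; for `k = 1` the pipette node carries stray
#' capacitance `C_p` and is integrated explicitly, so part of the injected
#' current is shunted before reaching the cell. `R_s` may be a per-sample
#' trace (unstable-access regime). Forward Euler is first-order: `dt` must
#' resolve both the membrane time constant and, for `k = 1`, the pipette
#' time constant `R_s C_p` (0.1 ms suffices for the default cell; use
#' 0.025 ms when `k = 1` or when adding recording noise).
#'
#' @param cell a [cell_params].
#' @param electrode an [electrode_model].
#' @param g_pair a `conductance_pair` (elements `g_e`, `g_i`, `dt`) or
#'   `NULL` for a silent cell.
#' @param I_m injected current trace, amperes.
#' @param dt sample interval, seconds.
#' @param V_init initial membrane potential, volts (defaults to `cell$V_l`).
#' @return object of class `sim_result`: list with `V_m`, `V_p`, `I_m`,
#'   `dt`, and the parameter objects.
#' @export
simulate_point_neuron <- function(cell, electrode, g_pair, I_m, dt,
                                  V_init = cell$V_l) {
  stopifnot(inherits(cell, "cell_params"), inherits(electrode, "electrode_model"))
  n <- length(I_m)
  if (is.null(g_pair)) {
    g_e <- numeric(n); g_i <- numeric(n)
  } else {
    if (!isTRUE(all.equal(g_pair$dt, dt)))
      stop("g_pair dt does not match simulation dt")
    g_e <- g_pair$g_e; g_i <- g_pair$g_i
  }
  if (length(g_e) != n || length(g_i) != n)
    stop("conductance and current traces must have equal length")
  res <- .point_euler(g_e, g_i, I_m, as.numeric(electrode$R_s), dt, cell$C,
                      cell$g_l, cell$V_l, cell$V_e, cell$V_i, electrode$k,
                      electrode$C_p, V_init)
  structure(list(V_m = res$V_m, V_p = res$V_p, I_m = I_m, dt = dt,
                 cell = cell, electrode = electrode),
            class = "sim_result")
}

#' Add recording noise to a simulated trace
#'
#' Noise is added to the recorded (pipette) voltage only; the membrane
#' voltage is left untouched.
#'
#' @param sim a `sim_result`.
#' @param noise numeric voltage noise trace (volts), same length as the
#'   recording.
#' @return the modified `sim_result`.
#' @export
add_noise <- function(sim, noise) {
  stopifnot(inherits(sim, "sim_result"))
  if (length(noise) != length(sim$V_p))
    stop("noise trace length does not match the recording")
  sim$V_p <- sim$V_p + noise
  sim
}
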