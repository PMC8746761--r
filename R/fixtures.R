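#' Reference ground-truth conductance programme
#'
#' The standard point-neuron test input: a regular 2 Hz depressing train
#' over seconds 0.5-2.5 (excitation and 4 ms-delayed inhibition, both
#' U = 0.7, 3 ms inactivation, recovery 0.5 s / 1.3 s) plus a 5 nS tonic
#' step in both conductances over seconds 3-4 of a 5 s trace. Every
#' element is parameterised; the defaults define the reference condition
#' used throughout the package's validation.
#'
#' @param duration trace duration, seconds.
#' @param dt sample interval, seconds.
#' @param event_times excitatory event times, seconds.
#' @param step_on,step_off,step_amp tonic step timing (seconds) and
#'   amplitude (siemens).
#' @param g_max per-event maximal conductance, siemens.
#' @return `conductance_pair` with elements `g_e`, `g_i`, `dt`.
#' @export
std_conductance_programme <- function(duration = 5, dt = 1e-4,
                                      event_times = seq(0.5, 2.5, by = 0.5),
                                      step_on = 3, step_off = 4,
                                      step_amp = 5e-9, g_max = 15e-9) {
  ev <- event_train(event_times, duration)
  pair <- make_ei_std_pair(
    ev,
    e_spec = synapse_spec(tau_rec = 0.5, g_max = g_max,
                          reversal_potential = 0),
    i_spec = synapse_spec(tau_rec = 1.3, g_max = g_max, delay = 0.004,
                          reversal_potential = -70e-3),
    dt = dt)
  step <- make_step_conductance(step_on, step_off, step_amp, duration, dt)
  pair$g_e <- pair$g_e + step
  pair$g_i <- pair$g_i + step
  pair
}

## Shared scaffolding for the point-neuron fixtures.
point_fixture <- function(g_pair, cell, electrode, stim, duration, dt,
                          noise = NULL, config) {
  I_m <- dual_sine_current(stim, duration, dt)
  sim <- simulate_point_neuron(cell, electrode, g_pair, I_m, dt)
  if (!is.null(noise)) sim <- add_noise(sim, noise)
  list(V_p = sim$V_p, V_m = sim$V_m, I_m = I_m, dt = dt,
       g_e = g_pair$g_e, g_i = g_pair$g_i, cell = cell,
       electrode = electrode, stim = stim, config = config)
}

#' Point-neuron validation fixtures
#'
#' Deterministic, fully parameterised in-silico experiments pairing a
#' ground-truth simulation with the matching extraction configuration:
#'
#' * `"std_train"` -- the reference condition: depressing train + tonic
#'   step, noiseless, fixed 30 MOhm electrode, dual 0.375 nA tones at
#'   210/315 Hz, dt = 0.1 ms.
#' * `"rs_wobble"` -- identical inputs but the access resistance wanders
#'   (smoothed Gaussian drift, SD 5 MOhm around 30 MOhm).
#' * `"noise"` -- identical inputs at dt = 0.025 ms with 0.04 mV Gaussian
#'   recording noise added to the pipette voltage; the extraction
#'   config adds a 180 Hz voltage lowpass to regularise the derivative.
#' * `"cp_step"` -- 20 MOhm electrode with 5 pF stray pipette capacitance
#'   (k = 1), dt = 0.025 ms; used to demonstrate stray-capacitance
#'   compensation.
#' * `"network"` -- correlated network-like E/I fluctuations (surrogate,
#'   correlation 0.8, 20 ms correlation time) after a 1 s silent lead-in,
#'   50 MOhm electrode, 0.5 nA tones; `i_shift` circularly shifts the
#'   inhibitory trace (10 s mimics uncorrelated inputs).
#'
#' @param name fixture name.
#' @param seed integer seed for the stochastic fixtures.
#' @param duration trace duration, seconds (default 5; `network` uses
#'   13 s).
#' @param i_shift inhibitory circular shift for `"network"`, seconds.
#' @return list with `V_p`, `V_m`, `I_m`, `dt`, ground truth `g_e`,
#'   `g_i`, the parameter objects, and the matching `config`.
#' @export
make_fixture <- function(name = c("std_train", "rs_wobble", "noise",
                                  "cp_step", "network"),
                         seed = 1, duration = NULL, i_shift = 0) {
  name <- match.arg(name)
  calib <- c(0.15, 0.48)
  if (name == "network") {
    dt <- 1e-4
    duration <- duration %||% 13
    surr <- make_network_surrogate(duration - 1, dt, tau_corr = 20e-3,
                                   ei_correlation = 0.8, i_shift = i_shift,
                                   seed = seed)
    lead <- round(1 / dt)
    pair <- structure(list(g_e = c(numeric(lead), surr$g_e),
                           g_i = c(numeric(lead), surr$g_i), dt = dt),
                      class = "conductance_pair")
    return(point_fixture(
      pair, cell_params(),
      electrode_model(R_s = 50e6),
      stimulus_spec(I_1 = 0.5e-9, I_2 = 0.5e-9),
      duration, dt,
      config = pipeline_config(calib_window = c(0.15, 0.9))))
  }
  duration <- duration %||% 5
  dt <- if (name %in% c("noise", "cp_step")) 2.5e-5 else 1e-4
  pair <- std_conductance_programme(duration, dt)
  cell <- cell_params()
  stim <- stimulus_spec()
  switch(name,
    std_train = point_fixture(
      pair, cell, electrode_model(R_s = 30e6), stim, duration, dt,
      config = pipeline_config(calib_window = calib)),
    rs_wobble = {
      rs <- make_rs_trace(rs_wobble_spec(30e6, 5e6, seed = seed),
                          duration, dt)
      point_fixture(pair, cell, electrode_model(R_s = rs), stim,
                    duration, dt,
                    config = pipeline_config(calib_window = calib))
    },
    noise = {
      nz <- make_recording_noise(duration, dt, sd = 0.04e-3, seed = seed)
      point_fixture(pair, cell, electrode_model(R_s = 30e6), stim,
                    duration, dt, noise = nz,
                    config = pipeline_config(calib_window = calib,
                                             lowpass = 180))
    },
    cp_step = point_fixture(
      pair, cell, electrode_model(R_s = 20e6, C_p = 5e-12, k = 1),
      stim, duration, dt,
      config = pipeline_config(calib_window = calib,
                               cp_compensation = TRUE)))
}
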