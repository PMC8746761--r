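#' Build a parametric passive ball-and-stick cable model
#'
#' Soma plus `n_dend` unbranched passive dendrites, discretised so that no
#' compartment exceeds 0.1 electrotonic length (and at most 25 um, to keep
#' synapse placement fine-grained). A parametric stand-in for detailed
#' pyramidal-cell morphologies: it reproduces the qualitative somatic
#' recording regime (current escape into the dendrite, distance-dependent
#' attenuation) without tying results to any particular reconstruction.
#'
#' @param n_dend number of dendrites (>= 1; the default 3 puts the somatic
#'   input resistance near 143 MOhm, the experimentally typical regime).
#' @param total_length length of each dendrite, micrometres.
#' @param soma_l,soma_d soma cylinder length/diameter, micrometres.
#' @param dend_d dendrite diameter, micrometres.
#' @param Ra axial resistivity, ohm cm.
#' @param cm specific capacitance, F/cm^2.
#' @param g_pas passive membrane conductance, S/cm^2 (default 1/15000
#'   S/cm^2, i.e. 15 kOhm cm^2).
#' @param e_pas leak reversal, volts.
#' @param max_seg upper bound on compartment length, micrometres (the
#'   effective bound is the smaller of this and 0.1 electrotonic length);
#'   halve it to check discretisation convergence.
#' @return object of class `cable_model`: per-compartment geometry,
#'   absolute capacitance/conductance, axial coupling to the parent, and
#'   path distance to the soma. Compartment 1 is the soma.
#' @export
build_ball_and_stick <- function(n_dend = 3, total_length = 600,
                                 soma_l = 20, soma_d = 20, dend_d = 2,
                                 Ra = 150, cm = 1e-6, g_pas = 1 / 15000,
                                 e_pas = -70e-3, max_seg = 25) {
  stopifnot(n_dend >= 1, total_length > 0, soma_l > 0, soma_d > 0,
            dend_d > 0, Ra > 0, cm > 0, g_pas > 0)
  Ra_si <- Ra / 100               # ohm cm -> ohm m
  cm_si <- cm * 1e4               # F/cm^2 -> F/m^2
  gp_si <- g_pas * 1e4            # S/cm^2 -> S/m^2
  rm_si <- 1 / gp_si              # ohm m^2
  lambda <- sqrt(rm_si * (dend_d * 1e-6) / (4 * Ra_si))  # m
  seg <- min(0.1 * lambda * 1e6, max_seg)                 # um
  nseg <- ceiling(total_length / seg)
  seg_l <- total_length / nseg
  L <- soma_l * 1e-6
  D <- soma_d * 1e-6
  parent <- 0L
  len <- L
  diam <- D
  dist <- 0
  for (d in seq_len(n_dend)) {
    base <- length(parent)
    for (k in seq_len(nseg)) {
      parent <- c(parent, if (k == 1) 1L else base + k - 1L)
      len <- c(len, seg_l * 1e-6)
      diam <- c(diam, dend_d * 1e-6)
      dist <- c(dist, (k - 0.5) * seg_l * 1e-6)
    }
  }
  area <- pi * diam * len
  r_half <- Ra_si * (len / 2) / (pi * (diam / 2)^2)  # axial half-resistance
  gax <- numeric(length(parent))
  for (i in 2:length(parent))
    gax[i] <- 1 / (r_half[i] + r_half[parent[i]])
  structure(list(parent = as.integer(parent), length = len, diam = diam,
                 area = area, cm_abs = cm_si * area, gpas_abs = gp_si * area,
                 gax = gax, e_pas = e_pas, path_dist = dist, soma = 1L,
                 lambda = lambda),
            class = "cable_model")
}

#' Steady-state somatic input resistance of a cable model
#'
#' Direct linear solve of the passive tree (no time stepping): injects a
#' unit current at the soma and returns the steady-state voltage
#' deflection.
#'
#' @param model a `cable_model`.
#' @return input resistance, ohms.
#' @export
cable_input_resistance <- function(model) {
  N <- length(model$parent)
  G <- diag(model$gpas_abs, N)
  for (i in 2:N) {
    p <- model$parent[i]
    G[i, i] <- G[i, i] + model$gax[i]
    G[p, p] <- G[p, p] + model$gax[i]
    G[i, p] <- G[i, p] - model$gax[i]
    G[p, i] <- G[p, i] - model$gax[i]
  }
  b <- numeric(N)
  b[model$soma] <- 1
  solve(G, b)[model$soma]
}

#' Synapse specification for the cable experiments
#'
#' Dual-exponential conductance kernel whose per-event amplitude is scaled
#' by the depressing-resource recursion (utilization `U`, recovery
#' `tau_rec`; facilitation is disabled, `tau_facil = 0`). Defaults are the
#' single-synapse distance-sweep condition.
#'
#' @param g_syn maximal synaptic conductance per event, siemens.
#' @param tau_rise,tau_decay kernel rise/decay time constants, seconds
#'   (`tau_rise < tau_decay`).
#' @param tau_rec resource recovery time constant, seconds.
#' @param tau_facil facilitation time constant, seconds (must be 0; kept
#'   as an explicit field).
#' @param U utilization constant.
#' @param E_v reversal potential, volts.
#' @return object of class `tm_dualexp_spec`.
#' @export
tm_dualexp_spec <- function(g_syn = 30e-9, tau_rise = 20e-3,
                            tau_decay = 50e-3, tau_rec = 200e-3,
                            tau_facil = 0, U = 0.2, E_v = 0) {
  if (tau_rise >= tau_decay) stop("tau_rise must be < tau_decay")
  if (tau_facil != 0) stop("facilitation is not supported (tau_facil must be 0)")
  stopifnot(g_syn >= 0, tau_rec > 0, U > 0, U <= 1)
  structure(list(g_syn = g_syn, tau_rise = tau_rise, tau_decay = tau_decay,
                 tau_rec = tau_rec, tau_facil = tau_facil, U = U, E_v = E_v),
            class = "tm_dualexp_spec")
}

#' Jittered regular event train
#'
#' Regular events at `rate` Hz over `[t_start, t_end)` with Gaussian
#' timing jitter (SD `jitter_sd`), sorted and kept strictly increasing.
#'
#' @param rate nominal event rate, hertz.
#' @param t_start,t_end active interval, seconds.
#' @param duration train duration, seconds.
#' @param jitter_sd Gaussian jitter SD, seconds.
#' @param seed integer RNG seed.
#' @return an [event_train].
#' @export
make_jittered_events <- function(rate = 10, t_start, t_end, duration,
                                 jitter_sd = 10e-3, seed = 1) {
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  tt <- seq(t_start, t_end - 1e-9, by = 1 / rate)
  tt <- sort(tt + stats::rnorm(length(tt), sd = jitter_sd))
  tt <- pmin(pmax(tt, 0), duration - 1e-9)
  tt <- tt[c(TRUE, diff(tt) > 1e-4)]
  event_train(tt, duration)
}

## Depressing dual-exponential conductance train (peak-normalised kernel).
tm_dualexp_conductance <- function(events, spec, dt) {
  stopifnot(inherits(spec, "tm_dualexp_spec"))
  amps <- tm_event_amplitudes(
    events, synapse_spec(U = spec$U, tau_inact = spec$tau_decay,
                         tau_rec = spec$tau_rec, g_max = spec$g_syn))$peaks
  n <- round(events$duration / dt)
  tr <- spec$tau_rise
  td <- spec$tau_decay
  tpk <- tr * td / (td - tr) * log(td / tr)
  norm <- 1 / (exp(-tpk / td) - exp(-tpk / tr))
  g <- numeric(n)
  for (k in seq_along(events$event_times)) {
    i0 <- floor(events$event_times[k] / dt) + 1
    if (i0 > n) next
    idx <- i0:n
    tt <- (idx - i0) * dt
    g[idx] <- g[idx] + amps[k] * norm * (exp(-tt / td) - exp(-tt / tr))
  }
  g
}

#' Place an excitatory/inhibitory synapse pair on a cable model
#'
#' Both synapses are attached to the compartment whose path distance to
#' the soma is nearest the requested distance.
#'
#' @param model a `cable_model`.
#' @param distance requested path distance, micrometres.
#' @return list with `comp` (compartment index) and `actual_distance`
#'   (micrometres).
#' @export
place_synapse_pair <- function(model, distance) {
  stopifnot(inherits(model, "cable_model"))
  d_um <- model$path_dist * 1e6
  if (distance > max(d_um) + 25)
    stop("requested distance exceeds the dendritic extent")
  comp <- which.min(abs(d_um - distance))
  list(comp = comp, actual_distance = d_um[comp])
}

#' Simulate somatic dual-sine current clamp on a cable model
#'
#' Backward-Euler (implicit) integration of the passive tree with
#' depressing dual-exponential conductance synapses at one compartment,
#' dual-sinusoid current injected at the soma through an access resistor.
#' The recorded pipette voltage is `V_p = V_soma + I_m * R_access` (no
#' pipette capacitance in cable mode).
#'
#' @param model a `cable_model`.
#' @param placement result of [place_synapse_pair].
#' @param e_events,i_events [event_train]s for the two synapses.
#' @param e_spec,i_spec [tm_dualexp_spec]s.
#' @param stimulus a [stimulus_spec].
#' @param access access resistance, ohms.
#' @param duration,dt seconds.
#' @return list with `V_p`, `V_soma`, `I_m`, ground-truth `g_e`, `g_i`,
#'   and `dt`.
#' @export
simulate_cable_cc <- function(model, placement, e_events, i_events,
                              e_spec, i_spec,
                              stimulus = stimulus_spec(I_1 = 0.25e-9,
                                                       I_2 = 0.25e-9),
                              access = 10e6, duration, dt) {
  g_e <- tm_dualexp_conductance(e_events, e_spec, dt)
  g_i <- tm_dualexp_conductance(i_events, i_spec, dt)
  I_m <- dual_sine_current(stimulus, duration, dt)
  V_soma <- .cable_integrate(model$parent - 1L, model$cm_abs,
                             model$gpas_abs, model$gax, model$e_pas,
                             placement$comp - 1L, g_e, e_spec$E_v,
                             placement$comp - 1L, g_i, i_spec$E_v,
                             model$soma - 1L, I_m,
                             FALSE, 0, 0, model$soma - 1L, dt, model$e_pas)
  list(V_p = V_soma + I_m * access, V_soma = V_soma, I_m = I_m,
       g_e = g_e, g_i = g_i, dt = dt)
}

#' Simulate somatic voltage clamp on a cable model
#'
#' Holds the soma at `hold` through an access resistor (modelled as a
#' clamp conductance `1/access` to the command potential) and returns the
#' conductance estimate of the non-isolated input:
#' `g = (I_clamp - baseline) / (hold - E_rev)`, with the holding current
#' measured over a silent pre-event window. Hold at the inhibitory
#' reversal to isolate excitation and vice versa.
#'
#' @inheritParams simulate_cable_cc
#' @param hold holding potential, volts.
#' @param E_rev reversal potential of the isolated (measured) input,
#'   volts; must differ from `hold`.
#' @param baseline_window silent window `c(t0, t1)` for the holding
#'   current, seconds.
#' @return list with `g_est` (siemens trace), `I_clamp`, `V_soma`, `dt`.
#' @export
simulate_cable_vc <- function(model, placement, e_events, i_events,
                              e_spec, i_spec, hold, E_rev,
                              access = 10e6, baseline_window = c(0.2, 1),
                              duration, dt) {
  if (hold == E_rev)
    stop("holding potential equals the measured input's reversal")
  g_e <- tm_dualexp_conductance(e_events, e_spec, dt)
  g_i <- tm_dualexp_conductance(i_events, i_spec, dt)
  n <- round(duration / dt)
  V_soma <- .cable_integrate(model$parent - 1L, model$cm_abs,
                             model$gpas_abs, model$gax, model$e_pas,
                             placement$comp - 1L, g_e, e_spec$E_v,
                             placement$comp - 1L, g_i, i_spec$E_v,
                             model$soma - 1L, numeric(n),
                             TRUE, 1 / access, hold, model$soma - 1L, dt,
                             model$e_pas)
  I_clamp <- (hold - V_soma) / access
  idx <- win_idx(baseline_window, dt, n)
  g_est <- (I_clamp - mean(I_clamp[idx])) / (hold - E_rev)
  list(g_est = g_est, I_clamp = I_clamp, V_soma = V_soma, dt = dt)
}

#' Measurement quality versus synaptic distance to the soma
#'
#' For each requested distance, places an E/I synapse pair, runs the
#' dual-sine current-clamp extraction and the two-hold voltage-clamp
#' comparison on the same event trains, and reports the Pearson
#' correlation of each estimate against the imposed conductances.
#'
#' @param model a `cable_model`.
#' @param distances path distances to test, micrometres (>= 3 values).
#' @param e_spec,i_spec [tm_dualexp_spec]s (defaults: the single-synapse
#'   condition, inhibitory reversal -75 mV).
#' @param duration trial duration, seconds.
#' @param dt sample interval, seconds.
#' @param event_t0 first event time, seconds (the preceding interval is
#'   the silent calibration window).
#' @param seed RNG seed for the jittered event trains.
#' @param access access resistance, ohms.
#' @return data.frame with columns `distance`, `actual_distance`,
#'   `r_e_method`, `r_i_method`, `r_e_vc`, `r_i_vc`.
#' @export
distance_sweep <- function(model, distances,
                           e_spec = tm_dualexp_spec(),
                           i_spec = tm_dualexp_spec(g_syn = 45e-9,
                                                    tau_rise = 30e-3,
                                                    tau_decay = 100e-3,
                                                    tau_rec = 600e-3,
                                                    U = 0.4, E_v = -75e-3),
                           duration = 4, dt = 1e-4, event_t0 = 1.3,
                           seed = 1, access = 10e6) {
  if (length(distances) < 3) stop("need at least 3 distances")
  e_events <- make_jittered_events(10, event_t0, duration - 0.3, duration,
                                   seed = seed)
  i_events <- make_jittered_events(10, event_t0, duration - 0.3, duration,
                                   seed = seed + 1000L)
  cfg <- pipeline_config(V_e = e_spec$E_v, V_i = i_spec$E_v,
                         calib_window = c(0.15, event_t0 - 0.2),
                         cable_correction = TRUE)
  out <- lapply(distances, function(d) {
    pl <- place_synapse_pair(model, d)
    cc <- simulate_cable_cc(model, pl, e_events, i_events, e_spec, i_spec,
                            access = access, duration = duration, dt = dt)
    fit <- estimate_conductances(cc$V_p, cc$I_m, dt, cfg)
    sc <- score_fit(fit, cc$g_e, cc$g_i)
    vce <- simulate_cable_vc(model, pl, e_events, i_events, e_spec, i_spec,
                             hold = i_spec$E_v, E_rev = e_spec$E_v,
                             access = access,
                             baseline_window = c(0.2, event_t0 - 0.2),
                             duration = duration, dt = dt)
    vci <- simulate_cable_vc(model, pl, e_events, i_events, e_spec, i_spec,
                             hold = e_spec$E_v, E_rev = i_spec$E_v,
                             access = access,
                             baseline_window = c(0.2, event_t0 - 0.2),
                             duration = duration, dt = dt)
    data.frame(distance = d, actual_distance = pl$actual_distance,
               r_e_method = sc$r_e, r_i_method = sc$r_i,
               r_e_vc = pearson_score(vce$g_est, cc$g_e, trim = fit$trim,
                                      dt = dt),
               r_i_vc = pearson_score(vci$g_est, cc$g_i, trim = fit$trim,
                                      dt = dt))
  })
  do.call(rbind, out)
}
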