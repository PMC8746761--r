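#' Synapse specification for short-term-depressing inputs
#'
#' Bundles the parameters of a depressing synapse in the two-variable
#' depletion/recovery formulation of short-term plasticity: each presynaptic
#' event releases a fraction `U` of the currently available resources `R_n`,
#' producing a conductance transient of peak `U * R_n * g_max` that decays
#' with `tau_inact`; resources recover towards 1 with `tau_rec`.
#'
#' @param U utilization (release fraction per event), in (0, 1].
#' @param tau_inact conductance inactivation (decay) time constant, seconds.
#' @param tau_rec resource recovery time constant, seconds.
#' @param g_max maximal per-event conductance, siemens.
#' @param delay onset delay applied to every event, seconds (>= 0).
#' @param reversal_potential synaptic reversal potential, volts.
#' @return An object of class `synapse_spec`.
#' @export
synapse_spec <- function(U = 0.7, tau_inact = 0.003, tau_rec = 0.5,
                         g_max = 15e-9, delay = 0,
                         reversal_potential = 0) {
  stopifnot(is.numeric(U), length(U) == 1L, U > 0, U <= 1)
  if (tau_inact <= 0 || tau_rec <= 0)
    stop("time constants must be > 0")
  if (g_max < 0) stop("g_max must be >= 0")
  if (delay < 0) stop("delay must be >= 0")
  structure(list(U = U, tau_inact = tau_inact, tau_rec = tau_rec,
                 g_max = g_max, delay = delay,
                 reversal_potential = reversal_potential),
            class = "synapse_spec")
}

#' Presynaptic event train
#'
#' @param event_times strictly increasing event times in seconds, all within
#'   `[0, duration)`. May be empty.
#' @param duration total duration of the train, seconds.
#' @return An object of class `event_train`.
#' @export
event_train <- function(event_times, duration) {
  event_times <- as.numeric(event_times)
  stopifnot(duration > 0)
  if (length(event_times)) {
    if (any(diff(event_times) <= 0))
      stop("event times must be strictly increasing")
    if (any(event_times < 0) || any(event_times >= duration))
      stop("event times must lie within [0, duration)")
  }
  structure(list(event_times = event_times, duration = duration),
            class = "event_train")
}

#' Per-event amplitudes of a depressing train
#'
#' Runs the depletion/recovery recursion over the events of a train and
#' returns the peak conductance contributed by each event:
#' `peak_n = U * R_n * g_max`, with
#' `R_(n+1) = 1 - (1 - R_n * (1 - U)) * exp(-dt_n / tau_rec)` and `R_1 = 1`.
#' Resources `R_n` always remain in `[0, 1]`.
#'
#' @param events an [event_train].
#' @param spec a [synapse_spec].
#' @return list with `peaks` (siemens) and `resources` (`R_n` before each
#'   event).
#' @export
tm_event_amplitudes <- function(events, spec) {
  stopifnot(inherits(events, "event_train"), inherits(spec, "synapse_spec"))
  tt <- events$event_times
  n <- length(tt)
  R <- numeric(n)
  if (n) {
    R[1] <- 1
    if (n > 1) {
      for (k in seq_len(n - 1)) {
        dtk <- tt[k + 1] - tt[k]
        R[k + 1] <- 1 - (1 - R[k] * (1 - spec$U)) * exp(-dtk / spec$tau_rec)
      }
    }
  }
  list(peaks = spec$U * R * spec$g_max, resources = R)
}

#' Depressing synaptic conductance trace
#'
#' Builds the conductance time course of a short-term-depressing synapse:
#' each event adds an instantaneous-rise transient of amplitude
#' `U * R_n * g_max` which decays exponentially with `tau_inact`. The
#' synapse's `delay` shifts every onset.
#'
#' @inheritParams tm_event_amplitudes
#' @param dt sample interval, seconds.
#' @return numeric conductance trace (siemens), length `duration / dt`.
#' @export
tm_depressing_conductance <- function(events, spec, dt) {
  stopifnot(dt > 0)
  amps <- tm_event_amplitudes(events, spec)$peaks
  n <- round(events$duration / dt)
  g <- numeric(n)
  t_on <- events$event_times + spec$delay
  for (k in seq_along(t_on)) {
    i0 <- floor(t_on[k] / dt) + 1
    if (i0 > n) next
    idx <- i0:n
    g[idx] <- g[idx] + amps[k] * exp(-((idx - i0) * dt) / spec$tau_inact)
  }
  g
}

#' Paired excitatory/inhibitory depressing conductance trains
#'
#' Generates an excitatory and an inhibitory conductance trace from the same
#' event train, with the inhibitory onsets delayed (4 ms by default) after
#' the excitatory ones. Default parameters are the depressing-train
#' reference condition: both synapses use `U = 0.7` and a 3 ms inactivation
#' time constant; excitation recovers with 0.5 s, inhibition with the longer
#' 1.3 s.
#'
#' @param events an [event_train] of (excitatory) event times.
#' @param e_spec,i_spec [synapse_spec] objects for excitation / inhibition.
#'   `i_spec$delay` defaults to 4 ms.
#' @param dt sample interval, seconds.
#' @return list of class `conductance_pair` with elements `g_e`, `g_i`
#'   (siemens) and `dt`.
#' @export
make_ei_std_pair <- function(events,
                             e_spec = synapse_spec(tau_rec = 0.5,
                                                   reversal_potential = 0),
                             i_spec = synapse_spec(tau_rec = 1.3,
                                                   delay = 0.004,
                                                   reversal_potential = -70e-3),
                             dt = 1e-4) {
  g_e <- tm_depressing_conductance(events, e_spec, dt)
  g_i <- tm_depressing_conductance(events, i_spec, dt)
  structure(list(g_e = g_e, g_i = g_i, dt = dt), class = "conductance_pair")
}

#' Step (tonic) conductance trace
#'
#' @param t_on,t_off step onset/offset, seconds (`0 <= t_on < t_off <=
#'   duration`); the step is on over `[t_on, t_off)`.
#' @param amplitude step amplitude, siemens.
#' @param duration trace duration, seconds.
#' @param dt sample interval, seconds.
#' @return numeric conductance trace (siemens).
#' @export
make_step_conductance <- function(t_on, t_off, amplitude, duration, dt) {
  if (t_off <= t_on) stop("t_off must be > t_on")
  stopifnot(t_on >= 0, t_off <= duration, dt > 0)
  n <- round(duration / dt)
  tvec <- (seq_len(n) - 1) * dt
  amplitude * as.numeric(tvec >= t_on & tvec < t_off)
}

## Exact AR(1) discretization of an Ornstein-Uhlenbeck process with unit
## stationary variance.
ou_process <- function(n, dt, tau) {
  a <- exp(-dt / tau)
  innov_sd <- sqrt(1 - a^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1)
  eps <- stats::rnorm(n - 1, sd = innov_sd)
  for (i in 2:n) x[i] <- a * x[i - 1] + eps[i - 1]
  x
}

#' Correlated network-like E/I conductance surrogate
#'
#' Stationary, temporally correlated (Ornstein-Uhlenbeck) excitatory and
#' inhibitory conductance traces standing in for the inputs a cell receives
#' inside an asynchronous balanced network. The two traces share a common
#' latent component so that their Pearson correlation before clipping equals
#' `ei_correlation`; `i_shift` circularly rotates the inhibitory trace
#' (a 10 s shift on a long trace destroys the correlation). Traces are
#' clipped at zero after construction.
#'
#' @param duration trace duration, seconds.
#' @param dt sample interval, seconds.
#' @param mean_e,mean_i mean conductances, siemens.
#' @param sd_e,sd_i stationary standard deviations, siemens.
#' @param tau_corr correlation time constant, seconds (> 0).
#' @param ei_correlation target pre-clipping Pearson correlation, in [-1, 1].
#' @param i_shift circular shift applied to the inhibitory trace, seconds.
#' @param seed integer RNG seed.
#' @return `conductance_pair` list: `g_e`, `g_i`, `dt`.
#' @export
make_network_surrogate <- function(duration, dt, mean_e = 10e-9,
                                   mean_i = 20e-9, sd_e = 3e-9, sd_i = 6e-9,
                                   tau_corr = 5e-3, ei_correlation = 0.8,
                                   i_shift = 0, seed = 1) {
  if (tau_corr <= 0) stop("tau_corr must be > 0")
  if (abs(ei_correlation) > 1) stop("|ei_correlation| must be <= 1")
  stopifnot(dt > 0, duration > 0)
  n <- round(duration / dt)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  z_c <- ou_process(n, dt, tau_corr)
  z_e <- ou_process(n, dt, tau_corr)
  z_i <- ou_process(n, dt, tau_corr)
  r <- abs(ei_correlation)
  s <- sign(ei_correlation + (ei_correlation == 0))
  x_e <- sqrt(r) * z_c + sqrt(1 - r) * z_e
  x_i <- s * sqrt(r) * z_c + sqrt(1 - r) * z_i
  g_e <- mean_e + sd_e * x_e
  g_i <- mean_i + sd_i * x_i
  if (i_shift != 0) {
    k <- round(i_shift / dt) %% n
    if (k > 0) g_i <- c(g_i[(n - k + 1):n], g_i[1:(n - k)])
  }
  structure(list(g_e = pmax(g_e, 0), g_i = pmax(g_i, 0), dt = dt),
            class = "conductance_pair")
}

#' Wandering access-resistance specification
#'
#' @param base_resistance fixed resistance the wobble rides on, ohms (> 0).
#' @param noise_sd standard deviation of the (smoothed) resistance noise,
#'   ohms.
#' @param lowpass_cutoff smoothing cutoff of the underlying Gaussian noise,
#'   hertz; the default 2 Hz gives the slow-drift regime.
#' @param seed integer RNG seed.
#' @return object of class `rs_wobble_spec`.
#' @export
rs_wobble_spec <- function(base_resistance = 30e6, noise_sd = 5e6,
                           lowpass_cutoff = 2, seed = 1) {
  if (base_resistance <= 0) stop("base_resistance must be > 0")
  stopifnot(noise_sd >= 0, lowpass_cutoff > 0)
  structure(list(base_resistance = base_resistance, noise_sd = noise_sd,
                 lowpass_cutoff = lowpass_cutoff, seed = seed),
            class = "rs_wobble_spec")
}

#' Slowly wandering access-resistance trace
#'
#' Lowpass-filters a Gaussian white-noise signal (zero-phase Gaussian
#' kernel, -3 dB at `lowpass_cutoff`, spectral tails vanishing within a
#' few multiples of the cutoff), rescales it to `noise_sd`, and adds it
#' to the fixed base resistance. The resulting band-limited trace models
#' the slow drift of electrode access resistance during a whole-cell
#' recording; circular convolution keeps the process stationary across
#' the whole trace.
#'
#' @param spec an [rs_wobble_spec].
#' @param duration trace duration, seconds.
#' @param dt sample interval, seconds.
#' @return numeric resistance trace (ohms), strictly positive.
#' @export
make_rs_trace <- function(spec, duration, dt) {
  stopifnot(inherits(spec, "rs_wobble_spec"), duration > 0, dt > 0)
  n <- round(duration / dt)
  old <- set_local_seed(spec$seed)
  on.exit(restore_seed(old))
  if (spec$noise_sd == 0) return(rep(spec$base_resistance, n))
  w <- stats::rnorm(n)
  sigma_f <- spec$lowpass_cutoff / sqrt(log(2))
  sigma_t <- 1 / (2 * pi * sigma_f)
  half <- min(ceiling(4 * sigma_t / dt), floor((n - 1) / 2))
  kk <- seq(-half, half)
  h <- exp(-(kk * dt)^2 / (2 * sigma_t^2))
  H <- stats::fft(c(h[(half + 1):(2 * half + 1)], numeric(n - 2 * half - 1),
                    h[1:half]))
  x <- Re(stats::fft(stats::fft(w) * H, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0) x <- x * (spec$noise_sd / s)
  rs <- spec$base_resistance + x
  if (any(rs <= 0))
    stop("resistance trace touched zero; use a smaller noise_sd")
  rs
}

#' Gaussian recording-noise trace
#'
#' Zero-mean white Gaussian voltage noise at a stated standard deviation
#' (0.04 mV reproduces the amplitude of typical open-pipette noise in a
#' slice setup).
#'
#' @param duration trace duration, seconds.
#' @param dt sample interval, seconds.
#' @param sd noise standard deviation, volts (>= 0).
#' @param seed integer RNG seed.
#' @return numeric voltage trace (volts).
#' @export
make_recording_noise <- function(duration, dt, sd = 0.04e-3, seed = 1) {
  if (sd < 0) stop("sd must be >= 0")
  stopifnot(duration > 0, dt > 0)
  n <- round(duration / dt)
  if (sd == 0) return(numeric(n))
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  stats::rnorm(n, sd = sd)
}

## Seed handling: scoped, restores the caller's RNG state.
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
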