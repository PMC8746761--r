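## Zero-phase application of a linear-phase FIR kernel by FFT convolution.
## The kernel must have odd length (even order n); the integer group delay
## n/2 is removed exactly, so the output is aligned with the input and has
## the same length. Samples within one kernel length of each end see the
## zero-padded boundary and are reported as the edge trim.
fir_apply <- function(x, h) {
  L <- length(h)
  if (L %% 2 == 0) stop("FIR kernel must have odd length (even order)")
  n <- length(x)
  gd <- (L - 1) / 2
  N <- stats::nextn(n + L - 1, 2)
  X <- stats::fft(c(x, numeric(N - n)))
  H <- stats::fft(c(h, rep(0 + 0i, N - L)))
  y <- stats::fft(X * H, inverse = TRUE) / N
  if (is.double(h)) y <- Re(y)
  y[(gd + 1):(gd + n)]
}

## Gaussian-envelope (Morlet-style) FIR bandpass kernel: a cosine carrier
## at f_center under a Gaussian window. Its frequency response is a
## Gaussian centred on f_center (amplitude exp(-df^2 / (2 sigma_f^2))),
## and -- crucially for time-resolved impedance work -- its envelope
## response has no time-domain sidelobes, so fast conductance transients
## are smoothed monotonically instead of ringing. sigma_f is set from the
## -3 dB half-bandwidth; the kernel is truncated at +-6 sigma_t (the truncation
## sidelobe floor, ~exp(-18), sits far below the cross-tone leakage that
## the circuit inversion would otherwise amplify) and normalised to unit gain at f_center.
fir_bandpass_kernel <- function(fs, f_center, half_bandwidth) {
  sigma_f <- half_bandwidth / sqrt(log(2))   # -3 dB at +-half_bandwidth
  sigma_t <- 1 / (2 * pi * sigma_f)
  half <- ceiling(6 * sigma_t * fs)
  kk <- seq(-half, half)
  h <- exp(-(kk / fs)^2 / (2 * sigma_t^2)) * cos(2 * pi * f_center * kk / fs)
  gain <- Mod(sum(h * exp(-2i * pi * f_center * kk / fs)))
  h / gain
}

## Complex (analytic) counterpart of the Gaussian bandpass: the same
## Gaussian envelope under a complex carrier e^{j w t}. Applying it yields
## the narrowband analytic signal in one strictly local convolution -- the
## kernel's own Gaussian roll-off suppresses negative frequencies, so no
## global Hilbert step (with its sensitivity to trace-end effects) is
## needed. Used by the impedance estimator, where even 1e-5 envelope
## ripple is amplified into percent-level conductance error.
fir_bandpass_kernel_c <- function(fs, f_center, half_bandwidth) {
  sigma_f <- half_bandwidth / sqrt(log(2))
  sigma_t <- 1 / (2 * pi * sigma_f)
  half <- ceiling(6 * sigma_t * fs)
  kk <- seq(-half, half)
  h <- exp(-(kk / fs)^2 / (2 * sigma_t^2)) *
    exp(2i * pi * f_center * kk / fs)
  gain <- Mod(sum(h * exp(-2i * pi * f_center * kk / fs)))
  h / gain
}

## Narrowband analytic signal of x around f_center (complex trace with
## `edge_trim` attribute).
narrowband_analytic <- function(x, dt, f_center, half_bandwidth = 10) {
  fs <- 1 / dt
  if (f_center - half_bandwidth <= 0 || f_center + half_bandwidth >= fs / 2)
    stop("passband must lie within (0, Nyquist)")
  h <- fir_bandpass_kernel_c(fs, f_center, half_bandwidth)
  y <- fir_apply(x, h)
  attr(y, "edge_trim") <- (length(h) - 1) / 2 + 1
  y
}

#' Zero-phase narrow-band filter around one stimulus frequency
#'
#' Isolates the component of a trace near `f_center` with a zero-phase
#' Gaussian-envelope FIR bandpass (-3 dB at `f_center +- half_bandwidth`,
#' Gaussian roll-off beyond). The Gaussian shape trades a soft spectral
#' edge for a ring-free envelope response, which is what makes the
#' instantaneous impedance usable across fast conductance transients; at
#' the default 10 Hz half-bandwidth the other stimulus tone 105 Hz away
#' is attenuated by far more than 100 dB. The returned trace carries an
#' `edge_trim` attribute: the number of samples at each end contaminated
#' by the kernel overlapping the trace boundary (half a kernel length).
#'
#' @param x numeric trace.
#' @param dt sample interval, seconds.
#' @param f_center passband centre frequency, hertz.
#' @param half_bandwidth -3 dB half-width of the passband, hertz; the
#'   envelope temporal resolution is `sigma_t = sqrt(log 2)/(2 pi
#'   half_bandwidth)` (about 13 ms at 10 Hz, 4.4 ms at 30 Hz).
#' @return filtered trace (same length) with attribute `edge_trim`
#'   (samples per end).
#' @export
narrowband_filter <- function(x, dt, f_center, half_bandwidth = 10) {
  fs <- 1 / dt
  if (f_center - half_bandwidth <= 0 || f_center + half_bandwidth >= fs / 2)
    stop("passband must lie within (0, Nyquist)")
  h <- fir_bandpass_kernel(fs, f_center, half_bandwidth)
  y <- fir_apply(x, h)
  attr(y, "edge_trim") <- (length(h) - 1) / 2 + 1
  y
}

#' Analytic signal (FFT-based Hilbert transform)
#'
#' Returns the complex analytic extension of a real trace: the real part
#' equals the input, the magnitude is the instantaneous envelope, and the
#' phase derivative gives the instantaneous frequency.
#'
#' @param x finite real numeric trace.
#' @return complex trace of the same length.
#' @export
analytic_signal <- function(x) {
  if (!all(is.finite(x))) stop("input must be finite")
  n <- length(x)
  X <- stats::fft(x)
  w <- numeric(n)
  if (n %% 2 == 0) {
    w[1] <- 1
    w[n / 2 + 1] <- 1
    w[2:(n / 2)] <- 2
  } else {
    w[1] <- 1
    w[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * w, inverse = TRUE) / n
}

#' Remove the stimulus tones from a recorded voltage
#'
#' Produces the "clean" membrane potential by subtracting the two
#' narrow-band components at the stimulus frequencies (a zero-phase
#' band-stop of half-width `half_width` around each tone). Optionally a
#' final zero-phase FIR lowpass is applied; with broadband recording noise
#' this regularises the subsequent time-derivative without touching the
#' (much slower) membrane dynamics. Set `lowpass` below the lower tone,
#' e.g. 180 Hz for 210/315 Hz stimulation.
#'
#' @param V recorded voltage trace, volts.
#' @param dt sample interval, seconds.
#' @param f1,f2 stimulus frequencies, hertz.
#' @param half_width half-width of each stop band, hertz (default 5).
#' @param lowpass optional lowpass cutoff, hertz, or `NULL` (default) for
#'   none.
#' @return cleaned voltage trace with attribute `edge_trim` (samples).
#' @export
clean_voltage <- function(V, dt, f1, f2, half_width = 5, lowpass = NULL) {
  if (abs(f1 - f2) <= 2 * half_width)
    stop("stop bands of the two stimulus frequencies overlap")
  fs <- 1 / dt
  b1 <- narrowband_filter(V, dt, f1, half_width)
  b2 <- narrowband_filter(V, dt, f2, half_width)
  out <- V - as.numeric(b1) - as.numeric(b2)
  trim <- attr(b1, "edge_trim")
  if (!is.null(lowpass)) {
    if (lowpass >= min(f1, f2))
      stop("lowpass cutoff must lie below both stimulus frequencies")
    n <- ceiling(5.5 * fs / (min(f1, f2) - lowpass))
    n <- n + n %% 2
    h <- as.numeric(signal::fir1(n, lowpass / (fs / 2), type = "low",
                                 window = signal::blackman(n + 1)))
    out <- fir_apply(out, h)
    trim <- max(trim, n / 2 + 1)
  }
  attr(out, "edge_trim") <- trim
  out
}
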