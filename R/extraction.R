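#' Leak conductance and resting potential from the quiet samples
#'
#' Takes the samples in the lowest `percentile` of the total-conductance
#' trace -- assumed to reflect the resting state with no evoked input --
#' and returns the mean conductance (`g_l` estimate) and the mean cleaned
#' voltage over those same samples (`V_l` estimate). With persistent
#' background synaptic activity this overestimates the true leak (the
#' quietest samples still contain synaptic conductance), a documented
#' bias of the percentile rule.
#'
#' @param V_clean cleaned voltage trace, volts.
#' @param g_t total-conductance trace, siemens (same length; `NA` allowed).
#' @param percentile percentage of lowest-conductance samples to use
#'   (default 5).
#' @return list with `g_l` (siemens) and `V_l` (volts).
#' @export
leak_and_rest <- function(V_clean, g_t, percentile = 5) {
  stopifnot(length(V_clean) == length(g_t), percentile > 0, percentile <= 100)
  ok <- which(!is.na(g_t) & !is.na(V_clean))
  thr <- stats::quantile(g_t[ok], percentile / 100, names = FALSE)
  sel <- ok[g_t[ok] <= thr]
  if (length(sel) < 100)
    warning("fewer than 100 samples below the leak percentile")
  list(g_l = mean(g_t[sel]), V_l = mean(V_clean[sel]))
}

#' Decompose total synaptic conductance into excitation and inhibition
#'
#' Per-sample inversion of the passive membrane equation. Writing
#' `V^x = V - V_x` for each reversal potential, the excitatory conductance
#' is
#' `g_e = (C dV/dt + g_l V^l + g_s V^i - I_slow) / (V^i - V^e)`
#' and `g_i = g_s - g_e`. The denominator equals `V_e - V_i` (a constant),
#' so samples where the voltage crosses either reversal are unproblematic.
#' The derivative is taken by central differences on the cleaned voltage.
#' `g_l` may be a scalar or a per-sample trace (the dynamically corrected
#' leak of [dendritic_leak_correction]).
#'
#' @param V_clean cleaned membrane voltage, volts.
#' @param g_s total synaptic conductance trace, siemens.
#' @param g_l leak conductance, siemens (scalar or trace).
#' @param V_l,V_e,V_i leak / excitatory / inhibitory reversal potentials,
#'   volts (`V_e != V_i`).
#' @param C membrane capacitance, farads.
#' @param dt sample interval, seconds.
#' @param I_slow non-sinusoidal component of the injected current, amperes
#'   (scalar 0 or a trace); the sinusoids' effect is carried by the
#'   impedance branch and must not be included here.
#' @return list with `g_e` and `g_i` traces (siemens); their sum equals
#'   `g_s` exactly where defined.
#' @export
decompose_ei <- function(V_clean, g_s, g_l, V_l, V_e, V_i, C, dt,
                         I_slow = 0) {
  if (V_e == V_i) stop("V_e and V_i must differ")
  n <- length(V_clean)
  stopifnot(length(g_s) == n)
  dVdt <- c(NA_real_,
            (V_clean[3:n] - V_clean[1:(n - 2)]) / (2 * dt),
            NA_real_)
  num <- C * dVdt + g_l * (V_clean - V_l) + g_s * (V_clean - V_i) - I_slow
  g_e <- num / (V_e - V_i)
  g_i <- g_s - g_e
  list(g_e = g_e, g_i = g_i)
}

#' Dynamic leak correction for somatic recordings of a dendritic cell
#'
#' In a spatially extended neuron the injected sinusoidal current partly
#' escapes into the dendrites, inflating the apparent leak. The empirical
#' correction replaces the constant leak with
#' `g_l'(t) = g_l (1 - exp(-(g_s(t)/g_l)^2))`: near rest the effective
#' leak collapses (most current escapes), while strong synaptic input
#' shunts the dendrites and restores the full leak.
#'
#' @param g_s estimated synaptic-conductance trace, siemens.
#' @param g_l estimated leak conductance, siemens (> 0).
#' @return corrected leak trace, siemens.
#' @export
dendritic_leak_correction <- function(g_s, g_l) {
  stopifnot(g_l > 0)
  g_l * (1 - exp(-(g_s / g_l)^2))
}

#' Pearson correlation between an estimate and its ground truth
#'
#' @param est,truth aligned traces of equal length.
#' @param trim margin removed from each end before scoring, seconds
#'   (use the filter edge trim).
#' @param dt sample interval, seconds (required when `trim > 0`).
#' @return Pearson correlation coefficient.
#' @export
pearson_score <- function(est, truth, trim = 0, dt = NULL) {
  stopifnot(length(est) == length(truth))
  n <- length(est)
  if (trim > 0) {
    if (is.null(dt)) stop("dt is required when trim > 0")
    k <- round(trim / dt)
    if (2 * k >= n) stop("trim removes the whole trace")
    est <- est[(k + 1):(n - k)]
    truth <- truth[(k + 1):(n - k)]
  }
  ok <- is.finite(est) & is.finite(truth)
  if (stats::sd(est[ok]) == 0 || stats::sd(truth[ok]) == 0)
    stop("undefined score: zero variance")
  stats::cor(est[ok], truth[ok])
}

#' Normalised cross-correlation over a lag range
#'
#' Mean-subtracted, normalised cross-correlation of two aligned traces for
#' lags in `[-max_lag, max_lag]`. Positive lags mean `b` follows `a`.
#'
#' @param a,b aligned traces of equal length.
#' @param max_lag maximum lag, seconds.
#' @param dt sample interval, seconds.
#' @return data.frame with columns `lag` (seconds) and `r`.
#' @export
cross_correlation <- function(a, b, max_lag, dt) {
  stopifnot(length(a) == length(b))
  K <- round(max_lag / dt)
  n <- length(a)
  if (K >= n) stop("max_lag must be shorter than the trace")
  a <- a - mean(a, na.rm = TRUE)
  b <- b - mean(b, na.rm = TRUE)
  cc <- stats::ccf(b, a, lag.max = K, plot = FALSE, na.action = stats::na.pass)
  data.frame(lag = as.numeric(cc$lag) * dt, r = as.numeric(cc$acf))
}
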