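#' Impedance of the electrode-plus-cell circuit
#'
#' Closed-form impedance of a series resistance in front of a parallel
#' conductance/capacitance (the passive point neuron seen through a
#' pipette):
#' `Z(f) = R_s + 1/(g + j w C)`, `w = 2 pi f`. Vectorised over any one of
#' `f`, `g`, `R_s`.
#'
#' @param f frequency, hertz.
#' @param g total membrane conductance, siemens.
#' @param C membrane capacitance, farads.
#' @param R_s series resistance, ohms.
#' @return complex impedance (ohms).
#' @export
circuit_impedance <- function(f, g, C, R_s = 0) {
  w <- 2 * pi * f
  R_s + 1 / (g + 1i * w * C)
}

## window (t0, t1) in seconds -> sample index range, checked against trim
win_idx <- function(window, dt, n, edge_trim = 0) {
  stopifnot(length(window) == 2, window[2] > window[1])
  i0 <- max(1L, floor(window[1] / dt) + 1L)
  i1 <- min(n, ceiling(window[2] / dt))
  if (i0 <= edge_trim || i1 > n - edge_trim)
    stop("window overlaps the filter edge-trim region")
  i0:i1
}

#' Coarse series-resistance estimate from band-passed traces
#'
#' Ratio of the discrete-Fourier magnitudes of the band-passed voltage and
#' current at the bin nearest the stimulus frequency, over a synaptically
#' silent window. This equals `|Z(f)|` of the whole circuit; at high
#' stimulus frequency it is dominated by the electrode resistance and
#' serves as the rough `R_s` used by the capacitance estimator.
#'
#' @param FV,FI band-passed voltage (volts) and current (amperes) at one
#'   stimulus frequency (see [narrowband_filter]).
#' @param dt sample interval, seconds.
#' @param f stimulus frequency, hertz.
#' @param window numeric `c(t0, t1)`, seconds; must span at least 10
#'   stimulus cycles and lie past the filter edge trim.
#' @return magnitude ratio (ohms).
#' @export
coarse_rs <- function(FV, FI, dt, f, window) {
  if (diff(window) < 10 / f)
    stop("window must span at least 10 stimulus cycles")
  trim <- max(attr(FV, "edge_trim") %||% 0, attr(FI, "edge_trim") %||% 0)
  idx <- win_idx(window, dt, length(FV), trim)
  v <- stats::fft(as.numeric(FV)[idx])
  a <- stats::fft(as.numeric(FI)[idx])
  freqs <- (seq_along(idx) - 1) / (length(idx) * dt)
  k <- which.min(abs(freqs[1:(length(idx) %/% 2 + 1)] - f))
  Mod(v[k]) / Mod(a[k])
}

#' Voltage-current phase estimate at one stimulus frequency
#'
#' Time-average, over a synaptically silent window, of the instantaneous
#' phase difference between the analytic signals of the band-passed
#' voltage and current, wrapped to `(-pi, pi]`.
#'
#' @inheritParams coarse_rs
#' @return phase in radians.
#' @export
phase_estimate <- function(FV, FI, dt, f, window) {
  if (diff(window) < 10 / f)
    stop("window must span at least 10 stimulus cycles")
  trim <- max(attr(FV, "edge_trim") %||% 0, attr(FI, "edge_trim") %||% 0)
  idx <- win_idx(window, dt, length(FV), trim)
  dphi <- Arg(analytic_signal(as.numeric(FV))[idx]) -
    Arg(analytic_signal(as.numeric(FI))[idx])
  dphi <- Arg(exp(1i * dphi))       # wrap each sample to (-pi, pi]
  Arg(mean(exp(1i * dphi)))         # circular mean
}

#' Phase-based estimate of the cell's total capacitance
#'
#' In the high-frequency regime (`(wC)^2 >> g^2`) the circuit impedance
#' reduces to `Z ~ R_s - j/(w C)`, so the capacitance follows from the
#' coarse resistance and the voltage-current phase:
#' `C_est = 1 / |tan(theta) * R_s * w|`.
#'
#' @param Rs_coarse coarse series-resistance estimate, ohms (> 0).
#' @param theta voltage-current phase, radians (non-zero).
#' @param f stimulus frequency, hertz.
#' @return capacitance estimate, farads.
#' @export
capacitance_estimate <- function(Rs_coarse, theta, f) {
  stopifnot(Rs_coarse > 0)
  if (theta == 0) stop("degenerate phase (theta = 0)")
  1 / abs(tan(theta) * Rs_coarse * 2 * pi * f)
}

#' Time-resolved complex impedance at one stimulus frequency
#'
#' Forms the narrowband analytic signals of voltage and current at `f`
#' (one zero-phase convolution with a complex Gaussian kernel each; see
#' [narrowband_filter] for the bandwidth convention) and returns the
#' per-sample complex ratio `Z(t) = HFV(t) / HFI(t)`. Samples where the
#' current envelope falls below `floor_frac` of its median are masked
#' (`NA`) with a warning.
#'
#' @param V,I recorded voltage (volts) and injected current (amperes).
#' @param dt sample interval, seconds.
#' @param f stimulus frequency, hertz.
#' @param half_bandwidth passband half-width, hertz.
#' @param floor_frac current-envelope floor as a fraction of its median.
#' @return complex impedance trace with attributes `frequency` and
#'   `edge_trim` (samples per end).
#' @export
impedance_trace <- function(V, I, dt, f, half_bandwidth = 10,
                            floor_frac = 0.01) {
  if (length(V) != length(I)) stop("V and I must have equal length")
  HV <- narrowband_analytic(V, dt, f, half_bandwidth)
  HI <- narrowband_analytic(I, dt, f, half_bandwidth)
  Z <- as.complex(HV) / as.complex(HI)
  env <- Mod(HI)
  lo <- env < floor_frac * stats::median(env)
  if (any(lo)) {
    warning(sum(lo), " samples with current envelope below floor; masked")
    Z[lo] <- NA_complex_
  }
  attr(Z, "frequency") <- f
  attr(Z, "edge_trim") <- attr(HV, "edge_trim")
  Z
}

#' Closed-form series resistance and total conductance from two impedances
#'
#' Inverts the circuit model `Z_k = R_s + 1/(g + j w_k C)` for the two
#' simultaneously measured impedance traces. Eliminating `g` gives a
#' quadratic in `R_s`,
#' `R^2 - (Z1 + Z2) R + Z1 Z2 - (Z2 - Z1)/(j C (w1 - w2)) = 0`,
#' evaluated per sample on the complex traces; the square-root branch is
#' chosen to give a physically admissible root (`Re(R_s) > 0`, smallest
#' relative imaginary residual), and `g = 1/(Z1 - R_s) - j w1 C`. Real
#' parts are returned; the residual imaginary magnitude is kept as a
#' diagnostic and samples with no admissible branch are masked.
#'
#' @param Z1,Z2 complex impedance traces from [impedance_trace] at the two
#'   distinct stimulus frequencies.
#' @param C cell capacitance, farads (> 0).
#' @param f1,f2 stimulus frequencies, hertz; default taken from the trace
#'   attributes.
#' @param method `"complex"` (default) evaluates the closed form on the
#'   complex traces; `"magnitude"` solves the magnitude system
#'   `|R + 1/(g + j w_k C)| = |Z_k|` per sample (vectorised Newton seeded
#'   by the complex solution), discarding the measured phases.
#' @return list with `Rs_t`, `g_t` (real traces), `imag_resid` (per-sample
#'   relative imaginary residual of the complex solution), `masked`
#'   (logical), `edge_trim`.
#' @export
solve_circuit <- function(Z1, Z2, C, f1 = attr(Z1, "frequency"),
                          f2 = attr(Z2, "frequency"),
                          method = c("complex", "magnitude")) {
  method <- match.arg(method)
  stopifnot(C > 0, length(Z1) == length(Z2))
  if (is.null(f1) || is.null(f2) || f1 == f2)
    stop("two distinct frequencies are required")
  ok <- !is.na(Z1) & !is.na(Z2)
  med1 <- stats::median(Mod(Z1[ok]))
  if (stats::median(Mod(Z1[ok] - Z2[ok])) < 1e-3 * med1)
    stop("degenerate impedance pair: Z1 and Z2 are indistinguishable")
  w1 <- 2 * pi * f1
  w2 <- 2 * pi * f2
  k <- (Z2 - Z1) / (1i * C * (w1 - w2))
  disc <- sqrt((Z1 - Z2)^2 + 4 * k)
  Ra <- ((Z1 + Z2) + disc) / 2
  Rb <- ((Z1 + Z2) - disc) / 2
  g_of <- function(R) 1 / (Z1 - R) - 1i * w1 * C
  ga <- g_of(Ra)
  gb <- g_of(Rb)
  pen <- function(R, g) {
    p <- abs(Im(R)) / (Mod(R) + 1) + abs(Im(g)) / (Mod(g) + 1e-12)
    p[Re(R) <= 0] <- Inf
    p
  }
  pa <- pen(Ra, ga)
  pb <- pen(Rb, gb)
  use_a <- pa <= pb
  R <- ifelse(use_a, Ra, Rb)
  g <- ifelse(use_a, ga, gb)
  resid <- pmin(pa, pb)
  masked <- !is.finite(resid)
  if (any(masked & ok))
    warning(sum(masked & ok), " samples with no admissible branch; masked")
  Rs_t <- Re(R)
  g_t <- Re(g)
  Rs_t[masked] <- NA_real_
  g_t[masked] <- NA_real_
  if (method == "magnitude") {
    mg <- magnitude_newton(Mod(Z1), Mod(Z2), C, w1, w2, Rs_t, g_t)
    Rs_t <- mg$R
    g_t <- mg$g
    bad <- !is.finite(Rs_t) | !is.finite(g_t)
    masked <- masked | bad
    Rs_t[masked] <- NA_real_
    g_t[masked] <- NA_real_
  }
  list(Rs_t = Rs_t, g_t = g_t, imag_resid = resid,
       masked = masked | !ok,
       edge_trim = max(attr(Z1, "edge_trim") %||% 0,
                       attr(Z2, "edge_trim") %||% 0))
}

## Per-sample Newton iteration on the magnitude system
##   F_k(R, g) = R^2 + (2 R g + 1) / u_k - |Z_k|^2,  u_k = g^2 + (w_k C)^2
## vectorised over samples, seeded by the complex-branch solution.
magnitude_newton <- function(a1, a2, C, w1, w2, R0, g0, iter = 12) {
  R <- R0
  g <- g0
  seed_bad <- !is.finite(R) | !is.finite(g)
  R[seed_bad] <- 0.8 * pmin(a1, a2)[seed_bad]
  g[seed_bad] <- 1e-9
  t1 <- (w1 * C)^2
  t2 <- (w2 * C)^2
  for (it in seq_len(iter)) {
    u1 <- g^2 + t1
    u2 <- g^2 + t2
    F1 <- R^2 + (2 * R * g + 1) / u1 - a1^2
    F2 <- R^2 + (2 * R * g + 1) / u2 - a2^2
    dF1R <- 2 * R + 2 * g / u1
    dF2R <- 2 * R + 2 * g / u2
    dF1g <- 2 * R / u1 - (2 * R * g + 1) * 2 * g / u1^2
    dF2g <- 2 * R / u2 - (2 * R * g + 1) * 2 * g / u2^2
    det <- dF1R * dF2g - dF1g * dF2R
    dR <- (F1 * dF2g - F2 * dF1g) / det
    dg <- (dF1R * F2 - dF2R * F1) / det
    R <- R - dR
    g <- g - dg
  }
  u1 <- g^2 + t1
  resid <- abs(R^2 + (2 * R * g + 1) / u1 - a1^2) / pmax(a1^2, 1e-30)
  bad <- !is.finite(resid) | resid > 1e-6
  R[bad] <- NA_real_
  g[bad] <- NA_real_
  list(R = R, g = g)
}

#' Numeric oracle for the two-frequency circuit inversion
#'
#' Independent brute-force solution of the magnitude system
#' `|R + 1/(g + j w_k C)| = |Z_k|`, `k = 1, 2`. Eliminating `R` through
#' the difference of the squared magnitudes reduces the system to a
#' single equation in `g`, which is bracketed on a dense grid and
#' polished with `uniroot`; every sign change is refined, so all roots
#' are enumerated. The magnitude system generically has two admissible
#' roots (the impedance-conductance curves of the two frequencies
#' re-intersect); the physical branch -- the one the complex-valued data
#' are consistent with -- is the smaller-conductance root, which is
#' returned. Used to cross-validate the closed form in [solve_circuit];
#' not meant for per-sample production use.
#'
#' @param absZ1,absZ2 impedance magnitudes, ohms (> 0).
#' @param C capacitance, farads.
#' @param f1,f2 the two stimulus frequencies, hertz.
#' @param g_max upper end of the conductance search range, siemens.
#' @return list with `Rs` (ohms), `g` (siemens), `roots` (all admissible
#'   roots as a data.frame) and `objective` (residual sum of squares of
#'   relative magnitude errors at the returned root).
#' @export
numeric_circuit_oracle <- function(absZ1, absZ2, C, f1, f2, g_max = 2e-6) {
  stopifnot(absZ1 > 0, absZ2 > 0)
  w1 <- 2 * pi * f1
  w2 <- 2 * pi * f2
  # 2 R g + 1 = (a1^2 - a2^2) u1 u2 / (C^2 (w2^2 - w1^2)),  u_k = g^2 + (w_k C)^2
  S <- function(g) {
    u1 <- g^2 + (w1 * C)^2
    u2 <- g^2 + (w2 * C)^2
    (absZ1^2 - absZ2^2) * u1 * u2 / (C^2 * (w2^2 - w1^2))
  }
  R_of <- function(g) (S(g) - 1) / (2 * pmax(g, 1e-16))
  Ff <- function(g) R_of(g)^2 + S(g) / (g^2 + (w1 * C)^2) - absZ1^2
  gg <- c(seq(1e-13, 1e-9, length.out = 200),
          10^seq(-9, log10(g_max), length.out = 3000))
  Fv <- Ff(gg)
  roots <- numeric(0)
  for (i in seq_len(length(gg) - 1)) {
    if (is.finite(Fv[i]) && is.finite(Fv[i + 1]) && Fv[i] * Fv[i + 1] < 0)
      roots <- c(roots,
                 stats::uniroot(Ff, c(gg[i], gg[i + 1]), tol = 1e-18)$root)
  }
  # boundary root at g = 0 (purely capacitive cell): both magnitudes must
  # then imply the same R^2
  R2a <- absZ1^2 - 1 / (w1 * C)^2
  R2b <- absZ2^2 - 1 / (w2 * C)^2
  if (abs(R2a - R2b) < 1e-6 * absZ1^2 && R2a > -1e-6 * absZ1^2)
    roots <- c(0, roots)
  Rr <- ifelse(roots == 0, sqrt(pmax(absZ1^2 - 1 / (w1 * C)^2, 0)),
               R_of(pmax(roots, 1e-12)))
  keep <- Rr > -1e-3 * absZ1 & roots >= 0
  roots <- roots[keep]
  Rr <- pmax(Rr[keep], 0)
  if (!length(roots)) stop("oracle found no admissible root")
  ord <- order(roots)
  g <- roots[ord[1]]
  R <- Rr[ord[1]]
  m <- Mod(R + 1 / (g + 1i * c(w1, w2) * C))
  list(Rs = R, g = g, roots = data.frame(g = roots[ord], Rs = Rr[ord]),
       objective = sum(((m - c(absZ1, absZ2)) / c(absZ1, absZ2))^2))
}

#' Pipette stray-capacitance estimate from the two impedance traces
#'
#' With stray capacitance `C_p` in parallel with the electrode-plus-cell
#' branch, the measured admittances differ by `j (w1 - w2) C_p` plus the
#' cell-branch admittance difference `Y1 - Y2`. The plain estimator
#' neglects that difference,
#' `C_p ~ Re < (1/Z1 - 1/Z2) / (j (w1 - w2)) >` averaged over a
#' synaptically silent window; it is adequate only when the stray term
#' dominates. When the cell capacitance is supplied, the estimate is
#' instead obtained by fitting the full three-parameter circuit model
#' `1/Z_k = 1/(R_s + 1/(g + j w_k C)) + j w_k C_p` to the two
#' window-averaged complex impedances (four real equations, three
#' unknowns, least squares) -- this stays accurate even when `Y1 - Y2`
#' is comparable to the stray term, as it is for a few-picofarad pipette
#' on a 20 MOhm electrode.
#'
#' @param Z1,Z2 complex impedance traces (see [impedance_trace]).
#' @param dt sample interval, seconds.
#' @param window pre-stimulus averaging window `c(t0, t1)`, seconds.
#' @param f1,f2 frequencies, hertz; default from trace attributes.
#' @param C known/estimated cell capacitance, farads; when supplied the
#'   model-based fit replaces the plain admittance-difference estimator.
#' @return capacitance estimate, farads (clamped at 0 with a warning if
#'   negative); attributes `imag_resid` (imaginary residual of the plain
#'   estimator) and `naive` (the plain Eq-16-style value).
#' @export
pipette_capacitance_estimate <- function(Z1, Z2, dt, window,
                                         f1 = attr(Z1, "frequency"),
                                         f2 = attr(Z2, "frequency"),
                                         C = NULL) {
  trim <- max(attr(Z1, "edge_trim") %||% 0, attr(Z2, "edge_trim") %||% 0)
  idx <- win_idx(window, dt, length(Z1), trim)
  w1 <- 2 * pi * f1
  w2 <- 2 * pi * f2
  z1 <- mean(Z1[idx], na.rm = TRUE)
  z2 <- mean(Z2[idx], na.rm = TRUE)
  cp_c <- (1 / z1 - 1 / z2) / (1i * (w1 - w2))
  cp <- Re(cp_c)
  naive <- cp
  if (!is.null(C)) {
    w <- c(w1, w2)
    zm <- c(z1, z2)
    obj <- function(p) {  # p = (Rs Mohm, g nS, Cp pF)
      y <- 1 / (p[1] * 1e6 + 1 / (p[2] * 1e-9 + 1i * w * C)) +
        1i * w * p[3] * 1e-12
      sum(Mod(1 / y - zm)^2) / Mod(z1)^2
    }
    fit <- stats::optim(c(Re(z2) / 1e6, 10, max(cp * 1e12, 1)), obj,
                        method = "L-BFGS-B", lower = c(1e-3, 0, 0),
                        control = list(factr = 1e3))
    cp <- fit$par[3] * 1e-12
  }
  if (cp < 0) {
    if (cp < -1e-12)
      warning("negative pipette-capacitance estimate; clamped to 0")
    cp <- 0
  }
  attr(cp, "imag_resid") <- abs(Im(cp_c))
  attr(cp, "naive") <- naive
  cp
}

#' Joint circuit calibration on a silent window
#'
#' Least-squares fit of the full recording-circuit model
#' `Z(w) = 1 / ( 1/(R_s + 1/(g + j w C)) + j w C_p )`
#' to the two window-averaged complex impedances. Two complex samples
#' give four real equations for the four unknowns `(R_s, g, C, C_p)`, so
#' the system is exactly determined; multi-start quasi-Newton avoids the
#' local minimum in which stray capacitance masquerades as a smaller cell
#' capacitance. Used by the pipeline when stray-capacitance compensation
#' is enabled, where the phase-based capacitance estimator alone is
#' biased. Note `g` is weakly identified from two frequencies in the
#' high-frequency regime; treat it as a by-product.
#'
#' @inheritParams pipette_capacitance_estimate
#' @return list with `Rs`, `g`, `C`, `Cp` (SI units) and `objective`
#'   (relative squared residual).
#' @export
calibrate_circuit <- function(Z1, Z2, dt, window,
                              f1 = attr(Z1, "frequency"),
                              f2 = attr(Z2, "frequency")) {
  trim <- max(attr(Z1, "edge_trim") %||% 0, attr(Z2, "edge_trim") %||% 0)
  idx <- win_idx(window, dt, length(Z1), trim)
  z <- c(mean(Z1[idx], na.rm = TRUE), mean(Z2[idx], na.rm = TRUE))
  w <- 2 * pi * c(f1, f2)
  obj <- function(p) {  # Rs Mohm, g nS, C nF, Cp pF
    y <- 1 / (p[1] * 1e6 + 1 / (p[2] * 1e-9 + 1i * w * p[3] * 1e-9)) +
      1i * w * p[4] * 1e-12
    sum(Mod(1 / y - z)^2) / Mod(z[1])^2
  }
  best <- NULL
  for (C0 in c(0.05, 0.1, 0.2, 0.5)) {
    for (Cp0 in c(0.5, 3, 10)) {
      fit <- tryCatch(
        stats::optim(c(Re(z[2]) / 1e6, 10, C0, Cp0), obj,
                     method = "L-BFGS-B", lower = c(1e-3, 0, 1e-3, 0),
                     control = list(factr = 1e2)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value))
        best <- fit
    }
  }
  if (is.null(best)) stop("circuit calibration failed to converge")
  list(Rs = best$par[1] * 1e6, g = best$par[2] * 1e-9,
       C = best$par[3] * 1e-9, Cp = best$par[4] * 1e-12,
       objective = best$value)
}

#' Remove an estimated stray capacitance from an impedance trace
#'
#' Subtracts the stray-capacitance admittance per sample:
#' `1/Z' = 1/Z - j w C_p`. Samples whose corrected admittance magnitude
#' falls near zero are masked.
#'
#' @param Z complex impedance trace.
#' @param Cp stray capacitance, farads (>= 0).
#' @param f frequency, hertz; default from the trace attribute.
#' @return corrected complex impedance trace (attributes preserved).
#' @export
compensate_cp <- function(Z, Cp, f = attr(Z, "frequency")) {
  if (Cp < 0) stop("Cp must be >= 0")
  if (Cp == 0) return(Z)
  Y <- 1 / Z - 1i * 2 * pi * f * Cp
  lo <- Mod(Y) < 1e-6 * stats::median(Mod(1 / Z), na.rm = TRUE)
  Zc <- 1 / Y
  if (any(lo, na.rm = TRUE)) {
    warning("near-singular corrected admittance; masked")
    Zc[which(lo)] <- NA_complex_
  }
  attributes(Zc) <- attributes(Z)
  Zc
}

`%||%` <- function(a, b) if (is.null(a)) b else a
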