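# Memoised heavy fixtures shared between test files: each is computed once
# per test run, on first use.
.fx_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fx_cache))
    assign(key, force(expr), envir = .fx_cache)
  get(key, envir = .fx_cache)
}

std_fixture <- function() cached("std", make_fixture("std_train"))

std_fit <- function() {
  fx <- std_fixture()
  cached("std_fit", estimate_conductances(fx$V_p, fx$I_m, fx$dt, fx$config))
}

# Analytic steady-state dual-tone pair (V, I) for a constant circuit: the
# voltage is synthesised directly from the circuit impedance, with no
# simulator in the loop.
analytic_vi <- function(g, C, Rs, duration = 2, dt = 1e-4,
                        f = c(210, 315), amp = 0.375e-9) {
  tt <- (seq_len(round(duration / dt)) - 1) * dt
  I <- numeric(length(tt))
  V <- numeric(length(tt))
  for (k in seq_along(f)) {
    Z <- circuit_impedance(f[k], g, C, Rs)
    I <- I + amp * sin(2 * pi * f[k] * tt)
    V <- V + amp * Mod(Z) * sin(2 * pi * f[k] * tt + Arg(Z))
  }
  list(V = V, I = I, dt = dt)
}

unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(p[1], p[1] + cumsum(d))
}
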