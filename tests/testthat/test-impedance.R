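test_that("high-frequency regime justifies the capacitive approximation", {
  g <- 1 / 100e6
  C <- 0.15e-9
  w <- 2 * pi * 100
  ratio <- (w * C)^2 / g^2
  second_term <- g / (g^2 + (w * C)^2)       # resistive cell term of Z
  expect_equal(ratio, 88.83, tolerance = 1e-3)
  expect_equal(second_term, 1.113e6, tolerance = 1e-3)
  # and the full impedance agrees with its decomposition
  Z <- circuit_impedance(100, g, C, 10e6)
  expect_equal(Re(Z), 10e6 + second_term, tolerance = 1e-12)
  expect_equal(Im(Z), -w * C / (g^2 + (w * C)^2), tolerance = 1e-12)
})

test_that("coarse Rs is the impedance magnitude at the stimulus tone", {
  vi <- analytic_vi(g = 10e-9, C = 0.15e-9, Rs = 30e6)
  FV <- narrowband_filter(vi$V, vi$dt, 315, 10)
  FI <- narrowband_filter(vi$I, vi$dt, 315, 10)
  r <- coarse_rs(FV, FI, vi$dt, 315, c(0.5, 1.5))
  expect_equal(r, Mod(circuit_impedance(315, 10e-9, 0.15e-9, 30e6)),
               tolerance = 0.005)
  # linearity: doubling the current halves the ratio
  FI2 <- FI * 2
  attr(FI2, "edge_trim") <- attr(FI, "edge_trim")
  expect_equal(coarse_rs(FV, FI2, vi$dt, 315, c(0.5, 1.5)), r / 2,
               tolerance = 1e-9)
  # pure series R + C circuit (g = 0) at high frequency: close to Rs
  vi0 <- analytic_vi(g = 0, C = 0.15e-9, Rs = 30e6, f = c(210, 315))
  FV0 <- narrowband_filter(vi0$V, vi0$dt, 315, 10)
  FI0 <- narrowband_filter(vi0$I, vi0$dt, 315, 10)
  expect_equal(coarse_rs(FV0, FI0, vi0$dt, 315, c(0.5, 1.5)), 30e6,
               tolerance = 0.02 * 30e6)
  expect_error(coarse_rs(FV, FI, vi$dt, 315, c(0.5, 0.52)), "cycles")
})

test_that("phase estimate matches the circuit phase", {
  vi <- analytic_vi(g = 1 / 150e6, C = 0.15e-9, Rs = 30e6)
  FV <- narrowband_filter(vi$V, vi$dt, 315, 10)
  FI <- narrowband_filter(vi$I, vi$dt, 315, 10)
  th <- phase_estimate(FV, FI, vi$dt, 315, c(0.5, 1.5))
  expect_lt(abs(th - Arg(circuit_impedance(315, 1 / 150e6, 0.15e-9, 30e6))),
            0.01)
  # V in phase with I -> 0; pure capacitor -> -pi/2
  dt <- 1e-4
  tt <- (0:19999) * dt
  s <- sin(2 * pi * 315 * tt)
  Fs <- narrowband_filter(s, dt, 315, 10)
  expect_lt(abs(phase_estimate(Fs, Fs, dt, 315, c(0.5, 1.5))), 1e-9)
  cpr <- narrowband_filter(sin(2 * pi * 315 * tt - pi / 2), dt, 315, 10)
  expect_lt(abs(phase_estimate(cpr, Fs, dt, 315, c(0.5, 1.5)) + pi / 2),
            0.01)
})

test_that("capacitance estimate inverts the phase relation", {
  C <- 0.15e-9
  Rs <- 30e6
  f <- 315
  theta <- -atan(1 / (2 * pi * f * C * Rs))
  expect_equal(capacitance_estimate(Rs, theta, f), C, tolerance = 1e-12)
  expect_error(capacitance_estimate(Rs, 0, f), "phase")
})

test_that("impedance trace is flat for a constant circuit and scales linearly", {
  vi <- analytic_vi(g = 10e-9, C = 0.15e-9, Rs = 30e6)
  Z1 <- impedance_trace(vi$V, vi$I, vi$dt, 210)
  k <- attr(Z1, "edge_trim")
  mid <- (k + 1):(length(Z1) - k)
  Zth <- circuit_impedance(210, 10e-9, 0.15e-9, 30e6)
  expect_lt(max(abs(Mod(Z1[mid]) - Mod(Zth))) / Mod(Zth), 0.01)
  Z1b <- impedance_trace(2 * vi$V, vi$I, vi$dt, 210)
  expect_equal(Mod(Z1b[mid]), 2 * Mod(Z1[mid]), tolerance = 1e-9)
})

test_that("impedance trace settles between levels across a conductance step", {
  # stitch two analytic steady states: g = 10 nS then 30 nS
  a <- analytic_vi(10e-9, 0.15e-9, 30e6, duration = 2)
  b <- analytic_vi(30e-9, 0.15e-9, 30e6, duration = 2)
  V <- c(a$V, b$V)
  I <- c(a$I, b$I)
  Z <- impedance_trace(V, I, a$dt, 315, half_bandwidth = 10)
  m1 <- Mod(circuit_impedance(315, 10e-9, 0.15e-9, 30e6))
  m2 <- Mod(circuit_impedance(315, 30e-9, 0.15e-9, 30e6))
  i1 <- round(1.5 / a$dt):round(1.9 / a$dt)
  i2 <- round(2.4 / a$dt):round(2.8 / a$dt)   # > 1/half_bandwidth past step
  expect_lt(max(abs(Mod(Z[i1]) - m1)) / m1, 0.01)
  expect_lt(max(abs(Mod(Z[i2]) - m2)) / m2, 0.01)
})

test_that("closed-form circuit inversion is exact on analytic impedances", {
  C <- 0.15e-9
  mk <- function(f, g, Rs, n = 100) {
    z <- rep(circuit_impedance(f, g, C, Rs), n)
    attr(z, "frequency") <- f
    attr(z, "edge_trim") <- 0
    z
  }
  for (meth in c("complex", "magnitude")) {
    sol <- solve_circuit(mk(210, 10e-9, 30e6), mk(315, 10e-9, 30e6), C,
                         method = meth)
    expect_lt(max(abs(sol$Rs_t - 30e6)) / 30e6, 1e-6)
    expect_lt(max(abs(sol$g_t - 10e-9)) / 10e-9, 1e-6)
  }
  # sweep g: exact recovery everywhere
  for (g in c(1e-9, 5e-9, 20e-9, 50e-9, 100e-9)) {
    sol <- solve_circuit(mk(210, g, 30e6), mk(315, g, 30e6), C)
    expect_lt(abs(sol$g_t[1] - g) / g, 1e-8)
  }
  # Rs = 0 limiting case
  sol0 <- solve_circuit(mk(210, 10e-9, 1e-2), mk(315, 10e-9, 1e-2), C)
  expect_lt(abs(sol0$Rs_t[1]), 1)
  expect_equal(sol0$g_t[1], 10e-9, tolerance = 1e-6)
  expect_error(solve_circuit(mk(210, 10e-9, 30e6), mk(315, 10e-9, 30e6,
                                                      n = 100) * 1 +
                               0 * 1i, C, f1 = 210, f2 = 210),
               "frequencies")
  expect_error(solve_circuit(mk(210, 10e-9, 30e6), {
    z <- mk(210, 10e-9, 30e6); attr(z, "frequency") <- 315; z
  }, C), "degenerate")
})

test_that("numeric oracle agrees with the closed form on random circuits", {
  set.seed(42)
  C <- 0.15e-9
  worst <- 0
  for (i in 1:100) {
    g <- runif(1, 1e-9, 100e-9)
    Rs <- runif(1, 10e6, 60e6)
    a1 <- Mod(circuit_impedance(210, g, C, Rs))
    a2 <- Mod(circuit_impedance(315, g, C, Rs))
    or <- numeric_circuit_oracle(a1, a2, C, 210, 315)
    z1 <- rep(circuit_impedance(210, g, C, Rs), 4)
    z2 <- rep(circuit_impedance(315, g, C, Rs), 4)
    attr(z1, "frequency") <- 210; attr(z1, "edge_trim") <- 0
    attr(z2, "frequency") <- 315; attr(z2, "edge_trim") <- 0
    cf <- solve_circuit(z1, z2, C)
    worst <- max(worst,
                 abs(or$Rs - cf$Rs_t[1]) / Rs,
                 abs(or$g - cf$g_t[1]) / g)
  }
  expect_lt(worst, 1e-5)
  # g = 0 circuit recovered as ~0
  or0 <- numeric_circuit_oracle(Mod(circuit_impedance(210, 0, C, 30e6)),
                                Mod(circuit_impedance(315, 0, C, 30e6)),
                                C, 210, 315)
  expect_lt(or0$g, 1e-11)
})

test_that("stray-capacitance estimation and compensation close the loop", {
  C <- 0.15e-9
  w1 <- 2 * pi * 210
  w2 <- 2 * pi * 315
  zfun <- function(w, Cp) 1 / (1 / (20e6 + 1 / (6.67e-9 + 1i * w * C)) +
                                 1i * w * Cp)
  mk <- function(z, f) {
    z <- rep(z, 2000)
    attr(z, "frequency") <- f
    attr(z, "edge_trim") <- 0
    z
  }
  Z1 <- mk(zfun(w1, 5e-12), 210)
  Z2 <- mk(zfun(w2, 5e-12), 315)
  # model-based fit recovers Cp exactly on exact impedances
  cp <- pipette_capacitance_estimate(Z1, Z2, 1e-4, c(0.01, 0.19), C = C)
  expect_lt(abs(as.numeric(cp) - 5e-12), 1e-3 * 5e-12)
  # joint calibration recovers the full circuit
  cal <- calibrate_circuit(Z1, Z2, 1e-4, c(0.01, 0.19))
  expect_lt(abs(cal$Rs - 20e6), 0.01 * 20e6)
  expect_lt(abs(cal$C - C), 0.01 * C)
  expect_lt(abs(cal$Cp - 5e-12), 0.05 * 5e-12)
  # compensation is the algebraic inverse of the stray admittance
  Z1c <- compensate_cp(Z1, 5e-12)
  expect_lt(Mod(as.complex(Z1c[1]) - (20e6 + 1 / (6.67e-9 + 1i * w1 * C))),
            1e-3)
  expect_identical(compensate_cp(Z1, 0), Z1)
  # identical impedances: plain estimator returns 0
  cp0 <- pipette_capacitance_estimate(Z1, mk(zfun(w1, 5e-12), 315), 1e-4,
                                      c(0.01, 0.19))
  expect_equal(as.numeric(cp0), 0)
})

test_that("k = 1 simulation yields a recoverable stray capacitance", {
  dt <- 2.5e-5
  n <- round(2 / dt)
  pair <- structure(list(g_e = numeric(n), g_i = numeric(n), dt = dt),
                    class = "conductance_pair")
  I <- dual_sine_current(stimulus_spec(), 2, dt)
  sim <- simulate_point_neuron(cell_params(),
                               electrode_model(20e6, C_p = 5e-12, k = 1),
                               pair, I, dt)
  Z1 <- impedance_trace(sim$V_p, I, dt, 210)
  Z2 <- impedance_trace(sim$V_p, I, dt, 315)
  cp <- pipette_capacitance_estimate(Z1, Z2, dt, c(0.15, 1.8), C = 0.15e-9)
  expect_lt(abs(cp - 5e-12) / 5e-12, 0.10)
  # k = 0 simulation: fitted stray capacitance is far below the cell C
  sim0 <- simulate_point_neuron(cell_params(), electrode_model(20e6),
                                pair, I, dt)
  Z1b <- impedance_trace(sim0$V_p, I, dt, 210)
  Z2b <- impedance_trace(sim0$V_p, I, dt, 315)
  cp0 <- pipette_capacitance_estimate(Z1b, Z2b, dt, c(0.15, 1.8),
                                      C = 0.15e-9)
  expect_lt(as.numeric(cp0), 0.02 * 0.15e-9)
})
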