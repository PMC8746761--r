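test_that("depressing-train amplitudes follow the resource recursion", {
  # independent oracle: per-event recursion written out step by step
  U <- 0.7; tau_rec <- 0.5; g_max <- 10e-9
  tt <- seq(0, 0.9, by = 0.1)              # 10 Hz train
  R <- 1
  peaks <- numeric(length(tt))
  for (k in seq_along(tt)) {
    peaks[k] <- U * R * g_max
    R <- 1 - (1 - R * (1 - U)) * exp(-0.1 / tau_rec)
  }
  ev <- event_train(tt, 1.5)
  spec <- synapse_spec(U = U, tau_rec = tau_rec, g_max = g_max)
  amps <- tm_event_amplitudes(ev, spec)
  expect_equal(amps$peaks, peaks, tolerance = 1e-12)
  expect_true(all(amps$resources >= 0 & amps$resources <= 1))
  # steady-state ratio against the closed-form fixed point
  Rstar <- (1 - exp(-0.1 / tau_rec)) / (1 - (1 - U) * exp(-0.1 / tau_rec))
  expect_equal(peaks[length(peaks)] / peaks[1], Rstar, tolerance = 1e-3)
})

test_that("single event releases full resources and decays with tau_inact", {
  dt <- 1e-4
  g <- tm_depressing_conductance(event_train(0, 0.1),
                                 synapse_spec(U = 0.7, g_max = 10e-9), dt)
  expect_equal(g[1], 7e-9, tolerance = 1e-12)
  expect_equal(g[31] / g[1], exp(-30 * dt / 0.003), tolerance = 1e-9)
  # widely separated events recover fully
  g2 <- tm_depressing_conductance(event_train(c(0, 50), 60),
                                  synapse_spec(U = 0.7, g_max = 10e-9,
                                               tau_rec = 0.5), 1e-3)
  expect_equal(max(g2[1:100]), max(g2[50001:50100]), tolerance = 1e-6)
  expect_true(all(g2 >= 0))
})

test_that("E/I pair applies the inhibitory onset delay", {
  ev <- event_train(1, 2)
  pair <- make_ei_std_pair(ev, dt = 1e-4)
  expect_s3_class(pair, "conductance_pair")
  i_on <- which(pair$g_i > 0)[1]
  e_on <- which(pair$g_e > 0)[1]
  expect_equal((i_on - e_on) * 1e-4, 0.004, tolerance = 1e-4)
  # empty train
  p0 <- make_ei_std_pair(event_train(numeric(0), 1), dt = 1e-4)
  expect_true(all(p0$g_e == 0) && all(p0$g_i == 0))
  # identical specs, zero delay: symmetry
  s <- synapse_spec(delay = 0)
  ps <- make_ei_std_pair(ev, e_spec = s, i_spec = s, dt = 1e-4)
  expect_identical(ps$g_e, ps$g_i)
  expect_error(synapse_spec(delay = -1e-3), "delay")
})

test_that("step conductance has the right support and integral", {
  dt <- 1e-4
  g <- make_step_conductance(3, 4, 5e-9, 5, dt)
  tt <- (seq_along(g) - 1) * dt
  expect_true(all(g[tt >= 3 & tt < 4] == 5e-9))
  expect_true(all(g[tt < 3 | tt >= 4] == 0))
  expect_equal(sum(g) * dt, 5e-9 * 1, tolerance = 5e-9 * dt)
  expect_true(all(make_step_conductance(1, 2, 0, 3, dt) == 0))
  expect_error(make_step_conductance(2, 2, 1e-9, 3, dt), "t_off")
})

test_that("network surrogate delivers the requested correlation structure", {
  n5 <- 1e5
  s1 <- make_network_surrogate(n5 * 1e-4, 1e-4, mean_e = 10e-9,
                               mean_i = 10e-9, sd_e = 2e-9, sd_i = 2e-9,
                               ei_correlation = 1, seed = 11)
  expect_gt(cor(s1$g_e, s1$g_i), 0.95)
  # 10 s circular shift with a short correlation time decorrelates
  s2 <- make_network_surrogate(20, 1e-3, tau_corr = 0.02,
                               ei_correlation = 1, i_shift = 10, seed = 12)
  expect_lt(abs(cor(s2$g_e, s2$g_i)), 0.1)
  # sd = 0: constant traces at the means
  s3 <- make_network_surrogate(1, 1e-3, mean_e = 4e-9, mean_i = 6e-9,
                               sd_e = 0, sd_i = 0, seed = 13)
  expect_true(all(s3$g_e == 4e-9) && all(s3$g_i == 6e-9))
  expect_true(all(s1$g_e >= 0) && all(s1$g_i >= 0))
  expect_error(make_network_surrogate(1, 1e-3, tau_corr = 0), "tau_corr")
  expect_error(make_network_surrogate(1, 1e-3, ei_correlation = 1.2),
               "ei_correlation")
})

test_that("requested pre-clipping correlation is recovered at large n", {
  for (rho in c(0.3, 0.8)) {
    s <- make_network_surrogate(100, 1e-4, mean_e = 50e-9, mean_i = 50e-9,
                                sd_e = 5e-9, sd_i = 5e-9, tau_corr = 2e-3,
                                ei_correlation = rho, seed = 21)
    # means far above zero: clipping never bites, so the sample r is the
    # pre-clipping r
    expect_lt(abs(cor(s$g_e, s$g_i) - rho), 0.05)
  }
})

test_that("access-resistance wobble is band-limited, centred, reproducible", {
  spec <- rs_wobble_spec(30e6, 2e6, seed = 5)
  rs <- make_rs_trace(spec, 20, 1e-3)
  expect_true(all(rs > 0))
  n_eff <- 20 * 2 * 2          # ~independent samples at 2 Hz cutoff
  expect_lt(abs(mean(rs) - 30e6), 3 * sd(rs) / sqrt(n_eff))
  expect_identical(rs, make_rs_trace(spec, 20, 1e-3))
  expect_equal(make_rs_trace(rs_wobble_spec(30e6, 0), 1, 1e-3),
               rep(30e6, 1000))
  expect_error(make_rs_trace(rs_wobble_spec(1e4, 1e6, seed = 1), 10, 1e-3),
               "noise_sd")
})

test_that("recording noise has the stated SD and is seed-reproducible", {
  nz <- make_recording_noise(10, 2.5e-5, sd = 0.04e-3, seed = 2)
  expect_lt(abs(sd(nz) - 0.04e-3) / 0.04e-3, 0.02)
  expect_lt(abs(mean(nz)), 3 * 0.04e-3 / sqrt(length(nz)))
  expect_identical(nz, make_recording_noise(10, 2.5e-5, sd = 0.04e-3,
                                            seed = 2))
  expect_true(all(make_recording_noise(1, 1e-3, sd = 0) == 0))
  expect_error(make_recording_noise(1, 1e-3, sd = -1), "sd")
})

test_that("event trains validate their invariants", {
  expect_error(event_train(c(0.2, 0.1), 1), "increasing")
  expect_error(event_train(c(0.1, 1.5), 1), "within")
  expect_silent(event_train(numeric(0), 1))
})
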