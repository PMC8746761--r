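test_that("input resistance matches closed forms", {
  # soma-dominated: 1 / (g_pas * area), with a negligible dendrite stub
  m1 <- build_ball_and_stick(n_dend = 1, total_length = 25, soma_l = 20,
                             soma_d = 20, dend_d = 0.01)
  expect_equal(cable_input_resistance(m1), 1 / m1$gpas_abs[1],
               tolerance = 0.01)
  # long thin cable: semi-infinite cable formula R_inf = Ra lambda / (pi a^2)
  m2 <- build_ball_and_stick(n_dend = 1, total_length = 3000, soma_l = 10,
                             soma_d = 2, dend_d = 2)
  Rinf <- (150 / 100) * m2$lambda / (pi * (1e-6)^2)
  expect_equal(cable_input_resistance(m2), Rinf, tolerance = 0.05)
  # default tree sits in the experimentally typical range
  expect_lt(abs(cable_input_resistance(build_ball_and_stick()) - 143e6),
            10e6)
})

test_that("discretisation is converged at the default compartment size", {
  m <- build_ball_and_stick()
  m_fine <- build_ball_and_stick(max_seg = 12.5)
  expect_equal(cable_input_resistance(m), cable_input_resistance(m_fine),
               tolerance = 0.01)
  # somatic transient response also converges
  dt <- 1e-4
  n <- round(0.5 / dt)
  I <- c(numeric(n / 2), rep(50e-12, n / 2))
  run <- function(mod) {
    dualsine:::.cable_integrate(mod$parent - 1L, mod$cm_abs, mod$gpas_abs,
                                mod$gax, mod$e_pas, -1L, numeric(n), 0,
                                -1L, numeric(n), 0, mod$soma - 1L, I,
                                FALSE, 0, 0, mod$soma - 1L, dt, mod$e_pas)
  }
  v1 <- run(m)
  v2 <- run(m_fine)
  expect_lt(max(abs(v1 - v2)) / diff(range(v1)), 0.01)
})

test_that("single-compartment cable agrees with the point-neuron simulator", {
  m <- build_ball_and_stick(n_dend = 1, total_length = 25, soma_l = 20,
                            soma_d = 20, dend_d = 0.01)
  dt <- 2.5e-5
  dur <- 1
  n <- round(dur / dt)
  ev <- make_jittered_events(10, 0.2, 0.8, dur, seed = 4)
  ge <- dualsine:::tm_dualexp_conductance(
    ev, tm_dualexp_spec(g_syn = 5e-9, tau_rise = 1e-3, tau_decay = 20e-3),
    dt)
  cellp <- cell_params(C = m$cm_abs[1], g_l = m$gpas_abs[1])
  pair <- structure(list(g_e = ge, g_i = ge * 0, dt = dt),
                    class = "conductance_pair")
  simP <- simulate_point_neuron(cellp, electrode_model(10e6), pair,
                                numeric(n), dt)
  Vc <- dualsine:::.cable_integrate(m$parent - 1L, m$cm_abs, m$gpas_abs,
                                    m$gax, m$e_pas, 0L, ge, 0, -1L,
                                    numeric(n), -75e-3, 0L, numeric(n),
                                    FALSE, 0, 0, 0L, dt, -70e-3)
  expect_lt(max(abs(Vc - simP$V_m)) / diff(range(simP$V_m)), 0.01)
})

test_that("silent cable stays at the leak reversal", {
  m <- build_ball_and_stick()
  pl <- place_synapse_pair(m, 100)
  cc <- simulate_cable_cc(m, pl, event_train(numeric(0), 1),
                          event_train(numeric(0), 1), tm_dualexp_spec(),
                          tm_dualexp_spec(E_v = -75e-3),
                          stimulus = stimulus_spec(I_1 = 0, I_2 = 0),
                          duration = 1, dt = 1e-4)
  expect_lt(max(abs(cc$V_soma - m$e_pas)), 1e-9)
})

test_that("synapse placement uses the nearest compartment", {
  m <- build_ball_and_stick()
  expect_equal(place_synapse_pair(m, 0)$comp, m$soma)
  pl <- place_synapse_pair(m, 400)
  expect_lt(abs(pl$actual_distance - 400), 25)
  expect_error(place_synapse_pair(m, 5000), "extent")
})

test_that("voltage clamp isolates conductances and attenuates with distance", {
  m <- build_ball_and_stick()
  dur <- 2.5
  dt <- 1e-4
  ev <- make_jittered_events(10, 1.2, 2.2, dur, seed = 5)
  silent <- event_train(numeric(0), dur)
  es <- tm_dualexp_spec()
  is <- tm_dualexp_spec(g_syn = 45e-9, tau_rise = 30e-3, tau_decay = 100e-3,
                        tau_rec = 600e-3, U = 0.4, E_v = -75e-3)
  # no events -> zero conductance after baseline subtraction
  pl <- place_synapse_pair(m, 50)
  vc0 <- simulate_cable_vc(m, pl, silent, silent, es, is, hold = -75e-3,
                           E_rev = 0, baseline_window = c(0.2, 1),
                           duration = dur, dt = dt)
  settled <- round(0.2 / dt):round(dur / dt)   # past the clamp onset
  expect_lt(max(abs(vc0$g_est[settled])), 1e-12)
  # near-somatic synapse with near-ideal access: amplitude within 5%
  pls <- place_synapse_pair(m, 0)
  ge <- dualsine:::tm_dualexp_conductance(ev, es, dt)
  vc1 <- simulate_cable_vc(m, pls, ev, silent, es, is, hold = -75e-3,
                           E_rev = 0, access = 0.1e6,
                           baseline_window = c(0.2, 1), duration = dur,
                           dt = dt)
  expect_lt(abs(max(vc1$g_est[settled]) - max(ge)) / max(ge), 0.05)
  # distal synapse: space clamp underestimates the amplitude
  pld <- place_synapse_pair(m, 450)
  vc2 <- simulate_cable_vc(m, pld, ev, silent, es, is, hold = -75e-3,
                           E_rev = 0, baseline_window = c(0.2, 1),
                           duration = dur, dt = dt)
  expect_lt(max(vc2$g_est[settled]), 0.6 * max(ge))
  expect_error(simulate_cable_vc(m, pls, ev, silent, es, is, hold = 0,
                                 E_rev = 0, duration = dur, dt = dt),
               "reversal")
})

test_that("dynamic leak correction rescues dendritic E/I decomposition", {
  m <- build_ball_and_stick()
  pl <- place_synapse_pair(m, 130)
  dur <- 4
  dt <- 1e-4
  e_ev <- make_jittered_events(10, 1.3, 3.7, dur, seed = 1)
  i_ev <- make_jittered_events(10, 1.3, 3.7, dur, seed = 1001)
  is <- tm_dualexp_spec(g_syn = 45e-9, tau_rise = 30e-3, tau_decay = 100e-3,
                        tau_rec = 600e-3, U = 0.4, E_v = -75e-3)
  cc <- simulate_cable_cc(m, pl, e_ev, i_ev, tm_dualexp_spec(), is,
                          duration = dur, dt = dt)
  r_i <- sapply(c(FALSE, TRUE), function(eq19) {
    cfg <- pipeline_config(V_e = 0, V_i = -75e-3,
                           calib_window = c(0.15, 1.1),
                           cable_correction = eq19)
    fit <- estimate_conductances(cc$V_p, cc$I_m, dt, cfg)
    score_fit(fit, cc$g_e, cc$g_i)$r_i
  })
  expect_gt(r_i[2], r_i[1])
  expect_gt(r_i[2], 0.9)
})

test_that("synapse specs and event jitter behave as declared", {
  expect_error(tm_dualexp_spec(tau_rise = 50e-3, tau_decay = 20e-3),
               "tau_rise")
  expect_error(tm_dualexp_spec(tau_facil = 0.1), "facilitation")
  ev1 <- make_jittered_events(10, 1, 2, 3, seed = 7)
  ev2 <- make_jittered_events(10, 1, 2, 3, seed = 7)
  expect_identical(ev1$event_times, ev2$event_times)
  expect_true(all(diff(ev1$event_times) > 0))
  expect_equal(length(ev1$event_times), 10, tolerance = 0.2)
})
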