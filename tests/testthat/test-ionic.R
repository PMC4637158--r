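test_that("both models are quiescent at their frozen rest state", {
  for (m in list(surrogate_model(), bondarenko_model())) {
    s0 <- cell_state(m)
    s1 <- reaction_step(m, s0, I_stim = 0)
    expect_lt(abs(s1$V - s0$V) / m$dt_o_default, m$quiescence_tol)
    # and over a full diffusion step worth of substeps
    s2 <- integrate_reaction(m, s0, I_stim = 0, N_o = 100L)
    expect_lt(abs(s2$V - s0$V), 0.01)
  }
})

test_that("integrate_reaction composes reaction steps", {
  m <- surrogate_model()
  s <- cell_state(m, V = -50) # displaced from rest
  one <- reaction_step(m, s, I_stim = 5, dt_o = 0.01)
  alt <- integrate_reaction(m, s, I_stim = 5, N_o = 1L, dt_o = 0.01)
  expect_equal(one, alt)
  many <- integrate_reaction(m, s, I_stim = 5, N_o = 10L, dt_o = 0.01)
  for (k in 1:10) s <- reaction_step(m, s, I_stim = 5, dt_o = 0.01)
  expect_equal(many$V, s$V)
  expect_equal(many$eta, s$eta)
})

test_that("suprathreshold pulse elicits an AP, subthreshold does not", {
  m <- surrogate_model()
  tr <- simulate_cell(m, T_end = 20,
                      pulses = data.frame(start = 1, duration = 2,
                                          amplitude = 15),
                      record_dt = 0.1)
  expect_true(any(tr$V > 0))
  t_cross <- min(tr$t[tr$V > 0])
  expect_lt(t_cross - 1, 5) # crosses 0 mV within 5 ms of pulse onset
  tr0 <- simulate_cell(m, T_end = 20,
                       pulses = data.frame(start = 1, duration = 2,
                                           amplitude = 1),
                       record_dt = 0.1)
  expect_false(any(tr0$V > 0))

  # reference adaptive-step integration of the same two-variable system
  # (independent oracle): the explicit-Euler trace and the 0 mV crossing
  # agree
  p <- as.list(m$pars)
  rhs <- function(t, y, parms) {
    u <- (y[1] - p$V_rest) / p$V_amp
    stim <- if (t >= 1 && t < 3) 15 else 0
    du <- y[2] * u^2 * (1 - u) / p$tau_in - u / p$tau_out + stim / p$V_amp
    dh <- if (u < p$u_gate) (1 - y[2]) / p$tau_open else -y[2] / p$tau_close
    list(c(p$V_amp * du, dh))
  }
  ref <- deSolve::lsoda(c(V = m$V_rest, h = 1), seq(0, 20, 0.1), rhs,
                        NULL, rtol = 1e-8, atol = 1e-8)
  t_cross_ref <- min(ref[ref[, "V"] > 0, "time"])
  expect_lt(abs(t_cross - t_cross_ref), 0.3)
  expect_lt(max(abs(tr$V - ref[, "V"])), 3) # mV, Euler vs adaptive
})

test_that("Bondarenko port has a murine AP morphology", {
  m <- bondarenko_model()
  expect_identical(m$n_states, 44L)
  tr <- simulate_cell(m, T_end = 120,
                      pulses = data.frame(start = 1, duration = 2,
                                          amplitude = 40),
                      record_dt = 0.25)
  vmax <- max(tr$V)
  expect_gt(vmax, 10)                       # overshooting upstroke
  expect_gt(max(diff(tr$V)) / 0.25, 50)     # rapid upstroke (mV/ms)
  v90 <- vmax - 0.9 * (vmax - tr$V[1])
  apd90 <- diff(range(tr$t[tr$V > v90]))
  expect_lt(apd90, 100)                     # APD well under 100 ms
  expect_lt(abs(tr$V[nrow(tr)] - m$V_rest), 2) # returns to rest
})

test_that("Markov chains conserve occupancy over 1e5 steps", {
  m <- bondarenko_model()
  chains <- list(
    ryr = c("P_C1", "P_O1", "P_O2", "P_C2"),
    lcc = c("C1", "C2", "C3", "C4", "O", "I1", "I2", "I3"),
    na = c("C_Na3", "C_Na2", "C_Na1", "O_Na", "IF_Na", "I1_Na", "I2_Na",
           "IC_Na2", "IC_Na3"),
    kr = c("C_K0", "C_K1", "C_K2", "O_K", "I_K"))
  V <- m$V_rest + 0
  eta <- matrix(as.numeric(m$init_state), ncol = 1)
  sums0 <- vapply(chains, function(ch)
    sum(eta[match(ch, m$state_names), 1]), 0)
  expect_equal(unname(sums0), rep(1, 4), tolerance = 1e-6)
  # 1e5 explicit-Euler substeps spanning an AP (stimulated at start)
  cardiomaze:::.ionic_step(m, V, eta, 40, 20000L, 1e-4)
  cardiomaze:::.ionic_step(m, V, eta, 0, 80000L, 1e-4)
  sums1 <- vapply(chains, function(ch)
    sum(eta[match(ch, m$state_names), 1]), 0)
  expect_lt(max(abs(sums1 - sums0)), 1e-4)
  # gates and occupancies stay in [0, 1]
  gate_idx <- match(c("a_to_f", "i_to_f", "n_Ks", "a_ur", "i_ur", "a_Kss"),
                    m$state_names)
  expect_true(all(eta[gate_idx, 1] >= 0 & eta[gate_idx, 1] <= 1))
})

test_that("reaction step errors constructively on non-finite state", {
  m <- surrogate_model()
  s <- cell_state(m)
  s$V <- NaN
  expect_error(reaction_step(m, s), "non-finite.*V")
})

test_that("threshold bisection brackets the frozen single-cell values", {
  thr <- find_threshold(surrogate_model())
  expect_gt(thr, 1)
  expect_lt(thr, 20)
})
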