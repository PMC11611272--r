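test_that("initial condition puts all material in the unbound pools", {
  p <- fission_params()
  s <- initial_state(p)
  expect_equal(unname(s), c(20, 15, numeric(30)))
  expect_equal(unname(conserved_quantities(s, p)), c(20, 15))
  nd <- dimensionless_params()
  expect_equal(unname(initial_state(nd)), c(4 / 3, 1, numeric(30)))
})

test_that("baseline trajectory shows damped oscillations and conserves mass", {
  traj <- simulate_fission(fission_params())
  expect_s3_class(traj, "fission_trajectory")
  expect_equal(length(traj$times), 2001)
  expect_lt(traj$conservation_drift, 1e-6)
  expect_gte(min(traj$states), -1e-9)
  expect_identical(classify_oscillation(traj), "damped")
})

test_that("raising the elongation rate switches on sustained oscillations", {
  traj <- simulate_fission(fission_params(k_plus = 5 * 1.75))
  expect_identical(classify_oscillation(traj), "sustained")
})

test_that("with fission off the TFR vanishes identically", {
  traj <- simulate_fission(fission_params(a = 0), t_end = 500, n_out = 300)
  expect_true(all(traj$tfr == 0))
  expect_true(all(traj$cumtf == 0))
  expect_identical(classify_oscillation(traj), "none")
})

test_that("the TFR counts only fission-competent oligomer sizes", {
  p <- fission_params()
  s <- initial_state(p)
  s["C26"] <- 1
  expect_equal(unname(total_fission_rate(s, p)), 5)
  s["C26"] <- 0; s["C25"] <- 1
  expect_equal(unname(total_fission_rate(s, p)), 0)
  traj <- simulate_fission(p, t_end = 100, n_out = 50)
  expect_equal(traj$tfr,
               p$a * rowSums(traj$states[, paste0("C", 26:30)]))
})

test_that("cumulative TF: closed form, window checks, quadrature vs ODE", {
  # constant TFR c over [0, L] integrates to c*L
  ft <- fake_trajectory(seq(0, 10, by = 0.1), rep(2.5, 101))
  expect_equal(as.numeric(cumulative_tf(ft)), 25, tolerance = 1e-12)
  expect_equal(as.numeric(cumulative_tf(ft, 2, 4)), 5, tolerance = 1e-12)
  expect_error(cumulative_tf(ft, -1, 5), "outside trajectory support")
  expect_error(cumulative_tf(ft, 5, 11), "outside trajectory support")

  # dense-grid trapezoid against the integrated auxiliary state
  traj <- simulate_fission(fission_params())
  v1 <- as.numeric(cumulative_tf(traj))
  v2 <- as.numeric(cumulative_tf(traj, method = "ode"))
  expect_lt(abs(v1 - v2) / v2, 1e-3)
  # refining the grid moves the trapezoid value by < 0.1 %
  fine <- simulate_fission(fission_params(), n_out = 4000)
  expect_lt(abs(as.numeric(cumulative_tf(fine)) - v2) / v2, 1e-3)
})

test_that("cumulative TF matches the augmented-state oracle on random models", {
  set.seed(33)
  for (k in 1:10) {
    p <- random_fission_params()
    traj <- simulate_fission(p, t_end = 1000, n_out = 1500)
    v_trap <- as.numeric(cumulative_tf(traj))
    v_ode <- as.numeric(cumulative_tf(traj, method = "ode"))
    expect_lt(abs(v_trap - v_ode) / max(v_ode, 1e-6), 1e-3)
  }
})

test_that("oscillation classifier handles edge cases and short windows", {
  tt <- seq(0, 10, by = 0.01)
  two_peaks <- fake_trajectory(tt, 1 + sin(tt))  # ~2 peaks only
  expect_error(classify_oscillation(two_peaks), "too short")
  flat <- fake_trajectory(tt, rep(0, length(tt)))
  expect_identical(classify_oscillation(flat), "none")
  monotone <- fake_trajectory(tt, 1 - exp(-tt))
  expect_identical(classify_oscillation(monotone), "none")
  many_sustained <- fake_trajectory(seq(0, 100, 0.01),
                                    1 + 0.5 * sin(seq(0, 100, 0.01)))
  expect_identical(classify_oscillation(many_sustained), "sustained")
  decaying <- fake_trajectory(seq(0, 100, 0.01),
                              1 + exp(-seq(0, 100, 0.01) / 10) *
                                sin(seq(0, 100, 0.01)))
  expect_identical(classify_oscillation(decaying), "damped")
})

test_that("halving solver tolerances leaves the TFR essentially unchanged", {
  p <- fission_params()
  a <- simulate_fission(p, t_end = 2000, n_out = 500)
  b <- simulate_fission(p, t_end = 2000, n_out = 500,
                        rtol = 5e-9, atol = 5e-11)
  expect_lt(max(abs(a$tfr - b$tfr)) / max(a$tfr), 1e-4)
})

test_that("solver failures surface as errors with diagnostics", {
  expect_error(simulate_fission(fission_params(), t_end = -5))
})
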