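test_that("canonical parameters map to mu=750, alpha=50, beta=150, zeta=0.2", {
  nd <- nondimensionalize(fission_params())
  expect_equal(nd$mu, 750, tolerance = 1e-12)
  expect_equal(nd$alpha, 50, tolerance = 1e-12)
  expect_equal(nd$beta, 150, tolerance = 1e-12)
  expect_equal(nd$zeta, 0.2, tolerance = 1e-12)
  expect_equal(nd$theta, 4 / 3, tolerance = 1e-12)
  expect_identical(nd$ell, 25L)
  expect_identical(nd$N_max, 30L)
})

test_that("unit rates give mu = 1 and a zero shrinkage rate is rejected", {
  p <- fission_params(k_plus = 1, k_minus = 1, M_total = 1)
  expect_equal(nondimensionalize(p)$mu, 1)
  p$k_minus <- 0  # bypass the constructor to exercise the division guard
  expect_error(nondimensionalize(p), "k_minus")
})

test_that("dimensionless groups are invariant under a common rate rescaling", {
  set.seed(11)
  for (k in 1:20) {
    p <- random_fission_params()
    f <- exp(runif(1, log(0.1), log(10)))
    q <- fission_params(k1 = p$k1 * f, k_m1 = p$k_m1 * f,
                        k_plus = p$k_plus * f, k_minus = p$k_minus * f,
                        a = p$a * f, gamma = p$gamma,
                        T_total = p$T_total, M_total = p$M_total)
    n1 <- nondimensionalize(p); n2 <- nondimensionalize(q)
    for (g in c("mu", "alpha", "beta", "zeta", "theta"))
      expect_equal(n1[[g]], n2[[g]], tolerance = 1e-12)
  }
})

test_that("dimensionless derivative at the start matches the scaled field", {
  nd <- dimensionless_params()
  d <- rhs_dimensionless(initial_state(nd), nd)
  expect_equal(unname(d[1]), -nd$gamma * nd$beta * nd$theta)  # -20
  expect_equal(unname(d[2]), -200)
  expect_equal(unname(d[3]), +200)
})

test_that("dimensionless conserved totals are (theta, 1) from the start", {
  nd <- dimensionless_params()
  expect_equal(unname(conserved_quantities(initial_state(nd), nd)),
               c(nd$theta, 1))
  s <- c(0, 0, 0, 0.5, numeric(28))  # only x2 = 0.5
  expect_equal(unname(conserved_quantities(s, nd)), c(0.1, 1))
})

test_that("rescaled dimensional trajectories match direct dimensionless runs", {
  p <- fission_params()
  traj <- simulate_fission(p, t_end = 2000, n_out = 800)
  direct <- simulate_fission(nondimensionalize(p),
                             t_end = 2000 * p$k_minus, n_out = 800)
  rs <- rescale_trajectory(traj)
  expect_equal(rs$times, direct$times)
  err <- max(abs(rs$states - direct$states)) / max(abs(direct$states))
  expect_lt(err, 1e-6)
  expect_lt(max(abs(rs$tfr - direct$tfr)) / max(direct$tfr), 1e-5)
})

test_that("fixed points map between representations under the scaling", {
  nd <- nondimensionalize(fission_params())
  ss <- find_steady_state(nd)
  # undo the scaling: C = M_total * x, and the dimensional field must vanish
  p <- fission_params()
  dim_state <- ss$fixed_point * p$M_total
  expect_lt(max(abs(rhs_dimensional(dim_state, p))),
            1e-8)  # k_minus * M_total rescales the residual
})
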