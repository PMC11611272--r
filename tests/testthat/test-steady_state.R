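test_that("analytic Jacobian matches central finite differences", {
  set.seed(55)
  for (k in 1:20) {
    p <- if (k %% 2) random_fission_params() else dimensionless_params()
    s <- random_state(p$N_max)
    f <- if (inherits(p, "fission_params_nd"))
      function(x) rhs_dimensionless(x, p) else function(x) rhs_dimensional(x, p)
    J <- unname(fission_jacobian(s, p))
    Jfd <- pracma::jacobian(f, s)
    expect_lt(max(abs(J - Jfd)) / max(abs(J)), 1e-6)
  }
})

test_that("conservation left-null-vectors annihilate the Jacobian everywhere", {
  set.seed(56)
  for (k in 1:20) {
    p <- random_fission_params()
    s <- random_state(p$N_max)
    J <- fission_jacobian(s, p)
    w <- c(1 / p$gamma, 0, seq_len(p$N_max))
    v <- c(0, 1, seq_len(p$N_max))
    scale <- max(abs(J))
    expect_lt(max(abs(w %*% J)) / scale, 1e-12)
    expect_lt(max(abs(v %*% J)) / scale, 1e-12)
  }
})

test_that("Newton finds a stable fixed point at the canonical parameters", {
  nd <- dimensionless_params()
  ss <- find_steady_state(nd)
  expect_lte(ss$residual_norm, 1e-11)
  expect_identical(ss$n_zero, 2L)
  expect_length(ss$eigenvalues, 32)
  nonzero <- ss$eigenvalues[Mod(ss$eigenvalues) >= 1e-8]
  expect_length(nonzero, 30)
  expect_true(all(Re(nonzero) < 0))
  expect_true(ss$stable)
  # the fixed point sits exactly on the conservation manifold
  q <- conserved_quantities(ss$fixed_point, nd)
  expect_lt(max(abs(q - c(nd$theta, 1))), 1e-12)
  # and the reported residual is the true field magnitude there
  expect_lt(max(abs(rhs_dimensionless(ss$fixed_point, nd))), 1e-11)
})

test_that("near-zero eigenvalues span the conservation left-null space", {
  nd <- dimensionless_params()
  ss <- find_steady_state(nd)
  J <- fission_jacobian(ss$fixed_point, nd)
  le <- eigen(t(J))
  idx <- which(Mod(le$values) < 1e-8)
  expect_length(idx, 2)
  basis <- cbind(c(1 / nd$gamma, 0, 1:30), c(0, 1, 1:30))
  for (i in idx) {
    u <- Re(le$vectors[, i])
    resid <- u - basis %*% qr.solve(basis, u)
    expect_lt(max(abs(resid)), 1e-6)
  }
})

test_that("increasing mu destabilizes the fixed point through a complex pair", {
  nd <- dimensionless_params()
  for (f in c(1.25, 1.75)) {
    p <- nd; p$mu <- 750 * f
    ss <- find_steady_state(p)
    expect_identical(ss$n_zero, 2L)
    expect_false(ss$stable)
    pos <- ss$eigenvalues[Re(ss$eigenvalues) > 0 &
                            Mod(ss$eigenvalues) >= 1e-8]
    expect_length(pos, 2)                       # one conjugate pair
    expect_true(all(abs(Im(pos)) > 1e-6))      # Hopf, not a real crossing
    expect_equal(sort(Im(pos)), sort(-Im(pos)))
  }
})

test_that("the Hopf point lies between the stable and unstable mu values", {
  mu_star <- find_hopf_mu(750, 937.5, tol_mu = 1)
  expect_gt(mu_star, 750)
  expect_lt(mu_star, 937.5)
  # just below: stable; just above: unstable
  p <- dimensionless_params()
  p$mu <- mu_star * 0.97
  expect_true(find_steady_state(p)$stable)
  p$mu <- mu_star * 1.03
  expect_false(find_steady_state(p)$stable)
})

test_that("bifurcation scan reproduces the branch structure of the diagram", {
  scan <- bifurcation_scan(750 * c(0.25, 1, 1.75))
  expect_identical(scan$stable, c(TRUE, TRUE, FALSE))
  expect_true(all(scan$n_zero == 2))
  # stable side: simulated late-window TFR collapses onto the fixed point
  for (i in 1:2) {
    expect_lt(abs(scan$tfr_max[i] - scan$tfr_fixed[i]),
              0.05 * scan$tfr_fixed[i] + 1e-6)
    expect_lt(abs(scan$tfr_min[i] - scan$tfr_fixed[i]),
              0.05 * scan$tfr_fixed[i] + 1e-6)
  }
  # unstable side: the limit cycle brackets the unstable fixed point
  expect_gt(scan$tfr_max[3], scan$tfr_fixed[3])
  expect_lt(scan$tfr_min[3], scan$tfr_fixed[3])
  expect_identical(scan$oscillation, c("damped", "damped", "sustained"))
})

test_that("a user-supplied guess off the manifold is projected and converges", {
  nd <- dimensionless_params()
  ss0 <- find_steady_state(nd)
  guess <- ss0$fixed_point * (1 + 1e-3)
  ss <- find_steady_state(nd, guess = guess)
  expect_lte(ss$residual_norm, 1e-11)
  expect_equal(unname(ss$fixed_point), unname(ss0$fixed_point),
               tolerance = 1e-8)
})
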