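test_that("Sobol' sequence reproduces the known van der Corput pattern", {
  X <- sobol_sequence(8, 2)
  expect_equal(X[, 1], c(0, 1/2, 3/4, 1/4, 3/8, 7/8, 5/8, 1/8))
  expect_equal(X[, 2], c(0, 1/2, 1/4, 3/4, 3/8, 7/8, 1/8, 5/8))
  expect_identical(sobol_sequence(64, 10), sobol_sequence(64, 10))
})

test_that("digitally shifted sequences stay uniform and seed-reproducible", {
  X1 <- sobol_sequence(2048, 5, seed = 7)
  X2 <- sobol_sequence(2048, 5, seed = 7)
  X3 <- sobol_sequence(2048, 5, seed = 8)
  expect_identical(X1, X2)
  expect_false(identical(X1, X3))
  expect_true(all(X1 >= 0 & X1 < 1))
  for (j in 1:5) {
    ks <- suppressWarnings(stats::ks.test(X1[, j], "punif"))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("Saltelli designs have N*(2D+2) rows and respect the bounds", {
  b4 <- list(k1 = c(0, 10), k_m1 = c(0, 10), k_plus = c(0, 10),
             k_minus = c(0, 1))
  d4 <- saltelli_sample(b4, base_N = 2048, seed = 1)
  expect_identical(nrow(d4$samples), 20480L)
  b5 <- c(b4, list(M_total = c(0, 30)))
  d5 <- saltelli_sample(b5, base_N = 2048, seed = 1)
  expect_identical(nrow(d5$samples), 24576L)
  for (nm in names(b5)) {
    expect_gte(min(d5$samples[, nm]), b5[[nm]][1])
    expect_lte(max(d5$samples[, nm]), b5[[nm]][2])
  }
  expect_error(saltelli_sample(b4, base_N = 100, seed = 1), "power of two")
})

test_that("indices of an additive function recover the variance shares", {
  a <- c(1, 2, 3, 4)
  truth <- a^2 / sum(a^2)   # Var(a_i X_i) = a_i^2/12 on U(0,1)
  design <- saltelli_sample(
    list(x1 = 0:1, x2 = 0:1, x3 = 0:1, x4 = 0:1), base_N = 1024, seed = 3)
  Y <- as.numeric(design$samples %*% a)
  res <- sobol_indices(Y, design, n_boot = 500, seed = 3)
  fo <- res$first_order
  expect_equal(fo$S1, truth, tolerance = 0.02)
  expect_equal(fo$ST, truth, tolerance = 0.02)
  # purely additive: every pairwise interaction is zero, within its CI
  so <- res$second_order
  expect_true(all(so$S2_lo - 1e-10 <= 0 & so$S2_hi + 1e-10 >= 0))
  expect_true(all(abs(so$S2) < 0.01))
})

test_that("indices of the Ishigami function match the analytic values", {
  a <- 7; b <- 0.1
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- a^2 / 8
  VT3 <- 8 * b^2 * pi^8 / 225
  V <- V1 + V2 + VT3
  truth_S1 <- c(V1 / V, V2 / V, 0)
  truth_ST <- c((V1 + VT3) / V, V2 / V, VT3 / V)
  design <- saltelli_sample(
    list(x1 = c(-pi, pi), x2 = c(-pi, pi), x3 = c(-pi, pi)),
    base_N = 2048, seed = 5)
  S <- design$samples
  Y <- sin(S[, 1]) + a * sin(S[, 2])^2 + b * S[, 3]^4 * sin(S[, 1])
  res <- sobol_indices(Y, design, n_boot = 500, seed = 5)
  expect_lt(max(abs(res$first_order$S1 - truth_S1)), 0.03)
  expect_lt(max(abs(res$first_order$ST - truth_ST)), 0.03)
  # the only true interaction is x1:x3
  s2 <- res$second_order
  expect_lt(abs(s2$S2[s2$pair == "x1:x3"] - VT3 / V), 0.05)
  expect_true(s2$S2_sig[s2$pair == "x1:x3"])
})

test_that("degenerate outputs are rejected", {
  design <- saltelli_sample(list(x1 = 0:1, x2 = 0:1), base_N = 8, seed = 1)
  expect_error(sobol_indices(rep(3, nrow(design$samples)), design),
               "variance")
  expect_error(sobol_indices(c(NA, numeric(nrow(design$samples) - 1)),
                             design), "missing")
})
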