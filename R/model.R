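#' Size-dependent fission rate
#'
#' Step function giving the fission rate of an oligomer of size `i`: zero for
#' sizes up to the threshold `ell` (a Drp1 spiral must fully encircle the
#' mitochondrion before it can constrict), and the constant `a` for sizes
#' `ell < i <= N_max`.
#'
#' @param i oligomer size(s), integer in `[1, N_max]`.
#' @param params a [fission_params()] or [dimensionless_params()] object (for
#'   the latter the rate returned is `alpha`).
#' @return Numeric vector of rates, same length as `i`.
#' @examples
#' p <- fission_params()
#' fission_rate(25, p)  # 0
#' fission_rate(26, p)  # 5
#' @export
fission_rate <- function(i, params) {
  r <- core_rates(params)
  if (any(i < 1 | i > r[["N_max"]] | i != floor(i)))
    stop("oligomer size 'i' must be an integer in [1, N_max]", call. = FALSE)
  ifelse(i > r[["ell"]], r[["a"]], 0)
}

# Shared mass-action vector field; `state` = (pool1, pool2, C_1..C_N).
# Identical in form for the dimensional and dimensionless systems (the
# latter via the parameter substitution in core_rates()).
rhs_core <- function(state, r) {
  N <- as.integer(r[["N_max"]]); ell <- as.integer(r[["ell"]])
  k1 <- r[["k1"]]; km1 <- r[["k_m1"]]; kp <- r[["k_plus"]]
  km <- r[["k_minus"]]; a <- r[["a"]]; gamma <- r[["gamma"]]
  if (length(state) != N + 2L)
    stop("state must have length N_max + 2", call. = FALSE)
  T <- state[[1]]; M <- state[[2]]; C <- state[3:(N + 2L)]
  f <- c(rep(0, ell), rep(a, N - ell))
  i <- seq_len(N)
  flux <- km1 * C[1] - k1 * T * M + sum(f * i * C)
  dC <- numeric(N)
  dC[1] <- k1 * T * M - km1 * C[1] + km * (2 * C[2] + sum(C[3:N])) -
    kp * (2 * C[1]^2 + sum(C[2:(N - 1)]) * C[1])
  j <- 2:(N - 1)
  dC[j] <- -kp * C[1] * (C[j] - C[j - 1]) + km * (C[j + 1] - C[j]) -
    f[j] * C[j]
  dC[N] <- kp * C[N - 1] * C[1] - km * C[N] - f[N] * C[N]
  c(gamma * flux, flux, dC)
}

#' Time derivative of the dimensional system
#'
#' Mass-action right-hand side for the state `(T, M, C1..CN)`: Drp1-Mff
#' binding/unbinding, stepwise oligomer elongation and shrinkage, and fission
#' of oligomers above the threshold size, which returns their Drp1 and Mff
#' content to the free pools. The cytosolic Drp1 balance carries the
#' compartment correction `gamma`.
#'
#' @param state numeric vector `(T, M, C1..CN)` of length `N_max + 2`, nM.
#' @param params a [fission_params()] object.
#' @return Named numeric vector of time derivatives, nM/s.
#' @export
rhs_dimensional <- function(state, params) {
  stopifnot(inherits(params, "fission_params"))
  d <- rhs_core(state, core_rates(params))
  names(d) <- state_names(params)
  d
}

#' Time derivative of the dimensionless system
#'
#' Right-hand side of the rescaled system in the variables
#' `(z, y, x1..xN) = (T, M, C1..CN) / M_total` with dimensionless time
#' `eta = k_minus * t`. It is constructed by substituting the scaled
#' variables into the dimensional field, which replaces the rates by the
#' groups `beta, zeta, mu, alpha` (and `k_minus` by 1).
#'
#' @param state numeric vector `(z, y, x1..xN)` of length `N_max + 2`.
#' @param params a [dimensionless_params()] object.
#' @return Named numeric vector of derivatives with respect to `eta`.
#' @export
rhs_dimensionless <- function(state, params) {
  stopifnot(inherits(params, "fission_params_nd"))
  d <- rhs_core(state, core_rates(params))
  names(d) <- state_names(params)
  d
}

#' Conserved quantities
#'
#' Total Drp1 and total Mff are conserved by the dynamics: fission and
#' disassembly only move material between the free pools and the oligomer
#' ladder. For a dimensional state this returns
#' `(T + gamma * sum(i * Ci), M + sum(i * Ci))`, which equal
#' `(T_total, M_total)` on any trajectory started from the standard initial
#' condition; for a dimensionless state it returns the analogous
#' `(z + gamma * sum(i * xi), y + sum(i * xi))`, equal to `(theta, 1)`.
#'
#' @param state state vector of length `N_max + 2`.
#' @param params a [fission_params()] or [dimensionless_params()] object.
#' @return Named numeric vector of the two conserved totals.
#' @export
conserved_quantities <- function(state, params) {
  r <- core_rates(params)
  N <- as.integer(r[["N_max"]])
  stopifnot(length(state) == N + 2L)
  s <- sum(seq_len(N) * state[3:(N + 2L)])
  out <- c(state[[1]] + r[["gamma"]] * s, state[[2]] + s)
  names(out) <- if (inherits(params, "fission_params_nd"))
    c("z_cons", "y_cons") else c("T_cons", "M_cons")
  out
}

#' Analytic Jacobian of the vector field
#'
#' Exact partial derivatives of [rhs_dimensional()] /
#' [rhs_dimensionless()] with respect to the state, as a dense
#' `(N_max + 2) x (N_max + 2)` matrix. The field is polynomial (quadratic),
#' so the entries are hand-derivable; the two conservation laws appear as
#' structural left null vectors `(1/gamma, 0, 1, 2, ..., N)` and
#' `(0, 1, 1, 2, ..., N)` at every state. Used by the Newton fixed-point
#' solver and the eigenvalue stability analysis.
#'
#' @inheritParams conserved_quantities
#' @return Numeric matrix of dimension `(N_max + 2)` squared.
#' @export
fission_jacobian <- function(state, params) {
  r <- core_rates(params)
  N <- as.integer(r[["N_max"]]); ell <- as.integer(r[["ell"]])
  k1 <- r[["k1"]]; km1 <- r[["k_m1"]]; kp <- r[["k_plus"]]
  km <- r[["k_minus"]]; a <- r[["a"]]; gamma <- r[["gamma"]]
  stopifnot(length(state) == N + 2L)
  T <- state[[1]]; M <- state[[2]]; C <- state[3:(N + 2L)]
  f <- c(rep(0, ell), rep(a, N - ell))
  n <- N + 2L
  J <- matrix(0, n, n)
  ci <- function(i) i + 2L  # column/row index of C_i

  # free-pool rows: flux = km1*C1 - k1*T*M + sum f(i)*i*Ci
  dflux <- numeric(n)
  dflux[1] <- -k1 * M
  dflux[2] <- -k1 * T
  dflux[ci(1)] <- km1
  idx <- which(f > 0)
  dflux[ci(idx)] <- dflux[ci(idx)] + f[idx] * idx
  J[1, ] <- gamma * dflux
  J[2, ] <- dflux

  # C1 row
  J[ci(1), 1] <- k1 * M
  J[ci(1), 2] <- k1 * T
  J[ci(1), ci(1)] <- -km1 - kp * (4 * C[1] + sum(C[2:(N - 1)]))
  J[ci(1), ci(2)] <- 2 * km - kp * C[1]
  if (N >= 4) J[ci(1), ci(3:(N - 1))] <- km - kp * C[1]
  J[ci(1), ci(N)] <- km

  # interior ladder rows, 2 <= i <= N-1
  for (i in 2:(N - 1)) {
    J[ci(i), ci(1)] <- J[ci(i), ci(1)] - kp * (C[i] - C[i - 1])
    if (i == 2) J[ci(i), ci(1)] <- J[ci(i), ci(1)] + kp * C[1]
    else J[ci(i), ci(i - 1)] <- J[ci(i), ci(i - 1)] + kp * C[1]
    J[ci(i), ci(i)] <- J[ci(i), ci(i)] - kp * C[1] - km - f[i]
    J[ci(i), ci(i + 1)] <- J[ci(i), ci(i + 1)] + km
  }

  # top row, i = N
  J[ci(N), ci(1)] <- J[ci(N), ci(1)] + kp * C[N - 1]
  J[ci(N), ci(N - 1)] <- J[ci(N), ci(N - 1)] + kp * C[1]
  J[ci(N), ci(N)] <- J[ci(N), ci(N)] - km - f[N]

  nm <- state_names(params)
  dimnames(J) <- list(nm, nm)
  J
}

#' Check a state for physical admissibility
#'
#' The mass-action field is polynomial and is integrated without clipping, so
#' a stiff solver may produce tiny negative concentrations of the order of
#' its tolerances. This validator errors when any component falls below
#' `-tol` (default 1e-9), the bound beyond which a state is treated as
#' unphysical rather than as roundoff.
#'
#' @param state state vector or a trajectory state matrix.
#' @param tol negativity tolerance, default `1e-9`.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
check_state <- function(state, tol = 1e-9) {
  m <- min(state)
  if (m < -tol)
    stop(sprintf("state has component %.3e below the negativity tolerance -%g",
                 m, tol), call. = FALSE)
  invisible(TRUE)
}
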