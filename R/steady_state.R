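#' Locate a fixed point of the dimensionless system
#'
#' Damped (backtracking line-search) Newton iteration on the
#' conservation-reduced system: the free pools are eliminated through the two
#' conserved totals, `z = theta - gamma * sum(i*xi)` and
#' `y = 1 - sum(i*xi)`, leaving a square, generically nonsingular
#' `N_max`-dimensional problem in the oligomer concentrations (the full
#' system's Jacobian is singular at every root because of the conservation
#' laws). The default initial guess is the late-window mean of a simulated
#' trajectory at the same parameters, which sits near the fixed point both
#' when it is stable and when it is surrounded by a limit cycle; the
#' trajectory's terminal state is tried as a fallback.
#'
#' After convergence the full analytic Jacobian is evaluated at the fixed
#' point and its complete eigenvalue spectrum computed; see
#' [eigen_stability()].
#'
#' @param params a [dimensionless_params()] object.
#' @param guess optional initial state (full `N_max + 2` vector); it is
#'   projected onto the conservation manifold through its oligomer part.
#' @param tol Newton tolerance on the sup-norm residual (default `1e-11`).
#' @param max_iter maximum Newton iterations per attempt.
#' @param zero_tol eigenvalues of modulus below this are attributed to the
#'   conservation laws (default `1e-8`).
#' @param t_guess horizon of the guess-generating simulation.
#' @return An object of class `steady_state`: `fixed_point`,
#'   `residual_norm`, `eigenvalues` (sorted by decreasing real part),
#'   `n_zero`, `max_re_nonzero`, `stable`, `iterations`.
#' @examples
#' \donttest{
#' ss <- find_steady_state(dimensionless_params())
#' ss$stable            # TRUE at the canonical parameters
#' ss$n_zero            # 2, one per conserved quantity
#' }
#' @export
find_steady_state <- function(params, guess = NULL, tol = 1e-11,
                              max_iter = 200, zero_tol = 1e-8,
                              t_guess = 500) {
  stopifnot(inherits(params, "fission_params_nd"))
  N <- params$N_max
  guesses <- if (!is.null(guess)) {
    stopifnot(length(guess) == N + 2)
    list(guess[3:(N + 2)])
  } else {
    traj <- simulate_fission(params, t_end = t_guess, n_out = 1000)
    late <- traj$times >= 0.5 * max(traj$times)
    list(colMeans(traj$states[late, 3:(N + 2), drop = FALSE]),
         traj$states[nrow(traj$states), 3:(N + 2)])
  }
  sol <- NULL
  for (g in guesses) {
    sol <- tryCatch(newton_reduced(g, params, tol, max_iter),
                    error = function(e) e)
    if (!inherits(sol, "error")) break
  }
  if (inherits(sol, "error"))
    stop("Newton iteration failed to converge: ", conditionMessage(sol),
         call. = FALSE)
  fp <- full_state(sol$x, params)
  res <- structure(list(
    fixed_point = fp,
    residual_norm = max(abs(rhs_dimensionless(fp, params))),
    iterations = sol$iter,
    params = params
  ), class = "steady_state")
  eigen_stability(res, zero_tol = zero_tol)
}

full_state <- function(x, params) {
  s <- sum(seq_along(x) * x)
  st <- c(params$theta - params$gamma * s, 1 - s, x)
  names(st) <- state_names(params)
  st
}

# residual of the reduced system: oligomer part of the field with the pools
# substituted from the conserved totals
reduced_residual <- function(x, params) {
  unname(rhs_dimensionless(full_state(x, params), params))[-(1:2)]
}

reduced_jacobian <- function(x, params) {
  N <- params$N_max
  J <- fission_jacobian(full_state(x, params), params)
  w <- seq_len(N)
  # chain rule for the eliminated pools: dz/dx_j = -gamma*j, dy/dx_j = -j
  J[3:(N + 2), 3:(N + 2), drop = FALSE] -
    outer(J[3:(N + 2), 1], params$gamma * w) -
    outer(J[3:(N + 2), 2], w)
}

newton_reduced <- function(x, params, tol, max_iter) {
  fx <- reduced_residual(x, params)
  nf <- max(abs(fx))
  for (iter in seq_len(max_iter)) {
    if (nf <= tol) return(list(x = x, iter = iter - 1L))
    A <- reduced_jacobian(x, params)
    step <- tryCatch(solve(A, -fx), error = function(e)
      stop("singular Newton matrix at iteration ", iter, call. = FALSE))
    lambda <- 1
    repeat {
      x_new <- x + lambda * step
      f_new <- reduced_residual(x_new, params)
      if (max(abs(f_new)) < nf || lambda < 2^-20) break
      lambda <- lambda / 2
    }
    if (max(abs(f_new)) >= nf && nf > tol)
      stop(sprintf("line search stalled (residual %.3e)", nf), call. = FALSE)
    x <- x_new; fx <- f_new; nf <- max(abs(fx))
  }
  if (nf <= tol) return(list(x = x, iter = max_iter))
  stop(sprintf("no convergence in %d iterations (residual %.3e)",
               max_iter, nf), call. = FALSE)
}

#' Eigenvalue spectrum and stability of a fixed point
#'
#' Evaluates the full analytic Jacobian at a converged fixed point and
#' computes its complete spectrum. The two conserved quantities force two
#' structurally zero eigenvalues at every fixed point; they are identified
#' by modulus below `zero_tol` and excluded from the stability verdict,
#' which is taken from the largest real part among the remaining
#' eigenvalues.
#'
#' @param x a `steady_state` object (from [find_steady_state()]) or a
#'   fixed-point state vector (then `params` is required).
#' @param params a [dimensionless_params()] object when `x` is a state.
#' @param zero_tol modulus threshold for the conservation eigenvalues.
#' @return The completed `steady_state` object with fields `eigenvalues`,
#'   `n_zero`, `max_re_nonzero`, `stable`.
#' @export
eigen_stability <- function(x, params = NULL, zero_tol = 1e-8) {
  if (inherits(x, "steady_state")) {
    res <- x
  } else {
    stopifnot(!is.null(params))
    res <- structure(list(fixed_point = x,
                          residual_norm = max(abs(rhs_dimensionless(x, params))),
                          params = params),
                     class = "steady_state")
  }
  J <- fission_jacobian(res$fixed_point, res$params)
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  nonzero <- Mod(ev) >= zero_tol
  res$eigenvalues <- ev
  res$zero_tol <- zero_tol
  res$n_zero <- sum(!nonzero)
  res$max_re_nonzero <- max(Re(ev[nonzero]))
  res$stable <- res$max_re_nonzero < 0
  res
}

#' @export
print.steady_state <- function(x, ...) {
  cat("<steady_state> dimensionless fission model\n")
  cat(sprintf("  residual sup-norm %.3e after %d Newton iteration(s)\n",
              x$residual_norm, x$iterations))
  cat(sprintf("  %d zero eigenvalue(s) (|lambda| < %g), %d nonzero\n",
              x$n_zero, x$zero_tol, length(x$eigenvalues) - x$n_zero))
  cat(sprintf("  max Re(nonzero) = %.5g  ->  %s\n", x$max_re_nonzero,
              if (x$stable) "stable" else "unstable"))
  invisible(x)
}

#' TFR at a fixed point
#'
#' @param ss a `steady_state` object.
#' @return The dimensionless TFR evaluated at the fixed point.
#' @export
steady_state_tfr <- function(ss) {
  stopifnot(inherits(ss, "steady_state"))
  unname(total_fission_rate(ss$fixed_point, ss$params))
}

#' Bifurcation scan over the build-to-disassembly ratio mu
#'
#' For each value of `mu` (other dimensionless parameters held at their
#' canonical values): simulate the system, classify the TFR, locate the
#' fixed point, compute its spectrum and the TFR at the fixed point, and
#' record the late-window extremes of the simulated TFR. While the fixed
#' point is stable the three TFR summaries coincide; past the Hopf point the
#' max/min branches open around the unstable fixed-point value.
#'
#' @param mu_values positive numeric vector of `mu` values to scan.
#' @param base a [dimensionless_params()] object supplying the fixed
#'   parameters.
#' @param t_end simulation horizon per scan point.
#' @param tail_frac fraction of the window used for the TFR extremes.
#' @param ... passed to [find_steady_state()].
#' @return A data frame of class `bifurcation_scan` with columns `mu`,
#'   `stable`, `max_re_nonzero`, `n_zero`, `tfr_fixed`, `tfr_max`,
#'   `tfr_min`, `oscillation`.
#' @export
bifurcation_scan <- function(mu_values, base = dimensionless_params(),
                             t_end = 500, tail_frac = 0.2, ...) {
  stopifnot(all(mu_values > 0))
  rows <- lapply(mu_values, function(mu) {
    p <- base; p$mu <- mu
    traj <- simulate_fission(p, t_end = t_end)
    late <- traj$times >= (1 - tail_frac) * max(traj$times)
    cls <- tryCatch(classify_oscillation(traj, tail_frac = tail_frac),
                    error = function(e) NA_character_)
    ss <- tryCatch(find_steady_state(p, ...), error = function(e) e)
    if (inherits(ss, "error"))
      stop(sprintf("steady-state search failed at mu = %g: %s",
                   mu, conditionMessage(ss)), call. = FALSE)
    data.frame(mu = mu, stable = ss$stable,
               max_re_nonzero = ss$max_re_nonzero, n_zero = ss$n_zero,
               tfr_fixed = steady_state_tfr(ss),
               tfr_max = max(traj$tfr[late]), tfr_min = min(traj$tfr[late]),
               oscillation = cls)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bifurcation_scan", class(out))
  out
}

#' Locate the Hopf point in mu by bisection
#'
#' Finds the `mu` at which the leading nonzero eigenvalue pair of the fixed
#' point crosses the imaginary axis, by root-finding on `max_re_nonzero`
#' between a stable and an unstable bracket.
#'
#' @param lower,upper bracketing `mu` values (stable below, unstable above).
#' @param base fixed dimensionless parameters.
#' @param tol_mu absolute tolerance on the located `mu`.
#' @param ... passed to [find_steady_state()].
#' @return The critical `mu` (numeric scalar).
#' @export
find_hopf_mu <- function(lower = 750, upper = 937.5,
                         base = dimensionless_params(), tol_mu = 0.5, ...) {
  f <- function(mu) {
    p <- base; p$mu <- mu
    find_steady_state(p, ...)$max_re_nonzero
  }
  stats::uniroot(f, c(lower, upper), tol = tol_mu)$root
}
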