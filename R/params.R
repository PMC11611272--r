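#' Dimensional parameter set for the fission model
#'
#' Container for the rate constants, total concentrations and structural
#' constants of the Drp1/Mff oligomerization model. Defaults are the canonical
#' parameter choices used throughout: association/dissociation of Drp1 with
#' Mff (`k1`, `k_m1`), oligomer elongation/shrinkage (`k_plus`, `k_minus`),
#' the above-threshold fission rate `a`, the membrane-to-cytosol effective
#' space ratio `gamma`, total tetrameric Drp1 `T_total` and total Mff
#' `M_total`, the fission threshold size `ell` and the maximum oligomer size
#' `N_max`.
#'
#' @param k1 association rate of cytosolic Drp1 with Mff, (nM s)^-1.
#' @param k_m1 dissociation rate of a Drp1-Mff complex into T and M, s^-1.
#' @param k_plus oligomer elongation rate, (nM s)^-1.
#' @param k_minus oligomer shrinkage rate, s^-1.
#' @param a fission rate of oligomers above the threshold size, s^-1.
#'   May be zero (fission switched off); all other rates must be positive.
#' @param gamma dimensionless ratio of outer-membrane to cytosolic
#'   effective space.
#' @param T_total total tetrameric Drp1 concentration, nM.
#' @param M_total total Mff concentration, nM.
#' @param ell fission threshold size: oligomers of size `i <= ell` cannot
#'   undergo fission, sizes `ell < i <= N_max` fission at rate `a`.
#' @param N_max maximum oligomer size tracked by the model (at least 4).
#' @return An object of class `fission_params`.
#' @examples
#' p <- fission_params()
#' nondimensionalize(p)$mu  # 750
#' @export
fission_params <- function(k1 = 1, k_m1 = 0.02, k_plus = 5, k_minus = 0.1,
                           a = 5, gamma = 0.1, T_total = 20, M_total = 15,
                           ell = 25, N_max = 30) {
  p <- list(k1 = k1, k_m1 = k_m1, k_plus = k_plus, k_minus = k_minus,
            a = a, gamma = gamma, T_total = T_total, M_total = M_total,
            ell = as.integer(ell), N_max = as.integer(N_max))
  validate_params(p, positive = c("k1", "k_m1", "k_plus", "k_minus",
                                  "gamma", "T_total", "M_total"))
  class(p) <- "fission_params"
  p
}

#' Dimensionless parameter set
#'
#' Parameters of the rescaled system obtained by measuring concentrations in
#' units of total Mff and time in units of `1/k_minus`: `mu = k_plus *
#' M_total / k_minus` (maximum build rate over disassembly rate), `alpha =
#' a / k_minus`, `beta = k1 * M_total / k_minus`, `zeta = k_m1 / k_minus`,
#' together with the space ratio `gamma` and the Drp1-to-Mff total ratio
#' `theta = T_total / M_total`, which fixes the initial condition through the
#' conserved quantities.
#'
#' @param mu,alpha,beta,zeta dimensionless rate groups (see Description).
#' @param gamma,theta space ratio and total-concentration ratio.
#' @param ell,N_max threshold and maximum oligomer size, as in
#'   [fission_params()].
#' @return An object of class `fission_params_nd`.
#' @export
dimensionless_params <- function(mu = 750, alpha = 50, beta = 150,
                                 zeta = 0.2, gamma = 0.1, theta = 4 / 3,
                                 ell = 25, N_max = 30) {
  p <- list(mu = mu, alpha = alpha, beta = beta, zeta = zeta,
            gamma = gamma, theta = theta,
            ell = as.integer(ell), N_max = as.integer(N_max))
  validate_params(p, positive = c("mu", "beta", "zeta", "gamma", "theta"))
  class(p) <- "fission_params_nd"
  p
}

validate_params <- function(p, positive) {
  bad <- character(0)
  num <- setdiff(names(p), c("ell", "N_max"))
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      bad <- c(bad, sprintf("'%s' must be a single finite number", f))
  }
  for (f in intersect(positive, num)) {
    v <- p[[f]]
    if (is.numeric(v) && length(v) == 1L && is.finite(v) && v <= 0)
      bad <- c(bad, sprintf("'%s' must be strictly positive", f))
  }
  for (f in intersect(c("a", "alpha"), names(p))) {
    v <- p[[f]]
    if (is.numeric(v) && length(v) == 1L && is.finite(v) && v < 0)
      bad <- c(bad, sprintf("'%s' must be non-negative", f))
  }
  if (is.na(p$N_max) || p$N_max < 4L)
    bad <- c(bad, "'N_max' must be an integer >= 4")
  if (is.na(p$ell) || p$ell < 1L || p$ell >= p$N_max)
    bad <- c(bad, "'ell' must satisfy 1 <= ell < N_max")
  if (length(bad))
    stop("invalid parameter set:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  invisible(p)
}

#' Nondimensionalize a dimensional parameter set
#'
#' Maps the dimensional rate constants onto the four dimensionless groups
#' `mu = k_plus * M_total / k_minus`, `alpha = a / k_minus`,
#' `beta = k1 * M_total / k_minus` and `zeta = k_m1 / k_minus`, carrying
#' `gamma`, `ell` and `N_max` over unchanged and recording
#' `theta = T_total / M_total`. The canonical parameter set maps to
#' `mu = 750`, `alpha = 50`, `beta = 150`, `zeta = 0.2`.
#'
#' @param params a [fission_params()] object.
#' @return A [dimensionless_params()] object.
#' @export
nondimensionalize <- function(params) {
  stopifnot(inherits(params, "fission_params"))
  if (params$k_minus <= 0)
    stop("cannot nondimensionalize: 'k_minus' must be positive ",
         "(time is rescaled by 1/k_minus)", call. = FALSE)
  dimensionless_params(
    mu    = params$k_plus * params$M_total / params$k_minus,
    alpha = params$a / params$k_minus,
    beta  = params$k1 * params$M_total / params$k_minus,
    zeta  = params$k_m1 / params$k_minus,
    gamma = params$gamma,
    theta = params$T_total / params$M_total,
    ell   = params$ell,
    N_max = params$N_max
  )
}

# Map either parameter class onto the common rate vector used by the vector
# field: (k1, k_m1, k_plus, k_minus, a, gamma, ell, N). The dimensionless
# system is the same field with k_minus = 1 and the rate groups substituted.
core_rates <- function(params) {
  if (inherits(params, "fission_params")) {
    c(k1 = params$k1, k_m1 = params$k_m1, k_plus = params$k_plus,
      k_minus = params$k_minus, a = params$a, gamma = params$gamma,
      ell = params$ell, N_max = params$N_max)
  } else if (inherits(params, "fission_params_nd")) {
    c(k1 = params$beta, k_m1 = params$zeta, k_plus = params$mu,
      k_minus = 1, a = params$alpha, gamma = params$gamma,
      ell = params$ell, N_max = params$N_max)
  } else {
    stop("'params' must be a fission_params or fission_params_nd object",
         call. = FALSE)
  }
}

state_names <- function(params) {
  if (inherits(params, "fission_params_nd"))
    c("z", "y", paste0("x", seq_len(params$N_max)))
  else
    c("T", "M", paste0("C", seq_len(params$N_max)))
}

#' @export
print.fission_params <- function(x, ...) {
  cat("Dimensional fission-model parameters\n")
  cat(sprintf("  k1 = %g (nM s)^-1   k_m1 = %g s^-1\n", x$k1, x$k_m1))
  cat(sprintf("  k_plus = %g (nM s)^-1   k_minus = %g s^-1\n",
              x$k_plus, x$k_minus))
  cat(sprintf("  a = %g s^-1   gamma = %g\n", x$a, x$gamma))
  cat(sprintf("  T_total = %g nM   M_total = %g nM\n", x$T_total, x$M_total))
  cat(sprintf("  threshold ell = %d, max size N = %d\n", x$ell, x$N_max))
  invisible(x)
}

#' @export
print.fission_params_nd <- function(x, ...) {
  cat("Dimensionless fission-model parameters\n")
  cat(sprintf("  mu = %g  alpha = %g  beta = %g  zeta = %g\n",
              x$mu, x$alpha, x$beta, x$zeta))
  cat(sprintf("  gamma = %g  theta = %g\n", x$gamma, x$theta))
  cat(sprintf("  threshold ell = %d, max size N = %d\n", x$ell, x$N_max))
  invisible(x)
}
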