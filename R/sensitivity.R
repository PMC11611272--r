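#' One-at-a-time parameter scan
#'
#' Exploratory local sensitivity analysis: one parameter is multiplied by
#' `{0.25, 0.75, 1, 1.25, 1.75}` (i.e. varied by +/-25% and +/-75% around
#' baseline) while all others stay at their baseline values; for each
#' multiplier the model is simulated over its standard window and the
#' cumulative total fission and oscillation class recorded. Works on either
#' the dimensional or the dimensionless system, selected by the class of
#' `params`. A failed simulation or classification is recorded for that
#' multiplier and the scan continues.
#'
#' @param params baseline [fission_params()] or [dimensionless_params()].
#' @param parameter name of the parameter to vary (a numeric scalar field
#'   of `params`, e.g. `"k_plus"` or `"mu"`).
#' @param multipliers multipliers applied to the baseline value; the
#'   baseline 1.0 is always included.
#' @param t_end window end; defaults to 5000 s (dimensional) or 500
#'   (dimensionless).
#' @param keep_trajectories keep the simulated trajectories on the result.
#' @param ... passed to [simulate_fission()].
#' @return An `oat_result`: data frame-like list with per-multiplier
#'   `value`, `cumulative_tf` and `oscillation`, plus metadata.
#' @export
oat_scan <- function(params, parameter,
                     multipliers = c(0.25, 0.75, 1, 1.25, 1.75),
                     t_end = NULL, keep_trajectories = FALSE, ...) {
  varied <- setdiff(names(params), c("ell", "N_max"))
  if (!parameter %in% varied)
    stop("'parameter' must be one of: ", paste(varied, collapse = ", "),
         call. = FALSE)
  multipliers <- sort(unique(c(multipliers, 1)))
  if (is.null(t_end)) t_end <- default_t_end(params)
  base_value <- params[[parameter]]
  trajs <- vector("list", length(multipliers))
  rows <- lapply(seq_along(multipliers), function(k) {
    m <- multipliers[k]
    p <- params; p[[parameter]] <- base_value * m
    out <- tryCatch({
      traj <- simulate_fission(p, t_end = t_end, ...)
      if (keep_trajectories) trajs[[k]] <<- traj
      cls <- tryCatch(classify_oscillation(traj),
                      error = function(e) NA_character_)
      data.frame(multiplier = m, value = base_value * m,
                 cumulative_tf = as.numeric(cumulative_tf(traj, method = "ode")),
                 oscillation = cls, error = NA_character_)
    }, error = function(e) {
      data.frame(multiplier = m, value = base_value * m,
                 cumulative_tf = NA_real_, oscillation = NA_character_,
                 error = conditionMessage(e))
    })
    out
  })
  structure(list(table = do.call(rbind, rows), parameter = parameter,
                 base_value = base_value, t_end = t_end,
                 system = if (inherits(params, "fission_params_nd"))
                   "dimensionless" else "dimensional",
                 trajectories = if (keep_trajectories) trajs),
            class = "oat_result")
}

#' @export
print.oat_result <- function(x, ...) {
  cat(sprintf("<oat_result> %s '%s' (baseline %g), window [0, %g]\n",
              x$system, x$parameter, x$base_value, x$t_end))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Global sensitivity analysis case definitions
#'
#' The three variance-based GSA configurations analysed for this model, with
#' the model output being the cumulative total fission over the case's
#' window:
#' \describe{
#'   \item{case1}{dimensional system; `k1`, `k_m1`, `k_plus` uniform on
#'     (0, 10) and `k_minus` uniform on (0, 1) (the output's active range);
#'     remaining parameters at canonical values; window `[0, 5000]` s.}
#'   \item{case2}{case1 plus `M_total` uniform on (0, 30).}
#'   \item{dimensionless}{`mu`, `alpha`, `beta`, `zeta` each uniform on
#'     (0, 2 x canonical), i.e. (0,1500), (0,100), (0,300), (0,0.4);
#'     window `[0, 500]`.}
#' }
#'
#' @param id one of `"case1"`, `"case2"`, `"dimensionless"`.
#' @return A `gsa_case`: list with `id`, `bounds`, `base` parameters,
#'   `t_end` and `system`.
#' @export
gsa_case <- function(id = c("case1", "case2", "dimensionless")) {
  id <- match.arg(id)
  def <- switch(id,
    case1 = list(
      bounds = list(k1 = c(0, 10), k_m1 = c(0, 10), k_plus = c(0, 10),
                    k_minus = c(0, 1)),
      base = fission_params(), t_end = 5000, system = "dimensional"),
    case2 = list(
      bounds = list(k1 = c(0, 10), k_m1 = c(0, 10), k_plus = c(0, 10),
                    k_minus = c(0, 1), M_total = c(0, 30)),
      base = fission_params(), t_end = 5000, system = "dimensional"),
    dimensionless = list(
      bounds = list(mu = c(0, 1500), alpha = c(0, 100), beta = c(0, 300),
                    zeta = c(0, 0.4)),
      base = dimensionless_params(), t_end = 500, system = "dimensionless"))
  structure(c(list(id = id), def), class = "gsa_case")
}

# cumulative TF from the terminal value of the integrated auxiliary state;
# minimal output grid, used on GSA sample rows
cumtf_terminal <- function(params, t_end, rtol, atol) {
  r <- core_rates(params)
  yini <- c(unname(initial_state(params)), 0)
  sol <- deSolve::ode(y = yini, times = c(0, t_end), func = "fission_derivs",
                      parms = unname(r), dllname = "mitofission",
                      initfunc = "fission_init", jactype = "fullint",
                      rtol = rtol, atol = atol, maxsteps = 500000)
  if (attr(sol, "istate")[1] < 0)
    stop("solver failure (istate ", attr(sol, "istate")[1], ")",
         call. = FALSE)
  sol[nrow(sol), length(yini) + 1]
}

#' Evaluate the GSA model output on a sample design
#'
#' Computes the cumulative total fission for every parameter tuple of a
#' Saltelli design under the given case. Rows whose integration fails are
#' retried with tighter tolerances; a row that still fails is imputed with
#' the median of the successful outputs and counted (silently dropping or
#' zeroing rows would bias the variance decomposition); more than
#' `max_fail_frac` failures is an error.
#'
#' @param case a [gsa_case()].
#' @param design a [saltelli_sample()] design whose columns match the
#'   case's parameters.
#' @param rtol,atol solver tolerances for the per-row integrations.
#' @param max_fail_frac hard-error threshold on the failed-row fraction.
#' @return Numeric vector `Y` with one cumulative-TF value per design row;
#'   failed row indices in attribute `"failed"`.
#' @export
evaluate_outputs <- function(case, design, rtol = 1e-8, atol = 1e-10,
                             max_fail_frac = 0.01) {
  stopifnot(inherits(case, "gsa_case"), inherits(design, "saltelli_design"))
  if (!identical(design$names, names(case$bounds)))
    stop("design columns do not match the case's parameters", call. = FALSE)
  S <- design$samples
  base <- case$base
  Y <- rep(NA_real_, nrow(S))
  for (r in seq_len(nrow(S))) {
    p <- base
    for (nm in design$names) p[[nm]] <- S[r, nm]
    Y[r] <- tryCatch(
      cumtf_terminal(p, case$t_end, rtol, atol),
      error = function(e) tryCatch(
        cumtf_terminal(p, case$t_end, rtol / 100, atol / 100),
        error = function(e2) NA_real_))
  }
  failed <- which(is.na(Y))
  if (length(failed) > max_fail_frac * length(Y))
    stop(sprintf("%d of %d integrations failed (> %g%%)", length(failed),
                 length(Y), 100 * max_fail_frac), call. = FALSE)
  if (length(failed)) Y[failed] <- stats::median(Y, na.rm = TRUE)
  attr(Y, "failed") <- failed
  Y
}

#' Run a complete GSA case
#'
#' End to end: Saltelli sampling, per-row model integration, Sobol index
#' estimation with bootstrap confidence intervals.
#'
#' @param id case id, see [gsa_case()].
#' @param base_N base sample size (power of two); the reference analyses
#'   use 2048, giving 20480 (D=4) or 24576 (D=5) model evaluations.
#' @param seed integer seed driving the design randomization and the
#'   bootstrap.
#' @param n_boot bootstrap resamples.
#' @param ... passed to [evaluate_outputs()].
#' @return A `sobol_result` (see [sobol_indices()]) with the case, design
#'   and raw outputs `Y` attached.
#' @export
run_gsa_case <- function(id, base_N = 2048, seed = 1, n_boot = 1000, ...) {
  case <- gsa_case(id)
  design <- saltelli_sample(case$bounds, base_N = base_N, seed = seed)
  Y <- evaluate_outputs(case, design, ...)
  res <- sobol_indices(as.numeric(Y), design, n_boot = n_boot, seed = seed)
  res$case <- case
  res$design <- design
  res$Y <- as.numeric(Y)
  res$n_failed <- length(attr(Y, "failed"))
  res
}
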