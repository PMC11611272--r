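#' Default run configuration
#'
#' Nested list with the four configuration sections and canonical defaults:
#' `model` (the dimensional parameters), `dimensionless` (derived from
#' `model` when omitted), `solver` (`rtol`, `atol`, `t_end`, `n_out`) and
#' `sensitivity` (`base_N`, `seed`, `n_boot`, `case`). A config resolved
#' from an empty file therefore reproduces the canonical runs
#' (`mu` resolves to 750).
#'
#' @return A `run_config` list.
#' @export
default_config <- function() {
  p <- fission_params()
  structure(list(
    model = p[setdiff(names(p), character(0))],
    dimensionless = NULL,
    solver = list(rtol = 1e-8, atol = 1e-10, t_end = NA, n_out = 2000),
    sensitivity = list(base_N = 2048, seed = 1, n_boot = 1000,
                       case = "case1"),
    outdir = "."
  ), class = "run_config")
}

#' Load and validate a run configuration
#'
#' Reads a YAML key-value file with any subset of the sections of
#' [default_config()]; missing sections and keys are filled from the
#' defaults, unknown keys produce a warning, and invalid values (e.g. a
#' non-positive rate) produce an error listing every violation. An empty
#' file yields the canonical configuration.
#'
#' @param path path to a YAML configuration file.
#' @return A validated `run_config` list with `$params`
#'   (a [fission_params()]) and `$params_nd` (a [dimensionless_params()])
#'   resolved.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- default_config()
  for (section in names(user)) {
    if (!section %in% names(cfg)) {
      warning("unknown config section '", section, "' ignored", call. = FALSE)
      next
    }
    if (section == "outdir") { cfg$outdir <- user$outdir; next }
    known <- if (section == "dimensionless")
      names(formals(dimensionless_params)) else names(cfg[[section]])
    if (section == "dimensionless" && is.null(cfg$dimensionless))
      cfg$dimensionless <- list()
    for (key in names(user[[section]])) {
      if (!key %in% known) {
        warning(sprintf("unknown key '%s.%s' ignored", section, key),
                call. = FALSE)
        next
      }
      cfg[[section]][[key]] <- user[[section]][[key]]
    }
  }
  cfg$params <- do.call(fission_params, cfg$model)
  cfg$params_nd <- if (is.null(cfg$dimensionless))
    nondimensionalize(cfg$params)
  else
    do.call(dimensionless_params, cfg$dimensionless)
  cfg
}

#' Save a run configuration
#'
#' Writes the configuration sections back to YAML; [load_config()] of the
#' written file restores the same resolved configuration.
#'
#' @param config a `run_config` list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  keep <- c("model", "dimensionless", "solver", "sensitivity", "outdir")
  out <- config[intersect(keep, names(config))]
  out <- Filter(Negate(is.null), out)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Export a trajectory as CSV
#'
#' One row per time point with columns `time,T,M,C1..CN,TFR`
#' (dimensional) or `eta,z,y,x1..xN,TFR` (dimensionless).
#'
#' @param traj a `fission_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "fission_trajectory"))
  df <- data.frame(traj$times, traj$states, traj$tfr, check.names = FALSE)
  names(df) <- c(if (traj$system == "dimensional") "time" else "eta",
                 colnames(traj$states), "TFR")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write GSA results (CSVs + provenance JSON)
#'
#' Writes `<prefix>_indices.csv` (`parameter,S1,S1_lo,S1_hi,ST,ST_lo,ST_hi`),
#' `<prefix>_pairs.csv` for the second-order indices,
#' `<prefix>_samples.csv` (the evaluated tuples and their cumulative TF,
#' the data behind the scatter diagnostics) and `<prefix>_run.json` with
#' full provenance (case, bounds, base_N, seed, bootstrap settings, failure
#' count, package version) sufficient to reproduce the run bit for bit.
#'
#' @param result a `sobol_result` from [run_gsa_case()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix, default the case id.
#' @return Character vector of the written paths, invisibly.
#' @export
write_sobol_results <- function(result, dir, prefix = NULL) {
  stopifnot(inherits(result, "sobol_result"))
  if (is.null(prefix)) prefix <- if (!is.null(result$case))
    result$case$id else "sobol"
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(dir, paste0(prefix, "_indices.csv"))
  f2 <- file.path(dir, paste0(prefix, "_pairs.csv"))
  f4 <- file.path(dir, paste0(prefix, "_run.json"))
  utils::write.csv(result$first_order, f1, row.names = FALSE, quote = FALSE)
  utils::write.csv(result$second_order, f2, row.names = FALSE, quote = FALSE)
  paths <- c(f1, f2)
  if (!is.null(result$design) && !is.null(result$Y)) {
    f3 <- file.path(dir, paste0(prefix, "_samples.csv"))
    sc <- data.frame(result$design$samples, cumulative_tf = result$Y,
                     check.names = FALSE)
    utils::write.csv(sc, f3, row.names = FALSE, quote = FALSE)
    paths <- c(paths, f3)
  }
  prov <- list(
    case = if (!is.null(result$case)) result$case$id,
    bounds = if (!is.null(result$case)) result$case$bounds,
    base_N = result$base_N, n_samples = result$n_samples,
    n_boot = result$n_boot, conf = result$conf, seed = result$seed,
    n_failed = result$n_failed,
    package = as.character(utils::packageVersion("mitofission")))
  jsonlite::write_json(prov, f4, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(paths, f4))
}
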