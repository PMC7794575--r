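# All numeric CSV output is written at 12 significant digits so fixture
# diffs are stable across platforms.
SIGNIF_DIGITS <- 12L

format_numeric_cols <- function(df) {
  for (nm in names(df))
    if (is.numeric(df[[nm]])) df[[nm]] <- signif(df[[nm]], SIGNIF_DIGITS)
  df
}

write_csv_stable <- function(df, path) {
  write.csv(format_numeric_cols(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write tracer observation tables
#'
#' CSV with header `treatment,time_h,pool,conc_mean,conc_sd,ape_mean,ape_sd`.
#' Validation errors name the offending rows: duplicate
#' (treatment, time, pool) keys, unknown treatment or pool labels, negative
#' concentrations or sds. Missing sds are permitted (the misfit floors
#' replace them). Writing then reading a table returns it unchanged at the
#' declared 12-significant-digit precision.
#'
#' @param path File path.
#' @return `read_observations()`: a validated observation data frame.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("observation file not found: ", path)
  obs <- read.csv(path, stringsAsFactors = FALSE)
  validate_observations(obs)
}

#' @rdname read_observations
#' @param observations Observation data frame.
#' @export
write_observations <- function(observations, path) {
  write_csv_stable(validate_observations(observations), path)
}

#' @rdname read_observations
#' @export
read_runoff_events <- function(path) {
  if (!file.exists(path)) stop("event file not found: ", path)
  runoff_events(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_observations
#' @param trajectory An `n15_trajectory`.
#' @export
write_trajectory <- function(trajectory, path) {
  write_csv_stable(as.data.frame(trajectory), path)
}

#' Read a model-structure configuration (YAML)
#'
#' The config maps each process id to `{active, kinetics, bounds}` and may
#' carry a `design` block overriding the incubation constants. Example:
#'
#' ```yaml
#' processes:
#'   O_NH4:   {active: true, kinetics: first, bounds: {k: [0, 10]}}
#'   O_Nrec:  {active: false}
#' n_lab0:    {bounds: [0, 200]}
#' design:
#'   amendment_nh4: 20
#'   enrichment_nh4: 9.44
#' ```
#'
#' Unlisted processes keep the package default structure and bounds.
#'
#' @param path YAML file path.
#' @return List with `model` (structure data frame), `params` (parameter
#'   table) and `design_overrides` (named list, possibly empty).
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  model <- default_model_structure()
  for (pid in names(cfg$processes)) {
    entry <- cfg$processes[[pid]]
    if (!pid %in% model$process_id) stop("unknown process in config: ", pid)
    if (!is.null(entry$active)) model <- set_active(model, pid, entry$active)
    if (!is.null(entry$kinetics)) model <- set_kinetics(model, pid,
                                                        entry$kinetics)
  }
  params <- default_parameters(model)
  for (pid in names(cfg$processes)) {
    bounds <- cfg$processes[[pid]]$bounds
    for (role in names(bounds)) {
      nm <- paste0(pid, ".", role)
      i <- match(nm, params$name)
      if (is.na(i)) stop("config bounds for absent parameter: ", nm)
      b <- as.numeric(unlist(bounds[[role]]))
      params$lower[i] <- b[1]
      params$upper[i] <- b[2]
      params$value[i] <- min(max(params$value[i], params$lower[i]),
                             params$upper[i])
    }
  }
  if (!is.null(cfg$n_lab0$bounds)) {
    i <- match("n_lab0", params$name)
    b <- as.numeric(unlist(cfg$n_lab0$bounds))
    params$lower[i] <- b[1]
    params$upper[i] <- b[2]
    params$value[i] <- min(max(params$value[i], params$lower[i]),
                           params$upper[i])
  }
  list(model = model, params = validate_parameters(params),
       design_overrides = if (is.null(cfg$design)) list() else cfg$design)
}

#' Write the result files of a fit
#'
#' Writes the posterior summary, gross rates, the pooled post-burn-in chain
#' archive and a run-metadata JSON (seed, schedule, acceptance rates, best
#' misfit, AIC) into a directory.
#'
#' @param fit An [fit_tracer_model()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_fit_results <- function(fit, dir) {
  stopifnot(inherits(fit, "n15_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    posterior = file.path(dir, "posterior_summary.csv"),
    rates = file.path(dir, "gross_rates.csv"),
    chain = file.path(dir, "chain.csv"),
    meta = file.path(dir, "run_info.json"))
  write_csv_stable(fit$posterior_summary, paths["posterior"])
  write_csv_stable(fit$gross_rates, paths["rates"])
  post <- do.call(rbind, lapply(fit$chains, function(x)
    x$chain[(x$burn_in + 1):x$n_iter, , drop = FALSE]))
  write_csv_stable(as.data.frame(post), paths["chain"])
  meta <- list(seed = fit$seed, n_chains = fit$n_chains, n_iter = fit$n_iter,
               acceptance_rates = round(fit$acceptance_rates, 4),
               best_misfit = fit$best_misfit, aic = fit$aic,
               n_obs = fit$n_obs, n_params = fit$n_params)
  jsonlite::write_json(meta, paths["meta"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
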