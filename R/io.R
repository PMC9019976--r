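#' Read a planning or scenario configuration file
#'
#' Reads a YAML (`.yaml`/`.yml`) or JSON (`.json`) configuration. A file
#' containing an `n_runs` field is interpreted as a simulation scenario and
#' returned via [scenario_config()]; otherwise it is a planning
#' configuration with fields `design`, `alpha`, `power_overall`, the five
#' accuracy parameters, optional `psi_d`/`psi_nd`, an optional `method`
#' (`"conventional"`, `"optimal"` or `"minimal"`) and optional per-endpoint
#' powers `power_se`/`power_sp` for the conventional method. Unknown keys
#' are rejected with an exhaustive list, and all probabilities are
#' range-checked by the constructors.
#'
#' @param path Path to the configuration file.
#' @return A `planning_config` or [scenario_config()] object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported configuration format '.", ext,
         "': use .yaml, .yml or .json"))
  if (is.null(raw) || !is.list(raw) || length(raw) == 0)
    stop("configuration file is empty or not a key-value mapping: ", path)
  if ("n_runs" %in% names(raw)) scenario_from_list(raw)
  else planning_from_list(raw)
}

planning_keys <- c("design", "alpha", "power_overall", "se_c", "se_e",
                   "sp_c", "sp_e", "prevalence", "psi_d", "psi_nd",
                   "method", "power_se", "power_sp")

planning_from_list <- function(raw) {
  unknown <- setdiff(names(raw), planning_keys)
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         " (allowed: ", paste(planning_keys, collapse = ", "), ")")
  required <- c("design", "se_c", "se_e", "sp_c", "sp_e", "prevalence")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0)
    stop("missing configuration keys: ", paste(missing, collapse = ", "))
  spec <- design_spec(raw$design,
                      alpha = raw$alpha %||% 0.05,
                      power_overall = raw$power_overall %||% 0.8)
  params <- accuracy_params(raw$se_c, raw$se_e, raw$sp_c, raw$sp_e,
                            raw$prevalence)
  dep <- NULL
  if (!is.null(raw$psi_d) || !is.null(raw$psi_nd)) {
    if (is.null(raw$psi_d) || is.null(raw$psi_nd))
      stop("psi_d and psi_nd must be given together")
    dep <- paired_dependence(raw$psi_d, raw$psi_nd)
  }
  method <- raw$method %||% "optimal"
  if (!method %in% c("conventional", "optimal", "minimal"))
    stop("method must be one of conventional, optimal, minimal")
  structure(list(spec = spec, params = params, dep = dep, method = method,
                 power_se = raw$power_se %||% 0.9,
                 power_sp = raw$power_sp %||% 0.9),
            class = "planning_config")
}

scenario_keys <- c("design", "se_c", "sp_c", "se_e", "sp_e", "se_e_assumed",
                   "sp_e_assumed", "pi_true", "pi_assumed", "psi_d_true",
                   "psi_nd_true", "psi_d_assumed", "psi_nd_assumed", "alpha",
                   "power_overall", "n_runs", "seed")

scenario_from_list <- function(raw) {
  unknown <- setdiff(names(raw), scenario_keys)
  if (length(unknown) > 0)
    stop("unknown scenario keys: ", paste(unknown, collapse = ", "),
         " (allowed: ", paste(scenario_keys, collapse = ", "), ")")
  do.call(scenario_config, raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the sample size calculation described by a planning configuration
#'
#' Dispatches on the configuration's `method`: `"conventional"` uses
#' [conventional_sample_size()] with the configured per-endpoint powers,
#' `"optimal"` uses [optimal_sample_size()] and `"minimal"` (paired only)
#' uses [minimal_sample_size_paired()].
#'
#' @param config A `planning_config` from [read_config()].
#' @return A `sample_size_result`.
#' @export
plan_sample_size <- function(config) {
  stopifnot(inherits(config, "planning_config"))
  switch(config$method,
    conventional = conventional_sample_size(config$spec, config$params,
                                            config$dep, config$power_se,
                                            config$power_sp),
    optimal = optimal_sample_size(config$spec, config$params, config$dep),
    minimal = minimal_sample_size_paired(config$spec, config$params))
}

#' Read a paired count table from JSON or CSV
#'
#' JSON files hold the eight cell counts as keys (`d11`, `d10`, `d01`,
#' `d00`, `nd11`, `nd10`, `nd01`, `nd00`); CSV files hold them as a
#' one-row table with those column names.
#'
#' @param path Path to the counts file.
#' @return A [paired_count_table()].
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::fromJSON(path),
    csv = as.list(utils::read.csv(path)[1, , drop = FALSE]),
    stop("unsupported counts format '.", ext, "': use .json or .csv"))
  cells <- c("d11", "d10", "d01", "d00", "nd11", "nd10", "nd01", "nd00")
  missing <- setdiff(cells, names(raw))
  if (length(missing) > 0)
    stop("counts file is missing cells: ", paste(missing, collapse = ", "))
  do.call(paired_count_table, lapply(raw[cells], as.numeric))
}

#' Write a machine-readable report
#'
#' Serializes a `sample_size_result` or `scenario_result` to JSON (full
#' structure, including inputs, method, split, unrounded and final sizes,
#' package version and, for scenarios, the seed) or to a one-row CSV of the
#' scalar fields with a stable column set.
#'
#' @param result A `sample_size_result` or `scenario_result`.
#' @param path Output path.
#' @param format `"json"` or `"csv"`.
#' @return Invisibly, the path written.
#' @export
write_report <- function(result, path, format = c("json", "csv")) {
  format <- match.arg(format)
  rep <- report_fields(result)
  if (format == "json") {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  } else {
    flat <- rep[vapply(rep, function(v)
      is.atomic(v) && length(v) == 1L, logical(1))]
    utils::write.csv(as.data.frame(flat), path, row.names = FALSE)
  }
  invisible(path)
}

report_fields <- function(result) {
  version <- as.character(utils::packageVersion("copriss"))
  if (inherits(result, "sample_size_result")) {
    list(tool = "copriss", version = version, kind = "sample_size",
         method = result$method, design = result$design,
         n_diseased = result$n_diseased,
         n_nondiseased = result$n_nondiseased,
         n_diseased_raw = result$n_diseased_raw,
         n_nondiseased_raw = result$n_nondiseased_raw,
         n_se_total = result$n_se_total, n_sp_total = result$n_sp_total,
         n_final = result$n_final,
         power_se = result$power_se, power_sp = result$power_sp,
         n_interim = result$n_interim %||% NULL,
         n_recommended = result$n_recommended %||% NULL)
  } else if (inherits(result, "scenario_result")) {
    list(tool = "copriss", version = version, kind = "scenario",
         design = result$config$design, adaptive = result$adaptive,
         seed = result$config$seed, n_runs = result$n_runs,
         rejection_rate = result$rejection_rate,
         mc_halfwidth = result$mc_halfwidth,
         n_true = result$n_true, n_mean = result$n_mean,
         n_median = result$n_median, rmse_n = result$rmse_n,
         bias_pi = unname(result$bias[["pi"]]),
         bias_psi_d = unname(result$bias[["psi_d"]]),
         bias_psi_nd = unname(result$bias[["psi_nd"]]),
         n_failures = result$n_failures)
  } else if (inherits(result, "copriss_ci")) {
    list(tool = "copriss", version = version, kind = "confidence_interval",
         method = result$method, level = result$level,
         estimate = result$estimate,
         lower = result$lower, upper = result$upper)
  } else {
    stop("write_report does not know how to serialize objects of class ",
         paste(class(result), collapse = "/"))
  }
}

#' Write the packaged example configuration fixtures
#'
#' Emits deterministic, byte-stable fixture files used by the examples and
#' the test suite: `table1_example.yaml` (the PET/CT pancreatic-cancer
#' example study planning parameters), `table3_interim_estimates.json`
#' (the blinded interim estimates of that study) and
#' `table4_initial_scenario.yaml` (the initial simulation scenario).
#'
#' @param outdir Directory to write into (created if needed).
#' @return Invisibly, the vector of paths written.
#' @export
make_fixtures <- function(outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)

  p1 <- file.path(outdir, "table1_example.yaml")
  writeLines(c(
    "# PET/CT vs CT example study: planning assumptions",
    "design: paired",
    "alpha: 0.05",
    "power_overall: 0.8",
    "se_c: 0.81",
    "se_e: 0.90",
    "sp_c: 0.66",
    "sp_e: 0.80",
    "prevalence: 0.47",
    "psi_d: 0.09",
    "psi_nd: 0.14",
    "method: optimal"), p1)
  paths <- c(paths, p1)

  p2 <- file.path(outdir, "table3_interim_estimates.json")
  writeLines(paste0(
    '{"pi_hat": 0.44, "psi_d_hat": 0.11, "psi_nd_hat": 0.14, ',
    '"n_interim": 133}'), p2)
  paths <- c(paths, p2)

  p3 <- file.path(outdir, "table4_initial_scenario.yaml")
  writeLines(c(
    "# initial operating-characteristics scenario (paired, superiority)",
    "design: paired",
    "se_c: 0.8",
    "sp_c: 0.7",
    "se_e: 0.9",
    "sp_e: 0.8",
    "pi_true: 0.2",
    "pi_assumed: 0.3",
    "psi_d_true: 0.11",
    "psi_nd_true: 0.14",
    "psi_d_assumed: 0.18",
    "psi_nd_assumed: 0.24",
    "alpha: 0.05",
    "power_overall: 0.8",
    "n_runs: 10000",
    "seed: 1"), p3)
  paths <- c(paths, p3)

  invisible(paths)
}

#' Read an interim-estimates JSON file
#'
#' @param path JSON file with `pi_hat`, `n_interim` and, for paired
#'   designs, `psi_d_hat` and `psi_nd_hat`.
#' @return An [interim_estimates()] object.
#' @export
read_interim_estimates <- function(path) {
  if (!file.exists(path)) stop("estimates file not found: ", path)
  raw <- jsonlite::fromJSON(path)
  interim_estimates(pi_hat = raw$pi_hat, n_interim = raw$n_interim,
                    psi_d_hat = raw$psi_d_hat, psi_nd_hat = raw$psi_nd_hat)
}
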