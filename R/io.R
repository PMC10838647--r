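#' Read observed GC profiles from CSV
#'
#' Reads a delimited text file of plasma GC measurements with required
#' columns `individual_id`, `class`, `time_min`, `gc_value` and optional
#' `gr_expression` / `group`. Class labels are matched case-insensitively
#' against the canonical set (`baseline`, `stress_induced`, `post_dex`,
#' `post_acth`, `recovery`). Validation errors name the offending rows.
#'
#' @param path file path.
#' @return An [observed_dataset()].
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  observed_dataset(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write observed GC profiles to CSV
#'
#' The written file round-trips through [read_observations()] exactly
#' (values formatted at full double precision).
#'
#' @param data an [observed_dataset()] (or coercible data frame).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(data, path) {
  data <- if (inherits(data, "hpa_obs")) data else observed_dataset(data)
  df <- as.data.frame(data)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a trajectory as tidy CSV
#'
#' Columns: `time_min` followed by the nine state components.
#'
#' @param traj an `hpa_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  names(df)[names(df) == "time"] <- "time_min"
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialise parameters or a fit result to JSON
#'
#' @param x an [hpa_params()] or `hpa_fit` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(x, path) {
  obj <- if (inherits(x, "hpa_fit")) {
    list(estimates = unclass(x$params), free = x$mask$free,
         logLik = x$logLik, sigma = x$sigma,
         convergence = x$convergence, n_obs = x$n_obs,
         counts = as.list(x$counts))
  } else if (inherits(x, "hpa_params")) {
    unclass(x)
  } else stop("cannot serialise object of class ", class(x)[1])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a run configuration (YAML or JSON)
#'
#' A run configuration may carry any of: `params` (named parameter
#' overrides to [hpa_params()]), `events` (list with `time`, `target`,
#' `amount`), `scheme` (named sampling times), `horizon`, `seed`, a
#' `synth` block (arguments to [population_spec()]), and grid settings
#' (`gr_grid`, `b_grid` or `n_gr`/`n_b`). Missing entries fall back to
#' package defaults.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return A named list of class `hpa_config` with resolved components
#'   `params`, `events`, `scheme`, `horizon`, `seed`, plus any raw extras.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  resolve_config(raw)
}

# raw config list -> validated components with defaults filled in
resolve_config <- function(raw) {
  if (is.null(raw)) raw <- list()
  params <- do.call(hpa_params, as.list(raw$params %||% list()))
  events <- if (!is.null(raw$events)) {
    ev <- raw$events
    injection_events(unlist(ev$time), unlist(ev$target), unlist(ev$amount))
  } else default_events()
  scheme <- if (!is.null(raw$scheme)) {
    s <- unlist(raw$scheme)
    do.call(sampling_scheme, as.list(s))
  } else sampling_scheme()
  structure(list(params = params, events = events, scheme = scheme,
                 horizon = raw$horizon %||% 180,
                 seed = as.integer(raw$seed %||% 1L),
                 raw = raw),
            class = "hpa_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line interface
#'
#' A thin command-line entry point over the package functions, usable as
#' `Rscript -e 'quit(status = hpaxis::hpa_cli())'` or via the shipped
#' launcher script `system.file("cli", "hpaxis.R", package = "hpaxis")`.
#'
#' Subcommands: `simulate`, `fit`, `sweep-gr`, `sweep-stressor`,
#' `associate`, `synth`. Common options: `--config <file>` (YAML/JSON run
#' configuration), `--out <dir>` (output directory, default `.`),
#' `--data <csv>` (observations, for `fit`), `--seed <int>` (overrides the
#' config seed). Each subcommand writes its outputs as CSV/JSON into the
#' output directory and logs a one-line summary to stderr.
#'
#' @param argv character vector of command-line arguments (default: the
#'   actual command line).
#' @return Integer exit status, invisibly: 0 success, 2 usage/config
#'   error, 1 runtime failure.
#' @export
hpa_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: hpaxis <simulate|fit|sweep-gr|sweep-stressor|associate|synth>",
    "[--config FILE] [--data FILE] [--out DIR] [--seed INT]")
  if (length(argv) < 1) {
    message(usage)
    return(invisible(2L))
  }
  cmd <- argv[1]
  opts <- parse_cli_options(argv[-1])
  if (is.null(opts)) {
    message(usage)
    return(invisible(2L))
  }
  known <- c("simulate", "fit", "sweep-gr", "sweep-stressor", "associate",
             "synth")
  if (!cmd %in% known) {
    message("unknown subcommand: ", cmd, "\n", usage)
    return(invisible(2L))
  }
  cfg <- tryCatch(
    if (!is.null(opts$config)) read_run_config(opts$config)
    else resolve_config(NULL),
    error = function(e) {
      message("config error: ", conditionMessage(e))
      NULL
    })
  if (is.null(cfg)) return(invisible(2L))
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  outdir <- opts$out %||% "."
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  status <- tryCatch({
    run_cli_command(cmd, cfg, opts, outdir)
    0L
  }, error = function(e) {
    message("error in '", cmd, "': ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_cli_options <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--") || i == length(args)) return(NULL)
    opts[[substring(a, 3)]] <- args[i + 1]
    i <- i + 2
  }
  opts
}

run_cli_command <- function(cmd, cfg, opts, outdir) {
  log1 <- function(...) message("[hpaxis ", cmd, "] ", ...)
  if (cmd == "simulate") {
    traj <- simulate_response(cfg$params, events = cfg$events,
                              horizon = cfg$horizon)
    path <- file.path(outdir, "trajectory.csv")
    write_trajectory(traj, path)
    s <- response_summary(traj)
    log1(sprintf("wrote %s (peak GC %.4g at %.4g min)", path, s$peak_O,
                 s$t_peak_O))
  } else if (cmd == "fit") {
    if (is.null(opts$data)) stop("'fit' requires --data <csv>")
    data <- read_observations(opts$data)
    start <- visual_start(data, base = cfg$params)
    free <- unlist(cfg$raw$mask$free) %||% c("G_tot", "k_O", "b_O")
    fit <- fit_hpa(data, mask = parameter_mask(free = free, start = start),
                   events = cfg$events, seed = cfg$seed,
                   n_starts = cfg$raw$fit$n_starts %||% 1)
    write_fit_json(fit, file.path(outdir, "fit.json"))
    write_observations(fit$fitted[setdiff(names(fit$fitted), "fitted_gc")],
                       file.path(outdir, "fitted_data.csv"))
    utils::write.csv(
      format(fit$fitted, digits = 15, trim = TRUE),
      file.path(outdir, "fitted_values.csv"), row.names = FALSE,
      quote = FALSE)
    log1(sprintf("wrote fit.json (logLik %.4f, converged %s)", fit$logLik,
                 fit$convergence))
  } else if (cmd == "sweep-gr") {
    sw <- sweep_gr(cfg$params, events = cfg$events, scheme = cfg$scheme,
                   horizon = cfg$horizon)
    path <- file.path(outdir, "sweep_gr.csv")
    utils::write.csv(format(as.data.frame(sw), digits = 15, trim = TRUE),
                     path, row.names = FALSE, quote = FALSE)
    log1("wrote ", path)
  } else if (cmd == "sweep-stressor") {
    sw <- sweep_stressor(cfg$params, horizon = cfg$horizon)
    path <- file.path(outdir, "sweep_stressor.csv")
    utils::write.csv(format(as.data.frame(sw), digits = 15, trim = TRUE),
                     path, row.names = FALSE, quote = FALSE)
    si <- sensitivity_index(sw)
    utils::write.csv(format(si, digits = 15, trim = TRUE),
                     file.path(outdir, "sensitivity_index.csv"),
                     row.names = FALSE, quote = FALSE)
    log1("wrote ", path, " and sensitivity_index.csv")
  } else if (cmd == "associate") {
    assoc <- association_analysis(cfg$params, seed = cfg$seed,
                                  n = cfg$raw$associate$n %||% 200,
                                  horizon = cfg$horizon)
    utils::write.csv(format(assoc$individuals, digits = 15, trim = TRUE),
                     file.path(outdir, "association_individuals.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(format(assoc$correlations, digits = 15, trim = TRUE),
                     file.path(outdir, "association_correlations.csv"),
                     row.names = FALSE, quote = FALSE)
    log1("wrote association tables (n = ", assoc$n, ")")
  } else if (cmd == "synth") {
    spec_args <- as.list(cfg$raw$synth %||% list())
    spec_args$seed <- spec_args$seed %||% cfg$seed
    spec <- do.call(population_spec, spec_args)
    pop <- generate_population(spec, base_params = cfg$params)
    write_observations(pop$observations,
                       file.path(outdir, "observations.csv"))
    utils::write.csv(format(pop$truth, digits = 15, trim = TRUE),
                     file.path(outdir, "truth.csv"), row.names = FALSE,
                     quote = FALSE)
    log1("wrote observations.csv and truth.csv (n = ", spec$n, ")")
  }
  invisible(NULL)
}
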