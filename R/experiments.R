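#' Wilson score confidence interval for a binomial proportion
#'
#' @param successes number(s) of successes, `0 <= successes <= n`.
#' @param n number of trials (positive).
#' @param confidence confidence level (default 0.95).
#' @return A list with vectors `estimate`, `lower`, `upper` and the scalar
#'   `confidence`. Bounds are guaranteed inside `[0, 1]`, contain the point
#'   estimate, and the lower bound is exactly 0 at zero successes (the upper
#'   exactly 1 at `successes = n`).
#' @export
wilson_interval <- function(successes, n, confidence = 0.95) {
  stopifnot(n >= 1, all(successes >= 0), all(successes <= n),
            confidence > 0, confidence < 1)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # pin the boundary cases exactly (rounding can leave a ~1e-17 residue)
  lower <- ifelse(successes == 0, 0, pmax(0, centre - half))
  upper <- ifelse(successes == n, 1, pmin(1, centre + half))
  list(estimate = p, lower = lower, upper = upper, confidence = confidence)
}

#' Validate an experiment configuration
#'
#' @param config a named list; see [run_experiment()] for recognised keys.
#' @return The config, with defaults filled in; errors list every offending
#'   field.
#' @export
validate_config <- function(config) {
  defaults <- list(algorithm = "online", T = 1.5, S = -0.2, alpha = 0.1,
                   epsilon = 0.01, delta = 0.98, K = 4096, horizon = 2e6,
                   n_samples = 100, n_inits = 250, seed = 1,
                   record_every = 1000, threshold = 0.4,
                   alpha_grid = NULL, epsilon_grid = NULL, K_grid = NULL,
                   delta_grid = NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  config <- utils::modifyList(defaults, config)
  problems <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(config$algorithm %in% c("online", "batch", "deterministic", "mbrn", "sweep"),
      "algorithm must be one of online/batch/deterministic/mbrn/sweep")
  chk(config$T > 1, "T must exceed 1")
  chk(config$S < 0, "S must be negative")
  chk(config$alpha >= 0 && config$alpha <= 1, "alpha must lie in [0, 1]")
  chk(config$epsilon >= 0 && config$epsilon < 1, "epsilon must lie in [0, 1)")
  chk(config$delta >= 0 && config$delta < 1, "delta must lie in [0, 1)")
  chk(config$K >= 1, "K must be a positive integer")
  chk(config$horizon >= 1, "horizon must be positive")
  chk(config$n_samples >= 1, "n_samples must be positive")
  chk(config$n_inits >= 1, "n_inits must be positive")
  chk(is.numeric(config$seed) && length(config$seed) == 1,
      "seed is mandatory for stochastic runs")
  if (length(problems)) stop("invalid config: ", paste(problems, collapse = "; "))
  config
}

#' Run a configured experiment and export its data
#'
#' Dispatches a declarative configuration to the matching driver and writes
#' its outputs: a CSV data table, a JSON metadata file recording every
#' parameter and seed, and a plain-text log. Identical configurations produce
#' identical outputs.
#'
#' Recognised `algorithm` values: `"online"` and `"batch"` (time series of
#' equilibrium fractions and cooperation), `"deterministic"` (learnability
#' grid over `alpha_grid` x `epsilon_grid`), `"mbrn"` (analytic stability
#' phase map over `epsilon_grid` x `delta_grid`), `"sweep"` (batch-learning
#' robustness sweep).
#'
#' @param config named list of configuration keys (see [validate_config()]).
#' @param out_dir output directory (created if absent).
#' @param name base name for the output files.
#' @return Invisibly, the result data frame; side effect: writes
#'   `<name>.csv`, `<name>.json` and `<name>.log` under `out_dir`.
#' @export
run_experiment <- function(config, out_dir = ".", name = config$algorithm) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  game <- ipd_game(config$T, config$S)
  params <- learner_params(config$alpha, config$epsilon, config$delta)
  data <- switch(config$algorithm,
    online = run_online(game, params, horizon = config$horizon,
                        n_samples = config$n_samples,
                        record_every = config$record_every,
                        seed = config$seed)$series,
    batch = run_batch(game, params, K = config$K, horizon = config$horizon,
                      n_samples = config$n_samples, seed = config$seed)$series,
    deterministic = learnability_grid(
      game,
      alpha_grid = config$alpha_grid %||% seq(0.01, 0.1, by = 0.01),
      epsilon_grid = config$epsilon_grid %||% seq(0.01, 0.1, by = 0.01),
      delta = config$delta, n_inits = config$n_inits, seed = config$seed),
    mbrn = phase_map(game,
                     epsilon_grid = config$epsilon_grid %||% seq(0, 0.5, by = 0.01),
                     delta_grid = config$delta_grid %||% seq(0, 0.99, by = 0.02)),
    sweep = robustness_sweep(game,
                             K_grid = config$K_grid %||% c(1000, 4096),
                             alpha_grid = config$alpha_grid %||% c(0.1, 0.3),
                             epsilon_grid = config$epsilon_grid %||% c(0.1),
                             delta = config$delta, horizon = config$horizon,
                             n_samples = config$n_samples,
                             threshold = config$threshold, seed = config$seed))
  csv <- file.path(out_dir, paste0(name, ".csv"))
  meta <- file.path(out_dir, paste0(name, ".json"))
  log <- file.path(out_dir, paste0(name, ".log"))
  utils::write.csv(data, csv, row.names = FALSE)
  jsonlite::write_json(
    list(config = config[!vapply(config, is.null, logical(1))],
         package_version = as.character(utils::packageVersion("ipdlearn")),
         columns = paste("fractions are proportions in [0,1];",
                         "time columns are environment steps")),
    meta, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(sprintf("[%s] algorithm=%s rows=%d -> %s",
                     format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                     config$algorithm, nrow(data), csv), log)
  invisible(data)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
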