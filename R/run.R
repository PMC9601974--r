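# Experiment registry: which generator each config name maps to and
# whether it draws random numbers (making a seed mandatory).
.experiments <- list(
  coin = list(fn = "coin_experiment", stochastic = TRUE),
  student = list(fn = "student_experiment", stochastic = FALSE),
  dating = list(fn = "dating_experiment", stochastic = FALSE),
  camp = list(fn = "camp_experiment", stochastic = FALSE),
  replication = list(fn = "replication_experiment", stochastic = FALSE),
  confounding = list(fn = "confounding_experiment", stochastic = FALSE),
  contraction = list(fn = "contraction_diagnostics", stochastic = TRUE)
)

config_error <- function(msg) {
  stop(structure(class = c("config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Validate a run configuration
#'
#' A configuration is a list (or path to a JSON file) with fields
#' `experiment` (a registered name), `params` (argument block for the
#' generator), and `seed` (mandatory for stochastic experiments).
#' Optional fields: `out`, `eps_grid`, `log_base`, `verbosity`.  Unknown
#' fields are rejected.
#'
#' @param config List or path to a JSON config file.
#' @return The validated config list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config)) config_error("config must be a list or JSON file")
  allowed <- c("experiment", "params", "seed", "out", "eps_grid",
               "log_base", "verbosity")
  extra <- setdiff(names(config), allowed)
  if (length(extra))
    config_error(paste("unknown config keys:", paste(extra, collapse = ", ")))
  if (is.null(config$experiment) ||
      !(config$experiment %in% names(.experiments)))
    config_error(paste("experiment must be one of:",
                       paste(names(.experiments), collapse = ", ")))
  if (isTRUE(.experiments[[config$experiment]]$stochastic) &&
      is.null(config$seed))
    config_error(paste0("seed is mandatory for the '", config$experiment,
                        "' experiment"))
  if (!is.null(config$log_base) && !(config$log_base %in% c("e", "2")))
    config_error("log_base must be 'e' or '2'")
  config$params <- as.list(config$params %||% list())
  config
}

run_generator <- function(config) {
  entry <- .experiments[[config$experiment]]
  args <- config$params
  if (config$experiment == "confounding") {
    ca <- args[intersect(names(args), c("beta", "x0", "cov_probs"))]
    rest <- args[setdiff(names(args), names(ca))]
    args <- c(list(model = do.call(causal_model, ca)), rest)
  }
  if (!is.null(config$seed) && isTRUE(entry$stochastic))
    args$seed <- config$seed
  do.call(get(entry$fn, envir = asNamespace("ainlearn")), args)
}

headline <- function(result) {
  if (inherits(result, "trajectory_record")) {
    n <- length(result$k)
    v <- assess_weak(result, n = result$k[n])
    list(Pk_A = result$P_A[n], Ik_plus = result$I_plus[n],
         weak_learning = v$evidence$weak_learning,
         weak_knowledge = v$outcome)
  } else if (inherits(result, "replication_result")) {
    list(Pk_A = result$P_A, Ik_plus = result$I_plus,
         weak_learning = result$weak_learning)
  } else if (inherits(result, "confounding_experiment")) {
    n <- nrow(result$table)
    list(Pk_A = result$table$P_A[n], P0_A = result$P0_A,
         log_risk_ratio = result$log_risk_ratio)
  } else if (inherits(result, "contraction_diagnostics")) {
    list(var_ratio = result$var_ratio, exponent = result$exponent)
  } else list()
}

#' Run an experiment from a configuration
#'
#' Executes the configured generator and, when an output directory is
#' given, writes a trajectory CSV, a verdict/headline JSON, and a run
#' manifest (config echo, seed, package version).
#'
#' @param config List or path to a JSON config file (see
#'   [validate_config()]).
#' @param out Output directory (overrides `config$out`; `NULL` writes
#'   nothing).
#' @return Invisibly, a list with the generator `result`, the `headline`
#'   summary, and the paths written.
#' @export
run_experiment <- function(config, out = NULL) {
  config <- validate_config(config)
  out <- out %||% config$out
  result <- run_generator(config)
  head <- headline(result)
  paths <- character()
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    if (inherits(result, "trajectory_record")) {
      p <- file.path(out, "trajectory.csv")
      utils::write.csv(as.data.frame(result), p, row.names = FALSE)
      paths <- c(paths, p)
    } else if (inherits(result, "confounding_experiment")) {
      p <- file.path(out, "trajectory.csv")
      utils::write.csv(result$table, p, row.names = FALSE)
      paths <- c(paths, p)
    }
    vp <- file.path(out, "verdicts.json")
    jsonlite::write_json(head, vp, auto_unbox = TRUE, digits = NA)
    mp <- file.path(out, "manifest.json")
    jsonlite::write_json(list(config = config,
                              seed = config$seed,
                              package = "ainlearn",
                              version = as.character(
                                utils::packageVersion("ainlearn"))),
                         mp, auto_unbox = TRUE, digits = NA, null = "null")
    paths <- c(paths, vp, mp)
  }
  invisible(list(result = result, headline = head, paths = paths))
}

#' Sweep one parameter of an experiment
#'
#' Re-runs an experiment over a grid of values for one parameter and
#' collects the headline outputs into a table.
#'
#' @param config Base configuration (list or JSON path).
#' @param parameter Name of the entry in `config$params` to vary.
#' @param grid Vector of values.
#' @param out Optional path of a CSV file to write.
#' @return Data frame with one row per grid value.
#' @export
sweep_experiment <- function(config, parameter, grid, out = NULL) {
  config <- validate_config(config)
  if (length(grid) == 0L) config_error("empty sweep grid")
  fn <- get(.experiments[[config$experiment]]$fn,
            envir = asNamespace("ainlearn"))
  known <- c(names(formals(fn)), "beta", "x0", "cov_probs")
  if (!(parameter %in% known))
    config_error(paste0("unknown sweep parameter '", parameter, "'"))
  rows <- lapply(grid, function(v) {
    cfg <- config
    cfg$params[[parameter]] <- v
    h <- run_experiment(cfg)$headline
    as.data.frame(c(stats::setNames(list(v), parameter), h))
  })
  tab <- do.call(rbind, rows)
  if (!is.null(out)) utils::write.csv(tab, out, row.names = FALSE)
  tab
}
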