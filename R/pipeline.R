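#' Run a reproducible analysis pipeline
#'
#' Orchestrates end-to-end runs on synthetic data: network simulation
#' followed by a mixture fit of its response histogram, behavioral generation
#' and estimation, circular-linear correlation mapping, or decoding. Every
#' stochastic stage receives a child seed derived deterministically from the
#' global seed and the stage name; the summary records the seeds and an MD5
#' hash of the configuration, and rerunning the same configuration and seed
#' produces byte-identical output files.
#'
#' @param config a named list, or a path to a JSON (or YAML, if the
#'   \pkg{yaml} package is installed) file. Required fields: `pipeline` (one
#'   of `"simulate"`, `"find_critical"`, `"behavior"`, `"correlate"`,
#'   `"decode"`, `"demo"`) and `seed`. Stage-specific fields are documented
#'   in the corresponding stage functions and all have defaults.
#' @param out_dir optional output directory; when given, writes
#'   `summary.json`, the configuration as `config.json`, and any stage tables
#'   as CSV.
#' @return the summary list, invisibly when `out_dir` is given.
#' @export
#' @examples
#' run_pipeline(list(pipeline = "behavior", seed = 1, n_trials = 200))$values
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_config(config)
  }
  if (!is.list(config)) stop("config must be a list or a file path")
  for (field in c("pipeline", "seed")) {
    if (is.null(config[[field]])) {
      stop("config validation: missing required field '", field, "'")
    }
  }
  pipelines <- c("simulate", "find_critical", "behavior", "correlate",
                 "decode", "demo")
  if (!config$pipeline %in% pipelines) {
    stop("config validation: unknown pipeline '", config$pipeline, "'")
  }
  seed <- as.integer(config$seed)
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(fileext = ".json")
  writeLines(cfg_json, tf)
  cfg_hash <- unname(tools::md5sum(tf))
  unlink(tf)

  get <- function(nm, default) if (is.null(config[[nm]])) default else config[[nm]]
  values <- list()
  tables <- list()
  stage_seeds <- list()
  stage <- function(nm) {
    s <- derive_seed(seed, nm)
    stage_seeds[[nm]] <<- s
    s
  }

  if (config$pipeline %in% c("simulate", "demo")) {
    n <- get("n_trials", if (config$pipeline == "demo") 40L else 400L)
    sch <- build_schedule(A_mask = get("A_mask", 62))
    exp <- run_experiment(n, params = cann_params(), schedule = sch,
                          noise_mode = get("noise_mode", "continuous"),
                          seed = stage("simulate"))
    values$regime_fraction <- exp$regime_fraction
    h <- response_histogram(x = exp$trials$offset)
    fit <- wm_mixture(h)
    values$sim_guess_rate <- fit$p_hat
    values$sim_rate_correct <- fit$rate_correct
    tables$sim_trials <- exp$trials
  }
  if (config$pipeline %in% c("find_critical", "demo")) {
    short <- get("delay", if (config$pipeline == "demo") 1.0 else 3.0)
    cr <- find_critical_mask(cann_params(),
                             build_schedule(delay = short),
                             lo_hz = get("lo_hz", 50), hi_hz = get("hi_hz", 65),
                             tol_hz = get("tol_hz", 1))
    values$A_critical <- cr$A_critical
  }
  if (config$pipeline %in% c("behavior", "demo")) {
    n <- get("n_trials", if (config$pipeline == "demo") 500L else 2000L)
    tr <- gen_behavior(n, p_guess = get("p_guess", 0.5),
                       sd_positions = get("sd_positions", 1),
                       seed = stage("behavior"))
    fit <- wm_mixture(tr)
    values$guess_rate <- fit$p_hat
    values$precision_sd <- fit$precision_sd
    values$rate_correct <- fit$rate_correct
    values$chance_rate_correct <- 0.25
    tables$behavior_trials <- tr
  }
  if (config$pipeline %in% c("correlate", "demo")) {
    ep <- gen_epochs(n_trials = get("n_trials", 120L),
                     times = seq(-0.2, 1.0, by = 0.01),
                     angle_windows = list(c(0.1, 0.6)),
                     seed = stage("correlate_data"))
    cm <- circ_map(ep, n_perm = get("n_perm", 100L),
                   seed = stage("correlate_null"))
    wa <- window_average(cm, windows = list(early = c(0.1, 0.3),
                                            p3b = c(0.3, 0.6)))
    values$delta_rho_early <- unname(attr(wa, "grand")["early"])
    values$delta_rho_p3b <- unname(attr(wa, "grand")["p3b"])
  }
  if (config$pipeline %in% c("decode", "demo")) {
    ep <- gen_epochs(n_trials = get("n_trials", 150L),
                     times = seq(-0.2, 0.8, by = 0.02),
                     seed = stage("decode_data"))
    tg <- temporal_generalization(ep, metric = "auc",
                                  seed = stage("decode_folds"),
                                  diag_only = TRUE)
    values$mean_auc <- mean(tg$diagonal)
    values$chance_auc <- 0.5
  }

  summary <- list(pipeline = config$pipeline, seed = seed,
                  config_hash = cfg_hash, stage_seeds = stage_seeds,
                  values = values)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(cfg_json, file.path(out_dir, "config.json"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (nm in names(tables)) {
      utils::write.csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    return(invisible(summary))
  }
  summary
}

# Read a pipeline configuration from JSON or YAML.
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Write an epoch set to a directory of plain files
#'
#' Stores the data array as an RDS file plus the time axis and labels as CSV
#' and a JSON manifest, so epoch sets can be passed between sessions.
#' [read_epochs()] restores the object.
#'
#' @param epochs an [epoch_set()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_epochs <- function(epochs, dir) {
  stopifnot(inherits(epochs, "epoch_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(epochs$data, file.path(dir, "data.rds"))
  labs <- data.frame(trial = seq_len(dim(epochs$data)[1]))
  if (!is.null(epochs$angles)) labs$angle <- epochs$angles
  if (!is.null(epochs$categories)) labs$category <- as.character(epochs$categories)
  utils::write.csv(labs, file.path(dir, "labels.csv"), row.names = FALSE)
  utils::write.csv(data.frame(time = epochs$times),
                   file.path(dir, "times.csv"), row.names = FALSE)
  jsonlite::write_json(list(dim = dim(epochs$data),
                            baseline_window = epochs$baseline_window),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read an epoch set written by [write_epochs()]
#'
#' @param dir directory produced by [write_epochs()].
#' @return an [epoch_set()].
#' @export
read_epochs <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  data <- readRDS(file.path(dir, "data.rds"))
  labs <- utils::read.csv(file.path(dir, "labels.csv"))
  times <- utils::read.csv(file.path(dir, "times.csv"))$time
  epoch_set(data, times,
            angles = labs$angle,
            categories = if ("category" %in% names(labs)) labs$category else NULL,
            baseline_window = man$baseline_window)
}
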