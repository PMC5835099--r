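# Configuration loading/validation, experiment dispatch, and plain-text
# writers for spike rasters and weight summaries.

default_experiment_config <- function(experiment = "conditioning") {
  base <- list(
    experiment = experiment,
    duration_ms = NULL,
    seed = 1L,
    output_dir = NULL,
    stdp = list(a_plus = 1, a_minus = 1, tau_plus = 10, tau_minus = 12),
    log_level = "info")
  extra <- switch(experiment,
    single_synapse = list(
      duration_ms = NULL,
      delays = seq(4, 3000, by = 100),
      d_c = 0.1,
      tau_c = 1000, tau_d = 200),
    reward_punishment = list(
      duration_ms = 14000,
      n_neurons = 10L, input_rate = 50,
      initial_weight = 1.5,
      reward_times = c(2000, 3000, 4000),
      punishment_times = c(8000, 9000, 10000),
      d_c_reward = 0.01, d_c_punishment = -0.002,
      stdp = list(a_plus = 60, a_minus = 60, tau_plus = 10, tau_minus = 12),
      tau_c = 100, tau_d = 5, w_min = 0, w_max = 6),
    conditioning = list(
      duration_ms = 60000,
      n_total = 200L, n_groups = 100L, connection_probability = 0.1,
      initial_weight = 1.5, inhibitory_weight = 10.0, w_max = 3.0,
      noise_weight = 0.7, noise_rate = 10, d_c = 0.002,
      tau_c = 1000, tau_d = 200,
      reward_group = 1L, snapshot_interval = 1000),
    stop(sprintf("unknown experiment '%s'", experiment)))
  utils::modifyList(base, extra)
}

merge_validated <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop(sprintf("unknown configuration key '%s'", full))
    if (is.list(defaults[[key]]) && !is.null(defaults[[key]])) {
      if (!is.list(user[[key]]))
        stop(sprintf("configuration key '%s' must be a mapping", full))
      defaults[[key]] <- merge_validated(defaults[[key]], user[[key]], full)
    } else {
      defaults[key] <- list(user[[key]]) # keeps explicit-NULL keys in place
    }
  }
  defaults
}

validate_config <- function(cfg) {
  positive <- function(nm) {
    v <- cfg[[nm]]
    if (!is.null(v) && (!is.numeric(v) || any(v <= 0)))
      stop(sprintf("configuration key '%s' must be strictly positive", nm))
  }
  for (nm in c("tau_c", "tau_d", "duration_ms", "input_rate", "noise_rate",
               "n_total", "n_neurons", "snapshot_interval"))
    positive(nm)
  for (nm in c("a_plus", "a_minus", "tau_plus", "tau_minus"))
    if (!is.null(cfg$stdp[[nm]]) && (!is.numeric(cfg$stdp[[nm]]) || cfg$stdp[[nm]] <= 0))
      stop(sprintf("configuration key 'stdp.%s' must be strictly positive", nm))
  if (!is.null(cfg$w_min) && !is.null(cfg$w_max) && cfg$w_min >= cfg$w_max)
    stop("configuration requires w_min < w_max")
  if (!is.null(cfg$connection_probability) &&
      (cfg$connection_probability <= 0 || cfg$connection_probability > 1))
    stop("configuration key 'connection_probability' must be in (0, 1]")
  invisible(cfg)
}

#' Load and validate an experiment configuration
#'
#' Reads a YAML file, merges it over the defaults of the named experiment
#' (`single_synapse`, `reward_punishment` or `conditioning`), rejects
#' unknown keys and validates values. An empty file yields the full default
#' configuration for the default experiment.
#'
#' @param path Path to a YAML configuration file.
#' @return An object of class `experiment_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("configuration file '%s' not found", path))
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  experiment <- if (!is.null(user$experiment)) user$experiment else "conditioning"
  cfg <- merge_validated(default_experiment_config(experiment), user)
  validate_config(cfg)
  structure(cfg, class = "experiment_config")
}

#' Save a configuration to YAML
#'
#' Round-trips through [load_config()]: saving and re-loading reproduces the
#' same configuration.
#'
#' @param cfg An `experiment_config` (or plain list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Write a spike raster as tab-separated text
#'
#' Columns: `time_ms`, `neuron_id`, `population`. Events must be
#' time-sorted; a header-only file is written for an empty raster.
#'
#' @param events Data frame with columns `time_ms`, `neuron_id`,
#'   `population`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(events, path) {
  if (nrow(events) > 0 && is.unsorted(events$time_ms))
    stop("spike events must be sorted by time")
  ok <- tryCatch({
    utils::write.table(events[, c("time_ms", "neuron_id", "population")],
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e)
    stop(sprintf("failed to write spikes to '%s': %s", path, conditionMessage(e))))
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a weight-summary table as CSV
#'
#' Columns: `time_ms`, `group_mean_nA`, `global_mean_nA`.
#'
#' @param rows Data frame with the three summary columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weight_summary <- function(rows, path) {
  tryCatch(
    utils::write.table(rows[, c("time_ms", "group_mean_nA", "global_mean_nA")],
                       path, sep = ",", quote = FALSE, row.names = FALSE),
    error = function(e)
      stop(sprintf("failed to write weight summary to '%s': %s",
                   path, conditionMessage(e))))
  invisible(path)
}

#' @rdname write_weight_summary
#' @export
read_weight_summary <- function(path) {
  utils::read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
}

#' Run a configured experiment and write its artifacts
#'
#' Dispatches on `cfg$experiment`, runs the experiment, and writes the spike
#' raster (`spikes.tsv`), a result table (`weights.csv` or `sweep.csv`), the
#' resolved configuration (`config.yaml`) and a run manifest
#' (`manifest.yaml`) into the output directory. Identical configurations and
#' seeds produce byte-identical data outputs.
#'
#' @param cfg An `experiment_config` from [load_config()], or a list
#'   accepted by it.
#' @param out_dir Output directory; overrides `cfg$output_dir`.
#' @return Invisibly, a list with the experiment result and the paths
#'   written.
#' @export
run_experiment <- function(cfg, out_dir = NULL) {
  if (!inherits(cfg, "experiment_config"))
    cfg <- structure(merge_validated(default_experiment_config(
      if (is.null(cfg$experiment)) "conditioning" else cfg$experiment), cfg),
      class = "experiment_config")
  validate_config(cfg)
  out_dir <- if (!is.null(out_dir)) out_dir else cfg$output_dir
  if (is.null(out_dir)) stop("no output directory given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  pc <- do.call(pair_stdp_config, cfg$stdp)

  paths <- character(0)
  result <- switch(cfg$experiment,
    single_synapse = {
      sweep_r <- sweep_dopamine_delay(cfg$delays, cfg$d_c, pair_cfg = pc,
        nm_cfg = neuromod_config(cfg$tau_c, cfg$tau_d, w_min = -Inf, w_max = Inf))
      sweep_p <- sweep_dopamine_delay(cfg$delays, -cfg$d_c, pair_cfg = pc,
        nm_cfg = neuromod_config(cfg$tau_c, cfg$tau_d, w_min = -Inf, w_max = Inf))
      tab <- data.frame(delay_ms = sweep_r$delay, reward_dw = sweep_r$delta_w,
                        punishment_dw = sweep_p$delta_w)
      p <- file.path(out_dir, "sweep.csv")
      utils::write.table(tab, p, sep = ",", quote = FALSE, row.names = FALSE)
      paths <- c(paths, p)
      list(sweep = tab)
    },
    reward_punishment = {
      r <- run_reward_punishment(cfg$duration_ms, cfg$seed, cfg$n_neurons,
        cfg$input_rate, cfg$initial_weight, cfg$reward_times,
        cfg$punishment_times, cfg$d_c_reward, cfg$d_c_punishment, pc,
        neuromod_config(cfg$tau_c, cfg$tau_d, cfg$w_min, cfg$w_max))
      p <- file.path(out_dir, "spikes.tsv")
      write_spikes(data.frame(time_ms = r$spikes$time,
                              neuron_id = r$spikes$neuron,
                              population = "excitatory"), p)
      paths <- c(paths, p)
      r
    },
    conditioning = {
      net <- build_conditioning_network(cfg$n_total, cfg$seed,
        n_groups = cfg$n_groups,
        connection_probability = cfg$connection_probability,
        initial_weight = cfg$initial_weight,
        inhibitory_weight = cfg$inhibitory_weight, w_max = cfg$w_max,
        noise_weight = cfg$noise_weight, noise_rate = cfg$noise_rate,
        d_c = cfg$d_c)
      r <- run_conditioning(net, cfg$duration_ms, cfg$seed,
        reward_group = cfg$reward_group,
        snapshot_interval = cfg$snapshot_interval, pair_cfg = pc)
      p1 <- file.path(out_dir, "weights.csv")
      write_weight_summary(r$summary, p1)
      pop <- ifelse(r$spikes$neuron <= net$n_exc, "excitatory", "inhibitory")
      p2 <- file.path(out_dir, "spikes.tsv")
      write_spikes(data.frame(time_ms = r$spikes$time,
                              neuron_id = r$spikes$neuron,
                              population = pop), p2)
      paths <- c(paths, p1, p2)
      r
    },
    stop(sprintf("unknown experiment '%s'", cfg$experiment)))

  cfg_path <- file.path(out_dir, "config.yaml")
  save_config(cfg, cfg_path)
  manifest <- list(experiment = cfg$experiment, seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("tristdp")),
                   r_version = R.version.string,
                   wall_clock_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(list(result = result, paths = c(paths, cfg_path, manifest_path)))
}
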