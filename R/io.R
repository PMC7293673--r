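# Delimited-text I/O. All external tables are UTF-8 CSV with a header row;
# time is in minutes and concentrations in mmol/L at every boundary.

#' Write / read a measured-series table
#'
#' Columns: `experiment_id, time_min, kind (target|TOC|H2O2), value, units`.
#'
#' @param data Data frame or [generate_synthetic()] result.
#' @param path File path.
#' @return `read_series()` returns the data frame; `write_series()` its
#'   path, invisibly.
#' @export
write_series <- function(data, path) {
  if (inherits(data, "synthetic_dataset")) data <- data$data
  stopifnot(all(c("experiment_id", "time_min", "kind", "value") %in%
                  names(data)))
  write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("experiment_id", "time_min", "kind", "value")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("series file missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(d$kind), c("target", "TOC", "H2O2"))
  if (length(bad)) stop("unknown observable kind(s): ",
                        paste(bad, collapse = ", "))
  d
}

#' Write a trajectory as a long table
#'
#' Columns: `time_min, compartment, species, concentration_mmol_per_L`.
#'
#' @param traj A [simulate_experiment()] result.
#' @param path File path.
#' @export
write_trajectory <- function(traj, path) {
  st <- traj$states
  d <- expand.grid(time_min = traj$time_min,
                   compartment = seq_len(dim(st)[2]),
                   species = traj$species, stringsAsFactors = FALSE)
  d$concentration_mmol_per_L <- as.vector(st)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration files
#'
#' A YAML file holding overrides for the simulation defaults. Unknown
#' fields are rejected, so typos fail loudly; missing fields keep the
#' defaults, which reproduce the reference configuration.
#'
#' @param path YAML file path (for `read_run_config`).
#' @param config Named list (for `validate_run_config`).
#' @return Validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is needed to read config files")
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @export
validate_run_config <- function(config) {
  defaults <- list(dt = 0.05, feed_duration = 30, record_every = 0.1,
                   normalization = "literal", sampling_compartment = 1,
                   seed = 1L, detection_limit = 0.005, sigma = 0.05)
  if (is.null(config)) config <- list()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("schema error: unknown config field(s): ",
         paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, config)
  if (!cfg$normalization %in% c("literal", "proportional"))
    stop("schema error: field 'normalization' must be literal|proportional")
  for (f in c("dt", "feed_duration", "record_every", "sigma"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0)
      stop("schema error: field '", f, "' must be a non-negative number")
  if (cfg$dt <= 0) stop("schema error: field 'dt' must be positive")
  cfg
}
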