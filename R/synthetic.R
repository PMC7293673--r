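# Synthetic assay generator: simulates a study at known ("true") parameters,
# samples each observable on its measurement grid and applies multiplicative
# measurement noise. Datasets are format-identical with measured data, so
# the calibration pipeline runs unchanged with or without real assays.

.derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 7919 * i) %% 2147483629)
}

#' Generate a synthetic measured dataset
#'
#' For each experiment the model is simulated at the supplied ("true")
#' constants, each applicable observable (target, TOC, H2O2) is sampled on
#' its measurement grid, and multiplicative Gaussian noise
#' `value * (1 + N(0, sigma))` is applied; negative draws are truncated to
#' zero and target values below the detection limit are dropped (absent
#' rows, as a real HPLC series would show). Each experiment uses a
#' deterministic per-row seed derived from `seed`, so a dataset is
#' reproducible row-by-row.
#'
#' @param experiments Character vector of registry ids, or a list of
#'   [experiment()] objects.
#' @param core True [core_constants()].
#' @param targets Named list of true [target_constants()] per compound;
#'   defaults to [reference_target_constants()] for registry compounds.
#' @param sigma Relative noise standard deviation (default 5%).
#' @param seed Master seed.
#' @param detection_limit Target detection limit, mmol/L; values below are
#'   dropped.
#' @param dt,feed_duration Passed to [simulate_experiment()].
#' @param normalization Competition normalization mode for the generator.
#' @return Object of class `synthetic_dataset`: `$data` (data frame
#'   `experiment_id, time_min, kind, value, units`), plus the generating
#'   truth, noise model and seed.
#' @examples
#' \donttest{
#' d <- generate_synthetic(c("BLANK_3", "BLANK_4"), seed = 42)
#' head(d$data)
#' }
#' @export
generate_synthetic <- function(experiments, core = core_constants(),
                               targets = NULL, sigma = 0.05, seed = 1L,
                               detection_limit = 0.005, dt = 0.05,
                               feed_duration = 30,
                               normalization = "literal") {
  stopifnot(sigma >= 0)
  if (is.character(experiments))
    experiments <- lapply(experiments, as_experiment)
  models <- list(blank = fenton_model(NULL, core = core,
                                      normalization = normalization))
  rows <- vector("list", length(experiments))
  for (i in seq_along(experiments)) {
    e <- experiments[[i]]
    cmp <- if (is.null(e$compound) || e$target0 == 0) NULL else e$compound
    key <- if (is.null(cmp)) "blank" else cmp
    if (is.null(models[[key]])) {
      tk <- if (!is.null(targets) && key %in% names(targets)) targets[[key]]
            else reference_target_constants(key)
      models[[key]] <- fenton_model(key, core = core, target = tk,
                                    normalization = normalization)
    }
    model <- models[[key]]
    kinds <- c(if (!is.null(cmp) &&
                   length(sampling_grid("target", cmp, e$duration_min)) > 0)
                 "target",
               if (!is.null(cmp)) "TOC",
               if (e$h2o2_0 > 0) "H2O2")
    if (length(kinds) == 0) next
    grids <- lapply(kinds, sampling_grid, compound = cmp,
                    duration_min = e$duration_min)
    traj <- simulate_experiment(model, e, dt = dt,
                                feed_duration = feed_duration,
                                times = sort(unique(unlist(grids))))
    set.seed(.derive_seed(seed, i))
    out <- lapply(seq_along(kinds), function(j) {
      s <- observable_series(traj, kinds[j])
      keep <- vapply(grids[[j]], function(t)
        which.min(abs(s$time_min - t)), 1L)
      v <- s$value[keep]
      v <- pmax(v * (1 + rnorm(length(v), 0, sigma)), 0)
      df <- data.frame(experiment_id = e$id, time_min = grids[[j]],
                       kind = kinds[j], value = v,
                       units = if (kinds[j] == "TOC") "mmolC_L" else "mmol_L",
                       stringsAsFactors = FALSE)
      if (kinds[j] == "target") df <- df[df$value >= detection_limit, ]
      df
    })
    rows[[i]] <- do.call(rbind, out)
  }
  structure(list(data = do.call(rbind, rows),
                 core = core, targets = targets, sigma = sigma, seed = seed,
                 detection_limit = detection_limit, dt = dt,
                 feed_duration = feed_duration,
                 experiments = experiments),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic dataset:", length(x$experiments), "experiments,",
      nrow(x$data), "observations, sigma =", x$sigma,
      ", seed =", x$seed, "\n")
  invisible(x)
}
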