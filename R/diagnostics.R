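# Built-in diagnostics: sensitivity of the headline observables to the
# oxidant feed window (whose physical duration is only known to be "fast")
# and a one-at-a-time rate-constant perturbation report.

#' Sensitivity of checkpoint observables to the H2O2 feed duration
#'
#' Re-simulates an assay over a range of feed windows and reports the TOC
#' conversion at 30 min and end of run and the H2O2 consumption at 10 min.
#'
#' @param model A [fenton_model()].
#' @param exp Experiment or registry id.
#' @param durations Feed windows to try, seconds.
#' @param dt Step, seconds.
#' @return Data frame, one row per feed duration.
#' @export
feed_sensitivity <- function(model, exp, durations = c(10, 30, 60),
                             dt = 0.05) {
  if (is.character(exp)) exp <- as_experiment(exp)
  do.call(rbind, lapply(durations, function(fd) {
    traj <- simulate_experiment(model, exp, dt = dt, feed_duration = fd)
    toc_s <- if (!model$blank && exp$target0 > 0)
      observable_series(traj, "TOC") else NULL
    h_s <- if (exp$h2o2_0 > 0) observable_series(traj, "H2O2") else NULL
    data.frame(
      feed_duration_s = fd,
      toc_conv_30min = if (is.null(toc_s)) NA else conversion(toc_s, 30),
      toc_conv_final = if (is.null(toc_s)) NA
        else conversion(toc_s, exp$duration_min),
      h2o2_cons_10min = if (is.null(h_s)) NA else conversion(h_s, 10))
  }))
}

#' One-at-a-time rate-constant perturbation report
#'
#' Perturbs each rate constant by `+/- rel` and reports the change in the
#' final TOC conversion (or final H2O2 consumption for a blank model). A
#' coarse local-sensitivity screen, not a global analysis.
#'
#' @param model A [fenton_model()].
#' @param exp Experiment or registry id.
#' @param rel Relative perturbation (default 10%).
#' @param dt Step, seconds.
#' @return Data frame `constant, low, base, high` of the observable value.
#' @export
perturbation_report <- function(model, exp, rel = 0.1, dt = 0.05) {
  if (is.character(exp)) exp <- as_experiment(exp)
  blank <- model$blank || exp$target0 == 0
  observable <- function(m) {
    traj <- simulate_experiment(m, exp, dt = dt)
    s <- observable_series(traj, if (blank) "H2O2" else "TOC")
    conversion(s, exp$duration_min)
  }
  ks <- c("k0", "k1", "k2", "k_elim",
          if (!blank) c("k_target", "k_fragment"))
  base <- observable(model)
  do.call(rbind, lapply(ks, function(k) {
    tweak <- function(f) {
      m <- model
      if (k %in% names(m$core)) m$core[[k]] <- m$core[[k]] * f
      else m$target[[k]] <- m$target[[k]] * f
      m
    }
    data.frame(constant = k, low = observable(tweak(1 - rel)), base = base,
               high = observable(tweak(1 + rel)))
  }))
}
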