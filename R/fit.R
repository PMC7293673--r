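# Staged parameter estimation: core constants from blank assays first, then
# the two target-specific constants per compound with the core held fixed.
# The search priority over observables (TOC > target > H2O2) is encoded as
# fixed residual weights; the optimizer is bounded Levenberg-Marquardt
# least squares with a seeded multistart.

#' Fitting options
#'
#' @param multistart Number of optimizer starts (the configured initial
#'   value plus log-uniform draws within the bounds).
#' @param seed Seed for the multistart draws (and anything else random in a
#'   fit); identical seed and options give identical results.
#' @param weights Residual weights per observable kind; the default 3:2:1
#'   encodes the TOC > target > H2O2 fitting priority.
#' @param dt,feed_duration Simulation settings used inside the objective.
#' @param h2o2_normalized Compare H2O2 as normalized series (default) or in
#'   mmol/L.
#' @param maxiter,ftol,ptol Levenberg-Marquardt controls.
#' @return List of class `fit_control`.
#' @export
fit_control <- function(multistart = 3L, seed = 1L,
                        weights = c(TOC = 3, target = 2, H2O2 = 1),
                        dt = 0.05, feed_duration = 30,
                        h2o2_normalized = TRUE,
                        maxiter = 100L, ftol = 1e-10, ptol = 1e-8) {
  stopifnot(multistart >= 1L, all(weights > 0),
            all(c("TOC", "target", "H2O2") %in% names(weights)))
  structure(list(multistart = as.integer(multistart), seed = as.integer(seed),
                 weights = weights, dt = dt, feed_duration = feed_duration,
                 h2o2_normalized = isTRUE(h2o2_normalized),
                 maxiter = maxiter, ftol = ftol, ptol = ptol),
            class = "fit_control")
}

.as_measured <- function(data) {
  if (inherits(data, "synthetic_dataset")) data <- data$data
  stopifnot(is.data.frame(data),
            all(c("experiment_id", "time_min", "kind", "value") %in% names(data)))
  data
}

.norm_reference <- function(exp, kind, nc) {
  switch(kind,
         target = exp$target0,
         TOC = nc * exp$target0,
         H2O2 = exp$h2o2_0)
}

# Residual vector over all experiments/kinds for a parameter-to-model map.
.residual_fn <- function(data, exps, model_for, control) {
  by_exp <- split(data, data$experiment_id)
  function(p) {
    res <- lapply(names(by_exp), function(id) {
      d <- by_exp[[id]]
      e <- exps[[id]]
      model <- model_for(p, e)
      traj <- simulate_experiment(model, e, dt = control$dt,
                                  feed_duration = control$feed_duration,
                                  record_every = e$duration_min,
                                  times = sort(unique(d$time_min)),
                                  auto_dt = FALSE)
      unlist(lapply(split(d, d$kind), function(dk) {
        kind <- dk$kind[1]
        ref <- .norm_reference(e, kind, model$mech$chain$nc)
        norm <- if (kind == "H2O2" && !control$h2o2_normalized) 1 else ref
        s <- observable_series(traj, kind)
        sim <- s$value[vapply(dk$time_min, function(t)
          which.min(abs(s$time_min - t)), 1L)]
        sqrt(control$weights[[kind]]) * (sim - dk$value) / norm
      }), use.names = FALSE)
    })
    unlist(res, use.names = FALSE)
  }
}

.multistart_lm <- function(fn, init, lower, upper, control) {
  set.seed(control$seed)
  starts <- list(init)
  if (control$multistart > 1L)
    for (i in seq_len(control$multistart - 1L))
      starts[[i + 1L]] <- setNames(
        exp(runif(length(init), log(lower), log(upper))), names(init))
  fits <- lapply(starts, function(p0)
    minpack.lm::nls.lm(par = p0, lower = lower, upper = upper, fn = fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = control$maxiter, ftol = control$ftol,
                         ptol = control$ptol)))
  dev <- vapply(fits, function(f) f$deviance, 0)
  best <- which.min(dev)
  list(fit = fits[[best]], starts = starts, best_start = best,
       deviances = dev)
}

.resolve_experiments <- function(data, experiments) {
  ids <- unique(data$experiment_id)
  if (is.null(experiments)) experiments <- ids
  if (is.character(experiments)) experiments <- lapply(experiments, as_experiment)
  exps <- setNames(experiments,
                   vapply(experiments, `[[`, "", "id"))
  missing <- setdiff(ids, names(exps))
  if (length(missing))
    stop("no experiment spec for data ids: ", paste(missing, collapse = ", "))
  exps
}

.new_fenton_fit <- function(stage, best, fn, fixed, bounds, data, exps,
                            control, compound = NULL) {
  est <- best$fit$par
  structure(list(stage = stage, coefficients = est, fixed = fixed,
                 bounds = bounds, compound = compound,
                 fit = list(deviance = best$fit$deviance,
                            niter = best$fit$niter,
                            message = best$fit$message,
                            rsstrace = best$fit$rsstrace,
                            start_deviances = best$deviances,
                            best_start = best$best_start),
                 data = data, experiments = exps, control = control),
            class = "fenton_fit")
}

#' Estimate the core constants from blank assays
#'
#' Stage one of the calibration: the target-independent constants are
#' estimated from assays performed without organics, using the normalized
#' H2O2 series. Dark assays constrain `k1` and `k2`; at least one irradiated
#' assay is required to identify `k0`. The HO* elimination constant has no
#' feedback on H2O2 in organics-free assays, so it is held fixed by default
#' (`free_k_elim = TRUE` frees it, with a flat objective in that direction).
#'
#' @param data Measured series (data frame or [generate_synthetic()]
#'   result) restricted to blank assays.
#' @param experiments Experiment specs or registry ids (default: resolved
#'   from the data ids).
#' @param init,lower,upper Named vectors over `k0, k1, k2` (and `k_elim` if
#'   freed). Defaults: literature ranges for `k1` (0.1-11.7 L/mol/s) and
#'   `k2` (63-76 L/mol/s), a decade around the reference photo constant for
#'   `k0`.
#' @param k_elim Fixed elimination constant (1/s).
#' @param free_k_elim Also estimate `k_elim` (see above).
#' @param fix_k0 Set when fitting dark-only data: fixes `k0` instead of
#'   estimating it (otherwise dark-only data raises an identifiability
#'   error).
#' @param control A [fit_control()].
#' @return A `fenton_fit` (stage `"core"`); `coef()` returns the estimates,
#'   `summary()` the per-assay RMSE table.
#' @export
fit_fenton_core <- function(data, experiments = NULL,
                            init = NULL, lower = NULL, upper = NULL,
                            k_elim = 7.5e-2, free_k_elim = FALSE,
                            fix_k0 = NULL, control = fit_control()) {
  data <- .as_measured(data)
  data <- data[data$kind == "H2O2", , drop = FALSE]
  if (nrow(data) == 0) stop("no H2O2 series in blank data")
  exps <- .resolve_experiments(data, experiments)
  with_target <- vapply(exps, function(e)
    !is.null(e$compound) && e$target0 > 0, NA)
  if (any(with_target))
    stop("core stage takes blank assays only; remove: ",
         paste(names(exps)[with_target], collapse = ", "))
  irr <- vapply(exps, `[[`, NA, "irradiated")
  if (!any(!irr)) stop("need at least one dark blank assay")
  free_k0 <- is.null(fix_k0)
  if (free_k0 && !any(irr))
    stop("identifiability error: k0 is free but no irradiated blank data ",
         "was given (fit dark-only data with fix_k0 =)")
  par_names <- c(if (free_k0) "k0", "k1", "k2", if (free_k_elim) "k_elim")
  defaults <- list(
    init = c(k0 = 5.6e-2, k1 = 5.9, k2 = 69.5, k_elim = 7.5e-2),
    lower = c(k0 = 5.6e-3, k1 = 0.1, k2 = 63.0, k_elim = 7.5e-3),
    upper = c(k0 = 5.6e-1, k1 = 11.7, k2 = 76.0, k_elim = 7.5e-1))
  pick <- function(user, def) {
    v <- def[par_names]
    if (!is.null(user)) v[names(user)] <- user
    v
  }
  init <- pick(init, defaults$init)
  lower <- pick(lower, defaults$lower)
  upper <- pick(upper, defaults$upper)

  model_for <- function(p, e) {
    fenton_model(NULL, core = core_constants(
      k0 = if (free_k0) p[["k0"]] else fix_k0,
      k1 = p[["k1"]], k2 = p[["k2"]],
      k_elim = if (free_k_elim) p[["k_elim"]] else k_elim))
  }
  fn <- .residual_fn(data, exps, model_for, control)
  best <- .multistart_lm(fn, init, lower, upper, control)
  fixed <- c(if (!free_k0) c(k0 = fix_k0),
             if (!free_k_elim) c(k_elim = k_elim))
  .new_fenton_fit("core", best, fn, fixed,
                  list(lower = lower, upper = upper, init = init),
                  data, exps, control)
}

#' Estimate the two target-specific constants of a compound
#'
#' Stage two: with the core constants fixed, `k_target` (first attack) and
#' `k_fragment` (all later breakage and the terminal mineralization) are
#' estimated from the target, TOC and H2O2 series, weighted by the
#' TOC > target > H2O2 priority of [fit_control()].
#'
#' @param compound Compound name or [target_compound()].
#' @param data Measured series for that compound's assays.
#' @param core Fixed [core_constants()], or a stage-one `fenton_fit`.
#' @param experiments Specs or ids (default from data).
#' @param init Named vector `c(k_target=, k_fragment=)`; defaults to the
#'   reference constants for registry compounds.
#' @param lower,upper Bounds; default one decade centred on `init`.
#' @param control A [fit_control()].
#' @return A `fenton_fit` (stage `"target"`).
#' @export
fit_fenton_target <- function(compound, data, core, experiments = NULL,
                              init = NULL, lower = NULL, upper = NULL,
                              control = fit_control()) {
  if (inherits(core, "fenton_fit")) core <- coef_as_core(core)
  stopifnot(inherits(core, "core_constants"))
  if (is.character(compound)) compound <- fenton_compounds(compound)
  data <- .as_measured(data)
  data <- data[data$kind %in% c("target", "TOC", "H2O2"), , drop = FALSE]
  if (nrow(data) == 0 || all(data$value == 0))
    stop("degenerate data: no usable (nonzero) series for ", compound$name)
  exps <- .resolve_experiments(data, experiments)
  ok <- vapply(exps, function(e)
    identical(e$compound, compound$name), NA)
  if (!all(ok))
    stop("experiments not using ", compound$name, ": ",
         paste(names(exps)[!ok], collapse = ", "))
  if (is.null(init)) {
    ref <- reference_target_constants(compound$name)
    init <- c(k_target = ref$k_target, k_fragment = ref$k_fragment)
  }
  if (is.null(lower)) lower <- init / sqrt(10)
  if (is.null(upper)) upper <- init * sqrt(10)
  names(lower) <- names(upper) <- names(init)

  model_for <- function(p, e) {
    fenton_model(compound, core = core,
                 target = target_constants(p[["k_target"]], p[["k_fragment"]]))
  }
  fn <- .residual_fn(data, exps, model_for, control)
  best <- .multistart_lm(fn, init, lower, upper, control)
  .new_fenton_fit("target", best, fn, unlist(core),
                  list(lower = lower, upper = upper, init = init),
                  data, exps, control, compound = compound)
}

#' Core constants from a stage-one fit
#' @param fit A stage `"core"` `fenton_fit`.
#' @return A [core_constants()] with estimated and fixed values combined.
#' @export
coef_as_core <- function(fit) {
  stopifnot(inherits(fit, "fenton_fit"), fit$stage == "core")
  p <- c(fit$coefficients, fit$fixed)
  core_constants(k0 = p[["k0"]], k1 = p[["k1"]], k2 = p[["k2"]],
                 k_elim = p[["k_elim"]])
}

.fit_model_for <- function(fit, e) {
  if (fit$stage == "core") {
    fenton_model(NULL, core = coef_as_core(fit))
  } else {
    fenton_model(fit$compound,
                 core = core_constants(k0 = fit$fixed[["k0"]],
                                       k1 = fit$fixed[["k1"]],
                                       k2 = fit$fixed[["k2"]],
                                       k_elim = fit$fixed[["k_elim"]]),
                 target = target_constants(fit$coefficients[["k_target"]],
                                           fit$coefficients[["k_fragment"]]))
  }
}

#' @export
coef.fenton_fit <- function(object, ...) object$coefficients

#' @export
print.fenton_fit <- function(x, ...) {
  cat("Staged Fenton calibration -", x$stage, "stage")
  if (!is.null(x$compound)) cat(" (", x$compound$name, ")", sep = "")
  cat("\n  estimates:\n")
  print(signif(x$coefficients, 4))
  if (length(x$fixed)) {
    cat("  fixed:\n"); print(signif(x$fixed, 4))
  }
  cat(sprintf("  deviance %.4g after %d iterations (%s)\n",
              x$fit$deviance, x$fit$niter, x$fit$message))
  invisible(x)
}

#' Per-assay, per-observable RMSE of a fit
#'
#' RMSE over the normalized series at the measured sampling times, reported
#' in percent; the summary row is the arithmetic mean over assays for each
#' observable kind.
#'
#' @param fit A `fenton_fit`.
#' @return Data frame `experiment_id, kind, n, rmse_pct`.
#' @export
rmse_table <- function(fit) {
  stopifnot(inherits(fit, "fenton_fit"))
  pred <- predict(fit)
  d <- merge(fit$data, pred, by = c("experiment_id", "time_min", "kind"),
             suffixes = c("", "_sim"))
  out <- do.call(rbind, lapply(split(d, d[c("kind", "experiment_id")], drop = TRUE),
    function(g) {
      e <- fit$experiments[[g$experiment_id[1]]]
      nc <- if (fit$stage == "core") 1 else fit$compound$nc
      ref <- .norm_reference(e, g$kind[1], nc)
      if (g$kind[1] == "H2O2" && !fit$control$h2o2_normalized) ref <- 1
      data.frame(experiment_id = g$experiment_id[1], kind = g$kind[1],
                 n = nrow(g),
                 rmse_pct = 100 * sqrt(mean(((g$value - g$value_sim) / ref)^2)))
    }))
  rownames(out) <- NULL
  out[order(out$experiment_id, out$kind), ]
}

#' @export
summary.fenton_fit <- function(object, ...) {
  tab <- rmse_table(object)
  avg <- vapply(split(tab$rmse_pct, tab$kind), mean, 0)
  structure(list(fit = object, rmse = tab, rmse_mean = avg),
            class = "summary.fenton_fit")
}

#' @export
print.summary.fenton_fit <- function(x, ...) {
  print(x$fit)
  cat("\nRMSE by assay (% of initial value):\n")
  print(x$rmse, row.names = FALSE)
  cat("\nMean RMSE per observable:\n")
  print(round(x$rmse_mean, 1))
  invisible(x)
}

#' @export
predict.fenton_fit <- function(object, experiments = NULL, times = NULL, ...) {
  exps <- if (is.null(experiments)) object$experiments
          else .resolve_experiments(
            data.frame(experiment_id = vapply(
              lapply(experiments, function(x)
                if (is.character(x)) as_experiment(x) else x),
              `[[`, "", "id")),
            lapply(experiments, function(x)
              if (is.character(x)) as_experiment(x) else x))
  by_exp <- split(object$data, object$data$experiment_id)
  out <- lapply(names(exps), function(id) {
    e <- exps[[id]]
    model <- .fit_model_for(object, e)
    d <- by_exp[[id]]
    tt <- if (!is.null(times)) times
          else if (!is.null(d)) sort(unique(d$time_min))
          else seq(0, e$duration_min, by = 1)
    traj <- simulate_experiment(model, e, dt = object$control$dt,
                                feed_duration = object$control$feed_duration,
                                record_every = e$duration_min, times = tt,
                                auto_dt = FALSE)
    kinds <- if (!is.null(d)) unique(d$kind)
             else c(if (!model$blank) c("target", "TOC"), "H2O2")
    do.call(rbind, lapply(kinds, function(k) {
      s <- observable_series(traj, k)
      tk <- if (!is.null(d)) sort(unique(d$time_min[d$kind == k])) else tt
      v <- s$value[vapply(tk, function(t) which.min(abs(s$time_min - t)), 1L)]
      data.frame(experiment_id = id, time_min = tk, kind = k, value = v,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, out)
}

#' @export
residuals.fenton_fit <- function(object, ...) {
  pred <- predict(object)
  d <- merge(object$data, pred, by = c("experiment_id", "time_min", "kind"),
             suffixes = c("", "_sim"))
  d$residual <- mapply(function(id, kind, y, ys) {
    e <- object$experiments[[id]]
    nc <- if (object$stage == "core") 1 else object$compound$nc
    ref <- .norm_reference(e, kind, nc)
    if (kind == "H2O2" && !object$control$h2o2_normalized) ref <- 1
    (y - ys) / ref
  }, d$experiment_id, d$kind, d$value, d$value_sim)
  d
}

#' @export
plot.fenton_fit <- function(x, experiment_id = NULL, ...) {
  ids <- if (is.null(experiment_id)) names(x$experiments)[1] else experiment_id
  for (id in ids) {
    e <- x$experiments[[id]]
    d <- x$data[x$data$experiment_id == id, ]
    model <- .fit_model_for(x, e)
    traj <- simulate_experiment(model, e, dt = x$control$dt,
                                feed_duration = x$control$feed_duration)
    kinds <- unique(d$kind)
    nc <- model$mech$chain$nc
    plot(NA, xlim = c(0, e$duration_min), ylim = c(0, 1.1),
         xlab = "time (min)", ylab = "normalized concentration",
         main = id, ...)
    for (j in seq_along(kinds)) {
      k <- kinds[j]
      ref <- .norm_reference(e, k, nc)
      s <- observable_series(traj, k)
      lines(s$time_min, s$value / ref, col = j, lwd = 2)
      dk <- d[d$kind == k, ]
      points(dk$time_min, dk$value / ref, col = j, pch = 19)
    }
    legend("topright", legend = kinds, col = seq_along(kinds),
           lwd = 2, pch = 19, bty = "n")
  }
  invisible(x)
}

#' @export
simulate.fenton_fit <- function(object, nsim = 1, seed = NULL, sigma = 0.05,
                                ...) {
  if (is.null(seed)) seed <- object$control$seed
  core <- if (object$stage == "core") coef_as_core(object)
          else core_constants(k0 = object$fixed[["k0"]],
                              k1 = object$fixed[["k1"]],
                              k2 = object$fixed[["k2"]],
                              k_elim = object$fixed[["k_elim"]])
  targets <- if (object$stage == "target")
    setNames(list(target_constants(object$coefficients[["k_target"]],
                                   object$coefficients[["k_fragment"]])),
             object$compound$name)
  sets <- lapply(seq_len(nsim), function(i)
    generate_synthetic(unname(object$experiments), core = core,
                       targets = targets, sigma = sigma,
                       seed = .derive_seed(seed, i),
                       dt = object$control$dt,
                       feed_duration = object$control$feed_duration, ...))
  if (nsim == 1) sets[[1]] else sets
}
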