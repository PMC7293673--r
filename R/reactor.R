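# The recirculating pilot plant: an ordered cycle of well-mixed compartments
# exchanging volume at the recirculation flow rate, with a finite-time H2O2
# feed into the tank and (optionally) one irradiated compartment.

#' Plant geometry
#'
#' @param volumes Compartment volumes in L (ordered along the recirculation
#'   cycle).
#' @param flow Recirculation flow rate, L/min.
#' @param irradiated_compartment 1-based index of the irradiated compartment,
#'   or 0 for dark operation.
#' @param feed_compartment 1-based index of the compartment receiving the
#'   H2O2 feed.
#' @param sampling_compartment Compartment whose concentrations stand for
#'   the measured samples (the reservoir tank by default).
#' @return Object of class `plant_spec`.
#' @export
plant_spec <- function(volumes, flow, irradiated_compartment = 0,
                       feed_compartment = 1, sampling_compartment = 1) {
  stopifnot(all(volumes > 0), flow > 0,
            irradiated_compartment %in% 0:length(volumes),
            feed_compartment %in% seq_along(volumes))
  structure(list(volumes = volumes, flow = flow,
                 irradiated_compartment = as.integer(irradiated_compartment),
                 feed_compartment = as.integer(feed_compartment),
                 sampling_compartment = as.integer(sampling_compartment)),
            class = "plant_spec")
}

#' Default four-compartment pilot plant
#'
#' A 15.0-L recirculating system: the 9.00-L reservoir tank (fed with H2O2
#' and sampled), two 2.25-L connecting sections and the 1.50-L annular
#' photo-reactor (compartment 3), with a 12.0 L/min recirculation flow.
#'
#' @param irradiated Logical; if `TRUE` compartment 3 is irradiated.
#' @return A [plant_spec()].
#' @examples
#' default_plant(TRUE)
#' @export
default_plant <- function(irradiated = FALSE) {
  plant_spec(volumes = c(9.00, 2.25, 1.50, 2.25), flow = 12.0,
             irradiated_compartment = if (irradiated) 3L else 0L)
}

#' @export
print.plant_spec <- function(x, ...) {
  cat("Recirculating plant:", length(x$volumes), "compartments,",
      sum(x$volumes), "L total,", x$flow, "L/min\n")
  cat("  volumes:", paste(x$volumes, "L"), "\n")
  cat("  irradiated compartment:",
      if (x$irradiated_compartment == 0) "none (dark)" else
        x$irradiated_compartment, "\n")
  invisible(x)
}

#' Describe an assay
#'
#' @param id Experiment identifier.
#' @param compound Compound name (`"PCT"`, `"SQX"`, `"FA"`, or `NULL` for a
#'   blank without organics).
#' @param target0 Initial target concentration, mmol/L.
#' @param fe2_0 Initial ferrous iron, mmol/L (all iron starts as Fe2+).
#' @param h2o2_0 Total H2O2 dose, mmol/L of plant volume, fed over the feed
#'   window at the start of the run.
#' @param irradiated Logical.
#' @param duration_min Run length, minutes.
#' @param pH Controlled pH (clamps H+/OH-).
#' @return Object of class `fenton_experiment`.
#' @export
experiment <- function(id, compound = NULL, target0 = 0, fe2_0 = 0,
                       h2o2_0 = 0, irradiated = FALSE, duration_min = 120,
                       pH = 2.8) {
  stopifnot(target0 >= 0, fe2_0 >= 0, h2o2_0 >= 0, duration_min > 0)
  structure(list(id = id, compound = compound, target0 = target0,
                 fe2_0 = fe2_0, h2o2_0 = h2o2_0,
                 irradiated = isTRUE(irradiated),
                 duration_min = duration_min, pH = pH),
            class = "fenton_experiment")
}

#' Bundle mechanism and rate constants into a runnable model
#'
#' The central object of the package: a compound (or none, for blank
#' assays), the target-independent core constants, the two target-specific
#' constants, and the normalization mode. Simulate it with
#' [simulate_experiment()] or fit it with [fit_fenton_core()] /
#' [fit_fenton_target()].
#'
#' @param compound A [target_compound()], a registry name, or `NULL` for the
#'   blank (organics-free) model.
#' @param core A [core_constants()].
#' @param target A [target_constants()]; defaults to the reference values for
#'   registry compounds and to zero rates for a blank.
#' @param normalization `"literal"` for the rate-weighted share `r_i^2/S`
#'   (default), `"proportional"` to leave the competing rates raw and let the
#'   per-step availability clamp allocate HO* proportionally.
#' @param pH Controlled pH.
#' @return Object of class `fenton_model`.
#' @examples
#' m <- fenton_model("PCT")
#' m
#' @export
fenton_model <- function(compound = NULL, core = core_constants(),
                         target = NULL,
                         normalization = c("literal", "proportional"),
                         pH = 2.8) {
  normalization <- match.arg(normalization)
  if (is.character(compound)) compound <- fenton_compounds(compound)
  if (is.null(compound)) {
    mech <- build_mechanism(target_compound("blank", "CH4"))
    if (is.null(target)) target <- target_constants(0, 0)
    blank <- TRUE
  } else {
    mech <- build_mechanism(compound)
    if (is.null(target)) target <- reference_target_constants(compound$name)
    blank <- FALSE
  }
  structure(list(compound = if (blank) NULL else compound, mech = mech,
                 core = core, target = target,
                 normalization = normalization, pH = pH, blank = blank),
            class = "fenton_model")
}

#' @export
print.fenton_model <- function(x, ...) {
  cat("Fenton / photo-Fenton kinetic model\n")
  if (x$blank) cat("  compound: none (blank core model)\n")
  else cat("  compound:", x$compound$name,
           sprintf("(NC = %d, %d reactions)\n", x$compound$nc,
                   nrow(x$mech$reactions)))
  with(x$core, cat(sprintf(
    "  core: k0 = %.3g 1/s, k1 = %.3g, k2 = %.3g L/mol/s, k_elim = %.3g 1/s\n",
    k0, k1, k2, k_elim)))
  if (!x$blank) with(x$target, cat(sprintf(
    "  target: k_target = %.3g, k_fragment = %.3g L/mol/s\n",
    k_target, k_fragment)))
  cat("  competition normalization:", x$normalization, "\n")
  invisible(x)
}

.integrated_names <- function(mech)
  c("fe2", "fe3", "h2o2", "r_ho", mech$species, "mineral", "sink")

#' One availability-clamped step of the whole plant (reference implementation)
#'
#' Advances every compartment by one explicit step: rates are evaluated and
#' normalized per compartment, the availability clamp scales any reaction
#' whose one-step consumption would exceed the current amount of a reactant,
#' concentrations are updated, the feed adds oxidant to the feed compartment,
#' and the cyclic advective exchange moves `flow * dt` litres along the loop.
#' This is the R reference for the compiled stepper used by
#' [simulate_experiment()]; both produce identical updates.
#'
#' @param state Numeric matrix, compartments x integrated species (columns
#'   `fe2, fe3, h2o2, r_ho, target, f1..fF, mineral, sink`), mol/L.
#' @param model A [fenton_model()].
#' @param plant A [plant_spec()].
#' @param dt Step, seconds. Must satisfy `flow * dt` < smallest volume.
#' @param feed_rate Oxidant feed, mol/s into the feed compartment (0 when
#'   the feed window is over).
#' @return Updated state matrix.
#' @export
plant_step <- function(state, model, plant, dt, feed_rate = 0) {
  stopifnot(is.matrix(state), nrow(state) == length(plant$volumes))
  Q <- plant$flow / 60
  if (Q * dt >= min(plant$volumes))
    stop("dt too large: one step moves more than a compartment volume")
  mech <- model$mech
  F_ <- mech$chain$n_fragments
  new <- state
  for (i in seq_len(nrow(state))) {
    sv <- species_vector(mech,
                         fe2 = state[i, "fe2"], fe3 = state[i, "fe3"],
                         h2o2 = state[i, "h2o2"], r_ho = state[i, "r_ho"],
                         organics = state[i, mech$species], pH = model$pH,
                         mineral = state[i, "mineral"],
                         sink = state[i, "sink"])
    core <- core_rates(sv, model$core,
                       irradiated = (i == plant$irradiated_compartment))
    comp <- competing_rates(sv, mech, model$target, model$core$k_elim)
    if (model$normalization == "literal") comp <- normalize_competition(comp)
    else comp$normalized <- TRUE
    cl <- availability_clamp(sv, core, comp, dt)
    d <- assemble_derivatives(sv, cl$core, cl$competing, mech)
    nm <- .integrated_names(mech)
    upd <- pmax(sv[nm] + dt * d[nm], 0)
    new[i, nm] <- upd
  }
  if (feed_rate > 0)
    new[plant$feed_compartment, "h2o2"] <-
      new[plant$feed_compartment, "h2o2"] +
      dt * feed_rate / plant$volumes[plant$feed_compartment]
  prev <- c(nrow(new), seq_len(nrow(new) - 1L))
  new + Q * dt * (new[prev, , drop = FALSE] - new) / plant$volumes
}

#' Scale reactions so one-step consumption never exceeds availability
#'
#' For every species s consumed at total rate `cons_s`, if
#' `dt * cons_s > c_s` all reactions consuming s are scaled by
#' `c_s / (dt * cons_s)`; a reaction consuming several limited species takes
#' the smallest factor.
#'
#' @param state A [species_vector()].
#' @param core,competing Rate lists ([core_rates()], normalized
#'   [normalize_competition()] output).
#' @param dt Step, seconds.
#' @return List with scaled `core`, `competing` and logical `clamped`.
#' @export
availability_clamp <- function(state, core, competing, dt) {
  fac <- function(c, cons) if (cons > 0) min(1, c / (dt * cons)) else 1
  orgs <- competing$r_b
  nm <- names(state)
  org_names <- nm[seq.int(9L, length(nm) - 2L)]
  f_fe3 <- fac(state[["fe3"]], core$r1 + core$r0)
  f_fe2 <- fac(state[["fe2"]], core$r2)
  f_h <- fac(state[["h2o2"]], core$r1 + core$r2)
  f_oh <- fac(state[["r_ho"]], competing$r_elim + sum(orgs))
  f_org <- vapply(seq_along(orgs),
                  function(j) fac(state[[org_names[j]]], orgs[j]), 0)
  core$r1 <- core$r1 * min(f_fe3, f_h)
  core$r0 <- core$r0 * f_fe3
  core$r2 <- core$r2 * min(f_fe2, f_h)
  competing$r_elim <- competing$r_elim * f_oh
  competing$r_b <- orgs * pmin(f_oh, f_org)
  list(core = core, competing = competing,
       clamped = any(c(f_fe3, f_fe2, f_h, f_oh, f_org) < 1))
}

#' Simulate an assay in the recirculating plant
#'
#' Runs the availability-controlled fixed-step scheme (compiled) over the
#' experiment duration. The H2O2 dose (`h2o2_0` times the plant volume) is
#' fed into the feed compartment over `feed_duration` seconds starting at
#' t = 0; iron starts fully ferrous and the target compound is premixed
#' uniformly, matching the experimental protocol.
#'
#' @param model A [fenton_model()]; its compound must match the experiment
#'   (blank experiments accept any model, organics are simply absent).
#' @param exp A [experiment()] or a registry id string.
#' @param plant A [plant_spec()]; defaults to [default_plant()] with the
#'   experiment's irradiation flag.
#' @param dt Step, seconds.
#' @param feed_duration H2O2 feed window, seconds.
#' @param record_every Recording interval, minutes.
#' @param times Extra times (minutes) to record exactly (e.g. sampling
#'   grids).
#' @param auto_dt If `TRUE`, halve `dt` (up to 4 times) whenever the
#'   availability clamp was active on more than 1% of steps.
#' @return Object of class `fenton_trajectory`: recorded times (min),
#'   a `time x compartment x species` concentration array (mmol/L), and the
#'   run metadata (`$diagnostics` reports the step actually used and the
#'   clamp activity).
#' @examples
#' \donttest{
#' tr <- simulate_experiment(fenton_model("PCT"), "EXP13_PCT")
#' plot(tr)
#' }
#' @export
simulate_experiment <- function(model, exp, plant = NULL, dt = 0.05,
                                feed_duration = 30, record_every = 0.1,
                                times = NULL, auto_dt = TRUE) {
  if (is.character(exp)) exp <- as_experiment(exp)
  stopifnot(inherits(model, "fenton_model"), inherits(exp, "fenton_experiment"))
  if (!is.null(exp$compound) && exp$target0 > 0) {
    if (model$blank || model$compound$name != exp$compound)
      stop("model compound does not match experiment ", exp$id)
  }
  if (is.null(plant)) plant <- default_plant(exp$irradiated)
  mech <- model$mech
  nspec <- 7L + mech$chain$n_fragments
  ncomp <- length(plant$volumes)

  run <- function(dt) {
    n_steps <- round(exp$duration_min * 60 / dt)
    rec_min <- sort(unique(c(seq(0, exp$duration_min, by = record_every),
                             times, exp$duration_min)))
    rec_steps <- sort(unique(pmin(round(rec_min * 60 / dt), n_steps)))
    state0 <- matrix(0, ncomp, nspec)
    state0[, 1] <- exp$fe2_0 * 1e-3
    state0[, 5] <- exp$target0 * 1e-3
    res <- simulate_plant_cpp(
      state0, plant$volumes, plant$flow / 60,
      plant$irradiated_compartment,
      model$core$k0, model$core$k1, model$core$k2, model$core$k_elim,
      model$target$k_target, model$target$k_fragment,
      mech$chain$fncs, mech$chain$doubling,
      plant$feed_compartment, exp$h2o2_0 * 1e-3 * sum(plant$volumes),
      feed_duration, dt, n_steps, as.integer(rec_steps),
      as.integer(model$normalization == "literal"))
    list(res = res, time_min = rec_steps * dt / 60)
  }

  halvings <- 0L
  repeat {
    out <- run(dt)
    frac <- out$res$clamped_steps / out$res$n_steps
    if (!auto_dt || frac <= 0.01 || halvings >= 4L) break
    dt <- dt / 2
    halvings <- halvings + 1L
  }
  if (frac > 0.01)
    warning("availability clamp active on ", round(100 * frac, 1),
            "% of steps; consider a smaller dt", call. = FALSE)
  states <- out$res$states * 1e3  # -> mmol/L
  dimnames(states) <- list(NULL, paste0("comp", seq_len(ncomp)),
                           .integrated_names(mech))
  structure(list(time_min = out$time_min, states = states,
                 species = .integrated_names(mech),
                 model = model, experiment = exp, plant = plant,
                 diagnostics = list(dt = dt, halvings = halvings,
                                    feed_duration = feed_duration,
                                    clamped_fraction = frac)),
            class = "fenton_trajectory")
}

#' @export
print.fenton_trajectory <- function(x, ...) {
  e <- x$experiment
  cat(sprintf("Simulated run %s (%s, %s): %g min, dt = %g s\n", e$id,
              if (is.null(e$compound)) "blank" else e$compound,
              if (e$irradiated) "irradiated" else "dark",
              e$duration_min, x$diagnostics$dt))
  cat(sprintf("  [target]0 = %g, [Fe2+]0 = %g, [H2O2]0 = %g mmol/L\n",
              e$target0, e$fe2_0, e$h2o2_0))
  if (!x$model$blank && e$target0 > 0) {
    toc <- observable_series(x, "TOC")
    cat(sprintf("  TOC conversion: %.1f%% at 30 min, %.1f%% final\n",
                100 * conversion(toc, 30), 100 * conversion(toc, max(toc$time_min))))
  }
  if (e$h2o2_0 > 0) {
    h <- observable_series(x, "H2O2")
    cat(sprintf("  H2O2 consumed: %.1f%% at 10 min\n", 100 * conversion(h, 10)))
  }
  invisible(x)
}

#' @export
plot.fenton_trajectory <- function(x, kinds = c("target", "TOC", "H2O2"),
                                   normalized = TRUE, ...) {
  if (x$model$blank || x$experiment$target0 == 0)
    kinds <- intersect(kinds, "H2O2")
  series <- lapply(kinds, function(k)
    observable_series(x, k, normalized = normalized))
  matplot(series[[1]]$time_min,
          do.call(cbind, lapply(series, `[[`, "value")),
          type = "l", lty = 1, lwd = 2,
          xlab = "time (min)",
          ylab = if (normalized) "normalized concentration" else "mmol/L",
          main = x$experiment$id, ...)
  legend("topright", legend = kinds, lty = 1, lwd = 2,
         col = seq_along(kinds), bty = "n")
  invisible(x)
}
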