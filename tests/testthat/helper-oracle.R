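# Shared fixtures and the independent stiff-ODE oracle.
#
# The oracle integrates the same rate field (assembled from the package's
# exported kinetics functions plus advection and feed) with deSolve::lsoda,
# independently of the compiled fixed-step path.

paper_core <- function() core_constants(5.6e-2, 5.0, 63.0, 7.5e-2)

pct_truth <- c(k_target = 1.5e3, k_fragment = 1.5e2)

# Tank observable series from an adaptive stiff integration of the plant.
ode_oracle_series <- function(model, exp, times_min, plant = NULL,
                              feed_duration = 30) {
  skip_if_not_installed("deSolve")
  if (is.null(plant)) plant <- default_plant(exp$irradiated)
  mech <- model$mech
  nm <- c("fe2", "fe3", "h2o2", "r_ho", mech$species, "mineral", "sink")
  ncomp <- length(plant$volumes)
  Q <- plant$flow / 60
  feed_mol <- exp$h2o2_0 * 1e-3 * sum(plant$volumes)
  prev <- c(ncomp, seq_len(ncomp - 1))
  field <- function(t, y, parms) {
    S <- matrix(pmax(y, 0), ncomp, length(nm), dimnames = list(NULL, nm))
    dS <- matrix(0, ncomp, length(nm))
    for (i in seq_len(ncomp)) {
      sv <- species_vector(mech, fe2 = S[i, "fe2"], fe3 = S[i, "fe3"],
                           h2o2 = S[i, "h2o2"], r_ho = S[i, "r_ho"],
                           organics = S[i, mech$species], pH = model$pH,
                           mineral = S[i, "mineral"], sink = S[i, "sink"])
      core <- core_rates(sv, model$core,
                         irradiated = (i == plant$irradiated_compartment))
      comp <- competing_rates(sv, mech, model$target, model$core$k_elim)
      if (model$normalization == "literal") comp <- normalize_competition(comp)
      else comp$normalized <- TRUE
      d <- assemble_derivatives(sv, core, comp, mech)
      dS[i, ] <- d[nm]
    }
    dS <- dS + Q * (S[prev, , drop = FALSE] - S) / plant$volumes
    if (parms$feeding && feed_mol > 0)
      dS[plant$feed_compartment, "h2o2"] <-
        dS[plant$feed_compartment, "h2o2"] +
        (feed_mol / feed_duration) / plant$volumes[plant$feed_compartment]
    list(as.vector(dS))
  }
  y0 <- matrix(0, ncomp, length(nm))
  y0[, 1] <- exp$fe2_0 * 1e-3
  y0[, 5] <- exp$target0 * 1e-3
  t_s <- times_min * 60
  # integrate the feed window and the rest separately (discontinuous source)
  ctrl <- list(rtol = 1e-8, atol = 1e-14)
  seg1 <- deSolve::lsoda(as.vector(y0), times = c(0, feed_duration),
                         func = field, parms = list(feeding = TRUE),
                         rtol = ctrl$rtol, atol = ctrl$atol)
  y1 <- as.numeric(seg1[nrow(seg1), -1])
  later <- sort(unique(c(feed_duration, t_s[t_s > feed_duration])))
  seg2 <- deSolve::lsoda(y1, times = later, func = field,
                         parms = list(feeding = FALSE),
                         rtol = ctrl$rtol, atol = ctrl$atol)
  states <- rbind(seg1[, -1, drop = FALSE], seg2[-1, -1, drop = FALSE])
  st_t <- c(seg1[, 1], seg2[-1, 1])
  tank <- function(tm) {
    y <- states[which.min(abs(st_t - tm * 60)), ]
    setNames(matrix(y, ncomp)[plant$sampling_compartment, ] * 1e3, nm)
  }
  out <- t(vapply(times_min, tank, numeric(length(nm))))
  data.frame(time_min = times_min, out, check.names = FALSE)
}

# Max relative disagreement between fixed-step and oracle tank observables.
compare_to_oracle <- function(model, exp, times_min, dt = 0.05) {
  traj <- simulate_experiment(model, exp, dt = dt, times = times_min)
  orc <- ode_oracle_series(model, exp, times_min)
  kinds <- c(if (!model$blank && exp$target0 > 0) c("target", "TOC"),
             if (exp$h2o2_0 > 0) "H2O2")
  worst <- 0
  for (k in kinds) {
    s <- observable_series(traj, k)
    fixed <- s$value[vapply(times_min, function(t)
      which.min(abs(s$time_min - t)), 1L)]
    ref <- attr(s, "reference")
    orc_v <- if (k == "target") orc$target
             else if (k == "H2O2") orc$h2o2
             else as.numeric(as.matrix(orc[model$mech$species]) %*%
                               model$mech$chain$fncs)
    worst <- max(worst, abs(fixed - orc_v) / ref)
  }
  worst
}

# Plant-wide totals (moles) for conservation checks.
plant_totals <- function(traj) {
  v <- traj$plant$volumes
  iron <- apply(traj$states[, , "fe2"] + traj$states[, , "fe3"], 1,
                function(s) sum(s * v))
  orgs <- traj$model$mech$species
  fnc <- traj$model$mech$chain$fncs
  carbon <- rep(0, length(traj$time_min))
  for (j in seq_along(orgs))
    carbon <- carbon + fnc[j] * apply(traj$states[, , orgs[j]], 1,
                                      function(s) sum(s * v))
  carbon <- carbon + apply(traj$states[, , "mineral"], 1,
                           function(s) sum(s * v))
  list(iron = iron, carbon = carbon)
}
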