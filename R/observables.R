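# Derived observables compared against measurements: TOC, conversions and
# the RMSE metric used to score fits.

#' Total organic carbon of a state
#'
#' Sums the fictitious carbon numbers times the concentrations of *all*
#' organic species (target and every fragment); mineralized carbon is
#' excluded. The result carries the concentration unit of the input as a
#' carbon concentration (mmol/L in, mmol-C/L out).
#'
#' @param x A [species_vector()], or a plain numeric vector of organic
#'   concentrations (target, f1, ..., fF).
#' @param chain A [fragment_chain()].
#' @return Carbon concentration; multiply by 12.011 to get mg-C/L from
#'   mmol-C/L.
#' @examples
#' toc(c(0.26, 0, 0, 0), fragment_chain(8))       # 2.08 mmol-C/L
#' toc(c(0, 0.10, 0.19, 0.32), fragment_chain(8)) # 1.10
#' @export
toc <- function(x, chain) {
  stopifnot(inherits(chain, "fragment_chain"))
  F_ <- chain$n_fragments
  if (inherits(x, "species_vector"))
    x <- x[c("target", if (F_ > 0) paste0("f", seq_len(F_)))]
  if (length(x) != F_ + 1L) stop("state not aligned with chain")
  sum(chain$fncs * x)
}

#' Extract an observable series from a trajectory
#'
#' @param traj A [simulate_experiment()] result.
#' @param kind `"target"`, `"TOC"` or `"H2O2"`.
#' @param compartment Compartment index, or `"average"` for the
#'   volume-weighted plant average. Defaults to the plant's sampling
#'   compartment (the tank).
#' @param normalized If `TRUE`, divide by the nominal initial value (the
#'   initial target or TOC concentration, or the total H2O2 dose).
#' @return Data frame `time_min`, `value` with attributes `kind` and
#'   `reference` (the nominal initial value in mmol/L).
#' @export
observable_series <- function(traj, kind = c("target", "TOC", "H2O2"),
                              compartment = NULL, normalized = FALSE) {
  kind <- match.arg(kind)
  if (is.null(compartment)) compartment <- traj$plant$sampling_compartment
  mech <- traj$model$mech
  pick <- function(species) {
    if (identical(compartment, "average")) {
      v <- traj$plant$volumes
      m <- traj$states[, , species, drop = FALSE]
      apply(m, 1, function(s) sum(s * v) / sum(v))
    } else traj$states[, compartment, species]
  }
  e <- traj$experiment
  if (kind == "target") {
    value <- pick("target"); ref <- e$target0
  } else if (kind == "H2O2") {
    value <- pick("h2o2"); ref <- e$h2o2_0
  } else {
    orgs <- vapply(mech$species, pick, numeric(length(traj$time_min)))
    if (is.null(dim(orgs))) orgs <- matrix(orgs, nrow = 1)
    value <- as.numeric(orgs %*% mech$chain$fncs)
    ref <- mech$chain$nc * e$target0
  }
  if (normalized) {
    if (ref <= 0) stop("cannot normalize ", kind, ": zero initial value")
    value <- value / ref
  }
  structure(data.frame(time_min = traj$time_min, value = value),
            kind = kind, reference = ref, normalized = normalized)
}

#' Conversion of an observable at a time point
#'
#' `1 - value(t) / reference`, where the reference is the series'
#' nominal initial value (its `reference` attribute when present, else the
#' value at the earliest time).
#'
#' @param series Data frame with `time_min` and `value` (e.g. from
#'   [observable_series()]).
#' @param t Time, minutes; the nearest available point is used.
#' @param reference Override for the initial value.
#' @return Conversion fraction.
#' @export
conversion <- function(series, t, reference = NULL) {
  if (is.null(reference)) {
    reference <- attr(series, "reference")
    if (isTRUE(attr(series, "normalized"))) reference <- 1
    if (is.null(reference)) reference <- series$value[which.min(series$time_min)]
  }
  if (!is.numeric(reference) || reference <= 0)
    stop("undefined conversion: zero initial value")
   1 - series$value[which.min(abs(series$time_min - t))] / reference
}

#' Root mean square error between two aligned series
#'
#' `sqrt(sum((y - y*)^2) / n)` over the common time grid; residuals are
#' taken as given (the convention is to compare normalized series), with no
#' further normalization by the mean.
#'
#' @param measured,simulated Data frames with `time_min` and `value` on the
#'   same time grid (order-insensitive; times must match within 1e-6 min).
#' @return The RMSE (dimensionless for normalized inputs).
#' @examples
#' a <- data.frame(time_min = c(0, 1), value = c(1, 0))
#' b <- data.frame(time_min = c(0, 1), value = c(0, 0))
#' rmse(a, b)  # sqrt(1/2)
#' @export
rmse <- function(measured, simulated) {
  m <- measured[order(measured$time_min), ]
  s <- simulated[order(simulated$time_min), ]
  if (nrow(m) != nrow(s) || any(abs(m$time_min - s$time_min) > 1e-6))
    stop("alignment error: series are not on the same time grid")
  sqrt(mean((m$value - s$value)^2))
}
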