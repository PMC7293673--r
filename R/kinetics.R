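# Rate laws for one well-mixed volume: simplified Fenton / photo-Fenton core,
# hydroxyl-radical elimination, breakage cascade, competitive-rate
# normalization and assembly of the concentration derivatives.
#
# Internal units are mol/L and seconds; all external interfaces use mmol/L
# and minutes.

#' Core (target-independent) rate constants
#'
#' @param k0 Photo-reduction constant (1/s); the irradiance is folded in.
#' @param k1 Fe3+ + H2O2 constant (L/mol/s).
#' @param k2 Fe2+ + H2O2 constant (L/mol/s).
#' @param k_elim First-order inefficient HO* elimination constant (1/s).
#' @return Object of class `core_constants`. Defaults are the constants
#'   estimated from blank assays of the reference pilot plant.
#' @export
core_constants <- function(k0 = 5.6e-2, k1 = 5.0, k2 = 63.0, k_elim = 7.5e-2) {
  stopifnot(k0 >= 0, k1 >= 0, k2 >= 0, k_elim >= 0)
  structure(list(k0 = k0, k1 = k1, k2 = k2, k_elim = k_elim),
            class = "core_constants")
}

#' Target-specific rate constants
#'
#' @param k_target Second-order constant of the first attack on the target
#'   (L/mol/s).
#' @param k_fragment Second-order constant of all subsequent fragment
#'   breakage steps and of the terminal mineralization step (L/mol/s).
#' @return Object of class `target_constants`.
#' @export
target_constants <- function(k_target, k_fragment) {
  stopifnot(k_target >= 0, k_fragment >= 0)
  structure(list(k_target = k_target, k_fragment = k_fragment),
            class = "target_constants")
}

#' Reference target constants for the built-in compounds
#' @param name `"PCT"`, `"SQX"` or `"FA"`.
#' @return A [target_constants()] object.
#' @export
reference_target_constants <- function(name) {
  switch(name,
         PCT = target_constants(15.0e2, 1.5e2),
         SQX = target_constants(4.5e2, 3.5e2),
         FA  = target_constants(65.0e-2, 7.5e-2),
         stop("no reference constants for compound: ", name))
}

#' Species concentration vector for one well-mixed volume
#'
#' Concentrations are in mol/L. `hp`, `ohn` and `h2o` are clamped by the
#' controlled pH (the water dissociation equilibrium is not integrated) and
#' `o2` is carried as an inert constant. `mineral` accumulates mineralized
#' carbon (mol-C/L) and `sink` the HO2* routed out of the mechanism.
#'
#' @param mech A [build_mechanism()] result (fixes the organic species set).
#' @param fe2,fe3,h2o2,r_ho Initial concentrations, mol/L.
#' @param organics Numeric vector of organic concentrations (target then
#'   fragments), mol/L; recycled from the target concentration if length 1.
#' @param pH Controlled pH; sets `hp = 10^-pH`, `ohn = Kw/hp`.
#' @param mineral,sink Cumulative pools, mol/L.
#' @return Named numeric vector of class `species_vector`.
#' @export
species_vector <- function(mech, fe2 = 0, fe3 = 0, h2o2 = 0, r_ho = 0,
                           organics = 0, pH = 2.8, mineral = 0, sink = 0) {
  F_ <- mech$chain$n_fragments
  if (length(organics) == 1L) organics <- c(organics, rep(0, F_))
  stopifnot(length(organics) == F_ + 1L)
  hp <- 10^(-pH)
  fe2 <- unname(fe2); fe3 <- unname(fe3); h2o2 <- unname(h2o2)
  r_ho <- unname(r_ho); organics <- unname(organics)
  mineral <- unname(mineral); sink <- unname(sink)
  x <- c(fe2 = fe2, fe3 = fe3, h2o2 = h2o2, r_ho = r_ho,
         hp = hp, ohn = 1e-14 / hp, h2o = 55.5, o2 = 0,
         setNames(organics, mech$species), mineral = mineral, sink = sink)
  if (any(x < 0)) stop("negative concentration in species vector")
  class(x) <- c("species_vector", "numeric")
  x
}

#' Core Fenton and photo-Fenton rates
#'
#' `r1 = k1 [Fe3+][H2O2]` (Fe3+ reduction by H2O2), `r2 = k2 [Fe2+][H2O2]`
#' (Fenton reaction producing HO*), `r0 = k0 [Fe3+]` under irradiation
#' (photo-reduction, irradiance folded into `k0`), else 0.
#'
#' @param state A [species_vector()].
#' @param k A [core_constants()].
#' @param irradiated Logical.
#' @return List with `r0`, `r1`, `r2` in mol/L/s.
#' @export
core_rates <- function(state, k, irradiated) {
  list(r0 = if (irradiated) k$k0 * state[["fe3"]] else 0,
       r1 = k$k1 * state[["fe3"]] * state[["h2o2"]],
       r2 = k$k2 * state[["fe2"]] * state[["h2o2"]])
}

#' Raw rates of the reactions competing for the hydroxyl radical
#'
#' The competing set is the first-order inefficient elimination
#' (`r_elim = k_elim [HO*]`) plus one second-order breakage rate per organic
#' species (`r_b = k_b [FR_b][HO*]`, with `k_0 = k_target` and
#' `k_b = k_fragment` for `b >= 1`, the last being the terminal
#' mineralization step).
#'
#' @param state A [species_vector()].
#' @param mech A [build_mechanism()] result.
#' @param kt A [target_constants()].
#' @param k_elim Elimination constant (1/s).
#' @return List with `r_elim` (scalar) and `r_b` (length F+1), mol/L/s,
#'   and `normalized = FALSE`.
#' @export
competing_rates <- function(state, mech, kt, k_elim) {
  oh <- state[["r_ho"]]
  kb <- c(kt$k_target, rep(kt$k_fragment, mech$chain$n_fragments))
  list(r_elim = k_elim * oh,
       r_b = unname(kb * state[mech$species] * oh),
       normalized = FALSE)
}

#' Competitive-rate normalization
#'
#' Each member of the HO*-competing set is replaced by its rate-weighted
#' share `r_i^2 / S`, where `S` is the summed rate of all competitors
#' (elimination plus every breakage step). This damps the stiffness of the
#' fast competitive radical reactions: no rate increases, and the faster a
#' competitor is relative to the pool the larger the share it keeps.
#'
#' @param competing Result of [competing_rates()].
#' @return Same shape with `normalized = TRUE`; all zero stays all zero.
#' @export
normalize_competition <- function(competing) {
  S <- competing$r_elim + sum(competing$r_b)
  if (S > 0) {
    competing$r_elim <- competing$r_elim^2 / S
    competing$r_b <- competing$r_b^2 / S
  }
  competing$normalized <- TRUE
  competing
}

#' Assemble species concentration derivatives for one well-mixed volume
#'
#' Iron cycles between Fe2+ and Fe3+ (total iron conserved); H2O2 is consumed
#' by both core reactions (the feed term belongs to the reactor); HO* is
#' produced by the Fenton and photo reactions and consumed by the normalized
#' competing set; each organic balance is `mult * r_{b-1} - r_b`; the
#' terminal step routes `FNC_F * r_F` into the mineralized-carbon pool; HO2*
#' from the Fe3+ reduction goes to the inert sink; pH-clamped species and O2
#' have zero derivative.
#'
#' @param state A [species_vector()].
#' @param core List from [core_rates()].
#' @param competing Normalized list from [normalize_competition()].
#' @param mech A [build_mechanism()] result.
#' @return Named derivative vector (mol/L/s) aligned with `state`.
#' @export
assemble_derivatives <- function(state, core, competing, mech) {
  if (!isTRUE(competing$normalized))
    stop("competing rates must be normalized before assembling derivatives")
  F_ <- mech$chain$n_fragments
  if (length(competing$r_b) != F_ + 1L)
    stop("mechanism/state dimension mismatch")
  d <- setNames(numeric(length(state)), names(state))
  r0 <- core$r0; r1 <- core$r1; r2 <- core$r2
  rb <- competing$r_b
  mult <- mech$chain$doubling
  d["fe3"] <- r2 - r1 - r0
  d["fe2"] <- -d[["fe3"]]
  d["h2o2"] <- -r1 - r2
  d["r_ho"] <- r2 + r0 - competing$r_elim - sum(rb)
  d["target"] <- -rb[1]
  if (F_ > 0)
    d[paste0("f", seq_len(F_))] <- mult * rb[seq_len(F_)] - rb[-1]
  d["mineral"] <- mech$chain$fncs[F_ + 1] * rb[F_ + 1]
  d["sink"] <- r1
  d
}
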