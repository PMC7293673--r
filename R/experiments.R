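# The design-of-experiments registry: blank assays and the factorial grids
# over the Fenton reagents for the three reference compounds. All runs are
# 120 min at pH 2.8, 28 C, 300-420 nm; "irradiated" means the 1.5-L annular
# reactor volume is lit.

.doe_registry <- function() {
  row <- function(id, compound, target0, h2o2, fe2, irr)
    data.frame(id = id, compound = compound, target0 = target0,
               h2o2_0 = h2o2, fe2_0 = fe2, irradiated = irr,
               duration_min = 120, pH = 2.8, temperature_C = 28,
               lambda_nm = "300-420", stringsAsFactors = FALSE)
  grid_pct <- expand.grid(fe2 = c(0.09, 0.13, 0.18),
                          h2o2 = c(2.78, 5.56, 11.12))
  grid_pct <- grid_pct[order(grid_pct$h2o2, grid_pct$fe2), ]
  pct <- do.call(rbind, c(
    lapply(1:9, function(i) row(paste0("EXP", i, "_PCT"), "PCT", 0.26,
                                grid_pct$h2o2[i], grid_pct$fe2[i], FALSE)),
    lapply(1:9, function(i) row(paste0("EXP", i + 9, "_PCT"), "PCT", 0.26,
                                grid_pct$h2o2[i], grid_pct$fe2[i], TRUE))))
  sqx_h <- c(3.47, 5.24, 6.94)
  sqx <- do.call(rbind, c(
    lapply(1:3, function(i) row(paste0("EXP", i, "_SQX"), "SQX", 0.08,
                                sqx_h[i], 0.18, FALSE)),
    lapply(1:3, function(i) row(paste0("EXP", i + 3, "_SQX"), "SQX", 0.08,
                                sqx_h[i], 0.18, TRUE))))
  fa <- rbind(row("EXP1_FA", "FA", 0.87, 0.88, 0.09, FALSE),
              row("EXP2_FA", "FA", 0.87, 1.76, 0.09, FALSE),
              row("EXP3_FA", "FA", 0.87, 0.88, 0.09, TRUE),
              row("EXP4_FA", "FA", 0.87, 1.76, 0.09, TRUE),
              row("EXP5_FA", "FA", 0.87, 4.41, 0.18, TRUE))
  blanks <- rbind(
    row("BLANK_1", NA, 0, 11.12, 0.00, FALSE),
    row("BLANK_2", NA, 0, 11.12, 0.00, TRUE),
    row("BLANK_3", NA, 0, 11.12, 0.18, FALSE),
    row("BLANK_4", NA, 0, 11.12, 0.18, TRUE),
    # reagent-role blanks run with the target compound present
    row("BLANK_5", "PCT", 0.26, 11.12, 0.00, FALSE),
    row("BLANK_6", "PCT", 0.26, 0.00, 0.18, FALSE),
    row("BLANK_7", "PCT", 0.26, 11.12, 0.00, TRUE),
    row("BLANK_8", "PCT", 0.26, 0.00, 0.18, TRUE),
    row("BLANK_9", "PCT", 0.26, 0.00, 0.00, TRUE),
    row("BLANK_10", "SQX", 0.08, 6.94, 0.00, FALSE),
    row("BLANK_11", "SQX", 0.08, 0.00, 0.18, FALSE),
    row("BLANK_12", "SQX", 0.08, 6.94, 0.00, TRUE),
    row("BLANK_13", "SQX", 0.08, 0.00, 0.18, TRUE),
    row("BLANK_14", "SQX", 0.08, 0.00, 0.00, TRUE))
  rbind(blanks, pct, sqx, fa)
}

#' Assay registry (blanks and factorial designs)
#'
#' All assays of the reference study: 14 blanks (the core-mechanism blanks
#' BLANK_1..4 without organics, and per-compound reagent-role blanks run
#' with the target present), the 18-run PCT factorial, the 6-run SQX
#' factorial and the 5 FA runs. Concentrations are mmol/L.
#'
#' @param compound Optional filter: `"PCT"`, `"SQX"`, `"FA"`, or `"blank"`
#'   for the organics-free blanks.
#' @return Data frame, one row per assay.
#' @examples
#' sum(grepl("^EXP", fenton_experiments("PCT")$id))  # the 18-run factorial
#' @export
fenton_experiments <- function(compound = NULL) {
  reg <- .doe_registry()
  if (is.null(compound)) return(reg)
  if (identical(compound, "blank")) return(reg[is.na(reg$compound), ])
  reg[!is.na(reg$compound) & reg$compound == compound, ]
}

#' Resolve a registry id into an experiment object
#'
#' @param id Assay id, e.g. `"EXP13_PCT"` or `"BLANK_3"`.
#' @return A [experiment()] object.
#' @export
as_experiment <- function(id) {
  reg <- .doe_registry()
  i <- match(id, reg$id)
  if (is.na(i)) stop("unknown experiment ID: ", id)
  r <- reg[i, ]
  experiment(id = r$id,
             compound = if (is.na(r$compound)) NULL else r$compound,
             target0 = r$target0, fe2_0 = r$fe2_0, h2o2_0 = r$h2o2_0,
             irradiated = r$irradiated, duration_min = r$duration_min,
             pH = r$pH)
}

#' Measurement sampling grids of the reference assays
#'
#' TOC was sampled every 15 min (instrument cycle time); H2O2 every 5 min up
#' to 30 min and then every 15 min; the target compound on a compound-
#' specific HPLC grid (dense early points for PCT; none for FA, whose single
#' carbon makes target and TOC coincide).
#'
#' @param kind `"target"`, `"TOC"` or `"H2O2"`.
#' @param compound Compound name (needed for `"target"`).
#' @param duration_min Assay length.
#' @return Numeric vector of sampling times in minutes (possibly empty).
#' @export
sampling_grid <- function(kind = c("target", "TOC", "H2O2"), compound = NULL,
                          duration_min = 120) {
  kind <- match.arg(kind)
  g <- switch(kind,
    TOC = seq(0, duration_min, by = 15),
    H2O2 = c(seq(0, min(30, duration_min), by = 5),
             if (duration_min >= 45) seq(45, duration_min, by = 15)),
    target = {
      if (is.null(compound)) stop("target grid needs a compound")
      switch(compound,
             PCT = c(0, 1.5, 2.5, 5, 7.5, 10, 15),
             SQX = c(0, 2, 5, 10, 15, 20, 25, 30, 45, 60, 75, 90, 120),
             FA = numeric(0),
             stop("unknown compound: ", compound))
    })
  g[g <= duration_min]
}
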