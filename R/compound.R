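# Target compounds: molecular formula, carbon count, mineralization
# stoichiometry and stoichiometric oxidant dosing.

.atomic_masses <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999,
                    S = 32.06, Na = 22.990)

#' Parse a Hill-notation molecular formula
#'
#' Supported elements are C, H, N, O, S and Na, which cover the compound
#' classes the mineralization balance can close (carbon to CO2, nitrogen to
#' HNO3, sulfur to H2SO4, sodium to NaOH).
#'
#' @param formula Character scalar, e.g. `"C8H9NO2"`.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C14H11N4NaO2S")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(tokens)) != nchar(formula))
    stop("cannot parse formula: ", formula)
  counts <- integer(0)
  for (tok in tokens) {
    el <- gsub("[0-9]", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(.atomic_masses))
      stop("unsupported element '", el, "' in formula ", formula)
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  counts
}

#' Molar mass of a parsed formula
#' @param counts Named element-count vector as returned by [parse_formula()].
#' @return Molar mass in g/mol.
#' @export
formula_mass <- function(counts) {
  sum(.atomic_masses[names(counts)] * counts)
}

#' Define a target compound
#'
#' A target compound seeds the algorithmic generation of its degradation
#' mechanism: the carbon count `nc` determines the fragmentation cascade and
#' the formula determines the mineralization stoichiometry.
#'
#' @param name Compound name (used for labels and registry lookup).
#' @param formula Hill-notation formula string.
#' @param molar_mass Molar mass in g/mol; defaults to the mass computed from
#'   the formula and must agree with it within 0.5 g/mol.
#' @return Object of class `target_compound` with fields `name`, `formula`
#'   (element counts), `molar_mass` and `nc`.
#' @examples
#' pct <- target_compound("PCT", "C8H9NO2")
#' pct$nc
#' @export
target_compound <- function(name, formula, molar_mass = NULL) {
  counts <- parse_formula(formula)
  if (!"C" %in% names(counts) || counts[["C"]] < 1L)
    stop("invalid compound: formula must contain at least one carbon atom")
  mass <- formula_mass(counts)
  if (is.null(molar_mass)) molar_mass <- mass
  if (abs(molar_mass - mass) > 0.5)
    stop("molar_mass ", molar_mass, " inconsistent with formula mass ",
         round(mass, 3))
  structure(list(name = name, formula = counts,
                 formula_string = formula,
                 molar_mass = molar_mass, nc = counts[["C"]]),
            class = "target_compound")
}

#' @export
print.target_compound <- function(x, ...) {
  cat("Target compound:", x$name, sprintf("(%s)", x$formula_string), "\n")
  cat("  molar mass:", round(x$molar_mass, 3), "g/mol   carbon count:",
      x$nc, "\n")
  cat("  H2O2 for total mineralization:",
      mineralization_stoichiometry(x), "mol/mol\n")
  invisible(x)
}

#' Built-in compound registry
#'
#' The three reference contaminants: paracetamol (PCT), sulfaquinoxaline
#' sodium salt (SQX) and formic acid (FA).
#'
#' @param name Optional compound name; if given, returns that single
#'   [target_compound()].
#' @return A named list of `target_compound` objects, or one compound.
#' @export
fenton_compounds <- function(name = NULL) {
  reg <- list(
    PCT = target_compound("PCT", "C8H9NO2"),
    SQX = target_compound("SQX", "C14H11N4NaO2S"),
    FA  = target_compound("FA", "CH2O2")
  )
  if (is.null(name)) return(reg)
  if (!name %in% names(reg)) stop("unknown compound: ", name)
  reg[[name]]
}

#' Read a compound registry file
#'
#' Plain-text CSV with columns `name`, `formula`, `molar_mass` (the latter
#' may be empty to use the formula mass).
#'
#' @param path File path.
#' @return Named list of [target_compound()] objects.
#' @export
read_compounds <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "formula") %in% names(df)))
  out <- lapply(seq_len(nrow(df)), function(i) {
    mm <- if ("molar_mass" %in% names(df) && !is.na(df$molar_mass[i]))
      df$molar_mass[i] else NULL
    target_compound(df$name[i], df$formula[i], mm)
  })
  names(out) <- df$name
  out
}

#' Moles of H2O2 per mole of compound for total mineralization
#'
#' Balances `compound + x H2O2 -> nC CO2 + nN HNO3 + nS H2SO4 + nNa NaOH +
#' w H2O`, with `w` fixed by the hydrogen balance. The oxygen balance must
#' then close exactly; a formula for which it does not is rejected.
#'
#' @param compound A [target_compound()].
#' @return The stoichiometric coefficient `x` (can be fractional).
#' @examples
#' mineralization_stoichiometry(fenton_compounds("PCT"))  # 21
#' @export
mineralization_stoichiometry <- function(compound) {
  f <- compound$formula
  n <- function(el) if (el %in% names(f)) f[[el]] else 0L
  c_ <- n("C"); h <- n("H"); nn <- n("N"); o <- n("O"); s <- n("S"); na <- n("Na")
  x <- (4 * c_ + h + 5 * nn + 6 * s + na - 2 * o) / 2
  if (x < 0) stop("stoichiometry error: formula ", compound$formula_string,
                  " needs no oxidant (negative H2O2 coefficient)")
  w <- (h + 2 * x - nn - 2 * s - na) / 2
  lhs_o <- o + 2 * x
  rhs_o <- 2 * c_ + 3 * nn + 4 * s + na + w
  if (abs(lhs_o - rhs_o) > 1e-9)
    stop("stoichiometry error: oxygen balance does not close for ",
         compound$formula_string)
  x
}

#' Stoichiometric H2O2 dose for a mass concentration of compound
#'
#' @param compound A [target_compound()].
#' @param conc_mg_per_L Mass concentration of the compound in mg/L.
#' @return H2O2 dose in mmol/L.
#' @examples
#' stoichiometric_dose(fenton_compounds("PCT"), 40)  # ~5.56
#' @export
stoichiometric_dose <- function(compound, conc_mg_per_L) {
  stopifnot(conc_mg_per_L > 0)
  (conc_mg_per_L / compound$molar_mass) * mineralization_stoichiometry(compound)
}
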