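test_that("fragment chains halve the carbon number down the cascade", {
  c8 <- fragment_chain(8)
  expect_equal(c8$fncs, c(8, 4, 2, 1))
  expect_equal(c8$n_fragments, 3L)
  expect_equal(c8$doubling, 2)

  c14 <- fragment_chain(14)
  expect_equal(c14$fncs, c(14, 7, 3.5, 1.75, 0.875))
  expect_equal(c14$n_fragments, 4L)

  c1 <- fragment_chain(1)
  expect_equal(c1$fncs, c(1, 1))
  expect_equal(c1$n_fragments, 1L)
  expect_equal(c1$doubling, 1)

  expect_equal(fragment_chain(2)$fncs, c(2, 1))
})

test_that("chain length brackets log2 of the carbon count and carbon is conserved stepwise", {
  for (nc in 2:64) {
    ch <- fragment_chain(nc)
    F_ <- ch$n_fragments
    expect_true(2^(F_ - 1) < nc && nc <= 2^F_)
    # each breakage makes `doubling` products carrying half the carbon
    expect_equal(ch$doubling * ch$fncs[-1], ch$fncs[-length(ch$fncs)])
    expect_true(all(ch$fncs > 0))
  }
})

test_that("invalid carbon counts are rejected", {
  expect_error(fragment_chain(0), "positive integer")
  expect_error(fragment_chain(2.5), "positive integer")
  expect_error(fragment_chain(-3), "positive integer")
})

test_that("mechanisms have one reaction per breakage plus terminal mineralization", {
  pct <- build_mechanism(fenton_compounds("PCT"))
  expect_equal(nrow(pct$reactions), 4L)
  expect_equal(pct$reactions$role, c("target", rep("fragment", 3)))
  expect_equal(pct$reactions$multiplicity, c(2, 2, 2, 1))
  expect_true(is.na(pct$reactions$product[4]))   # carbon leaves TOC

  sqx <- build_mechanism(fenton_compounds("SQX"))
  expect_equal(nrow(sqx$reactions), 5L)

  fa <- build_mechanism(fenton_compounds("FA"))
  expect_equal(nrow(fa$reactions), 2L)
  expect_equal(fa$reactions$multiplicity, c(1, 1))  # 1:1, no doubling
})

test_that("formula parsing and compound validation work", {
  expect_equal(parse_formula("C8H9NO2"),
               c(C = 8L, H = 9L, N = 1L, O = 2L))
  expect_equal(parse_formula("C14H11N4NaO2S")[["Na"]], 1L)
  expect_error(parse_formula("C8X2"), "unsupported element")
  expect_equal(formula_mass(parse_formula("CH2O2")), 46.041, tolerance = 1e-3)
  expect_error(target_compound("bad", "C8H9NO2", molar_mass = 160),
               "inconsistent")
  expect_error(target_compound("none", "H2O2"), "carbon")
})

test_that("mineralization coefficients match the balanced equations", {
  expect_equal(mineralization_stoichiometry(fenton_compounds("PCT")), 21)
  expect_equal(mineralization_stoichiometry(fenton_compounds("SQX")), 45)
  expect_equal(mineralization_stoichiometry(fenton_compounds("FA")), 1)
})

test_that("oxygen balance closes for random formulas (independent recount)", {
  set.seed(42)
  for (rep in 1:25) {
    counts <- c(C = sample(1:20, 1), H = sample(1:30, 1),
                N = sample(0:4, 1), O = sample(0:6, 1),
                S = sample(0:2, 1), Na = sample(0:1, 1))
    counts <- counts[counts > 0]
    fml <- paste0(names(counts), ifelse(counts > 1, counts, ""),
                  collapse = "")
    cmp <- target_compound("rand", fml)
    x <- mineralization_stoichiometry(cmp)
    # independent recount of every element on both sides
    n <- function(el) if (el %in% names(counts)) counts[[el]] else 0
    w <- (n("H") + 2 * x - n("N") - 2 * n("S") - n("Na")) / 2
    lhs <- c(C = n("C"), H = n("H") + 2 * x, N = n("N"),
             O = n("O") + 2 * x, S = n("S"), Na = n("Na"))
    rhs <- c(C = n("C"),
             H = n("N") + 2 * n("S") + n("Na") + 2 * w,
             N = n("N"),
             O = 2 * n("C") + 3 * n("N") + 4 * n("S") + n("Na") + w,
             S = n("S"), Na = n("Na"))
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("stoichiometric doses reproduce the assay design values", {
  expect_equal(round(stoichiometric_dose(fenton_compounds("PCT"), 40), 2),
               5.56)
  expect_equal(stoichiometric_dose(fenton_compounds("SQX"), 25), 3.47,
               tolerance = 0.03 / 3.47)
  d_fa <- stoichiometric_dose(fenton_compounds("FA"), 40)
  expect_true(d_fa >= 0.865 && d_fa <= 0.885)
})

test_that("the compound registry file reloads into identical compounds", {
  path <- system.file("extdata", "compounds.csv", package = "fentonsim")
  reg <- read_compounds(path)
  expect_named(reg, c("PCT", "SQX", "FA"))
  expect_equal(reg$PCT$nc, 8L)
  expect_equal(reg$SQX$molar_mass, fenton_compounds("SQX")$molar_mass,
               tolerance = 1e-3)
})
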