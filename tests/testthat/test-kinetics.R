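mech_pct <- build_mechanism(fenton_compounds("PCT"))

test_that("core rates follow the bimolecular laws and the photo switch", {
  k <- paper_core()
  s0 <- species_vector(mech_pct)
  r <- core_rates(s0, k, irradiated = TRUE)
  expect_equal(unlist(r), c(r0 = 0, r1 = 0, r2 = 0))

  s <- species_vector(mech_pct, fe2 = 1.8e-4, fe3 = 1e-5, h2o2 = 1.112e-2)
  r <- core_rates(s, k, irradiated = FALSE)
  expect_equal(r$r2, 1.261e-4, tolerance = 1e-3)
  expect_identical(r$r0, 0)
  expect_equal(core_rates(s, k, irradiated = TRUE)$r0, k$k0 * 1e-5)
})

test_that("competing rates scale with radical concentration", {
  kt <- target_constants(pct_truth[["k_target"]], pct_truth[["k_fragment"]])
  s <- species_vector(mech_pct, organics = c(2.6e-4, 0, 0, 0))
  r <- competing_rates(s, mech_pct, kt, k_elim = 7.5e-2)
  expect_true(all(unlist(r[c("r_elim", "r_b")]) == 0))  # no HO*, no rates

  s <- species_vector(mech_pct, r_ho = 1e-6, organics = c(2.6e-4, 0, 0, 0))
  r <- competing_rates(s, mech_pct, kt, k_elim = 7.5e-2)
  expect_equal(r$r_elim, 7.5e-8)
  expect_equal(r$r_b[1], 3.9e-7)
  expect_equal(r$r_b[-1], rep(0, 3))
})

test_that("competition normalization is the rate-weighted share r^2/S", {
  mk <- function(relim, rb) list(r_elim = relim, r_b = rb, normalized = FALSE)
  # single competitor passes through unchanged
  n1 <- normalize_competition(mk(0, c(3e-6, 0, 0, 0)))
  expect_equal(n1$r_b[1], 3e-6)
  # two equal competitors each keep half
  n2 <- normalize_competition(mk(2, c(2, 0, 0, 0)))
  expect_equal(n2$r_elim, 1)
  expect_equal(n2$r_b[1], 1)
  # all-zero in, all-zero out, no NaN
  n0 <- normalize_competition(mk(0, rep(0, 4)))
  expect_equal(c(n0$r_elim, n0$r_b), rep(0, 5))
})

test_that("normalization never increases any competing rate", {
  set.seed(1)
  for (i in 1:50) {
    raw <- mk <- list(r_elim = runif(1, 0, 1e-5),
                      r_b = runif(4, 0, 1e-5) * rbinom(4, 1, 0.7),
                      normalized = FALSE)
    nn <- normalize_competition(raw)
    expect_true(nn$r_elim <= raw$r_elim + 1e-20)
    expect_true(all(nn$r_b <= raw$r_b + 1e-20))
  }
})

test_that("derivatives conserve iron and total carbon for any state", {
  kt <- target_constants(pct_truth[["k_target"]], pct_truth[["k_fragment"]])
  set.seed(2)
  for (i in 1:20) {
    s <- species_vector(mech_pct, fe2 = runif(1, 0, 1e-3),
                        fe3 = runif(1, 0, 1e-3), h2o2 = runif(1, 0, 1e-2),
                        r_ho = runif(1, 0, 1e-6),
                        organics = runif(4, 0, 1e-3))
    core <- core_rates(s, paper_core(), irradiated = (i %% 2 == 0))
    comp <- normalize_competition(
      competing_rates(s, mech_pct, kt, 7.5e-2))
    d <- assemble_derivatives(s, core, comp, mech_pct)
    expect_equal(d[["fe2"]] + d[["fe3"]], 0)
    carbon_rate <- sum(mech_pct$chain$fncs *
                         d[c("target", "f1", "f2", "f3")]) + d[["mineral"]]
    expect_equal(carbon_rate, 0, tolerance = 1e-18)
  }
})

test_that("zero rates give zero derivatives and pH stays clamped", {
  s <- species_vector(mech_pct, fe2 = 1e-4, organics = c(1e-4, 0, 0, 0))
  core <- core_rates(s, core_constants(0, 0, 0, 0), irradiated = TRUE)
  comp <- normalize_competition(
    competing_rates(s, mech_pct, target_constants(0, 0), 0))
  d <- assemble_derivatives(s, core, comp, mech_pct)
  expect_true(all(d == 0))
  expect_equal(s[["hp"]], 10^-2.8)
  expect_equal(s[["ohn"]], 1e-14 / 10^-2.8)
  expect_equal(s[["h2o"]], 55.5)
})

test_that("without breakage constants the organics are inert (blank core)", {
  m <- fenton_model("PCT", target = target_constants(0, 0))
  e <- experiment("x", "PCT", target0 = 0.26, fe2_0 = 0.18, h2o2_0 = 11.12,
                  duration_min = 10)
  traj <- simulate_experiment(m, e, dt = 0.1)
  tgt <- observable_series(traj, "target", compartment = "average")
  expect_equal(tgt$value, rep(0.26, length(tgt$value)), tolerance = 1e-10)
})

test_that("the R reference step and the compiled step agree exactly", {
  set.seed(7)
  m <- fenton_model("PCT")
  plant <- default_plant(TRUE)
  nm <- c("fe2", "fe3", "h2o2", "r_ho", m$mech$species, "mineral", "sink")
  for (rep in 1:10) {
    st <- matrix(runif(4 * length(nm), 0, 1e-3), 4, length(nm),
                 dimnames = list(NULL, nm))
    r_step <- plant_step(st, m, plant, dt = 0.05, feed_rate = 2e-4)
    res <- fentonsim:::simulate_plant_cpp(
      st, plant$volumes, plant$flow / 60, 3,
      m$core$k0, m$core$k1, m$core$k2, m$core$k_elim,
      m$target$k_target, m$target$k_fragment,
      m$mech$chain$fncs, m$mech$chain$doubling,
      1, 2e-4 * 30, 30, 0.05, 1L, 1L, 1L)
    c_step <- matrix(res$states[1, , ], 4)
    expect_equal(unname(r_step), c_step, tolerance = 1e-14)
  }
})
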