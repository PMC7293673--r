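test_that("the assay registry matches the published designs", {
  pct <- fenton_experiments("PCT")
  expect_equal(sum(grepl("^EXP", pct$id)), 18L)   # factorial design
  expect_equal(sum(grepl("^BLANK", pct$id)), 5L)  # reagent-role blanks
  sqx <- fenton_experiments("SQX")
  expect_equal(sum(grepl("^EXP", sqx$id)), 6L)
  expect_equal(sum(grepl("^BLANK", sqx$id)), 5L)
  expect_equal(nrow(fenton_experiments("FA")), 5L)
  expect_equal(nrow(fenton_experiments("blank")), 4L)
  all_ids <- fenton_experiments()$id
  expect_equal(sum(grepl("^BLANK", all_ids)), 14L)
  expect_equal(nrow(fenton_experiments()), 43L)

  e <- as_experiment("EXP13_PCT")
  expect_equal(e$h2o2_0, 5.56)
  expect_equal(e$fe2_0, 0.09)
  expect_true(e$irradiated)
  expect_equal(e$target0, 0.26)
  e1 <- as_experiment("EXP1_PCT")
  expect_equal(c(e1$h2o2_0, e1$fe2_0), c(2.78, 0.09))
  expect_false(e1$irradiated)
  b6 <- as_experiment("BLANK_6")   # catalyst-role blank: PCT, no oxidant
  expect_equal(b6$compound, "PCT")
  expect_equal(b6$h2o2_0, 0)
  expect_error(as_experiment("EXP99_XYZ"), "unknown experiment")
})

test_that("every registry row is loadable and simulable with defaults", {
  reg <- fenton_experiments()
  for (id in reg$id) {
    e <- as_experiment(id)
    e$duration_min <- 2  # shortened probe; full runs are exercised elsewhere
    m <- if (is.null(e$compound)) fenton_model(NULL) else
      fenton_model(e$compound)
    traj <- simulate_experiment(m, e, dt = 0.1)
    expect_true(all(is.finite(traj$states)), label = id)
    expect_true(all(traj$states >= 0), label = id)
  }
})

test_that("series files round-trip through disk", {
  d <- generate_synthetic("EXP1_FA", sigma = 0.05, seed = 3, dt = 0.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_series(d, path)
  back <- read_series(path)
  expect_equal(back$value, d$data$value, tolerance = 1e-12)
  expect_equal(back$kind, d$data$kind)
  bad <- d$data; names(bad)[4] <- "conc"
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, path2, row.names = FALSE)
  expect_error(read_series(path2), "missing column")
})

test_that("trajectory files re-parse to the in-memory values", {
  m <- fenton_model("FA")
  e <- as_experiment("EXP1_FA"); e$duration_min <- 2
  traj <- simulate_experiment(m, e, dt = 0.1, record_every = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- read.csv(path)
  expect_equal(nrow(back),
               length(traj$time_min) * 4 * length(traj$species))
  probe <- back[back$species == "h2o2" & back$compartment == 1, ]
  expect_equal(probe$concentration_mmol_per_L,
               traj$states[, 1, "h2o2"], tolerance = 1e-12)
})

test_that("run configs are validated against the schema", {
  cfg <- validate_run_config(list(dt = 0.1, normalization = "proportional"))
  expect_equal(cfg$dt, 0.1)
  expect_equal(cfg$feed_duration, 30)  # default preserved
  expect_error(validate_run_config(list(timestep = 0.1)), "timestep")
  expect_error(validate_run_config(list(normalization = "other")),
               "normalization")
  expect_error(validate_run_config(list(dt = -1)), "'dt'")
})

test_that("the CLI simulates, reports checkpoints, and is deterministic", {
  out1 <- withr::local_tempdir()
  msg <- capture.output(
    fenton_cli(c("simulate", "--experiment", "EXP1_FA", "--out", out1)))
  expect_true(file.exists(file.path(out1, "EXP1_FA_trajectory.csv")))
  expect_true(file.exists(file.path(out1, "EXP1_FA_series.csv")))
  expect_true(any(grepl("TOC conversion", msg)))
  expect_true(any(grepl("H2O2 consumed", msg)))

  # synth: per-row seeds derived from the master seed, byte-identical reruns
  outa <- withr::local_tempdir(); outb <- withr::local_tempdir()
  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("dt: 0.5", "seed: 11"), cfg)
  suppressMessages({
    fenton_cli(c("synth", "--compound", "FA", "--out", outa,
                 "--config", cfg))
    fenton_cli(c("synth", "--compound", "FA", "--out", outb,
                 "--config", cfg))
  })
  fa <- list.files(outa)
  expect_length(fa, 5L)  # the FA design: five assays, no blanks
  for (f in fa)
    expect_identical(readLines(file.path(outa, f)),
                     readLines(file.path(outb, f)))

  # staged fit ordering is enforced
  expect_error(fenton_cli(c("fit", "--stage", "target", "--data", "x.csv")),
               "ordering error")
  expect_error(fenton_cli(c("nonsense")), "unknown subcommand")
  expect_error(fenton_cli(c("simulate", "--experiment")), "missing value")
})

test_that("the synth subcommand writes the full design of a compound", {
  out <- withr::local_tempdir()
  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("dt: 1.0", "seed: 2"), cfg)
  suppressMessages(
    fenton_cli(c("synth", "--compound", "SQX", "--out", out,
                 "--config", cfg)))
  files <- list.files(out)
  expect_length(files, 6L + 5L)  # 6 assays + 5 reagent-role blanks
  expect_true(all(paste0(fenton_experiments("SQX")$id, ".csv") %in% files))
  one <- read_series(file.path(out, "EXP2_SQX.csv"))
  expect_true(all(c("TOC", "H2O2") %in% one$kind))
})
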