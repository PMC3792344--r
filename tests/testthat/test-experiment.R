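test_that("conditions map onto configurations that differ only as named", {
  base <- default_config()
  ref <- condition_config("static_gradient", base)
  d10 <- condition_config("dwell_x10", base)
  expect_equal(d10$field$dwell_mean, 10 * ref$field$dwell_mean)
  d10$field$dwell_mean <- ref$field$dwell_mean
  d10$condition <- ref$condition
  expect_equal(d10, ref)   # nothing else moved
  eoff <- condition_config("entropy_off_gradient", base)
  expect_false(eoff$interchain_exclusion)
  eoff$interchain_exclusion <- TRUE
  eoff$condition <- ref$condition
  expect_equal(eoff, ref)
  sw <- condition_config("steepness_sweep", base, steepness = 0.5)
  expect_equal(sw$field$steepness, 0.5)
  nt <- condition_config("no_tether", base)
  expect_equal(nt$field$mode, "none")
  un <- condition_config("uniform", base)
  expect_equal(un$field$mode, "uniform")
  mp <- condition_config("mind_profile", base)
  expect_s3_class(mp$field$profile, "min_profile_series")
  ## the synthetic profile's full oscillation spans 2 * period MCS
  expect_equal(mp$field$mcs_per_second * base$mind_period_s, 2 * base$period)
  expect_error(condition_config("nonsense", base), "unknown condition")
})

test_that("run_experiment is reproducible and writes a full manifest", {
  dir1 <- tempfile(); dir2 <- tempfile()
  spec <- function(d) experiment_spec("no_tether", n_replicates = 2,
                                      seed_base = 7, n_mcs = 500,
                                      base = within(default_config(),
                                                    n_mix <- 100),
                                      record_every = 100, output_dir = d)
  e1 <- run_experiment(spec(dir1))
  e2 <- run_experiment(spec(dir2))
  expect_equal(e1$finals, e2$finals)
  expect_equal(e1$finals$seed, c(8, 9))   # seed_base + replicate index
  ## outputs are byte-identical across reruns
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  expect_setequal(c("run_001.csv", "run_002.csv", "finals.csv",
                    "manifest.json", "ensemble.json"), list.files(dir1))
  man <- jsonlite::read_json(file.path(dir1, "manifest.json"))
  expect_equal(man$condition, "no_tether")
  expect_equal(unlist(man$seeds), c(8, 9))
  expect_equal(man$n_mcs, 500)
  expect_true(!is.null(man$config_hash))
})

test_that("dwell_x10 manifests exactly a tenfold dwell time", {
  d <- tempfile()
  e <- run_experiment(experiment_spec("dwell_x10", n_replicates = 2,
                                      seed_base = 1, n_mcs = 200,
                                      base = within(default_config(),
                                                    n_mix <- 100),
                                      record_every = 0, output_dir = d))
  man <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_equal(man$field$dwell_mean, 10 * default_config()$dwell_mean)
})

test_that("condition comparison detects planted orderings", {
  set.seed(40)
  a <- fake_ensemble(pmin(0.45, abs(rnorm(40, 0.30, 0.05))), condition = "hi")
  b <- fake_ensemble(pmin(0.45, abs(rnorm(40, 0.15, 0.05))), condition = "lo")
  cmp <- compare_conditions(a, b)
  row_ab <- cmp[cmp$a == "hi" & cmp$b == "lo", ]
  expect_true(row_ab$significant)
  expect_gt(row_ab$effect, 0)
  row_ba <- cmp[cmp$a == "lo" & cmp$b == "hi", ]
  expect_false(row_ba$significant)
  ## identical ensembles: no significant difference either way
  set.seed(41)
  x <- fake_ensemble(abs(rnorm(40, 0.2, 0.05)), condition = "x")
  same <- compare_conditions(x, x)
  expect_false(any(same$significant))
  ## mismatched configurations are refused
  y <- fake_ensemble(abs(rnorm(40, 0.2, 0.05)), condition = "y",
                     n_mcs = 999)
  expect_error(compare_conditions(x, y), "different base configurations")
})

test_that("time to half separation reads the trace correctly", {
  tr1 <- data.frame(mcs = c(0, 100, 200, 300),
                    cm_rel_1 = c(0, -0.05, -0.2, -0.3),
                    cm_rel_2 = c(0, 0.05, 0.2, 0.3))
  tr2 <- data.frame(mcs = c(0, 100, 200, 300),
                    cm_rel_1 = c(0, 0, -0.05, -0.05),
                    cm_rel_2 = c(0, 0, 0.05, 0.05))
  ens <- structure(list(traces = list(tr1, tr2)), class = "seg_ensemble")
  expect_equal(time_to_half_separation(ens, 0.2), c(200, Inf))
})

test_that("run configs round-trip through flat YAML", {
  cfg <- default_config()
  cfg$p_max <- 0.07; cfg$n_mcs <- 12345
  path <- tempfile(fileext = ".yaml")
  write_run_config(cfg, path)
  back <- read_run_config(path)
  expect_equal(back[order(names(back))], cfg[order(names(cfg))])
  writeLines(c("p_max: 0.1", "bogus_key: 3"), path)
  expect_error(read_run_config(path), "unknown config keys")
})

test_that("fixture bundle is deterministic and self-consistent", {
  d1 <- tempfile(); d2 <- tempfile()
  generate_fixtures(d1, seed = 3)
  generate_fixtures(d2, seed = 3)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  ## each fixture passes its module validator
  st <- read_state(file.path(d1, "ring4_state.tsv"))
  expect_silent(validate_state(st))
  ## the ring-of-4 uses hand-checkable (2,0,0)-family bonds
  bonds <- st$pos[c(2:4, 1), ] - st$pos
  expect_true(all(bond_allowed(bonds)))
  expect_true(all(rowSums(bonds^2) == 4))
  prof <- read_min_profile(file.path(d1, "min_profile_2frame.tsv"))
  expect_equal(dim(prof$intensities), c(2L, 10L))
  tg <- utils::read.csv(file.path(d1, "two_gaussian_profile.csv"))
  sep <- nucleoid_separation(tg$position, tg$intensity)
  expect_equal(sep$n_nucleoids, 2L)
  tracks <- utils::read.csv(file.path(d1, "brownian_tracks.csv"))
  expect_equal(length(unique(tracks$track_id)), 100L)
  expect_s3_class(msd_curve(tracks, max_lag = 5), "data.frame")
})
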