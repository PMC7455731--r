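test_that("the simulator is deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 33, n_compounds = 30)
  lib1 <- simulate_library(cfg); lib2 <- simulate_library(cfg)
  expect_identical(lib1$truth, lib2$truth)
  expect_identical(lib1$compounds$id, lib2$compounds$id)
  r1 <- simulate_records(lib1, cfg); r2 <- simulate_records(lib2, cfg)
  expect_identical(r1, r2)
  s1 <- simulate_spectra(lib1, cfg); s2 <- simulate_spectra(lib2, cfg)
  expect_identical(s1$reference, s2$reference)
  expect_error(simulate_library(simulation_config(n_compounds = 10000)),
               "exceeds the bundled structure list")
})

test_that("zero jitter puts every compound exactly on its class power law", {
  cfg <- simulation_config(jitter_sd_pct = 0, seed = 12)
  lib <- simulate_library(cfg)
  cp <- cfg$class_params
  ci <- match(lib$compounds$superclass[match(lib$truth$compound_id,
                                             lib$compounds$id)],
              cp$superclass)
  expect_equal(lib$truth$ccs_true,
               cp$a[ci] * lib$truth$mz^cp$b[ci], tolerance = 1e-12)
})

test_that("noise-free, bias-free records reproduce the truth through unify", {
  cfg <- simulation_config(jitter_sd_pct = 1, noise_sd_pct = 0,
                           lab_bias_sd_pct = 0, outlier_rate = 0,
                           replicate_rate = 0, seed = 13)
  lib <- simulate_library(cfg)
  rec <- simulate_records(lib, cfg)
  expect_equal(rec$ccs, rec$ccs_true)
  res <- unify_ccs(rec, lib$compounds)
  # no faults injected: nothing removed at the trend-line stage
  expect_equal(sum(res$removed$stage == "trendline"), 0L)
  key <- paste(res$unified$compound_id, res$unified$adduct)
  tkey <- paste(lib$truth$compound_id, lib$truth$adduct)
  expect_equal(res$unified$unified_ccs,
               lib$truth$ccs_true[match(key, tkey)], tolerance = 1e-12)
})

test_that("records carry exact theoretical m/z unless faults are injected", {
  sim <- fix_sim()
  rec <- simulate_records(sim$lib, sim$cfg)
  comp <- sim$lib$compounds
  theo <- comp$mass[match(rec$compound_id, comp$id)] +
    adduct_table()$mass_shift[match(rec$adduct, adduct_table()$name)]
  expect_equal(rec$mz, theo, tolerance = 1e-12)
})

test_that("undegraded spectra score 1 and fully dropped spectra score 0", {
  sim <- fix_sim()
  clean <- simulate_spectra(sim$lib, sim$cfg, dropout_rate = 0,
                            intensity_noise_sd = 0, contaminant_rate = 0)
  for (i in sample(length(clean$reference), 10))
    expect_equal(msms_score(clean$experimental[[i]], clean$reference[[i]]), 1)
  gone <- simulate_spectra(sim$lib, sim$cfg, dropout_rate = 1,
                           contaminant_rate = 0)
  scores <- vapply(seq_along(gone$reference), function(i)
    msms_score(gone$experimental[[i]], gone$reference[[i]]), 0)
  expect_true(all(scores == 0))
})

test_that("degraded spectra match an independently coded oracle", {
  sim <- fix_sim()
  spec <- simulate_spectra(sim$lib, sim$cfg, dropout_rate = 0.2)
  # oracle: plain weighted cosine over reference peaks with sqrt weights,
  # greedy nearest alignment within 25 ppm
  oracle <- function(ex, rf) {
    m <- vapply(seq_len(nrow(rf$peaks)), function(i) {
      d <- abs(ex$peaks[, 1] - rf$peaks[i, 1])
      j <- which.min(d)
      if (d[j] <= max(rf$peaks[i, 1] * 25e-6, 0.002)) ex$peaks[j, 2] else 0
    }, 0)
    if (all(m == 0)) return(0)
    a <- sqrt(rf$peaks[, 2]); b <- sqrt(m)
    sum(a * b)^2 / (sum(a^2) * sum(b^2))
  }
  for (i in sample(length(spec$reference), 15)) {
    ex <- spec$experimental[[i]]; rf <- spec$reference[[i]]
    expect_equal(msms_score(ex, rf), oracle(ex, rf))
  }
})
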