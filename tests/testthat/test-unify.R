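test_that("within-dataset merge follows the 0.5% consistency rule", {
  # diff = (max-min)/mean*100: {200.0, 200.8} -> 0.399% -> merged mean
  r <- rbind(rec_row("a", "c1", 200.0), rec_row("b", "c1", 200.8))
  out <- merge_within_dataset(r)
  expect_equal(nrow(out$kept), 1L)
  expect_equal(out$kept$ccs, 200.4)
  expect_equal(out$kept$source_record_ids[[1]], c("a", "b"))
  expect_equal(nrow(out$removed), 0L)

  # {200.0, 201.2} -> 0.598% -> both removed
  r2 <- rbind(rec_row("a", "c1", 200.0), rec_row("b", "c1", 201.2))
  out2 <- merge_within_dataset(r2)
  expect_equal(nrow(out2$kept), 0L)
  expect_setequal(out2$removed$record_id, c("a", "b"))
  expect_true(all(out2$removed$stage == "intra-dataset"))

  # singleton passes through unchanged
  out3 <- merge_within_dataset(rec_row("a", "c1", 150))
  expect_equal(out3$kept$ccs, 150)
  expect_equal(nrow(out3$removed), 0L)
})

test_that("quality check removes structureless, off-whitelist and bad-m/z records", {
  comp <- compound_table(data.frame(id = "c1", smiles = "CCO"))
  theo <- compute_adduct_mz(comp$mass, "[M+H]+")
  wl <- adduct_table(training = TRUE)
  r <- rbind(
    rec_row("ok",    "c1", 120, mz = theo),
    rec_row("nomz",  "c1", 121),                            # passes m/z check
    rec_row("badmz", "c1", 122, mz = theo * (1 + 15e-6)),   # 15 ppm
    rec_row("nostr", "cX", 123, mz = theo),                 # unknown compound
    rec_row("badad", "c1", 124, adduct = "[M+K]+"))         # not in whitelist
  out <- quality_filter(r, comp, adducts = wl)
  expect_setequal(out$kept$record_id, c("ok", "nomz"))
  expect_equal(out$removed$reason[out$removed$record_id == "badmz"],
               "m/z error > 10 ppm")
  expect_equal(out$removed$reason[out$removed$record_id == "nostr"],
               "no chemical structure")
  expect_equal(out$removed$reason[out$removed$record_id == "badad"],
               "adduct not in whitelist")
  expect_true(all(out$removed$stage == "quality"))
})

test_that("clean simulated batches pass the quality check untouched", {
  sim <- fix_sim()
  rec <- simulate_records(sim$lib, sim$cfg)
  out <- quality_filter(rec, sim$lib$compounds)
  expect_equal(nrow(out$kept), nrow(rec))
  expect_equal(nrow(out$removed), 0L)
})

test_that("trend-line removal flags exactly the displaced record", {
  # 30 ions exactly on 8.5 * mz^0.52 with tiny noise; one displaced +25%
  set.seed(42)
  comp <- fix_sim()$lib$compounds
  fa <- comp[comp$superclass == "Fatty acyls", ][1:15, ]
  bz <- comp[comp$superclass == "Benzenoids", ][1:15, ]
  cc <- rbind(fa, bz); cc$superclass <- "OneClass"
  mz <- compute_adduct_mz(cc$mass, "[M+H]+")
  ccs <- 8.5 * mz^0.52 * (1 + rnorm(30, 0, 0.001))
  ccs[7] <- ccs[7] * 1.25
  r <- do.call(rbind, lapply(seq_len(30), function(i)
    rec_row(paste0("r", i), cc$id[i], ccs[i])))
  out <- remove_trendline_outliers(r, cc)
  expect_equal(out$removed$record_id, "r7")
  expect_equal(out$removed$stage, "trendline")

  # independently coded OLS prediction-interval oracle on the log-log fit
  x <- log(mz); y <- log(ccs); n <- length(x)
  b <- cov(x, y) / var(x); a <- mean(y) - b * mean(x)
  res <- y - (a + b * x)
  s2 <- sum(res^2) / (n - 2)
  half <- qt(0.995, n - 2) *
    sqrt(s2 * (1 + 1 / n + (x - mean(x))^2 / ((n - 1) * var(x))))
  expect_equal(which(abs(res) > half), 7L)
})

test_that("small or degenerate classes are not screened", {
  comp <- fix_sim()$lib$compounds[1:9, ]
  comp$superclass <- "Tiny"
  ccs <- c(500, rep(150, 8))   # wild value, but n = 9 < 10
  r <- do.call(rbind, lapply(1:9, function(i)
    rec_row(paste0("r", i), comp$id[i], ccs[i])))
  out <- remove_trendline_outliers(r, comp)
  expect_equal(nrow(out$removed), 0L)
})

test_that("unified values average with drift-tube priority", {
  # DTIM records win: mean(195.3, 195.7) = 195.5, TWIM ignored for the value
  r <- rbind(rec_row("a", "c1", 195.3, "DS1", instrument = "DTIM"),
             rec_row("b", "c1", 195.7, "DS2", instrument = "DTIM"),
             rec_row("c", "c1", 199.0, "DS3", instrument = "TWIM"))
  u <- compute_unified_ccs(r)
  expect_equal(u$unified_ccs, 195.5)
  expect_equal(u$n_datasets, 3L)
  expect_equal(u$n_dtim_datasets, 2L)
  # no DTIM: plain mean over platforms
  r2 <- rbind(rec_row("a", "c1", 210.0, "DS1", instrument = "TWIM"),
              rec_row("b", "c1", 212.0, "DS2", instrument = "TIMS"))
  expect_equal(compute_unified_ccs(r2)$unified_ccs, 211.0)
  # singleton
  expect_equal(compute_unified_ccs(rec_row("a", "c1", 150))$unified_ccs, 150)
  # bounded by sources, permutation invariant
  u3 <- compute_unified_ccs(r[c(3, 1, 2), ])
  expect_equal(u3$unified_ccs, u$unified_ccs)
})

test_that("confidence cascade maps the worked examples", {
  grid <- data.frame(n_datasets = c(2, 2, 2, 1),
                     n_dtim_datasets = c(2, 1, 0, 1),
                     max_diff_pct = c(0.8, 2.0, 3.5, 0))
  expect_equal(assign_confidence(grid)$level, c("1", "2", "Conflict", "3"))
  # >=2 DTIM datasets but 1% < diff <= 3% falls through to Level 2
  edge <- data.frame(n_datasets = 2, n_dtim_datasets = 2, max_diff_pct = 2)
  expect_equal(assign_confidence(edge)$level, "2")
})

test_that("the full pipeline conserves every input record", {
  sim <- fix_sim()
  rec <- simulate_records(sim$lib, sim$cfg)
  res <- unify_ccs(rec, sim$lib$compounds)
  src <- unname(unlist(res$unified$source_record_ids))
  expect_equal(sort(c(src, res$removed$record_id)), sort(rec$record_id))
  expect_equal(anyDuplicated(c(src, res$removed$record_id)), 0L)
  # unified values bounded by their sources
  for (i in sample(nrow(res$unified), 20)) {
    ccs <- rec$ccs[rec$record_id %in% res$unified$source_record_ids[[i]]]
    expect_gte(res$unified$unified_ccs[i], min(ccs))
    expect_lte(res$unified$unified_ccs[i], max(ccs))
  }
})
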