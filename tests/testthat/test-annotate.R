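test_that("tolerance objects validate their invariants", {
  tol <- match_tolerances()
  expect_equal(tol$ppm, 25); expect_equal(tol$tol_min, 2)
  expect_equal(tol$tol_max, 4); expect_equal(tol$w_ccs + tol$w_msms, 1)
  expect_error(match_tolerances(w_ccs = 0.5, w_msms = 0.6), "sum to 1")
  tol2 <- match_tolerances(w_ccs = 0.5, w_msms = 0.6,
                           allow_unnormalized = TRUE)
  expect_equal(tol2$w_msms, 0.6)
  expect_error(match_tolerances(tol_min = 5, tol_max = 4))
})

test_that("relative CCS error follows its definition", {
  expect_equal(delta_rela(204, 200), 2)
  expect_equal(delta_rela(200, 200), 0)
  expect_equal(delta_rela(190, 200), 5)
  expect_error(delta_rela(-1, 200), "positive")
})

test_that("the trapezoid score hits its branch values and boundaries", {
  expect_equal(ccs_match_score(1), 1)
  expect_equal(ccs_match_score(3), 0.5)
  expect_equal(ccs_match_score(5), 0)
  expect_equal(ccs_match_score(2), 1)    # inner boundary continuous
  expect_equal(ccs_match_score(4), 0)    # outer boundary continuous
  # degenerate equal tolerances become a step, not a division error
  step <- match_tolerances(tol_min = 3, tol_max = 3)
  expect_equal(ccs_match_score(c(2.9, 3, 3.1), step), c(1, 1, 0))
})

test_that("score integration reproduces worked values", {
  expect_equal(integrated_score(1, 1), 1)
  expect_equal(integrated_score(1, 0), 0.3)
  expect_equal(integrated_score(0, 1), 0.7)
  expect_equal(integrated_score(0.5, 0.5), 0.5)
  expect_error(integrated_score(1.5, 0))
})

test_that("reverse dot-product scores match an independent weighted cosine", {
  ref <- spectrum(c(100, 150, 200), c(100, 50, 10), 250)
  # experimental carries the first two peaks, misses the third
  exp1 <- spectrum(c(100, 150), c(100, 50), 250)
  a <- sqrt(c(100, 50, 10)); b <- sqrt(c(100, 50, 0))
  oracle <- sum(a * b)^2 / (sum(a^2) * sum(b^2))
  expect_equal(msms_score(exp1, ref), oracle)
  expect_equal(oracle, 0.9375)
  # identical spectra: 1; disjoint: 0
  expect_equal(msms_score(ref, ref), 1)
  expect_equal(msms_score(spectrum(c(300, 310), c(5, 5), 320), ref), 0)
  # experimental-only peaks are ignored (reverse semantics)
  exp2 <- spectrum(c(100, 150, 200, 231.3), c(100, 50, 10, 500), 250)
  expect_equal(msms_score(exp2, ref), 1)
})

test_that("external MS/MS scores are min-max rescaled within a candidate set", {
  expect_equal(rescale_scores(c(10, 55, 100)), c(0, 0.5, 1))
  expect_equal(rescale_scores(c(7, 7, 7)), c(1, 1, 1))
  expect_equal(rescale_scores(numeric()), numeric())
})

test_that("m/z retrieval matches a brute-force linear scan", {
  sim <- fix_sim()
  bm <- simulate_annotation_benchmark(sim$lib, sim$cfg, n_features = 20)
  tol <- match_tolerances()
  for (i in sample(nrow(bm$features), 5)) {
    f <- bm$features[i, ]
    hits <- match_mz(f$mz, f$polarity, bm$database)
    # oracle: scan every row, recompute the adduct m/z and the ppm error
    oracle <- vapply(seq_len(nrow(bm$database)), function(j) {
      row <- bm$database[j, ]
      if (row$adduct != "[M+H]+") return(FALSE)
      theo <- row$mass + get_adduct("[M+H]+")$mass_shift
      abs(f$mz - theo) / theo * 1e6 <= tol$ppm
    }, TRUE)
    expect_setequal(hits$id, bm$database$id[oracle])
    expect_true(all(hits$ppm_error <= tol$ppm))
  }
  # exact hit has zero ppm error; 30 ppm away is excluded
  db <- data.frame(id = "c1", name = "x", mass = 200, adduct = "[M+H]+",
                   ccs = 150, ccs_source = "unified-1")
  theo <- compute_adduct_mz(200, "[M+H]+")
  expect_equal(match_mz(theo, "+", db)$ppm_error, 0)
  expect_equal(nrow(match_mz(theo * (1 + 30e-6), "+", db)), 0L)
  expect_error(match_mz(100, "+", db[0, ]), "empty")
})

test_that("a planted true candidate outranks decoys", {
  theo <- compute_adduct_mz(300, "[M+H]+")
  db <- data.frame(
    id = c("true", "dec1", "dec2"), name = c("true", "dec1", "dec2"),
    mass = c(300, 300 + 2e-3, 300 - 1.5e-3), adduct = "[M+H]+",
    ccs = c(180, 195, 168), ccs_source = "unified-1",
    stringsAsFactors = FALSE)
  ref <- spectrum(c(90, 120, 161), c(100, 60, 30), theo)
  db_spectra <- list(true = ref,
                     dec1 = spectrum(c(70, 95), c(50, 50), theo),
                     dec2 = spectrum(c(88, 133), c(80, 20), theo))
  feature <- list(mz = theo, polarity = "+", ccs = 180.5, spectrum = ref)
  out <- rank_candidates(feature, db, db_spectra)
  expect_equal(out$id[out$rank == 1], "true")
  # decoys beyond the outer CCS tolerance are filtered before scoring
  expect_false("dec1" %in% out$id)   # delta ~ 8% > 4%
  stages <- attr(out, "stage_counts")
  expect_equal(unname(stages["mz"]), 3)
  expect_lte(stages["ccs"], stages["mz"])
})

test_that("disabling a dimension can only widen the candidate set", {
  sim <- fix_sim()
  bm <- simulate_annotation_benchmark(sim$lib, sim$cfg, n_features = 20)
  with_ccs <- annotate_features(bm$features, bm$database,
                                spectra = bm$spectra,
                                db_spectra = bm$db_spectra, use_ccs = TRUE)
  without <- annotate_features(bm$features, bm$database,
                               spectra = bm$spectra,
                               db_spectra = bm$db_spectra, use_ccs = FALSE)
  m <- merge(with_ccs$stages, without$stages, by = "feature_id",
             suffixes = c("_ccs", "_no"))
  expect_true(all(m$ccs_ccs <= m$ccs_no))
})

test_that("feature ids of the MxTyCz convention round-trip", {
  id <- feature_id(384.1129, 767, 181.9)
  expect_equal(id, "M384T767C182")
  parsed <- parse_feature_id(id)
  expect_equal(parsed$mz, 384)
  expect_equal(parsed$rt, 767)
  expect_equal(parsed$ccs, 182)
  expect_error(parse_feature_id("X12Y3"), "malformed")
})
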