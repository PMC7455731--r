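# Shared, lazily built fixtures (one simulator draw reused across files).

.fixture_cache <- new.env(parent = emptyenv())

fix_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    cfg <- simulation_config(seed = 101)
    lib <- simulate_library(cfg)
    .fixture_cache$sim <- list(cfg = cfg, lib = lib)
  }
  .fixture_cache$sim
}

# library over all nine positive adducts (training-scale fixture)
fix_sim_pos <- function() {
  if (is.null(.fixture_cache$sim_pos)) {
    cfg <- simulation_config(adducts = adduct_table(polarity = "+")$name,
                             seed = 202)
    lib <- simulate_library(cfg)
    .fixture_cache$sim_pos <- list(cfg = cfg, lib = lib)
  }
  .fixture_cache$sim_pos
}

# hand-built record table row
rec_row <- function(record_id, compound_id, ccs, dataset_id = "DS1",
                    adduct = "[M+H]+", instrument = "DTIM", polarity = "+",
                    mz = NA_real_, lab_id = dataset_id) {
  data.frame(record_id = record_id, compound_id = compound_id,
             adduct = adduct, ccs = ccs, mz = mz, dataset_id = dataset_id,
             lab_id = lab_id, instrument = instrument, polarity = polarity,
             stringsAsFactors = FALSE)
}

# independent brute-force tanimoto for the oracle comparisons
oracle_tanimoto <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  n_ab <- sum(a & b)
  denom <- sum(a) + sum(b) - n_ab
  if (denom == 0) 1 else n_ab / denom
}
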