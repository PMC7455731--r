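#' @title Deterministic pipeline simulator
#' @name simulate
#' @description Generates synthetic but structurally realistic fixtures for
#'   every pipeline stage: a compound library of real structures with
#'   class-specific power-law CCS ground truth (CCS = a * m/z^b, the same
#'   mass-mobility structure the trend-line outlier removal assumes),
#'   multi-laboratory record tables with configurable lab biases, replicate
#'   noise and injected outliers, toy fragment spectra with degraded
#'   experimental copies, and a decoy annotation benchmark. All draws are
#'   reproducible from the config seed.
NULL

#' Simulator configuration
#'
#' Defaults describe a plausible small-molecule study: four datasets (two
#' drift-tube, one travelling-wave, one trapped ion mobility), per-dataset
#' calibration biases of ~0.5%, replicate measurement noise of 0.3%, 2% of
#' records displaced by 25% (gross outliers), and compound-level deviations
#' of 2% around the class trend.
#'
#' @param n_compounds number of library compounds (default: all bundled
#'   structures).
#' @param adducts adduct names simulated per compound.
#' @param class_params data.frame (`superclass`, `a`, `b`) of power-law
#'   coefficients; defaults span CCS ~110-260 Angstrom^2 over the library
#'   mass range.
#' @param jitter_sd_pct compound-level deviation around the class trend (%).
#' @param noise_sd_pct replicate measurement noise (%).
#' @param lab_bias_sd_pct across-dataset calibration bias (%).
#' @param outlier_rate fraction of dataset-level measurements displaced.
#' @param outlier_magnitude_pct displacement magnitude (%).
#' @param n_datasets,instruments dataset count and instrument labels.
#' @param coverage probability a dataset measured a given ion.
#' @param replicate_rate probability of a duplicate record within a dataset.
#' @param seed integer seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_compounds = NULL,
                              adducts = c("[M+H]+", "[M-H]-"),
                              class_params = NULL,
                              jitter_sd_pct = 2, noise_sd_pct = 0.3,
                              lab_bias_sd_pct = 0.5,
                              outlier_rate = 0.02,
                              outlier_magnitude_pct = 25,
                              n_datasets = 4,
                              instruments = c("DTIM", "DTIM", "TWIM", "TIMS"),
                              coverage = 0.8, replicate_rate = 0.3,
                              seed = 1) {
  if (is.null(class_params))
    class_params <- data.frame(
      superclass = c("Amino acids and derivatives", "Carbohydrates",
                     "Fatty acyls", "Nucleosides and analogues", "Benzenoids"),
      a = c(9.0, 8.0, 10.5, 8.5, 9.5),
      b = c(0.50, 0.52, 0.50, 0.51, 0.48),
      stringsAsFactors = FALSE)
  stopifnot(outlier_rate >= 0, outlier_rate <= 1,
            coverage >= 0, coverage <= 1,
            replicate_rate >= 0, replicate_rate <= 1,
            length(instruments) == n_datasets)
  structure(list(n_compounds = n_compounds, adducts = adducts,
                 class_params = class_params,
                 jitter_sd_pct = jitter_sd_pct, noise_sd_pct = noise_sd_pct,
                 lab_bias_sd_pct = lab_bias_sd_pct,
                 outlier_rate = outlier_rate,
                 outlier_magnitude_pct = outlier_magnitude_pct,
                 n_datasets = n_datasets, instruments = instruments,
                 coverage = coverage, replicate_rate = replicate_rate,
                 seed = seed),
            class = "simulation_config")
}

#' Simulate a compound library with CCS ground truth
#'
#' Draws structures from the bundled catalogue of real small molecules and
#' assigns every compound x adduct a ground-truth CCS from its super class
#' power law `a * (m/z)^b` times a compound-level log-normal jitter.
#'
#' @param config [simulation_config()].
#' @return list with `compounds` (validated compound table incl.
#'   `superclass`) and `truth` (data.frame `compound_id`, `adduct`,
#'   `polarity`, `mz`, `ccs_true`).
#' @export
simulate_library <- function(config = simulation_config()) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  catalog <- .sim_structure_catalog()
  n <- config$n_compounds
  if (!is.null(n)) {
    if (n > nrow(catalog))
      stop("n_compounds exceeds the bundled structure list (", nrow(catalog), ")")
    catalog <- catalog[sort(sample(nrow(catalog), n)), , drop = FALSE]
  }
  compounds <- compound_table(catalog)
  adducts <- adduct_table()
  cp <- config$class_params
  rows <- expand.grid(i = seq_len(nrow(compounds)),
                      adduct = config$adducts,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ai <- match(rows$adduct, adducts$name)
  mz <- compounds$mass[rows$i] + adducts$mass_shift[ai]
  ci <- match(compounds$superclass[rows$i], cp$superclass)
  if (anyNA(ci)) stop("missing class_params for some super class")
  jitter <- exp(stats::rnorm(nrow(rows), 0, config$jitter_sd_pct / 100))
  truth <- data.frame(
    compound_id = compounds$id[rows$i],
    adduct = rows$adduct,
    polarity = adducts$polarity[ai],
    mz = mz,
    ccs_true = cp$a[ci] * mz^cp$b[ci] * jitter,
    stringsAsFactors = FALSE)
  list(compounds = compounds, truth = truth)
}

#' Simulate multi-laboratory CCS records
#'
#' For every ground-truth ion and dataset (with probability `coverage`):
#' one or two replicate records with value
#' `truth * (1 + lab bias) * (1 + noise)`; a fraction `outlier_rate` of
#' dataset-level measurements is displaced by `+/- outlier_magnitude_pct`
#' (both replicates, so the fault survives the within-dataset merge and must
#' be caught by the trend line). Fault labels are retained for oracle tests.
#'
#' @param library output of [simulate_library()].
#' @param config [simulation_config()].
#' @return CCS record table (see [unify]) with extra columns `is_outlier`
#'   and `ccs_true`.
#' @export
simulate_records <- function(library, config = simulation_config()) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1L)
  truth <- library$truth
  biases <- stats::rnorm(config$n_datasets, 0, config$lab_bias_sd_pct / 100)
  labs <- paste0("lab", rep(seq_len(max(1L, ceiling(config$n_datasets / 2))),
                            length.out = config$n_datasets))
  out <- list()
  for (d in seq_len(config$n_datasets)) {
    take <- stats::runif(nrow(truth)) < config$coverage
    if (!any(take)) next
    t_d <- truth[take, , drop = FALSE]
    displaced <- stats::runif(nrow(t_d)) < config$outlier_rate
    sign <- sample(c(-1, 1), nrow(t_d), replace = TRUE)
    level <- t_d$ccs_true * (1 + biases[d]) *
      ifelse(displaced, 1 + sign * config$outlier_magnitude_pct / 100, 1)
    nrep <- 1L + stats::rbinom(nrow(t_d), 1L, config$replicate_rate)
    idx <- rep(seq_len(nrow(t_d)), nrep)
    ccs <- level[idx] * (1 + stats::rnorm(length(idx), 0,
                                          config$noise_sd_pct / 100))
    out[[d]] <- data.frame(
      compound_id = t_d$compound_id[idx],
      adduct = t_d$adduct[idx],
      ccs = ccs,
      mz = t_d$mz[idx],
      dataset_id = paste0("DS", d),
      lab_id = labs[d],
      instrument = config$instruments[d],
      polarity = t_d$polarity[idx],
      is_outlier = displaced[idx],
      ccs_true = t_d$ccs_true[idx],
      stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, out)
  rec <- cbind(record_id = sprintf("R%05d", seq_len(nrow(rec))), rec)
  rec$record_id <- as.character(rec$record_id)
  rownames(rec) <- NULL
  rec
}

.toy_spectrum <- function(precursor_mz, name, n_peaks) {
  frag <- sort(stats::runif(n_peaks, 50, max(60, precursor_mz - 1)))
  inten <- stats::rexp(n_peaks)
  inten <- inten / max(inten) * 100
  spectrum(frag, inten, precursor_mz, c(NAME = name))
}

#' Simulate reference and degraded experimental spectra
#'
#' Reference spectra have 5-20 random fragment peaks below the precursor.
#' Experimental copies drop each peak with probability `dropout_rate`, blur
#' intensities with log-normal noise, and add contaminant peaks. A copy that
#' loses all its peaks is replaced by a single contaminant peak.
#'
#' @param library output of [simulate_library()].
#' @param config [simulation_config()].
#' @param adduct adduct defining the precursor m/z (default `"[M+H]+"`).
#' @param dropout_rate per-peak dropout probability (default 0.2).
#' @param intensity_noise_sd log-normal intensity noise sd (default 0.2).
#' @param contaminant_rate expected contaminant peaks per spectrum
#'   (default 1).
#' @return list with `reference` and `experimental`: named lists of
#'   [spectrum()] objects keyed by compound id.
#' @export
simulate_spectra <- function(library, config = simulation_config(),
                             adduct = "[M+H]+", dropout_rate = 0.2,
                             intensity_noise_sd = 0.2, contaminant_rate = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 2L)
  compounds <- library$compounds
  prec <- compute_adduct_mz(compounds$mass, adduct)
  reference <- experimental <- stats::setNames(vector("list", nrow(compounds)),
                                               compounds$id)
  for (i in seq_len(nrow(compounds))) {
    ref <- .toy_spectrum(prec[i], compounds$name[i],
                         sample(5:20, 1L))
    keep <- stats::runif(nrow(ref$peaks)) >= dropout_rate
    mz <- ref$peaks[keep, 1L]
    it <- ref$peaks[keep, 2L] *
      exp(stats::rnorm(sum(keep), 0, intensity_noise_sd))
    n_cont <- stats::rpois(1L, contaminant_rate)
    if (!length(mz)) n_cont <- max(n_cont, 1L)
    if (n_cont > 0L) {
      mz <- c(mz, stats::runif(n_cont, 50, max(60, prec[i] - 1)))
      it <- c(it, stats::runif(n_cont, 1, 30))
    }
    reference[[i]] <- ref
    experimental[[i]] <- spectrum(mz, it, prec[i],
                                  c(NAME = paste0(compounds$name[i], "_exp")))
  }
  list(reference = reference, experimental = experimental)
}

#' Simulate a decoy annotation benchmark
#'
#' Builds measured features from ground-truth ions (small m/z and CCS
#' measurement errors, degraded MS/MS spectra) and a candidate database that
#' contains the true compound (database CCS = truth with a prediction-like
#' error) plus mass decoys planted inside the ppm search window with CCS
#' values scattered around the feature value, some inside and some outside
#' the CCS tolerance. Every decoy gets an unrelated toy spectrum.
#'
#' @param library output of [simulate_library()].
#' @param config [simulation_config()].
#' @param n_features number of features (default 100; capped at the library
#'   positive-mode ions).
#' @param n_decoys decoys planted per feature (default 8).
#' @param adduct feature adduct (default `"[M+H]+"`).
#' @param db_ccs_error_sd_pct error of database CCS values vs truth (%).
#' @param decoy_ccs_spread_pct half-width of the uniform decoy CCS scatter
#'   (%), default 12 so roughly two thirds of decoys fall outside the 4%
#'   tolerance.
#' @return list with `features` (data.frame), `spectra`, `database`,
#'   `db_spectra`, `true_ids` (named by feature_id).
#' @export
simulate_annotation_benchmark <- function(library,
                                          config = simulation_config(),
                                          n_features = 100, n_decoys = 8,
                                          adduct = "[M+H]+",
                                          db_ccs_error_sd_pct = 1,
                                          decoy_ccs_spread_pct = 12) {
  spec <- simulate_spectra(library, config, adduct = adduct)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 3L)
  truth <- library$truth[library$truth$adduct == adduct, , drop = FALSE]
  n_features <- min(n_features, nrow(truth))
  pick <- sort(sample(nrow(truth), n_features))
  truth <- truth[pick, , drop = FALSE]
  compounds <- library$compounds

  feat_mz <- truth$mz * (1 + stats::rnorm(n_features, 0, 3e-6))
  feat_ccs <- truth$ccs_true * (1 + stats::rnorm(n_features, 0, 0.003))
  features <- data.frame(
    feature_id = feature_id(feat_mz, seq_len(n_features) * 10, feat_ccs),
    mz = feat_mz, rt = seq_len(n_features) * 10, ccs = feat_ccs,
    intensity = stats::rlnorm(n_features, 10, 1),
    polarity = truth$polarity,
    stringsAsFactors = FALSE)
  spectra <- stats::setNames(spec$experimental[truth$compound_id],
                             features$feature_id)

  # true candidates: whole library at exact mass, db CCS = truth + small error
  all_truth <- library$truth[library$truth$adduct == adduct, , drop = FALSE]
  database <- data.frame(
    id = all_truth$compound_id,
    name = compounds$name[match(all_truth$compound_id, compounds$id)],
    mass = compounds$mass[match(all_truth$compound_id, compounds$id)],
    adduct = adduct,
    ccs = all_truth$ccs_true *
      (1 + stats::rnorm(nrow(all_truth), 0, db_ccs_error_sd_pct / 100)),
    ccs_source = "unified-1",
    stringsAsFactors = FALSE)
  db_spectra <- spec$reference

  shift <- get_adduct(adduct)$mass_shift
  for (i in seq_len(n_features)) {
    dmz <- feat_mz[i] * (1 + stats::runif(n_decoys, -15e-6, 15e-6))
    dccs <- feat_ccs[i] *
      (1 + stats::runif(n_decoys, -decoy_ccs_spread_pct / 100,
                        decoy_ccs_spread_pct / 100))
    ids <- sprintf("DEC%03d_%02d", i, seq_len(n_decoys))
    database <- rbind(database, data.frame(
      id = ids, name = ids, mass = dmz - shift, adduct = adduct,
      ccs = dccs, ccs_source = "predicted-4", stringsAsFactors = FALSE))
    for (k in seq_len(n_decoys))
      db_spectra[[ids[k]]] <- .toy_spectrum(dmz[k], ids[k], sample(5:15, 1L))
  }
  list(features = features, spectra = spectra, database = database,
       db_spectra = db_spectra,
       true_ids = stats::setNames(truth$compound_id, features$feature_id))
}

#' Training instances from simulated ground truth
#'
#' Turns the library's ground-truth ions into (compound, adduct, ccs)
#' training pairs by adding measurement-level noise, emulating unified CCS
#' values ready for model training.
#'
#' @param library output of [simulate_library()] (use a config whose
#'   `adducts` covers the ion species wanted).
#' @param config [simulation_config()]; supplies `noise_sd_pct` and `seed`.
#' @param polarity optional filter, `"+"` or `"-"`.
#' @return data.frame `compound_id`, `adduct`, `ccs`, `ccs_true`.
#' @export
simulate_training_instances <- function(library,
                                        config = simulation_config(),
                                        polarity = NULL) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 4L)
  truth <- library$truth
  if (!is.null(polarity)) truth <- truth[truth$polarity == polarity, ,
                                         drop = FALSE]
  data.frame(compound_id = truth$compound_id, adduct = truth$adduct,
             ccs = truth$ccs_true *
               (1 + stats::rnorm(nrow(truth), 0, config$noise_sd_pct / 100)),
             ccs_true = truth$ccs_true, stringsAsFactors = FALSE)
}
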