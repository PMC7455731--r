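#' @title Standardization of multi-source CCS records
#' @name unify
#' @description Raw experimental collision cross-section records from several
#'   datasets, laboratories and instrument platforms are cleaned and merged
#'   into one consensus ("unified") CCS value per compound and adduct, with a
#'   confidence level. The pipeline is: quality check (structures, adduct
#'   whitelist, m/z accuracy), within-dataset replicate consistency (0.5%
#'   rule), power-law trend-line outlier removal per chemical super class
#'   (99% prediction interval), unified averaging with drift-tube (DTIM)
#'   priority, and confidence-level assignment.
#'
#'   Records are data.frames with columns `record_id`, `compound_id`,
#'   `adduct`, `ccs` (Angstrom^2), `mz` (reported ion m/z, may be `NA`),
#'   `dataset_id`, `lab_id`, `instrument` (`DTIM`/`TWIM`/`TIMS`) and
#'   `polarity`.
NULL

.INSTRUMENTS <- c("DTIM", "TWIM", "TIMS")

.removal_report <- function(record_id = character(), stage = character(),
                            reason = character()) {
  data.frame(record_id = as.character(record_id),
             stage = rep_len(stage, length(record_id)),
             reason = rep_len(reason, length(record_id)),
             stringsAsFactors = FALSE)
}

.check_records <- function(records) {
  need <- c("record_id", "compound_id", "adduct", "ccs", "dataset_id",
            "instrument", "polarity")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing columns: ", paste(miss, collapse = ", "))
  if (is.null(records$mz)) records$mz <- NA_real_
  if (is.null(records$lab_id)) records$lab_id <- records$dataset_id
  if (anyDuplicated(records$record_id)) stop("record_id must be unique")
  bad <- !(records$instrument %in% .INSTRUMENTS)
  if (any(bad)) stop("unknown instrument: ",
                     paste(unique(records$instrument[bad]), collapse = ", "))
  if (any(records$ccs <= 0, na.rm = TRUE)) stop("ccs must be positive")
  records
}

#' Maximum relative difference within a set of CCS values
#'
#' `(max - min) / mean * 100`, the replicate-consistency statistic used by the
#' 0.5% within-dataset rule and the 1%/3% confidence-level cut-offs. Zero for
#' singletons.
#'
#' @param ccs numeric vector of CCS values.
#' @return percentage difference (scalar, >= 0).
#' @export
max_diff_pct <- function(ccs) {
  if (length(ccs) <= 1L) return(0)
  (max(ccs) - min(ccs)) / mean(ccs) * 100
}

#' Quality check of raw CCS records
#'
#' Removes records whose compound has no parseable structure, whose adduct is
#' not on the whitelist (or disagrees in polarity), or whose reported m/z
#' deviates from the theoretical adduct m/z by more than `ppm_max`. Records
#' without a reported m/z pass the m/z sub-check.
#'
#' @param records CCS record table (see [unify]).
#' @param compounds compound table ([compound_table()]); used for structures
#'   and neutral masses. Compounds absent from the table count as
#'   structureless.
#' @param adducts adduct whitelist (default [adduct_table()]).
#' @param ppm_max maximum tolerated |m/z error| in ppm (default 10).
#' @return list with elements `kept` (records) and `removed` (removal report
#'   with columns `record_id`, `stage`, `reason`).
#' @export
quality_filter <- function(records, compounds, adducts = adduct_table(),
                           ppm_max = 10) {
  records <- .check_records(records)
  reason <- rep(NA_character_, nrow(records))

  known <- records$compound_id %in% compounds$id
  reason[!known] <- "no chemical structure"

  idx <- match(records$adduct, adducts$name)
  bad_add <- is.na(reason) & (is.na(idx) |
                              adducts$polarity[idx] != records$polarity)
  reason[bad_add] <- "adduct not in whitelist"

  mass <- compounds$mass[match(records$compound_id, compounds$id)]
  theo <- mass + adducts$mass_shift[idx]
  has_mz <- !is.na(records$mz)
  chk <- is.na(reason) & has_mz & !is.na(theo)
  err <- abs(records$mz - theo) / theo * 1e6
  bad_mz <- chk & err > ppm_max
  reason[bad_mz] <- sprintf("m/z error > %g ppm", ppm_max)

  removed <- .removal_report(records$record_id[!is.na(reason)], "quality",
                             reason[!is.na(reason)])
  list(kept = records[is.na(reason), , drop = FALSE], removed = removed)
}

#' Merge replicate records within each dataset
#'
#' For every (dataset, compound, adduct) group with more than one record the
#' maximum relative CCS difference is computed; if it exceeds `max_diff`
#' (default 0.5%) the whole group is removed as inconsistent, otherwise the
#' group is replaced by a single record carrying the arithmetic mean CCS.
#'
#' @param records CCS record table.
#' @param max_diff consistency threshold in percent (default 0.5).
#' @return list with `kept` (one record per dataset x compound x adduct; the
#'   surviving record keeps the first record's id and gains a
#'   `source_record_ids` list-column) and `removed` (removal report).
#' @export
merge_within_dataset <- function(records, max_diff = 0.5) {
  records <- .check_records(records)
  key <- interaction(records$dataset_id, records$compound_id, records$adduct,
                     drop = TRUE)
  keep_rows <- integer()
  merged_ccs <- numeric()
  sources <- list()
  removed_id <- character()
  removed_reason <- character()
  for (rows in split(seq_len(nrow(records)), key)) {
    d <- max_diff_pct(records$ccs[rows])
    if (d > max_diff) {
      removed_id <- c(removed_id, records$record_id[rows])
      removed_reason <- c(removed_reason,
                          rep(sprintf("within-dataset difference %.3f%% > %g%%",
                                      d, max_diff), length(rows)))
    } else {
      keep_rows <- c(keep_rows, rows[1L])
      merged_ccs <- c(merged_ccs, mean(records$ccs[rows]))
      sources[[length(sources) + 1L]] <- records$record_id[rows]
    }
  }
  kept <- records[keep_rows, , drop = FALSE]
  kept$ccs <- merged_ccs
  kept$source_record_ids <- sources
  rownames(kept) <- NULL
  list(kept = kept,
       removed = .removal_report(removed_id, "intra-dataset", removed_reason))
}

#' Remove trend-line outliers per chemical super class
#'
#' Within each (super class, polarity) stratum with at least `min_class_n`
#' records, the mass-mobility trend CCS = a * (m/z)^b is fitted by ordinary
#' least squares on log-log axes and records falling outside the two-sided
#' `pi_level` prediction interval are removed. Strata below `min_class_n`, or
#' with degenerate m/z spread, are left untouched.
#'
#' The ion m/z used as abscissa is the theoretical adduct m/z computed from
#' the compound's neutral mass (the reported m/z is used as a fallback).
#'
#' @param records merged CCS record table.
#' @param compounds compound table carrying `superclass` labels.
#' @param adducts adduct table for the m/z computation.
#' @param min_class_n minimum stratum size fitted (default 10).
#' @param pi_level prediction-interval coverage (default 0.99).
#' @return list with `kept` and `removed` (stage `"trendline"`).
#' @export
remove_trendline_outliers <- function(records, compounds,
                                      adducts = adduct_table(),
                                      min_class_n = 10, pi_level = 0.99) {
  records <- .check_records(records)
  ci <- match(records$compound_id, compounds$id)
  supercl <- compounds$superclass[ci]
  mass <- compounds$mass[ci]
  shift <- adducts$mass_shift[match(records$adduct, adducts$name)]
  mz <- mass + shift
  mz[is.na(mz)] <- records$mz[is.na(mz)]

  drop <- rep(FALSE, nrow(records))
  reason <- rep(NA_character_, nrow(records))
  stratum <- interaction(supercl, records$polarity, drop = TRUE)
  for (rows in split(seq_len(nrow(records)), stratum)) {
    if (length(rows) < min_class_n) next
    x <- log(mz[rows]); y <- log(records$ccs[rows])
    if (length(unique(x)) < 3L || stats::sd(x) == 0) {
      warning("degenerate m/z spread in stratum '",
              as.character(stratum[rows[1L]]), "'; skipped")
      next
    }
    fit <- stats::lm(y ~ x)
    # in-sample PI is intended here (screening the fitted points themselves)
    pi <- suppressWarnings(
      stats::predict(fit, interval = "prediction", level = pi_level))
    out <- y < pi[, "lwr"] | y > pi[, "upr"]
    out[is.na(out)] <- FALSE
    drop[rows[out]] <- TRUE
    reason[rows[out]] <- sprintf(
      "outside %g%% prediction interval of power-law trend (%s)",
      pi_level * 100, as.character(stratum[rows[1L]]))
  }
  list(kept = records[!drop, , drop = FALSE],
       removed = .removal_report(records$record_id[drop], "trendline",
                                 reason[drop]))
}

#' Compute unified CCS values
#'
#' Groups dataset-merged records by (compound, adduct). When at least one
#' drift-tube (DTIM) record is present the unified value is the mean of the
#' DTIM records only; otherwise it is the mean over all platforms. The
#' maximum relative difference is computed over all records of the group
#' (all platforms), as used by the confidence rules.
#'
#' @param records dataset-merged record table (one record per dataset).
#' @return data.frame with columns `compound_id`, `adduct`, `polarity`,
#'   `unified_ccs`, `n_datasets`, `n_dtim_datasets`, `max_diff_pct`,
#'   `instruments` (collapsed string) and list-column `source_record_ids`.
#' @export
compute_unified_ccs <- function(records) {
  records <- .check_records(records)
  if (is.null(records$source_record_ids))
    records$source_record_ids <- as.list(records$record_id)
  key <- interaction(records$compound_id, records$adduct, drop = TRUE)
  res <- lapply(split(seq_len(nrow(records)), key), function(rows) {
    g <- records[rows, , drop = FALSE]
    dt <- g$instrument == "DTIM"
    unified <- if (any(dt)) mean(g$ccs[dt]) else mean(g$ccs)
    data.frame(
      compound_id = g$compound_id[1L], adduct = g$adduct[1L],
      polarity = g$polarity[1L], unified_ccs = unified,
      n_datasets = length(unique(g$dataset_id)),
      n_dtim_datasets = length(unique(g$dataset_id[dt])),
      max_diff_pct = max_diff_pct(g$ccs),
      instruments = paste(sort(unique(g$instrument)), collapse = ";"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$source_record_ids <- lapply(split(seq_len(nrow(records)), key),
                                  function(rows)
                                    unlist(records$source_record_ids[rows]))
  rownames(out) <- NULL
  out
}

#' Assign confidence levels to unified CCS values
#'
#' Ordered decision cascade: Level 1 -- at least two independent datasets on
#' DTIM instruments and maximum difference <= `l1_max_diff` (1%); Level 2 --
#' at least two independent datasets (any commercial instruments) and maximum
#' difference <= `l2_max_diff` (3%); Conflict -- at least two datasets with
#' maximum difference above 3%; Level 3 -- a single dataset. Level 4 is
#' reserved for predicted values and never assigned here.
#'
#' @param unified output of [compute_unified_ccs()], or a data.frame with
#'   columns `n_datasets`, `n_dtim_datasets`, `max_diff_pct`.
#' @param l1_max_diff,l2_max_diff level cut-offs in percent.
#' @return the input with a `level` column (`"1"`, `"2"`, `"3"`, `"Conflict"`).
#' @export
assign_confidence <- function(unified, l1_max_diff = 1, l2_max_diff = 3) {
  lvl <- ifelse(unified$n_dtim_datasets >= 2 &
                  unified$max_diff_pct <= l1_max_diff, "1",
         ifelse(unified$n_datasets >= 2 &
                  unified$max_diff_pct <= l2_max_diff, "2",
         ifelse(unified$n_datasets >= 2, "Conflict", "3")))
  unified$level <- lvl
  unified
}

#' Run the full five-step standardization pipeline
#'
#' [quality_filter()], [merge_within_dataset()],
#' [remove_trendline_outliers()], [compute_unified_ccs()] and
#' [assign_confidence()] in sequence. Every input record ends up either in
#' exactly one unified value's source list or in exactly one removal-report
#' row.
#'
#' @param records raw CCS record table.
#' @param compounds compound table with `superclass` labels.
#' @param adducts adduct whitelist.
#' @param ppm_max,intra_max_diff,min_class_n,pi_level stage thresholds (see
#'   the stage functions).
#' @return list with `unified` (levelled unified table) and `removed`
#'   (combined removal report).
#' @export
unify_ccs <- function(records, compounds, adducts = adduct_table(),
                      ppm_max = 10, intra_max_diff = 0.5,
                      min_class_n = 10, pi_level = 0.99) {
  s1 <- quality_filter(records, compounds, adducts, ppm_max)
  s2 <- merge_within_dataset(s1$kept, intra_max_diff)
  s3 <- remove_trendline_outliers(s2$kept, compounds, adducts,
                                  min_class_n, pi_level)
  removed <- rbind(s1$removed, s2$removed,
                   .expand_merged_removals(s3$removed, s2$kept))
  unified <- assign_confidence(compute_unified_ccs(s3$kept))
  list(unified = unified, removed = removed)
}

# a trendline removal hits a merged record; expand it back to the raw ids so
# the record-conservation invariant holds
.expand_merged_removals <- function(removed, merged) {
  if (nrow(removed) == 0L) return(removed)
  idx <- match(removed$record_id, merged$record_id)
  src <- merged$source_record_ids[idx]
  n <- lengths(src)
  .removal_report(unlist(src), rep(removed$stage, n), rep(removed$reason, n))
}

#' Write unified CCS values to TSV
#'
#' @param unified unified table from [unify_ccs()].
#' @param path output path; the source-id list-column is collapsed with `;`.
#' @export
write_unified <- function(unified, path) {
  out <- unified
  out$source_record_ids <- vapply(out$source_record_ids, paste, "",
                                  collapse = ";")
  out$unified_ccs <- round(out$unified_ccs, 1)  # reporting convention: 0.1 A^2
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
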