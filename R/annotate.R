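#' @title Multi-dimensional metabolite annotation
#' @name annotate
#' @description Measured features (m/z, retention time, CCS, optional MS/MS
#'   spectrum) are matched against a candidate database in up to three
#'   dimensions: m/z within a ppm tolerance (protonated/deprotonated species
#'   by default), CCS with a trapezoidal match score (full score below the
#'   inner tolerance, linear decay to zero at the outer tolerance), and MS/MS
#'   with a reverse dot-product computed over reference-library peaks. The
#'   dimension scores are fused by a weighted sum and candidates are ranked.
#'
#'   The candidate database is a long-format data.frame with one row per
#'   compound x adduct: columns `id`, `name`, `mass` (neutral, Da), `adduct`,
#'   `ccs` (may be `NA`) and `ccs_source` (e.g. `"unified-1"` ...
#'   `"predicted-4"`).
NULL

#' Match tolerances and integration weights
#'
#' @param ppm m/z tolerance in ppm (default 25).
#' @param tol_min,tol_max inner and outer CCS tolerances in percent
#'   (defaults 2 and 4).
#' @param w_ccs,w_msms integration weights (defaults 0.3 and 0.7); must sum
#'   to 1 unless `allow_unnormalized`.
#' @param allow_unnormalized skip the weight-sum check.
#' @return list of class `match_tolerances`.
#' @export
match_tolerances <- function(ppm = 25, tol_min = 2, tol_max = 4,
                             w_ccs = 0.3, w_msms = 0.7,
                             allow_unnormalized = FALSE) {
  stopifnot(ppm > 0, tol_min >= 0, tol_max >= tol_min)
  if (!allow_unnormalized && abs(w_ccs + w_msms - 1) > 1e-9)
    stop("integration weights must sum to 1 (got ", w_ccs + w_msms,
         "); set allow_unnormalized = TRUE to override")
  structure(list(ppm = ppm, tol_min = tol_min, tol_max = tol_max,
                 w_ccs = w_ccs, w_msms = w_msms),
            class = "match_tolerances")
}

#' Retrieve candidates by m/z
#'
#' Returns database rows whose theoretical adduct m/z lies within the ppm
#' tolerance of the feature m/z, restricted to the configured adducts for the
#' feature's polarity (default: \[M+H\]+ / \[M-H\]- only).
#'
#' @param feature_mz measured m/z (Da).
#' @param polarity `"+"` or `"-"`.
#' @param database candidate table (see [annotate]).
#' @param tol [match_tolerances()].
#' @param allowed_adducts adduct names considered (default the
#'   protonated/deprotonated species of the polarity).
#' @param adducts adduct table.
#' @return candidate rows with added columns `theo_mz` and `ppm_error`.
#' @export
match_mz <- function(feature_mz, polarity, database,
                     tol = match_tolerances(),
                     allowed_adducts = NULL, adducts = adduct_table()) {
  if (!nrow(database)) stop("empty candidate database")
  polarity <- match.arg(polarity, c("+", "-"))
  if (is.null(allowed_adducts))
    allowed_adducts <- if (polarity == "+") "[M+H]+" else "[M-H]-"
  db <- database[database$adduct %in% allowed_adducts, , drop = FALSE]
  db$theo_mz <- db$mass + adducts$mass_shift[match(db$adduct, adducts$name)]
  db$ppm_error <- abs(feature_mz - db$theo_mz) / db$theo_mz * 1e6
  out <- db[db$ppm_error <= tol$ppm, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Relative CCS error (percent)
#'
#' @param ccs_pred candidate (database/predicted) CCS.
#' @param ccs_exp measured CCS.
#' @return `|ccs_pred - ccs_exp| / ccs_exp * 100`.
#' @export
delta_rela <- function(ccs_pred, ccs_exp) {
  if (any(ccs_pred <= 0, na.rm = TRUE) || any(ccs_exp <= 0, na.rm = TRUE))
    stop("CCS values must be positive")
  abs(ccs_pred - ccs_exp) / ccs_exp * 100
}

#' Trapezoidal CCS match score
#'
#' 1 below the inner tolerance, linear decay to 0 at the outer tolerance,
#' 0 beyond. With `tol_min == tol_max` the function degenerates to a step at
#' the shared tolerance.
#'
#' @param delta relative CCS error(s) in percent (>= 0).
#' @param tol [match_tolerances()] supplying `tol_min`, `tol_max`.
#' @return score(s) in \[0, 1\].
#' @export
#' @examples
#' ccs_match_score(c(1, 3, 5))  # 1.0, 0.5, 0.0
ccs_match_score <- function(delta, tol = match_tolerances()) {
  stopifnot(all(delta >= 0, na.rm = TRUE))
  if (tol$tol_max == tol$tol_min)
    return(ifelse(delta <= tol$tol_min, 1, 0))
  s <- 1 - (delta - tol$tol_min) / (tol$tol_max - tol$tol_min)
  pmin(pmax(s, 0), 1)
}

#' Reverse dot-product MS/MS match score
#'
#' Weighted-cosine similarity computed over the reference-library peaks only:
#' each reference peak is paired with the closest experimental peak within
#' the m/z tolerance (or intensity 0 when absent); experimental peaks with no
#' reference counterpart are ignored. Intensities are square-root transformed
#' before the cosine. The squared cosine is returned, in \[0, 1\].
#'
#' @param experimental,reference [spectrum()] objects.
#' @param mz_tol_ppm peak alignment tolerance in ppm (default 25).
#' @param min_abs_tol absolute floor on the alignment window in Da (low-mass
#'   fragments; default 0.002).
#' @return score in \[0, 1\]; 0 when no reference peak is matched.
#' @export
msms_score <- function(experimental, reference, mz_tol_ppm = 25,
                       min_abs_tol = 0.002) {
  stopifnot(inherits(experimental, "spectrum"), inherits(reference, "spectrum"))
  ref <- reference$peaks
  exp <- experimental$peaks
  matched <- numeric(nrow(ref))
  for (i in seq_len(nrow(ref))) {
    win <- max(ref[i, 1L] * mz_tol_ppm * 1e-6, min_abs_tol)
    d <- abs(exp[, 1L] - ref[i, 1L])
    j <- which.min(d)
    if (length(j) && d[j] <= win) matched[i] <- exp[j, 2L]
  }
  if (all(matched == 0)) return(0)
  a <- sqrt(ref[, 2L]); b <- sqrt(matched)
  (sum(a * b)^2) / (sum(a^2) * sum(b^2))
}

#' Integrated multi-dimensional match score
#'
#' @param s_ccs,s_msms CCS and MS/MS match scores in \[0, 1\].
#' @param tol [match_tolerances()] supplying the weights (defaults 0.3/0.7).
#' @return `w_ccs * s_ccs + w_msms * s_msms`.
#' @export
#' @examples
#' integrated_score(1, 0)  # 0.3
integrated_score <- function(s_ccs, s_msms, tol = match_tolerances()) {
  stopifnot(all(s_ccs >= 0 & s_ccs <= 1, na.rm = TRUE),
            all(s_msms >= 0 & s_msms <= 1, na.rm = TRUE))
  tol$w_ccs * s_ccs + tol$w_msms * s_msms
}

#' Min-max rescale scores to \[0, 1\]
#'
#' Used on external in-silico MS/MS tool scores within one feature's
#' candidate set before integration. A constant vector maps to all-1.
#'
#' @param x numeric scores.
#' @return rescaled scores (best = 1, worst = 0).
#' @export
rescale_scores <- function(x) {
  if (!length(x)) return(x)
  rng <- range(x, na.rm = TRUE)
  if (diff(rng) == 0) return(rep(1, length(x)))
  (x - rng[1L]) / diff(rng)
}

#' Score and rank candidates for one measured feature
#'
#' Pipeline: m/z retrieval, optional CCS filter (candidates beyond the outer
#' tolerance are removed) and trapezoidal scoring, optional MS/MS reverse
#' dot-product scoring, weighted integration, dense ranking. When a scoring
#' dimension is disabled (or unavailable) the weights renormalize onto the
#' remaining dimension.
#'
#' @param feature list or one-row data.frame with `mz`, `polarity`, `ccs`
#'   (optional) and `spectrum` (optional [spectrum()]).
#' @param database candidate table (see [annotate]).
#' @param db_spectra named list of reference [spectrum()] objects keyed by
#'   candidate `id` (required when `use_msms`).
#' @param tol [match_tolerances()].
#' @param use_ccs,use_msms enable the CCS / MS/MS dimensions.
#' @param msms_scores optional named numeric vector of externally computed
#'   MS/MS scores (e.g. from an in-silico tool) keyed by candidate id; they
#'   are min-max rescaled within the candidate set and replace the internal
#'   reverse dot-product.
#' @param allowed_adducts,adducts passed to [match_mz()].
#' @return data.frame of surviving candidates with `s_ccs`, `s_msms`,
#'   `s_integrated`, `rank` (dense, ties broken by smaller |ppm error| then
#'   id), ordered best first; attribute `stage_counts` records candidate
#'   counts after each stage.
#' @export
rank_candidates <- function(feature, database, db_spectra = NULL,
                            tol = match_tolerances(),
                            use_ccs = TRUE, use_msms = TRUE,
                            msms_scores = NULL,
                            allowed_adducts = NULL,
                            adducts = adduct_table()) {
  if (!use_ccs && !use_msms && is.null(msms_scores))
    stop("at least one scoring dimension must be enabled")
  cand <- match_mz(feature$mz, feature$polarity, database, tol,
                   allowed_adducts, adducts)
  stages <- c(mz = nrow(cand))

  has_ccs_dim <- use_ccs && !is.null(feature$ccs) && !is.na(feature$ccs)
  if (has_ccs_dim) {
    cand <- cand[!is.na(cand$ccs), , drop = FALSE]
    cand$delta_rela <- if (nrow(cand)) delta_rela(cand$ccs, feature$ccs)
                       else numeric()
    cand <- cand[cand$delta_rela <= tol$tol_max, , drop = FALSE]
    cand$s_ccs <- ccs_match_score(cand$delta_rela, tol)
  } else {
    cand$delta_rela <- NA_real_
    cand$s_ccs <- NA_real_
  }
  stages <- c(stages, ccs = nrow(cand))

  feat_spec <- feature$spectrum
  if (is.data.frame(feature) && !is.null(feature$spectrum))
    feat_spec <- feature$spectrum[[1L]]
  has_msms_dim <- FALSE
  if (nrow(cand)) {
    if (!is.null(msms_scores)) {
      s <- msms_scores[match(cand$id, names(msms_scores))]
      cand$s_msms <- rescale_scores(as.numeric(s))
      has_msms_dim <- TRUE
    } else if (use_msms && !is.null(feat_spec) && !is.null(db_spectra)) {
      cand$s_msms <- vapply(cand$id, function(id) {
        ref <- db_spectra[[id]]
        if (is.null(ref)) 0 else msms_score(feat_spec, ref, tol$ppm)
      }, 0)
      has_msms_dim <- TRUE
    } else cand$s_msms <- NA_real_
  } else cand$s_msms <- numeric()
  stages <- c(stages, msms = nrow(cand))

  if (nrow(cand)) {
    if (has_ccs_dim && has_msms_dim) {
      cand$s_integrated <- integrated_score(cand$s_ccs, cand$s_msms, tol)
    } else if (has_ccs_dim) {
      cand$s_integrated <- cand$s_ccs          # W_ccs renormalized to 1
    } else if (has_msms_dim) {
      cand$s_integrated <- cand$s_msms         # W_msms renormalized to 1
    } else {
      cand$s_integrated <- 1 - cand$ppm_error / tol$ppm  # m/z proximity only
    }
    o <- order(-cand$s_integrated, cand$ppm_error, cand$id)
    cand <- cand[o, , drop = FALSE]
    cand$rank <- cumsum(!duplicated(round(cand$s_integrated, 12)))
  } else cand$rank <- integer()
  rownames(cand) <- NULL
  attr(cand, "stage_counts") <- stages
  cand
}

#' Annotate a feature table
#'
#' Applies [rank_candidates()] to every row of a feature table. When several
#' spectra are supplied for one feature the most intense one is used.
#'
#' @param features data.frame with `feature_id`, `mz`, `polarity`, and
#'   optionally `rt`, `ccs`, `intensity`.
#' @param spectra named list of [spectrum()] objects (or lists of spectra)
#'   keyed by `feature_id`.
#' @param database,db_spectra,tol,use_ccs,use_msms,allowed_adducts,adducts
#'   passed to [rank_candidates()].
#' @return list with `annotations` (one data.frame row per feature x
#'   candidate) and `stages` (per-feature candidate counts after each stage).
#' @export
annotate_features <- function(features, database, spectra = NULL,
                              db_spectra = NULL, tol = match_tolerances(),
                              use_ccs = TRUE, use_msms = TRUE,
                              allowed_adducts = NULL,
                              adducts = adduct_table()) {
  ann <- list(); stg <- list()
  for (i in seq_len(nrow(features))) {
    f <- as.list(features[i, , drop = FALSE])
    fid <- as.character(f$feature_id)
    sp <- if (!is.null(spectra)) spectra[[fid]] else NULL
    if (!is.null(sp) && !inherits(sp, "spectrum")) {
      # several spectra: keep the most intense one
      tot <- vapply(sp, function(s) sum(s$peaks[, 2L]), 0)
      sp <- sp[[which.max(tot)]]
    }
    f$spectrum <- sp
    cand <- rank_candidates(f, database, db_spectra, tol, use_ccs, use_msms,
                            allowed_adducts = allowed_adducts,
                            adducts = adducts)
    stg[[fid]] <- attr(cand, "stage_counts")
    if (nrow(cand)) {
      cand <- cbind(feature_id = fid, cand)
      ann[[fid]] <- cand
    }
  }
  stages <- do.call(rbind, lapply(names(stg), function(id)
    data.frame(feature_id = id, t(stg[[id]]), stringsAsFactors = FALSE)))
  list(annotations = if (length(ann)) do.call(rbind, ann) else NULL,
       stages = stages)
}

#' Parse / build feature identifiers of the MxxxTyyyCzzz convention
#'
#' `M384T767C189` encodes m/z 384 (rounded), RT 767 s, CCS 189 Angstrom^2.
#'
#' @param mz,rt,ccs numeric vectors.
#' @return `feature_id()`: character ids. `parse_feature_id()`: data.frame
#'   with the rounded `mz`, `rt`, `ccs` components.
#' @export
feature_id <- function(mz, rt, ccs) {
  sprintf("M%dT%dC%d", round(mz), round(rt), round(ccs))
}

#' @rdname feature_id
#' @param id character vector of feature ids.
#' @export
parse_feature_id <- function(id) {
  m <- regmatches(id, regexec("^M([0-9]+)T([0-9]+)C([0-9]+)$", id))
  bad <- lengths(m) != 4L
  if (any(bad)) stop("malformed feature id: ", paste(id[bad], collapse = ", "))
  data.frame(mz = as.numeric(vapply(m, `[`, "", 2L)),
             rt = as.numeric(vapply(m, `[`, "", 3L)),
             ccs = as.numeric(vapply(m, `[`, "", 4L)))
}
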