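#' @title Machine-learning CCS prediction
#' @name ccsmodel
#' @description CCS values are predicted by epsilon support vector regression
#'   with a radial-basis-function kernel on selected, Z-scored molecular
#'   descriptors. One model is trained per ionization polarity; the ion
#'   species is encoded by appending the adduct mass shift and a one-hot
#'   adduct indicator to the descriptor vector. Each prediction carries a
#'   representative structure similarity (RSS) score against the training set
#'   as a reliability estimate, and is flagged confidence level 4.
NULL

#' Hyperparameter grid configuration
#'
#' The default grid crosses seven cost values `{0.001, 0.005, 0.025, 0.05,
#' 0.1, 0.25, 0.5} / N_MD` with fifteen kernel widths `2^1 ... 2^15`
#' (105 combinations), searched by ten-fold cross-validation with 100
#' repeats. `N_MD` is the number of selected descriptors.
#'
#' @param N_MD number of selected molecular descriptors (scales the C grid).
#' @param C_grid,gamma_grid override the grids directly.
#' @param folds,repeats cross-validation folds and repeats.
#' @return list of class `model_config`.
#' @export
model_config <- function(N_MD, C_grid = NULL, gamma_grid = NULL,
                         folds = 10, repeats = 100) {
  if (is.null(C_grid))
    C_grid <- c(0.001, 0.005, 0.025, 0.05, 0.1, 0.25, 0.5) / N_MD
  if (is.null(gamma_grid)) gamma_grid <- 2^(1:15)
  stopifnot(all(C_grid > 0), all(gamma_grid > 0))
  structure(list(C_grid = C_grid, gamma_grid = gamma_grid, folds = folds,
                 repeats = repeats, kernel = "radial", N_MD = N_MD),
            class = "model_config")
}

.svm_fit <- function(X, y, C, gamma) {
  scale_cols <- apply(X, 2L, stats::sd) > 0
  e1071::svm(X, y, type = "eps-regression", kernel = "radial",
             cost = C, gamma = gamma, scale = scale_cols,
             tolerance = 1e-3, shrinking = TRUE)
}

#' Tune SVR hyperparameters on a grid
#'
#' Every (C, gamma) grid point is scored by repeated k-fold cross-validation;
#' the score is the median relative error (%) of the held-out predictions,
#' averaged over repeats. The argmin pair is returned with ties broken by
#' smaller C, then smaller gamma, together with the full grid table for
#' audit.
#'
#' @param X feature matrix (preprocessed descriptors + adduct encoding).
#' @param y CCS targets.
#' @param config [model_config()].
#' @param seed integer seed for the fold stream.
#' @return list `C`, `gamma`, `cv_table` (one row per grid point with mean
#'   CV MRE).
#' @export
tune_hyperparameters <- function(X, y, config, seed = 1) {
  n <- length(y)
  if (n < config$folds)
    stop("fewer rows (", n, ") than folds (", config$folds,
         "); reduce `folds`")
  if (any(!is.finite(X)))
    stop("non-finite feature values in columns: ",
         paste(colnames(X)[apply(!is.finite(X), 2L, any)], collapse = ", "))
  grid <- expand.grid(C = config$C_grid, gamma = config$gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold_sets <- lapply(seq_len(config$repeats), function(r)
    sample(rep(seq_len(config$folds), length.out = n)))
  score_one <- function(C, gamma) {
    mres <- vapply(fold_sets, function(foldid) {
      pred <- rep(NA_real_, n)
      for (f in seq_len(config$folds)) {
        te <- foldid == f
        fit <- .svm_fit(X[!te, , drop = FALSE], y[!te], C, gamma)
        pred[te] <- stats::predict(fit, X[te, , drop = FALSE])
      }
      stats::median(abs(pred - y) / y) * 100
    }, 0)
    mean(mres)
  }
  grid$cv_mre <- mapply(score_one, grid$C, grid$gamma)
  o <- order(grid$cv_mre, grid$C, grid$gamma)
  best <- grid[o[1L], ]
  list(C = best$C, gamma = best$gamma, cv_table = grid)
}

.adduct_features <- function(adduct, levels, adducts = adduct_table()) {
  shift <- adducts$mass_shift[match(adduct, adducts$name)]
  onehot <- outer(adduct, levels, `==`) * 1
  colnames(onehot) <- paste0("adduct_", levels)
  cbind(adduct_shift = shift, onehot)
}

#' Train a CCS prediction model
#'
#' @param instances data.frame with `compound_id`, `adduct`, `ccs` (the
#'   training pairs, typically unified CCS values restricted to the training
#'   adduct whitelist with Conflict levels removed).
#' @param compounds compound table supplying structures.
#' @param polarity `"+"` or `"-"`; instances of the other polarity are
#'   rejected.
#' @param selection optional `selection_result` (or character vector of
#'   descriptor names) restricting the descriptor set.
#' @param C,gamma hyperparameters; when either is `NULL` they are tuned with
#'   [tune_hyperparameters()] under `config`.
#' @param config [model_config()]; defaults to the standard grid for the
#'   selected descriptor count.
#' @param adducts adduct table.
#' @param seed seed for tuning.
#' @return object of class `ccs_model`.
#' @export
train_ccs_model <- function(instances, compounds, polarity,
                            selection = NULL, C = NULL, gamma = NULL,
                            config = NULL, adducts = adduct_table(),
                            seed = 1) {
  polarity <- match.arg(polarity, c("+", "-"))
  pol <- adducts$polarity[match(instances$adduct, adducts$name)]
  if (any(is.na(pol))) stop("unknown adduct in training instances")
  if (any(pol != polarity)) stop("training instances of the wrong polarity")
  stopifnot(all(instances$ccs > 0))

  ids <- unique(instances$compound_id)
  comp <- compounds[match(ids, compounds$id), , drop = FALSE]
  D_raw <- compute_descriptors(comp)
  if (length(attr(D_raw, "failed")))
    stop("unparseable training structures: ",
         paste(attr(D_raw, "failed"), collapse = ", "))
  Z <- preprocess_descriptors(D_raw)
  if (!is.null(selection)) {
    sel <- if (inherits(selection, "selection_result")) selection$selected
           else selection
    sel <- intersect(sel, colnames(Z))
    if (!length(sel)) stop("no selected descriptor present in the matrix")
    center <- attr(Z, "center")[sel]; scl <- attr(Z, "scale")[sel]
    Z <- Z[, sel, drop = FALSE]
    attr(Z, "center") <- center; attr(Z, "scale") <- scl
  }
  adduct_levels <- sort(unique(instances$adduct))
  ri <- match(instances$compound_id, rownames(Z))
  X <- cbind(Z[ri, , drop = FALSE],
             .adduct_features(instances$adduct, adduct_levels, adducts))
  rownames(X) <- NULL
  y <- instances$ccs

  if (is.null(config)) config <- model_config(N_MD = ncol(Z))
  if (is.null(C) || is.null(gamma)) {
    tuned <- tune_hyperparameters(X, y, config, seed = seed)
    C <- tuned$C; gamma <- tuned$gamma; cv_table <- tuned$cv_table
  } else cv_table <- NULL

  fit <- .svm_fit(X, y, C, gamma)
  fitted_y <- stats::predict(fit, X)
  re <- abs(fitted_y - y) / y * 100
  fps <- compute_fingerprints(comp)

  structure(list(
    polarity = polarity,
    fit = fit,
    descriptors = colnames(Z),
    center = attr(Z, "center"), scale = attr(Z, "scale"),
    adduct_levels = adduct_levels,
    C = C, gamma = gamma, epsilon = fit$epsilon, config = config,
    cv_table = cv_table,
    training_fp = fps,
    training = instances,
    metrics = list(MRE = stats::median(re), ARE = mean(re),
                   R2 = stats::cor(fitted_y, y)^2),
    provenance = attr(D_raw, "provenance")
  ), class = "ccs_model")
}

#' @export
print.ccs_model <- function(x, ...) {
  cat("<ccs_model> polarity", x$polarity, "|", length(x$descriptors),
      "descriptors |", nrow(x$training), "training instances\n")
  cat(sprintf("  C = %.6g, gamma = %g, epsilon = %g\n", x$C, x$gamma,
              x$epsilon))
  cat(sprintf("  training MRE %.2f%%, ARE %.2f%%, R2 %.4f\n",
              x$metrics$MRE, x$metrics$ARE, x$metrics$R2))
  invisible(x)
}

#' Predict CCS values for new compounds
#'
#' Descriptors are computed, normalized with the model's stored statistics,
#' the adduct encoding appended, and the SVR evaluated. Every prediction
#' carries an RSS reliability score against the model's training fingerprints
#' and is flagged confidence level 4.
#'
#' @param model `ccs_model`.
#' @param compounds compound table (or named SMILES vector) to predict for.
#' @param adduct adduct name(s): one for all compounds or one per compound;
#'   polarity must match the model.
#' @param adducts adduct table.
#' @return data.frame with `compound_id`, `adduct`, `ccs`, `rss`,
#'   `rss_group`, `level` (`"4"`).
#' @export
predict_ccs <- function(model, compounds, adduct, adducts = adduct_table()) {
  if (is.character(compounds))
    compounds <- data.frame(id = names(compounds), smiles = compounds,
                            stringsAsFactors = FALSE)
  pol <- adducts$polarity[match(adduct, adducts$name)]
  if (any(is.na(pol))) stop("unknown adduct")
  if (any(pol != model$polarity))
    stop("adduct polarity does not match the model polarity '",
         model$polarity, "'")
  adduct <- rep(adduct, length.out = nrow(compounds))
  new_adduct <- setdiff(adduct, model$adduct_levels)
  if (length(new_adduct))
    warning("adduct(s) absent from training: ",
            paste(unique(new_adduct), collapse = ", "),
            "; encoded by mass shift only")
  comp_u <- compounds[!duplicated(compounds$id), , drop = FALSE]
  D <- compute_descriptors(comp_u)
  if (length(attr(D, "failed")))
    stop("unparseable structures: ",
         paste(attr(D, "failed"), collapse = ", "))
  Z <- apply_normalization(D, model$center, model$scale)
  Zi <- Z[match(compounds$id, rownames(Z)), , drop = FALSE]
  X <- cbind(Zi, .adduct_features(adduct, model$adduct_levels, adducts))
  rownames(X) <- NULL
  ccs <- as.numeric(stats::predict(model$fit, X))
  qfp <- compute_fingerprints(comp_u,
                              scheme = attr(model$training_fp, "scheme"))
  rss_u <- lapply(seq_len(nrow(qfp)), function(i)
    rss_score(qfp[i, ], model$training_fp))
  names(rss_u) <- rownames(qfp)
  rss_i <- rss_u[match(compounds$id, names(rss_u))]
  data.frame(compound_id = compounds$id, adduct = adduct, ccs = ccs,
             rss = vapply(rss_i, `[[`, 0, "rss"),
             rss_group = vapply(rss_i, `[[`, "", "group"),
             level = "4", stringsAsFactors = FALSE)
}

#' Evaluate predictions against experimental CCS values
#'
#' Relative error per pair is `|pred - exp| / exp * 100`. The report carries
#' the median (MRE) and mean (ARE) relative errors, the squared Pearson
#' correlation on raw CCS, and the cumulative error curve (fraction of
#' predictions with relative error below each threshold, in 0.5% steps).
#'
#' @param predicted,experimental numeric vectors of equal, nonzero length.
#' @return list of class `evaluation_report`: `MRE`, `ARE`, `R2`,
#'   `cumulative` (data.frame `threshold`, `fraction`), `relative_errors`.
#' @export
evaluate_predictions <- function(predicted, experimental) {
  if (!length(predicted) || length(predicted) != length(experimental))
    stop("need equal-length, non-empty prediction and reference vectors")
  re <- abs(predicted - experimental) / experimental * 100
  thr <- seq(0, ceiling(max(re) * 2) / 2 + 0.5, by = 0.5)
  cum <- data.frame(threshold = thr,
                    fraction = vapply(thr, function(t) mean(re <= t), 0))
  r2 <- if (length(re) > 1L && stats::sd(predicted) > 0)
    stats::cor(predicted, experimental)^2 else NA_real_
  structure(list(MRE = stats::median(re), ARE = mean(re), R2 = r2,
                 cumulative = cum, relative_errors = re),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n = %d | MRE %.2f%% | ARE %.2f%% | R2 %s\n",
              length(x$relative_errors), x$MRE, x$ARE,
              ifelse(is.na(x$R2), "NA", sprintf("%.4f", x$R2))))
  invisible(x)
}

#' Leave-one-superclass-out reliability experiment
#'
#' Instances are split into training and validation parts; for each chemical
#' super class a model is trained with that class removed from the training
#' part and evaluated on the validation part. Validation errors are labelled
#' `excluded` (compound belongs to the removed class) or not, and each
#' prediction carries its RSS against the reduced training set — the harness
#' behind the observation that structurally under-represented compounds
#' (low RSS) are predicted worse.
#'
#' @param instances training pairs (`compound_id`, `adduct`, `ccs`).
#' @param compounds compound table with `superclass` labels.
#' @param polarity model polarity.
#' @param valid_frac fraction held out for validation (default 0.2).
#' @param C,gamma fixed hyperparameters (tuning inside the loop is
#'   prohibitively slow; pass values tuned on the full set).
#' @param seed split seed.
#' @param adducts adduct table.
#' @return data.frame with one row per (validation instance x left-out
#'   class): `superclass_out`, `compound_id`, `adduct`, `superclass`,
#'   `excluded`, `ccs_true`, `ccs_pred`, `re`, `rss`.
#' @export
leave_class_out <- function(instances, compounds, polarity, C, gamma,
                            valid_frac = 0.2, seed = 1,
                            adducts = adduct_table()) {
  supercl <- compounds$superclass[match(instances$compound_id, compounds$id)]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- nrow(instances)
  valid <- logical(n)
  for (cls in unique(supercl)) {   # stratified split
    rows <- which(supercl == cls)
    valid[sample(rows, max(1L, round(valid_frac * length(rows))))] <- TRUE
  }
  out <- list()
  for (cls in unique(supercl)) {
    tr <- instances[!valid & supercl != cls, , drop = FALSE]
    va <- instances[valid, , drop = FALSE]
    model <- train_ccs_model(tr, compounds, polarity, C = C, gamma = gamma,
                             adducts = adducts)
    pred <- predict_ccs(model, compounds[match(va$compound_id, compounds$id),
                                         , drop = FALSE],
                        adduct = va$adduct, adducts = adducts)
    out[[cls]] <- data.frame(
      superclass_out = cls,
      compound_id = va$compound_id, adduct = va$adduct,
      superclass = supercl[valid],
      excluded = supercl[valid] == cls,
      ccs_true = va$ccs, ccs_pred = pred$ccs,
      re = abs(pred$ccs - va$ccs) / va$ccs * 100,
      rss = pred$rss, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
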