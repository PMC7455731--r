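#' @title Molecular descriptors and descriptor selection
#' @name descriptors
#' @description Numeric molecular descriptors are computed from SMILES
#'   structures through the OpenBabel/ChemmineR backend: bulk properties
#'   (logP, molar refractivity, TPSA, H-bond donor/acceptor counts),
#'   monoisotopic mass, per-element atom counts, ring and aromatic-ring
#'   counts, functional-group counts and derived composition ratios. The
#'   catalogue is recorded in the matrix provenance; it is backend-specific
#'   and deliberately not tied to any particular historical descriptor set.
NULL

.ELEMENTS <- c("C", "H", "N", "O", "S", "P", "F", "Cl", "Br", "I")

#' Compute a molecular descriptor matrix
#'
#' One row per compound, one column per descriptor. Unparseable structures
#' are reported via the `failed` attribute, never silently dropped.
#'
#' @param compounds compound table (needs `id`, `smiles`), or a character
#'   vector of SMILES named by id.
#' @return numeric matrix (rownames = compound ids) with attributes
#'   `provenance` (backend description) and `failed` (ids that did not parse).
#' @export
compute_descriptors <- function(compounds) {
  if (is.character(compounds))
    compounds <- data.frame(id = names(compounds), smiles = compounds,
                            stringsAsFactors = FALSE)
  smiles <- stats::setNames(as.character(compounds$smiles), compounds$id)
  sdf <- parse_structures(smiles)
  failed <- attr(sdf, "failed")
  if (length(sdf) == 0L) stop("no compound structure parsed")
  ids <- setdiff(names(smiles), failed)

  prop <- ChemmineR::propOB(sdf)
  num <- prop[, c("HBA1", "HBA2", "HBD", "logP", "MR", "MW", "TPSA", "nF")]
  exact_mass <- ChemmineR::exactMassOB(sdf)

  ac <- ChemmineR::atomcountMA(sdf, addH = TRUE)
  atoms <- matrix(0, nrow = length(sdf), ncol = length(.ELEMENTS),
                  dimnames = list(NULL, .ELEMENTS))
  common <- intersect(colnames(ac), .ELEMENTS)
  atoms[, common] <- ac[, common, drop = FALSE]

  rng <- ChemmineR::rings(sdf, type = "count", arom = TRUE)
  grp <- ChemmineR::groups(sdf, groups = "fctgroup", type = "countMA")

  heavy <- rowSums(atoms) - atoms[, "H"]
  hetero <- heavy - atoms[, "C"]
  safe_c <- pmax(atoms[, "C"], 1)
  X <- cbind(
    as.matrix(num),
    exact_mass = exact_mass,
    atoms,
    n_atoms = rowSums(atoms),
    n_heavy = heavy,
    n_hetero = hetero,
    rings = rng[, "RINGS"],
    aromatic_rings = rng[, "AROMATIC"],
    as.matrix(grp),
    ratio_HC = atoms[, "H"] / safe_c,
    ratio_OC = atoms[, "O"] / safe_c,
    ratio_NC = atoms[, "N"] / safe_c,
    hetero_frac = hetero / pmax(heavy, 1)
  )
  rownames(X) <- ids
  storage.mode(X) <- "double"
  attr(X, "provenance") <- paste0(
    "ChemmineR/OpenBabel backend; ", ncol(X), " descriptors: ",
    paste(colnames(X), collapse = ","))
  attr(X, "failed") <- failed
  X
}

#' K-nearest-neighbour imputation of missing cells
#'
#' Rows are compared by Euclidean distance over the columns both rows have
#' observed (distance scaled by the number of shared columns); each missing
#' cell is replaced by the mean of that column over the `k` nearest rows that
#' observe it. Falls back to the column mean when no neighbour observes the
#' column.
#'
#' @param X numeric matrix with `NA`s.
#' @param k neighbourhood size (default 5).
#' @return matrix without missing values.
#' @export
knn_impute <- function(X, k = 5) {
  if (!anyNA(X)) return(X)
  n <- nrow(X)
  col_means <- colMeans(X, na.rm = TRUE)
  miss_rows <- which(rowSums(is.na(X)) > 0L)
  for (i in miss_rows) {
    d <- rep(NA_real_, n)
    for (j in seq_len(n)) {
      if (j == i) next
      shared <- !is.na(X[i, ]) & !is.na(X[j, ])
      if (!any(shared)) next
      d[j] <- sqrt(sum((X[i, shared] - X[j, shared])^2) / sum(shared))
    }
    ord <- order(d, na.last = NA)
    for (col in which(is.na(X[i, ]))) {
      donors <- ord[!is.na(X[ord, col])]
      donors <- donors[seq_len(min(k, length(donors)))]
      X[i, col] <- if (length(donors)) mean(X[donors, col]) else col_means[col]
    }
  }
  X
}

#' Preprocess a descriptor matrix
#'
#' Drops non-differential (zero-variance or all-missing) columns, imputes the
#' remaining missing cells with [knn_impute()], and normalizes every column
#' to Z-scores. The column means and standard deviations are stored so the
#' identical transform can be applied to future query compounds.
#'
#' @param X raw descriptor matrix.
#' @param k KNN neighbourhood size.
#' @return normalized matrix with attributes `center`, `scale` (named numeric
#'   vectors over the retained columns) and `dropped` (removed column names).
#' @export
preprocess_descriptors <- function(X, k = 5) {
  all_na <- colSums(!is.na(X)) == 0L
  if (any(all_na))
    warning("all-missing descriptor columns dropped: ",
            paste(colnames(X)[all_na], collapse = ", "))
  X <- X[, !all_na, drop = FALSE]
  sds <- apply(X, 2L, stats::sd, na.rm = TRUE)
  keep <- !is.na(sds) & sds > 0
  dropped <- c(colnames(X)[!keep], names(all_na)[all_na])
  X <- X[, keep, drop = FALSE]
  X <- knn_impute(X, k = k)
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  Z <- sweep(sweep(X, 2L, center, "-"), 2L, scale, "/")
  attr(Z, "center") <- center
  attr(Z, "scale") <- scale
  attr(Z, "dropped") <- dropped
  Z
}

#' Apply stored normalization to new compounds
#'
#' @param X raw descriptor matrix for query compounds.
#' @param center,scale named statistics from [preprocess_descriptors()] (or a
#'   preprocessed matrix carrying them as attributes, passed as `center`).
#' @return Z-scored matrix restricted to the trained descriptor columns;
#'   missing cells are set to 0 (the training mean).
#' @export
apply_normalization <- function(X, center, scale = NULL) {
  if (is.matrix(center) && !is.null(attr(center, "center"))) {
    scale <- attr(center, "scale")
    center <- attr(center, "center")
  }
  cols <- names(center)
  miss <- setdiff(cols, colnames(X))
  if (length(miss)) stop("query matrix lacks descriptors: ",
                         paste(miss, collapse = ", "))
  Z <- sweep(sweep(X[, cols, drop = FALSE], 2L, center, "-"), 2L, scale, "/")
  Z[is.na(Z)] <- 0
  Z
}

# One recursive-elimination pass on (X, y): score each descriptor-set size by
# k-fold cross-validated LASSO (median relative error of pre-validated
# predictions at lambda.min), drop the descriptor with the smallest |coef|,
# recurse down to 2 columns. Among all scored sizes, the smallest set whose
# score is within `slack` (relative) of the best score is kept -- the
# parsimony rule that stops near-tied noise descriptors from riding along.
.rfe_once <- function(X, y, folds, slack = 0.25) {
  active <- colnames(X)
  sets <- list(); scores <- numeric()
  foldid <- sample(rep(seq_len(folds), length.out = length(y)))
  while (length(active) >= 2L) {
    cv <- glmnet::cv.glmnet(X[, active, drop = FALSE], y, nfolds = folds,
                            foldid = foldid, keep = TRUE)
    i <- match(cv$lambda.min, cv$lambda)
    pred <- cv$fit.preval[, i]
    sets[[length(sets) + 1L]] <- active
    scores <- c(scores, stats::median(abs(pred - y) / abs(y)) * 100)
    co <- stats::coef(cv, s = "lambda.min")[active, 1L]
    active <- active[-which.min(abs(co))]
  }
  ok <- which(scores <= min(scores) * (1 + slack))
  sets[[ok[length(ok)]]]   # sizes shrink along the path; last ok = smallest
}

#' Recursive feature elimination with cross-validation (RFECV)
#'
#' To remove the scale effect of the training set, random subsamples of 50,
#' 60, 70, 80 and 90% of the rows are drawn; on each subsample one recursive
#' LASSO elimination is run (the descriptor with the smallest absolute LASSO
#' coefficient is removed per step and every set size is scored by `folds`-fold
#' cross-validation; the best-scoring set is kept). Descriptors appearing in
#' more than `threshold` of the kept sets are selected. With the default 200
#' repeats per fraction (1000 total) the default threshold is 700; when the
#' total repeat count differs, `threshold` should be scaled proportionally.
#'
#' @param X preprocessed (Z-scored) descriptor matrix.
#' @param y CCS target vector.
#' @param fractions subsample fractions (default `seq(0.5, 0.9, 0.1)`).
#' @param reps_per_fraction repeats per fraction (default 200).
#' @param folds CV folds (default 10).
#' @param threshold selection frequency cut-off, on the scale of the total
#'   repeat count (default 700 when total = 1000; `NULL` scales 0.7
#'   proportionally).
#' @param seed integer seed for the subsampling stream.
#' @return list of class `selection_result`: `selected` (descriptor names),
#'   `frequencies` (named counts), `config`.
#' @export
rfecv_select <- function(X, y, fractions = seq(0.5, 0.9, 0.1),
                         reps_per_fraction = 200, folds = 10,
                         threshold = NULL, seed = 1) {
  total <- length(fractions) * reps_per_fraction
  if (is.null(threshold)) threshold <- 0.7 * total
  if (threshold >= total)
    stop("threshold (", threshold, ") must be below the total repeat count (",
         total, ")")
  stopifnot(nrow(X) == length(y), ncol(X) >= 2L)
  counts <- stats::setNames(numeric(ncol(X)), colnames(X))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (f in fractions) {
    for (r in seq_len(reps_per_fraction)) {
      rows <- sample(nrow(X), max(ceiling(f * nrow(X)), 3L * folds))
      set <- .rfe_once(X[rows, , drop = FALSE], y[rows], folds)
      counts[set] <- counts[set] + 1
    }
  }
  selected <- names(counts)[counts > threshold]
  if (!length(selected))  # never return an empty model
    selected <- names(counts)[which.max(counts)]
  structure(list(selected = selected, frequencies = counts,
                 config = list(fractions = fractions,
                               reps_per_fraction = reps_per_fraction,
                               folds = folds, threshold = threshold,
                               total = total, seed = seed)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>", length(x$selected), "descriptors selected of",
      length(x$frequencies), "\n")
  cat("  threshold:", x$config$threshold, "of", x$config$total, "repeats\n")
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Save / load a selection result as JSON
#'
#' @param x `selection_result`.
#' @param path JSON file path.
#' @export
write_selection <- function(x, path) {
  jsonlite::write_json(list(selected = x$selected,
                            frequencies = as.list(x$frequencies),
                            config = x$config),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(selected = j$selected,
                 frequencies = unlist(j$frequencies),
                 config = j$config),
            class = "selection_result")
}

# save/restore the RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
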