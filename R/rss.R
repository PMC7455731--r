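#' @title Representative structure similarity (RSS)
#' @name rss
#' @description The RSS score estimates how well a query structure is
#'   represented in a prediction model's training set, and hence how reliable
#'   its predicted CCS is likely to be. Molecular fingerprints are compared
#'   with the Tanimoto coefficient
#'   TC = |A intersect B| / (|A| + |B| - |A intersect B|),
#'   and RSS is the mean of the five highest TCs against the training set.
#'   Scores are banded into small (RSS <= 0.6), medium (0.6 < RSS <= 0.8) and
#'   large (RSS > 0.8) reliability groups.
NULL

#' Compute binary molecular fingerprints
#'
#' Path-based OpenBabel fingerprints (FP2: linear fragments up to seven atoms
#' hashed into 1024 bits) by default.
#'
#' @param compounds compound table (needs `id`, `smiles`) or named SMILES
#'   vector.
#' @param scheme OpenBabel fingerprint name (default `"FP2"`).
#' @return logical matrix, one row per compound (rownames = ids), with
#'   attribute `scheme`.
#' @export
compute_fingerprints <- function(compounds, scheme = "FP2") {
  if (is.character(compounds))
    compounds <- data.frame(id = names(compounds), smiles = compounds,
                            stringsAsFactors = FALSE)
  sdf <- parse_structures(stats::setNames(as.character(compounds$smiles),
                                          compounds$id))
  if (length(sdf) == 0L) stop("no compound structure parsed")
  fp <- ChemmineR::fingerprintOB(sdf, scheme)
  M <- methods::slot(fp, "fpma") > 0
  rownames(M) <- setdiff(compounds$id, attr(sdf, "failed"))
  attr(M, "scheme") <- scheme
  attr(M, "failed") <- attr(sdf, "failed")
  M
}

#' Tanimoto coefficient between fingerprints
#'
#' `tanimoto(a, b)` for two bit vectors, or one bit vector against every row
#' of a fingerprint matrix. Two empty fingerprints are defined as identical
#' (TC = 1).
#'
#' @param a logical/0-1 vector.
#' @param b logical/0-1 vector or matrix with `length(a)` columns.
#' @return TC in \[0, 1\] (vector when `b` is a matrix).
#' @export
#' @examples
#' tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 1/3
tanimoto <- function(a, b) {
  a <- as.logical(a)
  if (is.matrix(b)) {
    if (ncol(b) != length(a)) stop("fingerprint schemes/lengths differ")
    b <- b > 0
    inter <- as.vector(b %*% a)
    uni <- sum(a) + unname(rowSums(b)) - inter
    ifelse(uni == 0, 1, inter / uni)
  } else {
    if (length(b) != length(a)) stop("fingerprint schemes/lengths differ")
    b <- as.logical(b)
    inter <- sum(a & b)
    uni <- sum(a) + sum(b) - inter
    if (uni == 0) 1 else inter / uni
  }
}

#' RSS score of a structure against a training fingerprint set
#'
#' Tanimoto coefficients against all training fingerprints are sorted
#' descending and the top five (or all, if fewer are available) are averaged.
#'
#' @param query a SMILES string, or a logical fingerprint vector matching the
#'   training scheme.
#' @param training_fp training fingerprint matrix from
#'   [compute_fingerprints()].
#' @param n_top how many top coefficients to average (default 5).
#' @param exclude_self drop perfect self-matches (TC exactly 1 from an
#'   identical training structure) before averaging; used by leave-one-out
#'   experiments. Default `FALSE`: an identical training structure counts.
#' @return list of class `rss_result`: `rss`, `top_tcs`, `nearest_ids`,
#'   `group`, `scheme`.
#' @export
rss_score <- function(query, training_fp, n_top = 5, exclude_self = FALSE) {
  stopifnot(nrow(training_fp) >= 1L)
  if (is.character(query)) {
    qfp <- compute_fingerprints(c(q = query),
                                scheme = attr(training_fp, "scheme") %||% "FP2")
    if (nrow(qfp) == 0L) stop("query structure did not parse")
    query <- qfp[1L, ]
  }
  tc <- tanimoto(query, training_fp)
  names(tc) <- rownames(training_fp)
  if (exclude_self) tc <- tc[tc < 1]
  if (!length(tc)) stop("no training structures left to compare against")
  ord <- order(tc, decreasing = TRUE)
  top <- ord[seq_len(min(n_top, length(tc)))]
  rss <- mean(tc[top])
  structure(list(rss = rss, top_tcs = unname(tc[top]),
                 nearest_ids = names(tc)[top], group = rss_group(rss),
                 scheme = attr(training_fp, "scheme")),
            class = "rss_result")
}

#' @export
print.rss_result <- function(x, ...) {
  cat(sprintf("<rss_result> RSS = %.4f (%s group, scheme %s)\n",
              x$rss, x$group, x$scheme %||% "?"))
  invisible(x)
}

#' Reliability group of an RSS score
#'
#' @param rss numeric in \[0, 1\].
#' @return `"small"` (RSS <= 0.6), `"medium"` (0.6 < RSS <= 0.8) or `"large"`
#'   (RSS > 0.8); boundary values 0.6 and 0.8 fall in small and medium.
#' @export
rss_group <- function(rss) {
  if (any(rss < 0 | rss > 1)) stop("RSS must lie in [0, 1]")
  ifelse(rss <= 0.6, "small", ifelse(rss <= 0.8, "medium", "large"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
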