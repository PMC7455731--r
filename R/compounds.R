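#' @title Compound registry
#' @name compounds
#' @description Compounds are plain data.frames with one row per neutral
#'   structure. The canonical columns are `id`, `name`, `smiles`, `inchikey`,
#'   `formula`, `mass` (monoisotopic, Da) and the optional taxonomy columns
#'   `superclass`, `class`, `subclass`. Only `id` and `smiles` are required on
#'   ingest; masses and formulas are filled in from the structures.
NULL

.INCHIKEY_RE <- "^[A-Z]{14}-[A-Z]{10}-[A-Z]$"

.compound_cols <- c("id", "name", "smiles", "inchikey", "formula", "mass",
                    "superclass", "class", "subclass")

#' Parse SMILES structures into an SDF set
#'
#' Structures that fail to parse are reported (not silently dropped): the
#' return value carries a `failed` attribute with the offending ids.
#'
#' @param smiles character vector of SMILES strings, named by compound id.
#' @return `ChemmineR::SDFset` for the parseable structures, with attribute
#'   `failed` (character vector of ids that did not parse).
#' @export
parse_structures <- function(smiles) {
  if (is.null(names(smiles))) names(smiles) <- as.character(seq_along(smiles))
  empty <- is.na(smiles) | !nzchar(smiles)
  ok_smiles <- smiles[!empty]
  parse <- function(s)
    tryCatch(suppressWarnings(ChemmineR::smiles2sdf(s)),
             error = function(e) NULL)
  sdf <- if (length(ok_smiles)) parse(ok_smiles) else NULL
  if (is.null(sdf) && length(ok_smiles) > 1L) {
    # the batch failed outright: isolate the offenders one by one
    good <- names(ok_smiles)[vapply(names(ok_smiles), function(id)
      !is.null(parse(ok_smiles[id])), TRUE)]
    sdf <- if (length(good)) parse(ok_smiles[good]) else NULL
  }
  # the backend silently drops unparseable structures from a batch, so the
  # failure list comes from comparing returned ids against the input
  parsed <- if (is.null(sdf)) character() else ChemmineR::cid(sdf)
  valid <- if (is.null(sdf)) logical() else ChemmineR::validSDF(sdf)
  kept <- parsed[valid]
  if (!length(kept)) stop("no compound structure parsed")
  sdf <- sdf[valid]
  attr(sdf, "failed") <- setdiff(names(smiles), kept)
  sdf
}

#' Build a validated compound table
#'
#' Parses structures, computes monoisotopic masses and formulas where missing,
#' and validates InChIKeys against the 14-10-1 block pattern.
#'
#' @param df data.frame with at least `id` and `smiles`.
#' @return data.frame with the canonical compound columns; unparseable rows are
#'   dropped and reported via attribute `failed`.
#' @export
compound_table <- function(df) {
  stopifnot(is.data.frame(df), all(c("id", "smiles") %in% names(df)))
  if (anyDuplicated(df$id)) stop("compound ids must be unique")
  for (col in .compound_cols)
    if (is.null(df[[col]])) df[[col]] <- NA
  smiles <- stats::setNames(as.character(df$smiles), df$id)
  sdf <- parse_structures(smiles)
  failed <- attr(sdf, "failed")
  if (length(failed) == length(smiles)) stop("no compound structure parsed")
  df <- df[!(df$id %in% failed), , drop = FALSE]
  prop <- ChemmineR::propOB(sdf)
  mass <- ChemmineR::exactMassOB(sdf)
  miss <- is.na(df$mass)
  df$mass[miss] <- mass[miss]
  df$formula[is.na(df$formula)] <- prop$formula[is.na(df$formula)]
  if (any(df$mass <= 0, na.rm = TRUE)) stop("nonpositive neutral mass")
  has_key <- !is.na(df$inchikey) & nzchar(df$inchikey)
  bad_key <- has_key & !grepl(.INCHIKEY_RE, df$inchikey)
  if (any(bad_key))
    warning("malformed InChIKey for: ", paste(df$id[bad_key], collapse = ", "))
  out <- df[, .compound_cols]
  rownames(out) <- NULL
  attr(out, "failed") <- failed
  out
}

#' Read a compound table from CSV/TSV
#'
#' The file must carry a header; the separator is sniffed from the first line
#' (tab wins over comma). Column names are lower-cased; `structure` is accepted
#' as an alias for `smiles`.
#'
#' @param path file path (UTF-8 text).
#' @return validated compound table (see [compound_table()]).
#' @export
read_compound_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, quote = "\"",
                          stringsAsFactors = FALSE, comment.char = "",
                          fileEncoding = "UTF-8")
  names(df) <- tolower(names(df))
  if (is.null(df$smiles) && !is.null(df$structure)) df$smiles <- df$structure
  compound_table(df)
}

#' Write a compound table to TSV
#'
#' @param compounds compound table.
#' @param path output path.
#' @export
write_compound_table <- function(compounds, path) {
  utils::write.table(compounds[, intersect(.compound_cols, names(compounds))],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
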