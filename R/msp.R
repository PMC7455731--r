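#' @title MSP spectral library IO
#' @name msp
#' @description Spectra are lists with elements `peaks` (two-column numeric
#'   matrix, m/z and intensity, sorted by m/z), `precursor_mz` (Da or `NA`) and
#'   `metadata` (named character vector, canonical upper-case-first keys).
#'   The MSP dialect read here is the common NIST-style one: `KEY: value`
#'   header lines, a `Num Peaks:` line, then one `mz intensity` pair per line
#'   (tab or space separated), records separated by blank lines.
NULL

#' Construct a spectrum
#'
#' @param mz,intensity numeric vectors of equal length (at least one peak);
#'   intensities must be nonnegative.
#' @param precursor_mz precursor ion m/z (Da), or `NA`.
#' @param metadata named character vector of header fields.
#' @return a `spectrum` object; peaks are sorted by ascending m/z.
#' @export
spectrum <- function(mz, intensity, precursor_mz = NA_real_,
                     metadata = character()) {
  stopifnot(length(mz) == length(intensity), length(mz) >= 1L)
  if (any(intensity < 0)) stop("intensities must be >= 0")
  o <- order(mz)
  s <- list(peaks = cbind(mz = as.numeric(mz[o]),
                          intensity = as.numeric(intensity[o])),
            precursor_mz = as.numeric(precursor_mz),
            metadata = metadata)
  class(s) <- "spectrum"
  s
}

#' @export
print.spectrum <- function(x, ...) {
  nm <- if ("NAME" %in% names(x$metadata)) x$metadata[["NAME"]] else ""
  cat("<spectrum>", nm, "\n")
  cat("  precursor m/z:", x$precursor_mz, "\n")
  cat("  peaks:", nrow(x$peaks), "\n")
  invisible(x)
}

.canon_key <- function(key) {
  key <- trimws(key)
  up <- toupper(key)
  if (up == "PRECURSORMZ" || up == "PRECURSOR_MZ") return("PRECURSORMZ")
  if (up == "NUM PEAKS" || up == "NUMPEAKS") return("NUM PEAKS")
  up
}

#' Read an MSP spectral library
#'
#' Tolerant of lower-case keys and of tab or space separated peak lines.
#' Records whose peak-line count disagrees with their `Num Peaks` header are
#' skipped with a warning; the number of skipped records is available as
#' attribute `n_skipped` on the result.
#'
#' @param path MSP file path.
#' @return list of [spectrum()] objects (attribute `n_skipped`: records
#'   dropped because of malformed peak counts).
#' @export
read_msp <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  # split on blank lines into record blocks
  blank <- !nzchar(trimws(lines))
  grp <- cumsum(blank)
  blocks <- split(lines[!blank], grp[!blank])
  spectra <- list()
  n_skipped <- 0L
  for (block in blocks) {
    is_peak <- grepl("^\\s*[0-9]", block)
    header <- block[!is_peak]
    peak_lines <- block[is_peak]
    kv <- regmatches(header, regexec("^([^:]+):\\s*(.*)$", header))
    kv <- kv[lengths(kv) == 3L]
    meta <- stats::setNames(vapply(kv, `[`, "", 3L),
                            vapply(kv, function(x) .canon_key(x[2L]), ""))
    declared <- if ("NUM PEAKS" %in% names(meta))
      suppressWarnings(as.integer(meta[["NUM PEAKS"]])) else NA_integer_
    if (is.na(declared)) declared <- length(peak_lines)
    if (declared != length(peak_lines) || length(peak_lines) == 0L) {
      warning("MSP record '", if ("NAME" %in% names(meta)) meta[["NAME"]] else "?",
              "': declared ", declared, " peaks but found ",
              length(peak_lines), "; record skipped")
      n_skipped <- n_skipped + 1L
      next
    }
    vals <- lapply(strsplit(trimws(peak_lines), "[\t ;]+"), as.numeric)
    mz <- vapply(vals, `[`, 0, 1L)
    it <- vapply(vals, `[`, 0, 2L)
    prec <- if ("PRECURSORMZ" %in% names(meta))
      suppressWarnings(as.numeric(meta[["PRECURSORMZ"]])) else NA_real_
    meta <- meta[setdiff(names(meta), "NUM PEAKS")]
    spectra[[length(spectra) + 1L]] <- spectrum(mz, it, prec, meta)
  }
  attr(spectra, "n_skipped") <- n_skipped
  spectra
}

#' Write spectra to an MSP file
#'
#' Records are written in canonical form: upper-case keys with `NAME` first,
#' `PRECURSORMZ` when present, remaining metadata in alphabetical order,
#' `Num Peaks`, then tab-separated peaks sorted by m/z. [read_msp()] composed
#' with `write_msp()` is the identity on canonical records.
#'
#' @param spectra list of [spectrum()] objects.
#' @param path output file path.
#' @export
write_msp <- function(spectra, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (s in spectra) {
    meta <- s$metadata
    nm <- if ("NAME" %in% names(meta) && nzchar(meta[["NAME"]]))
      meta[["NAME"]] else "unknown"
    writeLines(paste0("NAME: ", nm), con)
    if (!is.na(s$precursor_mz))
      writeLines(paste0("PRECURSORMZ: ", format(s$precursor_mz, digits = 10)), con)
    rest <- meta[setdiff(names(meta), c("NAME", "PRECURSORMZ"))]
    for (k in sort(names(rest)))
      writeLines(paste0(k, ": ", rest[[k]]), con)
    writeLines(paste0("Num Peaks: ", nrow(s$peaks)), con)
    writeLines(paste0(format(s$peaks[, 1L], digits = 10, trim = TRUE), "\t",
                      format(s$peaks[, 2L], digits = 10, trim = TRUE)), con)
    writeLines("", con)
  }
  invisible(path)
}
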