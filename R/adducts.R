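#' @title Adduct arithmetic and mass-accuracy utilities
#' @name adducts
#' @description Electrospray adducts are handled as net ion mass shifts: the
#'   shift already folds in the electron mass, so the theoretical ion m/z of a
#'   singly charged adduct is simply `neutral_mass + mass_shift`.
NULL

# Monoisotopic proton mass (Da); the single constant all adduct shifts build on.
PROTON_MASS <- 1.00727646688
ELECTRON_MASS <- 0.00054857990

.H_ATOM <- 1.00782503207
.H2O <- 18.01056468403
.NA_ATOM <- 22.98976928
.K_ATOM <- 38.96370649
.NH3 <- 17.02654910112
.CH3CN <- 41.02654910112
.CH3OH <- 32.02621474611
.HCOOH <- 46.00547930326
.CH3COOH <- 60.02112936933
.CL_ATOM <- 34.96885268

.adduct_table <- function() {
  data.frame(
    name = c("[M+H]+", "[M+NH4]+", "[M+Na]+", "[M+K]+", "[M+H-H2O]+",
             "[M+H-2H2O]+", "[M+CH3CN+H]+", "[M+CH3OH+H]+", "[M+2Na-H]+",
             "[M-H]-", "[M+Na-2H]-", "[M+HCOO]-", "[M+CH3COO]-",
             "[M-H-H2O]-", "[M+Cl]-"),
    polarity = c(rep("+", 9L), rep("-", 6L)),
    mass_shift = c(
      PROTON_MASS,
      .NH3 + PROTON_MASS,
      .NA_ATOM - ELECTRON_MASS,
      .K_ATOM - ELECTRON_MASS,
      PROTON_MASS - .H2O,
      PROTON_MASS - 2 * .H2O,
      .CH3CN + PROTON_MASS,
      .CH3OH + PROTON_MASS,
      2 * .NA_ATOM - .H_ATOM - ELECTRON_MASS,
      -PROTON_MASS,
      .NA_ATOM - 2 * .H_ATOM + ELECTRON_MASS,
      .HCOOH - PROTON_MASS,
      .CH3COOH - PROTON_MASS,
      -PROTON_MASS - .H2O,
      .CL_ATOM + ELECTRON_MASS),
    charge = c(rep(1L, 9L), rep(-1L, 6L)),
    stringsAsFactors = FALSE
  )
}

#' Adduct whitelist
#'
#' Returns the table of supported electrospray adducts: nine positive and six
#' negative singly charged species. `mass_shift` is the net ion shift in Da
#' (electron mass included), so ion m/z = neutral mass + shift.
#'
#' @param polarity optional filter, `"+"` or `"-"`.
#' @param training if `TRUE`, restrict to the seven adducts used for training
#'   CCS prediction models: \[M+H\]+, \[M+Na\]+, \[M+NH4\]+, \[M+H-H2O\]+ in
#'   positive mode and \[M-H\]-, \[M+Na-2H\]-, \[M+HCOO\]- in negative mode.
#' @param extra optional data.frame with columns `name`, `polarity`,
#'   `mass_shift`, `charge` appended to the shipped table (user extension).
#' @return data.frame with columns `name`, `polarity`, `mass_shift`, `charge`.
#' @export
#' @examples
#' adduct_table(polarity = "+")
#' adduct_table(training = TRUE)
adduct_table <- function(polarity = NULL, training = FALSE, extra = NULL) {
  tab <- .adduct_table()
  if (!is.null(extra)) {
    need <- c("name", "polarity", "mass_shift", "charge")
    if (!all(need %in% names(extra)))
      stop("`extra` must have columns: ", paste(need, collapse = ", "))
    tab <- rbind(tab, extra[, need])
  }
  if (training) {
    keep <- c("[M+H]+", "[M+Na]+", "[M+NH4]+", "[M+H-H2O]+",
              "[M-H]-", "[M+Na-2H]-", "[M+HCOO]-")
    tab <- tab[tab$name %in% keep, , drop = FALSE]
  }
  if (!is.null(polarity)) {
    polarity <- match.arg(polarity, c("+", "-"))
    tab <- tab[tab$polarity == polarity, , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}

#' Look up one adduct by name
#'
#' @param name adduct name, e.g. `"[M+H]+"`.
#' @param adducts adduct table to search (default the shipped whitelist).
#' @return one-row data.frame.
#' @export
get_adduct <- function(name, adducts = adduct_table()) {
  hit <- adducts[adducts$name == name, , drop = FALSE]
  if (nrow(hit) == 0L)
    stop("Unknown adduct '", name, "'. Supported adducts: ",
         paste(adducts$name, collapse = ", "))
  hit[1L, , drop = FALSE]
}

#' Theoretical ion m/z for an adduct
#'
#' @param neutral_mass monoisotopic neutral mass in Da (positive scalar or
#'   vector).
#' @param adduct adduct name (string) or a one-row adduct table entry.
#' @param adducts adduct table used for the lookup when `adduct` is a name.
#' @return ion m/z in Da.
#' @export
#' @examples
#' compute_adduct_mz(180.06339, "[M+H]+")   # 181.07067
#' compute_adduct_mz(180.06339, "[M-H]-")   # 179.05611
compute_adduct_mz <- function(neutral_mass, adduct, adducts = adduct_table()) {
  if (any(!is.finite(neutral_mass)) || any(neutral_mass <= 0))
    stop("`neutral_mass` must be positive and finite")
  if (is.character(adduct)) adduct <- get_adduct(adduct, adducts)
  # |z| = 1 throughout; division by charge reserved for multiply charged ions
  neutral_mass + adduct$mass_shift
}

#' Mass error in parts per million
#'
#' @param observed,theoretical masses in Da, both positive.
#' @param signed if `TRUE` keep the sign of `observed - theoretical`.
#' @return error in ppm: `|observed - theoretical| / theoretical * 1e6`.
#' @export
#' @examples
#' ppm_error(100.0010, 100.0000)  # 10
ppm_error <- function(observed, theoretical, signed = FALSE) {
  if (any(!is.finite(observed)) || any(!is.finite(theoretical)) ||
      any(observed <= 0) || any(theoretical <= 0))
    stop("masses must be positive and finite")
  err <- (observed - theoretical) / theoretical * 1e6
  if (signed) err else abs(err)
}
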