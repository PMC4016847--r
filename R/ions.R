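# Singly charged positive-mode ion species.  Each label fixes the atoms added
# to and removed from the neutral molecule; m/z = neutral + added - removed -
# one electron (charge is +1 throughout: ESI positive mode, no multimers).

.ION_TABLE <- list(
  "[M+H]+"        = list(add = c(H = 1L),           rem = NULL),
  "[M+Na]+"       = list(add = c(Na = 1L),          rem = NULL),
  "[M+H-H2O]+"    = list(add = c(H = 1L),           rem = c(H = 2L, O = 1L)),
  "[M+H-2xH2O]+"  = list(add = c(H = 1L),           rem = c(H = 4L, O = 2L))
)

.normalize_ion_label <- function(label) {
  # Accept cosmetic variants seen in print: unicode minus, spaces, "2x"/"2 x".
  x <- gsub("−|–", "-", label)
  x <- gsub("[[:space:]]", "", x)
  x <- gsub("2x|2X|2×", "2x", x)
  x
}

#' Ion species descriptor
#'
#' Returns the adduct description for one of the in-scope singly charged
#' positive ion species: \code{"[M+H]+"}, \code{"[M+Na]+"},
#' \code{"[M+H-H2O]+"}, \code{"[M+H-2xH2O]+"}.
#'
#' @param label Ion species label.  Spaces and typographic minus signs are
#'   tolerated (\code{"[M + Na]+"} works).
#' @return A list with \code{label}, \code{atoms_added}, \code{atoms_removed}
#'   (both \code{chem_formula}) and \code{charge} (always \code{1L}).
#' @export
ion_species <- function(label) {
  key <- .normalize_ion_label(label)
  spec <- .ION_TABLE[[key]]
  if (is.null(spec)) {
    stop("unknown ion species: ", sQuote(label),
         " (known: ", paste(names(.ION_TABLE), collapse = ", "), ")", call. = FALSE)
  }
  list(
    label = key,
    atoms_added = chem_formula(if (is.null(spec$add)) integer() else spec$add),
    atoms_removed = chem_formula(if (is.null(spec$rem)) integer() else spec$rem),
    charge = 1L
  )
}

#' Theoretical m/z of an ion of a neutral molecule
#'
#' \code{(mass(f) + mass(added) - mass(removed) - m_e) / charge}, with the
#' electron mass subtracted for the positive charge.  Computed at full
#' precision; display formatting (4 decimal places) is left to the callers.
#'
#' @param f Neutral molecular formula (\code{chem_formula} or string).
#' @param ion Ion species label or the result of [ion_species()].
#' @return m/z in Th.
#' @examples
#' ion_mz("C45H76O19", "[M+Na]+") # 943.4873
#' ion_mz("C33H54O8", "[M+Na]+")  # 601.3711
#' @export
ion_mz <- function(f, ion = "[M+Na]+") {
  f <- .as_formula(f)
  if (is.character(ion)) ion <- ion_species(ion)
  # removal must not exceed neutral + added atoms
  avail <- formula_add(f, ion$atoms_added)
  ionf <- formula_subtract(avail, ion$atoms_removed) # errors if it would go negative
  (monoisotopic_mass(ionf) - .ELECTRON_MASS) / ion$charge
}

#' Mass error in parts per million
#'
#' \code{(theoretical - experimental) / theoretical * 1e6}.  This sign
#' convention reproduces the printed errors of the reference annotation table
#' (a heavier experimental mass gives a negative error).
#'
#' @param theoretical,experimental m/z values, both > 0.
#' @return Error in ppm, full precision (round to 1 decimal for display).
#' @examples
#' ppm_error(943.4873, 943.4886) # -1.4 at 1 dp
#' @export
ppm_error <- function(theoretical, experimental) {
  if (any(theoretical <= 0) || any(experimental <= 0)) {
    stop("m/z values must be positive", call. = FALSE)
  }
  (theoretical - experimental) / theoretical * 1e6
}
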