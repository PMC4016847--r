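#' @keywords internal
"_PACKAGE"

# Monoisotopic atomic masses (Da). C is exactly 12 by definition; the others
# are CODATA/IUPAC values to >= 6 decimal places, which is what it takes to
# reproduce sodiated-adduct m/z of ~900 Da glycosides at 4 decimal places.
.MONOISOTOPIC <- c(
  C  = 12,
  H  = 1.0078250319,
  O  = 15.9949146221,
  N  = 14.0030740052,
  Na = 22.98976928,
  S  = 31.97207117,
  P  = 30.97376163
)

# Electron rest mass (Da); subtracted once per positive charge.
.ELECTRON_MASS <- 0.00054857990907

#' Parse an elemental formula in Hill notation
#'
#' Parses strings such as \code{"C45H76O19"} into a named integer vector of
#' element counts.  Repeated element symbols are summed, so
#' \code{"CH3CH3"} equals \code{"C2H6"}.  Only elements with a defined
#' monoisotopic mass are accepted.
#'
#' @param text A single formula string, e.g. \code{"C45H76O19"} or
#'   \code{"H2O"}.  An element symbol may be followed by an optional positive
#'   integer count (absent means 1).
#' @return An object of class \code{chem_formula}: a named integer vector of
#'   element counts in Hill order (C, H, then alphabetical).
#' @examples
#' parse_formula("C45H76O19")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) {
    stop("empty formula string", call. = FALSE)
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1L]]
  tokens <- regmatches(text, gregexpr("([A-Z][a-z]?)([0-9]*)", text))[[1L]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    stop("cannot parse formula: ", sQuote(text), call. = FALSE)
  }
  syms <- sub("[0-9]*$", "", tokens)
  nums <- sub("^[A-Za-z]+", "", tokens)
  counts <- ifelse(nzchar(nums), suppressWarnings(as.integer(nums)), 1L)
  bad <- !(syms %in% names(.MONOISOTOPIC))
  if (any(bad)) {
    stop("unknown element symbol: ", paste(sQuote(unique(syms[bad])), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(counts)) || any(counts <= 0L)) {
    stop("element counts must be positive integers in ", sQuote(text), call. = FALSE)
  }
  out <- tapply(counts, syms, sum)
  chem_formula(stats::setNames(as.integer(out), names(out)))
}

#' Construct a chem_formula from named counts
#'
#' @param counts Named integer vector (element symbol -> count >= 0).
#'   Zero counts are dropped.
#' @return A \code{chem_formula} object in Hill order.
#' @export
chem_formula <- function(counts = integer()) {
  if (length(counts)) {
    stopifnot(!is.null(names(counts)), all(nzchar(names(counts))))
    counts <- counts[counts != 0L]
    if (any(counts < 0L)) {
      stop("negative element count in formula", call. = FALSE)
    }
    bad <- !(names(counts) %in% names(.MONOISOTOPIC))
    if (any(bad)) {
      stop("unknown element symbol: ",
           paste(sQuote(names(counts)[bad]), collapse = ", "), call. = FALSE)
    }
    counts <- counts[.hill_order(names(counts))]
  }
  structure(as.integer(counts), names = names(counts), class = "chem_formula")
}

.hill_order <- function(syms) {
  # Hill convention: C first, H second, then remaining symbols alphabetical.
  rank <- match(syms, c("C", "H"), nomatch = NA_integer_)
  order(ifelse(is.na(rank), 3L, rank), syms)
}

.as_formula <- function(f) {
  if (inherits(f, "chem_formula")) f else if (is.character(f)) parse_formula(f)
  else chem_formula(f)
}

#' Canonical Hill-notation string of a formula
#'
#' @param f A \code{chem_formula} (or a string, which is parsed first).
#' @return A single string; \code{parse_formula(formula_string(f))} equals
#'   \code{f}.
#' @export
formula_string <- function(f) {
  f <- .as_formula(f)
  if (!length(f)) return("")
  paste0(names(f), ifelse(f == 1L, "", f), collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<formula> ", formula_string(x), "  (", format(monoisotopic_mass(x), nsmall = 4),
      " Da)\n", sep = "")
  invisible(x)
}

#' @export
format.chem_formula <- function(x, ...) formula_string(x)

#' Formula arithmetic
#'
#' Element-wise sum or difference of two formulas.  Subtraction that would
#' drive any element negative is an error (you cannot remove atoms that are
#' not there).
#'
#' @param a,b \code{chem_formula} objects or formula strings.
#' @return A \code{chem_formula}.
#' @export
formula_add <- function(a, b) {
  a <- .as_formula(a); b <- .as_formula(b)
  syms <- union(names(a), names(b))
  out <- stats::setNames(integer(length(syms)), syms)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  chem_formula(out)
}

#' @rdname formula_add
#' @export
formula_subtract <- function(a, b) {
  a <- .as_formula(a); b <- .as_formula(b)
  syms <- union(names(a), names(b))
  out <- stats::setNames(integer(length(syms)), syms)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] - b
  if (any(out < 0L)) {
    stop("formula subtraction would give negative counts for: ",
         paste(names(out)[out < 0L], collapse = ", "), call. = FALSE)
  }
  chem_formula(out)
}

#' Monoisotopic mass of a formula
#'
#' Sum of count times monoisotopic atomic mass over all elements.  Additive:
#' \code{monoisotopic_mass(formula_add(a, b))} equals the sum of the parts.
#'
#' @param f A \code{chem_formula} or formula string.
#' @return Mass in Da (0 for the empty formula).
#' @examples
#' monoisotopic_mass("H2O")     # 18.0106
#' monoisotopic_mass("C6H10O5") # 162.0528, the glycosidic hexose residue
#' @export
monoisotopic_mass <- function(f) {
  f <- .as_formula(f)
  if (!length(f)) return(0)
  sum(as.numeric(f) * .MONOISOTOPIC[names(f)])
}
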