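#' Construct a QTOF spectrum record
#'
#' One chromatographic peak: retention time, observed precursor m/z, the
#' precursor ion species seen in-source, and the MS/MS fragment list.
#'
#' @param peak_id Peak identifier (coerced to character).
#' @param rt_min Retention time in minutes (>= 0).
#' @param precursor_mz Observed precursor m/z (> 0).
#' @param ions_seen Character vector of precursor ion species labels
#'   observed, e.g. \code{c("[M+Na]+", "[M+H-H2O]+")}.
#' @param fragments Numeric vector of observed fragment m/z (> 0).
#' @param intensities Optional numeric vector parallel to \code{fragments}.
#' @return A list of class \code{qtof_spectrum}.
#' @export
qtof_spectrum <- function(peak_id, rt_min, precursor_mz,
                          ions_seen = character(), fragments = numeric(),
                          intensities = NULL) {
  rt_min <- as.numeric(rt_min)
  precursor_mz <- as.numeric(precursor_mz)
  fragments <- as.numeric(fragments)
  stopifnot(length(rt_min) == 1L, length(precursor_mz) == 1L)
  if (is.na(rt_min) || rt_min < 0) stop("rt_min must be >= 0", call. = FALSE)
  if (is.na(precursor_mz) || precursor_mz <= 0) {
    stop("precursor_mz must be > 0", call. = FALSE)
  }
  if (length(fragments) && (anyNA(fragments) || any(fragments <= 0))) {
    stop("fragment m/z must all be > 0", call. = FALSE)
  }
  ions_seen <- vapply(as.character(ions_seen), .normalize_ion_label, "")
  if (!is.null(intensities)) {
    intensities <- as.numeric(intensities)
    stopifnot(length(intensities) == length(fragments))
  }
  structure(list(peak_id = as.character(peak_id), rt_min = rt_min,
                 precursor_mz = precursor_mz,
                 ions_seen = unname(ions_seen),
                 fragments = fragments, intensities = intensities),
            class = "qtof_spectrum")
}

#' @export
print.qtof_spectrum <- function(x, ...) {
  cat("<spectrum> peak ", x$peak_id, "  RT ", sprintf("%.1f", x$rt_min),
      " min  precursor ", sprintf("%.4f", x$precursor_mz),
      "  [", paste(x$ions_seen, collapse = ", "), "]\n",
      "  fragments: ", paste(sprintf("%.4f", x$fragments), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
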