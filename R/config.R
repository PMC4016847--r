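#' Pipeline configuration
#'
#' Bundles the tunable tolerances of the dereplication and assay stages.
#'
#' @param precursor_ppm_tol Precursor formula-match window in ppm (default 5;
#'   generous relative to the <= 2.8 ppm accuracy of a calibrated QTOF).
#' @param fragment_tol_da Absolute fragment-match window in Da (default 0.5,
#'   for nominal integer ladders).
#' @param fragment_tol_ppm Relative fragment window in ppm for accurate
#'   MS/MS spectra (default 20).
#' @param alpha Significance level of the assay statistics (default 0.05).
#' @param inhibition_formula \code{"blank-corrected"} (default) or
#'   \code{"raw-ratio"}; see [inhibition_percent()].
#' @param precursor_ion Ion species assumed for the observed precursor
#'   (default \code{"[M+Na]+"}).
#' @param seed Optional integer seed recorded for simulation runs.
#' @param library_path Optional path to a candidate library TSV
#'   (\code{NULL} = packaged library).
#' @return A list of class \code{screen_config}.
#' @export
screen_config <- function(precursor_ppm_tol = 5,
                          fragment_tol_da = 0.5,
                          fragment_tol_ppm = 20,
                          alpha = 0.05,
                          inhibition_formula = c("blank-corrected", "raw-ratio"),
                          precursor_ion = "[M+Na]+",
                          seed = NULL,
                          library_path = NULL) {
  inhibition_formula <- match.arg(inhibition_formula)
  stopifnot(precursor_ppm_tol > 0, fragment_tol_da > 0, fragment_tol_ppm > 0,
            alpha > 0, alpha < 1)
  structure(list(
    precursor_ppm_tol = precursor_ppm_tol,
    fragment_tol_da = fragment_tol_da,
    fragment_tol_ppm = fragment_tol_ppm,
    alpha = alpha,
    inhibition_formula = inhibition_formula,
    precursor_ion = precursor_ion,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    library_path = if (is.null(library_path)) NA_character_ else library_path
  ), class = "screen_config")
}

#' @export
print.screen_config <- function(x, ...) {
  cat("<screen config>\n")
  for (k in names(x)) cat("  ", k, " = ", format(x[[k]]), "\n", sep = "")
  invisible(x)
}

#' Read / write a flat key-value configuration file
#'
#' The format is one \code{key = value} pair per line, UTF-8, \code{'#'}
#' comments allowed.  A write/read round trip reproduces the configuration.
#'
#' @param path File path.
#' @return \code{read_config} returns a \code{screen_config};
#'   \code{write_config} returns \code{path} invisibly.
#' @export
read_config <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, 0L) != 2L
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
                     call. = FALSE)
  vals <- stats::setNames(vapply(kv, `[[`, "", 2L), vapply(kv, `[[`, "", 1L))
  num <- function(k, d) if (k %in% names(vals)) as.numeric(vals[[k]]) else d
  chr <- function(k, d) if (k %in% names(vals)) vals[[k]] else d
  screen_config(
    precursor_ppm_tol = num("precursor_ppm_tol", 5),
    fragment_tol_da = num("fragment_tol_da", 0.5),
    fragment_tol_ppm = num("fragment_tol_ppm", 20),
    alpha = num("alpha", 0.05),
    inhibition_formula = chr("inhibition_formula", "blank-corrected"),
    precursor_ion = chr("precursor_ion", "[M+Na]+"),
    seed = {
      s <- num("seed", NA_real_)
      if (is.na(s)) NULL else as.integer(s)
    },
    library_path = {
      p <- chr("library_path", NA_character_)
      if (is.na(p) || !nzchar(p)) NULL else p
    }
  )
}

#' @rdname read_config
#' @param config A \code{screen_config}.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "screen_config"))
  keep <- !vapply(config, function(v) is.na(v) || (is.character(v) && !nzchar(v)),
                  logical(1))
  writeLines(paste(names(config)[keep], unlist(lapply(config[keep], format)),
                   sep = " = "), path, useBytes = TRUE)
  invisible(path)
}
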