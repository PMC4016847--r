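# Readers and writers for the pipeline's text formats: tab-separated peak
# tables and annotation tables, MGF peak lists, and (through mzR) mzML.
# All tables are UTF-8, tab-separated, '#'-comment lines permitted, decimal
# point always '.'.

.PEAK_COLUMNS <- c("peak_id", "rt_min", "precursor_mz", "ions_seen", "fragments")

.split_numbers <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(numeric(0))
  vals <- suppressWarnings(as.numeric(trimws(strsplit(x, ",")[[1L]])))
  vals
}

#' Read a QTOF peak table
#'
#' Tab-separated, one row per chromatographic peak, with header columns
#' \code{peak_id}, \code{rt_min}, \code{precursor_mz}, \code{ions_seen}
#' (semicolon-joined ion species labels) and \code{fragments} (comma-joined
#' m/z values).  Malformed rows are reported with their line numbers.
#'
#' @param path Path to the TSV file.
#' @return A list of [qtof_spectrum()] objects.
#' @examples
#' peaks <- read_peak_table(system.file("extdata", "table2_peaks.tsv",
#'                                      package = "saponinscreen"))
#' length(peaks)
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("peak table is empty: ", path, call. = FALSE)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  missing <- setdiff(.PEAK_COLUMNS, header)
  if (length(missing)) {
    stop("peak table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(.PEAK_COLUMNS, header)
  body <- lines[-1L]
  body_lineno <- lineno[-1L]
  errors <- character()
  spectra <- list()
  for (i in seq_along(body)) {
    fields <- strsplit(body[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < length(header)) {
      fields <- c(fields, rep("", length(header) - length(fields)))
    }
    row <- fields[idx]
    rt <- suppressWarnings(as.numeric(row[2L]))
    prec <- suppressWarnings(as.numeric(row[3L]))
    frags <- .split_numbers(row[5L])
    problems <- c(
      if (is.na(rt)) "non-numeric rt_min",
      if (is.na(prec)) "non-numeric precursor_mz",
      if (anyNA(frags)) "non-numeric fragment m/z"
    )
    if (length(problems)) {
      errors <- c(errors, paste0("line ", body_lineno[i], ": ",
                                 paste(problems, collapse = "; ")))
      next
    }
    ions <- if (nzchar(trimws(row[4L]))) {
      trimws(strsplit(row[4L], ";")[[1L]])
    } else character()
    spectra[[length(spectra) + 1L]] <-
      qtof_spectrum(row[1L], rt, prec, ions, frags)
  }
  if (length(errors)) {
    stop("malformed peak table row(s):\n  ", paste(errors, collapse = "\n  "),
         call. = FALSE)
  }
  spectra
}

#' Write a QTOF peak table
#'
#' Inverse of [read_peak_table()]; numeric values are written with enough
#' digits to round-trip exactly.
#'
#' @param spectra A list of [qtof_spectrum()] objects.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_peak_table <- function(spectra, path) {
  if (inherits(spectra, "qtof_spectrum")) spectra <- list(spectra)
  rows <- vapply(spectra, function(s) {
    paste(s$peak_id, sprintf("%.17g", s$rt_min), sprintf("%.17g", s$precursor_mz),
          paste(s$ions_seen, collapse = ";"),
          paste(sprintf("%.17g", s$fragments), collapse = ","),
          sep = "\t")
  }, "")
  writeLines(c(paste(.PEAK_COLUMNS, collapse = "\t"), rows), path,
             useBytes = TRUE)
  invisible(path)
}

#' Read / write spectra in MGF format
#'
#' Minimal Mascot Generic Format support: \code{BEGIN IONS} blocks with
#' \code{TITLE}, \code{PEPMASS}, \code{RTINSECONDS} and an optional
#' \code{IONSSEEN} key (semicolon-joined precursor ion species; a
#' saponinscreen extension), followed by \code{m/z intensity} peak lines.
#' Retention time is converted to minutes on read.  Blocks without a
#' precursor are skipped with a warning.
#'
#' @param path File path.
#' @return \code{read_mgf} returns a list of [qtof_spectrum()] objects.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends) || any(ends < starts)) {
    stop("unbalanced BEGIN IONS / END IONS in ", path, call. = FALSE)
  }
  spectra <- list()
  skipped <- 0L
  for (b in seq_along(starts)) {
    block <- lines[(starts[b] + 1L):(ends[b] - 1L)]
    kv <- grepl("=", block, fixed = TRUE)
    keys <- toupper(sub("=.*$", "", block[kv]))
    vals <- sub("^[^=]*=", "", block[kv])
    getv <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
    pep <- suppressWarnings(as.numeric(strsplit(getv("PEPMASS"), "\\s+")[[1L]][1L]))
    if (is.na(pep)) {
      warning("MGF block ", b, " has no precursor; skipped", call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    rt_sec <- suppressWarnings(as.numeric(getv("RTINSECONDS")))
    title <- getv("TITLE")
    ions <- getv("IONSSEEN")
    peaks <- block[!kv]
    peaks <- peaks[nzchar(trimws(peaks))]
    pm <- do.call(rbind, lapply(peaks, function(ln) {
      suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1L]][1:2]))
    }))
    spectra[[length(spectra) + 1L]] <- qtof_spectrum(
      peak_id = if (is.na(title)) as.character(b) else title,
      rt_min = if (is.na(rt_sec)) 0 else rt_sec / 60,
      precursor_mz = pep,
      ions_seen = if (is.na(ions) || !nzchar(ions)) character() else
        trimws(strsplit(ions, ";")[[1L]]),
      fragments = if (is.null(pm)) numeric() else pm[, 1L],
      intensities = if (is.null(pm)) NULL else {
        ints <- pm[, 2L]
        if (anyNA(ints)) NULL else ints
      })
  }
  spectra
}

#' @rdname read_mgf
#' @param spectra A list of [qtof_spectrum()] objects.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "qtof_spectrum")) spectra <- list(spectra)
  out <- unlist(lapply(spectra, function(s) {
    ints <- if (is.null(s$intensities)) rep(100, length(s$fragments)) else s$intensities
    c("BEGIN IONS",
      paste0("TITLE=", s$peak_id),
      paste0("PEPMASS=", sprintf("%.17g", s$precursor_mz)),
      paste0("RTINSECONDS=", sprintf("%.17g", s$rt_min * 60)),
      if (length(s$ions_seen)) paste0("IONSSEEN=", paste(s$ions_seen, collapse = ";")),
      paste(sprintf("%.17g", s$fragments), sprintf("%.17g", ints)),
      "END IONS", "")
  }))
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Read MS2 spectra from an mzML file
#'
#' Uses the mzR package (proteowizard backend).  MS1-only scans are skipped
#' with a message reporting their count; retention times are converted from
#' seconds to minutes.  Precursor ion species cannot be stored in mzML and
#' are left empty.
#'
#' @param path Path to an mzML file.
#' @return A list of [qtof_spectrum()] objects (possibly empty).
#' @export
read_mzml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the mzR package", call. = FALSE)
  }
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  if (!nrow(hdr)) {
    warning("no spectra in ", path, call. = FALSE)
    return(list())
  }
  ms2 <- which(hdr$msLevel == 2L)
  n_ms1 <- sum(hdr$msLevel != 2L)
  if (n_ms1 > 0L) message(n_ms1, " non-MS2 scan(s) skipped")
  if (!length(ms2)) {
    warning("no MS2 scans in ", path, call. = FALSE)
    return(list())
  }
  lapply(ms2, function(i) {
    pk <- mzR::peaks(handle, i)
    qtof_spectrum(peak_id = as.character(hdr$acquisitionNum[i]),
                  rt_min = hdr$retentionTime[i] / 60,
                  precursor_mz = hdr$precursorMZ[i],
                  ions_seen = character(),
                  fragments = pk[, 1L],
                  intensities = pk[, 2L])
  })
}

#' Write an annotation table
#'
#' Tab-separated, in the conventional column order of an accurate-mass
#' annotation table: peak id, retention time, formula, selected ion,
#' theoretical and experimental m/z (4 decimal places), ppm error (1
#' decimal place), nominal fragment ladder, identification -- followed by
#' the rule-call columns.  [read_annotation_table()] parses it back.
#'
#' @param records A \code{saponin_annotation} data frame from
#'   [annotate_spectra()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_annotation_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  df <- as.data.frame(records)
  fmt <- df
  fmt$rt_min <- sprintf("%.1f", df$rt_min)
  fmt$theoretical_mz <- ifelse(is.na(df$theoretical_mz), "",
                               sprintf("%.4f", df$theoretical_mz))
  fmt$experimental_mz <- sprintf("%.4f", df$experimental_mz)
  fmt$error_ppm <- ifelse(is.na(df$error_ppm), "", sprintf("%.1f", df$error_ppm))
  cols <- c("peak_id", "rt_min", "formula", "selected_ion", "theoretical_mz",
            "experimental_mz", "error_ppm", "fragment_ions", "identification",
            "confidence", "skeleton_call", "n_hexose_call", "extra_oh_call",
            "ene_call", "matched_labels", "flag")
  cols <- cols[cols %in% names(fmt)]
  fmt <- fmt[, cols, drop = FALSE]
  fmt[] <- lapply(fmt, function(x) ifelse(is.na(x), "", as.character(x)))
  lines <- c(paste(cols, collapse = "\t"),
             if (nrow(fmt)) apply(fmt, 1L, paste, collapse = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read back an annotation table written by [write_annotation_table()]
#'
#' @param path Path to the TSV file.
#' @return A data frame with the annotation columns; numeric columns parsed,
#'   empty cells as NA.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           na.strings = "", colClasses = "character")
  for (col in c("rt_min", "theoretical_mz", "experimental_mz", "error_ppm")) {
    if (col %in% names(tab)) tab[[col]] <- as.numeric(tab[[col]])
  }
  for (col in c("n_hexose_call", "extra_oh_call")) {
    if (col %in% names(tab)) tab[[col]] <- as.integer(tab[[col]])
  }
  if ("ene_call" %in% names(tab)) tab$ene_call <- as.logical(tab$ene_call)
  if ("flag" %in% names(tab)) tab$flag[is.na(tab$flag)] <- ""
  if ("matched_labels" %in% names(tab)) {
    tab$matched_labels[is.na(tab$matched_labels)] <- ""
  }
  tab
}

#' Export a fragmentation tree as TSV
#'
#' @param tree A \code{fragmentation_tree}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fragment_table <- function(tree, path) {
  stopifnot(inherits(tree, "fragmentation_tree"))
  df <- as.data.frame(tree)
  df$mz <- sprintf("%.4f", df$mz)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}
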