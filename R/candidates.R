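# Candidate model: a saponin is an aglycone (steroid core) plus a count of
# isobaric dehydrated hexose residues.  Flags describe the features the MS
# rules can see: skeleton class, C22 hydroxyl (drives in-source dehydration),
# one optional extra aglycone hydroxyl (+16 Da series shift), Delta-25(27)
# unsaturation (E-ring loss mass), and the C25 epimer label used by the
# retention-time rule.

.HEXOSE_RESIDUE <- "C6H10O5" # 162.0528 Da neutral loss per glycosidic bond

.ERING_LOSSES <- c("C8H16O2", "C8H14O2", "C8H18O2")

#' Construct a saponin candidate
#'
#' @param name Unique candidate name.
#' @param aglycone_formula Elemental formula of the aglycone (string or
#'   \code{chem_formula}).
#' @param n_hexose Number of glycosidic hexose residues (>= 0).
#' @param skeleton \code{"furostanol"} or \code{"spirostanol"}.
#' @param c22_hydroxyl Logical; \code{TRUE} only for furostanols (the C22
#'   hydroxyl is what dehydrates in-source).
#' @param extra_aglycone_oh 0 or 1: one optional extra hydroxyl on the
#'   aglycone, shifting the deglycosylated ion series by +15.9949 Da.
#' @param ene_25_27 Logical; Delta-25(27) unsaturation.
#' @param c25_config \code{"R"}, \code{"S"} or \code{"unspecified"}.
#' @param rt_min Reference retention time in minutes (NA if unknown).
#' @param sugar_labels Informational sugar identities (MS cannot distinguish
#'   isobaric hexoses); character scalar like \code{"gal;glc;glc"}.
#' @param ladder_root Which protonated ion the hexose-loss ladder runs from:
#'   \code{"MH-H2O"} (dehydration precedes deglycosylation; the root is part
#'   of the reported ladder) or \code{"MH"} (losses from \code{[M+H]+}; the
#'   root is reported only if it is also the \code{head_ion}).  Default
#'   follows \code{c22_hydroxyl}.
#' @param head_ion For \code{ladder_root = "MH"} candidates, an optional
#'   additional reported ion heading the ladder: \code{"none"}, \code{"MH"}
#'   or \code{"MH-H2O"}.
#' @param post_deglyc_h2o Logical; an additional water loss after full
#'   deglycosylation (default: \code{extra_aglycone_oh == 1}).
#' @param ering_loss Neutral formula lost on E-ring cleavage (C20--C22 /
#'   C17--C20 bond cleavage): \code{"C8H16O2"} saturated, \code{"C8H14O2"}
#'   with 25(27)-ene, \code{"C8H18O2"} for the saturated dihydroxy case.
#'   Default follows \code{ene_25_27}.
#' @param is_standard Logical; authentic standard available.
#' @return A list of class \code{saponin_candidate}.
#' @export
saponin_candidate <- function(name, aglycone_formula, n_hexose,
                              skeleton = c("furostanol", "spirostanol"),
                              c22_hydroxyl = skeleton == "furostanol",
                              extra_aglycone_oh = 0L,
                              ene_25_27 = FALSE,
                              c25_config = "unspecified",
                              rt_min = NA_real_,
                              sugar_labels = "",
                              ladder_root = NULL,
                              head_ion = "none",
                              post_deglyc_h2o = NULL,
                              ering_loss = NULL,
                              is_standard = FALSE) {
  skeleton <- match.arg(skeleton)
  stopifnot(is.character(name), nzchar(name), n_hexose >= 0)
  if (!c25_config %in% c("R", "S", "unspecified")) {
    stop("c25_config must be 'R', 'S' or 'unspecified'", call. = FALSE)
  }
  if (isTRUE(c22_hydroxyl) && skeleton != "furostanol") {
    stop("a C22 hydroxyl implies a furostanol skeleton", call. = FALSE)
  }
  if (!extra_aglycone_oh %in% c(0L, 1L)) {
    stop("extra_aglycone_oh must be 0 or 1", call. = FALSE)
  }
  if (is.null(ladder_root)) ladder_root <- if (isTRUE(c22_hydroxyl)) "MH-H2O" else "MH"
  if (!ladder_root %in% c("MH-H2O", "MH")) {
    stop("ladder_root must be 'MH-H2O' or 'MH'", call. = FALSE)
  }
  if (!head_ion %in% c("none", "MH", "MH-H2O")) {
    stop("head_ion must be 'none', 'MH' or 'MH-H2O'", call. = FALSE)
  }
  if (is.null(post_deglyc_h2o)) post_deglyc_h2o <- extra_aglycone_oh == 1L
  if (is.null(ering_loss)) ering_loss <- if (isTRUE(ene_25_27)) "C8H14O2" else "C8H16O2"
  if (!ering_loss %in% .ERING_LOSSES) {
    stop("ering_loss must be one of: ", paste(.ERING_LOSSES, collapse = ", "),
         call. = FALSE)
  }
  structure(list(
    name = name,
    aglycone_formula = .as_formula(aglycone_formula),
    n_hexose = as.integer(n_hexose),
    skeleton = skeleton,
    c22_hydroxyl = isTRUE(c22_hydroxyl),
    extra_aglycone_oh = as.integer(extra_aglycone_oh),
    ene_25_27 = isTRUE(ene_25_27),
    c25_config = c25_config,
    rt_min = as.numeric(rt_min),
    sugar_labels = sugar_labels,
    ladder_root = ladder_root,
    head_ion = head_ion,
    post_deglyc_h2o = isTRUE(post_deglyc_h2o),
    ering_loss = ering_loss,
    is_standard = isTRUE(is_standard)
  ), class = "saponin_candidate")
}

#' @export
print.saponin_candidate <- function(x, ...) {
  cat("<saponin candidate> ", x$name, "\n",
      "  ", x$skeleton,
      if (x$c22_hydroxyl) " (C22-OH)", ", ",
      x$n_hexose, " hexose(s), aglycone ", formula_string(x$aglycone_formula),
      ", C25 ", x$c25_config,
      if (x$is_standard) ", authentic standard", "\n",
      "  molecular formula ", formula_string(molecular_formula(x)),
      "  [M+Na]+ ", sprintf("%.4f", ion_mz(molecular_formula(x), "[M+Na]+")), "\n",
      sep = "")
  invisible(x)
}

#' Molecular formula of a candidate
#'
#' Aglycone formula plus \code{n_hexose} dehydrated hexose residues
#' (\code{C6H10O5} each).
#'
#' @param candidate A \code{saponin_candidate}.
#' @return A \code{chem_formula}.
#' @export
molecular_formula <- function(candidate) {
  stopifnot(inherits(candidate, "saponin_candidate"))
  f <- candidate$aglycone_formula
  if (candidate$n_hexose > 0L) {
    hex <- parse_formula(.HEXOSE_RESIDUE)
    for (i in seq_len(candidate$n_hexose)) f <- formula_add(f, hex)
  }
  f
}

#' Load a saponin candidate library
#'
#' Reads a tab-separated candidate table (\code{'#'} comment lines allowed)
#' into a list of [saponin_candidate()] objects.  With \code{path = NULL} the
#' packaged library of fifteen Anemarrhena saponins (six of them authentic
#' standards) is loaded.
#'
#' @param path Path to a library TSV, or \code{NULL} for the packaged one.
#' @return An object of class \code{candidate_set}: a named list of
#'   candidates in library (elution) order.
#' @export
saponin_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "saponin_library.tsv", package = "saponinscreen")
  }
  if (!file.exists(path)) stop("library file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE)
  needed <- c("name", "skeleton", "c22_hydroxyl", "extra_aglycone_oh",
              "ene_25_27", "n_hexose", "aglycone_formula", "c25_config")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop("library file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tab$name)) {
    stop("candidate names must be unique", call. = FALSE)
  }
  cands <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    saponin_candidate(
      name = r$name,
      aglycone_formula = r$aglycone_formula,
      n_hexose = r$n_hexose,
      skeleton = r$skeleton,
      c22_hydroxyl = as.logical(r$c22_hydroxyl),
      extra_aglycone_oh = r$extra_aglycone_oh,
      ene_25_27 = as.logical(r$ene_25_27),
      c25_config = r$c25_config,
      rt_min = if ("rt_min" %in% names(tab)) r$rt_min else NA_real_,
      sugar_labels = if ("sugar_labels" %in% names(tab)) r$sugar_labels else "",
      ladder_root = if ("ladder_root" %in% names(tab)) r$ladder_root else NULL,
      head_ion = if ("head_ion" %in% names(tab)) r$head_ion else "none",
      post_deglyc_h2o = if ("post_deglyc_h2o" %in% names(tab)) as.logical(r$post_deglyc_h2o) else NULL,
      ering_loss = if ("ering_loss" %in% names(tab)) r$ering_loss else NULL,
      is_standard = if ("is_standard" %in% names(tab)) as.logical(r$is_standard) else FALSE
    )
  })
  names(cands) <- tab$name
  structure(cands, class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("<candidate set> ", length(x), " saponin candidates (",
      sum(vapply(x, `[[`, TRUE, "is_standard")), " authentic standards)\n", sep = "")
  for (cand in x) {
    cat(sprintf("  %-34s %s  %d hexose(s)  [M+Na]+ %.4f\n", cand$name,
                formula_string(molecular_formula(cand)), cand$n_hexose,
                ion_mz(molecular_formula(cand), "[M+Na]+")))
  }
  invisible(x)
}

#' Candidates sharing a molecular formula
#'
#' @param library A \code{candidate_set}.
#' @param formula A formula string or \code{chem_formula}.
#' @return The sub-list of candidates whose molecular formula equals
#'   \code{formula}, in library order (possibly empty).
#' @export
isomer_group <- function(library, formula) {
  stopifnot(inherits(library, "candidate_set"))
  key <- formula_string(.as_formula(formula))
  keep <- vapply(library, function(cand) {
    formula_string(molecular_formula(cand)) == key
  }, logical(1))
  structure(library[keep], class = "candidate_set")
}

#' Names of the authentic standards in a library
#'
#' @param library A \code{candidate_set}.
#' @return Character vector of candidate names flagged as standards.
#' @export
standard_names <- function(library) {
  stopifnot(inherits(library, "candidate_set"))
  names(library)[vapply(library, `[[`, TRUE, "is_standard")]
}
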