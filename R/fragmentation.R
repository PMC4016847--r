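# In-silico ESI-MS/MS fragmentation of saponin glycosides, positive mode,
# singly charged ions only.  The tree follows the diagnostic loss sequence of
# steroidal saponins: optional in-source dehydration (C22-OH furostanols),
# successive neutral losses of dehydrated hexose residues (162.0528 Da) down
# to the aglycone ion, an optional further dehydration, E-ring cleavage
# (C8H16O2 / C8H14O2 / C8H18O2), and a final water loss.

.H2O <- "H2O"

.IN_SCOPE_LOSSES <- c(H2O = "H2O", hexose = "C6H10O5",
                      ering_sat = "C8H16O2", ering_ene = "C8H14O2",
                      ering_dihydroxy = "C8H18O2")

#' Predict the fragmentation tree of a saponin candidate
#'
#' Generates the theoretical positive-mode fragment ions of a candidate:
#' the \code{[M+Na]+} adduct, the protonated-series root (\code{[M+H-H2O]+}
#' for C22-hydroxy furostanols, \code{[M+H]+} otherwise), the full hexose
#' ladder, the optional post-deglycosylation dehydration, E-ring cleavage of
#' the aglycone ion and a final water loss.  The \code{reported} column marks
#' the ions that make up the conventionally reported fragment ladder (the
#' sodiated precursor and an unobserved \code{[M+H]+} root are kept in the
#' tree but not reported).
#'
#' @param candidate A [saponin_candidate()].
#' @return An object of class \code{fragmentation_tree}: a data frame with
#'   columns \code{label}, \code{formula} (ion composition), \code{mz}
#'   (full precision), \code{step} (generation depth; 0 = precursor adducts),
#'   \code{parent} (label of the parent ion or NA), \code{loss} (neutral
#'   formula lost from the parent) and \code{reported}.
#' @examples
#' lib <- saponin_library()
#' predict_fragments(lib[["Timosaponin BII"]])
#' @export
predict_fragments <- function(candidate) {
  stopifnot(inherits(candidate, "saponin_candidate"))
  M <- molecular_formula(candidate)
  rows <- list()
  add_ion <- function(label, formula, step, parent, loss, reported) {
    rows[[length(rows) + 1L]] <<- data.frame(
      label = label, formula = formula_string(formula),
      mz = (monoisotopic_mass(formula) - .ELECTRON_MASS),
      step = step, parent = parent, loss = loss, reported = reported,
      stringsAsFactors = FALSE)
    formula
  }

  # precursor adducts, step 0
  add_ion("[M+Na]+", formula_add(M, c(Na = 1L)), 0L, NA_character_,
          NA_character_, FALSE)
  mh <- formula_add(M, c(H = 1L))

  if (candidate$ladder_root == "MH-H2O") {
    root_label <- "[M+H-H2O]+"
    root_f <- add_ion(root_label, formula_subtract(mh, .H2O), 0L,
                      NA_character_, NA_character_, TRUE)
  } else {
    root_label <- "[M+H]+"
    root_f <- add_ion(root_label, mh, 0L, NA_character_, NA_character_,
                      candidate$head_ion == "MH")
    if (candidate$head_ion == "MH-H2O") {
      add_ion("[M+H-H2O]+", formula_subtract(mh, .H2O), 1L, root_label,
              .H2O, TRUE)
    }
  }

  # hexose ladder
  stem <- sub("\\]\\+$", "", root_label)
  cur_label <- root_label
  cur_f <- root_f
  cur_step <- 0L
  if (candidate$n_hexose > 0L) {
    for (k in seq_len(candidate$n_hexose)) {
      lab <- paste0(stem, if (k == 1L) "-162" else paste0("-", k, "x162"), "]+")
      cur_f <- formula_subtract(cur_f, .HEXOSE_RESIDUE)
      add_ion(lab, cur_f, cur_step + k, cur_label, .HEXOSE_RESIDUE, TRUE)
      cur_label <- lab
    }
    cur_step <- cur_step + candidate$n_hexose
  }

  # optional dehydration after full deglycosylation
  deglyc_label <- cur_label; deglyc_f <- cur_f; deglyc_step <- cur_step
  if (candidate$post_deglyc_h2o) {
    lab <- paste0(sub("\\]\\+$", "", deglyc_label), "-H2O]+")
    wf <- formula_subtract(deglyc_f, .H2O)
    add_ion(lab, wf, deglyc_step + 1L, deglyc_label, .H2O, TRUE)
    if (candidate$extra_aglycone_oh == 1L) {
      # the extra hydroxyl dehydrates before the E-ring cleaves
      cur_label <- lab; cur_f <- wf; cur_step <- deglyc_step + 1L
    }
  }

  # E-ring cleavage (C20-C22 / C17-C20 bonds) and final water loss
  elab <- paste0(sub("\\]\\+$", "", cur_label), "-", candidate$ering_loss, "]+")
  ef <- formula_subtract(cur_f, candidate$ering_loss)
  add_ion(elab, ef, cur_step + 1L, cur_label, candidate$ering_loss, TRUE)
  flab <- paste0(sub("\\]\\+$", "", elab), "-H2O]+")
  add_ion(flab, formula_subtract(ef, .H2O), cur_step + 2L, elab, .H2O, TRUE)

  tree <- do.call(rbind, rows)
  if (anyDuplicated(tree$label)) stop("internal: duplicate ion labels", call. = FALSE)
  structure(tree, candidate = candidate$name, class = c("fragmentation_tree", "data.frame"))
}

#' @export
print.fragmentation_tree <- function(x, ...) {
  cat("<fragmentation tree> ", attr(x, "candidate"), "\n", sep = "")
  df <- as.data.frame(x)
  df$mz <- sprintf("%.4f", df$mz)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Nominal fragment ladder of a tree
#'
#' The reported protonated-series ions rounded to integer m/z, in descending
#' order -- the form in which glycoside fragment ladders are conventionally
#' printed.
#'
#' @param tree A \code{fragmentation_tree}.
#' @return Integer vector of nominal m/z, descending.
#' @export
nominal_ladder <- function(tree) {
  stopifnot(inherits(tree, "fragmentation_tree"))
  mz <- tree$mz[tree$reported]
  sort(unique(as.integer(round(mz))), decreasing = TRUE)
}

#' Match observed fragments against a predicted tree
#'
#' Greedy nearest-neighbour matching of the reported predicted ions against
#' an observed fragment list, each observed peak used at most once.  Coverage
#' is the fraction of reported predicted ions that found a match.
#'
#' @param tree A \code{fragmentation_tree}.
#' @param observed Numeric vector of observed fragment m/z.
#' @param tol_da Absolute matching window in Da (default 0.5, suitable for
#'   nominal integer ladders).  Ignored when \code{tol_ppm} is given.
#' @param tol_ppm Optional relative window in ppm for accurate spectra.
#' @return A list of class \code{fragment_match}: \code{matches} (data frame
#'   with \code{label}, \code{predicted_mz}, \code{observed_mz},
#'   \code{delta_mz}), \code{coverage} in [0, 1], and \code{n_predicted}.
#' @export
match_fragments <- function(tree, observed, tol_da = 0.5, tol_ppm = NULL) {
  stopifnot(inherits(tree, "fragmentation_tree"))
  pred <- as.data.frame(tree)[tree$reported, , drop = FALSE]
  if (nrow(pred) == 0L) {
    stop("tree has no reported fragment ions; candidate unusable", call. = FALSE)
  }
  pred <- pred[order(pred$mz, decreasing = TRUE), , drop = FALSE]
  observed <- as.numeric(observed)
  used <- rep(FALSE, length(observed))
  out <- data.frame(label = character(), predicted_mz = numeric(),
                    observed_mz = numeric(), delta_mz = numeric(),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pred))) {
    p <- pred$mz[i]
    tol <- if (!is.null(tol_ppm)) p * tol_ppm * 1e-6 else tol_da
    if (!length(observed)) break
    d <- abs(observed - p)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol) {
      used[j] <- TRUE
      out <- rbind(out, data.frame(label = pred$label[i], predicted_mz = p,
                                   observed_mz = observed[j],
                                   delta_mz = observed[j] - p,
                                   stringsAsFactors = FALSE))
    }
  }
  structure(list(matches = out,
                 coverage = nrow(out) / nrow(pred),
                 n_predicted = nrow(pred)),
            class = "fragment_match")
}

#' @export
print.fragment_match <- function(x, ...) {
  cat("<fragment match> ", nrow(x$matches), "/", x$n_predicted,
      " predicted ions matched (coverage ", sprintf("%.2f", x$coverage), ")\n",
      sep = "")
  if (nrow(x$matches)) print(x$matches, row.names = FALSE)
  invisible(x)
}

#' Precursor ion species expected for a candidate
#'
#' C22-hydroxy furostanols dehydrate in-source, so they show \code{[M+Na]+}
#' and \code{[M+H-H2O]+} but no \code{[M+H]+}; all other skeletons show
#' \code{[M+Na]+} and \code{[M+H]+}.
#'
#' @param candidate A [saponin_candidate()].
#' @return Character vector of ion species labels.
#' @export
expected_precursor_ions <- function(candidate) {
  stopifnot(inherits(candidate, "saponin_candidate"))
  if (candidate$c22_hydroxyl) c("[M+Na]+", "[M+H-H2O]+") else c("[M+Na]+", "[M+H]+")
}
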