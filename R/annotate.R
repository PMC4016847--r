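# The rule cascade that turns a peak table into annotation records:
# (1) formula match on the precursor within a ppm window;
# (2) full coverage of the candidate's predicted fragment ladder;
# (3) skeleton / hydroxylation calls must not contradict the candidate;
# (4) C25 epimers resolved by elution order (25R later than 25S on C18);
# (5) confidence tiers: standard-confirmed / tentative / class-only.

#' Skeleton class call from the precursor ion species
#'
#' C22-hydroxy furostanols dehydrate in-source: they show \code{[M+Na]+} and
#' \code{[M+H-H2O]+} but no \code{[M+H]+}.  A visible \code{[M+H]+} points to
#' a spirostanol-type skeleton.
#'
#' @param ions_seen Character vector of ion species labels, or a
#'   \code{qtof_spectrum}.
#' @return \code{"furostanol+C22-OH"}, \code{"spirostanol-type"} or
#'   \code{"undetermined"}.
#' @export
classify_skeleton <- function(ions_seen) {
  if (inherits(ions_seen, "qtof_spectrum")) ions_seen <- ions_seen$ions_seen
  if (!length(ions_seen)) stop("no precursor ion species given", call. = FALSE)
  ions <- vapply(ions_seen, .normalize_ion_label, "")
  if ("[M+H]+" %in% ions) return("spirostanol-type")
  if (all(c("[M+Na]+", "[M+H-H2O]+") %in% ions)) return("furostanol+C22-OH")
  "undetermined"
}

#' Count successive hexose losses below a ladder root
#'
#' Length of the longest chain \code{root - 162.0528 * k}, k = 1, 2, ...,
#' whose members are all present in the fragment list within tolerance.
#'
#' @param fragments Numeric vector of fragment m/z.
#' @param root_mz m/z of the ladder root ion.
#' @param tol_da Matching window in Da (default 0.5).
#' @param min_mz Lower bound for a sugar-loss rung (default 350).  Glycosidic
#'   losses terminate at the aglycone ion; below ~350 the only steroid ions
#'   are E-ring cleavage products, whose spacing from the aglycone ion
#'   (144.115 + 18.011 Da) is indistinguishable from a hexose loss at unit
#'   resolution.
#' @return Integer count of consecutive hexose losses (0 if none).
#' @export
count_hexose_losses <- function(fragments, root_mz, tol_da = 0.5,
                                min_mz = 350) {
  stopifnot(tol_da > 0, root_mz > 0)
  hex <- monoisotopic_mass(.HEXOSE_RESIDUE)
  k <- 0L
  repeat {
    target <- root_mz - (k + 1L) * hex
    if (target < min_mz || !length(fragments) ||
        !any(abs(fragments - target) <= tol_da)) break
    k <- k + 1L
  }
  k
}

#' Aglycone hydroxylation state from the diagnostic ion series
#'
#' The unsubstituted sarsasapogenin-type aglycone gives the nominal
#' \{417, 273, 255\} triple; one extra hydroxyl shifts the series to
#' \{433, 415\} (with \{271, 253\} supporting).
#'
#' @param fragments Numeric vector of fragment m/z.
#' @param tol_da Matching window in Da (default 0.5).
#' @return \code{0L}, \code{1L}, or \code{NA_integer_} when neither series is
#'   present.  Both series present is an ambiguity error.
#' @export
aglycone_hydroxylation_state <- function(fragments, tol_da = 0.5) {
  stopifnot(tol_da > 0)
  near <- function(x) length(fragments) && any(abs(fragments - x) <= tol_da)
  plain <- near(417) && near(273) && near(255)
  hydroxy <- near(433) && near(415)
  if (plain && hydroxy) {
    stop("ambiguous aglycone series: both {417,273,255} and {433,415} present",
         call. = FALSE)
  }
  if (plain) return(0L)
  if (hydroxy) return(1L)
  NA_integer_
}

# Assign candidates of one isomer group to RT-sorted spectra.
# `cands` in library order; returns candidate names parallel to `rt_order`.
.assign_isomers <- function(cand_names, configs, rts) {
  n <- length(rts)
  ord <- order(rts)
  take <- cand_names[seq_len(min(n, length(cand_names)))]
  assigned <- rep(NA_character_, n)
  assigned[ord] <- c(take, rep(NA_character_, max(0L, n - length(cand_names))))
  # pairwise epimer rule: with exactly one R and one S variant assigned,
  # the later-eluting spectrum must carry the 25R candidate
  cfg <- configs[match(assigned, cand_names)]
  iR <- which(!is.na(cfg) & cfg == "R")
  iS <- which(!is.na(cfg) & cfg == "S")
  if (length(iR) == 1L && length(iS) == 1L && rts[iR] < rts[iS]) {
    tmp <- assigned[iR]; assigned[iR] <- assigned[iS]; assigned[iS] <- tmp
  }
  assigned
}

#' Resolve C25 epimers within an isomer group by retention time
#'
#' On reversed-phase C18 chromatography the 25R epimer of a steroidal
#' saponin elutes later than the 25S epimer.  Given annotation records that
#' share a molecular formula and fragment pattern, and the matching isomer
#' group of candidates, the later-eluting record receives the 25R candidate.
#' Singletons are returned unchanged; records beyond the number of available
#' candidates are flagged \code{"unresolved"}.
#'
#' @param records A data frame with at least \code{rt_min} and
#'   \code{identification} columns (one row per peak).
#' @param group A \code{candidate_set} of isomer candidates in library order.
#' @return \code{records} with \code{identification} (and a \code{flag}
#'   column) updated.
#' @export
assign_c25_configuration <- function(records, group) {
  stopifnot(is.data.frame(records), inherits(group, "candidate_set"))
  if (!nrow(records) || length(group) <= 1L && nrow(records) <= 1L) {
    return(records)
  }
  configs <- vapply(group, `[[`, "", "c25_config")
  assigned <- .assign_isomers(names(group), configs, records$rt_min)
  if (!"flag" %in% names(records)) records$flag <- ""
  unres <- is.na(assigned)
  records$identification <- ifelse(unres, "unassigned", assigned)
  records$flag[unres] <- "unresolved"
  records
}

#' Annotate QTOF spectra against a candidate library
#'
#' Runs the full identification cascade on a list of spectra and returns one
#' annotation record per spectrum.  A record whose precursor matches no
#' library formula within tolerance (or whose fragments match no candidate
#' ladder completely) is returned with identification \code{"unassigned"}
#' and class-level calls only.
#'
#' @param spectra A list of [qtof_spectrum()] objects (or a single one).
#' @param library A \code{candidate_set} from [saponin_library()].
#' @param config A [screen_config()]; supplies the precursor ppm tolerance
#'   and fragment tolerance.
#' @return An object of class \code{saponin_annotation}: a data frame with
#'   one row per input spectrum, in input order, holding the assigned
#'   formula, selected ion, theoretical and experimental m/z, ppm error,
#'   matched fragment labels, rule calls, identification and confidence.
#' @examples
#' peaks <- read_peak_table(system.file("extdata", "table2_peaks.tsv",
#'                                      package = "saponinscreen"))
#' ann <- annotate_spectra(peaks, saponin_library())
#' ann$identification
#' @export
annotate_spectra <- function(spectra, library = saponin_library(),
                             config = screen_config()) {
  if (inherits(spectra, "qtof_spectrum")) spectra <- list(spectra)
  stopifnot(length(spectra) > 0, inherits(library, "candidate_set"),
            inherits(config, "screen_config"))
  n <- length(spectra)

  theo_mz <- vapply(library, function(cand) {
    ion_mz(molecular_formula(cand), config$precursor_ion)
  }, 0)
  trees <- lapply(library, predict_fragments)

  per_peak <- vector("list", n)
  for (i in seq_len(n)) {
    s <- spectra[[i]]
    stopifnot(inherits(s, "qtof_spectrum"))
    skel <- if (length(s$ions_seen)) classify_skeleton(s$ions_seen) else "undetermined"
    hyd <- tryCatch(aglycone_hydroxylation_state(s$fragments, config$fragment_tol_da),
                    error = function(e) "ambiguous")
    ambiguous_series <- identical(hyd, "ambiguous")
    if (ambiguous_series) hyd <- NA_integer_

    keep <- character()
    matched_labels <- character()
    for (nm in names(library)) {
      cand <- library[[nm]]
      if (abs(ppm_error(theo_mz[[nm]], s$precursor_mz)) > config$precursor_ppm_tol) next
      m <- match_fragments(trees[[nm]], s$fragments, tol_da = config$fragment_tol_da)
      if (m$coverage < 1) next
      if (skel == "furostanol+C22-OH" && !cand$c22_hydroxyl) next
      if (skel == "spirostanol-type" && cand$c22_hydroxyl) next
      if (!is.na(hyd) && hyd != cand$extra_aglycone_oh) next
      keep <- c(keep, nm)
      if (length(keep) == 1L) {
        matched_labels <- paste(m$matches$label, collapse = ";")
      }
    }
    per_peak[[i]] <- list(spectrum = s, skeleton_call = skel, hyd_call = hyd,
                          candidates = keep, matched_labels = matched_labels,
                          flag = if (ambiguous_series) "ambiguous-series" else "")
  }

  # group spectra whose surviving candidate sets are identical and ambiguous
  set_key <- vapply(per_peak, function(p) paste(p$candidates, collapse = "|"), "")
  final_name <- rep("unassigned", n)
  flags <- vapply(per_peak, `[[`, "", "flag")
  for (key in unique(set_key)) {
    idx <- which(set_key == key)
    cands <- per_peak[[idx[1L]]]$candidates
    if (length(cands) == 0L) next
    if (length(cands) == 1L) { final_name[idx] <- cands; next }
    rts <- vapply(idx, function(i) per_peak[[i]]$spectrum$rt_min, 0)
    configs <- vapply(library[cands], `[[`, "", "c25_config")
    assigned <- .assign_isomers(cands, configs, rts)
    unres <- is.na(assigned)
    final_name[idx] <- ifelse(unres, "unassigned", assigned)
    flags[idx][unres] <- "unresolved"
    if (length(idx) < length(cands)) {
      # RT cannot separate all isomer possibilities: class-level call only
      flags[idx][!unres] <- ifelse(nzchar(flags[idx][!unres]),
                                   flags[idx][!unres], "isomer-ambiguous")
    }
  }

  recs <- lapply(seq_len(n), function(i) {
    p <- per_peak[[i]]
    s <- p$spectrum
    nm <- final_name[i]
    if (nm != "unassigned") {
      cand <- library[[nm]]
      f <- molecular_formula(cand)
      # the reported error belongs to the reported (4 dp) theoretical mass
      theo <- round(theo_mz[[nm]], 4)
      root <- if (cand$ladder_root == "MH-H2O") {
        ion_mz(f, "[M+H-H2O]+")
      } else ion_mz(f, "[M+H]+")
      nhex <- count_hexose_losses(s$fragments, root, config$fragment_tol_da)
      conf <- if (flags[i] == "isomer-ambiguous") "class-only"
              else if (cand$is_standard) "standard-confirmed" else "tentative"
      data.frame(peak_id = s$peak_id, rt_min = s$rt_min,
                 formula = formula_string(f),
                 selected_ion = config$precursor_ion,
                 theoretical_mz = theo, experimental_mz = s$precursor_mz,
                 error_ppm = ppm_error(theo, s$precursor_mz),
                 fragment_ions = paste(nominal_ladder(trees[[nm]]), collapse = ","),
                 matched_labels = p$matched_labels,
                 skeleton_call = p$skeleton_call,
                 n_hexose_call = nhex,
                 extra_oh_call = p$hyd_call,
                 ene_call = cand$ene_25_27,
                 identification = nm, confidence = conf, flag = flags[i],
                 stringsAsFactors = FALSE)
    } else {
      # class-only record: derive what the rules alone can say
      mh <- s$precursor_mz - monoisotopic_mass(chem_formula(c(Na = 1L))) +
        monoisotopic_mass(chem_formula(c(H = 1L)))
      nhex <- max(count_hexose_losses(s$fragments, mh, config$fragment_tol_da),
                  count_hexose_losses(s$fragments, mh - monoisotopic_mass("H2O"),
                                      config$fragment_tol_da))
      data.frame(peak_id = s$peak_id, rt_min = s$rt_min,
                 formula = NA_character_, selected_ion = config$precursor_ion,
                 theoretical_mz = NA_real_, experimental_mz = s$precursor_mz,
                 error_ppm = NA_real_, fragment_ions = "",
                 matched_labels = "",
                 skeleton_call = p$skeleton_call, n_hexose_call = nhex,
                 extra_oh_call = p$hyd_call, ene_call = NA,
                 identification = "unassigned", confidence = "class-only",
                 flag = flags[i], stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, recs)
  structure(out, config = config, class = c("saponin_annotation", "data.frame"))
}

#' @export
print.saponin_annotation <- function(x, ...) {
  cat("<annotation> ", nrow(x), " peak(s), ",
      sum(x$identification != "unassigned"), " assigned\n", sep = "")
  df <- as.data.frame(x)
  df$theoretical_mz <- ifelse(is.na(df$theoretical_mz), NA,
                              sprintf("%.4f", df$theoretical_mz))
  df$experimental_mz <- sprintf("%.4f", df$experimental_mz)
  df$error_ppm <- ifelse(is.na(df$error_ppm), NA, sprintf("%.1f", df$error_ppm))
  print(df[, c("peak_id", "rt_min", "formula", "selected_ion",
               "theoretical_mz", "experimental_mz", "error_ppm",
               "identification", "confidence")], row.names = FALSE)
  invisible(x)
}
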