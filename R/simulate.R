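# Seeded generators that emulate the data the analysis stages consume:
# QTOF glycoside spectra (sodiated precursor with Gaussian ppm error, the
# predicted fragment ladder with absolute Gaussian error, uniform decoy
# peaks kept away from true ions) and 96-well Ellman plates (Gaussian OD
# noise around the control and inhibited-sample means).  Every generator is
# a pure function of its arguments and seed.

.with_seed <- function(seed, fun) {
  if (is.null(seed) || is.na(seed)) return(fun())
  genv <- globalenv()
  old <- if (exists(".Random.seed", genv, inherits = FALSE)) {
    get(".Random.seed", genv)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", genv, inherits = FALSE)) rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(as.integer(seed))
  fun()
}

#' Simulate a QTOF spectrum of a library candidate
#'
#' The precursor is the theoretical sodiated adduct with multiplicative
#' Gaussian ppm error; the fragments are the candidate's predicted ladder
#' (full precision) with additive Gaussian error, plus uniform decoy peaks
#' excluded from a +/- 1 Da window around every true ladder ion so the
#' ground truth stays well defined.  With all noise at zero the output is
#' exactly the theoretical spectrum.
#'
#' @param candidate A [saponin_candidate()] or a candidate name.
#' @param library A \code{candidate_set}; used to resolve names and default
#'   retention times.
#' @param ppm_sigma SD of the precursor mass error in ppm (default 1.4,
#'   putting ~95\% of simulated errors within the +/- 2.8 ppm band a
#'   calibrated QTOF achieves).
#' @param frag_sigma SD of the absolute fragment mass error in Da
#'   (default 0.15).
#' @param n_decoy Number of decoy peaks (default 0).
#' @param decoy_range Numeric length-2 m/z range for decoys (default
#'   c(100, precursor)).
#' @param rt_jitter_min SD of retention-time jitter in minutes (default 0.2).
#' @param peak_id Identifier for the simulated peak (default the candidate
#'   name).
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A [qtof_spectrum()].
#' @export
simulate_spectrum <- function(candidate, library = saponin_library(),
                              ppm_sigma = 1.4, frag_sigma = 0.15,
                              n_decoy = 0L, decoy_range = NULL,
                              rt_jitter_min = 0.2, peak_id = NULL,
                              seed = NULL) {
  if (is.character(candidate)) {
    if (!candidate %in% names(library)) {
      stop("unknown candidate: ", sQuote(candidate), call. = FALSE)
    }
    candidate <- library[[candidate]]
  }
  stopifnot(inherits(candidate, "saponin_candidate"),
            ppm_sigma >= 0, frag_sigma >= 0, n_decoy >= 0)
  .with_seed(seed, function() {
    tree <- predict_fragments(candidate)
    ladder <- sort(unique(tree$mz[tree$reported]), decreasing = TRUE)
    prec_theo <- ion_mz(molecular_formula(candidate), "[M+Na]+")
    precursor <- prec_theo * (1 + stats::rnorm(1L, 0, ppm_sigma) / 1e6)
    frags <- ladder + stats::rnorm(length(ladder), 0, frag_sigma)
    if (n_decoy > 0L) {
      rng <- if (is.null(decoy_range)) c(100, prec_theo) else decoy_range
      decoys <- numeric(0)
      while (length(decoys) < n_decoy) {
        d <- stats::runif(n_decoy, rng[1L], rng[2L])
        d <- d[vapply(d, function(x) all(abs(x - ladder) > 1), TRUE)]
        decoys <- c(decoys, d)
      }
      frags <- c(frags, decoys[seq_len(n_decoy)])
    }
    rt0 <- if (is.finite(candidate$rt_min)) candidate$rt_min else 50
    rt <- max(0, rt0 + stats::rnorm(1L, 0, rt_jitter_min))
    qtof_spectrum(peak_id = if (is.null(peak_id)) candidate$name else peak_id,
                  rt_min = rt, precursor_mz = precursor,
                  ions_seen = expected_precursor_ions(candidate),
                  fragments = sort(frags, decreasing = TRUE))
  })
}

#' Simulate an Ellman assay plate
#'
#' Control wells are Normal(control_od, od_sigma^2); sample wells are
#' Normal(blank_od + (control_od - blank_od) * (1 - inhibition/100),
#' od_sigma^2); blank wells are held at the blank mean.  With
#' \code{od_sigma = 0} the per-well inhibition recovers the truth exactly.
#'
#' @param true_inhibition True percent inhibition in [0, 100].
#' @param control_od Mean uninhibited OD at 412 nm (default 1.0).
#' @param blank_od Blank (no-enzyme) OD (default 0.08).
#' @param od_sigma SD of the OD noise (default 0.02).
#' @param n Number of sample wells (= replicate wells per plate, default 6).
#' @param agent_id,enzyme,concentration,replicate_index Plate metadata.
#' @param seed Integer seed.
#' @return A [plate_assay()] with one row each of sample, control and blank
#'   wells.
#' @export
simulate_plate <- function(true_inhibition, control_od = 1.0, blank_od = 0.08,
                           od_sigma = 0.02, n = 6L, agent_id = "agent",
                           enzyme = c("AChE", "BuChE"),
                           concentration = NA_real_, replicate_index = 1L,
                           seed = NULL) {
  enzyme <- match.arg(enzyme)
  stopifnot(true_inhibition >= 0, true_inhibition <= 100, od_sigma >= 0,
            n >= 3L, control_od > blank_od)
  .with_seed(seed, function() {
    sample_mean <- blank_od + (control_od - blank_od) * (1 - true_inhibition / 100)
    readings <- rbind(
      sample  = pmax(0, stats::rnorm(n, sample_mean, od_sigma)),
      control = pmax(0, stats::rnorm(n, control_od, od_sigma)),
      blank   = rep(blank_od, n)
    )
    roles <- matrix(rep(c("sample", "control", "blank"), n), nrow = 3L,
                    dimnames = NULL)
    plate_assay(readings, roles, agent_id = agent_id, enzyme = enzyme,
                concentration = concentration,
                replicate_index = replicate_index)
  })
}

#' Simulate a full inhibition screen
#'
#' One plate per agent, enzyme and replicate, from a table of true
#' inhibition percentages.
#'
#' @param effects Data frame with columns \code{agent_id}, \code{enzyme},
#'   \code{inhibition} (true percent inhibition; NA rows are skipped as
#'   "not detected").
#' @param n_rep Replicate plates per agent and enzyme (default 3).
#' @param seed Integer seed (per-plate seeds are derived from it).
#' @param ... Passed to [simulate_plate()] (noise level, well count, ...).
#' @return A list of [plate_assay()] objects.
#' @export
simulate_screen <- function(effects, n_rep = 3L, seed = NULL, ...) {
  stopifnot(is.data.frame(effects),
            all(c("agent_id", "enzyme", "inhibition") %in% names(effects)))
  effects <- effects[!is.na(effects$inhibition), , drop = FALSE]
  if (!nrow(effects)) return(list())
  .with_seed(seed, function() {
    plates <- list()
    for (i in seq_len(nrow(effects))) {
      for (r in seq_len(n_rep)) {
        plates[[length(plates) + 1L]] <- simulate_plate(
          effects$inhibition[i], agent_id = effects$agent_id[i],
          enzyme = effects$enzyme[i], replicate_index = r, seed = NULL, ...)
      }
    }
    plates
  })
}

#' Summarise a list of plates into per-agent inhibition results
#'
#' Each plate contributes one replicate value (the mean inhibition over its
#' sample wells); plates sharing agent and enzyme are summarised together.
#'
#' @param plates A list of [plate_assay()] objects.
#' @param formula Inhibition formula variant, see [inhibition_percent()].
#' @return A data frame with one row per agent and enzyme
#'   (\code{agent_id}, \code{enzyme}, \code{mean_inhibition}, \code{sem},
#'   \code{n}).
#' @export
analyze_screen <- function(plates, formula = c("blank-corrected", "raw-ratio")) {
  formula <- match.arg(formula)
  stopifnot(length(plates) > 0)
  key <- vapply(plates, function(p) paste(p$agent_id, p$enzyme, sep = "\r"), "")
  out <- lapply(unique(key), function(k) {
    grp <- plates[key == k]
    vals <- vapply(grp, function(p) mean(plate_inhibition(p, formula)), 0)
    summarize_inhibition(vals, agent_id = grp[[1L]]$agent_id,
                         enzyme = grp[[1L]]$enzyme)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Built-in screening effect presets
#'
#' \code{"extracts"}: the packaged extract screening summary (BuChE means of
#' the solvent x technique grid) as simulated truths, agents labelled
#' \code{"solvent/technique"}.  \code{"fractions"}: a synthetic profile of
#' the ethanol-fraction screen of the ethyl acetate extract, with the 60\%
#' ethanol fraction dominant -- the fraction-level screen is only reported
#' graphically, so these values are package-chosen plausible truths, not
#' measurements.
#'
#' @param name Preset name.
#' @return A data frame with columns \code{agent_id}, \code{enzyme},
#'   \code{inhibition} suitable for [simulate_screen()].
#' @export
screen_effects_preset <- function(name = c("extracts", "fractions")) {
  name <- match.arg(name)
  if (name == "extracts") {
    tab <- read_screen_table(system.file("extdata", "extract_screen.tsv",
                                         package = "saponinscreen"))
    tab <- tab[tab$role == "extract" & tab$enzyme == "BuChE", , drop = FALSE]
    data.frame(agent_id = paste(tab$agent_id, tab$technique, sep = "/"),
               enzyme = tab$enzyme, inhibition = tab$mean_inhibition,
               stringsAsFactors = FALSE)
  } else {
    data.frame(
      agent_id = c("0% ethanol (water)", "20% ethanol", "40% ethanol",
                   "60% ethanol", "80% ethanol", "95% ethanol"),
      enzyme = "BuChE",
      inhibition = c(2, 12, 28, 68, 35, 15),
      stringsAsFactors = FALSE
    )
  }
}
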