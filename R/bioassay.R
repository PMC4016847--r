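# Ellman-type cholinesterase inhibition analytics: the enzyme releases
# thiocholine, which reacts with DTNB to a chromophore read at 412 nm, so
# inhibition shows as reduced optical density relative to the uninhibited
# control.  Single-concentration percent inhibition only; no kinetics.

#' Percent inhibition from optical densities
#'
#' Blank-corrected ratio (default):
#' \deqn{(1 - (OD_{sample} - OD_{blank}) / (OD_{control} - OD_{blank})) \times 100}
#' With \code{formula = "raw-ratio"} the blank is ignored:
#' \code{(1 - sample/control) * 100}.
#'
#' The result is invariant under rescaling all three ODs by a common positive
#' factor, and anchors at 0 (sample equals control) and 100 (sample equals
#' blank).
#'
#' @param sample_od,control_od,blank_od Optical densities at 412 nm;
#'   \code{sample_od} may be a vector.
#' @param formula \code{"blank-corrected"} or \code{"raw-ratio"}.
#' @return Percent inhibition (same length as \code{sample_od}).
#' @examples
#' inhibition_percent(0.55, 1.00, 0.10) # 50
#' @export
inhibition_percent <- function(sample_od, control_od, blank_od = 0,
                               formula = c("blank-corrected", "raw-ratio")) {
  formula <- match.arg(formula)
  stopifnot(all(sample_od >= 0), control_od >= 0, blank_od >= 0)
  if (formula == "raw-ratio") blank_od <- 0
  if (control_od <= blank_od) {
    stop("assay failure: control OD must exceed blank OD", call. = FALSE)
  }
  (1 - (sample_od - blank_od) / (control_od - blank_od)) * 100
}

#' Construct a plate assay
#'
#' @param readings Numeric matrix of ODs at 412 nm (any well layout).
#' @param roles Character matrix of the same dimension with entries
#'   \code{"sample"}, \code{"control"}, \code{"blank"} or \code{""} (unused).
#' @param agent_id Agent identifier.
#' @param enzyme \code{"AChE"} or \code{"BuChE"}.
#' @param concentration Agent concentration in mg/mL (1 for extracts, 0.1
#'   for pure compounds, by assay convention); metadata only.
#' @param replicate_index Replicate number (metadata).
#' @return A list of class \code{plate_assay}.
#' @export
plate_assay <- function(readings, roles, agent_id, enzyme = c("AChE", "BuChE"),
                        concentration = NA_real_, replicate_index = 1L) {
  enzyme <- match.arg(enzyme)
  readings <- as.matrix(readings)
  roles <- as.matrix(roles)
  stopifnot(identical(dim(readings), dim(roles)))
  if (any(readings < 0, na.rm = TRUE)) stop("ODs must be >= 0", call. = FALSE)
  ok_roles <- c("sample", "control", "blank", "")
  if (!all(roles %in% ok_roles)) {
    stop("roles must be 'sample', 'control', 'blank' or ''", call. = FALSE)
  }
  if (!any(roles == "control") || !any(roles == "blank")) {
    stop("plate needs at least one control and one blank well", call. = FALSE)
  }
  structure(list(readings = readings, roles = roles, agent_id = agent_id,
                 enzyme = enzyme, concentration = concentration,
                 replicate_index = as.integer(replicate_index)),
            class = "plate_assay")
}

#' @export
print.plate_assay <- function(x, ...) {
  cat("<plate assay> ", x$agent_id, " / ", x$enzyme,
      "  (", sum(x$roles == "sample"), " sample, ",
      sum(x$roles == "control"), " control, ",
      sum(x$roles == "blank"), " blank wells)\n", sep = "")
  invisible(x)
}

#' Per-well percent inhibition of a plate
#'
#' Applies [inhibition_percent()] to every sample well, using the mean
#' control and mean blank OD of the plate.
#'
#' @param plate A [plate_assay()].
#' @param formula Passed to [inhibition_percent()].
#' @return Numeric vector, one value per sample well.
#' @export
plate_inhibition <- function(plate, formula = c("blank-corrected", "raw-ratio")) {
  stopifnot(inherits(plate, "plate_assay"))
  formula <- match.arg(formula)
  ctrl <- mean(plate$readings[plate$roles == "control"])
  blank <- mean(plate$readings[plate$roles == "blank"])
  smp <- plate$readings[plate$roles == "sample"]
  if (!length(smp)) stop("plate has no sample wells", call. = FALSE)
  inhibition_percent(smp, ctrl, blank, formula = formula)
}

#' Replicate summary of percent-inhibition values
#'
#' @param values Numeric vector of percent inhibition, one per replicate
#'   (n >= 3, the minimum the assay design prescribes).
#' @param agent_id,enzyme Metadata carried into the result.
#' @return A one-row data frame of class \code{inhibition_result} with
#'   \code{agent_id}, \code{enzyme}, \code{mean_inhibition}, \code{sem}
#'   (standard error, sd / sqrt(n)) and \code{n}.
#' @examples
#' summarize_inhibition(c(40, 50, 60)) # mean 50, SEM 5.77
#' @export
summarize_inhibition <- function(values, agent_id = NA_character_,
                                 enzyme = NA_character_) {
  values <- as.numeric(values)
  if (length(values) < 3L) {
    stop("insufficient replicates: n >= 3 required, got ", length(values),
         call. = FALSE)
  }
  structure(data.frame(agent_id = agent_id, enzyme = enzyme,
                       mean_inhibition = mean(values),
                       sem = stats::sd(values) / sqrt(length(values)),
                       n = length(values), stringsAsFactors = FALSE),
            class = c("inhibition_result", "data.frame"))
}

#' One-way ANOVA with Fisher's LSD post hoc comparisons
#'
#' Fits \code{stats::aov} on the long data, then performs least significant
#' difference pairwise comparisons: t statistics on group mean differences
#' using the pooled within-group mean square and its residual degrees of
#' freedom.
#'
#' @param groups Named list (agent -> numeric replicate values), each of
#'   length >= 3.
#' @param alpha Significance level for the flags (default 0.05).
#' @return A list of class \code{anova_lsd} with \code{anova} (data frame:
#'   F, df1, df2, p), \code{pairs} (data frame: a, b, diff, se, t, p,
#'   significant) and \code{alpha}.
#' @export
anova_lsd <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2L, !is.null(names(groups)))
  ns <- lengths(groups)
  if (any(ns < 3L)) stop("every group needs n >= 3 replicates", call. = FALSE)
  long <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), ns), levels = names(groups))
  )
  fit <- stats::aov(value ~ group, data = long)
  dfe <- stats::df.residual(fit)
  mse <- stats::deviance(fit) / dfe
  if (mse <= .Machine$double.eps) {
    stop("degenerate within-group variance: LSD undefined", call. = FALSE)
  }
  tab <- stats::anova(fit)
  means <- vapply(groups, mean, 0)
  cmb <- utils::combn(names(groups), 2L)
  pairs <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
    a <- cmb[1L, k]; b <- cmb[2L, k]
    se <- sqrt(mse * (1 / ns[[a]] + 1 / ns[[b]]))
    tval <- (means[[a]] - means[[b]]) / se
    p <- 2 * stats::pt(-abs(tval), dfe)
    data.frame(a = a, b = b, diff = means[[a]] - means[[b]], se = se,
               t = tval, p = p, significant = p < alpha,
               stringsAsFactors = FALSE)
  }))
  structure(list(
    anova = data.frame(F = tab["group", "F value"], df1 = tab["group", "Df"],
                       df2 = dfe, p = tab["group", "Pr(>F)"]),
    pairs = pairs, alpha = alpha
  ), class = "anova_lsd")
}

#' @export
print.anova_lsd <- function(x, ...) {
  cat(sprintf("<one-way ANOVA> F(%d, %d) = %.3f, p = %.4g\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p))
  cat("LSD pairwise comparisons (alpha =", x$alpha, "):\n")
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Rank agents by mean percent inhibition
#'
#' Descending by mean inhibition; ties broken by ascending SEM, then by
#' agent id.  Agents with no detectable inhibition (\code{NA} mean, the
#' "not detected" entries of a screening table) are excluded from the
#' ranking rather than treated as zero.
#'
#' @param results A data frame with columns \code{agent_id}, \code{enzyme},
#'   \code{mean_inhibition}, \code{sem} (e.g. rbind-ed
#'   [summarize_inhibition()] rows).  All rows must share one enzyme.
#' @return A data frame of class \code{inhibition_ranking}, ordered, with a
#'   \code{rank} column; the top agent is row 1.
#' @export
rank_agents <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("agent_id", "enzyme", "mean_inhibition", "sem") %in% names(results)))
  if (!nrow(results)) stop("no results to rank", call. = FALSE)
  enz <- unique(results$enzyme)
  if (length(enz) != 1L) {
    stop("all results must concern the same enzyme; got: ",
         paste(enz, collapse = ", "), call. = FALSE)
  }
  detected <- results[!is.na(results$mean_inhibition), , drop = FALSE]
  if (!nrow(detected)) stop("no detected inhibition to rank", call. = FALSE)
  ord <- order(-detected$mean_inhibition, detected$sem, detected$agent_id)
  out <- detected[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("inhibition_ranking", "data.frame"))
}

#' @export
print.inhibition_ranking <- function(x, ...) {
  cat("<ranking> ", x$enzyme[1L], " inhibition, top agent: ", x$agent_id[1L],
      sprintf(" (%.1f%%)\n", x$mean_inhibition[1L]), sep = "")
  df <- as.data.frame(x)
  df$mean_inhibition <- sprintf("%.1f", df$mean_inhibition)
  df$sem <- sprintf("%.1f", df$sem)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Read a screening summary table
#'
#' Reads a tab-separated inhibition summary (one row per agent and enzyme,
#' \code{'#'} comments allowed) with columns \code{agent_id}, \code{enzyme},
#' \code{mean_inhibition}, \code{sem}, and optionally \code{technique},
#' \code{role} and \code{n}.  Empty / \code{ND} means are read as not
#' detected (\code{NA}).
#'
#' @param path Path to the TSV file.
#' @return A data frame.
#' @export
read_screen_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           na.strings = c("NA", "ND", ""))
  needed <- c("agent_id", "enzyme", "mean_inhibition", "sem")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop("screen table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tab$mean_inhibition <- as.numeric(tab$mean_inhibition)
  tab$sem <- as.numeric(tab$sem)
  tab
}

#' Read a plate OD grid with a parallel role grid
#'
#' @param path Path to a TSV whose numeric grid is the OD readings.
#' @param roles_path Path to a TSV of identical dimensions with the well
#'   roles (\code{sample} / \code{control} / \code{blank} / empty).
#' @param agent_id,enzyme,concentration,replicate_index Plate metadata.
#' @return A [plate_assay()].
#' @export
read_plate <- function(path, roles_path, agent_id = "agent",
                       enzyme = c("AChE", "BuChE"), concentration = NA_real_,
                       replicate_index = 1L) {
  enzyme <- match.arg(enzyme)
  readings <- as.matrix(utils::read.delim(path, header = FALSE,
                                          comment.char = "#"))
  roles <- as.matrix(utils::read.delim(roles_path, header = FALSE,
                                       comment.char = "#",
                                       stringsAsFactors = FALSE,
                                       colClasses = "character"))
  if (!is.numeric(readings)) stop("plate readings must be numeric", call. = FALSE)
  roles[is.na(roles)] <- ""
  plate_assay(readings, roles, agent_id = agent_id, enzyme = enzyme,
              concentration = concentration, replicate_index = replicate_index)
}

#' Write a plate assay to a pair of TSV grids
#'
#' @param plate A [plate_assay()].
#' @param path,roles_path Output paths for the OD grid and the role grid.
#' @return \code{path}, invisibly.
#' @export
write_plate <- function(plate, path, roles_path) {
  stopifnot(inherits(plate, "plate_assay"))
  utils::write.table(plate$readings, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  utils::write.table(plate$roles, roles_path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
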