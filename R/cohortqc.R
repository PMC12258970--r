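#' Cohort stratification thresholds
#'
#' Defaults reproduce the filters that isolate treatment-naive,
#' microsatellite-stable, DNA-repair-proficient colorectal cohorts:
#' hypermutated samples (over 100,000 substitutions or over 7,000 indels)
#' and under-sequenced samples (under 1,000 substitutions) are removed, as
#' are samples whose SBS-96 profile has cosine similarity greater than
#' 0.80 to any supplied flag signature (profiles of base-excision-repair
#' deficiency processes such as those linked to MUTYH, NTHL1 and OGG1).
#' All inequalities are strict, so boundary samples are retained.
#'
#' @param max_sbs,max_indels,min_sbs Burden bounds (defaults 100000, 7000,
#'   1000).
#' @param flag_cosine Cosine threshold for flag-signature removal
#'   (default 0.80).
#' @param flag_signatures Optional 96 x F matrix of flag profiles.
#' @param manual_exclusions Character vector of sample ids to remove
#'   unconditionally (ad-hoc exclusions).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(max_sbs = 100000, max_indels = 7000,
                          min_sbs = 1000, flag_cosine = 0.80,
                          flag_signatures = NULL,
                          manual_exclusions = character()) {
  stopifnot(min_sbs < max_sbs, flag_cosine > 0, flag_cosine < 1)
  structure(list(max_sbs = max_sbs, max_indels = max_indels,
                 min_sbs = min_sbs, flag_cosine = flag_cosine,
                 flag_signatures = flag_signatures,
                 manual_exclusions = manual_exclusions),
            class = "qc_thresholds")
}

#' Filter a cohort to a repair-proficient analysis set
#'
#' Applies the stratification decisions in fixed precedence: manual
#' exclusion, then hypermutator (`sbs > max_sbs` or
#' `indels > max_indels`), then low count (`sbs < min_sbs`), then flag
#' signature (cosine of the sample's normalized SBS-96 profile to any flag
#' profile strictly greater than `flag_cosine`). Each sample receives
#' exactly one decision.
#'
#' @param m Mutational matrix (collapsed to SBS-96 internally for the
#'   flag-cosine rule; burden counts are column sums of the input).
#' @param indel_counts Named per-sample indel totals; missing samples are
#'   treated as 0 with a warning.
#' @param thresholds A [qc_thresholds()].
#' @return A `qc_report` list: `report` data.frame (sample, sbs_count,
#'   indel_count, max_flag_cosine, flag_hit_name, decision) and
#'   `retained_samples`.
#' @export
qc_filter <- function(m, indel_counts = NULL,
                      thresholds = qc_thresholds()) {
  samples <- colnames(m)
  sbs <- colSums(m)
  if (is.null(indel_counts)) indel_counts <- stats::setNames(
    rep(0, length(samples)), samples)
  if (!all(samples %in% names(indel_counts))) {
    warning("missing indel counts treated as 0")
  }
  ind <- stats::setNames(rep(0, length(samples)), samples)
  common <- intersect(samples, names(indel_counts))
  ind[common] <- indel_counts[common]

  m96 <- collapse_matrix(m)
  maxcos <- rep(NA_real_, length(samples))
  hit <- rep(NA_character_, length(samples))
  fs <- thresholds$flag_signatures
  if (!is.null(fs)) {
    fs <- as.matrix(fs)
    nonzero <- sbs > 0
    cm <- cosine_matrix(m96[, nonzero, drop = FALSE], fs)
    maxcos[nonzero] <- apply(cm, 1, max)
    hit[nonzero] <- colnames(fs)[apply(cm, 1, which.max)]
  }

  decision <- rep("retained", length(samples))
  decision[!is.na(maxcos) & maxcos > thresholds$flag_cosine] <-
    "removed_flag_signature"
  decision[sbs < thresholds$min_sbs] <- "removed_low_count"
  decision[sbs > thresholds$max_sbs | ind > thresholds$max_indels] <-
    "removed_hypermutator"
  decision[samples %in% thresholds$manual_exclusions] <- "removed_manual"
  hit[decision != "removed_flag_signature"] <- NA_character_

  report <- data.frame(sample = samples, sbs_count = as.integer(sbs),
                       indel_count = as.integer(round(ind)),
                       max_flag_cosine = maxcos, flag_hit_name = hit,
                       decision = decision, stringsAsFactors = FALSE)
  structure(list(report = report,
                 retained_samples = samples[decision == "retained"]),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>", nrow(x$report), "samples,",
      length(x$retained_samples), "retained\n")
  print(table(x$report$decision))
  invisible(x)
}
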