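#' Configuration for clonal timing classification
#'
#' @param ccf_clonal_threshold Mutations with cancer cell fraction (CCF)
#'   strictly above this are treated as clonal (default 0.95).
#' @param min_per_phase Minimum early-clonal and late-clonal mutation
#'   counts for a sample to be timing-eligible (default 256).
#' @param gain_rule How a copy-number gain is recognized; currently
#'   `"major_cn_ge_2"` (major allele copy number of at least 2).
#' @return A `timing_config` list.
#' @export
timing_config <- function(ccf_clonal_threshold = 0.95,
                          min_per_phase = 256,
                          gain_rule = "major_cn_ge_2") {
  stopifnot(ccf_clonal_threshold > 0, ccf_clonal_threshold <= 1,
            min_per_phase >= 0)
  gain_rule <- match.arg(gain_rule, "major_cn_ge_2")
  structure(list(ccf_clonal_threshold = ccf_clonal_threshold,
                 min_per_phase = min_per_phase, gain_rule = gain_rule),
            class = "timing_config")
}

#' Classify mutations as early or late clonal
#'
#' Within copy-number-gained segments, a clonal mutation present on more
#' than one chromosome copy must predate the gain (early clonal), while a
#' clonal mutation on one copy or fewer postdates it (late clonal). The
#' rule applies only to clonal mutations (CCF strictly above the
#' threshold) in segments where the major allele has gained
#' (`major_cn >= 2`); everything else — subclonal mutations, copy-neutral
#' segments, or records missing any required annotation — is
#' `unclassified`.
#'
#' @param ccf,multiplicity,major_cn Numeric vectors (recycled annotations
#'   of equal length); `NA` means the annotation is absent.
#' @param config A [timing_config()].
#' @return Character vector in `early_clonal`, `late_clonal`,
#'   `unclassified`.
#' @export
classify_timing <- function(ccf, multiplicity, major_cn,
                            config = timing_config()) {
  n <- max(length(ccf), length(multiplicity), length(major_cn))
  ccf <- rep_len(ccf, n)
  multiplicity <- rep_len(multiplicity, n)
  major_cn <- rep_len(major_cn, n)
  out <- rep("unclassified", n)
  usable <- !is.na(ccf) & !is.na(multiplicity) & !is.na(major_cn) &
    ccf > config$ccf_clonal_threshold & major_cn >= 2
  out[usable & multiplicity >= 2] <- "early_clonal"
  out[usable & multiplicity <= 1] <- "late_clonal"
  out
}

#' Split a cohort into early- and late-clonal catalogs
#'
#' Labels every record with [classify_timing()], builds phase-specific
#' mutational matrices over the full sample set, and flags samples with at
#' least `min_per_phase` mutations in both phases as timing-eligible.
#' Ineligible samples remain as columns but are excluded from
#' `eligible_samples`.
#'
#' @param records Record data.frame with `ccf`, `multiplicity`, `major_cn`.
#' @param config A [timing_config()].
#' @param schema Schema for the phase catalogs.
#' @return A `timed_catalogs` list: `early`, `late` (matrices),
#'   `labels` (per-record), `eligible_samples`, `min_per_phase`.
#' @export
split_catalogs <- function(records, config = timing_config(),
                           schema = sbs_schema("SBS96")) {
  lab <- classify_timing(records$ccf, records$multiplicity,
                         records$major_cn, config)
  samples <- unique(records$sample)
  early <- build_matrix(records[lab == "early_clonal", , drop = FALSE],
                        schema, samples = samples)
  late <- build_matrix(records[lab == "late_clonal", , drop = FALSE],
                       schema, samples = samples)
  eligible <- samples[colSums(early) >= config$min_per_phase &
                      colSums(late) >= config$min_per_phase]
  structure(list(early = early, late = late, labels = lab,
                 eligible_samples = eligible,
                 min_per_phase = config$min_per_phase),
            class = "timed_catalogs")
}

#' McNemar-style contrast of paired positivity calls
#'
#' Tests whether a signature is positive in different numbers of samples
#' between two paired conditions (early vs late clonal mutations of the
#' same samples). With `b` = positive-early-only and `c` =
#' positive-late-only discordant counts, the test is an exact two-sided
#' binomial test of `b` against `Binomial(b + c, 1/2)` when `b + c < 25`,
#' and a chi-square test with continuity correction otherwise; `p = 1`
#' when there is no discordance.
#'
#' @param pos_early,pos_late Equal-length logical vectors over the same
#'   (eligible) samples.
#' @return A `contrast_result` list: `n_early_only`, `n_late_only`,
#'   `n_both`, `n_neither`, `statistic`, `p_value`, `method`.
#' @export
timing_contrast <- function(pos_early, pos_late) {
  stopifnot(length(pos_early) == length(pos_late))
  b <- sum(pos_early & !pos_late)
  cc <- sum(!pos_early & pos_late)
  both <- sum(pos_early & pos_late)
  neither <- sum(!pos_early & !pos_late)
  n <- b + cc
  if (n == 0) {
    p <- 1; stat <- 0; method <- "exact_binomial"
  } else if (n < 25) {
    p <- min(1, 2 * stats::pbinom(min(b, cc), n, 0.5))
    stat <- min(b, cc)
    method <- "exact_binomial"
  } else {
    stat <- (abs(b - cc) - 1)^2 / n
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "chi_square_cc"
  }
  structure(list(n_early_only = b, n_late_only = cc, n_both = both,
                 n_neither = neither, statistic = stat, p_value = p,
                 method = method),
            class = "contrast_result")
}

#' Signature attribution within early and late clonal catalogs
#'
#' Runs [attribute_cohort()] independently on the early- and late-clonal
#' matrices restricted to timing-eligible samples.
#'
#' @param timed A `timed_catalogs` object from [split_catalogs()].
#' @param signatures Channels x K signature matrix (same schema as the
#'   phase catalogs).
#' @param prune_delta Passed to [attribute_cohort()].
#' @return List with `early` and `late` activity matrices
#'   (K x eligible-samples).
#' @export
phase_attribution <- function(timed, signatures, prune_delta = 0.002) {
  el <- timed$eligible_samples
  list(early = attribute_cohort(timed$early[, el, drop = FALSE],
                                signatures, prune_delta),
       late = attribute_cohort(timed$late[, el, drop = FALSE],
                               signatures, prune_delta))
}
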