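#' Generate well-separated synthetic reference signatures
#'
#' Each signature is a 96-channel simplex concentrating 60-90% of its mass
#' on a few randomly chosen peak channels (Dirichlet-split) with the
#' remainder Dirichlet-spread over all channels. Candidates are
#' rejection-resampled until every pairwise cosine similarity — including
#' against the profiles in `avoid` — stays below `max_pairwise_cosine`.
#' Deterministic given `seed`.
#'
#' @param K Number of signatures to generate.
#' @param n_peaks Integer (low, high) range for the number of peak
#'   channels per signature.
#' @param max_pairwise_cosine Strict upper bound on pairwise cosines.
#' @param seed Integer seed.
#' @param peak_mass (low, high) range for the total mass on peaks.
#' @param avoid Optional 96 x A matrix of existing profiles the new
#'   signatures must also be dissimilar to.
#' @param max_attempts Resampling budget per signature before erroring.
#' @param name_prefix Column-name prefix (default `"SIM"`).
#' @return 96 x K matrix of column simplices (canonical channel rownames).
#' @export
generate_reference_signatures <- function(K, n_peaks = c(2, 5),
                                          max_pairwise_cosine = 0.5,
                                          seed = 1,
                                          peak_mass = c(0.6, 0.9),
                                          avoid = NULL,
                                          max_attempts = 1000,
                                          name_prefix = "SIM") {
  stopifnot(K >= 1, max_pairwise_cosine > 0, max_pairwise_cosine <= 1)
  set.seed(seed)
  labels <- sbs96_labels()
  accepted <- if (is.null(avoid)) NULL else as.matrix(avoid)
  out <- matrix(0, 96, K, dimnames = list(labels,
                                          paste0(name_prefix, seq_len(K))))
  for (j in seq_len(K)) {
    done <- FALSE
    for (att in seq_len(max_attempts)) {
      np <- sample(n_peaks[1]:n_peaks[2], 1)
      peaks <- sample.int(96, np)
      mass <- stats::runif(1, peak_mass[1], peak_mass[2])
      g_peak <- stats::rgamma(np, shape = 1)
      g_bg <- stats::rgamma(96, shape = 0.5)
      sig <- g_bg / sum(g_bg) * (1 - mass)
      sig[peaks] <- sig[peaks] + mass * g_peak / sum(g_peak)
      sig <- sig / sum(sig)
      if (is.null(accepted) ||
          all(cosine_matrix(accepted, matrix(sig)) < max_pairwise_cosine)) {
        out[, j] <- sig
        accepted <- cbind(accepted, sig)
        done <- TRUE
        break
      }
    }
    if (!done) {
      stop("could not draw signature ", j, " with all pairwise cosines < ",
           max_pairwise_cosine, " in ", max_attempts, " attempts")
    }
  }
  out
}

#' Define a synthetic cohort scenario
#'
#' The scenario fixes the statistical structure the analysis assumes:
#' lognormal per-sample substitution burdens (around 10^4 for
#' microsatellite-stable samples), sparse signature exposures with
#' per-signature prevalences, a weak late-clonal target signature present
#' in roughly half of samples at 5-10% of their mutations, optional
#' hypermutator spike-ins at an order of magnitude higher burden, and
#' indel burdens that rise with target-signature activity.
#'
#' @param n_samples Cohort size.
#' @param signatures 96 x K truth signature matrix; generated by
#'   [generate_reference_signatures()] (pairwise cosine < 0.5) when `NULL`.
#' @param prevalence Per-signature activity probability. Defaults give a
#'   ubiquitous background signature, two intermediate signatures, and the
#'   target at prevalence 0.53.
#' @param contribution_range K x 2 matrix of (low, high) proportion ranges
#'   drawn per active signature; the target's drawn proportion is imposed
#'   exactly and the rest renormalized. Default target range (0.05, 0.10).
#' @param burden_log10_mean,burden_log10_sd Lognormal burden parameters
#'   (defaults 4 and 0.25: median 10^4 substitutions).
#' @param n_hypermutators,hypermutator_burden Spike-in count and burden
#'   (defaults 0 and 100000).
#' @param target_signature_index Which signature is the weak late target
#'   (default the last).
#' @param target_late_fraction Probability that a clonal target mutation
#'   is late (default 0.9).
#' @param early_enrichment Per-signature early:late odds for non-target
#'   signatures (default 1 = timing-neutral).
#' @param gained_genome_fraction Fraction of mutations falling in
#'   copy-number-gained segments (default 0.4).
#' @param subclonal_fraction Fraction of mutations that are subclonal
#'   (default 0.1).
#' @param indel_baseline,indel_link_slope Poisson indel model: log-mean =
#'   `log(indel_baseline) + slope * (target activity / total mutations)`.
#'   Defaults 1500 and 3.5 (about a 1.3-fold indel excess in
#'   target-positive samples).
#' @param seed Integer seed; every simulation stage derives its stream
#'   from it.
#' @return A `cohort_scenario` list.
#' @export
cohort_scenario <- function(n_samples = 300, signatures = NULL,
                            prevalence = NULL, contribution_range = NULL,
                            burden_log10_mean = 4, burden_log10_sd = 0.25,
                            n_hypermutators = 0,
                            hypermutator_burden = 100000,
                            target_signature_index = NULL,
                            target_late_fraction = 0.9,
                            early_enrichment = NULL,
                            gained_genome_fraction = 0.4,
                            subclonal_fraction = 0.1,
                            indel_baseline = 1500,
                            indel_link_slope = 3.5,
                            seed = 1) {
  if (is.null(signatures)) {
    signatures <- generate_reference_signatures(4, seed = seed)
  }
  K <- ncol(signatures)
  if (is.null(target_signature_index)) target_signature_index <- K
  if (is.null(prevalence)) {
    # sparse exposures: no signature is ubiquitous, so each signature has
    # samples lacking every other one — this is what makes the pure
    # signature profiles identifiable vertices of the data cone
    prevalence <- seq(0.8, 0.6, length.out = K)
    prevalence[target_signature_index] <- 0.53
  }
  if (is.null(contribution_range)) {
    contribution_range <- matrix(rep(c(0.1, 1), K), K, 2, byrow = TRUE)
    contribution_range[target_signature_index, ] <- c(0.05, 0.10)
  }
  if (is.null(early_enrichment)) early_enrichment <- rep(1, K)
  stopifnot(all(prevalence >= 0 & prevalence <= 1),
            nrow(contribution_range) == K,
            all(contribution_range >= 0 & contribution_range <= 1),
            all(contribution_range[, 1] <= contribution_range[, 2]),
            is.finite(burden_log10_mean), is.finite(burden_log10_sd),
            target_late_fraction >= 0, target_late_fraction <= 1,
            gained_genome_fraction >= 0, gained_genome_fraction <= 1)
  structure(list(n_samples = n_samples, signatures = signatures,
                 prevalence = prevalence,
                 contribution_range = contribution_range,
                 burden_log10_mean = burden_log10_mean,
                 burden_log10_sd = burden_log10_sd,
                 n_hypermutators = n_hypermutators,
                 hypermutator_burden = hypermutator_burden,
                 target_signature_index = target_signature_index,
                 target_late_fraction = target_late_fraction,
                 early_enrichment = early_enrichment,
                 gained_genome_fraction = gained_genome_fraction,
                 subclonal_fraction = subclonal_fraction,
                 indel_baseline = indel_baseline,
                 indel_link_slope = indel_link_slope,
                 seed = as.integer(seed)),
            class = "cohort_scenario")
}

# expand per-signature channel counts into record scaffolds
synthesize_records <- function(channel_labels, sample_ids, sig_truth) {
  n <- length(channel_labels)
  f5 <- substr(channel_labels, 1L, 1L)
  ref <- substr(channel_labels, 3L, 3L)
  alt <- substr(channel_labels, 5L, 5L)
  f3 <- substr(channel_labels, 7L, 7L)
  o5 <- sample(BASES, n, replace = TRUE)
  o3 <- sample(BASES, n, replace = TRUE)
  penta <- paste0(o5, f5, ref, f3, o3)
  flip <- stats::runif(n) < 0.5
  penta[flip] <- revcomp(penta[flip])
  ref[flip] <- unname(COMP[ref[flip]])
  alt[flip] <- unname(COMP[alt[flip]])
  strand <- sample(c("non_transcribed", "gene_forward", "gene_reverse"),
                   n, replace = TRUE, prob = c(0.5, 0.25, 0.25))
  data.frame(sample = sample_ids, chrom = "chrSIM", pos = seq_len(n) * 10L,
             ref = ref, alt = alt, pentacontext = penta,
             strand_status = strand, ccf = NA_real_,
             multiplicity = NA_real_, major_cn = NA_real_,
             minor_cn = NA_real_, signature_truth = sig_truth,
             stringsAsFactors = FALSE)
}

#' Simulate a cohort with known ground-truth exposures
#'
#' Draws, per sample: a lognormal total burden; the set of active
#' signatures (per-signature prevalence); per-signature contribution
#' proportions from the scenario ranges (the target signature's proportion
#' imposed exactly, the others renormalized); per-signature mutation
#' counts (multinomial); and per-signature channel counts (multinomial
#' from the signature profile). A sample drawing zero active signatures is
#' assigned a flat background profile, tracked in a dedicated
#' `Background` truth row. Records are then synthesized with
#' channel-consistent pentanucleotide contexts, random outer flanks,
#' random strand representation (half the records are written on the
#' purine strand to exercise classification), and synthetic coordinates
#' on one virtual contig.
#'
#' The RNG stream is seeded once from the scenario; the record-synthesis
#' stage uses a sub-seed drawn first, so catalogs are bit-identical
#' whether or not records are materialized.
#'
#' @param scenario A [cohort_scenario()].
#' @param records Materialize per-mutation records (default TRUE); set
#'   FALSE for matrix-only simulations at large burdens.
#' @return A `simulated_cohort` list: `matrix` (96 x n counts),
#'   `true_exposures` ((K+1) x n counts, `Background` last),
#'   `records` (or NULL), `signatures`, `scenario`.
#' @export
simulate_cohort <- function(scenario, records = TRUE) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  set.seed(scenario$seed)
  rec_seed <- sample.int(.Machine$integer.max - 1, 1)
  K <- ncol(scenario$signatures)
  n <- scenario$n_samples
  labels <- sbs96_labels()
  flat <- rep(1 / 96, 96)
  sample_ids <- sprintf("SIM%04d", seq_len(n))
  counts <- matrix(0L, 96, n, dimnames = list(labels, sample_ids))
  expo <- matrix(0, K + 1, n,
                 dimnames = list(c(colnames(scenario$signatures),
                                   "Background"), sample_ids))
  per_sig_channels <- vector("list", n)
  ti <- scenario$target_signature_index
  for (i in seq_len(n)) {
    burden <- max(1L, as.integer(round(
      10^stats::rnorm(1, scenario$burden_log10_mean,
                      scenario$burden_log10_sd))))
    active <- which(stats::runif(K) < scenario$prevalence)
    if (identical(active, ti) && K > 1) {
      # the target is a low-contribution signature by construction; a
      # sample cannot consist of it alone, so the most prevalent other
      # signature carries the remainder
      others <- seq_len(K)[-ti]
      active <- sort(c(ti, others[which.max(scenario$prevalence[others])]))
    }
    if (!length(active)) {
      message("sample ", sample_ids[i],
              " drew no active signature; assigned flat background")
      ch <- as.integer(stats::rmultinom(1, burden, flat))
      counts[, i] <- ch
      expo["Background", i] <- burden
      per_sig_channels[[i]] <- list(Background = ch)
      next
    }
    u <- stats::runif(length(active),
                      scenario$contribution_range[active, 1],
                      scenario$contribution_range[active, 2])
    names(u) <- colnames(scenario$signatures)[active]
    if (ti %in% active && length(active) > 1) {
      pt <- u[which(active == ti)]
      p <- u
      p[active != ti] <- u[active != ti] / sum(u[active != ti]) * (1 - pt)
      p[active == ti] <- pt
    } else {
      p <- u / sum(u)
    }
    nk <- as.integer(stats::rmultinom(1, burden, p))
    chl <- list()
    for (a in seq_along(active)) {
      if (nk[a] == 0) next
      ch <- as.integer(stats::rmultinom(1, nk[a],
                                        scenario$signatures[, active[a]]))
      counts[, i] <- counts[, i] + ch
      chl[[names(u)[a]]] <- ch
    }
    expo[active, i] <- nk
    per_sig_channels[[i]] <- chl
  }
  recs <- NULL
  if (records) {
    set.seed(rec_seed)
    lab_v <- character(0); sam_v <- character(0); sig_v <- character(0)
    lab_list <- vector("list", n)
    for (i in seq_len(n)) {
      chl <- per_sig_channels[[i]]
      li <- lapply(names(chl), function(nm) {
        cbind(rep(labels, chl[[nm]]), nm)
      })
      lab_list[[i]] <- cbind(do.call(rbind, li), sample_ids[i])
    }
    all <- do.call(rbind, lab_list)
    recs <- synthesize_records(all[, 1], all[, 3], all[, 2])
    recs <- mutation_records(recs)
  }
  attr(counts, "schema") <- "SBS96"
  structure(list(matrix = counts, true_exposures = expo, records = recs,
                 signatures = scenario$signatures, scenario = scenario),
            class = "simulated_cohort")
}

#' Append hypermutator samples to a simulated cohort
#'
#' Adds `n` samples each carrying `burden` mutations drawn multinomially
#' from `signature_profile` — by default a dedicated "MMR-like" synthetic
#' signature generated to be dissimilar (cosine < 0.5) to every baseline
#' signature, emulating mismatch-repair-deficient hypermutators whose
#' order-of-magnitude higher burdens can mask weak signatures when cohorts
#' are not stratified by repair status. Truth exposures gain a
#' `Hypermutator` row.
#'
#' @param cohort A `simulated_cohort`.
#' @param n Number of spiked samples (0 returns the cohort unchanged).
#' @param burden Mutations per spiked sample.
#' @param signature_profile Optional 96-vector profile.
#' @return The extended `simulated_cohort`.
#' @export
spike_hypermutators <- function(cohort,
                                n = cohort$scenario$n_hypermutators,
                                burden = cohort$scenario$hypermutator_burden,
                                signature_profile = NULL) {
  stopifnot(n >= 0)
  if (n == 0) return(cohort)
  set.seed(cohort$scenario$seed + 1L)
  if (is.null(signature_profile)) {
    signature_profile <- generate_reference_signatures(
      1, seed = cohort$scenario$seed + 2L, avoid = cohort$signatures,
      name_prefix = "MMRlike")[, 1]
  }
  ids <- sprintf("HYP%04d", seq_len(n))
  labels <- rownames(cohort$matrix)
  add <- matrix(0L, 96, n, dimnames = list(labels, ids))
  for (i in seq_len(n)) {
    add[, i] <- as.integer(stats::rmultinom(1, burden, signature_profile))
  }
  m <- cbind(cohort$matrix, add)
  attr(m, "schema") <- "SBS96"
  expo <- rbind(cohort$true_exposures,
                Hypermutator = rep(0, ncol(cohort$true_exposures)))
  expo <- cbind(expo, matrix(0, nrow(expo), n,
                             dimnames = list(rownames(expo), ids)))
  expo["Hypermutator", ids] <- burden
  if (!is.null(cohort$records)) {
    lab_all <- unlist(lapply(seq_len(n), function(i) {
      rep(labels, add[, i])
    }))
    sam_all <- rep(ids, colSums(add))
    newrec <- synthesize_records(lab_all, sam_all, "Hypermutator")
    newrec <- mutation_records(newrec)
    cohort$records <- rbind(cohort$records, newrec)
  }
  cohort$matrix <- m
  cohort$true_exposures <- expo
  cohort$hypermutator_profile <- signature_profile
  cohort$hypermutator_samples <- ids
  cohort
}

#' Add clonal-timing structure to simulated records
#'
#' Assigns each record to a copy-number-gained segment (major 2 / minor 1)
#' with probability `gained_genome_fraction` or a neutral (1/1) segment
#' otherwise; marks a `subclonal_fraction` of records subclonal with CCF
#' drawn in (0.3, 0.95] and the rest clonal with CCF in (0.99, 1]. Each
#' clonal record draws an early/late truth phase from its truth
#' signature's odds: the target signature is late with probability
#' `target_late_fraction`, the others with odds set by
#' `early_enrichment` (1 = timing-neutral). In gained segments early
#' mutations carry multiplicity 2 and late mutations multiplicity 1;
#' neutral segments always carry multiplicity 1 (so their phase is not
#' observable downstream).
#'
#' @param cohort A `simulated_cohort` with records.
#' @param gained_genome_fraction,subclonal_fraction,target_late_fraction,early_enrichment
#'   Override the scenario values.
#' @return The cohort with `ccf`, `multiplicity`, `major_cn`, `minor_cn`
#'   and `timing_truth` filled in on its records.
#' @export
simulate_timing <- function(cohort,
    gained_genome_fraction = cohort$scenario$gained_genome_fraction,
    subclonal_fraction = cohort$scenario$subclonal_fraction,
    target_late_fraction = cohort$scenario$target_late_fraction,
    early_enrichment = cohort$scenario$early_enrichment) {
  stopifnot(!is.null(cohort$records),
            gained_genome_fraction >= 0, gained_genome_fraction <= 1)
  set.seed(cohort$scenario$seed + 3L)
  recs <- cohort$records
  n <- nrow(recs)
  K <- ncol(cohort$signatures)
  signames <- colnames(cohort$signatures)
  p_late <- stats::setNames(1 / (1 + early_enrichment), signames)
  p_late[signames[cohort$scenario$target_signature_index]] <-
    target_late_fraction
  p_late <- c(p_late, Background = 0.5, Hypermutator = 0.5)

  gained <- stats::runif(n) < gained_genome_fraction
  subcl <- stats::runif(n) < subclonal_fraction
  ccf <- ifelse(subcl, stats::runif(n, 0.30, 0.95),
                stats::runif(n, 0.9901, 1.0))
  late <- stats::runif(n) < p_late[recs$signature_truth]
  mult <- ifelse(gained & !late, 2L, 1L)
  recs$ccf <- ccf
  recs$multiplicity <- as.numeric(mult)
  recs$major_cn <- ifelse(gained, 2, 1)
  recs$minor_cn <- 1
  recs$timing_truth <- ifelse(subcl, "subclonal",
                              ifelse(late, "late", "early"))
  cohort$records <- recs
  cohort
}

#' Simulate indel burdens correlated with target-signature activity
#'
#' Per-sample indel counts are Poisson with
#' `log(mean) = log(baseline) + slope * x`, where `x` is the sample's
#' target-signature activity as a fraction of its total mutations. A zero
#' slope gives the null (uncorrelated) case; the default scenario slope
#' produces roughly a 1.3-fold mean excess in target-positive samples.
#' Spiked hypermutator samples instead draw around
#' `baseline * hypermutator_factor` indels — mismatch-repair-deficient
#' tumors are indel-rich by an order of magnitude, which is what lets
#' burden-based cohort filters catch them.
#'
#' @param cohort A `simulated_cohort`.
#' @param baseline Baseline indel count (> 0).
#' @param slope Link slope on the log scale.
#' @param hypermutator_factor Multiplier on `baseline` for spiked
#'   hypermutator samples (default 20).
#' @return Named integer vector of per-sample indel counts.
#' @export
simulate_indel_burden <- function(cohort,
                                  baseline = cohort$scenario$indel_baseline,
                                  slope = cohort$scenario$indel_link_slope,
                                  hypermutator_factor = 20) {
  stopifnot(baseline > 0)
  set.seed(cohort$scenario$seed + 4L)
  ti <- cohort$scenario$target_signature_index
  tname <- colnames(cohort$signatures)[ti]
  tot <- colSums(cohort$matrix)
  x <- cohort$true_exposures[tname, ] / pmax(tot, 1)
  lam <- exp(log(baseline) + slope * x)
  if (!is.null(cohort$hypermutator_samples)) {
    lam[cohort$hypermutator_samples] <- baseline * hypermutator_factor
  }
  stats::setNames(as.integer(stats::rpois(length(lam), lam)),
                  colnames(cohort$matrix))
}
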