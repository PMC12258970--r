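# Independent oracles used across the suite; deliberately naive
# implementations kept separate from the code paths they check.

# exhaustive simplex-grid optimum for decomposition weights: best
# reconstruction cosine over the weight simplex at the given resolution
grid_best_weights <- function(target, refs, step = 0.01) {
  refs <- as.matrix(refs)
  k <- ncol(refs)
  grid <- seq(0, 1, by = step)
  best <- list(cos = -Inf, w = NULL)
  if (k == 2) {
    for (w1 in grid) {
      w <- c(w1, 1 - w1)
      rec <- refs %*% w
      if (sum(rec) == 0) next
      cs <- cosine_similarity(target, as.vector(rec))
      if (cs > best$cos) best <- list(cos = cs, w = w)
    }
  } else if (k == 3) {
    for (w1 in grid) for (w2 in seq(0, 1 - w1, by = step)) {
      w <- c(w1, w2, 1 - w1 - w2)
      rec <- refs %*% w
      if (sum(rec) == 0) next
      cs <- cosine_similarity(target, as.vector(rec))
      if (cs > best$cos) best <- list(cos = cs, w = w)
    }
  } else {
    stop("grid oracle supports 2 or 3 references")
  }
  best
}

# literal transcription of the early/late rule for a single mutation
timing_rule_oracle <- function(ccf, multiplicity, major_cn,
                               threshold = 0.95) {
  if (is.na(ccf) || is.na(multiplicity) || is.na(major_cn)) {
    return("unclassified")
  }
  if (ccf <= threshold) return("unclassified")
  if (major_cn < 2) return("unclassified")
  if (multiplicity >= 2) return("early_clonal")
  "late_clonal"
}

# closed-form two-sided exact binomial McNemar p-value
mcnemar_exact_oracle <- function(b, cc) {
  n <- b + cc
  if (n == 0) return(1)
  m <- min(b, cc)
  min(1, 2 * sum(choose(n, 0:m) * 0.5^n))
}

# random simplex over 96 channels
random_profile <- function(concentration = 0.3) {
  g <- stats::rgamma(96, shape = concentration)
  g / sum(g)
}

# small well-separated truth set + multinomial cohort used by several
# tests; sparse prevalences give the compositional spread that makes the
# signature vertices identifiable
make_toy_cohort <- function(n_samples, burden, K = 3, seed = 42) {
  sigs <- generate_reference_signatures(K, seed = seed)
  sc <- cohort_scenario(
    n_samples = n_samples, signatures = sigs,
    prevalence = seq(0.95, 0.65, length.out = K),
    contribution_range = matrix(rep(c(0.2, 1), K), K, 2, byrow = TRUE),
    burden_log10_mean = log10(burden), burden_log10_sd = 0,
    target_signature_index = K, seed = seed)
  simulate_cohort(sc, records = FALSE)
}
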