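test_that("generated reference signatures are separated simplices", {
  sigs <- generate_reference_signatures(4, max_pairwise_cosine = 0.5,
                                        seed = 3)
  expect_equal(dim(sigs), c(96, 4))
  expect_true(all(sigs >= 0))
  expect_equal(unname(colSums(sigs)), rep(1, 4), tolerance = 1e-9)
  cm <- crossprod(sigs) /
    outer(sqrt(colSums(sigs^2)), sqrt(colSums(sigs^2)))
  expect_true(all(cm[upper.tri(cm)] < 0.5))
  # bit-identical under the same seed
  expect_identical(sigs, generate_reference_signatures(4, seed = 3))
  # infeasible separation errors out with the constraint named
  expect_error(generate_reference_signatures(50, max_pairwise_cosine = 0.02,
                                             max_attempts = 5),
               "cosines")
})

test_that("single-source cohorts reproduce their generating signature", {
  sig <- generate_reference_signatures(1, seed = 9)
  sc <- cohort_scenario(n_samples = 6, signatures = sig, prevalence = 1,
                        contribution_range = matrix(c(1, 1), 1, 2),
                        burden_log10_mean = log10(5000),
                        burden_log10_sd = 0, seed = 9)
  co <- simulate_cohort(sc, records = FALSE)
  expect_true(all(colSums(co$matrix) == 5000))
  agg <- rowSums(co$matrix)
  expect_gte(cosine_similarity(agg, sig[, 1]), 0.999)
})

test_that("aggregate catalogs match the exposure-weighted truth mixture", {
  co <- make_toy_cohort(n_samples = 100, burden = 10000, K = 4, seed = 21)
  agg <- rowSums(co$matrix)
  truth_mix <- co$signatures %*%
    rowSums(co$true_exposures)[colnames(co$signatures)]
  expect_gte(cosine_similarity(agg, as.vector(truth_mix)), 0.99)
})

test_that("exposure truth obeys prevalence and conservation", {
  sigs <- generate_reference_signatures(3, seed = 4)
  sc <- cohort_scenario(n_samples = 40, signatures = sigs,
                        prevalence = c(1, 0, 0.6),
                        burden_log10_mean = 3, seed = 4)
  co <- simulate_cohort(sc)
  expect_true(all(co$true_exposures[2, ] == 0))  # prevalence-0 row
  expect_equal(sum(co$true_exposures), sum(co$matrix))
  expect_equal(unname(colSums(co$true_exposures)),
               unname(colSums(co$matrix)))
  expect_equal(nrow(co$records), sum(co$matrix))
  # per-sample record counts equal truth column sums
  expect_equal(unname(table(co$records$sample)[colnames(co$matrix)]),
               unname(colSums(co$true_exposures)),
               ignore_attr = TRUE)
})

test_that("simulation is bit-reproducible and record-independent", {
  sc <- cohort_scenario(n_samples = 10, burden_log10_mean = 2.8, seed = 77)
  a <- simulate_cohort(sc)
  b <- simulate_cohort(sc)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$records, b$records)
  nomat <- simulate_cohort(sc, records = FALSE)
  expect_identical(a$matrix, nomat$matrix)  # records don't shift the stream
  # records validate and rebuild the same catalog through classification
  rebuilt <- build_matrix(a$records, sbs_schema("SBS96"),
                          samples = colnames(a$matrix))
  expect_equal(rebuilt[, ], a$matrix[, ], ignore_attr = TRUE)
})

test_that("burden scaling law: +log10(2) on the mean doubles the median", {
  sc1 <- cohort_scenario(n_samples = 80, burden_log10_mean = 3, seed = 31)
  sc2 <- cohort_scenario(n_samples = 80,
                         burden_log10_mean = 3 + log10(2), seed = 31)
  m1 <- stats::median(colSums(simulate_cohort(sc1, records = FALSE)$matrix))
  m2 <- stats::median(colSums(simulate_cohort(sc2, records = FALSE)$matrix))
  expect_lt(abs(m2 / m1 - 2), 0.2)
})

test_that("hypermutator spike-ins extend the cohort at the stated burden", {
  sc <- cohort_scenario(n_samples = 20, seed = 15)  # burden median 10^4
  co <- simulate_cohort(sc, records = FALSE)
  expect_identical(spike_hypermutators(co, n = 0), co)  # identity at n=0
  sp <- spike_hypermutators(co, n = 6, burden = 100000)
  expect_equal(ncol(sp$matrix), 26)
  hyp <- sp$hypermutator_samples
  expect_true(all(colSums(sp$matrix[, hyp]) == 100000))
  expect_true(all(sp$true_exposures["Hypermutator", hyp] == 100000))
  # order-of-magnitude burden contrast between spiked and baseline samples
  ratio <- stats::median(colSums(sp$matrix[, hyp])) /
    stats::median(colSums(co$matrix))
  expect_gt(ratio, 7); expect_lt(ratio, 14)
  # spiked profile dissimilar to every baseline signature
  cm <- apply(co$signatures, 2, cosine_similarity,
              b = sp$hypermutator_profile)
  expect_true(all(cm < 0.5))
})

test_that("timing structure follows the per-signature late odds", {
  sigs <- generate_reference_signatures(3, seed = 8)
  sc <- cohort_scenario(n_samples = 30, signatures = sigs,
                        prevalence = rep(1, 3),
                        burden_log10_mean = 3.2, target_signature_index = 3,
                        target_late_fraction = 0.9, seed = 8)
  co <- simulate_timing(simulate_cohort(sc))
  recs <- co$records
  clonal <- recs$timing_truth != "subclonal"
  # timing-neutral signatures split early/late evenly
  neut <- clonal & recs$signature_truth != colnames(sigs)[3]
  frac_late <- mean(recs$timing_truth[neut] == "late")
  expect_lt(abs(frac_late - 0.5), 3 / sqrt(sum(neut)))
  # >=80% of gained-segment target mutations carry multiplicity 1
  targ <- recs$signature_truth == colnames(sigs)[3] & recs$major_cn >= 2 &
    clonal
  expect_gte(mean(recs$multiplicity[targ] == 1), 0.8)
  # no gains means nothing is classifiable downstream
  co0 <- simulate_timing(co, gained_genome_fraction = 0)
  lab <- classify_timing(co0$records$ccf, co0$records$multiplicity,
                         co0$records$major_cn)
  expect_true(all(lab == "unclassified"))
})

test_that("indel burdens decouple from the target at zero slope", {
  sc <- cohort_scenario(n_samples = 200, seed = 19)
  co <- simulate_cohort(sc, records = FALSE)
  ind <- simulate_indel_burden(co, slope = 0)
  tname <- colnames(co$signatures)[co$scenario$target_signature_index]
  rho <- rank_correlation(as.numeric(ind),
                          co$true_exposures[tname, ] /
                            colSums(co$matrix))
  expect_lt(abs(rho), 0.15)
})
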