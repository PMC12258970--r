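make_catalog <- function(K = 6, seed = 71, tags = NULL) {
  sigs <- generate_reference_signatures(K, seed = seed,
                                        name_prefix = "REF")
  reference_catalog(sigs, tags)
}

test_that("nonnegative least squares weights recover constructed mixtures", {
  cat6 <- make_catalog()
  refs <- cat6$signatures
  # identity
  w <- fit_weights(refs[, 3], refs)
  expect_equal(unname(w[3]), 1, tolerance = 1e-8)
  # disjoint supports force the exact split
  r1 <- c(rep(1 / 48, 48), rep(0, 48))
  r2 <- c(rep(0, 48), rep(1 / 48, 48))
  w2 <- fit_weights(0.5 * r1 + 0.5 * r2, cbind(a = r1, b = r2))
  expect_equal(unname(w2), c(0.5, 0.5), tolerance = 1e-10)
  # low-coherence 70/30 mixture against the simplex-grid oracle
  set.seed(14)
  repeat {
    a <- random_profile(); b <- random_profile()
    if (cosine_similarity(a, b) < 0.3) break
  }
  target <- 0.7 * a + 0.3 * b
  w3 <- fit_weights(target, cbind(a = a, b = b))
  expect_equal(unname(w3), c(0.7, 0.3), tolerance = 0.02)
  oracle <- grid_best_weights(target, cbind(a, b))
  expect_equal(unname(w3), oracle$w, tolerance = 0.02)
  expect_error(fit_weights(rep(0, 96), refs), "zero")
})

test_that("forward-selection decomposition matches the grid oracle", {
  set.seed(25)
  for (rep in 1:20) {
    k <- sample(2:3, 1)
    refs <- generate_reference_signatures(k, seed = 1000 + rep,
                                          name_prefix = "R")
    # material components only: a share s gains roughly s^2/2 of
    # reconstruction cosine, so shares below ~15% fall under the
    # forward-selection add threshold by design
    w_true <- stats::runif(k, 0.5, 1); w_true <- w_true / sum(w_true)
    target <- as.vector(refs %*% w_true)
    cat_k <- reference_catalog(refs)
    d <- decompose_signature(target, cat_k, mode = "naive")
    oracle <- grid_best_weights(target, refs)
    expect_true(all(abs(d$weights[colnames(refs)] - oracle$w) <= 0.02))
  }
})

test_that("decomposition handles exact, novel, and excluded targets", {
  tags <- list(REF1 = "treatment", REF2 = "ultraviolet")
  cat6 <- make_catalog(tags = tags)
  refs <- cat6$signatures
  # exact reference: full weight, cosine 1, not novel
  d <- decompose_signature(refs[, "REF3"], cat6, mode = "naive")
  expect_equal(unname(d$weights["REF3"]), 1, tolerance = 1e-6)
  expect_gte(d$reconstruction_cosine, 1 - 1e-9)
  expect_false(d$novel)
  # target concentrated where the references carry least mass: novel
  least <- order(rowSums(refs))[1:4]
  novel_target <- numeric(96)
  novel_target[least] <- 0.25
  d2 <- decompose_signature(novel_target, cat6, mode = "naive")
  expect_lt(d2$reconstruction_cosine, 0.90)
  expect_true(d2$novel)
  # exclusion law: excluded tag gets exactly zero weight even for a
  # perfect match
  d3 <- decompose_signature(refs[, "REF1"], cat6, mode = "optimized",
                            excluded_subgroups = "treatment")
  expect_equal(unname(d3$weights["REF1"]), 0)
  # optimized mode requires an exclusion set; exhausting it errors
  expect_error(decompose_signature(refs[, 1], cat6, mode = "optimized"),
               "non-empty")
  allcat <- reference_catalog(refs[, 1:2, drop = FALSE],
                              list(REF1 = "artifact", REF2 = "artifact"))
  expect_error(decompose_signature(refs[, 3], allcat, mode = "optimized",
                                   excluded_subgroups = "artifact"),
               "artifact")
})

test_that("a four-way constructed mixture is recovered within tolerance", {
  refs <- generate_reference_signatures(6, seed = 99, name_prefix = "REF")
  cat6 <- reference_catalog(refs)
  w_true <- c(REF1 = 0.145, REF2 = 0.409, REF3 = 0.326, REF4 = 0.120)
  target <- as.vector(refs[, names(w_true)] %*% w_true)
  d <- decompose_signature(target, cat6, mode = "naive")
  expect_true(all(abs(d$weights[names(w_true)] - w_true) <= 0.05))
  expect_gte(d$reconstruction_cosine, 0.99)
})

test_that("naive reconstruction is never worse than optimized", {
  tags <- list(REF1 = "mismatch_repair_deficiency",
               REF2 = "polymerase_deficiency", REF5 = "treatment")
  cat6 <- make_catalog(tags = tags)
  set.seed(18)
  for (i in 1:10) {
    target <- random_profile()
    dn <- decompose_signature(target, cat6, mode = "naive")
    dop <- decompose_signature(target, cat6, mode = "optimized",
      excluded_subgroups = c("mismatch_repair_deficiency",
                             "polymerase_deficiency", "treatment"))
    expect_gte(dn$reconstruction_cosine,
               dop$reconstruction_cosine - 1e-9)
    # excluded-tag references never receive weight
    expect_equal(unname(dop$weights[c("REF1", "REF2", "REF5")]),
                 c(0, 0, 0))
  }
})

test_that("novelty flag flips exactly at the 0.90 threshold", {
  refs <- generate_reference_signatures(2, seed = 5, name_prefix = "REF")
  cat2 <- reference_catalog(refs)
  set.seed(77)
  # construct targets straddling the threshold by blending a reference
  # with an off-support residual, then check flag == (cosine < 0.90)
  resid <- random_profile(0.1)
  for (mix in seq(0.1, 0.9, by = 0.1)) {
    target <- mix * refs[, 1] + (1 - mix) * resid
    target <- target / sum(target)
    d <- decompose_signature(target, cat2, mode = "naive")
    expect_identical(d$novel, d$reconstruction_cosine < 0.90)
  }
})

test_that("signature matching recovers permutations and noisy replicates", {
  refs <- generate_reference_signatures(5, seed = 41, name_prefix = "X")
  self <- match_signatures(refs, refs)
  expect_equal(self$a, self$b)
  expect_equal(self$cosine, rep(1, 5), tolerance = 1e-12)
  perm <- c(3, 1, 5, 2, 4)
  shuffled <- refs[, perm]
  mt <- match_signatures(refs, shuffled)
  expect_equal(mt$b, mt$a)  # inverse permutation recovered
  expect_equal(mt$cosine, rep(1, 5), tolerance = 1e-12)
  # two noisy replicate extractions of a common truth stay matched
  co <- make_toy_cohort(n_samples = 60, burden = 2000, K = 3, seed = 61)
  e1 <- extract_signatures(co$matrix[, 1:30], 3, n_replicates = 5, seed = 1)
  e2 <- extract_signatures(co$matrix[, 31:60], 3, n_replicates = 5, seed = 2)
  mt2 <- match_signatures(e1$solutions[["3"]]$consensus_signatures,
                          e2$solutions[["3"]]$consensus_signatures)
  expect_true(all(mt2$cosine >= 0.95))
})
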