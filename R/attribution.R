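#' Attribute one sample's mutations to signatures with backward pruning
#'
#' Fits the sample's channel counts onto the signature set by nonnegative
#' least squares, then prunes for sparsity: the signature whose removal
#' least degrades the sample reconstruction cosine is repeatedly zeroed
#' while that degradation stays below `prune_delta`. Surviving activities
#' are refit and scaled so they sum to the sample's mutation count. If
#' pruning would remove every signature, the single best-cosine signature
#' is kept with a warning.
#'
#' @param column Nonnegative channel-count vector (sum > 0).
#' @param signatures Channels x K signature matrix (column simplices).
#' @param prune_delta Maximum tolerated reconstruction-cosine loss per
#'   pruning step. The default 0.002 keeps true contributions down to
#'   about 6% of a sample's mutations (a contribution of share `s` costs
#'   roughly `s^2/2` of reconstruction cosine) while still zeroing
#'   noise-level fits.
#' @return Named numeric vector of attributed mutation counts (length K,
#'   zeros for pruned signatures), summing to `sum(column)`.
#' @export
attribute_sample <- function(column, signatures, prune_delta = 0.002) {
  column <- as.vector(column)
  total <- sum(column)
  if (total <= 0) stop("column sum must be positive")
  signatures <- as.matrix(signatures)
  K <- ncol(signatures)
  active <- seq_len(K)
  current <- fit_cosine(column, signatures)
  while (length(active) > 1) {
    without <- vapply(seq_along(active), function(i) {
      fit_cosine(column, signatures[, active[-i], drop = FALSE])
    }, numeric(1))
    i <- which.max(without)
    if (current - without[i] < prune_delta) {
      active <- active[-i]
      current <- without[i]
    } else {
      break
    }
  }
  w <- fit_weights(column, signatures[, active, drop = FALSE],
                   normalize = FALSE)
  if (sum(w) == 0) {
    warning("no signature survived pruning; keeping best single signature")
    single <- vapply(seq_len(K), function(j) {
      cosine_similarity(column, signatures[, j])
    }, numeric(1))
    active <- which.max(single)
    w <- stats::setNames(1, colnames(signatures)[active])
  }
  act <- stats::setNames(numeric(K), colnames(signatures))
  act[active] <- w / sum(w) * total
  act
}

#' Attribute signature activities across a cohort
#'
#' Column-wise [attribute_sample()]; all-zero sample columns receive zero
#' activities with a message.
#'
#' @param m Channels x samples count matrix (same schema as `signatures`).
#' @param signatures Channels x K signature matrix.
#' @param prune_delta Passed to [attribute_sample()].
#' @return K x samples activity matrix (attributed mutation counts).
#' @export
attribute_cohort <- function(m, signatures, prune_delta = 0.002) {
  signatures <- as.matrix(signatures)
  if (nrow(m) != nrow(signatures)) {
    stop("matrix and signatures use different schemas")
  }
  K <- ncol(signatures)
  out <- matrix(0, K, ncol(m),
                dimnames = list(colnames(signatures), colnames(m)))
  zero <- colSums(m) == 0
  if (any(zero)) {
    message(sum(zero), " all-zero sample(s) received zero activities")
  }
  for (j in which(!zero)) {
    out[, j] <- attribute_sample(m[, j], signatures, prune_delta)
  }
  out
}

#' Per-sample signature positivity calls
#'
#' A sample is called positive for a signature when its pruned attributed
#' activity reaches `min_mutations` (default 1, i.e. any nonzero pruned
#' activity).
#'
#' @param exposures K x samples activity matrix.
#' @param min_mutations Nonnegative activity floor.
#' @return Logical K x samples matrix with attribute `min_mutations`.
#' @export
positivity <- function(exposures, min_mutations = 1) {
  stopifnot(min_mutations >= 0)
  out <- exposures >= min_mutations
  attr(out, "min_mutations") <- min_mutations
  out
}

#' Write an activity matrix as TSV (rows = samples)
#' @param exposures K x samples matrix.
#' @param path Output path.
#' @export
write_activity_tsv <- function(exposures, path) {
  df <- data.frame(Sample = colnames(exposures), t(exposures),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
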