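#' Bootstrap a mutational catalog
#'
#' Resamples each sample column independently from a multinomial
#' distribution with `n` equal to the original column total and
#' probabilities proportional to the original column, so column sums are
#' preserved exactly. All-zero columns are copied unchanged with a warning.
#'
#' @param m Channels x samples count matrix.
#' @param seed Integer seed; the resample is a pure function of `(m, seed)`.
#' @return A resampled matrix with the same dimensions and attributes.
#' @export
bootstrap_catalog <- function(m, seed) {
  set.seed(seed)
  out <- m
  cs <- colSums(m)
  if (any(cs == 0)) warning("zero column(s) copied unchanged")
  for (j in which(cs > 0)) {
    out[, j] <- as.integer(stats::rmultinom(1, cs[j], m[, j] / cs[j]))
  }
  out
}

#' Nonnegative matrix factorization under generalized KL divergence
#'
#' Factorizes a nonnegative catalog `V ~ W H` by multiplicative updates
#' minimizing the generalized Kullback-Leibler divergence (the
#' Poisson-consistent objective for count data), from random uniform
#' initialization scaled to the matrix mass. The objective is
#' non-increasing across iterations; iteration stops when the relative
#' objective change falls below `tol` or at `max_iter`. Signature columns
#' are normalized to sum 1 with the scale moved into the exposures.
#'
#' @param m Nonnegative channels x samples matrix.
#' @param k Number of signatures (`1 <= k <= min(dim(m))`).
#' @param seed Integer seed for the random initialization(s).
#' @param max_iter,tol Stopping rule (defaults 10000 and 1e-9 relative
#'   change).
#' @param n_inits Number of random restarts; the run with the lowest
#'   final objective is kept. Multiplicative updates can stall in
#'   clearly inferior local minima from unlucky starts, and restarts
#'   selected by objective are the standard remedy.
#' @return A `factor_pair` list: `signatures` (channels x k, columns sum to
#'   1), `exposures` (k x samples), `objective`, `trace` (objective values
#'   at every check), `iterations`.
#' @export
nmf_factorize <- function(m, k, seed, max_iter = 10000, tol = 1e-9,
                          n_inits = 1) {
  m <- as.matrix(m)
  if (k < 1 || k > min(dim(m))) {
    stop("k must be between 1 and min(channels, samples)")
  }
  if (any(m < 0)) stop("matrix must be nonnegative")
  set.seed(seed)
  nr <- nrow(m); nc <- ncol(m)
  fit <- NULL
  for (i in seq_len(n_inits)) {
    W0 <- matrix(stats::runif(nr * k, min = .Machine$double.eps, max = 1),
                 nr, k)
    H0 <- matrix(stats::runif(k * nc, min = .Machine$double.eps, max = 1),
                 k, nc)
    H0 <- H0 * (sum(m) / sum(W0 %*% H0))
    cand <- nmf_kl_cpp(m, W0, H0, as.integer(max_iter), tol, 10L)
    if (is.null(fit) || cand$objective < fit$objective) fit <- cand
  }
  W <- fit$W; H <- fit$H
  scale <- colSums(W)
  scale[scale == 0] <- 1
  W <- sweep(W, 2, scale, "/")
  H <- H * scale
  dimnames(W) <- list(rownames(m), paste0("S", seq_len(k)))
  dimnames(H) <- list(paste0("S", seq_len(k)), colnames(m))
  structure(list(signatures = W, exposures = H, objective = fit$objective,
                 trace = fit$trace, iterations = fit$iterations),
            class = "factor_pair")
}

# greedy one-to-one assignment of the columns of S (k of them) to the k
# centroid columns, highest-cosine pair first; deterministic on ties
greedy_assign <- function(S, centroids) {
  k <- ncol(centroids)
  cm <- cosine_matrix(S, centroids)
  assign <- integer(k) # assign[i] = centroid index for signature i
  for (step in seq_len(k)) {
    idx <- arrayInd(which.max(cm), dim(cm))
    assign[idx[1]] <- idx[2]
    cm[idx[1], ] <- -Inf
    cm[, idx[2]] <- -Inf
  }
  assign
}

#' Consensus clustering of replicate NMF solutions
#'
#' Pools the signatures of all bootstrap replicates and partitions them
#' into `k` clusters by iterated matching under cosine distance: each
#' replicate's `k` signatures are greedily one-to-one assigned to the
#' current centroids (highest-cosine pair first), centroids are recomputed
#' as normalized means, and the procedure repeats until assignments are
#' stable. Per-cluster stability is the mean silhouette width of the
#' cluster members under cosine distance (for `k = 1`, where the
#' silhouette is undefined, the mean member-to-centroid cosine is reported
#' instead). Consensus signatures are the centroids.
#'
#' @param replicate_factors List of [nmf_factorize()] results, each of rank
#'   `k`.
#' @param k The common rank.
#' @param max_iter Cap on matching iterations.
#' @return A `consensus_solution` list: `k`, `consensus_signatures`
#'   (channels x k simplex columns), `per_signature_stability`,
#'   `replicate_count`.
#' @export
cluster_solutions <- function(replicate_factors, k, max_iter = 100) {
  R <- length(replicate_factors)
  stopifnot(R >= 1)
  for (f in replicate_factors) {
    if (ncol(f$signatures) != k) stop("all replicates must have rank k")
  }
  pool <- do.call(cbind, lapply(replicate_factors,
                                function(f) f$signatures))
  centroids <- replicate_factors[[1]]$signatures
  assign <- rep(NA_integer_, ncol(pool))
  for (iter in seq_len(max_iter)) {
    new_assign <- integer(ncol(pool))
    for (r in seq_len(R)) {
      cols <- ((r - 1) * k + 1):(r * k)
      new_assign[cols] <- greedy_assign(pool[, cols, drop = FALSE],
                                        centroids)
    }
    for (j in seq_len(k)) {
      mem <- pool[, new_assign == j, drop = FALSE]
      cen <- rowMeans(mem)
      s <- sum(cen)
      centroids[, j] <- if (s > 0) cen / s else cen
    }
    if (identical(new_assign, assign)) break
    assign <- new_assign
  }
  stability <- rep(NA_real_, k)
  if (R >= 2) {
    d <- 1 - cosine_matrix(pool, pool)
    sil <- numeric(ncol(pool))
    for (i in seq_len(ncol(pool))) {
      own <- which(assign == assign[i])
      own <- setdiff(own, i)
      if (k == 1) {
        sil[i] <- cosine_similarity(pool[, i], centroids[, 1])
        next
      }
      a <- if (length(own)) mean(d[i, own]) else 0
      b <- min(vapply(setdiff(seq_len(k), assign[i]), function(j) {
        mean(d[i, assign == j])
      }, numeric(1)))
      sil[i] <- if (length(own)) (b - a) / max(a, b) else 0
    }
    stability <- vapply(seq_len(k), function(j) mean(sil[assign == j]),
                        numeric(1))
  }
  colnames(centroids) <- paste0("DN", seq_len(k))
  structure(list(k = k, consensus_signatures = centroids,
                 per_signature_stability = stability,
                 replicate_count = R),
            class = "consensus_solution")
}

# mean over samples of cosine(column, reconstruction from signatures
# refit by nonnegative least squares)
reconstruction_cosine <- function(m, signatures) {
  vals <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    if (sum(col) == 0) return(NA_real_)
    w <- fit_weights(col, signatures, normalize = FALSE)
    rec <- signatures %*% w
    if (sum(rec) == 0) return(0)
    cosine_similarity(col, as.vector(rec))
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' De novo signature extraction with bootstrap stability
#'
#' For each candidate rank `k`, draws `n_replicates` bootstrap catalogs,
#' factorizes each by KL-NMF, and summarizes the replicates into a
#' consensus solution with per-signature stability
#' ([cluster_solutions()]). The mean reconstruction cosine of each
#' consensus is computed against the original (un-resampled) catalog by
#' nonnegative-least-squares refitting. The suggested rank is the largest
#' `k` whose minimum per-signature stability is at least `stability_floor`
#' and whose mean reconstruction cosine is at least `recon_floor`; if no
#' rank qualifies, the rank maximizing (min stability + mean reconstruction
#' cosine) is suggested with a warning.
#'
#' @param m Channels x samples count matrix (any schema; SBS-288 catalogs
#'   are factorized natively and can be collapsed afterwards for
#'   comparison).
#' @param k_range Integer vector of candidate ranks.
#' @param n_replicates Bootstrap replicates per rank (>= 2; default 30).
#' @param seed Integer seed controlling all resampling and initialization.
#' @param stability_floor,recon_floor Rank-admission thresholds (defaults
#'   0.8 and 0.95).
#' @param max_iter,tol,n_inits Passed to [nmf_factorize()]. The extraction
#'   defaults cap each replicate at 3,000 multiplicative updates (bootstrap
#'   replicates are noisy resamples, early stopping regularizes the weak
#'   components, and recovery quality on validation cohorts is unchanged
#'   relative to much larger caps) and take the best of 3 random restarts
#'   per replicate, which removes the occasional clearly inferior local
#'   minimum that would otherwise depress consensus stability.
#' @return An `extraction_result` list: `solutions` (one
#'   `consensus_solution` per rank, each with `mean_reconstruction_cosine`
#'   filled in), `suggested_k`, `seed`.
#' @export
extract_signatures <- function(m, k_range, n_replicates = 30, seed = 1,
                               stability_floor = 0.8, recon_floor = 0.95,
                               max_iter = 3000, tol = 1e-9, n_inits = 3) {
  stopifnot(length(k_range) >= 1, n_replicates >= 2)
  cs <- colSums(m)
  if (any(cs == 0)) {
    warning("dropping ", sum(cs == 0), " all-zero sample column(s)")
    m <- m[, cs > 0, drop = FALSE]
  }
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1,
                             2 * length(k_range) * n_replicates),
                  nrow = 2)
  solutions <- list()
  idx <- 0
  for (k in k_range) {
    reps <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      idx <- idx + 1
      b <- bootstrap_catalog(m, seeds[1, idx])
      reps[[r]] <- nmf_factorize(b, k, seeds[2, idx],
                                 max_iter = max_iter, tol = tol,
                                 n_inits = n_inits)
    }
    sol <- cluster_solutions(reps, k)
    sol$mean_reconstruction_cosine <-
      reconstruction_cosine(m, sol$consensus_signatures)
    solutions[[as.character(k)]] <- sol
  }
  min_stab <- vapply(solutions, function(s) {
    if (all(is.na(s$per_signature_stability))) -Inf
    else min(s$per_signature_stability)
  }, numeric(1))
  recon <- vapply(solutions, function(s) s$mean_reconstruction_cosine,
                  numeric(1))
  ok <- min_stab >= stability_floor & recon >= recon_floor
  if (any(ok)) {
    suggested_k <- max(k_range[ok])
  } else {
    warning("no rank met the stability/reconstruction rule; ",
            "suggesting the best compromise rank")
    suggested_k <- k_range[which.max(min_stab + recon)]
  }
  structure(list(solutions = solutions, suggested_k = suggested_k,
                 seed = seed, k_range = k_range,
                 min_stability = min_stab,
                 mean_reconstruction_cosine = recon),
            class = "extraction_result")
}

#' @export
print.extraction_result <- function(x, ...) {
  cat("<extraction_result> ranks", paste(x$k_range, collapse = ","),
      "| suggested k =", x$suggested_k, "\n")
  for (k in names(x$solutions)) {
    s <- x$solutions[[k]]
    cat(sprintf("  k=%s  min stability %.3f  mean recon cosine %.4f\n",
                k, min(s$per_signature_stability),
                s$mean_reconstruction_cosine))
  }
  invisible(x)
}
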