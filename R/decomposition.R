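REFERENCE_SUBGROUPS <- c("artifact", "ultraviolet", "lymphoid",
                         "mismatch_repair_deficiency",
                         "polymerase_deficiency",
                         "base_excision_repair_deficiency",
                         "treatment", "clock_like", "none")

#' Construct a tagged reference signature catalog
#'
#' A reference catalog is a set of SBS-96 signature profiles together with
#' per-signature subgroup tags (e.g. `artifact`, `treatment`,
#' `mismatch_repair_deficiency`) used by the optimized decomposition mode
#' to exclude biologically implausible references.
#'
#' @param signatures 96 x R matrix of column-simplex profiles with unique
#'   column names.
#' @param tags Named list (one entry per signature) of character vectors
#'   drawn from the supported subgroup vocabulary; missing entries get
#'   `"none"`.
#' @return A `reference_catalog` list with elements `signatures`, `tags`.
#' @export
reference_catalog <- function(signatures, tags = NULL) {
  signatures <- as.matrix(signatures)
  if (is.null(colnames(signatures)) ||
      anyDuplicated(colnames(signatures))) {
    stop("signatures must have unique column names")
  }
  if (is.null(tags)) tags <- list()
  full <- stats::setNames(vector("list", ncol(signatures)),
                          colnames(signatures))
  for (nm in colnames(signatures)) {
    tg <- tags[[nm]]
    if (is.null(tg) || !length(tg)) tg <- "none"
    bad <- setdiff(tg, REFERENCE_SUBGROUPS)
    if (length(bad)) stop("unknown subgroup tag(s): ",
                          paste(bad, collapse = ", "))
    full[[nm]] <- tg
  }
  structure(list(signatures = normalize_cols(signatures), tags = full),
            class = "reference_catalog")
}

#' Read a reference catalog from TSV files
#'
#' @param signatures_path Matrix TSV (`MutationType` column + one column
#'   per reference).
#' @param tags_path Optional two-column TSV (`signature`, `tags` with
#'   comma-separated subgroup tags).
#' @return A [reference_catalog()].
#' @export
read_reference_catalog <- function(signatures_path, tags_path = NULL) {
  sigs <- read_matrix_tsv(signatures_path)
  tags <- NULL
  if (!is.null(tags_path)) {
    tdf <- utils::read.delim(tags_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    tags <- stats::setNames(
      lapply(strsplit(tdf$tags, ","), trimws), tdf$signature)
  }
  reference_catalog(sigs, tags)
}

#' Nonnegative least-squares weights of a target onto references
#'
#' @param target Nonnegative 96-vector (typically a signature simplex).
#' @param refs Matrix of reference profiles (one per column).
#' @param normalize Renormalize the weights to sum 1 (default).
#' @return Named weight vector (one entry per reference).
#' @export
fit_weights <- function(target, refs, normalize = TRUE) {
  refs <- as.matrix(refs)
  if (ncol(refs) < 1) stop("reference set is empty")
  if (sum(target) == 0) stop("all-zero target")
  w <- pracma::lsqnonneg(refs, as.vector(target))$x
  if (normalize) {
    s <- sum(w)
    if (s > 0) w <- w / s
  }
  stats::setNames(w, colnames(refs))
}

fit_cosine <- function(target, refs) {
  w <- fit_weights(target, refs, normalize = FALSE)
  rec <- as.vector(as.matrix(refs) %*% w)
  if (sum(rec) == 0) return(0)
  cosine_similarity(target, rec)
}

#' Decompose a de novo signature into reference signatures
#'
#' Expresses a target SBS-96 profile as a nonnegative mixture of reference
#' signatures by greedy forward selection: starting from the single
#' best-cosine reference, the candidate giving the largest increase in
#' nonnegative-least-squares reconstruction cosine is added while the
#' increase is at least `add_threshold`; a single removal pass then drops
#' any selected reference whose removal costs less than `add_threshold` of
#' reconstruction cosine. In `optimized` mode, references carrying any
#' excluded subgroup tag are removed from the candidate set before
#' selection (mirroring decompositions that exclude e.g. treatment or
#' repair-deficiency signatures in cohorts where those processes are
#' implausible); `naive` mode uses the full catalog. A target whose final
#' reconstruction cosine falls below `novelty_threshold` is flagged as
#' novel, i.e. not explicable by the known references.
#'
#' @param target SBS-96 simplex (96-vector).
#' @param catalog A [reference_catalog()].
#' @param mode `"naive"` or `"optimized"`.
#' @param excluded_subgroups Character vector of tags to exclude (required
#'   non-empty in optimized mode).
#' @param add_threshold Minimum reconstruction-cosine gain to add (and
#'   cost to keep) a reference; default 0.01.
#' @param novelty_threshold Reconstruction cosine below which the target
#'   is called novel; default 0.90.
#' @return A `decomposition_result` list: `weights` (all references; zero
#'   off-selection, selected weights sum to 1), `reconstruction_cosine`,
#'   `novel`, `mode`, `excluded_subgroups`, `selected`.
#' @export
decompose_signature <- function(target, catalog,
                                mode = c("optimized", "naive"),
                                excluded_subgroups = character(),
                                add_threshold = 0.01,
                                novelty_threshold = 0.90) {
  mode <- match.arg(mode)
  stopifnot(inherits(catalog, "reference_catalog"))
  if (mode == "optimized" && !length(excluded_subgroups)) {
    stop("optimized mode requires a non-empty excluded_subgroups set")
  }
  if (mode == "naive") excluded_subgroups <- character()
  keep <- vapply(catalog$tags, function(tg) {
    !any(tg %in% excluded_subgroups)
  }, logical(1))
  if (!any(keep)) {
    stop("no candidate references remain after excluding subgroups: ",
         paste(excluded_subgroups, collapse = ", "))
  }
  refs <- catalog$signatures[, keep, drop = FALSE]
  target <- as.vector(target)

  single <- vapply(seq_len(ncol(refs)), function(j) {
    cosine_similarity(target, refs[, j])
  }, numeric(1))
  selected <- colnames(refs)[which.max(single)]
  current <- max(single)
  remaining <- setdiff(colnames(refs), selected)
  # forward selection
  while (length(remaining)) {
    gains <- vapply(remaining, function(nm) {
      fit_cosine(target, refs[, c(selected, nm), drop = FALSE]) - current
    }, numeric(1))
    if (max(gains) < add_threshold) break
    best <- remaining[which.max(gains)]
    selected <- c(selected, best)
    current <- current + max(gains)
    remaining <- setdiff(remaining, best)
  }
  # one removal pass, least-weighted first
  if (length(selected) > 1) {
    w0 <- fit_weights(target, refs[, selected, drop = FALSE])
    for (nm in names(sort(w0))) {
      if (length(selected) == 1) break
      rest <- setdiff(selected, nm)
      without <- fit_cosine(target, refs[, rest, drop = FALSE])
      if (current - without < add_threshold) {
        selected <- rest
        current <- without
      }
    }
  }
  wsel <- fit_weights(target, refs[, selected, drop = FALSE])
  recon <- fit_cosine(target, refs[, selected, drop = FALSE])
  weights <- stats::setNames(numeric(ncol(catalog$signatures)),
                             colnames(catalog$signatures))
  weights[names(wsel)] <- wsel
  structure(list(weights = weights, reconstruction_cosine = recon,
                 novel = recon < novelty_threshold, mode = mode,
                 excluded_subgroups = excluded_subgroups,
                 selected = selected),
            class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat("<decomposition_result>", x$mode, "mode; reconstruction cosine",
      sprintf("%.4f", x$reconstruction_cosine),
      if (x$novel) "(novel)" else "", "\n")
  w <- x$weights[x$weights > 0]
  for (nm in names(sort(w, decreasing = TRUE))) {
    cat(sprintf("  %s  %.1f%%\n", nm, 100 * w[nm]))
  }
  invisible(x)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
  }))
}

#' Optimal one-to-one matching between two signature sets
#'
#' Finds the one-to-one pairing of signatures maximizing total cosine
#' similarity. Sets on different schemas are collapsed to SBS-96 first.
#' The assignment is exact (exhaustive) when both sets have at most 8
#' signatures, and a deterministic greedy best-pair-first approximation
#' beyond that.
#'
#' @param setA,setB Channel x signature matrices.
#' @return A data.frame with columns `a`, `b` (column names) and `cosine`,
#'   one row per matched pair (`min(ncol(A), ncol(B))` rows).
#' @export
match_signatures <- function(setA, setB) {
  if (nrow(setA) != nrow(setB)) {
    setA <- collapse_matrix(setA)
    setB <- collapse_matrix(setB)
  }
  swap <- ncol(setA) > ncol(setB)
  if (swap) { tmp <- setA; setA <- setB; setB <- tmp }
  nA <- ncol(setA); nB <- ncol(setB)
  cm <- cosine_matrix(setA, setB)
  if (nB <= 8) {
    perms <- permutations_of(nB)
    scores <- apply(perms, 1, function(p) {
      sum(cm[cbind(seq_len(nA), p[seq_len(nA)])])
    })
    p <- perms[which.max(scores), ][seq_len(nA)]
    pairs <- data.frame(a = colnames(setA), b = colnames(setB)[p],
                        cosine = cm[cbind(seq_len(nA), p)],
                        stringsAsFactors = FALSE)
  } else {
    work <- cm
    pairs <- NULL
    for (i in seq_len(nA)) {
      idx <- arrayInd(which.max(work), dim(work))
      pairs <- rbind(pairs, data.frame(
        a = colnames(setA)[idx[1]], b = colnames(setB)[idx[2]],
        cosine = cm[idx[1], idx[2]], stringsAsFactors = FALSE))
      work[idx[1], ] <- -Inf
      work[, idx[2]] <- -Inf
    }
    pairs <- pairs[order(match(pairs$a, colnames(setA))), ]
  }
  if (swap) {
    pairs <- data.frame(a = pairs$b, b = pairs$a, cosine = pairs$cosine,
                        stringsAsFactors = FALSE)
  }
  rownames(pairs) <- NULL
  pairs
}
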