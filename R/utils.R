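#' Cosine similarity between two nonnegative vectors
#'
#' The package-wide comparison metric for mutational profiles:
#' `dot(a, b) / (||a|| ||b||)`. Errors on zero vectors.
#'
#' @param a,b Numeric vectors of equal length.
#' @return A scalar in `[0, 1]` for nonnegative inputs.
#' @examples
#' cosine_similarity(c(1, 1, 0), c(1, 0, 0)) # 1/sqrt(2)
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero vector")
  sum(a * b) / (na * nb)
}

# all pairwise cosines between columns of A and columns of B
cosine_matrix <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  An <- sqrt(colSums(A^2)); Bn <- sqrt(colSums(B^2))
  crossprod(A, B) / outer(An, Bn)
}

# columns normalized to sum 1
normalize_cols <- function(m) {
  s <- colSums(m)
  s[s == 0] <- 1
  sweep(m, 2, s, "/")
}

#' Spearman rank correlation with average-rank ties
#'
#' @param a,b Numeric vectors (length >= 3).
#' @return Spearman's rho, or `NA` (with a message) when either vector is
#'   constant.
#' @export
rank_correlation <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3) {
    stop("need two equal-length vectors of length >= 3")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    message("rank correlation undefined for constant vector")
    return(NA_real_)
  }
  stats::cor(a, b, method = "spearman")
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()]).
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "BH")
}
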