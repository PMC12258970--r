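#' Compare two signatures within one substitution-type block
#'
#' Extracts the 16 trinucleotide channels of the given substitution type
#' from each SBS-96 profile, renormalizes each slice to sum 1, and reports
#' cosine similarity and Spearman correlation between the slices. Used to
#' ask whether two signatures that look similar overall differ inside the
#' block that dominates them (e.g. the C>A component).
#'
#' @param sigA,sigB SBS-96 profiles (96-vectors in canonical channel
#'   order, or named by channel label).
#' @param substitution_type One of `"C>A"`, `"C>G"`, `"C>T"`, `"T>A"`,
#'   `"T>C"`, `"T>G"`.
#' @return A `subcontext_comparison` list: `substitution_type`, `cosine`,
#'   `spearman_rho`, `sliceA`, `sliceB`.
#' @export
compare_subcontext <- function(sigA, sigB, substitution_type) {
  substitution_type <- match.arg(substitution_type, SUB_TYPES)
  labels <- sbs96_labels()
  sigA <- as.vector(sigA); sigB <- as.vector(sigB)
  if (length(sigA) != 96 || length(sigB) != 96) {
    stop("inputs must be SBS-96 profiles")
  }
  idx <- grepl(paste0("[", substitution_type, "]"), labels, fixed = TRUE)
  a <- sigA[idx]; b <- sigB[idx]
  if (sum(a) == 0 || sum(b) == 0) {
    stop("zero mass in the ", substitution_type, " slice")
  }
  a <- a / sum(a); b <- b / sum(b)
  structure(list(substitution_type = substitution_type,
                 cosine = cosine_similarity(a, b),
                 spearman_rho = rank_correlation(a, b),
                 sliceA = stats::setNames(a, labels[idx]),
                 sliceB = stats::setNames(b, labels[idx])),
            class = "subcontext_comparison")
}

#' Covariate-adjusted burden association with signature status
#'
#' Fits a log-linear normal model `log(burden) ~ status + covariates` and
#' reports the status coefficient as a fold change (`exp(coefficient)`)
#' with its normal-theory p-value. The log-normal family is the default
#' reading of a generalized linear model for strictly positive burden
#' counts; categorical covariates are expanded to treatment-coded
#' indicators by the model matrix. Covariates dropped as collinear are
#' reported with a warning.
#'
#' @param status Logical (or 0/1) vector: signature-positive indicator.
#' @param burden Strictly positive response (e.g. per-sample indel count).
#' @param covariates Optional data.frame of adjustment columns.
#' @param response_name Label carried into the result.
#' @return An `association_result` list: `response_name`, `fold_change`,
#'   `coefficient` (log scale), `p_value`, `n`, `covariate_names`.
#' @export
burden_association <- function(status, burden, covariates = NULL,
                               response_name = "burden") {
  status <- as.logical(status)
  stopifnot(length(status) == length(burden))
  if (any(burden <= 0)) stop("burdens must be strictly positive")
  df <- data.frame(.logb = log(burden), .status = status)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(burden))
    df <- cbind(df, covariates)
  }
  if (nrow(df) <= ncol(df) + 2) stop("too few samples for the model")
  fit <- stats::lm(.logb ~ ., data = df)
  cf <- summary(fit)$coefficients
  dropped <- setdiff(names(stats::coef(fit)), rownames(cf))
  if (length(dropped)) {
    warning("collinear term(s) dropped: ", paste(dropped, collapse = ", "))
  }
  est <- cf[".statusTRUE", "Estimate"]
  p <- cf[".statusTRUE", "Pr(>|t|)"]
  structure(list(response_name = response_name,
                 fold_change = exp(est), coefficient = est, p_value = p,
                 n = nrow(df),
                 covariate_names = if (is.null(covariates)) character()
                                   else names(covariates)),
            class = "association_result")
}

#' Batch burden associations with Benjamini-Hochberg q-values
#'
#' Runs [burden_association()] for each named response and adjusts the
#' batch of p-values by [bh_adjust()].
#'
#' @param status Positivity indicator shared by all responses.
#' @param burdens Named list of positive response vectors.
#' @param covariates Optional shared covariate data.frame.
#' @return data.frame with one row per response: `response`,
#'   `fold_change`, `coefficient`, `p_value`, `q_value`, `n`.
#' @export
associate_burdens <- function(status, burdens, covariates = NULL) {
  res <- lapply(names(burdens), function(nm) {
    burden_association(status, burdens[[nm]], covariates, nm)
  })
  out <- data.frame(
    response = vapply(res, `[[`, character(1), "response_name"),
    fold_change = vapply(res, `[[`, numeric(1), "fold_change"),
    coefficient = vapply(res, `[[`, numeric(1), "coefficient"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    n = vapply(res, `[[`, numeric(1), "n"),
    stringsAsFactors = FALSE)
  out$q_value <- bh_adjust(out$p_value)
  out[, c("response", "fold_change", "coefficient", "p_value",
          "q_value", "n")]
}
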