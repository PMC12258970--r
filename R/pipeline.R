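# ---- thin command-line pipeline over the package functions ----

parse_flags <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      out[[key]] <- TRUE
      i <- i + 1
    } else {
      out[[key]] <- args[i + 1]
      i <- i + 2
    }
  }
  out
}

flag <- function(flags, name, default = NULL, required = FALSE) {
  v <- flags[[name]]
  if (is.null(v)) {
    if (required) stop("missing required flag --", name)
    return(default)
  }
  v
}

cli_simulate <- function(flags) {
  seed <- as.integer(flag(flags, "seed", 1))
  n <- as.integer(flag(flags, "n-samples", 300))
  cfgpath <- flag(flags, "config")
  outdir <- flag(flags, "outdir", required = TRUE)
  extra <- list()
  if (!is.null(cfgpath)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("--config requires the yaml package")
    }
    extra <- yaml::read_yaml(cfgpath)
  }
  extra$seed <- seed
  if (is.null(extra$n_samples)) extra$n_samples <- n
  scenario <- do.call(cohort_scenario, extra)
  cohort <- simulate_cohort(scenario)
  cohort <- spike_hypermutators(cohort)
  cohort <- simulate_timing(cohort)
  indels <- simulate_indel_burden(cohort)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(cohort$matrix, file.path(outdir, "catalog.tsv"))
  write_matrix_tsv(cohort$true_exposures,
                   file.path(outdir, "truth_exposures.tsv"))
  write_matrix_tsv(cohort$signatures,
                   file.path(outdir, "truth_signatures.tsv"))
  utils::write.table(
    data.frame(sample = names(indels), indels = indels),
    file.path(outdir, "indel_burdens.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_mutation_table(cohort$records, file.path(outdir, "records.tsv"))
  utils::write.table(
    data.frame(sample = cohort$records$sample,
               signature_truth = cohort$records$signature_truth,
               timing_truth = cohort$records$timing_truth),
    file.path(outdir, "records_truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(outdir)
}

cli_matrix <- function(flags) {
  recs <- read_mutation_table(flag(flags, "input", required = TRUE))
  schema <- sbs_schema(flag(flags, "schema", "SBS96"))
  m <- build_matrix(recs, schema)
  write_matrix_tsv(m, flag(flags, "out", required = TRUE))
}

cli_qc <- function(flags) {
  m <- read_matrix_tsv(flag(flags, "matrix", required = TRUE))
  ind <- NULL
  ipath <- flag(flags, "indels")
  if (!is.null(ipath)) {
    idf <- utils::read.delim(ipath, sep = "\t")
    ind <- stats::setNames(idf$indels, idf$sample)
  }
  fs <- flag(flags, "flags")
  th <- qc_thresholds(
    max_sbs = as.numeric(flag(flags, "max-sbs", 100000)),
    max_indels = as.numeric(flag(flags, "max-indels", 7000)),
    min_sbs = as.numeric(flag(flags, "min-sbs", 1000)),
    flag_cosine = as.numeric(flag(flags, "flag-cosine", 0.80)),
    flag_signatures = if (is.null(fs)) NULL else read_matrix_tsv(fs))
  rep <- qc_filter(m, ind, th)
  utils::write.table(rep$report, flag(flags, "out", required = TRUE),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  retained <- flag(flags, "retained-matrix")
  if (!is.null(retained)) {
    write_matrix_tsv(m[, rep$retained_samples, drop = FALSE], retained)
  }
}

cli_extract <- function(flags) {
  m <- read_matrix_tsv(flag(flags, "matrix", required = TRUE))
  ks <- as.integer(flag(flags, "kmin", 2)):as.integer(flag(flags, "kmax", 6))
  res <- extract_signatures(
    m, ks,
    n_replicates = as.integer(flag(flags, "replicates", 30)),
    seed = as.integer(flag(flags, "seed", 1)))
  outdir <- flag(flags, "outdir", required = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (k in names(res$solutions)) {
    write_matrix_tsv(res$solutions[[k]]$consensus_signatures,
                     file.path(outdir, paste0("signatures_k", k, ".tsv")))
  }
  metrics <- data.frame(
    k = res$k_range, min_stability = res$min_stability,
    mean_reconstruction_cosine = res$mean_reconstruction_cosine,
    suggested = res$k_range == res$suggested_k)
  utils::write.table(metrics, file.path(outdir, "rank_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(paste0("suggested_k\t", res$suggested_k),
               paste0("seed\t", res$seed)),
             file.path(outdir, "run_summary.tsv"))
}

cli_decompose <- function(flags) {
  targets <- read_matrix_tsv(flag(flags, "signatures", required = TRUE))
  catalog <- read_reference_catalog(flag(flags, "refs", required = TRUE),
                                    flag(flags, "tags"))
  mode <- flag(flags, "mode", "naive")
  excl <- flag(flags, "exclude", "")
  excl <- if (nzchar(excl)) strsplit(excl, ",")[[1]] else character()
  rows <- list()
  for (j in seq_len(ncol(targets))) {
    d <- decompose_signature(collapse_matrix(targets)[, j], catalog,
                             mode = mode, excluded_subgroups = excl)
    w <- d$weights[d$weights > 0]
    rows[[j]] <- data.frame(
      target = colnames(targets)[j], mode = d$mode,
      reference = names(w), weight_percent = 100 * unname(w),
      reconstruction_cosine = d$reconstruction_cosine, novel = d$novel)
  }
  utils::write.table(do.call(rbind, rows),
                     flag(flags, "out", required = TRUE),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

cli_attribute <- function(flags) {
  m <- read_matrix_tsv(flag(flags, "matrix", required = TRUE))
  sigs <- read_matrix_tsv(flag(flags, "signatures", required = TRUE))
  expo <- attribute_cohort(m, sigs,
    prune_delta = as.numeric(flag(flags, "prune-delta", 0.002)))
  write_activity_tsv(expo, flag(flags, "out", required = TRUE))
}

cli_timing <- function(flags) {
  recs <- read_mutation_table(flag(flags, "records", required = TRUE))
  sigs <- read_matrix_tsv(flag(flags, "signatures", required = TRUE))
  cfg <- timing_config(
    ccf_clonal_threshold = as.numeric(flag(flags, "ccf-threshold", 0.95)),
    min_per_phase = as.integer(flag(flags, "min-per-phase", 256)))
  timed <- split_catalogs(recs, cfg)
  phases <- phase_attribution(timed, sigs)
  pe <- positivity(phases$early); pl <- positivity(phases$late)
  rows <- lapply(rownames(pe), function(s) {
    ct <- timing_contrast(pe[s, ], pl[s, ])
    data.frame(signature = s, early_only = ct$n_early_only,
               late_only = ct$n_late_only, both = ct$n_both,
               neither = ct$n_neither, p_value = ct$p_value,
               method = ct$method)
  })
  utils::write.table(do.call(rbind, rows),
                     flag(flags, "out", required = TRUE),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

cli_associate <- function(flags) {
  act <- utils::read.delim(flag(flags, "activity", required = TRUE),
                           check.names = FALSE)
  sig <- flag(flags, "signature", required = TRUE)
  bdf <- utils::read.delim(flag(flags, "burdens", required = TRUE),
                           check.names = FALSE)
  stopifnot(all(act$Sample == bdf$sample) || all(act$Sample %in% bdf$sample))
  bdf <- bdf[match(act$Sample, bdf$sample), , drop = FALSE]
  status <- act[[sig]] >= as.numeric(flag(flags, "min-mutations", 1))
  burdens <- as.list(bdf[, setdiff(names(bdf), "sample"), drop = FALSE])
  res <- associate_burdens(status, burdens)
  utils::write.table(res, flag(flags, "out", required = TRUE),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

cli_compare <- function(flags) {
  A <- read_matrix_tsv(flag(flags, "first", required = TRUE))
  B <- read_matrix_tsv(flag(flags, "second", required = TRUE))
  pairs <- match_signatures(A, B)
  utils::write.table(pairs, flag(flags, "out", required = TRUE),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Command-line pipeline dispatcher
#'
#' Implements the shell interface used by `inst/scripts/sigstratum-cli.R`:
#' subcommands `simulate`, `matrix`, `qc`, `extract`, `decompose`,
#' `attribute`, `timing`, `associate` and `compare`, each a thin wrapper
#' over the corresponding package functions reading and writing the
#' package's TSV formats. Every stochastic stage takes an explicit
#' `--seed`, so outputs are a pure function of (inputs, flags, seed).
#'
#' @param argv Character vector: subcommand followed by `--flag value`
#'   pairs.
#' @return Invisibly `0`; errors propagate as conditions (the script
#'   wrapper maps them to exit codes: 2 for usage errors, 1 otherwise).
#' @export
sigstratum_cli <- function(argv) {
  if (!length(argv)) {
    stop(structure(class = c("usage_error", "error", "condition"),
      list(message = paste(
        "usage: sigstratum-cli.R",
        "<simulate|matrix|qc|extract|decompose|attribute|timing|associate|compare>",
        "[--flag value ...]"), call = NULL)))
  }
  cmd <- argv[1]
  flags <- parse_flags(argv[-1])
  handler <- switch(cmd,
    simulate = cli_simulate, matrix = cli_matrix, qc = cli_qc,
    extract = cli_extract, decompose = cli_decompose,
    attribute = cli_attribute, timing = cli_timing,
    associate = cli_associate, compare = cli_compare,
    stop(structure(class = c("usage_error", "error", "condition"),
      list(message = paste0("unknown subcommand: ", cmd), call = NULL))))
  handler(flags)
  invisible(0)
}
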