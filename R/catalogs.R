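RECORD_COLS <- c("sample", "chrom", "pos", "ref", "alt", "pentacontext",
                 "strand_status", "ccf", "multiplicity", "major_cn",
                 "minor_cn")

#' Construct a validated table of somatic substitution records
#'
#' The package-wide mutation record container is a plain `data.frame` with
#' columns `sample`, `chrom`, `pos` (1-based), `ref`, `alt`, `pentacontext`
#' (5-base reference-strand context centered on the mutated base),
#' `strand_status`, and optional clonality/copy-number annotations `ccf`,
#' `multiplicity`, `major_cn`, `minor_cn`. This constructor fills missing
#' optional columns with `NA` and enforces the record invariants: the
#' reference base equals the context center, `ref != alt`, and
#' `minor_cn <= major_cn` where both are present.
#'
#' @param df A data.frame with at least the required columns.
#' @param validate Reject invalid rows (default) rather than erroring.
#' @return A `data.frame` of records; attribute `rejected` tabulates the
#'   number of dropped rows per reason.
#' @export
mutation_records <- function(df, validate = TRUE) {
  req <- c("sample", "chrom", "pos", "ref", "alt", "pentacontext")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  if (!"strand_status" %in% names(df)) df$strand_status <- "non_transcribed"
  for (cc in c("ccf", "multiplicity", "major_cn", "minor_cn")) {
    if (!cc %in% names(df)) df[[cc]] <- NA_real_
  }
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))
  df$pentacontext <- toupper(as.character(df$pentacontext))
  df$sample <- as.character(df$sample)
  df$pos <- as.integer(df$pos)
  rejected <- integer(0)
  if (validate) {
    bad_ctx <- is.na(df$pentacontext) | nchar(df$pentacontext) != 5L |
      substr(df$pentacontext, 3L, 3L) != df$ref
    bad_ctx[is.na(bad_ctx)] <- TRUE
    bad_allele <- !(df$ref %in% BASES) | !(df$alt %in% BASES) |
      df$ref == df$alt
    bad_cn <- !is.na(df$major_cn) & !is.na(df$minor_cn) &
      df$minor_cn > df$major_cn
    bad <- bad_ctx | bad_allele | bad_cn
    rejected <- c(context_ref_mismatch = sum(bad_ctx & !bad_allele),
                  invalid_alleles = sum(bad_allele),
                  minor_exceeds_major = sum(bad_cn & !bad_ctx & !bad_allele))
    df <- df[!bad, , drop = FALSE]
  }
  extra <- setdiff(names(df), RECORD_COLS)
  df <- df[, c(RECORD_COLS, extra), drop = FALSE]
  rownames(df) <- NULL
  attr(df, "rejected") <- rejected
  df
}

#' Read somatic substitutions from the package TSV dialect
#'
#' Expects a tab-separated file with header columns `sample`, `chrom`,
#' `pos`, `ref`, `alt`, `pentacontext`, `strand_status` and optionally
#' `ccf`, `multiplicity`, `major_cn`, `minor_cn` (empty = absent).
#' Malformed rows are dropped and counted.
#'
#' @param path Path to a TSV file.
#' @return Validated records as from [mutation_records()].
#' @export
read_mutation_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (cc in c("pos", "multiplicity", "major_cn", "minor_cn")) {
    if (cc %in% names(df)) df[[cc]] <- suppressWarnings(as.integer(df[[cc]]))
  }
  if ("ccf" %in% names(df)) {
    df$ccf <- suppressWarnings(as.numeric(df$ccf))
  }
  recs <- mutation_records(df)
  rej <- attr(recs, "rejected")
  if (length(rej) && sum(rej) > 0) {
    message(sum(rej), " malformed record(s) rejected while reading ", path)
  }
  recs
}

#' Write records in the package TSV dialect
#' @param records A record data.frame.
#' @param path Output path.
#' @export
write_mutation_table <- function(records, path) {
  utils::write.table(records[, RECORD_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a minimal VCF subset as mutation records
#'
#' Reads CHROM/POS/REF/ALT from a VCF, keeping `FILTER == PASS` (or `.`)
#' single-base substitution rows only. Multi-allelic ALT fields are split
#' into one record per alternate allele; indels and MNVs are skipped with a
#' counted reason. Pentanucleotide context is left empty and must be filled
#' with [annotate_context()].
#'
#' @param path Path to an (uncompressed) VCF file.
#' @param sample_id Sample to assign to all records.
#' @return Records (unvalidated contexts) plus a `skipped` attribute.
#' @export
read_mutation_vcf <- function(path, sample_id) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  skipped <- c(non_pass = 0L, not_snv = 0L)
  if (!length(lines)) {
    return(mutation_records(data.frame(sample = character(),
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), pentacontext = character()), validate = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  rows <- lapply(fields, function(f) {
    filt <- if (length(f) >= 7) f[7] else "PASS"
    if (!filt %in% c("PASS", ".")) {
      skipped["non_pass"] <<- skipped["non_pass"] + 1L
      return(NULL)
    }
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    keep <- nchar(f[4]) == 1L & nchar(alts) == 1L & alts %in% BASES &
      f[4] %in% BASES
    skipped["not_snv"] <<- skipped["not_snv"] + sum(!keep)
    if (!any(keep)) return(NULL)
    data.frame(sample = sample_id, chrom = f[1], pos = as.integer(f[2]),
               ref = f[4], alt = alts[keep], pentacontext = NA_character_,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(sample = character(), chrom = character(),
                     pos = integer(), ref = character(), alt = character(),
                     pentacontext = character())
  }
  recs <- mutation_records(df, validate = FALSE)
  attr(recs, "skipped") <- skipped
  recs
}

#' Fill pentanucleotide contexts from a reference FASTA
#'
#' Slices the uppercase reference sequence at `[pos - 2, pos + 2]` for each
#' record. Records within two bases of a contig edge, on a missing contig,
#' or whose existing `pentacontext` disagrees with the reference are
#' rejected with a counted reason. Soft-masked (lowercase) bases are
#' uppercased before comparison. Requires the `Biostrings` package.
#'
#' @param records A record data.frame.
#' @param genome_fasta Path to a FASTA file containing all referenced
#'   contigs.
#' @return Records with `pentacontext` filled; attribute `rejected` counts
#'   dropped rows per reason.
#' @export
annotate_context <- function(records, genome_fasta) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("annotate_context requires the Biostrings package")
  }
  genome <- Biostrings::readDNAStringSet(genome_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  known <- records$chrom %in% names(genome)
  inb <- known & records$pos >= 3L &
    records$pos <= (lens[records$chrom] - 2L)
  ctx <- rep(NA_character_, nrow(records))
  if (any(inb)) {
    ctx[inb] <- toupper(as.character(Biostrings::subseq(
      genome[records$chrom[inb]],
      start = records$pos[inb] - 2L, end = records$pos[inb] + 2L)))
  }
  had <- !is.na(records$pentacontext) & nzchar(records$pentacontext)
  disagree <- had & !is.na(ctx) & toupper(records$pentacontext) != ctx
  rejected <- c(missing_contig = sum(!known),
                contig_edge = sum(known & !inb),
                context_disagrees = sum(disagree))
  keep <- inb & !disagree
  records$pentacontext <- ctx
  out <- mutation_records(records[keep, , drop = FALSE])
  attr(out, "rejected") <- c(rejected, attr(out, "rejected"))
  out
}

#' Build a channels-by-samples mutational matrix
#'
#' Classifies each record under the given schema and aggregates counts per
#' (channel, sample). Samples with no classifiable record appear as
#' all-zero columns. Rejected records (ambiguous context bases etc.) are
#' excluded and tabulated in the `rejected` attribute, so the matrix total
#' equals the number of accepted records.
#'
#' @param records A record data.frame (may have zero rows if `samples` is
#'   given).
#' @param schema An [sbs_schema()].
#' @param samples Optional explicit ordered sample set; defaults to the
#'   samples present in `records`.
#' @return Integer matrix (channels x samples) with channel-label rownames,
#'   sample colnames, and attributes `schema` and `rejected`.
#' @export
build_matrix <- function(records, schema = sbs_schema("SBS96"),
                         samples = NULL) {
  if (is.null(samples)) samples <- unique(records$sample)
  if (nrow(records) == 0 && is.null(samples)) {
    stop("empty record set and no explicit sample list")
  }
  labels <- schema$channel_labels
  if (nrow(records) > 0) {
    ch <- classify_sbs(records$ref, records$alt, records$pentacontext,
                       records$strand_status, schema)
    keep <- !is.na(ch)
    counts <- table(factor(ch[keep], levels = labels),
                    factor(records$sample[keep], levels = samples))
    m <- matrix(as.integer(counts), nrow = length(labels),
                dimnames = list(labels, samples))
    rej <- attr(ch, "reasons")
  } else {
    m <- matrix(0L, nrow = length(labels), ncol = length(samples),
                dimnames = list(labels, samples))
    rej <- table(character(0))
  }
  attr(m, "schema") <- schema$name
  attr(m, "rejected") <- rej
  m
}

matrix_schema <- function(m) {
  sc <- attr(m, "schema")
  if (!is.null(sc)) return(sc)
  switch(as.character(nrow(m)), "96" = "SBS96", "288" = "SBS288",
         "1536" = "SBS1536",
         stop("cannot infer schema from ", nrow(m), " rows"))
}

#' Collapse an SBS-288 or SBS-1536 matrix to SBS-96
#'
#' Sums counts over transcriptional strand categories (SBS-288) or the
#' outer pentanucleotide flanks (SBS-1536). Column totals are preserved
#' exactly; an SBS-96 input is returned unchanged.
#'
#' @param m A mutational matrix (or signature matrix) with schema rownames.
#' @return A 96-row matrix in canonical channel order.
#' @export
collapse_matrix <- function(m) {
  sc <- matrix_schema(m)
  l96 <- sbs96_labels()
  if (sc == "SBS96") return(m)
  key <- if (sc == "SBS288") {
    sub("^[TUN]:", "", rownames(m))
  } else {
    sub("^([ACGT])([ACGT])\\[([ACGT]>[ACGT])\\]([ACGT])([ACGT])$",
        "\\2[\\3]\\4", rownames(m))
  }
  out <- rowsum(m, group = key)[l96, , drop = FALSE]
  if (is.integer(m)) storage.mode(out) <- "integer"
  attr(out, "schema") <- "SBS96"
  out
}

#' Write a mutational (or signature) matrix as TSV
#'
#' First column `MutationType` carries the channel labels in canonical
#' order; one column per sample/signature follows.
#' @param m Matrix with channel rownames.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(MutationType = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#' @param path Path to the TSV.
#' @return Numeric matrix with channel rownames and a `schema` attribute
#'   inferred from the row count.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$MutationType
  attr(m, "schema") <- matrix_schema(m)
  m
}
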