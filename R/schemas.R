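#' @useDynLib sigstratum, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

BASES <- c("A", "C", "G", "T")
SUB_TYPES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

sbs96_labels <- function() {
  unlist(lapply(SUB_TYPES, function(ty) {
    as.vector(t(outer(BASES, BASES, function(f5, f3) {
      paste0(f5, "[", ty, "]", f3)
    })))
  }))
}

sbs288_labels <- function() {
  l96 <- sbs96_labels()
  c(paste0("T:", l96), paste0("U:", l96), paste0("N:", l96))
}

sbs1536_labels <- function() {
  di <- as.vector(t(outer(BASES, BASES, paste0)))
  unlist(lapply(SUB_TYPES, function(ty) {
    as.vector(t(outer(di, di, function(p5, p3) {
      paste0(p5, "[", ty, "]", p3)
    })))
  }))
}

#' Substitution classification schemas
#'
#' Constructs one of the three single base substitution (SBS) classification
#' schemas used throughout the package. SBS-96 classifies each substitution
#' by the pyrimidine of the mutated Watson-Crick base pair and its immediate
#' 5' and 3' flanking bases (6 substitution types x 16 trinucleotide
#' contexts). SBS-288 adds a transcriptional category prefix: `T:` when the
#' mutated pyrimidine lies on a gene's template (transcribed) strand, `U:`
#' when on the coding (un-transcribed) strand, and `N:` for non-genic loci.
#' SBS-1536 extends the context to the pentanucleotide (two bases on each
#' side), giving 256 contexts per substitution type.
#'
#' Channel label order is fixed: substitution-type blocks in the order
#' C>A, C>G, C>T, T>A, T>C, T>G, lexicographic flanks within each block;
#' SBS-288 is prefix-major in the order `T:`, `U:`, `N:`. Both SBS-288 and
#' SBS-1536 are fully collapsible to SBS-96 (see [collapse_matrix()]).
#'
#' @param name One of `"SBS96"`, `"SBS288"`, `"SBS1536"`.
#' @return A list of class `sbs_schema` with elements `name` and
#'   `channel_labels` (length 96, 288 or 1536).
#' @examples
#' sc <- sbs_schema("SBS96")
#' length(sc$channel_labels)
#' @export
sbs_schema <- function(name = c("SBS96", "SBS288", "SBS1536")) {
  name <- match.arg(name)
  labels <- switch(name,
    SBS96 = sbs96_labels(),
    SBS288 = sbs288_labels(),
    SBS1536 = sbs1536_labels()
  )
  structure(list(name = name, channel_labels = labels), class = "sbs_schema")
}

#' @export
print.sbs_schema <- function(x, ...) {
  cat("<sbs_schema>", x$name, "with", length(x$channel_labels),
      "channels\n")
  invisible(x)
}

revcomp <- function(s) {
  vapply(strsplit(s, ""), function(ch) {
    paste(rev(unname(COMP[ch])), collapse = "")
  }, character(1))
}

#' Classify substitutions into schema channels
#'
#' Maps each substitution, described by its reference/alternate alleles and
#' reference-strand pentanucleotide context, to a channel label of the given
#' schema. Purine-reference records are reverse-complemented so that the
#' mutated pyrimidine defines the channel. For SBS-288 the transcriptional
#' prefix is derived from `strand_status` together with the strand carrying
#' the pyrimidine: on a forward-strand gene the reference strand is the
#' coding strand, so a reference-strand pyrimidine is classified `U:` and a
#' reverse-strand pyrimidine `T:`; the converse holds for reverse-strand
#' genes. Loci outside genes, or covered by genes on both strands, are `N:`.
#'
#' Records with an ambiguous base (`N`) in a required context position, or
#' whose context/alleles are inconsistent, get `NA` and are counted as
#' rejected by [build_matrix()].
#'
#' @param ref,alt Character vectors of single reference/alternate bases.
#' @param pentacontext Character vector of 5-base reference-strand contexts
#'   centered on the mutated base.
#' @param strand_status Character vector in `non_transcribed`,
#'   `gene_forward`, `gene_reverse`, `gene_both`; required for SBS-288.
#' @param schema An [sbs_schema()].
#' @return Character vector of channel labels (`NA` for rejected records)
#'   with a `reasons` attribute tabulating rejection causes.
#' @examples
#' classify_sbs("C", "T", "AACAA", schema = sbs_schema("SBS96"))
#' classify_sbs("G", "A", "TTGGA", schema = sbs_schema("SBS96"))
#' @export
classify_sbs <- function(ref, alt, pentacontext, strand_status = NULL,
                         schema = sbs_schema("SBS96")) {
  stopifnot(inherits(schema, "sbs_schema"))
  n <- length(ref)
  ref <- toupper(ref); alt <- toupper(alt)
  pentacontext <- toupper(pentacontext)
  out <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)

  ok <- ref %in% BASES & alt %in% BASES &
    !is.na(pentacontext) & nchar(pentacontext) == 5L
  ok[is.na(ok)] <- FALSE
  reason[!ok] <- "malformed_alleles_or_context"
  center <- substr(pentacontext, 3L, 3L)
  mism <- ok & center != ref
  reason[mism] <- "context_ref_mismatch"
  ok <- ok & !mism
  same <- ok & ref == alt
  reason[same] <- "ref_equals_alt"
  ok <- ok & !same

  # orient on the pyrimidine strand
  pyr <- ref %in% c("C", "T")
  ctx <- pentacontext
  flip <- ok & !pyr
  ctx[flip] <- revcomp(pentacontext[flip])
  aalt <- alt
  aalt[flip] <- unname(COMP[alt[flip]])
  aref <- ifelse(flip, unname(COMP[ref]), ref)

  need2 <- schema$name == "SBS1536"
  ctx_core <- if (need2) ctx else substr(ctx, 2L, 4L)
  hasN <- ok & grepl("N", ctx_core, fixed = TRUE)
  reason[hasN] <- "ambiguous_context_base"
  ok <- ok & !hasN

  ty <- paste0(aref, ">", aalt)
  lab <- rep(NA_character_, n)
  if (schema$name == "SBS1536") {
    lab[ok] <- paste0(substr(ctx[ok], 1L, 2L), "[", ty[ok], "]",
                      substr(ctx[ok], 4L, 5L))
  } else {
    lab[ok] <- paste0(substr(ctx[ok], 2L, 2L), "[", ty[ok], "]",
                      substr(ctx[ok], 4L, 4L))
  }

  if (schema$name == "SBS288") {
    if (is.null(strand_status)) {
      stop("strand_status is required for SBS288 classification")
    }
    bad <- ok & !(strand_status %in% c("non_transcribed", "gene_forward",
                                       "gene_reverse", "gene_both"))
    reason[bad] <- "invalid_strand_status"
    ok <- ok & !bad
    # pyrimidine on reference strand?
    pyr_ref <- ref %in% c("C", "T")
    prefix <- rep("N", n)
    fw <- strand_status == "gene_forward"
    rv <- strand_status == "gene_reverse"
    # forward gene: reference strand is coding; template is the reverse
    prefix[fw & !pyr_ref] <- "T"
    prefix[fw & pyr_ref] <- "U"
    prefix[rv & pyr_ref] <- "T"
    prefix[rv & !pyr_ref] <- "U"
    lab[ok] <- paste0(prefix[ok], ":", lab[ok])
  }

  lab[!ok] <- NA_character_
  structure(lab, reasons = table(reason[!ok]))
}
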