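test_that("pyrimidine and purine references map to the same channel family", {
  sc96 <- sbs_schema("SBS96")
  expect_equal(as.vector(classify_sbs("C", "T", "AACAA", schema = sc96)),
               "A[C>T]A")
  # purine reference: manual reverse-complement oracle
  # revcomp(TTGGA) = TCCAA, center C>T, flanks C/A
  expect_equal(as.vector(classify_sbs("G", "A", "TTGGA", schema = sc96)),
               "C[C>T]A")
  sc288 <- sbs_schema("SBS288")
  expect_equal(as.vector(classify_sbs("C", "A", "AACAA",
                                      strand_status = "non_transcribed",
                                      schema = sc288)),
               "N:A[C>A]A")
  # reference-strand pyrimidine on a forward gene sits on the coding strand
  expect_equal(as.vector(classify_sbs("C", "A", "AACAA",
                                      strand_status = "gene_forward",
                                      schema = sc288)),
               "U:A[C>A]A")
  expect_equal(as.vector(classify_sbs("C", "A", "AACAA",
                                      strand_status = "gene_reverse",
                                      schema = sc288)),
               "T:A[C>A]A")
  # bidirectional loci fall in the non-transcribed category by convention
  expect_equal(as.vector(classify_sbs("C", "A", "AACAA",
                                      strand_status = "gene_both",
                                      schema = sc288)),
               "N:A[C>A]A")
})

test_that("ambiguous bases in required positions reject the record", {
  sc96 <- sbs_schema("SBS96")
  out <- classify_sbs(c("C", "C"), c("T", "T"), c("ANCAA", "NACAN"),
                      schema = sc96)
  expect_true(is.na(out[1]))         # N inside the trinucleotide
  expect_equal(as.vector(out[2]), "A[C>T]A")  # N only in outer flanks
  out1536 <- classify_sbs("C", "T", "NACAA", schema = sbs_schema("SBS1536"))
  expect_true(is.na(out1536[1]))     # outer flank needed at 1536
})

test_that("strand-complement involution holds over all 96 trinucleotide cases", {
  flanks <- expand.grid(f5 = BASES, f3 = BASES,
                        stringsAsFactors = FALSE)
  subs <- list(c("C", "A"), c("C", "G"), c("C", "T"),
               c("T", "A"), c("T", "C"), c("T", "G"))
  swap_strand <- c(non_transcribed = "non_transcribed",
                   gene_forward = "gene_reverse",
                   gene_reverse = "gene_forward")
  sc <- sbs_schema("SBS288")
  for (s in subs) {
    for (i in seq_len(nrow(flanks))) {
      penta <- paste0("A", flanks$f5[i], s[1], flanks$f3[i], "T")
      for (strand in names(swap_strand)) {
        a <- classify_sbs(s[1], s[2], penta, strand, sc)
        rc_penta <- vapply(strsplit(penta, ""), function(ch)
          paste(rev(unname(c(A = "T", C = "G", G = "C", T = "A")[ch])),
                collapse = ""), character(1))
        b <- classify_sbs(c(A = "T", C = "G", G = "C", T = "A")[s[1]],
                          c(A = "T", C = "G", G = "C", T = "A")[s[2]],
                          rc_penta, swap_strand[[strand]], sc)
        expect_identical(as.vector(a), as.vector(b))
      }
    }
  }
})

test_that("matrices have exactly the schema's channel count and conserve records", {
  set.seed(5)
  co <- simulate_cohort(cohort_scenario(n_samples = 4,
                                        burden_log10_mean = 2.5, seed = 5))
  for (nm in c("SBS96", "SBS288", "SBS1536")) {
    m <- build_matrix(co$records, sbs_schema(nm))
    expect_equal(nrow(m), c(SBS96 = 96, SBS288 = 288, SBS1536 = 1536)[[nm]])
    expect_equal(sum(m), nrow(co$records))   # conservation
  }
  # empty record set with a declared sample
  empty <- build_matrix(co$records[0, ], sbs_schema("SBS96"),
                        samples = "s1")
  expect_equal(dim(empty), c(96, 1))
  expect_true(all(empty == 0))
})

test_that("collapse preserves column totals and commutes with aggregation", {
  set.seed(6)
  co <- simulate_cohort(cohort_scenario(n_samples = 5,
                                        burden_log10_mean = 2.7, seed = 6))
  m96 <- build_matrix(co$records, sbs_schema("SBS96"))
  m288 <- build_matrix(co$records, sbs_schema("SBS288"))
  m1536 <- build_matrix(co$records, sbs_schema("SBS1536"))
  expect_identical(collapse_matrix(m288)[rownames(m96), ], m96[, ])
  expect_identical(collapse_matrix(m1536)[rownames(m96), ], m96[, ])
  expect_equal(colSums(collapse_matrix(m288)), colSums(m288))
  expect_equal(colSums(collapse_matrix(m1536)), colSums(m1536))
  expect_identical(collapse_matrix(m96), m96)  # identity on SBS-96
  # forced strand sum on one channel
  m <- matrix(0L, 288, 1, dimnames = list(sbs_schema("SBS288")$channel_labels,
                                          "s"))
  m["T:A[C>A]A", 1] <- 2L; m["U:A[C>A]A", 1] <- 3L; m["N:A[C>A]A", 1] <- 5L
  expect_equal(collapse_matrix(m)["A[C>A]A", 1], 10L)
})

test_that("mutation TSV round-trips and malformed rows are rejected", {
  df <- data.frame(sample = c("s1", "s1", "s2"), chrom = "chr1",
                   pos = c(10L, 20L, 30L), ref = c("C", "T", "G"),
                   alt = c("A", "G", "A"),
                   pentacontext = c("AACAA", "GGTCC", "ATGGA"),
                   strand_status = "non_transcribed")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mutation_table(mutation_records(df), path)
  back <- read_mutation_table(path)
  expect_equal(nrow(back), 3)
  expect_equal(back$pentacontext, df$pentacontext)
  # context/ref mismatch dropped with a count
  df$ref[2] <- "C"
  recs <- mutation_records(df)
  expect_equal(nrow(recs), 2)
  expect_equal(sum(attr(recs, "rejected")), 1)
  # missing required column is fatal and names the column
  expect_error(mutation_records(df[, setdiff(names(df), "pos")]), "pos")
})

test_that("minimal VCF reading splits multi-allelic rows and keeps PASS only", {
  vcf <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
           "chr1\t100\t.\tC\tA,T\t.\tPASS\t.",
           "chr1\t200\t.\tG\tA\t.\tlowqual\t.",
           "chr1\t300\t.\tC\tCT\t.\tPASS\t.",
           "chr1\t400\t.\tT\tG\t.\tPASS\t.")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  recs <- read_mutation_vcf(path, "s1")
  expect_equal(nrow(recs), 3)  # 2 from multi-allelic + 1 plain SNV
  expect_equal(attr(recs, "skipped")[["non_pass"]], 1)
  expect_equal(attr(recs, "skipped")[["not_snv"]], 1)
})

test_that("context annotation slices the reference and enforces margins", {
  skip_if_not_installed("Biostrings")
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">toy", "AAAcAAA"), fa)  # soft-masked center
  recs <- mutation_records(data.frame(
    sample = "s1", chrom = "toy", pos = c(4L, 2L, 4L),
    ref = c("C", "A", "C"), alt = c("T", "G", "T"),
    pentacontext = c("", "", "AACTA")), validate = FALSE)
  out <- annotate_context(recs, fa)
  # pos 4 with no prior context annotated (lowercase uppercased);
  # pos 2 rejected at the margin; disagreeing prior context rejected
  expect_equal(nrow(out), 1)
  expect_equal(out$pentacontext, "AACAA")
  rej <- attr(out, "rejected")
  expect_equal(rej[["contig_edge"]], 1)
  expect_equal(rej[["context_disagrees"]], 1)
})
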