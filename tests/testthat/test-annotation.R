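# Helpers to write a minimal GTF in code.
gtf_line <- function(chrom, type, start, end, strand, gene, tx = NULL,
                     gene_type = "protein_coding", tx_type = NULL) {
  attr <- sprintf('gene_id "%s"; gene_type "%s";', gene, gene_type)
  if (!is.null(tx))
    attr <- paste0(attr, sprintf(' transcript_id "%s"; transcript_type "%s";',
                                 tx, if (is.null(tx_type)) gene_type else tx_type))
  paste(chrom, "test", type, start, end, ".", strand, ".", attr, sep = "\t")
}
write_gtf <- function(lines) {
  f <- tempfile(fileext = ".gtf")
  writeLines(lines, f)
  f
}

test_that("introns are exon complements and intergenic flanks a central gene", {
  f <- write_gtf(c(
    gtf_line("chr1", "gene", 301, 700, "+", "g1"),
    gtf_line("chr1", "transcript", 301, 700, "+", "g1", "t1"),
    gtf_line("chr1", "exon", 301, 400, "+", "g1", "t1"),
    gtf_line("chr1", "exon", 501, 600, "+", "g1", "t1")))
  gr <- suppressWarnings(parse_annotation(f, seqlengths = c(chr1 = 1000L)))
  introns <- gr[gr$feature_type == "intron"]
  expect_equal(length(introns), 1L)
  expect_equal(BiocGenerics::start(introns), 401L)
  expect_equal(BiocGenerics::end(introns), 500L)
  inter <- gr[gr$feature_type == "intergenic"]
  expect_equal(length(inter), 2L)
  expect_equal(sort(BiocGenerics::start(inter)), c(1L, 701L))
  expect_equal(sort(BiocGenerics::end(inter)), c(300L, 1000L))
})

test_that("single-exon transcripts produce no introns", {
  f <- write_gtf(c(
    gtf_line("chr1", "transcript", 10, 90, "+", "g1", "t1"),
    gtf_line("chr1", "exon", 10, 90, "+", "g1", "t1")))
  gr <- parse_annotation(f)
  expect_equal(sum(gr$feature_type == "intron"), 0L)
})

test_that("malformed GTF lines and missing transcript ids are reported", {
  bad <- write_gtf(c(gtf_line("chr1", "exon", 1, 50, "+", "g", "t"),
                     "chr1\ttest\texon\tnot_a_number\t50"))
  expect_error(parse_annotation(bad), "line 2")
  noid <- write_gtf(c("chr1\ttest\texon\t1\t50\t.\t+\t.\tgene_id \"g\";"))
  expect_warning(gr <- parse_annotation(noid), "transcript_id")
  expect_equal(length(gr), 0L)
})

test_that("feature sequence extraction handles strand and multi-exon splicing", {
  genome <- c(chr1 = "ATGCCCGGGTTTAAACCCGGGTTTAAACCC")  # 30 nt
  plus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 3), strand = "+")
  expect_identical(extract_feature_sequence(plus, genome), "ATG")
  minus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 3), strand = "-")
  expect_identical(extract_feature_sequence(minus, genome), "CAT")
  # two-exon minus-strand transcript: 3'-genomic exon comes first, each
  # piece reverse-complemented
  ex <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(4, 16), c(9, 21)),
                               strand = "-")
  manual <- paste0(revcomp(substr(genome, 16, 21)), revcomp(substr(genome, 4, 9)))
  expect_identical(extract_feature_sequence(ex, genome), manual)
  out <- GenomicRanges::GRanges("chr1", IRanges::IRanges(25, 40), strand = "+")
  expect_error(extract_feature_sequence(out, genome), "out of bounds")
})

test_that("CDS overlap classification distinguishes frame from frameshift", {
  cds <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 160), strand = "+")
  same <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 160), strand = "+")
  expect_identical(classify_cds_overlap(same, cds), "in_frame")
  # in-frame internal ORF (offset by a whole codon)
  inframe <- GenomicRanges::GRanges("chr1", IRanges::IRanges(104, 130), strand = "+")
  expect_identical(classify_cds_overlap(inframe, cds), "in_frame")
  shift <- GenomicRanges::GRanges("chr1", IRanges::IRanges(102, 131), strand = "+")
  expect_identical(classify_cds_overlap(shift, cds), "frameshift")
  away <- GenomicRanges::GRanges("chr1", IRanges::IRanges(500, 550), strand = "+")
  expect_identical(classify_cds_overlap(away, cds), "none")
  anti <- GenomicRanges::GRanges("chr1", IRanges::IRanges(110, 140), strand = "-")
  expect_identical(classify_cds_overlap(anti, cds), "frameshift")
  # phase is counted through introns: second CDS piece keeps the running frame
  cds2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 201), c(130, 260)),
                                 strand = "+")
  piece2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(201, 230), strand = "+")
  expect_identical(classify_cds_overlap(piece2, cds2), "in_frame")
})

test_that("build_strata produces labelled strata and applies dedup rules", {
  set.seed(5)
  nonstop <- setdiff(names(Biostrings::GENETIC_CODE),
                     names(which(Biostrings::GENETIC_CODE == "*")))
  cds <- paste0("ATG", paste(sample(nonstop, 40, replace = TRUE), collapse = ""),
                "TAA")
  lnc_seq <- random_dna(400)
  genome <- c(chr1 = paste0(random_dna(500), cds, random_dna(400), lnc_seq,
                            random_dna(300)))
  cds_start <- 501L; cds_end <- 500L + nchar(cds)
  lnc_start <- cds_end + 401L; lnc_end <- lnc_start + 399L
  f <- write_gtf(c(
    gtf_line("chr1", "gene", cds_start, cds_end, "+", "g1"),
    gtf_line("chr1", "transcript", cds_start, cds_end, "+", "g1", "t1"),
    gtf_line("chr1", "exon", cds_start, cds_end, "+", "g1", "t1"),
    gtf_line("chr1", "CDS", cds_start, cds_end - 3L, "+", "g1", "t1"),
    gtf_line("chr1", "gene", lnc_start, lnc_end, "+", "g2", gene_type = "lncRNA"),
    gtf_line("chr1", "transcript", lnc_start, lnc_end, "+", "g2", "t2",
             gene_type = "lncRNA"),
    gtf_line("chr1", "exon", lnc_start, lnc_end, "+", "g2", "t2",
             gene_type = "lncRNA")))
  feats <- suppressWarnings(
    parse_annotation(f, seqlengths = c(chr1 = nchar(genome[[1]]))))
  db <- build_strata(feats, genome)
  expect_true(all(c("cds_main", "intergenic") %in% db$stratum))
  expect_identical(db[db$stratum == "cds_main"]$aa_seq,
                   sub("\\*$", "", translate_fuzzy(cds)))
  # lncRNA stratum present iff an ORF >= 8 aa exists on the lncRNA (seeded
  # sequence contains one)
  expect_true("lncRNA" %in% db$stratum)
  # every ORF retranslates to its stored protein
  for (r in sample(nrow(db), min(25, nrow(db))))
    expect_identical(sub("\\*$", "", suppressWarnings(
      translate_fuzzy(db$nt_seq[r]))), db$aa_seq[r])
  # no stored protein is shorter than 5 aa and none contains a stop
  expect_true(all(nchar(db$aa_seq) >= 5L))
  expect_false(any(grepl("*", db$aa_seq, fixed = TRUE)))
  # expression-informed strata are a subset of exhaustive strata
  expr <- data.frame(transcript_id = c("t1", "t2"), rep1 = c(50, 3),
                     rep2 = c(60, 2))
  db_inf <- suppressWarnings(build_strata(feats, genome, expression = expr))
  expect_true(all(db_inf$orf_id %in% db$orf_id))
  expect_false("lncRNA" %in% db_inf$stratum)   # t2 unexpressed
  expect_true("cds_main" %in% db_inf$stratum)
})
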