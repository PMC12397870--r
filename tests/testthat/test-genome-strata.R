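test_that("fuzzy translation resolves unambiguous degenerate codons and X's the rest", {
  expect_identical(translate_fuzzy("GCN"), "A")   # every GCN codon is alanine
  expect_identical(translate_fuzzy("ATN"), "X")   # ATG = M but ATA/C/T = I
  expect_identical(translate_fuzzy("TAA"), "*")
  expect_identical(translate_fuzzy("TAR"), "*")   # TAA and TAG both stop
  expect_identical(translate_fuzzy("ATGGCNTAA"), "MA*")
  expect_warning(translate_fuzzy("ATGG"), "partial codon")
  expect_error(translate_fuzzy("AT!"), "illegal")
  # agreement with explicit IUPAC expansion on random fuzzy codons
  set.seed(42)
  for (i in 1:50) {
    codon <- random_dna(3, alphabet = names(iupac_expand))
    expect_identical(translate_fuzzy(codon), unname(oracle_codon(codon)),
                     label = codon)
  }
})

test_that("find_orfs reports the longest ORF per stop with the 5-codon start set", {
  o <- find_orfs(paste0("ATG", strrep("GCC", 7), "TAA"))
  expect_equal(nrow(o), 1L)
  expect_identical(o$aa_seq, "MAAAAAAA")
  expect_true(o$has_stop)
  # two in-frame starts, one stop: only the most upstream start reported
  o2 <- find_orfs(paste0("ATGATG", strrep("GCC", 7), "TAA"), min_aa = 8L)
  expect_equal(sum(o2$frame == 0L), 1L)
  expect_identical(o2$aa_seq[o2$frame == 0L], "MMAAAAAAA")
  # no listed start codon anywhere
  expect_equal(nrow(find_orfs(strrep("TTT", 30))), 0L)
  # run-off ORF without stop is flagged and suppressible
  o3 <- find_orfs(paste0("ATG", strrep("GCC", 10)))
  expect_false(any(o3$has_stop))
  expect_equal(nrow(find_orfs(paste0("ATG", strrep("GCC", 10)),
                              include_no_stop = FALSE)), 0L)
})

test_that("find_orfs agrees with the brute-force scanner on random sequences", {
  set.seed(101)
  n_checked <- 0L
  for (i in 1:200) {
    L <- sample(30:300, 1)
    alphabet <- if (i %% 4 == 0) names(iupac_expand) else c("A", "C", "G", "T")
    nt <- random_dna(L, alphabet)
    got <- find_orfs(nt, min_aa = 8L)
    want <- oracle_find_orfs(nt, min_aa = 8L)
    got <- got[order(got$frame, got$start), c("start", "end", "frame", "has_stop")]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, label = paste("seq", i))
    n_checked <- n_checked + nrow(want)
  }
  expect_gt(n_checked, 50)  # the comparison actually exercised ORFs
})

test_that("six-frame translation set is strand-flip invariant up to relabelling", {
  set.seed(7)
  for (i in 1:20) {
    nt <- random_dna(sample(30:90, 1))
    f <- six_frame_translations(nt)
    g <- six_frame_translations(revcomp(nt))
    expect_setequal(unname(f), unname(g))
    # forward frames of one strand are the reverse frames of the other
    expect_identical(unname(f[1:3]), unname(g[4:6]))
  }
})

test_that("edit distance is a metric and matches the DP oracle", {
  expect_equal(edit_distance("", "ABC"), 3L)
  expect_equal(edit_distance("PEPTIDE", "PEPTIDE"), 0L)
  expect_equal(edit_distance("kitten", "sitting"), 3L)
  set.seed(11)
  for (i in 1:30) {
    a <- random_protein(sample(0:12, 1)); b <- random_protein(sample(0:12, 1))
    c_ <- random_protein(sample(0:12, 1))
    dab <- edit_distance(a, b)
    expect_equal(dab, dp_edit_distance(a, b))
    expect_equal(dab, edit_distance(b, a))
    expect_lte(dab, edit_distance(a, c_) + edit_distance(c_, b))
  }
})

test_that("detect_main_orf finds the frame matching the reference protein", {
  set.seed(3)
  cds <- paste0("ATG", paste(sample(NONSTOP <- setdiff(
    names(Biostrings::GENETIC_CODE),
    names(which(Biostrings::GENETIC_CODE == "*"))), 40, replace = TRUE),
    collapse = ""))
  ref <- translate_fuzzy(cds)
  expect_equal(as.integer(detect_main_orf(ref, cds)), 0L)
  # one leading nt shifts the match to frame 1
  expect_equal(as.integer(detect_main_orf(ref, paste0("G", cds))), 1L)
  # reverse-complement puts it in frames 3-5
  expect_gte(as.integer(detect_main_orf(ref, revcomp(cds))), 3L)
  d <- attr(detect_main_orf(ref, cds), "distance")
  expect_length(d, 6L)
  expect_equal(unname(which.min(d)) - 1L, 0L)
})

test_that("expression filter requires the threshold in every replicate", {
  tab <- data.frame(transcript_id = c("t1", "t2", "t3"),
                    rep1 = c(12, 12, 3), rep2 = c(15, 9, 4))
  expect_identical(filter_expressed(tab, 10), "t1")
  expect_identical(filter_expressed(tab, 10, mode = "any"), c("t1", "t2"))
  expect_identical(filter_expressed(tab, 0), c("t1", "t2", "t3"))
})
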