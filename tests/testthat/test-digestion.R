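test_that("tryptic digestion matches the brute-force substring oracle", {
  d0 <- tryptic_digest("AAKGGGRCC", length_range = c(1, 30), max_missed = 0)
  expect_setequal(d0$sequence, c("AAK", "GGGR", "CC"))
  d1 <- tryptic_digest("AAKGGGRCC", length_range = c(1, 30), max_missed = 1)
  expect_setequal(d1$sequence, c("AAK", "GGGR", "CC", "AAKGGGR", "GGGRCC"))
  # no cleavage sites: whole protein iff within range
  expect_identical(tryptic_digest("AAAAA", length_range = c(1, 30))$sequence,
                   "AAAAA")
  expect_equal(nrow(tryptic_digest("AAAAA", length_range = c(1, 3))), 0L)
  set.seed(21)
  for (i in 1:25) {
    p <- random_protein(sample(5:60, 1))
    mm <- sample(c(0, 1, 2, Inf), 1)
    pr <- sample(c(TRUE, FALSE), 1)
    rng <- c(1L, sample(5:40, 1))
    got <- tryptic_digest(p, length_range = rng, max_missed = mm,
                          proline_rule = pr, drop_x = FALSE)
    want <- oracle_tryptic(p, rng, mm, pr)
    expect_identical(sort(got$sequence), sort(want), label = p)
    # records carry their true origin substring
    if (nrow(got))
      expect_identical(got$sequence, substring(p, got$start, got$end))
  }
})

test_that("nonspecific windows enumerate exactly L - N + 1 peptides per length", {
  w <- nonspecific_windows(random_protein(9), length_range = c(8, 9))
  expect_equal(nrow(w), 3L)
  expect_equal(sum(nchar(w$sequence) == 8L), 2L)
  expect_equal(sum(nchar(w$sequence) == 9L), 1L)
  expect_equal(nrow(nonspecific_windows(random_protein(6),
                                        length_range = c(8, 15))), 0L)
  set.seed(31)
  for (i in 1:20) {
    L <- sample(8:200, 1)
    p <- random_protein(L)
    w <- nonspecific_windows(p, length_range = c(8, 15), drop_x = FALSE)
    for (N in 8:15)
      expect_equal(sum(nchar(w$sequence) == N), max(0L, L - N + 1L))
    expect_identical(w$sequence, substring(p, w$start, w$end))
  }
})

test_that("peptides with undefined mass (X) are dropped and counted", {
  w <- nonspecific_windows("AAAAXAAAAAAA", length_range = c(8, 8))
  expect_false(any(grepl("X", w$sequence)))
  expect_equal(attr(w, "n_dropped_x"), 5L)  # windows 1..5 cover position 5
})

test_that("protein chunking covers the protein with exact overlaps", {
  ch <- chunk_protein(random_protein(100), max_len = 50, overlap = 20)
  expect_equal(ch$offset, c(0L, 30L, 60L))
  expect_equal(nchar(ch$sequence), c(50L, 50L, 40L))
  one <- chunk_protein(random_protein(30), max_len = 50, overlap = 20)
  expect_equal(nrow(one), 1L)
  expect_error(chunk_protein("AAA", max_len = 10, overlap = 10), "overlap")
  set.seed(41)
  for (i in 1:15) {
    L <- sample(20:300, 1); ml <- sample(30:80, 1); ov <- sample(5:(ml - 1), 1)
    p <- random_protein(L)
    ch <- chunk_protein(p, max_len = ml, overlap = ov)
    expect_true(all(nchar(ch$sequence) <= ml))
    # reassembling from offsets reproduces the protein
    rebuilt <- rep(NA_character_, L)
    for (r in seq_len(nrow(ch))) {
      idx <- ch$offset[r] + seq_len(nchar(ch$sequence[r]))
      rebuilt[idx] <- strsplit(ch$sequence[r], "")[[1]]
    }
    expect_identical(paste(rebuilt, collapse = ""), p)
    if (nrow(ch) > 1L) {
      ends <- ch$offset + nchar(ch$sequence)
      expect_true(all(ends[-nrow(ch)] - ch$offset[-1] == ov))
    }
  }
})

test_that("chunked cis generation equals whole-protein generation with sufficient overlap", {
  set.seed(51)
  N <- 8L; Imax <- 5
  for (i in 1:5) {
    p <- random_protein(90)
    whole <- generate_cis_spliced(p, N = N, Imax = Imax)
    ch <- chunk_protein(p, max_len = 40, overlap = N + Imax)
    parts <- lapply(seq_len(nrow(ch)), function(r)
      generate_cis_spliced(ch$sequence[r], N = N, Imax = Imax)$sequence)
    expect_setequal(unique(unlist(parts)), unique(whole$sequence))
  }
})

test_that("dedup keeps one row per distinct sequence and the full mapping", {
  recs <- data.table::rbindlist(list(
    nonspecific_windows("AAAAAAAAK", "p1", c(9, 9)),
    nonspecific_windows("AAAAAAAAK", "p2", c(9, 9))))
  dd <- dedup_peptides(recs)
  expect_equal(length(dd$unique), 1L)
  expect_equal(nrow(dd$mapping), 2L)
  empty <- dedup_peptides(recs[0])
  expect_length(empty$unique, 0L)
  expect_equal(nrow(empty$mapping), 0L)
  expect_lte(length(dd$unique), nrow(dd$mapping))
})

test_that("partition prefixes follow the rule-specific width", {
  expect_identical(peptide_prefix(c("ACDEF", "KLMNP"), "tryptic"), c("A", "K"))
  expect_identical(peptide_prefix("ACDEF", "nonspecific"), "AC")
  expect_identical(peptide_prefix("ACDEF", "cis_spliced"), "AC")
})
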