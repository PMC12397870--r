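test_that("target-decoy q-values follow the counting rule with monotonization", {
  psms <- data.frame(score = c(10, 9, 8, 9.5),
                     is_decoy = c(FALSE, FALSE, FALSE, TRUE))
  q <- tdc_qvalues(psms)$q_value
  expect_equal(q[1], 0)
  expect_equal(q[2], 1 / 3)
  expect_equal(q[3], 1 / 3)
  # decoys below every target: all target q = 0
  psms2 <- data.frame(score = c(5, 4, 1, 0.5),
                      is_decoy = c(FALSE, FALSE, TRUE, TRUE))
  expect_true(all(tdc_qvalues(psms2)$q_value[1:2] == 0))
  expect_warning(tdc_qvalues(data.frame(score = 1:3, is_decoy = rep(FALSE, 3))),
                 "no decoys")
  # +1 variant is uniformly at least as conservative
  q1 <- tdc_qvalues(psms, plus_one = TRUE)$q_value
  expect_true(all(q1 >= q))
})

test_that("q-values equal the reference brute-force implementation", {
  set.seed(191)
  for (i in 1:10) {
    n <- sample(20:120, 1)
    score <- round(c(rnorm(n, 10, 2), rnorm(n, 8, 2)),
                   sample(c(1, 2, Inf), 1))  # induce ties sometimes
    is_decoy <- rep(c(FALSE, TRUE), each = n)
    got <- tdc_qvalues(data.frame(score = score, is_decoy = is_decoy))$q_value
    expect_equal(got, oracle_qvalues(score, is_decoy), tolerance = 1e-12)
    # monotone: higher score never has larger q
    ord <- order(score, decreasing = TRUE)
    expect_true(all(diff(got[ord]) >= -1e-12))
  }
})

test_that("combined strategy keeps the min-q record per spectrum, ties canonical", {
  can <- data.frame(spectrum_id = c("s1", "s2", "s3"),
                    sequence = c("A", "B", "C"),
                    q_value = c(0.005, 0.02, 0.01))
  exp_ <- data.frame(spectrum_id = c("s1", "s2", "s4"),
                     sequence = c("A2", "B2", "D"),
                     q_value = c(0.02, 0.02, 0.001))
  m <- combined_strategy(can, exp_)
  expect_equal(nrow(m), 4L)
  expect_equal(anyDuplicated(m$spectrum_id), 0L)
  expect_identical(m$database_label[m$spectrum_id == "s1"], "canonical")
  expect_identical(m$database_label[m$spectrum_id == "s2"], "canonical")  # tie
  expect_identical(m$database_label[m$spectrum_id == "s4"], "expanded")
  expect_identical(m$sequence[m$spectrum_id == "s3"], "C")
  # property: always the minimum q among the candidates
  for (s in m$spectrum_id) {
    qs <- c(can$q_value[can$spectrum_id == s], exp_$q_value[exp_$spectrum_id == s])
    expect_equal(m$q_value[m$spectrum_id == s], min(qs))
  }
})

test_that("group-specific FDR processes each group independently", {
  set.seed(201)
  scores <- c(rnorm(50, 10, 1), rnorm(50, 7, 1))
  g1 <- data.frame(score = scores, is_decoy = rep(c(FALSE, TRUE), each = 50),
                   group = "a")
  g2 <- g1; g2$group <- "b"
  both <- rbind(g1, g2)
  q <- group_specific_fdr(both)$q_value
  expect_equal(q[both$group == "a"], q[both$group == "b"])
  pooled <- tdc_qvalues(g1)$q_value
  expect_equal(q[both$group == "a"], pooled)
  # group of high-scoring decoys: its targets get large q
  bad <- data.frame(score = c(5, 6, 20, 21), is_decoy = c(FALSE, FALSE, TRUE, TRUE),
                    group = "bad")
  qb <- group_specific_fdr(bad)$q_value
  expect_true(all(qb[!bad$is_decoy] >= 0.5))
  expect_error(group_specific_fdr(data.frame(score = 1, is_decoy = FALSE,
                                             group = NA)), "labelled")
})

test_that("identification report counts are monotone in the threshold", {
  psms <- data.frame(
    spectrum_id = paste0("s", 1:10),
    sequence = c("P1", "P1", "P2", "P3", "P4", "P5", "P6", "P7", "P8", "P9"),
    q_value = c(0.001, 0.002, 0.004, 0.008, 0.009, 0.02, 0.03, 0.04, 0.06, 0.2),
    is_decoy = FALSE,
    database_label = rep(c("canonical", "expanded"), 5))
  rep_ <- identification_report(psms, fdr_grid = c(0.0005, 0.005, 0.01, 0.05))
  expect_equal(rep_$n_psms, c(0L, 3L, 5L, 8L))     # hand-counted
  expect_equal(rep_$n_peptides, c(0L, 2L, 4L, 7L)) # P1 counted once
  expect_true(all(diff(rep_$n_psms) >= 0))
  expect_true(all(diff(rep_$n_peptides) >= 0))
  expect_equal(rep_$frac_noncanonical[3], 2 / 5)
})

test_that("empirical FDR is controlled on simulated score mixtures", {
  set.seed(211)
  emp_fdr <- replicate(30, {
    n_true <- 300; n_false <- 300
    truth <- c(rep(TRUE, n_true), rep(FALSE, n_false))
    target_scores <- c(rnorm(n_true, 12, 2), rnorm(n_false, 8, 2))
    decoy_scores <- rnorm(n_false, 8, 2)
    psms <- data.frame(score = c(target_scores, decoy_scores),
                       is_decoy = rep(c(FALSE, TRUE), c(600, n_false)))
    q <- tdc_qvalues(psms)$q_value
    acc <- !psms$is_decoy & q <= 0.01
    if (!any(acc)) return(0)
    mean(!truth[acc[1:600]])
  })
  expect_lte(mean(emp_fdr), 0.02)
})
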