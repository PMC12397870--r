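test_that("neutral mass inverts the m/z relation", {
  expect_equal(neutral_mass(500, 2), 997.98545, tolerance = 1e-7)
  M <- 1234.5678
  expect_equal(neutral_mass(M + mass_constants()$proton, 1), M)
  expect_error(neutral_mass(500, 0), "charge")
})

test_that("MW filter equals the all-pairs brute force and honors the window", {
  expect_true(mw_filter(1000.000, 1000.004, ppm = 5))
  expect_false(mw_filter(1000.000, 1000.006, ppm = 5))
  expect_false(mw_filter(1000, numeric(0), ppm = 5))
  set.seed(131)
  masses <- runif(2000, 700, 1600)
  obs <- runif(300, 700, 1600)
  obs[1:50] <- masses[1:50] * (1 + runif(50, -4e-6, 4e-6))  # planted hits
  got <- mw_filter(masses, obs, ppm = 5)
  expect_identical(got, oracle_mw(masses, obs, 5))
  expect_true(all(got[1:50]))
})

test_that("RT model recovers exact additive data and calibrated thresholds", {
  set.seed(141)
  truth <- rt_true_model()
  seqs <- replicate(120, random_protein(sample(8:14, 1)))
  rts <- pepspace:::.rt_of(seqs, truth)
  m <- fit_rt_model(data.frame(sequence = seqs, rt = rts))
  # noiseless additive data: held-out error threshold collapses to ~0
  expect_lt(m$error_threshold, 1e-6)
  pred <- predict(m, seqs)
  expect_equal(as.numeric(pred), rts, tolerance = 1e-6)
  # noisy data: threshold approximates the 0.99 quantile of |N(0, sigma)|
  seqs2 <- replicate(400, random_protein(sample(8:14, 1)))
  rts2 <- pepspace:::.rt_of(seqs2, truth) + rnorm(length(seqs2), 0, 0.5)
  m2 <- fit_rt_model(data.frame(sequence = seqs2, rt = rts2))
  expect_gt(m2$error_threshold, 0.5 * 2.576 * 0.7)
  expect_lt(m2$error_threshold, 0.5 * 2.576 * 1.4)
  expect_error(fit_rt_model(data.frame(sequence = rep("PEPTIDEK", 30),
                                       rt = 1:30)), "20 distinct")
})

test_that("coefficient recovery improves with calibration size", {
  truth <- rt_true_model()
  err_at <- function(n, seed) {
    set.seed(seed)
    seqs <- replicate(n, random_protein(sample(8:14, 1)))
    rts <- pepspace:::.rt_of(seqs, truth) + rnorm(n, 0, 0.5)
    m <- fit_rt_model(data.frame(sequence = seqs, rt = rts))
    co <- coef(m)[names(truth$coefficients)]
    mean(abs(co - truth$coefficients))
  }
  e200 <- err_at(200, 1); e2000 <- err_at(2000, 1)
  expect_lt(e2000, e200)
  expect_lt(e2000, 0.1)
})

test_that("sequences with untrained residues are flagged and excluded", {
  set.seed(151)
  # calibration without tryptophan
  seqs <- replicate(60, random_protein(10, residues = setdiff(amino_acids(), "W")))
  m <- fit_rt_model(data.frame(sequence = seqs,
                               rt = pepspace:::.rt_of(seqs) + rnorm(60, 0, 0.2)))
  expect_false("W" %in% m$trained_residues)
  p <- predict(m, c("AAAAAAAAAA", "AAAAWAAAAA"))
  expect_false(is.na(p[1]))
  expect_true(is.na(p[2]))
  expect_identical(attr(p, "excluded"), c(FALSE, TRUE))
})

test_that("joint MW+RT filter requires one observation satisfying both", {
  # peptide matches MW on obs A only and RT on obs B only -> dropped
  obs <- data.frame(neutral_mass = c(1000.000, 1200.000), rt = c(30, 10))
  keep <- mw_rt_filter(masses = 1000.000, rt_pred = 10, obs,
                       ppm = 5, rt_tolerance = 1)
  expect_false(as.logical(keep))
  keep2 <- mw_rt_filter(masses = 1000.000, rt_pred = 30.5, obs,
                        ppm = 5, rt_tolerance = 1)
  expect_true(as.logical(keep2))
  # independent mode allows different observations
  keep3 <- mw_rt_filter(1000.000, 10, obs, ppm = 5, rt_tolerance = 1,
                        joint = FALSE)
  expect_true(as.logical(keep3))
  # NA prediction falls back to MW-only, flagged
  keep4 <- mw_rt_filter(c(1000.000, 999), c(NA, NA), obs, ppm = 5,
                        rt_tolerance = 1)
  expect_identical(as.logical(keep4), c(TRUE, FALSE))
  expect_identical(attr(keep4, "mw_only"), c(TRUE, TRUE))
})

test_that("MW+RT filter equals the all-pairs oracle and stages are nested", {
  set.seed(161)
  n <- 3000
  masses <- runif(n, 700, 1600)
  rt_pred <- runif(n, 5, 60)
  rt_pred[sample(n, 100)] <- NA
  obs_mass <- c(masses[1:200] * (1 + runif(200, -4e-6, 4e-6)),
                runif(300, 700, 1600))
  obs_rt <- c(rt_pred[1:200] + runif(200, -0.8, 0.8), runif(300, 5, 60))
  obs_rt[is.na(obs_rt)] <- runif(sum(is.na(obs_rt)), 5, 60)
  obs <- data.frame(neutral_mass = obs_mass, rt = obs_rt)
  got <- mw_rt_filter(masses, rt_pred, obs, ppm = 5, rt_tolerance = 1)
  want <- oracle_mw_rt(masses, rt_pred, obs_mass, obs_rt, 5, 1)
  expect_identical(as.logical(got), want)
  mw_only <- mw_filter(masses, obs_mass, ppm = 5)
  expect_true(all(!as.logical(got) | mw_only))   # MW-RT-kept subset of MW-kept
})

test_that("HLA filter keeps binders at the threshold and skips out-of-range lengths", {
  fake <- function(peptides, allele) {
    v <- rep(9999, length(peptides))
    v[startsWith(peptides, "A")] <- 4999
    v[startsWith(peptides, "C")] <- 5001
    v
  }
  peps <- c("AAAAAAAAA", "CCCCCCCCC", "DDDDDDDDD",
            paste(rep("W", 16), collapse = ""))
  keep <- hla_filter(peps, fake, alleles = "X", ic50_threshold = 5000)
  expect_identical(as.logical(keep), c(TRUE, FALSE, FALSE, TRUE))
  expect_identical(attr(keep, "not_evaluated"), c(FALSE, FALSE, FALSE, TRUE))
  # multiple alleles: minimum rule
  fake2 <- function(peptides, allele)
    if (allele == "good") rep(100, length(peptides)) else rep(9999, length(peptides))
  expect_true(all(hla_filter(peps[1:3], fake2, alleles = c("bad", "good"))))
  expect_error(hla_filter(peps[1:3], function(p, a) stop("boom"), "X"),
               "predictor failed")
  # bundled toy predictor is deterministic and in a plausible range
  ic <- toy_hla_predictor(peps[1:3], "HLA-A02:01")
  expect_identical(ic, toy_hla_predictor(peps[1:3], "HLA-A02:01"))
  expect_true(all(ic > 0 & ic < 1e6))
})

test_that("decoy databases preserve composition and event counts", {
  expect_identical(unname(make_decoys(c(p = "ACDE"))), "EDCA")
  set.seed(171)
  prots <- setNames(replicate(30, random_protein(sample(20:80, 1))),
                    paste0("p", 1:30))
  dec <- make_decoys(prots)
  expect_identical(names(dec), paste0("rev_", names(prots)))
  for (i in seq_along(prots)) {
    expect_identical(sort(strsplit(prots[[i]], "")[[1]]),
                     sort(strsplit(dec[[i]], "")[[1]]))
    # unfiltered nonspecific event counts are composition-independent
    t_n <- nrow(nonspecific_windows(prots[[i]], drop_x = FALSE))
    d_n <- nrow(nonspecific_windows(dec[[i]], drop_x = FALSE))
    expect_equal(t_n, d_n)
    # mass multisets of 9-mers coincide after sorting
    tm <- sort(peptide_mass(nonspecific_windows(prots[[i]],
                                                length_range = c(9, 9))$sequence))
    dm <- sort(peptide_mass(nonspecific_windows(dec[[i]],
                                                length_range = c(9, 9))$sequence))
    expect_equal(tm, dm, tolerance = 1e-9)
  }
})

test_that("observation reader derives neutral mass and deduplicates", {
  f <- tempfile(fileext = ".tsv")
  data.table::fwrite(data.table::data.table(
    mz = c(500, 500, 600), charge = c(2L, 2L, 1L),
    rt_minutes = c(10, 10, 20)), f, sep = "\t")
  obs <- read_observations(f)
  expect_equal(nrow(obs), 2L)   # exact duplicate removed
  expect_equal(obs$neutral_mass[1], neutral_mass(500, 2))
})
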