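## Synthetic fixture generation: a toy genome + annotation + expression +
## MS1 observation tables + RT calibration PSMs + simulated PSM score
## tables, all deterministic under a seed. The generator emulates the
## *structure* of real inputs (gene models with UTRs/introns, lncRNA,
## intergenic gaps; precursor masses with ppm-scale error; additive
## chromatography with Gaussian noise; two-component PSM score mixtures) —
## not real biology.

NONSTOP_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                          names(which(Biostrings::GENETIC_CODE == "*")))

#' True additive retention coefficients used by the fixture generator
#'
#' Hydrophobicity-ordered per-residue retention contributions (minutes) with
#' intercept, used to simulate calibration RTs and observation RTs. Having
#' the truth available lets tests check parameter recovery.
#'
#' @return List with `intercept` (minutes) and `coefficients` (named numeric
#'   vector over the 20 residues).
#' @export
rt_true_model <- function() {
  list(intercept = 5,
       coefficients = c(
         W = 11.0, F = 10.0, L = 9.3, I = 8.3, M = 5.7, V = 5.0, Y = 4.0,
         P = 2.9, A = 0.8, C = 0.8, E = 0.7, T = 0.4, G = 0.0, Q = -0.3,
         D = -0.5, S = -0.8, N = -1.2, K = -2.1, H = -2.1, R = -2.6))
}

.rt_of <- function(sequences, truth = rt_true_model()) {
  X <- .residue_counts(sequences)
  truth$intercept + as.vector(X[, names(truth$coefficients)] %*%
                                truth$coefficients)
}

.random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")

.random_cds <- function(n_codons) {
  paste0("ATG",
         paste(sample(NONSTOP_CODONS, n_codons - 2L, replace = TRUE),
               collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1L))
}

.gtf_attr <- function(gene_id, transcript_id = NULL, gene_type = "protein_coding",
                      transcript_type = NULL) {
  a <- sprintf('gene_id "%s"; gene_type "%s";', gene_id, gene_type)
  if (!is.null(transcript_id))
    a <- paste0(a, sprintf(' transcript_id "%s"; transcript_type "%s";',
                           transcript_id,
                           if (is.null(transcript_type)) gene_type else transcript_type))
  a
}

#' Generate a complete toy input set
#'
#' Writes, under `out_dir`: `genome.fasta` (2 chromosomes, ~50 kb total),
#' `annotation.gtf` (coding genes with 5'/3'-UTRs and introns on both
#' strands, lncRNA genes, intergenic gaps), `expression.tsv` (two
#' replicates; some transcripts deliberately below the expression cutoff),
#' per-run observation tables `observations_run<i>.tsv` (m/z, charge,
#' RT of peptides truly present, with ppm-scale mass jitter, plus mass
#' decoys), `calibration.tsv` (peptide, RT from the true additive model plus
#' Gaussian noise) and `psms.tsv` (simulated two-component target/decoy PSM
#' scores). All randomness derives from `seed`.
#'
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @param n_coding,n_lnc Genes per chromosome.
#' @param chrom_len Approximate chromosome length (bp).
#' @param n_runs Number of MS runs (observation tables).
#' @param n_obs_true Planted-peptide observations per run.
#' @param n_obs_decoy Decoy-mass observations per run.
#' @param n_calibration Calibration PSMs.
#' @param rt_sigma RT noise standard deviation (minutes; default 0.5).
#' @param mass_jitter_ppm Observation mass error scale (uniform in
#'   +/- this many ppm; default 2, inside the 5 ppm search tolerance).
#' @param n_psm_true,n_psm_false True/false target PSMs in the score table.
#' @return Invisibly, a list with file paths, the planted-peptide table and
#'   all generation parameters.
#' @export
generate_fixtures <- function(seed, out_dir,
                              n_coding = 3L, n_lnc = 1L,
                              chrom_len = 25000L, n_runs = 2L,
                              n_obs_true = 300L, n_obs_decoy = 150L,
                              n_calibration = 300L, rt_sigma = 0.5,
                              mass_jitter_ppm = 2,
                              n_psm_true = 400L, n_psm_false = 400L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  chroms <- character(0)
  gtf <- character(0)
  tx_ids <- character(0)

  for (ci in 1:2) {
    chrom <- paste0("chr", ci)
    parts <- character(0)
    cursor <- 0L   # length written so far
    emit <- function(type, start, end, strand, attr)
      gtf <<- c(gtf, paste(chrom, "toy", type, start, end, ".", strand, ".",
                           attr, sep = "\t"))
    add_seq <- function(s) { parts <<- c(parts, s); cursor <<- cursor + nchar(s) }

    n_genes <- n_coding + n_lnc
    kinds <- sample(c(rep("coding", n_coding), rep("lnc", n_lnc)))
    for (gi in seq_len(n_genes)) {
      add_seq(.random_dna(sample(400:1200, 1L)))   # intergenic gap
      strand <- sample(c("+", "-"), 1L)
      gene_id <- sprintf("G%d_%d", ci, gi)
      tx_id <- sprintf("T%d_%d", ci, gi)
      tx_ids <- c(tx_ids, tx_id)
      if (kinds[gi] == "coding") {
        utr5 <- .random_dna(sample(60:150, 1L))
        utr3 <- .random_dna(sample(60:200, 1L))
        cds <- .random_cds(sample(60:150, 1L))    # 58-148 aa products
        split_at <- 3L * sample(5:(nchar(cds) %/% 3L - 5L), 1L)
        cds1 <- substr(cds, 1L, split_at)
        cds2 <- substr(cds, split_at + 1L, nchar(cds))
        intron <- .random_dna(sample(120:400, 1L))
        tx_sense <- c(utr5, cds1, intron, cds2, utr3)
        block <- paste(tx_sense, collapse = "")
        gs <- cursor + 1L; ge <- cursor + nchar(block)
        if (strand == "+") {
          o <- cursor
          p <- function(len) { r <- c(o + 1L, o + len); o <<- o + len; r }
          c_utr5 <- p(nchar(utr5)); c_cds1 <- p(nchar(cds1))
          c_int <- p(nchar(intron)); c_cds2 <- p(nchar(cds2))
          c_utr3 <- p(nchar(utr3))
          add_seq(block)
        } else {
          ## minus strand: transcript-sense pieces occupy the block from its
          ## genomic END downward
          o <- ge + 1L
          p <- function(len) { r <- c(o - len, o - 1L); o <<- o - len; r }
          c_utr5 <- p(nchar(utr5)); c_cds1 <- p(nchar(cds1))
          c_int <- p(nchar(intron)); c_cds2 <- p(nchar(cds2))
          c_utr3 <- p(nchar(utr3))
          add_seq(revcomp(block))
        }
        exon1 <- range(c(c_utr5, c_cds1)); exon2 <- range(c(c_cds2, c_utr3))
        at <- .gtf_attr(gene_id, tx_id)
        emit("gene", gs, ge, strand, .gtf_attr(gene_id))
        emit("transcript", gs, ge, strand, at)
        emit("exon", exon1[1], exon1[2], strand, at)
        emit("exon", exon2[1], exon2[2], strand, at)
        emit("CDS", c_cds1[1], c_cds1[2], strand, at)
        emit("CDS", c_cds2[1], c_cds2[2], strand, at)
        emit("five_prime_utr", c_utr5[1], c_utr5[2], strand, at)
        emit("three_prime_utr", c_utr3[1], c_utr3[2], strand, at)
      } else {
        ex1 <- .random_dna(sample(200:500, 1L))
        intr <- .random_dna(sample(150:400, 1L))
        ex2 <- .random_dna(sample(200:500, 1L))
        block <- paste0(ex1, intr, ex2)
        gs <- cursor + 1L; ge <- cursor + nchar(block)
        e1 <- c(gs, gs + nchar(ex1) - 1L)
        e2 <- c(ge - nchar(ex2) + 1L, ge)
        add_seq(block)
        at <- .gtf_attr(gene_id, tx_id, gene_type = "lncRNA")
        emit("gene", gs, ge, strand, .gtf_attr(gene_id, gene_type = "lncRNA"))
        emit("transcript", gs, ge, strand, at)
        emit("exon", e1[1], e1[2], strand, at)
        emit("exon", e2[1], e2[2], strand, at)
      }
    }
    pad <- chrom_len - cursor
    if (pad > 0L) add_seq(.random_dna(pad))
    chroms[chrom] <- paste(parts, collapse = "")
  }

  genome_path <- file.path(out_dir, "genome.fasta")
  gtf_path <- file.path(out_dir, "annotation.gtf")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(chroms), genome_path)
  writeLines(c("## toy annotation", gtf), gtf_path)

  ## expression: two replicates; ~20% of transcripts fail the >= 10-count
  ## per-replicate rule in exactly one replicate
  n_tx <- length(tx_ids)
  low <- seq_along(tx_ids) %in% sample(n_tx, max(1L, round(0.2 * n_tx)))
  rep1 <- ifelse(low, sample(0:9, n_tx, replace = TRUE),
                 sample(20:200, n_tx, replace = TRUE))
  rep2 <- sample(20:200, n_tx, replace = TRUE)
  expression <- data.table::data.table(transcript_id = tx_ids,
                                       rep1 = rep1, rep2 = rep2)
  expr_path <- file.path(out_dir, "expression.tsv")
  data.table::fwrite(expression, expr_path, sep = "\t")

  ## peptides truly present: nonspecific windows of the coding products
  genome <- stats::setNames(as.character(chroms), names(chroms))
  feats <- parse_annotation(gtf_path, seqlengths = vapply(chroms, nchar, 1L))
  strata <- build_strata(feats, genome)
  cds <- strata[strata$stratum == "cds_main"]
  pool <- data.table::rbindlist(lapply(seq_len(nrow(cds)), function(i)
    nonspecific_windows(cds$aa_seq[i], cds$orf_id[i],
                        length_range = c(8L, 12L))))
  pool <- unique(pool, by = "sequence")
  truth <- rt_true_model()

  obs_paths <- character(n_runs)
  planted <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    pick <- pool[sample(nrow(pool), min(n_obs_true, nrow(pool)))]
    m <- peptide_mass(pick$sequence)
    m_obs <- m * (1 + stats::runif(length(m), -mass_jitter_ppm,
                                   mass_jitter_ppm) * 1e-6)
    rt_obs <- .rt_of(pick$sequence, truth) + stats::rnorm(length(m), 0, rt_sigma)
    rt_obs <- pmax(rt_obs, 0.1)
    charge <- sample(2:3, length(m), replace = TRUE)
    decoy_m <- sample(m, n_obs_decoy, replace = TRUE) + 0.5
    decoy_rt <- stats::runif(n_obs_decoy, 0.1, max(rt_obs))
    decoy_ch <- sample(2:3, n_obs_decoy, replace = TRUE)
    obs <- data.table::data.table(
      mz = c(m_obs / charge + MASS_PROTON, decoy_m / decoy_ch + MASS_PROTON),
      charge = c(charge, decoy_ch),
      rt_minutes = round(c(rt_obs, decoy_rt), 4))
    obs_paths[r] <- file.path(out_dir, sprintf("observations_run%d.tsv", r))
    data.table::fwrite(obs, obs_paths[r], sep = "\t")
    planted[[r]] <- data.table::data.table(run = r, sequence = pick$sequence)
  }

  ## calibration PSMs from the same chromatography truth
  cal_pick <- pool[sample(nrow(pool), min(n_calibration, nrow(pool)))]
  calibration <- data.table::data.table(
    sequence = cal_pick$sequence,
    rt_minutes = round(.rt_of(cal_pick$sequence, truth) +
                         stats::rnorm(nrow(cal_pick), 0, rt_sigma), 4))
  cal_path <- file.path(out_dir, "calibration.tsv")
  data.table::fwrite(calibration, cal_path, sep = "\t")

  ## simulated PSM scores: true targets from the high component, false
  ## targets and decoys from the null component
  n_dec <- n_psm_false
  psms <- data.table::data.table(
    spectrum_id = sprintf("sp%05d", seq_len(n_psm_true + n_psm_false + n_dec)),
    sequence = sample(pool$sequence, n_psm_true + n_psm_false + n_dec,
                      replace = TRUE),
    score = c(stats::rnorm(n_psm_true, 12, 2),
              stats::rnorm(n_psm_false, 8, 2),
              stats::rnorm(n_dec, 8, 2)),
    is_decoy = rep(c(FALSE, FALSE, TRUE), c(n_psm_true, n_psm_false, n_dec)),
    database_label = sample(c("canonical", "expanded"),
                            n_psm_true + n_psm_false + n_dec, replace = TRUE),
    group = sample(c("cds_main", "noncanonical"),
                   n_psm_true + n_psm_false + n_dec, replace = TRUE))
  psm_path <- file.path(out_dir, "psms.tsv")
  data.table::fwrite(psms, psm_path, sep = "\t")

  params <- list(seed = seed, n_coding = n_coding, n_lnc = n_lnc,
                 chrom_len = chrom_len, n_runs = n_runs,
                 n_obs_true = n_obs_true, n_obs_decoy = n_obs_decoy,
                 n_calibration = n_calibration, rt_sigma = rt_sigma,
                 mass_jitter_ppm = mass_jitter_ppm,
                 rt_truth = truth)
  writeLines(deparse(params), file.path(out_dir, "params.txt"))
  invisible(list(genome = genome_path, gtf = gtf_path,
                 expression = expr_path, observations = obs_paths,
                 calibration = cal_path, psms = psm_path,
                 planted = data.table::rbindlist(planted),
                 params = params))
}
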