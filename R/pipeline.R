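## End-to-end orchestration: strata construction -> peptide generation
## (tryptic / nonspecific / cis-spliced) -> uniqueness aggregation -> mass
## computation -> data-driven filtering per MS run -> stratum statistics.
## Work units (stratum x rule) are independent and mergeable in any order;
## everything is deterministic given the configuration.

#' Default pipeline configuration
#'
#' All thresholds in one place, at field-standard defaults: 5 ppm MS1 error,
#' 0.99 RT-error quantile, 5000 nM IC50 cutoff, expression cutoff of 10
#' counts in every replicate.
#'
#' @param ... Overrides for any default entry.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    ppm = 5,
    rt_quantile = 0.99,
    rt_folds = 5L,
    ic50_threshold = 5000,
    hla_alleles = c("HLA-A02:01", "HLA-B07:02"),
    use_hla = TRUE,
    expression_threshold = 10,
    expression_mode = "every",
    tryptic_lengths = c(5L, 30L),
    tryptic_max_missed = 2L,
    nonspecific_lengths = c(8L, 12L),
    cis_length = 9L,
    cis_lext = 1L,
    cis_imax = 25,
    cis_strata = "cds_main",
    chunk_max_len = 1000L,
    chunk_overlap = NULL,   # default N_max + Imax, set at run time
    with_decoys = FALSE,
    store_backend = "auto",
    store_partitions = c("rule", "stratum", "length"),
    seed = 1L)
  utils::modifyList(cfg, list(...))
}

#' Generate all peptides for a stratum-labelled protein database
#'
#' Runs tryptic digestion and nonspecific windows on every protein, and
#' cis-spliced generation (with a shared precomputed coordinate index, and
#' chunking of proteins longer than `chunk_max_len`) on the strata listed in
#' `config$cis_strata`.
#'
#' @param strata_db `data.table` from [build_strata()] (needs `orf_id`,
#'   `stratum`, `aa_seq`, `parent_gene`).
#' @param config List from [pipeline_config()].
#' @return `data.table` of peptide records with `stratum` and `origin_gene`.
#' @export
generate_peptides <- function(strata_db, config = pipeline_config()) {
  recs <- list()
  overlap <- if (is.null(config$chunk_overlap))
    config$cis_length + ifelse(is.finite(config$cis_imax), config$cis_imax,
                               config$chunk_max_len %/% 2L)
  else config$chunk_overlap
  Lmax <- min(max(nchar(strata_db$aa_seq), 2L), config$chunk_max_len)
  cis_index <- list(
    forward = build_splice_index(Lmax, config$cis_length, config$cis_lext,
                                 config$cis_imax, "forward"),
    reverse = build_splice_index(Lmax, config$cis_length, config$cis_lext,
                                 config$cis_imax, "reverse"))
  for (i in seq_len(nrow(strata_db))) {
    aa <- strata_db$aa_seq[i]
    oid <- strata_db$orf_id[i]
    stratum <- strata_db$stratum[i]
    gene <- strata_db$parent_gene[i]
    tag <- function(dt) {
      if (!nrow(dt)) return(NULL)
      dt$stratum <- stratum; dt$origin_gene <- gene; dt
    }
    recs[[length(recs) + 1L]] <-
      tag(tryptic_digest(aa, oid, config$tryptic_lengths,
                         config$tryptic_max_missed))
    recs[[length(recs) + 1L]] <-
      tag(nonspecific_windows(aa, oid, config$nonspecific_lengths))
    if (stratum %in% config$cis_strata) {
      chunks <- chunk_protein(aa, oid, config$chunk_max_len, overlap)
      cis <- lapply(seq_len(nrow(chunks)), function(ci) {
        r <- generate_cis_spliced(chunks$sequence[ci], oid,
                                  N = config$cis_length,
                                  Lext = config$cis_lext,
                                  Imax = config$cis_imax,
                                  index = cis_index)
        if (nrow(r)) {
          off <- chunks$offset[ci]
          r[, `:=`(sr_i = sr_i + off, sr_j = sr_j + off,
                   sr_k = sr_k + off, sr_n = sr_n + off)]
        }
        r
      })
      cis <- unique(data.table::rbindlist(cis))
      recs[[length(recs) + 1L]] <- tag(cis)
    }
  }
  data.table::rbindlist(recs[!vapply(recs, is.null, logical(1))], fill = TRUE)
}

#' Distinct-peptide counts per stratum, rule, length and filter stage
#'
#' @param peptides Peptide table with `sequence`, `stratum`, `rule` and
#'   logical stage columns (e.g. `keep_mw`, `keep_mw_rt`, `keep_mw_rt_hla`).
#' @param stages Character vector of stage column names, in filtering order;
#'   the unfiltered stage is always included first.
#' @return `data.table` with `stratum`, `rule`, `length`, `stage`,
#'   `n_unique`; counts are non-increasing along stages within a group.
#' @export
strata_statistics <- function(peptides,
                              stages = grep("^keep_", names(peptides),
                                            value = TRUE)) {
  dt <- data.table::as.data.table(peptides)
  dt[, length := nchar(sequence)]
  out <- list(dt[, list(stage = "unfiltered",
                        n_unique = data.table::uniqueN(sequence)),
                 by = c("stratum", "rule", "length")])
  for (s in stages) {
    out[[length(out) + 1L]] <-
      dt[dt[[s]] == TRUE,
         list(stage = s, n_unique = data.table::uniqueN(sequence)),
         by = c("stratum", "rule", "length")]
  }
  res <- data.table::rbindlist(out)
  ## absent combinations are zero-count stages
  base <- unique(res[, c("stratum", "rule", "length")])
  full <- base[, data.table::data.table(stage = c("unfiltered", stages)),
               by = c("stratum", "rule", "length")]
  res <- merge(full, res, by = c("stratum", "rule", "length", "stage"),
               all.x = TRUE)
  res[is.na(n_unique), n_unique := 0L]
  res[, stage := factor(stage, levels = c("unfiltered", stages))]
  data.table::setorder(res, stratum, rule, length, stage)
  res[]
}

#' Run the search-space construction pipeline on file inputs
#'
#' Reads the genome, annotation and (optionally) expression table, builds
#' the protein strata, generates peptides, computes monoisotopic masses,
#' fits the retention-time model on the calibration PSMs, filters per MS
#' run (MW, then MW+RT, then optionally HLA binding with the bundled toy
#' predictor), and writes per-group unique-peptide FASTA, the partitioned
#' mapping store and a stage-wise statistics table.
#'
#' @param genome_fasta,gtf Paths to genome FASTA and GTF annotation.
#' @param observation_files Character vector of per-run observation tables.
#' @param calibration_file Calibration PSM table (`sequence`,
#'   `rt_minutes`).
#' @param expression_file Optional expression table; when given the strata
#'   are restricted to expressed transcripts.
#' @param out_dir Output directory.
#' @param config List from [pipeline_config()].
#' @return List with `strata`, `peptides` (with per-run keep columns),
#'   `rt_model`, `stats` (per-run + averaged), and output paths.
#' @export
run_pipeline <- function(genome_fasta, gtf, observation_files,
                         calibration_file, expression_file = NULL,
                         out_dir = tempfile("pepspace_out_"),
                         config = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome_dss <- Biostrings::readDNAStringSet(genome_fasta)
  names(genome_dss) <- sub("\\s.*$", "", names(genome_dss))
  genome <- stats::setNames(as.character(genome_dss), names(genome_dss))
  seqlens <- stats::setNames(nchar(genome), names(genome))
  feats <- parse_annotation(gtf, seqlengths = seqlens)
  expression <- if (!is.null(expression_file))
    data.table::fread(expression_file) else NULL
  strata_db <- build_strata(feats, genome, expression = expression,
                            expression_threshold = config$expression_threshold,
                            expression_mode = config$expression_mode)
  if (config$with_decoys) {
    dec <- make_decoys(stats::setNames(strata_db$aa_seq, strata_db$orf_id))
    dec_db <- data.table::copy(strata_db)
    dec_db[, `:=`(orf_id = names(dec), aa_seq = unname(dec),
                  stratum = paste0("decoy_", stratum))]
    strata_db <- rbind(strata_db, dec_db)
  }
  peptides <- generate_peptides(strata_db, config)
  dd <- dedup_peptides(peptides)
  peptides <- dd$mapping
  umass <- data.table::data.table(sequence = dd$unique)
  umass[, mass := peptide_mass(sequence)]

  calibration <- data.table::fread(calibration_file)
  rt_model <- fit_rt_model(
    data.frame(sequence = calibration$sequence, rt = calibration$rt_minutes),
    folds = config$rt_folds, quantile = config$rt_quantile,
    seed = config$seed)
  rt_pred <- predict(rt_model, umass$sequence)
  ## spliced peptides have no contiguous origin but a defined composition,
  ## so both MW and RT prediction apply to them

  ## binding prediction is observation-independent: computed once
  keep_hla_global <- if (isTRUE(config$use_hla))
    as.logical(hla_filter(umass$sequence, toy_hla_predictor,
                          alleles = config$hla_alleles,
                          ic50_threshold = config$ic50_threshold))
  else NULL

  stats_runs <- list()
  keep_cols <- character(0)
  log_lines <- character(0)
  for (r in seq_along(observation_files)) {
    t0 <- Sys.time()
    obs <- read_observations(observation_files[r],
                             source_run = paste0("run", r))
    keep_mw <- mw_filter(umass$mass, obs, ppm = config$ppm)
    keep_mwrt <- mw_rt_filter(umass$mass, as.numeric(rt_pred), obs,
                              ppm = config$ppm,
                              rt_tolerance = rt_model$error_threshold)
    keep_mwrt <- as.logical(keep_mwrt) & keep_mw
    cols <- paste0(c("keep_mw_", "keep_mwrt_"), "run", r)
    umass[, (cols[1]) := keep_mw]
    umass[, (cols[2]) := keep_mwrt]
    if (!is.null(keep_hla_global)) {
      col3 <- paste0("keep_mwrthla_run", r)
      umass[, (col3) := keep_mwrt & keep_hla_global]
      cols <- c(cols, col3)
    }
    keep_cols <- c(keep_cols, cols)
    pep_r <- merge(peptides, umass[, c("sequence", cols), with = FALSE],
                   by = "sequence")
    stats_runs[[r]] <- strata_statistics(pep_r, stages = cols)
    data.table::setnames(stats_runs[[r]], "stage", "stage_col")
    stats_runs[[r]][, `:=`(run = paste0("run", r),
                           stage = sub("_run[0-9]+$", "",
                                       as.character(stage_col)))]
    stats_runs[[r]][, stage_col := NULL]
    log_lines <- c(log_lines, sprintf(
      "run%d: %d observations, %d/%d MW, %d MW+RT kept (%.1fs)",
      r, nrow(obs), sum(keep_mw), nrow(umass), sum(keep_mwrt),
      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  stats <- data.table::rbindlist(stats_runs)
  stats_mean <- stats[, list(n_unique = mean(n_unique)),
                      by = c("stratum", "rule", "length", "stage")]

  ## per-group unique FASTA: peptides passing MW+RT in any run
  mwrt_cols <- grep("^keep_mwrt_", names(umass), value = TRUE)
  kept <- umass[rowSums(as.matrix(umass[, mwrt_cols, with = FALSE])) > 0]
  fasta_path <- file.path(out_dir, "unique_peptides_mwrt.fasta")
  aa <- Biostrings::AAStringSet(kept$sequence)
  names(aa) <- paste0("pep", seq_len(nrow(kept)))
  Biostrings::writeXStringSet(aa, fasta_path)

  store_dir <- file.path(out_dir, "peptide_store")
  write_peptide_store(merge(peptides,
                            umass[, c("sequence", "mass", keep_cols),
                                  with = FALSE],
                            by = "sequence"),
                      store_dir, backend = config$store_backend,
                      partitioning = config$store_partitions)
  stats_path <- file.path(out_dir, "strata_stats.tsv")
  data.table::fwrite(stats[order(stratum, rule, length, stage, run)],
                     stats_path, sep = "\t")
  writeLines(log_lines, file.path(out_dir, "pipeline_log.txt"))

  list(strata = strata_db, peptides = peptides, unique_masses = umass,
       rt_model = rt_model, stats = stats, stats_mean = stats_mean,
       paths = list(out_dir = out_dir, fasta = fasta_path,
                    store = store_dir, stats = stats_path))
}
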