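#' Build stratum-labelled protein databases from genome and annotation
#'
#' The exhaustive search-space constructor. Annotated CDS translations form
#' the `cds_main` stratum; ORFs discovered by [find_orfs()] on CDS transcript
#' sequences that overlap the CDS out of frame form `cds_offframe`; 5'-UTR,
#' 3'-UTR, intron, intergenic (both strands, strandless) and lncRNA features
#' are scanned for ORFs with the five-codon start set. Every discovered ORF
#' is overlap-classified against the annotated CDS of its chromosome.
#'
#' Post-processing: exact duplicates
#' (identical id and sequence, e.g. X/Y pseudo-autosomal genes) are removed,
#' proteins shorter than `min_aa_keep` residues are dropped, and, when an
#' expression table is given, ORFs are restricted to expressed transcripts
#' (intergenic features carry no transcript and are always retained).
#'
#' @param features `GRanges` from [parse_annotation()].
#' @param genome Named `DNAStringSet` or named character vector.
#' @param expression Optional expression `data.frame`
#'   (see [filter_expressed()]).
#' @param min_aa_orf Minimal ORF length at discovery (default 8).
#' @param min_aa_keep Minimal protein length kept after dedup (default 5).
#' @param start_codons Start-codon set for ORF discovery.
#' @param expression_threshold,expression_mode Passed to [filter_expressed()].
#' @param include_no_stop Keep ORFs lacking a stop codon (flagged)?
#' @param out_dir If non-`NULL`, write one protein FASTA per stratum there,
#'   headers `orf_id|stratum|parent_transcript|parent_gene|overlap_class`.
#' @return `data.table` with columns `orf_id`, `stratum`, `nt_seq`, `aa_seq`,
#'   `frame`, `cds_overlap_class`, `parent_transcript`, `parent_gene`,
#'   `has_stop`.
#' @export
build_strata <- function(features, genome, expression = NULL,
                         min_aa_orf = 8L, min_aa_keep = 5L,
                         start_codons = ORF_START_CODONS,
                         expression_threshold = 10,
                         expression_mode = "every",
                         include_no_stop = TRUE,
                         out_dir = NULL) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  ft <- features$feature_type
  cds_all <- features[ft == "CDS"]
  cds_by_tx <- if (length(cds_all))
    GenomicRanges::split(cds_all, cds_all$transcript_id) else list()
  gene_of_tx <- features$gene_id[match(names(cds_by_tx), features$transcript_id)]
  names(gene_of_tx) <- names(cds_by_tx)

  rows <- list()
  add_row <- function(orf_id, stratum, nt, aa, frame, klass, tx, gene, has_stop)
    rows[[length(rows) + 1L]] <<- data.table::data.table(
      orf_id = orf_id, stratum = stratum, nt_seq = nt, aa_seq = aa,
      frame = frame, cds_overlap_class = klass,
      parent_transcript = tx, parent_gene = gene, has_stop = has_stop)

  ## --- cds_main: annotated CDS translations (U mapped to X upstream) -----
  for (tx in names(cds_by_tx)) {
    pieces <- cds_by_tx[[tx]]
    nt <- extract_feature_sequence(pieces, genome)
    aa <- suppressWarnings(translate_fuzzy(nt))
    aa <- sub("\\*.*$", "", aa)  # strip stop and anything past it
    add_row(paste0(tx, "_main"), "cds_main", nt, aa, 0L, "in_frame",
            tx, gene_of_tx[[tx]], grepl("\\*", suppressWarnings(translate_fuzzy(nt))))
  }

  ## flat CDS piece vectors for a cheap overlap prefilter: the phase
  ## comparison only runs for transcripts that actually share bases
  cds_units <- lapply(as.list(cds_by_tx), .unit_from_gr)
  cds_tab <- if (length(cds_all)) list(
    chrom = as.character(GenomeInfoDb::seqnames(cds_all)),
    start = BiocGenerics::start(cds_all), end = BiocGenerics::end(cds_all),
    tx = cds_all$transcript_id) else NULL
  classify_orf <- function(orf_unit) {
    if (!length(orf_unit$start) || is.null(cds_tab)) return("none")
    sel <- cds_tab$chrom == orf_unit$chrom
    if (!any(sel)) return("none")
    hit <- logical(sum(sel))
    cs <- cds_tab$start[sel]; ce <- cds_tab$end[sel]
    for (p in seq_along(orf_unit$start))
      hit <- hit | (cs <= orf_unit$end[p] & ce >= orf_unit$start[p])
    cand <- unique(cds_tab$tx[sel][hit])
    if (!length(cand)) return("none")
    klass <- "none"
    for (tx in cand) {
      k <- .classify_overlap_units(orf_unit, cds_units[[tx]])
      if (k == "in_frame") return("in_frame")
      if (k == "frameshift") klass <- "frameshift"
    }
    klass
  }

  scan_unit <- function(unit_gr, unit_seq, stratum, unit_id, tx, gene,
                        strand_tag = "") {
    orfs <- find_orfs(unit_seq, start_codons = start_codons,
                      min_aa = min_aa_orf, include_no_stop = include_no_stop)
    if (!nrow(orfs)) return(invisible())
    unit <- .unit_from_gr(unit_gr)
    klass <- character(nrow(orfs))
    for (r in seq_len(nrow(orfs)))
      klass[r] <- classify_orf(.unit_local_to_genomic(unit, orfs$start[r],
                                                      orfs$end[r]))
    keep <- if (stratum == "cds_offframe") klass == "frameshift"
            else rep(TRUE, nrow(orfs))
    if (!any(keep)) return(invisible())
    orfs <- orfs[keep, , drop = FALSE]; klass <- klass[keep]
    rows[[length(rows) + 1L]] <<- data.table::data.table(
      orf_id = paste0(unit_id, strand_tag, "_f", orfs$frame, "_", orfs$start),
      stratum = stratum,
      nt_seq = substring(unit_seq, orfs$start, orfs$end),
      aa_seq = orfs$aa_seq, frame = orfs$frame, cds_overlap_class = klass,
      parent_transcript = tx, parent_gene = gene, has_stop = orfs$has_stop)
  }

  ## --- cds_offframe: rescan CDS transcript sequences -----------------------
  for (tx in names(cds_by_tx)) {
    pieces <- cds_by_tx[[tx]]
    nt <- extract_feature_sequence(pieces, genome)
    scan_unit(pieces, nt, "cds_offframe", paste0(tx, "_cdsscan"),
              tx, gene_of_tx[[tx]])
  }

  ## --- UTRs and introns: one unit per feature row --------------------------
  for (stratum in c("UTR5", "UTR3", "intron")) {
    rows_f <- features[ft == stratum]
    lab <- c(UTR5 = "utr5", UTR3 = "utr3", intron = "intron")[[stratum]]
    for (i in seq_along(rows_f)) {
      unit <- rows_f[i]
      nt <- extract_feature_sequence(unit, genome)
      tx <- unit$transcript_id
      gene <- unit$gene_id
      scan_unit(unit, nt, lab,
                paste0(tx, "_", lab, "_", BiocGenerics::start(unit)), tx, gene)
    }
  }

  ## --- lncRNA: spliced exons per flagged transcript -------------------------
  lnc_tx <- unique(features$transcript_id[ft == "lncRNA"])
  ex <- features[ft == "exon"]
  for (tx in lnc_tx) {
    unit <- ex[ex$transcript_id == tx]
    if (!length(unit)) unit <- features[ft == "lncRNA" & features$transcript_id == tx]
    nt <- extract_feature_sequence(unit, genome)
    scan_unit(unit, nt, "lncRNA", paste0(tx, "_lnc"),
              tx, unit$gene_id[1])
  }

  ## --- intergenic: strandless, both strands scanned -------------------------
  ig <- features[ft == "intergenic"]
  for (i in seq_along(ig)) {
    unit <- ig[i]
    base_id <- paste0("intergenic_", as.character(GenomeInfoDb::seqnames(unit)),
                      "_", BiocGenerics::start(unit))
    plus <- unit; BiocGenerics::strand(plus) <- "+"
    scan_unit(plus, extract_feature_sequence(plus, genome), "intergenic",
              base_id, NA_character_, NA_character_, "_plus")
    minus <- unit; BiocGenerics::strand(minus) <- "-"
    scan_unit(minus, extract_feature_sequence(minus, genome), "intergenic",
              base_id, NA_character_, NA_character_, "_minus")
  }

  db <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(orf_id = character(), stratum = character(),
                           nt_seq = character(), aa_seq = character(),
                           frame = integer(), cds_overlap_class = character(),
                           parent_transcript = character(),
                           parent_gene = character(), has_stop = logical())

  ## selenocysteine / readthrough are not modelled: U becomes X
  db[, aa_seq := gsub("U", "X", aa_seq, fixed = TRUE)]
  ## exact duplicates (identical id + sequence)
  db <- unique(db, by = c("orf_id", "aa_seq"))
  db <- db[nchar(aa_seq) >= min_aa_keep]
  if (!is.null(expression)) {
    expressed <- filter_expressed(expression, threshold = expression_threshold,
                                  mode = expression_mode)
    missing_tx <- setdiff(stats::na.omit(unique(db$parent_transcript)),
                          expression$transcript_id)
    if (length(missing_tx))
      warning(length(missing_tx),
              " transcript(s) absent from expression table; treated as unexpressed")
    db <- db[is.na(parent_transcript) | parent_transcript %in% expressed]
  }
  data.table::setorder(db, stratum, orf_id)
  if (!is.null(out_dir)) write_strata_fasta(db, out_dir)
  db[]
}

#' Write one protein FASTA per stratum
#'
#' @param db Strata table from [build_strata()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_strata_fasta <- function(db, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in unique(db$stratum)) {
    sub <- db[db$stratum == s]
    aa <- Biostrings::AAStringSet(sub$aa_seq)
    names(aa) <- paste(sub$orf_id, sub$stratum, sub$parent_transcript,
                       sub$parent_gene, sub$cds_overlap_class, sep = "|")
    p <- file.path(out_dir, paste0(s, ".fasta"))
    Biostrings::writeXStringSet(aa, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
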