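## GTF ingestion and interval bookkeeping.
##
## Coordinates: GTF is 1-based inclusive and is parsed as such by rtracklayer;
## all downstream interval arithmetic stays on GRanges (1-based inclusive),
## so no manual convention juggling happens outside this file.

#' Parse a GTF annotation into genomic features
#'
#' Reads a GENCODE/Ensembl-dialect GTF and returns a `GRanges` of typed
#' features: `gene`, `transcript`, `exon`, `CDS`, `UTR5`, `UTR3`, plus derived
#' `intron` features (gaps between consecutive exons of a transcript),
#' `lncRNA` transcript features (biotype attribute equal to `"lncRNA"`) and,
#' when chromosome lengths are supplied, strandless `intergenic` features
#' (chromosome minus the union of gene spans).
#'
#' Plain `UTR` rows (GENCODE GTF does not distinguish) are reclassified to
#' `UTR5`/`UTR3` by their position relative to the transcript's CDS.
#' Malformed lines abort with the offending line number; non-gene records
#' lacking a `transcript_id` are rejected with a warning.
#'
#' @param gtf_file Path to a GTF file.
#' @param seqlengths Optional named integer vector of chromosome lengths
#'   (e.g. `Biostrings::width` of the genome), required for intergenic
#'   derivation.
#' @return `GRanges` with metadata columns `feature_type`, `transcript_id`,
#'   `gene_id`.
#' @export
parse_annotation <- function(gtf_file, seqlengths = NULL) {
  .validate_gtf_lines(gtf_file)
  gr <- rtracklayer::import(gtf_file, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$transcript_id)) mc$transcript_id <- NA_character_
  if (is.null(mc$gene_id)) mc$gene_id <- NA_character_
  type <- as.character(mc$type)
  bad <- type != "gene" & is.na(mc$transcript_id)
  if (any(bad)) {
    warning(sum(bad), " record(s) without transcript_id rejected")
    gr <- gr[!bad]; mc <- S4Vectors::mcols(gr); type <- as.character(mc$type)
  }
  biotype <- mc$transcript_type
  if (is.null(biotype)) biotype <- mc$transcript_biotype
  if (is.null(biotype)) biotype <- rep(NA_character_, length(gr))

  map <- c(gene = "gene", transcript = "transcript", exon = "exon",
           CDS = "CDS", five_prime_utr = "UTR5", three_prime_utr = "UTR3",
           UTR = "UTR")
  keep <- type %in% names(map)
  gr <- gr[keep]
  ftype <- unname(map[type[keep]])
  biotype <- biotype[keep]
  mc <- S4Vectors::mcols(gr)

  out <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(gr), IRanges::ranges(gr),
    strand = BiocGenerics::strand(gr),
    feature_type = ftype,
    transcript_id = as.character(mc$transcript_id),
    gene_id = as.character(mc$gene_id))

  ## Split unlabelled UTRs by position relative to the transcript's CDS.
  utr_idx <- which(out$feature_type == "UTR")
  if (length(utr_idx)) {
    cds <- out[out$feature_type == "CDS"]
    cds_start <- tapply(BiocGenerics::start(cds), cds$transcript_id, min)
    cds_end <- tapply(BiocGenerics::end(cds), cds$transcript_id, max)
    for (i in utr_idx) {
      tx <- out$transcript_id[i]
      if (!tx %in% names(cds_start)) next
      plus <- as.character(BiocGenerics::strand(out[i])) != "-"
      before <- BiocGenerics::end(out[i]) < cds_start[[tx]]
      ## 5' UTR sits upstream of the CDS in transcription direction
      out$feature_type[i] <- if (before == plus) "UTR5" else "UTR3"
    }
  }

  ## Introns: per-transcript exonic complement within the transcript span.
  ex <- out[out$feature_type == "exon"]
  if (length(ex)) {
    ex_by_tx <- GenomicRanges::split(ex, ex$transcript_id)
    gaps <- GenomicRanges::psetdiff(BiocGenerics::unlist(range(ex_by_tx)),
                                    ex_by_tx)
    gaps <- BiocGenerics::unlist(gaps)
    if (length(gaps)) {
      tx_of <- names(gaps)
      gene_of <- out$gene_id[match(tx_of, out$transcript_id)]
      introns <- GenomicRanges::GRanges(
        GenomeInfoDb::seqnames(gaps), IRanges::ranges(gaps),
        strand = BiocGenerics::strand(gaps),
        feature_type = "intron", transcript_id = tx_of, gene_id = gene_of)
      names(introns) <- NULL
      out <- c(out, introns)
    }
  }

  ## lncRNA transcript flags from the biotype attribute.
  is_lnc <- !is.na(biotype) & biotype == "lncRNA" & ftype == "transcript"
  if (any(is_lnc)) {
    ## indices refer to the pre-intron block of `out`, which is unchanged
    lnc <- out[which(is_lnc)]
    lnc$feature_type <- "lncRNA"
    out <- c(out, lnc)
  }

  ## Intergenic: chromosome minus union of gene spans (strandless).
  if (!is.null(seqlengths)) {
    genes <- GenomicRanges::reduce(
      GenomicRanges::GRanges(GenomeInfoDb::seqnames(out),
                             IRanges::ranges(out), strand = "*"),
      ignore.strand = TRUE)
    inter <- list()
    for (chr in names(seqlengths)) {
      g <- genes[GenomeInfoDb::seqnames(genes) == chr]
      ir <- IRanges::setdiff(IRanges::IRanges(1L, seqlengths[[chr]]),
                             IRanges::ranges(g))
      if (length(ir))
        inter[[chr]] <- GenomicRanges::GRanges(
          chr, ir, strand = "*", feature_type = "intergenic",
          transcript_id = NA_character_, gene_id = NA_character_)
    }
    if (length(inter)) out <- c(out, do.call(c, unname(inter)))
  }
  out
}

.validate_gtf_lines <- function(gtf_file) {
  lines <- readLines(gtf_file, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L)
      stop("malformed GTF at line ", i, ": expected 9 tab-separated fields")
    s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e) || s > e)
      stop("malformed GTF at line ", i, ": bad coordinates '",
           f[4], "'..'", f[5], "'")
  }
  invisible(TRUE)
}

#' Extract the nucleotide sequence of a (possibly multi-interval) feature
#'
#' Pieces are concatenated in transcription order: ascending start on the
#' plus strand, descending start on the minus strand with each piece
#' reverse-complemented. Strandless features are read off the plus strand.
#'
#' @param feature `GRanges` holding the piece(s) of one feature (one
#'   transcript's exons, one intron, ...), all on one chromosome/strand.
#' @param genome Named `DNAStringSet` (or named character vector) of
#'   chromosome sequences.
#' @return Single nucleotide string.
#' @export
extract_feature_sequence <- function(feature, genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  chr <- as.character(GenomeInfoDb::seqnames(feature))
  if (length(unique(chr)) != 1L) stop("feature pieces on multiple chromosomes")
  chr <- chr[1]
  if (!chr %in% names(genome))
    stop("chromosome '", chr, "' absent from genome for feature ",
         paste(utils::head(feature$transcript_id, 1), collapse = ""))
  chrseq <- genome[[chr]]
  st <- BiocGenerics::start(feature); en <- BiocGenerics::end(feature)
  if (any(st < 1L) || any(en > length(chrseq)))
    stop("coordinates out of bounds for feature on ", chr,
         " [", min(st), "..", max(en), "]")
  minus <- as.character(BiocGenerics::strand(feature))[1] == "-"
  ord <- order(st, decreasing = minus)
  pieces <- vapply(ord, function(i)
    as.character(Biostrings::subseq(chrseq, st[i], en[i])), character(1))
  if (minus) pieces <- vapply(pieces, revcomp, character(1), USE.NAMES = FALSE)
  paste(pieces, collapse = "")
}

## Plain-vector "unit" representation of a (possibly multi-piece) feature,
## in transcription order. S4 construction per ORF is far too slow for the
## scan loops, so the hot path works on these; the exported GRanges API
## wraps them.
.unit_from_gr <- function(feature) {
  minus <- as.character(BiocGenerics::strand(feature))[1] == "-"
  ord <- order(BiocGenerics::start(feature), decreasing = minus)
  list(chrom = as.character(GenomeInfoDb::seqnames(feature))[1],
       minus = minus,
       start = BiocGenerics::start(feature)[ord],
       end = BiocGenerics::end(feature)[ord])
}

## Map a local [lstart, lend] (1-based, feature-sequence coordinates) to
## genomic piece coordinates. Returns a list of `start`/`end` vectors.
.unit_local_to_genomic <- function(unit, lstart, lend) {
  w <- unit$end - unit$start + 1L
  cum <- cumsum(w)
  off <- c(0L, cum[-length(cum)])
  gs <- integer(0); ge <- integer(0)
  for (p in seq_along(w)) {
    a <- max(lstart, off[p] + 1L); b <- min(lend, cum[p])
    if (a > b) next
    if (!unit$minus) {
      gs <- c(gs, unit$start[p] + (a - off[p] - 1L))
      ge <- c(ge, unit$start[p] + (b - off[p] - 1L))
    } else {
      ge <- c(ge, unit$end[p] - (a - off[p] - 1L))
      gs <- c(gs, unit$end[p] - (b - off[p] - 1L))
    }
  }
  list(chrom = unit$chrom, minus = unit$minus, start = gs, end = ge)
}

## Codon phase (0/1/2) of genomic positions within a unit, counted in
## transcription order from the unit's first base.
.unit_phase <- function(unit, pos) {
  w <- unit$end - unit$start + 1L
  off <- c(0L, cumsum(w)[-length(w)])
  res <- rep(NA_integer_, length(pos))
  for (p in seq_along(w)) {
    in_p <- pos >= unit$start[p] & pos <= unit$end[p]
    if (!any(in_p)) next
    local <- if (!unit$minus) off[p] + (pos[in_p] - unit$start[p] + 1L)
             else off[p] + (unit$end[p] - pos[in_p] + 1L)
    res[in_p] <- (local - 1L) %% 3L
  }
  res
}

## Core overlap classification on plain units.
.classify_overlap_units <- function(orf_unit, cds_unit) {
  if (!length(orf_unit$start) || !length(cds_unit$start)) return("none")
  if (orf_unit$chrom != cds_unit$chrom) return("none")
  probes <- integer(0)
  for (a in seq_along(orf_unit$start))
    for (b in seq_along(cds_unit$start)) {
      lo <- max(orf_unit$start[a], cds_unit$start[b])
      hi <- min(orf_unit$end[a], cds_unit$end[b])
      if (lo <= hi) probes <- c(probes, lo)
    }
  if (!length(probes)) return("none")
  if (orf_unit$minus != cds_unit$minus) return("frameshift")
  ph_o <- .unit_phase(orf_unit, probes)
  ph_c <- .unit_phase(cds_unit, probes)
  if (all(!is.na(ph_o) & !is.na(ph_c) & ph_o == ph_c)) "in_frame"
  else "frameshift"
}

## GRanges wrapper kept for internal callers that already hold GRanges.
local_to_genomic <- function(feature, lstart, lend) {
  u <- .unit_local_to_genomic(.unit_from_gr(feature), lstart, lend)
  if (!length(u$start)) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(u$chrom, IRanges::IRanges(u$start, u$end),
                         strand = if (u$minus) "-" else "+")
}

#' Classify an ORF's overlap with annotated coding sequence
#'
#' Returns `"none"` when the ORF shares no bases with the CDS, `"in_frame"`
#' when every shared base has the same codon phase in the ORF and in the CDS
#' (same strand), and `"frameshift"` otherwise (including opposite-strand
#' overlap, where phases are not comparable).
#'
#' @param orf_gr `GRanges` of the ORF's genomic piece(s).
#' @param cds_gr `GRanges` of the CDS piece(s) of one transcript.
#' @return One of `"none"`, `"frameshift"`, `"in_frame"`.
#' @export
classify_cds_overlap <- function(orf_gr, cds_gr) {
  if (!length(orf_gr) || !length(cds_gr)) return("none")
  ## one probe base per contiguous shared piece suffices: phases advance in
  ## lockstep inside a piece that lies within single pieces of both features
  .classify_overlap_units(.unit_from_gr(orf_gr), .unit_from_gr(cds_gr))
}

#' Select expressed transcripts from a count table
#'
#' A transcript is called expressed when its count reaches `threshold` in
#' every biological replicate (`mode = "every"`, the default, the stricter
#' reading of a per-replicate cutoff) or in at least one (`mode = "any"`).
#'
#' @param expression `data.frame` with column `transcript_id` and one numeric
#'   column per replicate.
#' @param threshold Minimal count (default 10).
#' @param mode `"every"` or `"any"`.
#' @return Character vector of expressed transcript ids.
#' @export
filter_expressed <- function(expression, threshold = 10, mode = c("every", "any")) {
  mode <- match.arg(mode)
  stopifnot(threshold >= 0, "transcript_id" %in% names(expression))
  counts <- as.matrix(expression[, setdiff(names(expression), "transcript_id"),
                                 drop = FALSE])
  if (anyNA(counts)) stop("missing replicate counts")
  ok <- if (mode == "every") apply(counts >= threshold, 1L, all)
        else apply(counts >= threshold, 1L, any)
  expression$transcript_id[ok]
}
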