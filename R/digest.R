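## In-silico hydrolysis: tryptic and nonspecific peptide generation,
## protein chunking for bounded-memory processing, and uniqueness
## aggregation.

.peptide_record <- function(sequence = character(), origin_id = character(),
                            start = integer(), end = integer(),
                            rule = character()) {
  data.table::data.table(sequence = sequence, origin_id = origin_id,
                         start = start, end = end, rule = rule)
}

#' Tryptic digestion with configurable missed cleavages
#'
#' Cleaves after every lysine (K) and arginine (R); fully-tryptic peptides
#' are substrings whose termini are both cleavage sites or protein termini.
#' By default cleavage before proline is not suppressed and the number of
#' missed cleavages is unlimited within the length cap, matching an
#' exhaustive search space; both are configurable.
#'
#' @param protein Single amino-acid string.
#' @param origin_id Identifier stored in the records.
#' @param length_range Integer vector `c(min, max)` peptide length.
#' @param max_missed Maximal internal K/R count (default `Inf`).
#' @param proline_rule Suppress cleavage when the following residue is P?
#' @param drop_x Drop peptides containing `X` (mass undefined)? Default TRUE;
#'   the number dropped is available as attribute `"n_dropped_x"`.
#' @return `data.table` of peptide records (`sequence`, `origin_id`, `start`,
#'   `end`, `rule`, `missed`), positions 1-based inclusive in the protein.
#' @examples
#' tryptic_digest("AAKGGGRCC", length_range = c(1, 30), max_missed = 0)
#' @export
tryptic_digest <- function(protein, origin_id = "protein",
                           length_range = c(5L, 30L), max_missed = Inf,
                           proline_rule = FALSE, drop_x = TRUE) {
  stopifnot(nchar(protein) > 0L)
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  L <- length(chars)
  sites <- which(chars %in% c("K", "R"))
  if (proline_rule && length(sites))
    sites <- sites[!(sites < L & chars[sites + 1L] == "P")]
  bounds <- unique(c(0L, sites[sites < L], L))  # positions after which cuts occur
  nb <- length(bounds)
  if (nb < 2L) return(.peptide_record())
  ii <- rep(seq_len(nb - 1L), times = (nb - 1L):1L)
  jj <- unlist(lapply(seq_len(nb - 1L), function(i) (i + 1L):nb))
  start <- bounds[ii] + 1L
  end <- bounds[jj]
  missed <- jj - ii - 1L
  len <- end - start + 1L
  keep <- len >= length_range[1] & len <= length_range[2] & missed <= max_missed
  if (!any(keep)) return(.peptide_record())
  start <- start[keep]; end <- end[keep]; missed <- missed[keep]
  seqs <- substring(protein, start, end)
  out <- .peptide_record(seqs, origin_id, start, end, "tryptic")
  out[, missed := missed]
  .drop_x(out, drop_x)
}

#' Nonspecific sliding-window peptides
#'
#' Every substring of each length in `length_range`, with origin coordinates.
#' For a protein of length L there are exactly `L - N + 1` windows of
#' length N (and one when L equals N).
#'
#' @inheritParams tryptic_digest
#' @return `data.table` of peptide records with `rule = "nonspecific"`.
#' @export
nonspecific_windows <- function(protein, origin_id = "protein",
                                length_range = c(8L, 15L), drop_x = TRUE) {
  L <- nchar(protein)
  recs <- list()
  for (N in seq.int(length_range[1], length_range[2])) {
    if (L < N) next
    start <- seq_len(L - N + 1L)
    recs[[length(recs) + 1L]] <-
      .peptide_record(substring(protein, start, start + N - 1L),
                      origin_id, start, start + N - 1L, "nonspecific")
  }
  out <- if (length(recs)) data.table::rbindlist(recs) else .peptide_record()
  .drop_x(out, drop_x)
}

.drop_x <- function(dt, drop_x) {
  if (!drop_x || !nrow(dt)) {
    data.table::setattr(dt, "n_dropped_x", 0L)
    return(dt[])
  }
  has_x <- grepl("X", dt$sequence, fixed = TRUE)
  out <- dt[!has_x]
  data.table::setattr(out, "n_dropped_x", sum(has_x))
  out[]
}

#' Split a long protein into overlapping chunks
#'
#' Consecutive chunks share exactly `overlap` residues, so every substring of
#' length at most `overlap` is wholly contained in at least one chunk. The
#' default overlap for spliced-peptide generation should be
#' `N_max + Imax` (no spliced peptide spans more residues), with the
#' doubled-intervening convention `2 * Imax` available for compatibility.
#'
#' @param protein Amino-acid string.
#' @param origin_id Identifier.
#' @param max_len Maximal chunk length.
#' @param overlap Residues shared by consecutive chunks (`< max_len`).
#' @return `data.table` with `chunk_id`, `origin_id`, `offset` (0-based
#'   offset of the chunk within the protein) and `sequence`.
#' @export
chunk_protein <- function(protein, origin_id = "protein", max_len, overlap) {
  if (overlap >= max_len) stop("overlap must be smaller than max_len")
  L <- nchar(protein)
  if (L <= max_len) {
    return(data.table::data.table(chunk_id = paste0(origin_id, "_c1"),
                                  origin_id = origin_id, offset = 0L,
                                  sequence = protein))
  }
  step <- max_len - overlap
  starts <- seq.int(1L, L, by = step)
  ## stop once the previous chunk already reaches the protein end
  starts <- starts[c(TRUE, (starts[-length(starts)] + max_len - 1L) < L)]
  keep <- c(TRUE, starts[-1L] + overlap - 1L <= L)  # guard degenerate tail
  starts <- starts[keep]
  ends <- pmin(starts + max_len - 1L, L)
  data.table::data.table(
    chunk_id = paste0(origin_id, "_c", seq_along(starts)),
    origin_id = origin_id, offset = starts - 1L,
    sequence = substring(protein, starts, ends))
}

#' Collapse peptide records to unique sequences plus a mapping table
#'
#' @param records `data.table` of peptide records.
#' @return List with `unique` (character vector of distinct sequences) and
#'   `mapping` (the full record table, every origin/coordinate tuple kept,
#'   exact duplicate rows removed).
#' @export
dedup_peptides <- function(records) {
  if (!nrow(records))
    return(list(unique = character(0), mapping = records))
  mapping <- unique(records)
  list(unique = unique(mapping$sequence), mapping = mapping)
}

#' Partition key of a peptide sequence
#'
#' Storage partitioning uses the first residue for tryptic peptides and the
#' first two residues for nonspecific and spliced peptides.
#'
#' @param sequence Character vector of peptides.
#' @param rule Generation rule (vector or scalar).
#' @return Character vector of prefixes.
#' @export
peptide_prefix <- function(sequence, rule) {
  n <- ifelse(rule == "tryptic", 1L, 2L)
  substring(sequence, 1L, n)
}
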