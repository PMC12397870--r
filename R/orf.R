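#' Discover open reading frames in a nucleotide sequence
#'
#' Scans the three forward frames of `nt_seq`. In each frame, codon positions
#' are classified as start codons (literal match against `start_codons`),
#' stop codons (fuzzy translation equal to `"*"`), or ordinary codons. For
#' every stop codon at most one ORF is reported: the longest one, i.e. the one
#' beginning at the most upstream start codon after the previous stop in that
#' frame. ORFs shorter than `min_aa` residues (stop excluded) are dropped.
#'
#' A trailing open segment with a start codon but no downstream stop is
#' reported with `has_stop = FALSE` when `include_no_stop` is `TRUE`
#' (the default, the permissive choice; such ORFs are flagged so callers can
#' filter them).
#'
#' @param nt_seq Single nucleotide string (IUPAC alphabet).
#' @param start_codons Character vector of start codons.
#' @param min_aa Minimal ORF length in amino acids, stop excluded.
#' @param include_no_stop Keep ORFs running off the 3' end?
#' @return A `data.frame` with columns `start`, `end` (1-based nucleotide
#'   positions of the coding sequence, stop codon excluded), `frame` (0-2),
#'   `aa_seq` (never contains `"*"`; may contain `"X"`), `has_stop`.
#' @examples
#' find_orfs(paste0("ATG", strrep("GCC", 7), "TAA"), min_aa = 8)
#' @export
find_orfs <- function(nt_seq, start_codons = ORF_START_CODONS, min_aa = 8L,
                      include_no_stop = TRUE) {
  stopifnot(is.character(nt_seq), length(nt_seq) == 1L)
  nt_seq <- toupper(nt_seq)
  L <- nchar(nt_seq)
  out <- list()
  for (frame in 0:2) {
    n_cod <- (L - frame) %/% 3L
    if (n_cod < 1L) next
    cod_start <- frame + 1L + 3L * (seq_len(n_cod) - 1L)
    codons <- substring(nt_seq, cod_start, cod_start + 2L)
    aa <- vapply(codons, translate_codon, character(1), USE.NAMES = FALSE)
    is_stop <- aa == "*"
    is_start <- codons %in% start_codons
    stop_idx <- which(is_stop)
    for (s in seq_along(stop_idx)) {
      lo <- if (s == 1L) 1L else stop_idx[s - 1L] + 1L
      hi <- stop_idx[s] - 1L
      if (hi < lo) next
      starts_here <- which(is_start[lo:hi]) + lo - 1L
      if (!length(starts_here)) next
      a <- starts_here[1L]
      len_aa <- stop_idx[s] - a
      if (len_aa < min_aa) next
      out[[length(out) + 1L]] <- data.frame(
        start = cod_start[a], end = cod_start[stop_idx[s]] - 1L,
        frame = frame,
        aa_seq = paste(aa[a:(stop_idx[s] - 1L)], collapse = ""),
        has_stop = TRUE, stringsAsFactors = FALSE)
    }
    if (include_no_stop) {
      lo <- if (length(stop_idx)) stop_idx[length(stop_idx)] + 1L else 1L
      if (lo <= n_cod) {
        starts_here <- which(is_start[lo:n_cod]) + lo - 1L
        if (length(starts_here)) {
          a <- starts_here[1L]
          len_aa <- n_cod - a + 1L
          if (len_aa >= min_aa) {
            out[[length(out) + 1L]] <- data.frame(
              start = cod_start[a], end = cod_start[n_cod] + 2L,
              frame = frame,
              aa_seq = paste(aa[a:n_cod], collapse = ""),
              has_stop = FALSE, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(), frame = integer(),
                      aa_seq = character(), has_stop = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Generalized Levenshtein edit distance
#'
#' Minimal number of single-character insertions, deletions and substitutions
#' turning `a` into `b`. Delegates to [utils::adist()].
#'
#' @param a,b Character strings (vectorized over pairs).
#' @return Integer distance(s).
#' @export
edit_distance <- function(a, b) {
  as.integer(diag(utils::adist(a, b)))
}

#' Tag the main ORF frame of a transcript by edit distance
#'
#' Translates the transcript in all six frames and returns the index (0-5) of
#' the frame whose translation has minimal edit distance to the reference
#' protein. Frames 0-2 are forward, 3-5 reverse-complement. Ties are broken
#' toward the lowest frame index and reported via the `"tie"` attribute.
#'
#' @param reference_protein Reference amino-acid string.
#' @param transcript_nt Transcript nucleotide string (length >= 3).
#' @return Integer frame index in 0..5, with attributes `"distance"` (the six
#'   distances) and `"tie"` (logical).
#' @export
detect_main_orf <- function(reference_protein, transcript_nt) {
  stopifnot(nchar(transcript_nt) >= 3L)
  frames <- six_frame_translations(transcript_nt)
  d <- vapply(frames, function(f) edit_distance(f, reference_protein), integer(1))
  best <- which.min(d) - 1L   # which.min takes the first minimum -> lowest index
  tie <- sum(d == min(d)) > 1L
  if (tie)
    message("detect_main_orf: tie between frames ",
            paste(which(d == min(d)) - 1L, collapse = ","),
            "; choosing frame ", best)
  structure(best, distance = d, tie = tie)
}
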