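## Fuzzy codon translation.
##
## Codons containing IUPAC ambiguity letters are translated only when every
## expansion agrees on a single residue (or when every expansion is a stop);
## otherwise they become X. The stop sentinel is "*".

IUPAC_MAP <- c(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

.codon_env <- new.env(parent = emptyenv())

## Translate one codon (possibly ambiguous) to a single residue, "*" or "X".
translate_codon <- function(codon) {
  cached <- .codon_env[[codon]]
  if (!is.null(cached)) return(cached)
  letters3 <- strsplit(codon, "", fixed = TRUE)[[1]]
  exp <- IUPAC_MAP[letters3]
  if (anyNA(exp)) stop("illegal nucleotide in codon: ", codon)
  combos <- expand.grid(strsplit(exp[1], "")[[1]],
                        strsplit(exp[2], "")[[1]],
                        strsplit(exp[3], "")[[1]],
                        stringsAsFactors = FALSE)
  codons <- paste0(combos[[1]], combos[[2]], combos[[3]])
  aas <- unique(unname(Biostrings::GENETIC_CODE[codons]))
  out <- if (length(aas) == 1L) aas else "X"
  .codon_env[[codon]] <- out
  out
}

#' Translate a nucleotide sequence with fuzzy-codon handling
#'
#' Translates `nt_seq` in frame 0 using the standard genetic code. Codons
#' containing IUPAC ambiguity characters are resolved when all expansions
#' encode the same residue (e.g. `"GCN"` is always alanine) or are all stop
#' codons; truly ambiguous codons translate to `"X"`. Stop codons are rendered
#' as `"*"`. A trailing partial codon is dropped with a warning.
#'
#' @param nt_seq A single nucleotide string over the IUPAC alphabet.
#' @return Single amino-acid string (may contain `"X"` and `"*"`).
#' @examples
#' translate_fuzzy("GCNATGTAA")  # "AM*"
#' @export
translate_fuzzy <- function(nt_seq) {
  stopifnot(is.character(nt_seq), length(nt_seq) == 1L)
  nt_seq <- toupper(nt_seq)
  n <- nchar(nt_seq)
  if (n %% 3L != 0L) {
    warning("sequence length not divisible by 3; trailing partial codon dropped")
    n <- n - (n %% 3L)
  }
  if (n == 0L) return("")
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(nt_seq, starts, starts + 2L)
  bad <- !grepl("^[ACGTURYSWKMBDHVN]{3}$", codons)
  if (any(bad)) stop("illegal character in codon(s): ",
                     paste(unique(codons[bad]), collapse = ", "))
  paste(vapply(codons, translate_codon, character(1)), collapse = "")
}

#' Reverse complement of a nucleotide string
#'
#' IUPAC-aware reverse complement (thin wrapper around Biostrings).
#'
#' @param nt_seq Single nucleotide string.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(nt_seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt_seq)))
}

#' Six-frame translations of a transcript
#'
#' Frames 0-2 translate the forward sequence at offsets 0, 1, 2; frames 3-5
#' translate the reverse complement at offsets 0, 1, 2. Trailing partial
#' codons are dropped silently.
#'
#' @param nt_seq Single nucleotide string.
#' @return Character vector of 6 translations, names `"0"`..`"5"`.
#' @export
six_frame_translations <- function(nt_seq) {
  nt_seq <- toupper(nt_seq)
  rc <- revcomp(nt_seq)
  frames <- character(6)
  for (f in 0:5) {
    s <- if (f < 3L) substring(nt_seq, f + 1L) else substring(rc, f - 2L)
    n <- nchar(s) - (nchar(s) %% 3L)
    frames[f + 1L] <- if (n > 0L)
      suppressWarnings(translate_fuzzy(substr(s, 1L, n))) else ""
  }
  names(frames) <- as.character(0:5)
  frames
}
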