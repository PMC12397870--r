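# Independent brute-force oracles. These deliberately re-derive results from
# first principles (exhaustive enumeration, textbook DP) and share no code
# with the implementation they check.

# Levenshtein distance by the textbook dynamic program.
dp_edit_distance <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  d <- matrix(0L, length(x) + 1L, length(y) + 1L)
  d[, 1] <- 0:length(x); d[1, ] <- 0:length(y)
  for (i in seq_along(x)) for (j in seq_along(y))
    d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                           d[i, j] + (x[i] != y[j]))
  d[length(x) + 1L, length(y) + 1L]
}

# Fuzzy codon translation by explicit expansion of IUPAC codes.
iupac_expand <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
                  S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT",
                  D = "AGT", H = "ACT", V = "ACG", N = "ACGT")
.oracle_codon_cache <- new.env(parent = emptyenv())
oracle_codon <- function(codon) {
  v <- .oracle_codon_cache[[codon]]
  if (!is.null(v)) return(v)
  ch <- strsplit(codon, "")[[1]]
  opts <- lapply(ch, function(c) strsplit(iupac_expand[[c]], "")[[1]])
  aa <- unique(apply(expand.grid(opts), 1, function(r)
    Biostrings::GENETIC_CODE[[paste(r, collapse = "")]]))
  aa <- if (length(aa) == 1L) aa else "X"
  assign(codon, aa, .oracle_codon_cache)
  aa
}

# ORF scanner oracle: enumerate every start-codon position, extend codon by
# codon to the first stop, group by (frame, stop), keep the most upstream
# start; optionally report run-off ORFs without a stop.
oracle_find_orfs <- function(nt, starts = c("ATG", "CTG", "GTG", "ATC", "ACG"),
                             min_aa = 8L, include_no_stop = TRUE) {
  L <- nchar(nt)
  found <- list()
  for (p in seq_len(max(L - 2L, 0L))) {
    if (!substr(nt, p, p + 2L) %in% starts) next
    q <- p; stopped <- FALSE
    while (q + 2L <= L) {
      if (oracle_codon(substr(nt, q, q + 2L)) == "*") { stopped <- TRUE; break }
      q <- q + 3L
    }
    # q = start of the stop codon, or of the first codon that no longer fits
    n_aa <- (q - p) %/% 3L
    if (n_aa < min_aa) next
    if (!stopped && !include_no_stop) next
    key <- paste0("f", (p - 1L) %% 3L, "_",
                  if (stopped) paste0("stop", q) else "nostop")
    if (is.null(found[[key]]) || p < found[[key]]$start)
      found[[key]] <- list(start = p, end = q - 1L,
                           frame = (p - 1L) %% 3L, has_stop = stopped)
  }
  out <- do.call(rbind, lapply(found, function(f)
    data.frame(start = f$start, end = f$end, frame = f$frame,
               has_stop = f$has_stop)))
  if (is.null(out)) data.frame(start = integer(), end = integer(),
                               frame = integer(), has_stop = logical()) else
    out[order(out$frame, out$start), , drop = FALSE]
}

# Tryptic digestion oracle: enumerate all substrings, keep those with valid
# termini and missed-cleavage count.
oracle_tryptic <- function(protein, length_range = c(1L, 100L),
                           max_missed = Inf, proline_rule = FALSE) {
  ch <- strsplit(protein, "")[[1]]; L <- length(ch)
  is_site <- ch %in% c("K", "R")
  if (proline_rule) is_site <- is_site & !(c(ch[-1], "") == "P")
  res <- character(0)
  for (i in seq_len(L)) for (j in i:L) {
    len <- j - i + 1L
    if (len < length_range[1] || len > length_range[2]) next
    nterm_ok <- i == 1L || is_site[i - 1L]
    cterm_ok <- j == L || is_site[j]
    if (!nterm_ok || !cterm_ok) next
    missed <- if (j > i) sum(is_site[i:(j - 1L)]) else 0L
    if (missed > max_missed) next
    res <- c(res, paste(ch[i:j], collapse = ""))
  }
  res
}

# All-pairs MW filter oracle.
oracle_mw <- function(masses, obs, ppm) {
  vapply(masses, function(m) any(abs(m - obs) <= ppm * 1e-6 * obs), logical(1))
}

# All-pairs joint MW+RT oracle (one observation must satisfy both).
oracle_mw_rt <- function(masses, rt_pred, obs_mass, obs_rt, ppm, rt_tol) {
  vapply(seq_along(masses), function(i) {
    if (is.na(rt_pred[i]))
      return(any(abs(masses[i] - obs_mass) <= ppm * 1e-6 * obs_mass))
    any(abs(masses[i] - obs_mass) <= ppm * 1e-6 * obs_mass &
          abs(rt_pred[i] - obs_rt) <= rt_tol)
  }, logical(1))
}

# Reference q-value computation: per-threshold counting without any
# sorting tricks.
oracle_qvalues <- function(score, is_decoy) {
  fdr_at <- function(s) {
    d <- sum(is_decoy & score >= s); t <- sum(!is_decoy & score >= s)
    d / max(1, t)
  }
  fdr <- vapply(score, fdr_at, numeric(1))
  q <- vapply(score, function(s) min(fdr[score <= s]), numeric(1))
  pmin(q, 1)
}

random_protein <- function(n, residues = amino_acids()) {
  paste(sample(residues, n, replace = TRUE), collapse = "")
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
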