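## Proteasome-catalyzed peptide splicing: coordinate-index construction and
## spliced-sequence generation. A spliced peptide is the concatenation of two
## disjoint contiguous substrate fragments ("splice reactants"); the first
## reactant (i..j) forms the peptide N-terminus. Forward cis keeps substrate
## order (k > j, intervening gap k-j-1 in [1, Imax]); reverse cis inverts it
## (i > n, gap i-n-1 in [0, Imax]). Gap 0 is illegal in forward ligation
## (it would reproduce a non-spliced substring) but legal in reverse.

#' Precompute splice-reactant coordinate tuples
#'
#' Enumerates all `(i, j, k, n)` tuples valid for a substrate of length `L`,
#' peptide length `N`, minimal reactant length `Lext` and maximal intervening
#' sequence length `Imax`. The index is computed once for the longest
#' substrate and can be reused for shorter ones by filtering tuples whose
#' coordinates exceed the shorter length (see [filter_splice_index()]).
#'
#' @param L Substrate length.
#' @param N Peptide length.
#' @param Lext Minimal splice-reactant length (default 1).
#' @param Imax Maximal intervening length; `Inf` for no cap (default 25).
#' @param direction `"forward"` or `"reverse"`.
#' @return `data.table` with integer columns `i`, `j`, `k`, `n`.
#' @export
build_splice_index <- function(L, N, Lext = 1L, Imax = 25, direction) {
  direction <- match.arg(direction, c("forward", "reverse"))
  empty <- data.table::data.table(i = integer(), j = integer(),
                                  k = integer(), n = integer())
  if (N < 2L * Lext || L < N) return(empty)
  gmax <- if (is.finite(Imax)) Imax else L
  res <- vector("list", N - 2L * Lext + 1L)
  idx <- 0L
  for (a in Lext:(N - Lext)) {        # first-reactant length
    b <- N - a
    idx <- idx + 1L
    if (direction == "forward") {
      gmin <- 1L
      if (gmax < gmin) next
      grid <- data.table::CJ(i = seq_len(L), g = seq.int(gmin, gmax))
      grid[, j := i + a - 1L]
      grid[, k := j + 1L + g]
      grid[, n := k + b - 1L]
    } else {
      gmin <- 0L
      grid <- data.table::CJ(k = seq_len(L), g = seq.int(gmin, gmax))
      grid[, n := k + b - 1L]
      grid[, i := n + 1L + g]
      grid[, j := i + a - 1L]
    }
    res[[idx]] <- grid[i >= 1L & j <= L & k >= 1L & n <= L,
                       list(i, j, k, n)]
  }
  out <- data.table::rbindlist(res[!vapply(res, is.null, logical(1))])
  if (!nrow(out)) return(empty)
  data.table::setorder(out, i, j, k, n)
  out[]
}

#' Restrict a splice index to a shorter substrate
#'
#' @param index Index from [build_splice_index()].
#' @param L Substrate length to restrict to.
#' @return Filtered `data.table`.
#' @export
filter_splice_index <- function(index, L) {
  index[index$i <= L & index$j <= L & index$k <= L & index$n <= L]
}

#' Intervening sequence length of a splice event
#'
#' Forward cis: distance between `j` and `k` (`k - j - 1`); reverse cis:
#' distance between `n` and `i` (`i - n - 1`). Overlapping reactants are an
#' error.
#'
#' @param sr_coords Numeric vector or list `(i, j, k, n)`, or a `data.frame`
#'   with those columns (vectorized).
#' @param direction `"forward"` or `"reverse"`.
#' @return Integer intervening length(s).
#' @export
intervening_length <- function(sr_coords, direction) {
  direction <- match.arg(direction, c("forward", "reverse"))
  if (is.data.frame(sr_coords)) {
    i <- sr_coords$i; j <- sr_coords$j; k <- sr_coords$k; n <- sr_coords$n
  } else {
    i <- sr_coords[[1]]; j <- sr_coords[[2]]
    k <- sr_coords[[3]]; n <- sr_coords[[4]]
  }
  gap <- if (direction == "forward") k - j - 1L else i - n - 1L
  if (any(gap < if (direction == "forward") 1L else 0L))
    stop("overlapping or adjacent reactants: invalid ", direction, " tuple")
  as.integer(gap)
}

#' Generate cis-spliced peptides from one substrate
#'
#' Applies a splice-reactant coordinate index to the protein sequence:
#' each record's sequence is `substr(protein, i, j)` concatenated with
#' `substr(protein, k, n)`.
#'
#' @param protein Amino-acid string.
#' @param origin_id Identifier stored in the records.
#' @param N Peptide length.
#' @param Lext Minimal reactant length.
#' @param Imax Maximal intervening length (`Inf` allowed).
#' @param direction `"forward"`, `"reverse"` or `"both"`.
#' @param index Optional precomputed index list
#'   (`list(forward = , reverse = )`) for a substrate at least this long.
#' @param drop_x Drop peptides containing `X`?
#' @return `data.table` of peptide records with `sr_i`, `sr_j`, `sr_k`,
#'   `sr_n`, `intervening`, `direction`, `rule = "cis_spliced"`.
#' @export
generate_cis_spliced <- function(protein, origin_id = "protein", N,
                                 Lext = 1L, Imax = 25, direction = "both",
                                 index = NULL, drop_x = TRUE) {
  L <- nchar(protein)
  dirs <- if (direction == "both") c("forward", "reverse") else
    match.arg(direction, c("forward", "reverse"))
  recs <- list()
  for (d in dirs) {
    idx <- if (!is.null(index) && !is.null(index[[d]]))
      filter_splice_index(index[[d]], L)
    else build_splice_index(L, N, Lext, Imax, d)
    if (!nrow(idx)) next
    seqs <- paste0(substring(protein, idx$i, idx$j),
                   substring(protein, idx$k, idx$n))
    dt <- data.table::data.table(
      sequence = seqs, origin_id = origin_id,
      start = NA_integer_, end = NA_integer_, rule = "cis_spliced",
      sr_i = idx$i, sr_j = idx$j, sr_k = idx$k, sr_n = idx$n,
      intervening = intervening_length(idx, d), direction = d)
    recs[[d]] <- dt
  }
  out <- if (length(recs)) data.table::rbindlist(recs) else
    data.table::data.table(sequence = character(), origin_id = character(),
                           start = integer(), end = integer(),
                           rule = character(), sr_i = integer(),
                           sr_j = integer(), sr_k = integer(),
                           sr_n = integer(), intervening = integer(),
                           direction = character())
  .drop_x(out, drop_x)
}

#' Generate trans-spliced peptides between two substrates
#'
#' First reactant from `proteinA`, second from `proteinB`; first-reactant
#' lengths run over `[max(Lext, N - L2), min(L1, N - Lext)]`. Provided for
#' testing and counting; the pipeline counts trans events analytically.
#'
#' @param proteinA,proteinB Amino-acid strings with distinct origins.
#' @param originA,originB Origin identifiers (must differ).
#' @param N Peptide length.
#' @param Lext Minimal reactant length.
#' @param drop_x Drop peptides containing `X`?
#' @return `data.table` of records with `rule = "trans_spliced"`.
#' @export
generate_trans_spliced <- function(proteinA, proteinB, originA = "A",
                                   originB = "B", N, Lext = 1L,
                                   drop_x = TRUE) {
  if (identical(originA, originB)) stop("trans splicing requires distinct origins")
  L1 <- nchar(proteinA); L2 <- nchar(proteinB)
  sr1min <- max(Lext, N - L2); sr1max <- min(L1, N - Lext)
  empty <- data.table::data.table(sequence = character(),
                                  origin_id = character(),
                                  origin2_id = character(),
                                  rule = character(), sr_i = integer(),
                                  sr_j = integer(), sr_k = integer(),
                                  sr_n = integer())
  if (sr1min > sr1max) return(.drop_x(empty, drop_x))
  recs <- list()
  for (a in sr1min:sr1max) {
    b <- N - a
    iA <- seq_len(L1 - a + 1L)
    kB <- seq_len(L2 - b + 1L)
    grid <- data.table::CJ(i = iA, k = kB)
    recs[[length(recs) + 1L]] <- data.table::data.table(
      sequence = paste0(substring(proteinA, grid$i, grid$i + a - 1L),
                        substring(proteinB, grid$k, grid$k + b - 1L)),
      origin_id = originA, origin2_id = originB, rule = "trans_spliced",
      sr_i = grid$i, sr_j = grid$i + a - 1L,
      sr_k = grid$k, sr_n = grid$k + b - 1L)
  }
  .drop_x(data.table::rbindlist(recs), drop_x)
}

#' Brute-force count of splice events (enumeration oracle)
#'
#' Literal quadruple-loop count of valid `(i, j, k, n)` tuples, implemented
#' in C++ for speed. Independent of [build_splice_index()] and of the
#' closed-form counts; used to validate both.
#'
#' @param L Substrate length (at most 200).
#' @param N Peptide length.
#' @param Lext Minimal reactant length.
#' @param Imax Maximal intervening length (`Inf` allowed).
#' @param direction `"forward"` or `"reverse"`.
#' @return Numeric count.
#' @export
enumerate_splice_events <- function(L, N, Lext = 1L, Imax = Inf, direction) {
  direction <- match.arg(direction, c("forward", "reverse"))
  enum_cis_events_cpp(as.integer(L), as.integer(N), as.integer(Lext),
                      as.numeric(Imax), direction)
}

#' Brute-force count of trans-splicing events
#'
#' @param L1,L2 Substrate lengths (at most 200).
#' @param N Peptide length.
#' @param Lext Minimal reactant length.
#' @return Numeric count.
#' @export
enumerate_trans_events <- function(L1, L2, N, Lext = 1L) {
  enum_trans_events_cpp(as.integer(L1), as.integer(L2), as.integer(N),
                        as.integer(Lext))
}
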