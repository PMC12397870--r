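## Closed-form counting of peptide-generation events.
##
## The Imax-restricted closed forms apply when the intervening-length cap
## actually binds, i.e. when Imax < L - N (the maximal achievable gap);
## otherwise the unrestricted forms apply. The two branches coincide at
## Imax = L - N. This branch assignment is validated exhaustively against
## the enumeration oracle (see tests); counts are returned as doubles since
## proteome-scale totals exceed integer range.

.w <- function(N, Lext) N - 2 * Lext + 1   # number of reactant-length splits

#' Count non-spliced peptides of length N in a substrate of length L
#'
#' `L - N + 1` for `L >= N`, `0` otherwise.
#'
#' @param L Substrate length(s).
#' @param N Peptide length(s).
#' @return Numeric count(s); vectorized.
#' @export
count_nonspliced <- function(L, N) {
  ifelse(L < N, 0, L - N + 1)
}

#' Count forward cis-spliced peptide events
#'
#' Unrestricted: `(N - 2 Lext + 1)(L - N)(L - N + 1) / 2`. With a binding
#' intervening cap (`Imax < L - N`):
#' `-Imax (N - 2 Lext + 1)(Imax - 2L + 2N - 1) / 2`.
#'
#' @param L Substrate length.
#' @param N Peptide length.
#' @param Lext Minimal splice-reactant length (default 1).
#' @param Imax Maximal intervening length; `Inf` for unrestricted.
#' @return Numeric event count.
#' @export
count_cis_forward <- function(L, N, Lext = 1, Imax = Inf) {
  if (N < 2 * Lext || L < N) return(0)
  w <- .w(N, Lext)
  if (is.finite(Imax) && Imax < L - N)
    -0.5 * Imax * w * (Imax - 2 * L + 2 * N - 1)
  else
    0.5 * w * (L - N) * (L - N + 1)
}

#' Count reverse cis-spliced peptide events
#'
#' Unrestricted: `(N - 2 Lext + 1)(L - N + 1)(L - N + 2) / 2`. With a binding
#' cap: `(N - 2 Lext + 1)(Imax + 1)(1 - Imax/2 + L - N)`.
#'
#' @inheritParams count_cis_forward
#' @return Numeric event count.
#' @export
count_cis_reverse <- function(L, N, Lext = 1, Imax = Inf) {
  if (N < 2 * Lext || L < N) return(0)
  w <- .w(N, Lext)
  if (is.finite(Imax) && Imax < L - N)
    w * (Imax + 1) * (1 - 0.5 * Imax + L - N)
  else
    0.5 * w * (L - N + 1) * (L - N + 2)
}

#' Count all cis-spliced peptide events (forward + reverse)
#'
#' @inheritParams count_cis_forward
#' @return Numeric event count.
#' @export
count_cis_total <- function(L, N, Lext = 1, Imax = Inf) {
  count_cis_forward(L, N, Lext, Imax) + count_cis_reverse(L, N, Lext, Imax)
}

#' Count trans-spliced peptide events between two substrates
#'
#' Explicit sum over first-reactant lengths
#' `SR1` in `[max(Lext, N - L2), min(L1, N - Lext)]` of
#' `(L1 - SR1 + 1)(L2 - N + SR1 + 1)`, clamped at zero when the range is
#' empty.
#'
#' @param L1,L2 Substrate lengths.
#' @param N Peptide length.
#' @param Lext Minimal splice-reactant length.
#' @return Numeric event count.
#' @export
count_trans <- function(L1, L2, N, Lext = 1) {
  sr1min <- max(Lext, N - L2)
  sr1max <- min(L1, N - Lext)
  if (sr1min > sr1max) return(0)
  sr1 <- sr1min:sr1max
  max(0, sum((L1 - sr1 + 1) * (L2 - N + sr1 + 1)))
}

#' Closed-form expansion of the trans-splicing count
#'
#' Polynomial expansion of the explicit sum in [count_trans()]; kept as an
#' independent algebraic cross-check.
#'
#' @inheritParams count_trans
#' @return Numeric event count.
#' @export
count_trans_closed <- function(L1, L2, N, Lext = 1) {
  a <- max(Lext, N - L2)   # SR1min
  b <- min(L1, N - Lext)   # SR1max
  if (a > b) return(0)
  x <- -(1 / 6) * (1 + b - a) *
    (-6 - 6 * L1 - 6 * L2 - 6 * L1 * L2 +
       b - 3 * L1 * b + 3 * L2 * b + 2 * b^2 -
       a - 3 * L1 * a + 3 * L2 * a + 2 * b * a + 2 * a^2 +
       6 * N + 6 * L1 * N - 3 * b * N - 3 * a * N)
  max(0, x)
}

#' Expected number of unique spliced sequences (finite-alphabet upper bound)
#'
#' Under independent sampling with replacement of `M` splicing events from
#' the `20^N` possible length-`N` sequences, the expected number of distinct
#' sequences is `20^N (1 - (1 - 20^-N)^M)`. Evaluated in log space via
#' `expm1`/`log1p`, which avoids the catastrophic cancellation that direct
#' evaluation suffers for large `M` and `N`; accurate to better than 1e-12
#' relative error over the supported range. An upper bound only: it accounts
#' for finite-sampling redundancy, not for splicing specificity or residue
#' composition.
#'
#' @param N Peptide length (>= 1).
#' @param M Number of splicing events (non-negative; may exceed 1e15).
#' @param alphabet_size Residue alphabet size (default 20; configurable for
#'   toy alphabets).
#' @return Numeric expectation in `[0, min(M, alphabet_size^N)]`.
#' @examples
#' expected_unique(1, 2)   # 20 * (1 - (19/20)^2) = 1.95
#' @export
expected_unique <- function(N, M, alphabet_size = AA_ALPHABET_SIZE) {
  stopifnot(N >= 1, M >= 0)
  S <- alphabet_size^N
  ## 1 - (1 - 1/S)^M, cancellation-free
  S * (-expm1(M * log1p(-1 / S)))
}

#' Tabulate search-space counts over a parameter grid
#'
#' Convenience wrapper producing the inflation curves of theoretical peptide
#' counts over user grids of substrate length, peptide length, minimal
#' reactant length and intervening cap.
#'
#' @param L,N,Lext,Imax Numeric vectors; the full cross product is tabulated.
#' @return `data.table` with columns `L`, `N`, `Lext`, `Imax`,
#'   `nonspliced`, `cis_forward`, `cis_reverse`, `cis_total`.
#' @export
count_grid <- function(L, N, Lext = 1, Imax = Inf) {
  grid <- data.table::CJ(L = L, N = N, Lext = Lext, Imax = Imax)
  grid[, nonspliced := count_nonspliced(L, N)]
  grid[, cis_forward := mapply(count_cis_forward, L, N, Lext, Imax)]
  grid[, cis_reverse := mapply(count_cis_reverse, L, N, Lext, Imax)]
  grid[, cis_total := cis_forward + cis_reverse]
  grid[]
}
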