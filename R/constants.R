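#' @useDynLib pepspace, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

## Monoisotopic residue masses (Da), standard 20 amino acids.
## All mass constants live here; nothing else hardcodes a mass.
AA_MONO <- c(
  G = 57.02146372, A = 71.03711381, S = 87.03202844, P = 97.05276385,
  V = 99.06841395, T = 101.04767847, C = 103.00918448, L = 113.08406398,
  I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857751,
  K = 128.09496302, E = 129.04259309, M = 131.04048509, H = 137.05891186,
  F = 147.06841391, R = 156.10111102, Y = 163.06332853, W = 186.07931295
)

MASS_WATER  <- 18.0105646863
MASS_PROTON <- 1.00727646688

## Size of the amino-acid alphabet used by the expected-unique upper bound.
AA_ALPHABET_SIZE <- 20L

#' Standard amino-acid alphabet
#'
#' The 20 standard residue letters, in the order used by the internal
#' monoisotopic mass table.
#'
#' @return Character vector of 20 single-letter residue codes.
#' @export
amino_acids <- function() names(AA_MONO)

#' Monoisotopic mass constants
#'
#' Returns the residue monoisotopic masses together with the water and proton
#' masses used throughout mass computation and precursor handling.
#'
#' @return A list with elements `residues` (named numeric vector of 20 residue
#'   masses in Da), `water` and `proton` (Da).
#' @export
mass_constants <- function() {
  list(residues = AA_MONO, water = MASS_WATER, proton = MASS_PROTON)
}

## Start codons used for ORF discovery on (non-)canonical strata.
ORF_START_CODONS <- c("ATG", "CTG", "GTG", "ATC", "ACG")

STRATA_LEVELS <- c("cds_main", "cds_offframe", "utr5", "utr3", "intron",
                   "intergenic", "lncRNA")
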