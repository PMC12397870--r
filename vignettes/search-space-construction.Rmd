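---
title: "Constructing and pre-filtering proteogenomic search spaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and pre-filtering proteogenomic search spaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepspace)
```

## The problem

Standard proteomic search engines match MS2 spectra against a database of
candidate peptides. For HLA class I immunopeptidomics the candidate space is
not the canonical proteome: presented 8–15-mers arise from noncanonical open
reading frames (off-frame CDS, UTRs, introns, intergenic regions, lncRNA)
and from proteasome-catalyzed peptide splicing (PCPS), which ligates two
non-contiguous fragments of one substrate (cis) or of two substrates
(trans). Enumerated exhaustively, these strata inflate the search space by
many orders of magnitude, degrading both sensitivity and FDR estimation.
`pepspace` builds those strata explicitly, counts them analytically, and
shrinks them with data-driven filters (observed precursor masses, calibrated
retention-time prediction, HLA-binding prediction) before any search engine
is involved.

## Strata construction

`parse_annotation()` reads a GENCODE-dialect GTF via `rtracklayer` (GTF is
1-based inclusive; all interval arithmetic stays on `GRanges`, so no
coordinate-convention conversion leaks out of the parser). Introns are
derived as exonic complements per transcript, intergenic regions as the
chromosome minus the union of gene spans (strandless; both strands are
scanned), and lncRNA transcripts are flagged from the biotype attribute.

ORF discovery (`find_orfs()`) scans the three forward frames of each
feature sequence for ORFs beginning at `ATG`, `CTG`, `GTG`, `ATC` or `ACG`
and reports, per stop codon, only the longest ORF (the most upstream start
after the previous stop), at least 8 amino acids long. Translation is
"fuzzy": IUPAC-ambiguous codons are translated when all expansions agree
(e.g. `GCN` → A) or are all stops, and are `X` otherwise. Three choices here
were genuinely open and are resolved as follows:

* **ORFs running off the 3' end** (no stop codon) are reported with a
  `has_stop = FALSE` flag and included by default — the permissive choice;
  callers filter on the flag.
* **Minimum ORF length counts amino acids excluding the stop**, and the stop
  sentinel `*` never appears in a stored protein.
* **Selenocysteine and readthrough** are not modelled; `U` is mapped to `X`
  (whose peptides are then dropped at generation, since their mass is
  undefined).

Overlap with annotated CDS is classified per ORF as `none`, `frameshift` or
`in_frame` by comparing codon phase on every shared base, with phase counted
in transcription order through multi-exon features. Opposite-strand overlap
is classified `frameshift` (overlapping but never comparable in phase). ORFs
rescanned from CDS sequences contribute the `cds_offframe` stratum only when
frameshifted — in-frame hits are fragments of the main product. The main-ORF
tag itself uses the generalized Levenshtein distance between a reference
protein and all six frame translations (`detect_main_orf()`), ties broken
toward the lowest frame index and logged.

Post-processing removes exact duplicates (identical id and sequence, the
X/Y pseudo-autosomal case) and proteins shorter than 5 residues. Expression
gating keeps transcripts with at least 10 counts in **every** biological
replicate — the stricter reading of a per-replicate cutoff; `mode = "any"`
is available since the looser reading is defensible. Intergenic ORFs carry
no transcript and are never expression-gated.

## Peptide generation

Tryptic digestion cleaves after K/R. Two deliberate defaults differ from
conventional proteomics: cleavage before proline is **not** suppressed (a
`proline_rule` flag restores it), and missed cleavages are unlimited within
the length cap, because the object being built is an exhaustive search
space, not a digest prediction. Nonspecific peptides are sliding windows of
each length in range — exactly `L − N + 1` per length.

Cis-spliced peptides are generated from a precomputed coordinate index:
each event is a 4-tuple `(i, j, k, n)` bounding the two splice reactants,
and a peptide is two `substring` operations plus a concatenation. The index
is computed once for the longest substrate and filtered for shorter ones.
The geometric constraints:

* reactant lengths ≥ `Lext` (default 1) and summing to `N`;
* reactant intervals disjoint — one substrate molecule cannot reuse
  residues;
* forward cis: second reactant strictly downstream with intervening gap in
  `[1, Imax]` — gap 0 would reproduce a non-spliced substring;
* reverse cis: first reactant downstream of the second with gap in
  `[0, Imax]` — adjacent reverse concatenation is a genuine rearrangement.
  The reverse closed form at `L = N` equals `N − 2·Lext + 1 > 0`, which is
  only reachable if gap 0 is legal, confirming the convention.

Long proteins are chunked with an overlap of `N_max + Imax` so that no
spliced peptide can span farther than one chunk; the doubled-intervening
convention `2·Imax` is available for compatibility (the two coincide
whenever `Imax ≥ N_max`). Chunked generation followed by deduplication is
tested to equal whole-protein generation.

Trans-spliced generation (first reactant from substrate A, second from B)
is implemented for testing and counting but is off in the pipeline: trans
spaces are astronomically large and are treated analytically.

## Analytic counts

For substrate length `L`, peptide length `N`, minimal reactant `Lext` and
intervening cap `Imax`, with `w = N − 2·Lext + 1`:

* non-spliced: `L − N + 1` (1 at `L = N`);
* forward cis, unrestricted: `w (L−N)(L−N+1) / 2`; with a binding cap:
  `−Imax · w · (Imax − 2L + 2N − 1) / 2`;
* reverse cis, unrestricted: `w (L−N+1)(L−N+2) / 2`; with a binding cap:
  `w (Imax + 1)(1 − Imax/2 + L − N)`;
* trans: `Σ (L1 − SR1 + 1)(L2 − N + SR1 + 1)` over first-reactant lengths
  `SR1 ∈ [max(Lext, N−L2), min(L1, N−Lext)]`, clamped at 0.

The restricted forms apply **iff `Imax < L − N`**, i.e. when the cap
actually binds; the branches coincide at `Imax = L − N`. Assigning the
branches the other way yields negative counts on trivially checkable cases,
so the brute-force tuple enumerator (`enumerate_splice_events()`, a literal
quadruple loop in C++) is the authority: the test suite demands exact
agreement over the full grid `L ∈ [2,60]`, `N ∈ [2,15]`, `Lext ∈ {1,2}`,
`Imax ∈ {0,1,2,5,25,∞}`, zero discrepancies tolerated.

The expected number of distinct spliced sequences under `M` independent
events is `20^N (1 − (1 − 20^{-N})^M)` — an upper bound that accounts for
finite-sampling redundancy only. Direct evaluation cancels catastrophically
for large `M`, so it is computed as `20^N · (−expm1(M · log1p(−20^{-N})))`,
which the suite checks against 60-digit decimal arithmetic to better than
1e-12 relative error at `M = 10^16`, `N = 15`. No arbitrary-precision
rational type is carried around; the log-space double path meets the
precision requirement across the supported range, and exact rational
evaluation is used in tests where it is representable (e.g.
`20(1 − (19/20)^2) = 1.95`).

## PTM expansion

`peptide_mass()` is the letter-frequency matrix times the residue
monoisotopic mass vector, plus water (18.0105646863 Da); fixed
residue-targeted deltas fold into the residue mass, fixed terminus-targeted
deltas add once per peptide. All mass constants live in one table. Variable
PTMs expand combinatorially with at most `max_mods = 2` assignments, one
per site; the peptide N-terminus is a site distinct from residue 1's side
chain, so N-terminal acetylation can co-occur with a position-1
modification. Two copies of the same PTM type on two sites are allowed —
any ≤ 2-site assignment counts. Counts are reported with positional isomers
kept or collapsed (distinct multiset of PTM names). Variable-PTM forms are
filtered by mass only; retention-time prediction for arbitrary PTMs is not
reliable and is not attempted.

## Data-driven filters

Precursor observations are reduced to neutral masses
(`charge·mz − charge·1.00727646688`), deduplicated at (1e-5 Da, 1e-3 min)
resolution — duplicates carry no filtering information. The MW filter keeps
a peptide iff its mass falls in a symmetric ppm window around **some
observed** mass (window relative to the observation, matching how detection
uncertainty is specified); it is an interval join that the suite compares
against the all-pairs brute force at 1e4 × 1e3 scale.

The retention-time model is the classic additive composition model:
`RT = intercept + Σ count_r · coef_r`, fitted by least squares and exposed
as an S3 `rt_model` with `print`/`coef`/`predict`/`residuals` methods. The
filtering threshold is estimated by 5-fold cross-validation **split on
unique peptide sequences** (duplicated sequences must not leak across
folds): per fold, the 0.99 quantile of held-out absolute residuals; the
threshold is the fold mean. With Gaussian noise σ the threshold estimates
2.576σ, which the suite verifies within ±15% at σ = 0.5 min, n = 2000, over
20 seeded replicates. Residues absent from calibration are excluded from
the trained set and peptides containing them fall back to MW-only
filtering, flagged. The joint filter requires a **single observation** to
satisfy both the mass and the RT window — "could explain both" read
per-observation; `joint = FALSE` relaxes this to independent windows since
the looser reading is also defensible.

HLA-binding filtering is a pluggable interface: any function
`(sequences, allele) → IC50 nM`. Peptides of 8–15 residues are kept iff the
minimum IC50 over alleles is ≤ 5000 nM; other lengths pass through flagged
as not evaluated. The bundled `toy_hla_predictor()` is a deterministic
position-weight-matrix scorer mapped monotonically to an IC50-like scale —
it reproduces the shape of a binding predictor for tests and examples, not
real binding; production use plugs in an external predictor's tabular
output.

Decoys are reversed protein sequences processed by the identical
generation/filter cascade. Because window counts and residue composition
are reversal-invariant, per-protein unfiltered nonspecific event counts and
mass multisets match between targets and decoys exactly — the property that
makes the strategy fair, and a tested invariant.

## FDR post-processing

`tdc_qvalues()` estimates FDR(s) as `#decoys(score ≥ s) / max(1,
#targets(score ≥ s))` with tie groups sharing their threshold, and q-values
as the running minimum from the most permissive threshold upward. The +1
decoy pseudo-count is off by default and available by flag. The combined
identification strategy keeps, per spectrum, the record with the smaller
q-value, ties resolved toward the canonical database; group-specific FDR
applies the estimator independently within stratum groups. On simulated
two-component score mixtures the empirical FDR at q ≤ 0.01 stays ≤ 0.02
averaged over 100 replicates — a calibration sanity check, not a precision
claim.

## Synthetic data: what it emulates, what it does not

`generate_fixtures()` produces a complete toy study: two chromosomes
(~50 kb total) with multi-exon coding genes on both strands (planted
stop-free CDS, 5'/3'-UTRs, introns), lncRNA genes and intergenic gaps; a
two-replicate expression table with ~20% of transcripts deliberately below
the 10-count cutoff in one replicate; per-run precursor tables whose true
entries are masses of actually generated peptides jittered uniformly within
±2 ppm (inside the 5 ppm search tolerance) with retention times from a
fixed additive truth (`rt_true_model()`) plus N(0, 0.5 min) noise, mixed
with +0.5 Da mass decoys; calibration PSMs from the same chromatography
truth; and a two-component PSM score table (true targets N(12,2), false
targets and decoys N(8,2)). Everything derives from one seed and reruns
byte-identically.

These fixtures exercise coordinate arithmetic, strand handling, filter
calibration and FDR behaviour. They do **not** emulate codon usage, splice
site motifs, homology between paralogs, correlated chromatographic drift,
charge-state-dependent detectability, or realistic score distributions — so
passing tests demonstrate algorithmic correctness on structurally realistic
input, not biological fidelity of any particular rate.

## Problem sizes and numerical choices

Default analysis sizes were chosen so a complete study runs on a laptop
core: fixture genome ~50 kb, coding products ≤ ~150 aa, cis splicing at
N = 9, Imax = 25 restricted to the CDS main-ORF stratum (mirroring the
convention that spliced spaces are only built on the expression-informed
canonical stratum), nonspecific windows 8–12. A full pipeline run completes
in well under five minutes; enumeration oracles cover substrates to L = 60
(the C++ enumerator guards at L = 200). Storage partitions default to
rule/stratum/length with the sequence prefix as a column: the deepest
layout also partitions by prefix (1 leading residue for tryptic,
2 otherwise), which pays off at proteome scale but produces thousands of
near-empty files at toy scale; `write_peptide_store(partitioning = )`
restores the deep layout.

Other numeric conventions: counts are returned as doubles (proteome-scale
totals exceed 32-bit integers); fold assignment in cross-validation is
seeded and recorded in the fitted object; the ppm window is closed
(boundary kept), as is the IC50 threshold.

## Known limitations

* The GTF reader targets the GENCODE/Ensembl attribute dialect
  (`gene_id`, `transcript_id`, `gene_type`/`transcript_type` or
  `*_biotype`); other dialects need renaming upstream.
* PCPS is enumerated, not scored: no biological splicing preference is
  modelled.
* Trans-splicing is counted analytically and generated only for testing.
* The bundled HLA predictor is a stand-in; no real binding model ships with
  the package.
* RNA-seq quantification, transcript assembly, fusion detection and search
  engines are out of scope — inputs arrive as tables/FASTA produced by
  dedicated tools.
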