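# pepspace

Exhaustive proteogenomic search-space construction and data-driven
pre-filtering for mass-spectrometry proteomics and HLA class I
immunopeptidomics.

## The problem

Search engines identify peptides by matching MS2 spectra against a candidate
database. For immunopeptidomics the candidates go far beyond the canonical
proteome: noncanonical open reading frames (off-frame CDS, 5′/3′-UTRs,
introns, intergenic regions, lncRNA) and proteasome-catalyzed peptide
splicing (PCPS) — ligation of two non-contiguous fragments of one substrate
(*cis*) or two substrates (*trans*) — expand the space by orders of
magnitude, hurting both sensitivity and FDR estimation. `pepspace` builds
these strata explicitly, counts them in closed form, and shrinks them with
experiment-driven filters before any search engine runs.

For a substrate of length *L*, peptide length *N*, minimal splice-reactant
length *L*<sub>ext</sub> and intervening-length cap *I*<sub>max</sub>
(with *w* = *N* − 2*L*<sub>ext</sub> + 1):

- non-spliced: *L* − *N* + 1
- forward cis (cap not binding): ½ *w* (*L*−*N*)(*L*−*N*+1)
- reverse cis (cap not binding): ½ *w* (*L*−*N*+1)(*L*−*N*+2)
- trans: Σ (*L*₁−SR1+1)(*L*₂−*N*+SR1+1) over valid first-reactant lengths

with *I*<sub>max</sub>-restricted variants when the cap binds
(*I*<sub>max</sub> < *L* − *N*), and the expected number of distinct spliced
sequences under *M* events bounded by 20^*N* (1 − (1 − 20^−*N*)^*M*).
Every closed form is validated against a brute-force coordinate enumerator.

## What the package does

- **`genome strata`** — `parse_annotation()`, `build_strata()`: GTF + genome
  FASTA → per-stratum protein FASTA (CDS main/off-frame, UTR5/3, intron,
  intergenic, lncRNA), with fuzzy six-frame translation, five-codon start
  set, CDS-overlap phase classification and optional RNA-seq expression
  gating.
- **digestion & splicing** — `tryptic_digest()`, `nonspecific_windows()`,
  `generate_cis_spliced()`, `generate_trans_spliced()`, `chunk_protein()`,
  `dedup_peptides()`: peptide generation with origin coordinates and
  splice-reactant positions.
- **combinatorics** — `count_cis_forward/reverse/total()`, `count_trans()`,
  `expected_unique()`, `enumerate_splice_events()` (C++ oracle).
- **PTMs** — `peptide_mass()`, `expand_variable_ptms()`,
  `count_modified_forms()`, `ptm_preset_common()` (the 8 common
  modifications), `load_ptm_table()`.
- **filters** — `mw_filter()` (ppm window around observed precursor
  masses), `fit_rt_model()` (additive retention model, cross-validated
  0.99-quantile error threshold), `mw_rt_filter()` (joint per-observation),
  `hla_filter()` (pluggable IC50 predictor, 5000 nM default),
  `make_decoys()`.
- **multimapping** — `count_origins()`, `strata_overlap()`,
  `unique_peptide_orf_fraction()`.
- **identification** — `tdc_qvalues()`, `combined_strategy()`,
  `group_specific_fdr()`, `identification_report()`.
- **workflow** — `run_pipeline()`, `strata_statistics()`,
  `write_peptide_store()` (hive-partitioned parquet via arrow, delimited
  fallback), `generate_fixtures()` (complete seeded synthetic study), plus
  a thin CLI at `inst/scripts/pepspace-cli.R`.

## Worked example

```r
library(pepspace)

# How many peptides can a 150-residue protein yield at N = 9?
count_nonspliced(150, 9)          # 142
count_cis_total(150, 9, 1, 25)    # 52736   (cis, intervening <= 25)
count_trans(150, 150, 9, 1)       # 171656  (trans, two such proteins)

# The events are real, not just counted:
generate_cis_spliced("ACDE", N = 3, direction = "forward")$sequence
# [1] "ADE" "ACE"      -- reactants (1,1)+(3,4) and (1,2)+(4,4)

peptide_mass(c("G", "PEPTIDE"))
# [1]  75.03203 799.35996   (monoisotopic, Da)

# A complete synthetic study, end to end:
fx  <- generate_fixtures(seed = 1, out_dir = "fx")
res <- run_pipeline(fx$genome, fx$gtf, fx$observations, fx$calibration,
                    expression_file = fx$expression, out_dir = "out")
res$rt_model
# Additive retention-time model
#   calibration PSMs: 300
#   trained residues: GASPVTCLINDQKEMHFRYW
#   error threshold : 1.291 min (0.99 quantile, 5 folds)
```

The fitted threshold sits at the analytic value 2.576 σ = 1.288 min for the
σ = 0.5 min noise the fixture injects. `res$stats` tabulates distinct
peptides per stratum × rule × length × filter stage and is non-increasing
along unfiltered → MW → MW+RT → MW+RT+HLA; on this fixture the MW filter
keeps ~5% of the 9-mer cis space and the joint MW+RT filter ~1%.

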