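## Peptide-origin ambiguity analytics: how many distinct ORFs/genes a
## peptide maps to, how strongly strata overlap, and which ORFs retain at
## least one stratum-unique peptide.

#' Histogram of peptides by number of distinct origins
#'
#' Counts the number of distinct origins (ORFs or genes) per peptide, then
#' the number of peptides per origin count. The histogram masses sum to the
#' number of unique peptides.
#'
#' @param mapping `data.table`/`data.frame` with columns `sequence`,
#'   `origin_orf` and (for `level = "gene"`) `origin_gene`.
#' @param level Count distinct `"orf"` or `"gene"` origins.
#' @return `data.table` with `n_origins` and `n_peptides`, sorted by
#'   `n_origins`.
#' @export
count_origins <- function(mapping, level = c("orf", "gene")) {
  level <- match.arg(level)
  dt <- data.table::as.data.table(mapping)
  col <- if (level == "orf") "origin_orf" else "origin_gene"
  if (!col %in% names(dt)) stop("mapping table lacks column ", col)
  per_pep <- dt[, list(n_origins = data.table::uniqueN(.SD[[1]])),
                by = "sequence", .SDcols = col]
  out <- per_pep[, list(n_peptides = .N), by = "n_origins"]
  data.table::setorder(out, n_origins)
  out[]
}

#' Pairwise shared peptides between strata
#'
#' For each ordered pair of strata (A, B): the shared distinct-peptide count
#' `|A n B|` and the fraction `|A n B| / |A|`. The count matrix is symmetric;
#' the fraction matrix is not.
#'
#' @param strata Named list of character vectors (peptide sets per stratum);
#'   at least two.
#' @return List with matrices `shared` (counts) and `fraction`
#'   (row stratum = denominator).
#' @export
strata_overlap <- function(strata) {
  if (length(strata) < 2L) stop("need at least two strata")
  strata <- lapply(strata, unique)
  ns <- names(strata)
  shared <- matrix(0, length(strata), length(strata), dimnames = list(ns, ns))
  for (a in ns) for (b in ns)
    shared[a, b] <- length(intersect(strata[[a]], strata[[b]]))
  sizes <- vapply(strata, length, integer(1))
  fraction <- sweep(shared, 1L, pmax(sizes, 1L), "/")
  fraction[sizes == 0L, ] <- NA_real_
  list(shared = shared, fraction = fraction)
}

#' Fraction of ORFs with at least one stratum-unique peptide
#'
#' An ORF of the focal stratum counts when at least one of its peptides maps
#' to no other ORF in *any* stratum (under the same generation rule). The
#' returned value is the fraction of such ORFs among the stratum's ORFs;
#' an empty stratum yields `NA` (reported as absent).
#'
#' @param stratum Focal stratum label.
#' @param mapping Combined mapping table across strata with columns
#'   `sequence`, `stratum`, `origin_orf`, `rule`.
#' @param rule Generation rule considered (default `"tryptic"`).
#' @return Numeric fraction in `[0, 1]`, or `NA` for an empty stratum.
#' @export
unique_peptide_orf_fraction <- function(stratum, mapping, rule = "tryptic") {
  dt <- data.table::as.data.table(mapping)
  ## select with plain vectors: the argument names shadow column names
  sel_rule <- dt[["rule"]] == rule
  dt <- dt[which(sel_rule)]
  sel_stratum <- dt[["stratum"]] == stratum
  focal <- dt[which(sel_stratum)]
  if (!nrow(focal)) return(NA_real_)
  n_orfs_per_pep <- dt[, list(n = data.table::uniqueN(origin_orf)),
                       by = "sequence"]
  unique_peps <- n_orfs_per_pep$sequence[n_orfs_per_pep$n == 1L]
  has_unique <- focal[, list(ok = any(sequence %in% unique_peps)),
                      by = "origin_orf"]
  mean(has_unique$ok)
}

#' Cross-strata summary with canonical priority
#'
#' Collapses a mapping table to one stratum per peptide for reporting:
#' peptides present in `cds_main` are reported under `cds_main`; remaining
#' ties are broken by the stratum order of `priority`. Raw mapping tables
#' are left untouched.
#'
#' @param mapping Mapping table with `sequence` and `stratum`.
#' @param priority Stratum priority order (first wins).
#' @return `data.table` with one row per distinct peptide (`sequence`,
#'   `stratum`).
#' @export
assign_canonical_priority <- function(mapping, priority = STRATA_LEVELS) {
  dt <- data.table::as.data.table(mapping)
  dt <- unique(dt[, c("sequence", "stratum")])
  dt[, .ord := match(stratum, priority)]
  data.table::setorder(dt, sequence, .ord)
  out <- dt[!duplicated(sequence)]
  out[, .ord := NULL]
  out[]
}
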