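## Target-decoy FDR utilities and the naive / combined / group-specific
## identification strategies as PSM-table post-processing.
## FDRhat(s) = #decoys(score >= s) / max(1, #targets(score >= s));
## q-values are the running minimum of FDRhat from the most permissive
## threshold upward.

#' Assign target-decoy q-values to a PSM table
#'
#' @param psms `data.table`/`data.frame` with numeric `score` (higher is
#'   better) and logical `is_decoy`.
#' @param plus_one Add the +1 pseudo-count to the decoy tally
#'   (conservative variant)? Default `FALSE` (plain decoy/target ratio).
#' @return The input as a `data.table` with a `q_value` column appended
#'   (row order preserved).
#' @export
tdc_qvalues <- function(psms, plus_one = FALSE) {
  dt <- data.table::as.data.table(psms)
  stopifnot(all(c("score", "is_decoy") %in% names(dt)))
  if (!any(dt$is_decoy)) {
    warning("no decoys present; all q-values set to 0")
    dt$q_value <- 0
    return(dt[])
  }
  ord <- order(dt$score, decreasing = TRUE)
  sc <- dt$score[ord]
  dec <- cumsum(dt$is_decoy[ord])
  tar <- cumsum(!dt$is_decoy[ord])
  ## ties share the same threshold: propagate tie-group totals upward
  first_of_tie <- c(TRUE, sc[-1] != sc[-length(sc)])
  grp <- cumsum(first_of_tie)                      # tie-group index per row
  grp_end <- which(c(sc[-1] != sc[-length(sc)], TRUE))  # last row per group
  dec_g <- dec[grp_end][grp]
  tar_g <- tar[grp_end][grp]
  fdr <- (dec_g + if (plus_one) 1 else 0) / pmax(1, tar_g)
  q <- rev(cummin(rev(fdr)))
  q <- pmin(q, 1)
  dt$q_value <- q[order(ord)]
  dt[]
}

#' Merge canonical and expanded search results (combined strategy)
#'
#' Per spectrum, keeps the record with the smaller q-value; ties prefer the
#' canonical database (preferential selection of canonical peptides).
#' Spectra present in only one table pass through.
#'
#' @param psms_canonical,psms_expanded q-valued PSM tables with columns
#'   `spectrum_id`, `q_value`; a `database_label` column is added/overwritten
#'   with `"canonical"` / `"expanded"`.
#' @return Merged `data.table`, exactly one record per `spectrum_id`.
#' @export
combined_strategy <- function(psms_canonical, psms_expanded) {
  can <- data.table::as.data.table(psms_canonical)
  exp_ <- data.table::as.data.table(psms_expanded)
  can$database_label <- "canonical"
  exp_$database_label <- "expanded"
  both <- data.table::rbindlist(list(can, exp_), fill = TRUE)
  ## canonical first so that ties resolve toward it
  both[, .pref := ifelse(database_label == "canonical", 0L, 1L)]
  data.table::setorder(both, spectrum_id, q_value, .pref)
  out <- both[!duplicated(spectrum_id)]
  out[, .pref := NULL]
  out[]
}

#' Group-specific FDR: q-values computed independently per group
#'
#' @param psms PSM table with `score`, `is_decoy` and a grouping column.
#' @param group_col Name of the grouping column (default `"group"`).
#' @param plus_one Passed to [tdc_qvalues()].
#' @return `data.table` with per-group `q_value` (row order preserved).
#' @export
group_specific_fdr <- function(psms, group_col = "group", plus_one = FALSE) {
  dt <- data.table::as.data.table(psms)
  if (!group_col %in% names(dt)) stop("missing grouping column ", group_col)
  if (anyNA(dt[[group_col]])) stop("every PSM must be labelled with a group")
  dt$.row <- seq_len(nrow(dt))
  parts <- split(dt, dt[[group_col]])
  parts <- lapply(parts, function(p) {
    if (!any(p$is_decoy)) {
      warning("group '", p[[group_col]][1], "' has no decoys; q = 0 within group")
      p$q_value <- 0
      p
    } else tdc_qvalues(p, plus_one = plus_one)
  })
  out <- data.table::rbindlist(parts)
  data.table::setorder(out, .row)
  out[, .row := NULL]
  out[]
}

#' Identification counts across an FDR threshold grid
#'
#' For each threshold: accepted target PSM count, unique peptide count, and
#' the fraction of accepted PSMs from the expanded database (noncanonical).
#'
#' @param merged q-valued PSM table (targets and decoys; decoys are excluded
#'   from the counts) with columns `sequence`, `q_value`, `is_decoy` and
#'   optionally `database_label`.
#' @param fdr_grid Numeric thresholds (default 0.001-0.05).
#' @return `data.table` with `fdr`, `n_psms`, `n_peptides`,
#'   `frac_noncanonical`.
#' @export
identification_report <- function(merged,
                                  fdr_grid = c(0.001, 0.005, 0.01, 0.05)) {
  dt <- data.table::as.data.table(merged)
  targets <- dt[!dt$is_decoy]
  has_label <- "database_label" %in% names(targets)
  out <- lapply(sort(fdr_grid), function(a) {
    acc <- targets[targets$q_value <= a]
    data.table::data.table(
      fdr = a, n_psms = nrow(acc),
      n_peptides = data.table::uniqueN(acc$sequence),
      frac_noncanonical = if (has_label && nrow(acc))
        mean(acc$database_label == "expanded") else NA_real_)
  })
  data.table::rbindlist(out)
}
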