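## Post-translational modifications: monoisotopic mass computation and
## combinatorial expansion of fixed and variable PTMs.
##
## A "site" is either a residue position (1..nchar) or one of the termini
## ("N-term", "C-term"). At most one PTM per site; the peptide N-terminus and
## the side chain of residue 1 are distinct sites, so N-terminal acetylation
## can co-occur with a modification at position 1.

#' Define a post-translational modification
#'
#' @param name Modification name (free text, Unimod-style names welcome).
#' @param target Single residue letter, `"N-term"` or `"C-term"`.
#' @param delta_mass Monoisotopic mass shift in Da.
#' @param fixed Is the modification fixed (always applied) rather than
#'   variable?
#' @return A one-row `data.table` PTM definition.
#' @export
ptm_definition <- function(name, target, delta_mass, fixed = FALSE) {
  ok <- target %in% c(names(AA_MONO), "N-term", "C-term")
  if (!all(ok)) stop("invalid PTM target(s): ",
                     paste(unique(target[!ok]), collapse = ", "))
  if (!all(is.finite(delta_mass))) stop("delta_mass must be finite")
  data.table::data.table(name = name, target = target,
                         delta_mass = as.numeric(delta_mass),
                         fixed = as.logical(fixed))
}

#' The built-in common-PTM preset
#'
#' Eight definitions: peptide N-terminal acetylation, carbamidomethylation of
#' cysteine, deamidation of asparagine and glutamine, oxidation of
#' methionine, and phosphorylation of serine, threonine and tyrosine. All
#' entries are variable, matching their use for combinatorial search-space
#' expansion; set the `fixed` column afterwards to pin any of them.
#'
#' @return `data.table` of 8 PTM definitions.
#' @export
ptm_preset_common <- function() {
  rbind(
    ptm_definition("Acetyl",          "N-term", 42.0105646863),
    ptm_definition("Carbamidomethyl", "C",      57.0214637236),
    ptm_definition("Deamidated",      "N",       0.9840155848),
    ptm_definition("Deamidated",      "Q",       0.9840155848),
    ptm_definition("Oxidation",       "M",      15.9949146221),
    ptm_definition("Phospho",         "S",      79.9663304084),
    ptm_definition("Phospho",         "T",      79.9663304084),
    ptm_definition("Phospho",         "Y",      79.9663304084))
}

#' Load PTM definitions from a delimited table
#'
#' Expects columns `name`, `target`, `delta_mass`, `fixed` (tab- or
#' comma-separated; autodetected by [data.table::fread()]). Duplicate
#' `(name, target)` pairs and non-numeric mass shifts are errors.
#'
#' @param path Path to the delimited file.
#' @return `data.table` of PTM definitions.
#' @export
load_ptm_table <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = c("name", "target")))
  if (!nrow(dt))
    return(ptm_definition(character(0), character(0), numeric(0), logical(0)))
  req <- c("name", "target", "delta_mass", "fixed")
  if (!all(req %in% names(dt)))
    stop("PTM table must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(dt[, c("name", "target")]))
    stop("duplicate (name, target) pair in PTM table")
  if (!is.numeric(dt$delta_mass))
    stop("non-numeric delta_mass in PTM table")
  ptm_definition(dt$name, dt$target, dt$delta_mass, as.logical(dt$fixed))
}

#' Monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus water, with fixed modifications
#' folded in: residue-targeted fixed deltas are added per matching residue;
#' terminus-targeted fixed deltas are added once per peptide (after checking
#' that the terminal residue matches when the definition also names one).
#' Sequences containing `X` (or any non-standard letter) and empty sequences
#' are errors: their mass is undefined.
#'
#' @param sequence Character vector of peptide sequences over the 20
#'   standard residues.
#' @param fixed_mods Optional PTM definition table; only rows with
#'   `fixed = TRUE` are applied.
#' @return Numeric vector of monoisotopic masses (Da).
#' @examples
#' peptide_mass("G")        # 75.03203
#' peptide_mass("PEPTIDE")  # 799.35997
#' @export
peptide_mass <- function(sequence, fixed_mods = NULL) {
  if (!length(sequence)) return(numeric(0))
  if (any(!nzchar(sequence))) stop("empty peptide sequence")
  aa <- Biostrings::AAStringSet(sequence)
  freq <- Biostrings::letterFrequency(aa, letters = names(AA_MONO))
  nres <- Biostrings::width(aa)
  if (any(rowSums(freq) != nres))
    stop("sequence contains residues outside the standard alphabet ",
         "(X or illegal characters)")
  ## letter-frequency matrix times the (diagonal of) residue masses
  masses <- as.vector(freq %*% AA_MONO) + MASS_WATER
  if (!is.null(fixed_mods) && nrow(fixed_mods)) {
    fm <- fixed_mods[fixed_mods$fixed, , drop = FALSE]
    for (r in seq_len(nrow(fm))) {
      tgt <- fm$target[r]
      if (tgt %in% names(AA_MONO)) {
        masses <- masses + freq[, tgt] * fm$delta_mass[r]
      } else {
        masses <- masses + fm$delta_mass[r]  # terminus mod: once per peptide
      }
    }
  }
  unname(masses)
}

## All eligible (site, ptm-row) assignments for one peptide.
.ptm_sites <- function(sequence, ptm_set) {
  vars <- ptm_set[!ptm_set$fixed, , drop = FALSE]
  if (!nrow(vars)) return(data.table::data.table(site = character(),
                                                 ptm_row = integer()))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  out <- list()
  for (r in seq_len(nrow(vars))) {
    tgt <- vars$target[r]
    if (tgt == "N-term") {
      out[[length(out) + 1L]] <- data.table::data.table(site = "N-term", ptm_row = r)
    } else if (tgt == "C-term") {
      out[[length(out) + 1L]] <- data.table::data.table(site = "C-term", ptm_row = r)
    } else {
      pos <- which(chars == tgt)
      if (length(pos))
        out[[length(out) + 1L]] <- data.table::data.table(site = as.character(pos),
                                                          ptm_row = r)
    }
  }
  if (!length(out)) return(data.table::data.table(site = character(),
                                                  ptm_row = integer()))
  data.table::rbindlist(out)
}

#' Expand all variable-PTM forms of a peptide
#'
#' Enumerates every assignment of 0 to `max_mods` variable PTMs to eligible
#' sites, at most one per site, always including the unmodified form. Fixed
#' modifications contribute to every form's mass but not to the combination
#' count.
#'
#' @param sequence Single peptide string.
#' @param ptm_set PTM definition table (fixed rows applied to mass, variable
#'   rows expanded).
#' @param max_mods Maximal number of variable PTMs per peptide (default 2).
#' @return `data.table` with `sequence`, `mods` (semicolon-joined
#'   `name@site`), `n_mods` and `mass`.
#' @export
expand_variable_ptms <- function(sequence, ptm_set, max_mods = 2L) {
  stopifnot(max_mods >= 0L)
  base_mass <- peptide_mass(sequence, fixed_mods = ptm_set)
  vars <- ptm_set[!ptm_set$fixed, , drop = FALSE]
  sites <- .ptm_sites(sequence, ptm_set)
  forms <- list(data.table::data.table(sequence = sequence, mods = "",
                                       n_mods = 0L, mass = base_mass))
  if (nrow(sites) && max_mods >= 1L) {
    for (m in seq_len(min(max_mods, nrow(sites)))) {
      combos <- utils::combn(nrow(sites), m)
      for (cix in seq_len(ncol(combos))) {
        rows <- sites[combos[, cix]]
        if (anyDuplicated(rows$site)) next   # one PTM per site
        delta <- sum(vars$delta_mass[rows$ptm_row])
        lab <- paste(paste0(vars$name[rows$ptm_row], "@", rows$site),
                     collapse = ";")
        forms[[length(forms) + 1L]] <- data.table::data.table(
          sequence = sequence, mods = lab, n_mods = m,
          mass = base_mass + delta)
      }
    }
  }
  data.table::rbindlist(forms)
}

#' Count modified forms of a peptide
#'
#' With `collapse_isomers = FALSE`, the number of positional forms (equal to
#' the number of rows of [expand_variable_ptms()]); with `TRUE`, positional
#' isomers carrying the same multiset of PTM names are merged.
#'
#' @inheritParams expand_variable_ptms
#' @param collapse_isomers Merge positional isomers?
#' @return Integer count.
#' @export
count_modified_forms <- function(sequence, ptm_set, max_mods = 2L,
                                 collapse_isomers = FALSE) {
  forms <- expand_variable_ptms(sequence, ptm_set, max_mods)
  if (!collapse_isomers) return(nrow(forms))
  key <- vapply(strsplit(forms$mods, ";", fixed = TRUE), function(m) {
    paste(sort(sub("@.*$", "", m)), collapse = ";")
  }, character(1))
  length(unique(key))
}
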