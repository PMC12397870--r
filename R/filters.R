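## Data-driven pre-filtering of generated peptides against MS1 evidence:
## precursor-mass (ppm window around each observed neutral mass),
## joint mass + retention-time matching, and pluggable HLA-binding
## prediction. Plus reversed-sequence decoy construction.

#' Neutral (uncharged) mass from m/z and charge
#'
#' `charge * mz - charge * proton_mass`, proton mass 1.00727646688 Da.
#'
#' @param mz Mass-to-charge ratio(s).
#' @param charge Positive integer charge state(s).
#' @return Neutral monoisotopic mass(es) in Da.
#' @export
neutral_mass <- function(mz, charge) {
  if (any(charge < 1)) stop("charge must be >= 1")
  charge * mz - charge * MASS_PROTON
}

#' Read a precursor observation table
#'
#' Delimited file with columns `mz`, `charge`, `rt_minutes` (one file per MS
#' run). Observations are deduplicated on (neutral mass, RT) rounded to
#' (1e-5 Da, 1e-3 min): duplicates carry no filtering information.
#'
#' @param path Path to the delimited file.
#' @param source_run Run identifier stored with the observations.
#' @return `data.table` with `mz`, `charge`, `rt`, `neutral_mass`,
#'   `source_run`.
#' @export
read_observations <- function(path, source_run = basename(path)) {
  dt <- data.table::fread(path)
  req <- c("mz", "charge", "rt_minutes")
  if (!all(req %in% names(dt)))
    stop("observation table must have columns: ", paste(req, collapse = ", "))
  out <- data.table::data.table(
    mz = dt$mz, charge = as.integer(dt$charge), rt = dt$rt_minutes,
    neutral_mass = neutral_mass(dt$mz, dt$charge), source_run = source_run)
  out[, `:=`(.m = round(neutral_mass, 5), .r = round(rt, 3))]
  out <- unique(out, by = c(".m", ".r"))
  out[, c(".m", ".r") := NULL]
  out[]
}

#' Filter peptide masses against observed precursor masses
#'
#' A peptide is kept iff some observation's neutral mass is within
#' `ppm * 1e-6 * neutral_mass` of the peptide mass — a symmetric window
#' around each *observed* mass. Implemented as an interval join
#' ([data.table::inrange()]); equals the all-pairs brute force.
#'
#' @param masses Numeric vector of peptide monoisotopic masses.
#' @param observations `data.table` from [read_observations()] (or any table
#'   with a `neutral_mass` column), or a numeric vector of neutral masses.
#' @param ppm MS1 tolerance in parts per million (> 0).
#' @return Logical keep mask, one element per peptide.
#' @export
mw_filter <- function(masses, observations, ppm = 5) {
  stopifnot(ppm > 0)
  obs <- if (is.numeric(observations)) observations else observations$neutral_mass
  if (!length(obs)) return(rep(FALSE, length(masses)))
  tol <- ppm * 1e-6 * obs
  data.table::inrange(masses, obs - tol, obs + tol)
}

#' Joint mass and retention-time filter
#'
#' A peptide is kept iff a *single* observation satisfies both the ppm mass
#' window and `|rt_pred - rt_obs| <= rt_tolerance` (the model's
#' cross-validated error threshold). Peptides whose RT cannot be predicted
#' (`NA`, e.g. untrained residues or variable PTMs) fall back to MW-only
#' filtering and are flagged in the `"mw_only"` attribute. Set
#' `joint = FALSE` to allow the mass and RT conditions to be satisfied by
#' different observations.
#'
#' @param masses Peptide masses (Da).
#' @param rt_pred Predicted retention times (minutes; `NA` allowed).
#' @param observations Table with `neutral_mass` and `rt` columns.
#' @param ppm MS1 tolerance (ppm).
#' @param rt_tolerance Absolute RT tolerance (minutes); typically
#'   `model$error_threshold`.
#' @param joint Require one observation to satisfy both conditions?
#' @return Logical keep mask with attribute `"mw_only"`.
#' @export
mw_rt_filter <- function(masses, rt_pred, observations, ppm = 5,
                         rt_tolerance, joint = TRUE) {
  stopifnot(length(masses) == length(rt_pred), ppm > 0, rt_tolerance > 0)
  rt_pred <- as.numeric(rt_pred)
  obs <- data.table::as.data.table(observations)
  mw_only <- is.na(rt_pred)
  keep <- logical(length(masses))
  if (nrow(obs)) {
    tol <- ppm * 1e-6 * obs$neutral_mass
    lo <- obs$neutral_mass - tol; hi <- obs$neutral_mass + tol
    if (joint) {
      pep <- data.table::data.table(mass = masses, rt = rt_pred,
                                    idx = seq_along(masses))
      win <- data.table::data.table(lo = lo, hi = hi,
                                    rlo = obs$rt - rt_tolerance,
                                    rhi = obs$rt + rt_tolerance)
      hit <- pep[!mw_only][win,
        on = .(mass >= lo, mass <= hi, rt >= rlo, rt <= rhi),
        nomatch = NULL, .(idx = x.idx)]
      keep[unique(hit$idx)] <- TRUE
    } else {
      mass_ok <- data.table::inrange(masses, lo, hi)
      rt_ok <- data.table::inrange(rt_pred, obs$rt - rt_tolerance,
                                   obs$rt + rt_tolerance)
      keep[!mw_only] <- (mass_ok & rt_ok)[!mw_only]
    }
    keep[mw_only] <- data.table::inrange(masses[mw_only], lo, hi)
  }
  structure(keep, mw_only = mw_only)
}

#' Filter peptides by predicted HLA-I binding affinity
#'
#' Peptides within `length_range` are kept iff the minimum over `alleles` of
#' the predicted IC50 is at or below `ic50_threshold` (nM). Peptides outside
#' the length range are not evaluated and pass through, flagged in the
#' `"not_evaluated"` attribute.
#'
#' @param peptides Character vector of sequences.
#' @param predictor Function `(sequences, allele) -> IC50 nM` (see
#'   [toy_hla_predictor()] for the bundled example, or wrap any external
#'   tool's tabular output).
#' @param alleles Character vector of allele names.
#' @param ic50_threshold IC50 cutoff in nM (default 5000).
#' @param length_range Lengths evaluated (default 8-15).
#' @return Logical keep mask with attribute `"not_evaluated"`.
#' @export
hla_filter <- function(peptides, predictor, alleles, ic50_threshold = 5000,
                       length_range = c(8L, 15L)) {
  len <- nchar(peptides)
  eval_mask <- len >= length_range[1] & len <= length_range[2]
  keep <- rep(TRUE, length(peptides))
  if (any(eval_mask)) {
    sub <- peptides[eval_mask]
    ic50 <- rep(Inf, length(sub))
    for (al in alleles) {
      v <- tryCatch(predictor(sub, al), error = function(e)
        stop("HLA predictor failed for allele ", al, " on ", length(sub),
             " peptide(s) (first: ", sub[1], "): ", conditionMessage(e)))
      ic50 <- pmin(ic50, v)
    }
    keep[eval_mask] <- ic50 <= ic50_threshold
  }
  structure(keep, not_evaluated = !eval_mask)
}

#' Bundled toy HLA-binding predictor
#'
#' A position-weight-matrix scorer mapped monotonically onto an IC50-like
#' nanomolar scale, for tests and examples only — it emulates the *shape* of
#' a binding predictor (per-allele anchor preferences, 50 nM-50,000 nM
#' range), not real binding. The PWM is derived deterministically from the
#' allele name, so predictions are reproducible.
#'
#' @param peptides Character vector (any length; positions map onto 9 PWM
#'   columns).
#' @param allele Allele name (seeds the PWM).
#' @return Numeric IC50-like values (nM).
#' @export
toy_hla_predictor <- function(peptides, allele) {
  seed <- sum(utf8ToInt(allele)) %% 100000L
  pwm <- .with_seed(seed, matrix(stats::runif(20L * 9L), nrow = 20L,
                                 dimnames = list(names(AA_MONO), NULL)))
  pwm <- sweep(pwm, 2L, colSums(pwm), "/")
  logw <- log(pwm * 20)
  lens <- nchar(peptides)
  s <- numeric(length(peptides))
  for (L in unique(lens)) {          # vectorized per length class
    idx <- which(lens == L)
    pos <- pmin(pmax(round(seq(1, 9, length.out = L)), 1L), 9L)
    rows <- matrix(match(unlist(strsplit(peptides[idx], "", fixed = TRUE)),
                         rownames(pwm)), nrow = L)
    vals <- matrix(logw[cbind(as.vector(rows), rep(pos, times = length(idx)))],
                   nrow = L)
    sc <- colMeans(vals, na.rm = TRUE)  # NA rows: nonstandard residues
    sc[is.nan(sc)] <- 0
    s[idx] <- sc
  }
  ## monotone map: high score -> low IC50, range ~[50, 50000] nM
  50000^(1 - stats::plogis(3 * s)) * 50^stats::plogis(3 * s)
}

#' Reverse a protein database to build decoys
#'
#' Every sequence is reversed and ids get the `"rev_"` prefix; downstream
#' peptide generation and filtering applied to the decoy database mirrors
#' the targets exactly, which is what makes the decoy strategy fair.
#'
#' @param proteins Named character vector (or `AAStringSet`) of protein
#'   sequences.
#' @return Named character vector of reversed sequences.
#' @export
make_decoys <- function(proteins) {
  if (methods::is(proteins, "XStringSet"))
    proteins <- stats::setNames(as.character(proteins), names(proteins))
  rev_seq <- vapply(strsplit(proteins, "", fixed = TRUE),
                    function(ch) paste(rev(ch), collapse = ""), character(1),
                    USE.NAMES = FALSE)
  stats::setNames(rev_seq, paste0("rev_", names(proteins)))
}
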