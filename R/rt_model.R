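## Additive retention-time model: RT ~ intercept + sum of per-residue
## coefficients (composition features), the classic additive retention
## predictor. Fitted by least squares; the filtering error threshold is the
## cross-validated quantile of held-out absolute residuals.

.residue_counts <- function(sequences) {
  freq <- Biostrings::letterFrequency(Biostrings::AAStringSet(sequences),
                                      letters = names(AA_MONO))
  storage.mode(freq) <- "double"
  freq
}

#' Fit an additive retention-time model from calibration PSMs
#'
#' Least-squares fit of observed retention times on residue-count features
#' plus an intercept. The prediction-error threshold used for filtering is
#' estimated by cross-validation with folds split on unique peptide
#' sequences: within each fold, the chosen `quantile` of held-out absolute
#' residuals is taken, and the threshold is the mean across folds.
#'
#' Residues absent from the calibration set are excluded from the trained
#' residue set; peptides containing them cannot be predicted and are flagged
#' by [predict.rt_model()].
#'
#' @param calibration `data.frame` with columns `sequence` and `rt` (minutes).
#' @param folds Number of cross-validation folds (default 5).
#' @param quantile Quantile of absolute held-out residuals (default 0.99).
#' @param length_correction Add a peptide-length column to the design?
#'   Default `FALSE` (plain additive form).
#' @param seed Seed for the fold assignment (logged in the fitted object).
#' @return An object of class `rt_model` with elements `coefficients`
#'   (intercept first), `error_threshold` (minutes), `trained_residues`,
#'   `fold_thresholds`, `folds`, `seed`, `n_calibration`.
#' @export
fit_rt_model <- function(calibration, folds = 5L, quantile = 0.99,
                         length_correction = FALSE, seed = 1L) {
  stopifnot(all(c("sequence", "rt") %in% names(calibration)))
  calibration <- calibration[!is.na(calibration$sequence) &
                               !is.na(calibration$rt), , drop = FALSE]
  useqs <- unique(calibration$sequence)
  if (length(useqs) < 20L)
    stop("need at least 20 distinct calibration sequences, got ",
         length(useqs))
  design_of <- function(seqs) {
    X <- .residue_counts(seqs)
    if (length_correction) X <- cbind(X, length = nchar(seqs))
    X
  }
  X_all <- design_of(calibration$sequence)
  trained <- names(AA_MONO)[colSums(X_all[, names(AA_MONO), drop = FALSE]) > 0]

  fit_ls <- function(X, y) {
    keep <- colSums(abs(X)) > 0
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X[, keep, drop = FALSE]), y)
    co <- fit$coefficients
    co[is.na(co)] <- 0
    full <- stats::setNames(numeric(ncol(X) + 1L),
                            c("(Intercept)", colnames(X)))
    full[names(co)] <- co
    full
  }

  ## cross-validation split on unique sequences
  fold_of <- stats::setNames(
    .with_seed(seed, sample(rep_len(seq_len(folds), length(useqs)))), useqs)
  fold_thr <- numeric(folds)
  for (f in seq_len(folds)) {
    hold <- calibration$sequence %in% useqs[fold_of[useqs] == f]
    if (!any(hold) || sum(!hold) < 2L) { fold_thr[f] <- NA_real_; next }
    co <- fit_ls(design_of(calibration$sequence[!hold]),
                 calibration$rt[!hold])
    Xh <- design_of(calibration$sequence[hold])
    pred <- as.vector(cbind(1, Xh) %*% co)
    fold_thr[f] <- stats::quantile(abs(calibration$rt[hold] - pred),
                                   probs = quantile, names = FALSE)
  }
  co_full <- fit_ls(X_all, calibration$rt)
  structure(list(coefficients = co_full,
                 error_threshold = mean(fold_thr, na.rm = TRUE),
                 trained_residues = trained,
                 fold_thresholds = fold_thr,
                 folds = folds, quantile = quantile,
                 length_correction = length_correction,
                 seed = seed,
                 n_calibration = nrow(calibration),
                 fitted_rt = as.vector(cbind(1, X_all) %*% co_full),
                 calibration_rt = calibration$rt),
            class = "rt_model")
}

## evaluate expr under a local seed without disturbing the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' @export
print.rt_model <- function(x, ...) {
  cat("Additive retention-time model\n")
  cat("  calibration PSMs:", x$n_calibration, "\n")
  cat("  trained residues:", paste(x$trained_residues, collapse = ""), "\n")
  cat(sprintf("  error threshold : %.3f min (%.2f quantile, %d folds)\n",
              x$error_threshold, x$quantile, x$folds))
  invisible(x)
}

#' @export
coef.rt_model <- function(object, ...) object$coefficients

#' @export
residuals.rt_model <- function(object, ...) {
  object$calibration_rt - object$fitted_rt
}

#' Predict retention times for peptide sequences
#'
#' Sequences containing residues outside the trained residue set cannot be
#' predicted: they receive `NA` and are listed in the `"excluded"` attribute.
#'
#' @param object Fitted `rt_model`.
#' @param sequences Character vector of peptides.
#' @param ... Unused.
#' @return Numeric vector of predicted retention times (minutes) with
#'   attribute `"excluded"` (logical vector).
#' @export
predict.rt_model <- function(object, sequences, ...) {
  X <- .residue_counts(sequences)
  if (object$length_correction) X <- cbind(X, length = nchar(sequences))
  untrained <- setdiff(names(AA_MONO), object$trained_residues)
  excluded <- if (length(untrained))
    rowSums(X[, untrained, drop = FALSE]) > 0 else rep(FALSE, length(sequences))
  pred <- as.vector(cbind(1, X) %*% object$coefficients)
  pred[excluded] <- NA_real_
  structure(pred, excluded = excluded)
}
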