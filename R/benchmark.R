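# Classifier validation metrics and the Kd <-> binding-energy pairing.

#' Confusion-table metrics
#'
#' Standard validation statistics for a binary classifier: true positive
#' rate tp/(tp+fn), false positive rate fp/(fp+tn), precision
#' tp/(tp+fp), balanced accuracy (TPR + TNR)/2, and the TPR/FPR ratio (a
#' ratio of 1 means predictions are no better than random). Degenerate
#' margins yield NA fields; a zero FPR with positive TPR yields an
#' infinite ratio, flagged via `ratio_infinite`.
#'
#' @param tp,fp,tn,fn Non-negative integer cell counts.
#' @return List with `tpr`, `fpr`, `precision`, `balanced_accuracy`,
#'   `tpr_fpr_ratio`, `ratio_infinite`.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn > 0)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  fpr <- if (fp + tn > 0) fp / (fp + tn) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  ba <- if (!is.na(tpr) && !is.na(fpr)) (tpr + (1 - fpr)) / 2 else NA_real_
  inf <- !is.na(fpr) && fpr == 0 && !is.na(tpr) && tpr > 0
  ratio <- if (is.na(tpr) || is.na(fpr)) NA_real_
           else if (fpr == 0) Inf else tpr / fpr
  list(tpr = tpr, fpr = fpr, precision = precision, balanced_accuracy = ba,
       tpr_fpr_ratio = ratio, ratio_infinite = inf)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p-value under the hypergeometric null, two-sided by the
#' probability-mass extremeness criterion: sum the probabilities of all
#' tables with the observed margins whose probability does not exceed
#' that of the observed table (up to a small relative tolerance against
#' ties in floating point), the convention of standard exact-test
#' implementations.
#'
#' @param tp,fp,tn,fn Cell counts of the 2x2 table (rows: predicted
#'   positive/negative, columns: condition positive/negative, any
#'   consistent orientation; the p-value is invariant under row and
#'   column swaps).
#' @return The exact two-sided p-value.
#' @export
fisher_exact_two_sided <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  m <- tp + fn          # condition positives
  n <- fp + tn          # condition negatives
  k <- tp + fp          # predicted positives
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tp, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

GAS_CONSTANT_KCAL <- 1.987e-3  # kcal / (mol K)

#' Convert a dissociation constant to binding free energy
#'
#' Delta G = R T ln(Kd) with R = 1.987e-3 kcal/(mol K); monotone
#' increasing in Kd. At 298 K a Kd of 1e-9 M maps to about -12.3
#' kcal/mol and 1e-6 M to about -8.2 kcal/mol, the usual
#' strong-permanent / weak-transient landmarks.
#'
#' @param kd Dissociation constant in molar (> 0); vectorized.
#' @param temperature Temperature in Kelvin, default 298.
#' @return Binding free energy in kcal/mol.
#' @export
kd_to_delta_g <- function(kd, temperature = 298) {
  if (any(kd <= 0)) stop("kd must be positive")
  GAS_CONSTANT_KCAL * temperature * log(kd)
}

#' Inverse of [kd_to_delta_g()]
#' @param delta_g Binding free energy in kcal/mol.
#' @param temperature Temperature in Kelvin, default 298.
#' @return Dissociation constant in molar.
#' @export
delta_g_to_kd <- function(delta_g, temperature = 298) {
  exp(delta_g / (GAS_CONSTANT_KCAL * temperature))
}

#' Affinity-based ground-truth strength labels
#'
#' Benchmark label construction from experimental binding energies:
#' strong iff delta G < -12 kcal/mol (Kd below the nanomolar landmark),
#' weak iff delta G > -8 kcal/mol (Kd above the micromolar landmark),
#' intermediate energies excluded (NA).
#'
#' @param delta_g Experimental binding free energies (kcal/mol).
#' @return Character vector in {"strong", "weak", NA}.
#' @export
affinity_truth_labels <- function(delta_g) {
  out <- rep(NA_character_, length(delta_g))
  out[delta_g < -12] <- "strong"
  out[delta_g > -8] <- "weak"
  out
}
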