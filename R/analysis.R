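
# The three analysis modes over docking score tables: enrichment (logarithmic
# ROC AUC), rank correlation (Spearman rho, Kendall tau-b with tie counts),
# and threshold-based quadrant classification.

#' Labeled active/decoy score set
#'
#' @param ligand_id Character vector of ids.
#' @param score Numeric docking scores (finite).
#' @param label `"active"` / `"decoy"` per entry.
#' @param direction Score direction, `"lower_better"` (default; most docking
#'   engines) or `"higher_better"` (fitness-style scores).
#' @return An object of class `labeled_scores`.
#' @export
labeled_scores <- function(ligand_id, score, label,
                           direction = c("lower_better", "higher_better")) {
  direction <- match.arg(direction)
  stopifnot(length(ligand_id) == length(score),
            length(score) == length(label))
  if (!all(is.finite(score))) fail("all scores must be finite")
  label <- as.character(label)
  if (!all(label %in% c("active", "decoy")))
    fail("labels must be 'active' or 'decoy'")
  structure(list(ligand_id = as.character(ligand_id), score = as.numeric(score),
                 label = label, direction = direction,
                 n = length(score)),
            class = "labeled_scores")
}

# scores on a "higher is better" goodness scale
.goodness <- function(score, direction)
  if (direction == "higher_better") score else -score

#' Enrichment: logarithmic ROC AUC
#'
#' Orders the screen best-score-first and, for the i-th active recovered,
#' takes the false positive rate `beta_i` = (decoys ranked better) / (total
#' decoys). The statistic is `mean(log10(1 / beta_i))` over actives. A score
#' tie between an active and a decoy ranks the decoy first, making reported
#' enrichment conservative; `beta = 0` (an active recovered before any decoy)
#' is clipped below at `1 / n_decoys` so early perfect recovery stays finite,
#' and the number of clipped actives is reported. Random selection gives
#' 0.434 (= log10 e) in expectation; the classical ROC AUC (also returned)
#' gives 0.5.
#'
#' @param data A [labeled_scores()] with at least one active and one decoy.
#' @return An `enrichment_result`: list with `proc_auc`, `roc_auc`, `betas`
#'   (per-active FPRs after clipping), `n`, `n_actives`, `n_decoys`,
#'   `n_clipped`.
#' @export
proc_auc <- function(data) {
  stopifnot(inherits(data, "labeled_scores"))
  act <- data$label == "active"
  n_act <- sum(act); n_dec <- sum(!act)
  if (n_act == 0L) fail("no actives in the score set")
  if (n_dec == 0L) fail("no decoys in the score set")
  g <- .goodness(data$score, data$direction)
  # best first; decoys ahead of actives on tied scores (pessimistic)
  ord <- order(-g, act)
  sorted_active <- act[ord]
  decoys_before <- cumsum(!sorted_active)[sorted_active]
  beta_raw <- decoys_before / n_dec
  n_clipped <- sum(beta_raw < 1 / n_dec)
  betas <- pmax(beta_raw, 1 / n_dec)
  structure(list(
    proc_auc = mean(log10(1 / betas)),
    roc_auc = roc_auc(data),
    betas = betas,
    n = data$n, n_actives = n_act, n_decoys = n_dec,
    n_clipped = n_clipped
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment> pROC AUC = %.4f (random 0.434), ROC AUC = %.4f (random 0.5); %d actives / %d decoys, %d clipped\n",
    x$proc_auc, x$roc_auc, x$n_actives, x$n_decoys, x$n_clipped))
  invisible(x)
}

#' Classical ROC AUC
#'
#' Trapezoidal area under TPR vs FPR, computed by the rank (Mann-Whitney)
#' identity; tied active/decoy scores contribute one half.
#'
#' @param data A [labeled_scores()].
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(data) {
  stopifnot(inherits(data, "labeled_scores"))
  act <- data$label == "active"
  n_act <- sum(act); n_dec <- sum(!act)
  if (n_act == 0L) fail("no actives in the score set")
  if (n_dec == 0L) fail("no decoys in the score set")
  g <- .goodness(data$score, data$direction)
  r <- rank(g)                       # average ranks on ties
  (sum(r[act]) - n_act * (n_act + 1) / 2) / (n_act * n_dec)
}

#' Paired docking/experimental measurements
#'
#' @param dock Numeric docking scores.
#' @param exper Numeric experimental values, same length (>= 2).
#' @param dock_direction,exp_direction Orientation of each variable
#'   (`"higher_better"` default). Correlations are computed between the two
#'   variables on their "better is larger" scales, so perfectly co-monotonic
#'   data scores +1 regardless of sign conventions.
#' @param loq Optional logical vector flagging values censored at the
#'   experimental limit of quantification (carried as metadata; censoring
#'   produces ties, which is why the tau-b tie accounting matters).
#' @return An object of class `paired_measurements`.
#' @export
paired_measurements <- function(dock, exper,
                                dock_direction = c("higher_better",
                                                   "lower_better"),
                                exp_direction = c("higher_better",
                                                  "lower_better"),
                                loq = NULL) {
  dock_direction <- match.arg(dock_direction)
  exp_direction <- match.arg(exp_direction)
  stopifnot(is.numeric(dock), is.numeric(exper))
  if (length(dock) != length(exper)) fail("dock and exper lengths differ")
  if (length(dock) < 2L) fail("need at least 2 paired measurements")
  if (!all(is.finite(dock)) || !all(is.finite(exper)))
    fail("all measurements must be finite")
  if (!is.null(loq) && length(loq) != length(dock))
    fail("loq flags must match measurement length")
  structure(list(dock = dock, exper = exper,
                 dock_direction = dock_direction,
                 exp_direction = exp_direction,
                 loq = loq, n = length(dock)),
            class = "paired_measurements")
}

#' Spearman rank correlation
#'
#' Fractional (average) ranks on both sides; with no ties this equals the
#' classical `1 - 6 sum(d_i^2) / (n (n^2 - 1))` rank-difference form. A
#' constant vector on either side leaves the coefficient undefined.
#'
#' @param data A [paired_measurements()].
#' @return A `correlation_result` with `rho`, the rank differences `d`, and
#'   `undefined` flag (`rho` is `NA` when undefined).
#' @export
spearman_rho <- function(data) {
  stopifnot(inherits(data, "paired_measurements"))
  x <- .goodness(data$dock, data$dock_direction)
  y <- .goodness(data$exper, data$exp_direction)
  rx <- rank(x); ry <- rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  vx <- sum(dx^2); vy <- sum(dy^2)
  undefined <- vx == 0 || vy == 0
  rho <- if (undefined) NA_real_ else sum(dx * dy) / sqrt(vx * vy)
  structure(list(rho = rho, d = rx - ry, n = data$n, undefined = undefined),
            class = "correlation_result")
}

#' Kendall tau-b rank correlation
#'
#' Classifies all `n(n-1)/2` pairs as concordant, discordant, tied on the
#' docking side only, tied on the experimental side only, or tied on both
#' (excluded from every count, per the tau-b convention), then evaluates
#' `(C - D) / sqrt((C + D + T_dock)(C + D + T_exp))`. Unlike Spearman, the
#' denominator accounts for ties, which matters for assay values censored at
#' a limit of quantification. An all-tied side gives denominator zero and an
#' undefined (NA) coefficient, not an error.
#'
#' @param data A [paired_measurements()].
#' @return A `correlation_result` with `tau_b`, pair counts `C`, `D`,
#'   `T_dock`, `T_exp`, `T_both`, and `undefined` flag.
#' @export
kendall_tau_b <- function(data) {
  stopifnot(inherits(data, "paired_measurements"))
  x <- .goodness(data$dock, data$dock_direction)
  y <- .goodness(data$exper, data$exp_direction)
  n <- data$n
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  dx <- sign(x[ij[, 2]] - x[ij[, 1]])
  dy <- sign(y[ij[, 2]] - y[ij[, 1]])
  C <- sum(dx * dy > 0)
  D <- sum(dx * dy < 0)
  T_dock <- sum(dx == 0 & dy != 0)
  T_exp <- sum(dy == 0 & dx != 0)
  T_both <- sum(dx == 0 & dy == 0)
  den <- sqrt((C + D + T_dock) * (C + D + T_exp))
  undefined <- den == 0
  structure(list(tau_b = if (undefined) NA_real_ else (C - D) / den,
                 C = C, D = D, T_dock = T_dock, T_exp = T_exp,
                 T_both = T_both, n = n, undefined = undefined),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (!is.null(x$rho))
    cat(sprintf("<correlation> Spearman rho = %s (n = %d)\n",
                format(x$rho, digits = 4), x$n))
  if (!is.null(x$tau_b))
    cat(sprintf(
      "<correlation> Kendall tau-b = %s (C = %d, D = %d, T_dock = %d, T_exp = %d, n = %d)\n",
      format(x$tau_b, digits = 4), x$C, x$D, x$T_dock, x$T_exp, x$n))
  invisible(x)
}

#' Thresholds analysis
#'
#' Classifies each compound against hard boundaries on the docking score and
#' the experimental value. A value better than *or equal to* its threshold
#' counts as "active" on that axis (one consistent boundary rule, relevant
#' when the experimental threshold sits at a censored LOQ value). Quadrants:
#' TP (both active), FP (dock active only), FN (experiment active only),
#' TN (neither).
#'
#' @param data A [paired_measurements()].
#' @param score_thr Finite docking-score threshold.
#' @param exp_thr Finite experimental threshold.
#' @return A `threshold_report`: list with `counts` (named TP/FP/FN/TN),
#'   `fractions`, the thresholds and `n`.
#' @export
thresholds_report <- function(data, score_thr, exp_thr) {
  stopifnot(inherits(data, "paired_measurements"))
  if (!is_num(score_thr) || !is_num(exp_thr))
    fail("thresholds must be finite numbers")
  dock_active <- .goodness(data$dock, data$dock_direction) >=
    .goodness(score_thr, data$dock_direction)
  exp_active <- .goodness(data$exper, data$exp_direction) >=
    .goodness(exp_thr, data$exp_direction)
  counts <- c(TP = sum(dock_active & exp_active),
              FP = sum(dock_active & !exp_active),
              FN = sum(!dock_active & exp_active),
              TN = sum(!dock_active & !exp_active))
  structure(list(counts = counts, fractions = counts / data$n,
                 score_threshold = score_thr, exp_threshold = exp_thr,
                 n = data$n),
            class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf(
    "<thresholds> score <=/>= %s, experiment <=/>= %s (boundary counts as active)\n",
    format(x$score_threshold), format(x$exp_threshold)))
  print(x$counts)
  invisible(x)
}
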