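# Voxelwise prediction assessment of cumulative decorrelation maps against
# ablation masks: ROC and precision-recall curves, areas, optimal and
# 90%-specificity thresholds, the minimum-achievable-AUPR correction, and
# significance tests scaled by the effective number of independent
# predictions.

#' Collect voxelwise (score, label) pairs from a trial
#'
#' Pairs each evaluation-ROI voxel's log10-scaled cumulative decorrelation
#' (the prediction score) with its ground-truth ablation label. Voxels with
#' zero cumulative decorrelation receive a floor score one decade below the
#' smallest positive score, so they rank below every observed value.
#'
#' @param cum A `cumulative_map`.
#' @param truth An `ablation_mask` (ground truth).
#' @param eval_roi Logical array or `ablation_mask` selecting the evaluation
#'   ROI (typically the 25 mm-radius sphere around the needle tip).
#' @return A data frame with columns `score` (log10 ms^-1) and `label`
#'   (0/1), plus attributes `skew` (class skew pi) and `degenerate` (TRUE
#'   when truth has no positive or no negative voxel in the ROI, in which
#'   case downstream curves are undefined).
#' @export
collect_predictions <- function(cum, truth, eval_roi) {
  if (inherits(eval_roi, "ablation_mask")) eval_roi <- eval_roi$mask
  tr <- if (inherits(truth, "ablation_mask")) truth$mask else truth
  sel <- eval_roi & !is.na(cum$delta)
  vals <- cum$delta[sel]
  labs <- as.integer(tr[sel])
  pos <- vals > 0
  if (any(pos)) {
    floor_score <- min(log10(vals[pos])) - 1
    score <- ifelse(pos, log10(pmax(vals, .Machine$double.xmin)), floor_score)
  } else {
    score <- rep(-Inf, length(vals))
  }
  out <- data.frame(score = score, label = labs)
  attr(out, "skew") <- mean(labs)
  attr(out, "degenerate") <- !(any(labs == 1) && any(labs == 0))
  out
}

# Shared curve scaffolding: order scores descending, group ties, and return
# cumulative positive / negative counts at each distinct threshold.
threshold_counts <- function(score, label) {
  if (!(any(label == 1) && any(label == 0)))
    stop("degenerate group: need both positive and negative voxels",
         call. = FALSE)
  o <- order(score, decreasing = TRUE)
  s <- score[o]; y <- label[o]
  idx <- which(rev(!duplicated(rev(s))))   # last index of each tie group
  tp <- cumsum(y)[idx]
  fp <- cumsum(1 - y)[idx]
  list(threshold = s[idx], tp = tp, fp = fp,
       n_pos = sum(label == 1), n_neg = sum(label == 0))
}

#' ROC analysis of a voxel prediction group
#'
#' Builds the ROC curve over all distinct score thresholds (ties grouped;
#' prediction is positive where `score >= threshold`), computes AUROC by the
#' trapezoid rule (equal to the tie-corrected Mann-Whitney statistic), the
#' threshold maximizing Youden's J = TPR - FPR, and the 90%-specificity
#' cutoff: the smallest threshold achieving specificity >= 0.90, i.e. the
#' most sensitive operating point still meeting the specificity requirement.
#'
#' @param group Data frame with `score` and `label` columns (see
#'   [collect_predictions()]), or two vectors via `score=`/`label=`.
#' @param specificity_target Specificity level for the reported cutoff.
#' @return List with `curve` (threshold, fpr, tpr), `auroc`,
#'   `threshold_jmax`, `jmax`, `threshold_spec`, `sensitivity_at_spec`,
#'   `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(group, specificity_target = 0.90) {
  tc <- threshold_counts(group$score, group$label)
  tpr <- tc$tp / tc$n_pos
  fpr <- tc$fp / tc$n_neg
  # prepend the all-negative operating point
  fpr0 <- c(0, fpr); tpr0 <- c(0, tpr)
  auroc <- sum(diff(fpr0) * (utils::head(tpr0, -1) + utils::tail(tpr0, -1)) / 2)
  j <- tpr - fpr
  jbest <- which.max(j)
  ok <- fpr <= 1 - specificity_target + 1e-12
  if (any(ok)) {
    k <- max(which(ok))   # smallest threshold (ties toward sensitivity)
    thr_spec <- tc$threshold[k]
    sens_spec <- tpr[k]
  } else {
    thr_spec <- NA_real_; sens_spec <- NA_real_
  }
  list(curve = data.frame(threshold = tc$threshold, fpr = fpr, tpr = tpr),
       auroc = auroc,
       threshold_jmax = tc$threshold[jbest], jmax = j[jbest],
       threshold_spec = thr_spec, sensitivity_at_spec = sens_spec,
       specificity_target = specificity_target,
       n_pos = tc$n_pos, n_neg = tc$n_neg)
}

#' Precision-recall analysis of a voxel prediction group
#'
#' Builds the PR curve over all distinct thresholds (ties grouped), computes
#' AUPR by the trapezoid rule over the stepwise empirical curve (an
#' average-precision summation is available via `method`), and the threshold
#' maximizing the F1 score (harmonic mean of precision and recall; identical
#' to the Dice coefficient of the thresholded map against truth).
#'
#' @param group Data frame with `score` and `label` columns.
#' @param method `"trapezoid"` (default) or `"average_precision"`.
#' @return List with `curve` (threshold, recall, precision), `aupr`, `skew`,
#'   `aupr_min`, `threshold_f1max`, `f1max`, `n_pos`, `n_neg`.
#' @export
pr_analysis <- function(group, method = c("trapezoid", "average_precision")) {
  method <- match.arg(method)
  tc <- threshold_counts(group$score, group$label)
  recall <- tc$tp / tc$n_pos
  precision <- tc$tp / (tc$tp + tc$fp)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  fbest <- which.max(f1)
  if (method == "trapezoid") {
    aupr <- sum(diff(c(0, recall)) *
                  (c(precision[1], utils::head(precision, -1)) + precision) / 2)
  } else {
    aupr <- sum(diff(c(0, recall)) * precision)
  }
  skew <- tc$n_pos / (tc$n_pos + tc$n_neg)
  list(curve = data.frame(threshold = tc$threshold, recall = recall,
                          precision = precision, f1 = f1),
       aupr = aupr, skew = skew, aupr_min = min_achievable_aupr(skew),
       threshold_f1max = tc$threshold[fbest], f1max = f1[fbest],
       n_pos = tc$n_pos, n_neg = tc$n_neg)
}

#' Full prediction assessment of one voxel group
#'
#' Convenience wrapper combining [roc_analysis()] and [pr_analysis()] and the
#' effective-sample-size bookkeeping.
#'
#' @param group Data frame with `score` and `label`.
#' @param l_mm,sigma_mm Grid pitch and window width for the effective
#'   fraction (defaults 0.5 and 3).
#' @return An object of class `prediction_result`.
#' @export
prediction_result <- function(group, l_mm = 0.5, sigma_mm = 3) {
  roc <- roc_analysis(group)
  pr <- pr_analysis(group)
  n_tot <- nrow(group)
  frac <- effective_fraction(l_mm, sigma_mm)
  structure(list(roc = roc, pr = pr, auroc = roc$auroc, aupr = pr$aupr,
                 aupr_min = pr$aupr_min, skew = pr$skew,
                 n_total = n_tot, neff_fraction = frac,
                 n_effective = frac * n_tot),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> AUROC %.3f, AUPR %.3f (floor %.4f), skew %.3f, Ntot %d (Neff %.0f)\n",
              x$auroc, x$aupr, x$aupr_min, x$skew, x$n_total, x$n_effective))
  invisible(x)
}

#' Minimum achievable area under a PR curve
#'
#' The PR curve of a non-informative ranking cannot fall below
#' `precision(r) = pi * r / (pi * r + 1 - pi)`; integrating over recall gives
#' the closed form `1 + (1 - pi) * log(1 - pi) / pi`, which tends to `pi / 2`
#' as the class skew vanishes. Subtracting (or at least reporting) this floor
#' keeps AUPR comparisons meaningful across skews; for skews at or below 0.1
#' the floor is small enough to neglect.
#'
#' @param skew Class skew pi in (0, 1).
#' @return The minimum achievable AUPR.
#' @export
min_achievable_aupr <- function(skew) {
  if (any(skew <= 0 | skew >= 1))
    stop("skew must lie in (0, 1)", call. = FALSE)
  1 + (1 - skew) * log1p(-skew) / skew
}

#' Effective fraction of independent voxel predictions
#'
#' Voxels within one correlation window are not independent predictions; the
#' effective fraction `Neff / Ntot = sqrt(2 * (l / d)^3)` with
#' `d = 2.355 * sigma` (the window's full width at half maximum) discounts
#' the voxel count accordingly.
#'
#' @param l_mm Isotropic grid step in mm.
#' @param sigma_mm Gaussian window width parameter in mm.
#' @return The fraction `Neff / Ntot`.
#' @export
effective_fraction <- function(l_mm, sigma_mm) {
  if (any(l_mm <= 0) || any(sigma_mm <= 0))
    stop("l_mm and sigma_mm must be positive", call. = FALSE)
  d <- 2.355 * sigma_mm
  sqrt(2 * (l_mm / d)^3)
}

# Hanley-McNeil-type variance of an AUC estimate at given positive/negative
# counts (the general, distribution-free model).
auc_variance <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  (auc * (1 - auc) + max(n_pos - 1, 0) * (q1 - auc^2) +
     max(n_neg - 1, 0) * (q2 - auc^2)) / (n_pos * n_neg)
}

#' Z test comparing AUROC values with effective-sample-size scaling
#'
#' Compares a group's AUROC against another group (two-tailed by default) or
#' against the no-information null AUROC = 0.5 (one-tailed by default),
#' using the general Hanley-McNeil model for the AUC standard error. The
#' spatial correlation of voxels is accounted for by evaluating the
#' variances at `Neff = neff_fraction * Ntot` positives and negatives
#' (proportions preserved); alternatively (`scale_mode = "z_factor"`) the Z
#' score computed at full counts is multiplied by `sqrt(neff_fraction)`.
#'
#' @param result_a A `prediction_result` (or list with `auroc`, and `roc`
#'   carrying `n_pos`, `n_neg`).
#' @param result_b Second group, or `NULL` to test against AUROC = 0.5.
#' @param neff_fraction Effective fraction `Neff / Ntot` (1 = independent).
#' @param sidedness `"one"` or `"two"`; defaults to one-tailed against the
#'   null and two-tailed between groups.
#' @param scale_mode `"neff"` (default) or `"z_factor"`.
#' @return List with `z`, `p`, `delta_auc`, `se`.
#' @export
compare_auroc <- function(result_a, result_b = NULL, neff_fraction = 1,
                          sidedness = NULL,
                          scale_mode = c("neff", "z_factor")) {
  scale_mode <- match.arg(scale_mode)
  if (is.null(sidedness)) sidedness <- if (is.null(result_b)) "one" else "two"
  sidedness <- match.arg(sidedness, c("one", "two"))
  f <- if (scale_mode == "neff") neff_fraction else 1
  get_parts <- function(r) {
    np <- r$roc$n_pos; nn <- r$roc$n_neg
    if (np < 1 || nn < 1)
      stop("degenerate group: no positives or no negatives", call. = FALSE)
    list(auc = r$auroc, v = auc_variance(r$auroc, np * f, nn * f))
  }
  a <- get_parts(result_a)
  if (is.null(result_b)) {
    delta <- a$auc - 0.5
    v <- a$v
  } else {
    b <- get_parts(result_b)
    delta <- a$auc - b$auc
    v <- a$v + b$v
  }
  se <- sqrt(v)
  z <- if (se == 0) 0 else delta / se
  if (scale_mode == "z_factor") z <- z * sqrt(neff_fraction)
  p <- if (sidedness == "one") stats::pnorm(z, lower.tail = FALSE)
       else 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  list(z = z, p = min(p, 1), delta_auc = delta, se = se,
       sidedness = sidedness)
}

# AUPR of raw vectors (internal, used by the bootstrap).
aupr_of <- function(score, label) {
  tc <- threshold_counts(score, label)
  recall <- tc$tp / tc$n_pos
  precision <- tc$tp / (tc$tp + tc$fp)
  sum(diff(c(0, recall)) *
        (c(precision[1], utils::head(precision, -1)) + precision) / 2)
}

#' Bootstrap Z test for a difference in AUPR
#'
#' Resamples the (score, label) pairs of each group independently with
#' replacement, recomputes the AUPR difference for each draw, and forms a Z
#' score from the observed difference and the bootstrap standard error. The
#' standard error is inflated by `1 / sqrt(neff_fraction)` to account for the
#' effective number of independent voxels. Seeded and reproducible.
#'
#' @param group_a,group_b Data frames with `score` and `label`.
#' @param n_boot Number of bootstrap draws (default 5000).
#' @param neff_fraction Effective fraction `Neff / Ntot`.
#' @param seed Integer seed.
#' @return List with `z`, `p` (two-tailed), `delta_aupr`, `se`.
#' @export
compare_aupr_bootstrap <- function(group_a, group_b, n_boot = 5000,
                                   neff_fraction = 1, seed) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  obs <- aupr_of(group_a$score, group_a$label) -
    aupr_of(group_b$score, group_b$label)
  na <- nrow(group_a); nb <- nrow(group_b)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      ia <- sample.int(na, na, replace = TRUE)
      ib <- sample.int(nb, nb, replace = TRUE)
      ga_s <- group_a$score[ia]; ga_l <- group_a$label[ia]
      gb_s <- group_b$score[ib]; gb_l <- group_b$label[ib]
      if (!(any(ga_l == 1) && any(ga_l == 0) &&
            any(gb_l == 1) && any(gb_l == 0))) return(NA_real_)
      aupr_of(ga_s, ga_l) - aupr_of(gb_s, gb_l)
    }, numeric(1))
  })
  boots <- boots[!is.na(boots)]
  se <- stats::sd(boots) / sqrt(neff_fraction)
  z <- if (se == 0) 0 else obs / se
  p <- min(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  list(z = z, p = p, delta_aupr = obs, se = se, n_boot = length(boots))
}
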