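# Group-level statistics on trial outcome tables: success-rate proportions
# and chi-squared tests, normality / variance screens, three-factor
# ANOVA or Kruskal-Wallis with post hocs, variance F tests, and the simple
# and tissue-condition multiple regressions.

TISSUES <- c("normal", "steatotic", "cirrhotic")
LABELS <- c("UC", "SC", "USC")

#' Validate and coerce an outcome table
#'
#' One row per trial with the fixed vocabularies for tissue and control
#' condition and the four numeric outcomes.
#'
#' @param df Data frame with columns `trial_id`, `tissue`, `label`,
#'   `gender`, `volume_ml`, `rate_ml_min`, `dice_vs_target`,
#'   `final_roi_log10`, `duration_min`.
#' @return The validated data frame (class `outcome_table` prepended).
#' @export
outcome_table <- function(df) {
  need <- c("trial_id", "tissue", "label", "gender", "volume_ml",
            "rate_ml_min", "dice_vs_target", "final_roi_log10",
            "duration_min")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing outcome columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(df$tissue %in% TISSUES))
    stop("tissue must be one of: ", paste(TISSUES, collapse = ", "),
         call. = FALSE)
  if (!all(df$label %in% LABELS))
    stop("label must be one of: ", paste(LABELS, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$trial_id))
    stop("one row per trial required", call. = FALSE)
  num <- c("volume_ml", "rate_ml_min", "dice_vs_target", "final_roi_log10",
           "duration_min")
  for (v in num) {
    df[[v]] <- as.numeric(df[[v]])
    if (any(!is.finite(df[[v]])))
      stop("non-finite values in ", v, call. = FALSE)
  }
  class(df) <- unique(c("outcome_table", class(df)))
  df
}

#' Control success rates with pairwise chi-squared comparisons
#'
#' Success proportions per tissue condition (SC trials over control
#' attempts) and pairwise 2x2 Pearson chi-squared tests (df = 1) between
#' tissues. The continuity correction is off by default; it can be enabled.
#'
#' @param successes Named integer vector of SC counts per tissue.
#' @param attempts Named integer vector of control attempts per tissue
#'   (same names).
#' @param correct Apply Yates' continuity correction.
#' @return List with `proportions` (fractions), `percent`, and `pairwise`
#'   (data frame of group pair, chi-squared statistic and p value).
#' @export
success_rates <- function(successes, attempts, correct = FALSE) {
  if (!identical(names(successes), names(attempts)))
    stop("successes and attempts must share names", call. = FALSE)
  if (any(successes > attempts) || any(attempts <= 0))
    stop("counts inconsistent", call. = FALSE)
  props <- successes / attempts
  groups <- names(successes)
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(g) {
    tab <- rbind(c(successes[g[1]], attempts[g[1]] - successes[g[1]]),
                 c(successes[g[2]], attempts[g[2]] - successes[g[2]]))
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    data.frame(group_a = g[1], group_b = g[2],
               chisq = unname(ct$statistic), p = unname(ct$p.value))
  }))
  list(proportions = props, percent = 100 * props, pairwise = pw)
}

#' Normality and variance-homogeneity screens
#'
#' Shapiro-Wilk per tissue-by-control group and Bartlett's test across
#' groups, for one outcome variable. The routing decision mirrors the
#' analysis protocol: the parametric branch (ANOVA + Tukey) is taken when
#' variances are homogeneous (Bartlett p >= alpha), the rank branch
#' (Kruskal-Wallis + Dunn) otherwise.
#'
#' @param table An [outcome_table()].
#' @param outcome Name of the outcome column.
#' @param alpha Significance level for routing (default 0.05).
#' @return List with `shapiro` (per-group data frame), `bartlett_p`,
#'   `normal` (all groups pass Shapiro at alpha), `homogeneous`, and
#'   `branch` (`"parametric"` or `"rank"`).
#' @export
screen_assumptions <- function(table, outcome, alpha = 0.05) {
  y <- table[[outcome]]
  g <- interaction(table$tissue, table$label, drop = TRUE)
  sw <- do.call(rbind, lapply(levels(g), function(lv) {
    yy <- y[g == lv]
    p <- if (length(yy) >= 3 && stats::sd(yy) > 0)
      stats::shapiro.test(yy)$p.value else NA_real_
    data.frame(group = lv, n = length(yy), shapiro_p = p)
  }))
  keep <- tapply(y, g, function(v) length(v) >= 2 && stats::sd(v) > 0)
  if (sum(keep) < 2 || stats::sd(y) == 0)
    stop("degenerate outcome: no variation to test", call. = FALSE)
  bt <- stats::bartlett.test(y[g %in% names(keep)[keep]],
                             droplevels(g[g %in% names(keep)[keep]]))
  homo <- bt$p.value >= alpha
  list(shapiro = sw, bartlett_p = bt$p.value,
       normal = all(is.na(sw$shapiro_p) | sw$shapiro_p >= alpha),
       homogeneous = homo,
       branch = if (homo) "parametric" else "rank")
}

# Dunn's rank-based post hoc test for all pairwise comparisons of one
# factor, with tie correction and Bonferroni adjustment.
dunn_test <- function(y, g, p_adjust = "bonferroni") {
  g <- droplevels(as.factor(g))
  n <- length(y)
  r <- rank(y)
  ties <- table(y)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  lv <- levels(g)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  res <- do.call(rbind, lapply(pairs, function(pr) {
    i <- g == pr[1]; j <- g == pr[2]
    ni <- sum(i); nj <- sum(j)
    zden <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ni + 1 / nj))
    z <- (mean(r[i]) - mean(r[j])) / zden
    data.frame(group_a = pr[1], group_b = pr[2], z = z,
               p = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  }))
  res$p_adj <- stats::p.adjust(res$p, method = p_adjust)
  res
}

#' Omnibus comparison of an outcome across tissue, control and gender
#'
#' Routes by [screen_assumptions()]: with homogeneous variances, a
#' three-factor ANOVA (type-II sums of squares, appropriate for the
#' unbalanced and incomplete design) followed by Tukey's HSD on significant
#' factors; otherwise per-factor Kruskal-Wallis rank-sum tests followed by
#' Dunn's test with Bonferroni adjustment on significant factors.
#'
#' @param table An [outcome_table()].
#' @param outcome Name of the outcome column.
#' @param alpha Significance level.
#' @return List with `branch`, `screen`, `omnibus` (per-factor p values) and
#'   `posthoc` (per significant factor, adjusted pairwise results).
#' @export
group_compare <- function(table, outcome, alpha = 0.05) {
  if (stats::sd(table[[outcome]]) == 0)
    stop("degenerate outcome: constant values", call. = FALSE)
  scr <- screen_assumptions(table, outcome, alpha)
  df <- data.frame(y = table[[outcome]],
                   tissue = factor(table$tissue, TISSUES),
                   control = factor(table$label, LABELS),
                   gender = factor(table$gender))
  df <- droplevels(df)
  factors <- c("tissue", "control", "gender")
  factors <- factors[vapply(factors, function(f) nlevels(df[[f]]) >= 2,
                            logical(1))]
  posthoc <- list()
  if (scr$branch == "parametric") {
    fml <- stats::as.formula(paste("y ~", paste(factors, collapse = " + ")))
    fit <- stats::lm(fml, data = df)
    an <- car::Anova(fit, type = 2)
    omni <- stats::setNames(an[factors, "Pr(>F)"], factors)
    for (f in names(omni)) {
      if (!is.na(omni[f]) && omni[f] < alpha) {
        aovfit <- stats::aov(fml, data = df)
        tk <- stats::TukeyHSD(aovfit, which = f)[[f]]
        posthoc[[f]] <- data.frame(comparison = rownames(tk),
                                   diff = tk[, "diff"],
                                   p_adj = tk[, "p adj"],
                                   row.names = NULL)
      }
    }
  } else {
    omni <- vapply(factors, function(f)
      stats::kruskal.test(df$y, df[[f]])$p.value, numeric(1))
    for (f in names(omni)) {
      if (!is.na(omni[f]) && omni[f] < alpha)
        posthoc[[f]] <- dunn_test(df$y, df[[f]])
    }
  }
  list(branch = scr$branch, screen = scr, omnibus = omni, posthoc = posthoc)
}

#' Two-sample F test for equality of variances
#'
#' @param x,y Numeric samples.
#' @return List with `statistic` (ratio of sample variances), `p`
#'   (two-sided) and `df`.
#' @export
variance_f_test <- function(x, y) {
  vt <- stats::var.test(x, y)
  list(statistic = unname(vt$statistic), p = vt$p.value,
       df = unname(vt$parameter))
}

regression_result <- function(fit, y) {
  sm <- summary(fit)
  fitted <- stats::fitted(fit)
  fstat <- sm$fstatistic
  overall_p <- if (is.null(fstat)) NA_real_
    else unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  structure(list(
    coefficients = data.frame(term = rownames(sm$coefficients),
                              estimate = sm$coefficients[, "Estimate"],
                              se = sm$coefficients[, "Std. Error"],
                              p = sm$coefficients[, "Pr(>|t|)"],
                              row.names = NULL),
    r = if (stats::sd(fitted) == 0) 0 else stats::cor(fitted, y),
    rmse = sqrt(mean((fitted - y)^2)),
    overall_p = overall_p,
    n = length(y), fit = fit), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> n=%d, r=%.3f, RMSE=%.4g, overall p=%.3g\n",
              x$n, x$r, x$rmse, x$overall_p))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Simple linear regression of an outcome on echo decorrelation
#'
#' Ordinary least squares line of best fit, reporting the Pearson
#' correlation between fitted and measured values, the RMS error, the
#' two-sided p value for the slope, and the overall F-test p.
#'
#' @param y Outcome values.
#' @param x Predictor (typically final log10-scaled ROI-average
#'   decorrelation).
#' @return A `regression_result`.
#' @export
simple_regression <- function(y, x) {
  if (length(y) != length(x)) stop("length mismatch", call. = FALSE)
  regression_result(stats::lm(y ~ x), y)
}

#' Multiple regression of an outcome on decorrelation and tissue condition
#'
#' OLS with intercept, the final log10-scaled ROI-average cumulative
#' decorrelation, and binary indicators for steatosis and cirrhosis.
#' Rank-deficient designs (e.g. collinear duplicate predictors) are an
#' error rather than being silently dropped.
#'
#' @param outcome Outcome values.
#' @param final_roi_log10 Decorrelation predictor.
#' @param steatotic_flag,cirrhotic_flag 0/1 tissue indicators.
#' @return A `regression_result`.
#' @export
tissue_regression <- function(outcome, final_roi_log10, steatotic_flag,
                              cirrhotic_flag) {
  X <- data.frame(y = outcome, logD = final_roi_log10,
                  steatotic = as.numeric(steatotic_flag),
                  cirrhotic = as.numeric(cirrhotic_flag))
  fit <- stats::lm(y ~ logD + steatotic + cirrhotic, data = X)
  if (fit$qr$rank < 4 || any(is.na(stats::coef(fit))))
    stop("rank-deficient design: collinear predictors", call. = FALSE)
  regression_result(fit, X$y)
}
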