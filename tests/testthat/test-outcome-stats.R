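test_that("success rates reproduce the printed trial counts and hand-checked
           chi-squared values", {
  sr <- success_rates(c(normal = 14, steatotic = 11, cirrhotic = 6),
                      c(normal = 16, steatotic = 24, cirrhotic = 15))
  expect_equal(unname(sr$percent), c(87.5, 11 / 24 * 100, 40.0))
  # hand-computed Pearson chi-squared on the 2x2 tables (no correction):
  # normal vs steatotic: expected 10/6/15/9 -> chi2 = 16 * sum(1/e) = 7.1111
  ns <- sr$pairwise[sr$pairwise$group_a == "normal" &
                      sr$pairwise$group_b == "steatotic", ]
  expect_equal(ns$chisq, 16 * (1 / 10 + 1 / 6 + 1 / 15 + 1 / 9),
               tolerance = 1e-9)
  expect_equal(ns$p, 0.00766, tolerance = 1e-3)
  nc <- sr$pairwise[sr$pairwise$group_a == "normal" &
                      sr$pairwise$group_b == "cirrhotic", ]
  expect_equal(nc$chisq, 31 * (14 * 9 - 2 * 6)^2 / (16 * 15 * 20 * 11),
               tolerance = 1e-9)
  expect_equal(nc$p, 0.005740, tolerance = 1e-3)
  # equal proportions: chi2 = 0, p = 1
  eq <- success_rates(c(a = 8, b = 8), c(a = 16, b = 16))
  expect_equal(eq$pairwise$chisq, 0)
  expect_equal(eq$pairwise$p, 1)
  expect_error(success_rates(c(a = 5), c(b = 4)), "names")
  expect_error(success_rates(c(a = 5), c(a = 4)), "inconsistent")
})

test_that("assumption screens route to the expected branch", {
  tab <- fake_outcomes(n_per_group = 10, seed = 21)
  scr <- screen_assumptions(tab, "volume_ml")
  expect_true(scr$homogeneous)
  expect_equal(scr$branch, "parametric")
  expect_equal(nrow(scr$shapiro), 9)
  # a 10x variance group flips Bartlett
  het <- fake_outcomes(n_per_group = 14, seed = 22, rate_sd_mult = 10)
  scr2 <- screen_assumptions(het, "rate_ml_min")
  expect_lt(scr2$bartlett_p, 0.01)
  expect_equal(scr2$branch, "rank")
  con <- tab
  con$volume_ml <- 1
  expect_error(screen_assumptions(con, "volume_ml"), "degenerate")
})

test_that("group comparison finds a planted tissue effect and flags
           constant outcomes", {
  shifted <- fake_outcomes(n_per_group = 14, seed = 23, tissue_shift = 2)
  gc <- group_compare(shifted, "volume_ml")
  expect_equal(gc$branch, "parametric")
  expect_lt(gc$omnibus[["tissue"]], 0.01)
  expect_true("tissue" %in% names(gc$posthoc))
  ph <- gc$posthoc$tissue
  expect_true(any(ph$p_adj < 0.05))
  con <- shifted
  con$volume_ml <- 2
  expect_error(group_compare(con, "volume_ml"), "degenerate")
})

test_that("rank branch runs Kruskal-Wallis with Dunn post hocs", {
  het <- fake_outcomes(n_per_group = 14, seed = 24, rate_sd_mult = 10)
  het$rate_ml_min <- het$rate_ml_min +
    ifelse(het$tissue == "normal", 1.0, 0)   # median shift
  gc <- group_compare(het, "rate_ml_min")
  expect_equal(gc$branch, "rank")
  expect_lt(gc$omnibus[["tissue"]], 0.05)
  dn <- gc$posthoc$tissue
  expect_true(all(c("z", "p_adj") %in% names(dn)))
  expect_true(all(dn$p_adj >= dn$p - 1e-12))
  # two-group Dunn z agrees with the Kruskal-Wallis chi-squared
  y <- c(rnorm(10), rnorm(10) + 2)
  g <- rep(c("a", "b"), each = 10)
  dz <- echodecorr:::dunn_test(y, g)$z
  kw <- stats::kruskal.test(y, factor(g))$statistic
  expect_equal(dz^2, unname(kw), tolerance = 1e-9)
})

test_that("variance F test equals the sample-variance ratio", {
  set.seed(25)
  x <- rnorm(14); y <- rnorm(14, sd = 2)
  ft <- variance_f_test(x, y)
  expect_equal(ft$statistic, var(x) / var(y), tolerance = 1e-12)
  same <- variance_f_test(x, x)
  expect_equal(same$statistic, 1)
  expect_equal(same$p, 1)
})

test_that("simple regression matches closed-form normal equations", {
  # exact line
  x <- c(1, 2, 3, 4, 5)
  r <- suppressWarnings(simple_regression(2 * x, x))
  expect_equal(r$r, 1)
  expect_lt(r$rmse, 1e-12)
  expect_equal(r$coefficients$estimate[2], 2)
  # printed 5-point toy set, hand normal equations
  xt <- c(-3.2, -2.9, -2.7, -2.5, -2.1)
  yt <- c(2.1, 3.4, 3.0, 4.4, 4.9)
  slope <- sum((xt - mean(xt)) * (yt - mean(yt))) / sum((xt - mean(xt))^2)
  inter <- mean(yt) - slope * mean(xt)
  rt <- simple_regression(yt, xt)
  expect_equal(rt$coefficients$estimate, c(inter, slope), tolerance = 1e-12)
  expect_equal(rt$r, abs(cor(xt, yt)), tolerance = 1e-12)
})

test_that("tissue regression recovers exact coefficients and rejects
           collinear designs", {
  set.seed(26)
  n <- 60
  logd <- rnorm(n, -2.8, 0.4)
  ste <- rbinom(n, 1, 0.4)
  cir <- ifelse(ste == 1, 0, rbinom(n, 1, 0.5))
  y <- 1 + 0.5 * logd - 0.8 * ste
  r <- suppressWarnings(tissue_regression(y, logd, ste, cir))
  expect_equal(r$coefficients$estimate, c(1, 0.5, -0.8, 0),
               tolerance = 1e-10)
  expect_lt(r$rmse, 1e-10)
  expect_error(tissue_regression(y, logd, ste, ste), "collinear")
})

test_that("planted steatosis effect is recovered at the study scale", {
  # n = 97 trials, true steatosis effect -1.0 ml, noise sigma = 1: the 95%
  # interval for the steatosis coefficient should cover the truth in almost
  # all replicates
  covered <- vapply(1:40, function(rep) {
    set.seed(300 + rep)
    n <- 97
    logd <- rnorm(n, -2.8, 0.4)
    ste <- rbinom(n, 1, 0.39)
    cir <- ifelse(ste == 1, 0, rbinom(n, 1, 0.48))
    y <- 4 + 0.3 * logd - 1.0 * ste + 0.2 * cir + rnorm(n, 0, 1)
    r <- tissue_regression(y, logd, ste, cir)
    est <- r$coefficients$estimate[3]
    se <- r$coefficients$se[3]
    abs(est + 1) <= stats::qnorm(0.975) * se
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})
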