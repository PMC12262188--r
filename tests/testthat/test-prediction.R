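test_that("collected predictions have the geometric class skew and flag
           degenerate truth", {
  grid <- cartesian_grid(60, 0.5)
  eval_roi <- sphere_mask(grid, c(0, 0, 0), 50)
  truth <- sphere_mask(grid, c(0, 0, 0), 20)
  cum <- empty_cumulative(grid)
  set.seed(1)
  cum$delta[] <- runif(length(cum$delta), 0, 0.02)
  g <- collect_predictions(cum, truth, eval_roi)
  expect_equal(nrow(g), sum(eval_roi$mask))
  # 20 mm sphere inside a 25 mm-radius ROI: skew (10/25)^3 = 0.064 <= 0.07
  expect_equal(attr(g, "skew"), 0.064, tolerance = 0.02)
  expect_lte(attr(g, "skew"), 0.07)
  expect_false(attr(g, "degenerate"))
  # empty truth: all labels zero, flagged
  none <- ablation_mask(array(FALSE, echodecorr:::grid_dim(grid)), grid)
  g0 <- collect_predictions(cum, none, eval_roi)
  expect_true(attr(g0, "degenerate"))
  expect_true(all(g0$label == 0))
  # zero voxels score strictly below every positive value
  cumz <- cum
  idx <- which(eval_roi$mask)[1:100]
  cumz$delta[idx] <- 0
  gz <- collect_predictions(cumz, truth, eval_roi)
  zmin <- min(gz$score[gz$score > min(gz$score)])
  expect_lt(min(gz$score), zmin)
})

test_that("AUROC equals brute-force concordant-pair counting", {
  # printed toy: scores .9 .8 .7 .6, labels 1 1 0 1 -> AUROC 2/3
  g <- data.frame(score = c(0.9, 0.8, 0.7, 0.6), label = c(1, 1, 0, 1))
  expect_equal(roc_analysis(g)$auroc, 2 / 3)
  # random instances incl. ties, <= 200 voxels
  set.seed(2)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    score <- sample(seq(-5, -1, by = 0.25), n, replace = TRUE)  # many ties
    label <- rbinom(n, 1, 0.3)
    if (sum(label) == 0 || sum(label) == n) next
    g <- data.frame(score = score, label = label)
    expect_equal(roc_analysis(g)$auroc, pair_count_auroc(score, label),
                 tolerance = 1e-12)
  }
})

test_that("AUROC agrees with pROC and is ~0.5 for permuted labels", {
  skip_if_not_installed("pROC")
  set.seed(3)
  n <- 500
  score <- rnorm(n) + 0.8 * (label <- rbinom(n, 1, 0.3))
  g <- data.frame(score = score, label = label)
  ours <- roc_analysis(g)$auroc
  ref <- suppressMessages(pROC::auc(pROC::roc(label, score, quiet = TRUE)))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
  # permuted null at 1e4 voxels
  set.seed(4)
  gp <- data.frame(score = rnorm(1e4), label = rbinom(1e4, 1, 0.1))
  expect_equal(roc_analysis(gp)$auroc, 0.5, tolerance = 0.04)
})

test_that("Youden and 90%-specificity thresholds match exhaustive sweeps", {
  set.seed(5)
  n <- 400
  label <- rbinom(n, 1, 0.3)
  score <- round(rnorm(n) + label, 1)
  g <- data.frame(score = score, label = label)
  r <- roc_analysis(g)
  # exhaustive sweep over candidate thresholds
  cand <- sort(unique(score))
  j <- vapply(cand, function(t) {
    pred <- score >= t
    tpr <- sum(pred & label == 1) / sum(label == 1)
    fpr <- sum(pred & label == 0) / sum(label == 0)
    tpr - fpr
  }, numeric(1))
  expect_equal(r$jmax, max(j))
  expect_equal(r$threshold_jmax, cand[which.max(j)])
  # smallest threshold with specificity >= 0.9
  spec <- vapply(cand, function(t)
    1 - sum(score >= t & label == 0) / sum(label == 0), numeric(1))
  ok <- cand[spec >= 0.9]
  expect_equal(r$threshold_spec, min(ok))
  expect_equal(r$sensitivity_at_spec,
               sum(score >= min(ok) & label == 1) / sum(label == 1))
  # perfect separation
  gp <- data.frame(score = c(3, 2, 1, 0), label = c(1, 1, 0, 0))
  rp <- roc_analysis(gp)
  expect_equal(rp$auroc, 1)
  expect_equal(rp$jmax, 1)
})

test_that("PR curve matches an exhaustive enumeration oracle", {
  # six-voxel toy: scores 6..1, labels 1 1 0 1 0 0
  g <- data.frame(score = 6:1, label = c(1, 1, 0, 1, 0, 0))
  p <- pr_analysis(g)
  # oracle: walk thresholds by hand
  cand <- sort(unique(g$score), decreasing = TRUE)
  rec <- prec <- numeric(length(cand))
  for (i in seq_along(cand)) {
    pred <- g$score >= cand[i]
    rec[i] <- sum(pred & g$label == 1) / sum(g$label == 1)
    prec[i] <- sum(pred & g$label == 1) / sum(pred)
  }
  aupr_oracle <- sum(diff(c(0, rec)) *
                       (c(prec[1], head(prec, -1)) + prec) / 2)
  expect_equal(p$aupr, aupr_oracle)
  expect_equal(p$curve$recall, rec)
  expect_equal(p$curve$precision, prec)
  # lowest threshold predicts everything positive: precision = skew there
  expect_equal(p$curve$precision[length(cand)], 0.5)
  # perfect separation
  pp <- pr_analysis(data.frame(score = c(2, 2, 1, 1),
                               label = c(1, 1, 0, 0)))
  expect_equal(pp$aupr, 1)
  expect_equal(pp$f1max, 1)
})

test_that("F1 at any threshold equals the Dice of the thresholded map", {
  grid <- cartesian_grid(20, 1)
  eval_roi <- sphere_mask(grid, c(0, 0, 0), 18)
  truth <- sphere_mask(grid, c(0, 0, 0), 10)
  cum <- empty_cumulative(grid)
  set.seed(6)
  cum$delta[] <- 10^runif(length(cum$delta), -5, -1)
  g <- collect_predictions(cum, truth, eval_roi)
  p <- pr_analysis(g)
  for (i in seq(1, nrow(p$curve), by = 37)) {
    th <- p$curve$threshold[i]
    pred_mask <- !is.na(cum$delta) & log10(cum$delta) >= th & eval_roi$mask
    truth_roi <- truth$mask & eval_roi$mask
    expect_equal(p$curve$f1[i], dice(pred_mask, truth_roi))
  }
})

test_that("AUPR is floored by the minimum achievable area and tends to the
           skew for permuted labels", {
  set.seed(7)
  for (i in 1:10) {
    n <- sample(50:200, 1)
    g <- data.frame(score = rnorm(n), label = rbinom(n, 1, 0.2))
    if (sum(g$label) == 0 || sum(g$label) == n) next
    p <- pr_analysis(g)
    expect_gte(p$aupr, min_achievable_aupr(p$skew) - 1e-12)
  }
  gp <- data.frame(score = rnorm(1e4), label = rbinom(1e4, 1, 0.15))
  expect_equal(pr_analysis(gp)$aupr, mean(gp$label), tolerance = 0.15)
})

test_that("minimum achievable AUPR matches numeric integration of the
           minimum PR curve and its small-skew limit", {
  for (pi_ in c(1e-4, 0.01, 0.064, 0.1, 0.3)) {
    oracle <- stats::integrate(function(r) pi_ * r / (pi_ * r + 1 - pi_),
                               0, 1, rel.tol = 1e-12)$value
    expect_equal(min_achievable_aupr(pi_), oracle, tolerance = 1e-9)
  }
  # pi -> 0 limit: pi / 2
  expect_equal(min_achievable_aupr(1e-4), 1e-4 / 2, tolerance = 0.01)
  # the skew-0.1 bound used by the neglect rule
  expect_lte(min_achievable_aupr(0.1), 0.052)
  expect_error(min_achievable_aupr(0), "skew")
})

test_that("effective fraction follows sqrt(2 (l/d)^3) with d = 2.355 sigma", {
  expect_equal(effective_fraction(0.5, 3), sqrt(2 * (0.5 / 7.065)^3),
               tolerance = 1e-12)
  expect_equal(effective_fraction(0.5, 3), 0.02663, tolerance = 1e-5 / 0.02663)
  # algebraic identity: l chosen so 2 (l/d)^3 = 1
  d <- 2.355 * 3
  l1 <- d / 2^(1 / 3)
  expect_equal(effective_fraction(l1, 3), 1)
  # monotone in l, antitone in sigma
  ls <- seq(0.1, 2, by = 0.1)
  expect_true(all(diff(effective_fraction(ls, 3)) > 0))
  ss <- seq(1, 6, by = 0.5)
  expect_true(all(diff(effective_fraction(0.5, ss)) < 0))
})

test_that("AUROC Z test handles identity, null and degenerate cases", {
  set.seed(8)
  g <- data.frame(score = rnorm(300) + 0.5 * (lab <- rbinom(300, 1, 0.3)),
                  label = lab)
  r <- prediction_result(g)
  same <- compare_auroc(r, r, neff_fraction = 1)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  # AUROC exactly 0.5 against the null: Z = 0
  r5 <- r; r5$auroc <- 0.5
  expect_equal(compare_auroc(r5, NULL)$z, 0)
  # degenerate group errors
  bad <- r; bad$roc$n_pos <- 0
  expect_error(compare_auroc(bad, NULL), "degenerate")
  # Neff scaling shrinks |Z|
  z_full <- compare_auroc(r, NULL, neff_fraction = 1)$z
  z_eff <- compare_auroc(r, NULL, neff_fraction = 0.0266)$z
  expect_lt(abs(z_eff), abs(z_full))
  # the z_factor mode multiplies the full-N Z by sqrt(fraction)
  z_fac <- compare_auroc(r, NULL, neff_fraction = 0.25,
                         scale_mode = "z_factor")$z
  expect_equal(z_fac, z_full * 0.5, tolerance = 1e-12)
})

test_that("bootstrap AUPR comparison is seeded, symmetric-null and detects
           a real gap", {
  set.seed(9)
  ga <- data.frame(score = rnorm(300) + 1.5 * (la <- rbinom(300, 1, 0.3)),
                   label = la)
  gb <- data.frame(score = rnorm(300) + 0.2 * (lb <- rbinom(300, 1, 0.3)),
                   label = lb)
  b1 <- compare_aupr_bootstrap(ga, gb, n_boot = 300, seed = 11)
  b2 <- compare_aupr_bootstrap(ga, gb, n_boot = 300, seed = 11)
  expect_identical(b1$z, b2$z)
  same <- compare_aupr_bootstrap(ga, ga, n_boot = 300, seed = 12)
  expect_lt(abs(same$z), 0.1)
  expect_gt(same$p, 0.9)
  expect_lt(b1$p, 0.05)   # strong separation difference is detected
})
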