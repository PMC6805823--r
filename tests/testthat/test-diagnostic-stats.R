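test_that("confusion matrices tally predictions against truth", {
  truth <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  pred <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  cm <- confusion_matrix(pred, truth)
  expect_equal(cm$tp, 2); expect_equal(cm$fn, 1)
  expect_equal(cm$fp, 1); expect_equal(cm$tn, 2)
  all_right <- confusion_matrix(truth, truth)
  expect_equal(all_right$fp + all_right$fn, 0)
  flipped <- confusion_matrix(!truth, truth)
  expect_equal(flipped$tp + flipped$tn, 0)
  expect_error(confusion_matrix(pred[1:3], truth), "length mismatch")
})

test_that("diagnostic summary reports exact proportions and intervals", {
  s <- suppressWarnings(
    diagnostic_summary(as_confusion_matrix(tp = 10, fn = 0, tn = 10,
                                           fp = 0)))
  expect_equal(c(s$sensitivity, s$specificity, s$ppv, s$npv), rep(1, 4))
  # Clopper-Pearson against the stats::binom.test oracle
  for (case in list(c(188, 212), c(844, 2033), c(7, 12))) {
    ours <- clopper_pearson_ci(case[1], case[2])
    ref <- stats::binom.test(case[1], case[2])$conf.int
    expect_equal(ours, as.numeric(ref), tolerance = 1e-9)
    p <- case[1] / case[2]
    expect_true(ours[1] <= p && p <= ours[2])
  }
  expect_error(diagnostic_summary(as_confusion_matrix(5, 5, 0, 0)),
               "condition-negative")
})

test_that("Bayes identity links likelihood ratios to predictive values", {
  set.seed(21)
  for (i in 1:50) {
    cm <- as_confusion_matrix(tp = sample(1:500, 1), fn = sample(1:500, 1),
                              tn = sample(1:500, 1), fp = sample(1:500, 1))
    s <- diagnostic_summary(cm)
    expect_equal(post_test_probability(s$prevalence, s$plr), s$ppv,
                 tolerance = 1e-12)
    expect_equal(1 - post_test_probability(s$prevalence, s$nlr), s$npv,
                 tolerance = 1e-12)
  }
  expect_error(post_test_probability(0, 2), "strictly inside")
  expect_error(post_test_probability(1, 2), "strictly inside")
})

test_that("likelihood ratios handle boundary specificities", {
  lr <- likelihood_ratios(1.0, 0.5)
  expect_equal(lr$plr, 2.0)
  expect_equal(lr$nlr, 0.0)
  expect_warning(lr1 <- likelihood_ratios(0.9, 1), "infinite")
  expect_true(is.infinite(lr1$plr))
  expect_warning(lr0 <- likelihood_ratios(0.9, 0), "undefined")
  expect_true(is.na(lr0$nlr))
})

test_that("AUC equals brute-force pair counting and obeys symmetry", {
  # perfectly separated scores
  expect_equal(roc_auc(c(1, 2, 3, 11, 12, 13),
                       c(F, F, F, T, T, T))$auc, 1)
  pair_auc <- function(s, y) {  # O(n^2) oracle with 0.5 tie credit
    pos <- s[y]; neg <- s[!y]
    tot <- 0
    for (p in pos) for (q in neg)
      tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
    tot / (length(pos) * length(neg))
  }
  set.seed(31)
  for (i in 1:10) {
    n <- sample(8:20, 1)
    s <- sample(1:6, n, replace = TRUE)  # heavy ties
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    r <- roc_auc(s, y)
    expect_equal(r$auc, pair_auc(s, y), tolerance = 1e-12)
    expect_equal(r$auc, auc_mw(s, y), tolerance = 1e-12)
    expect_equal(roc_auc(-s, y)$auc, 1 - r$auc, tolerance = 1e-12)
    expect_equal(roc_auc(exp(s), y)$auc, r$auc, tolerance = 1e-12)
    # curve is monotone in both coordinates
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$sensitivity) >= 0))
  }
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("paired DeLong test is rank-invariant and null-calibrated", {
  set.seed(41)
  n <- 120
  y <- rep(c(TRUE, FALSE), c(40, 80))
  a <- rnorm(n) + y
  same <- delong_paired_test(a, a, y)
  expect_equal(same$p_value, 1)
  mono <- delong_paired_test(a, qlogis(plogis(a)) * 3 + 2, y)
  expect_lt(abs(mono$auc_a - mono$auc_b), 1e-12)
  # agreement with a patient-resampling bootstrap oracle
  b <- a + rnorm(n, sd = 1.2)
  dl <- delong_paired_test(a, b, y)
  B <- 4000
  d <- numeric(B)
  for (i in seq_len(B)) {
    idx <- sample.int(n, replace = TRUE)
    if (length(unique(y[idx])) < 2) { d[i] <- NA; next }
    d[i] <- auc_mw(a[idx], y[idx]) - auc_mw(b[idx], y[idx])
  }
  d <- d[!is.na(d)]
  boot_p <- 2 * min(mean(d <= 0), mean(d >= 0))
  expect_lt(abs(dl$p_value - min(boot_p, 1)), 0.05)
})

test_that("Hanley-McNeil variance matches the closed form", {
  same <- hanley_unpaired_test(0.7, 50, 100, 0.7, 50, 100)
  expect_equal(same$p_value, 1)
  # at AUC = 0.5, Q1 = Q2 = 1/3
  hv <- function(auc, n1, n0) {
    q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
    (auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
        (n0 - 1) * (q2 - auc^2)) / (n1 * n0)
  }
  v_closed <- (0.25 + (49 + 99) * (1 / 3 - 0.25)) / (50 * 100)
  expect_equal(hv(0.5, 50, 100), v_closed, tolerance = 1e-12)
  z_small <- hanley_unpaired_test(0.75, 30, 60, 0.70, 30, 60)
  z_big <- hanley_unpaired_test(0.75, 300, 600, 0.70, 300, 600)
  expect_lt(z_big$p_value, z_small$p_value)  # more data, smaller p
  expect_error(hanley_unpaired_test(0.7, 0, 10, 0.6, 5, 5), "degenerate")
})

test_that("chi-square test matches hand computation, no continuity correction", {
  # hand computation: X2 = N (ad - bc)^2 / (r1 r2 c1 c2)
  tab <- matrix(c(12, 28, 30, 10), 2, byrow = TRUE)
  x2 <- 80 * (12 * 10 - 28 * 30)^2 / (40 * 40 * 42 * 38)
  ct <- chi_square_test(tab)
  expect_equal(ct$statistic, x2, tolerance = 1e-12)
  same <- chi_square_test(matrix(c(20, 80, 10, 40), 2, byrow = TRUE))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)
  expect_error(chi_square_test(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("t, ANOVA and Pearson wrappers reproduce standard definitions", {
  g <- c(1.2, 1.9, 2.4, 3.1)
  expect_equal(summary_tests(g, g, method = "t")$statistic, 0)
  expect_equal(summary_tests(x = 1:10, y = 1:10,
                             method = "pearson")$estimate, 1)
  # 3-group toy ANOVA against the hand-computed F statistic
  g1 <- c(1, 2, 3); g2 <- c(2, 3, 4); g3 <- c(6, 7, 8)
  gm <- mean(c(g1, g2, g3))
  ssb <- 3 * ((mean(g1) - gm)^2 + (mean(g2) - gm)^2 + (mean(g3) - gm)^2)
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2) +
    sum((g3 - mean(g3))^2)
  f_hand <- (ssb / 2) / (ssw / 6)
  an <- summary_tests(groups = list(g1, g2, g3), method = "anova")
  expect_equal(an$statistic, f_hand, tolerance = 1e-12)
  expect_error(summary_tests(c(1, 1), c(1, 1), method = "t"), "zero variance")
})

test_that("stratified performance reuses the pooled machinery per stratum", {
  set.seed(51)
  n <- 300
  co <- data.frame(
    cad_score = sample(0:99, n, TRUE),
    disease_level = sample(disease_levels(), n, TRUE, prob = c(.4, .4, .2)),
    sex = sample(c("male", "female"), n, TRUE))
  pooled <- stratified_performance(co, rep("all", n))
  direct <- diagnostic_summary(confusion_matrix(
    co$cad_score > 20, co$disease_level == "significant_cad"))
  expect_equal(pooled$all$summary$sensitivity, direct$sensitivity)
  expect_equal(pooled$all$auc,
               roc_auc(co$cad_score,
                       co$disease_level == "significant_cad")$auc)
  # per-stratum sensitivities match a hand tally
  bysex <- stratified_performance(co, "sex")
  for (s in c("male", "female")) {
    sel <- co$sex == s
    tp <- sum(co$cad_score[sel] > 20 &
                co$disease_level[sel] == "significant_cad")
    npos <- sum(co$disease_level[sel] == "significant_cad")
    expect_equal(bysex[[s]]$summary$sensitivity, tp / npos)
  }
  # a stratum without events: AUC omitted, specificity still available
  co0 <- co[co$disease_level != "significant_cad", ]
  res0 <- stratified_performance(co0, rep("noevents", nrow(co0)))
  expect_true(is.na(res0$noevents$auc))
  expect_equal(res0$noevents$specificity, mean(co0$cad_score <= 20))
})
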