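#' Confusion matrix of a binary rule against disease status
#'
#' @param predictions logical (or 0/1) test-positive indicator.
#' @param truth logical (or 0/1) disease indicator (significant-CAD vs
#'   other).
#' @return object of class `confusion_matrix`: list with `tp`, `fp`, `tn`,
#'   `fn`.
#' @seealso [as_confusion_matrix()] to build one directly from counts.
#' @export
confusion_matrix <- function(predictions, truth) {
  p <- as.logical(predictions); t <- as.logical(truth)
  if (length(p) != length(t)) stop("length mismatch", call. = FALSE)
  if (anyNA(p) || anyNA(t)) stop("missing values", call. = FALSE)
  as_confusion_matrix(tp = sum(p & t), fn = sum(!p & t),
                      tn = sum(!p & !t), fp = sum(p & !t))
}

#' @param tp,fn,tn,fp non-negative counts.
#' @rdname confusion_matrix
#' @export
as_confusion_matrix <- function(tp, fn, tn, fp) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(counts < 0) || sum(counts) == 0)
    stop("counts must be non-negative with a positive total", call. = FALSE)
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2,
              dimnames = list(test = c("positive", "negative"),
                              disease = c("present", "absent")))
  print(m)
  invisible(x)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' The exact (beta-quantile) interval; the default method for every
#' proportion the package reports.
#'
#' @param x successes.
#' @param n trials.
#' @param conf confidence level (default 0.95).
#' @return numeric `c(lower, upper)`.
#' @export
clopper_pearson_ci <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lower <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lower, upper)
}

#' Diagnostic performance summary of a 2x2 table
#'
#' Sensitivity, specificity, predictive values (with exact Clopper-Pearson
#' 95% confidence intervals), likelihood ratios and prevalence. A metric
#' with a zero denominator is returned as `NA` and flagged in `undefined`.
#'
#' @param cm a `confusion_matrix`.
#' @param conf confidence level for the intervals (default 0.95).
#' @return object of class `diagnostic_summary`: list of point estimates
#'   (proportions), `*_ci` interval pairs, `plr`, `nlr`, `prevalence` and
#'   counts.
#' @export
diagnostic_summary <- function(cm, conf = 0.95) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fn <- cm$fn; tn <- cm$tn; fp <- cm$fp
  npos <- tp + fn; nneg <- tn + fp
  if (npos == 0 || nneg == 0)
    stop("need both condition-positive and condition-negative patients",
         call. = FALSE)
  prop <- function(x, n) if (n > 0) x / n else NA_real_
  ci <- function(x, n) if (n > 0) clopper_pearson_ci(x, n, conf) else
    c(NA_real_, NA_real_)
  sens <- prop(tp, npos); spec <- prop(tn, nneg)
  ppv <- prop(tp, tp + fp); npv <- prop(tn, tn + fn)
  lr <- likelihood_ratios(sens, spec)
  undefined <- c(ppv = tp + fp == 0, npv = tn + fn == 0,
                 plr = !is.finite(lr$plr), nlr = is.na(lr$nlr))
  structure(list(
    sensitivity = sens, sensitivity_ci = ci(tp, npos),
    specificity = spec, specificity_ci = ci(tn, nneg),
    ppv = ppv, ppv_ci = ci(tp, tp + fp),
    npv = npv, npv_ci = ci(tn, tn + fn),
    plr = lr$plr, nlr = lr$nlr,
    prevalence = npos / (npos + nneg),
    counts = c(tp = tp, fn = fn, tn = tn, fp = fp),
    undefined = undefined, conf = conf),
    class = "diagnostic_summary")
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  pc <- function(v) sprintf("%.1f%%", 100 * v)
  row <- function(name, v, ci)
    cat(sprintf("  %-22s %s (%s-%s)\n", name, pc(v), pc(ci[1]), pc(ci[2])))
  cat("<diagnostic_summary>\n")
  cat(sprintf("  %-22s %s\n", "Prevalence", pc(x$prevalence)))
  row("Sensitivity", x$sensitivity, x$sensitivity_ci)
  row("Specificity", x$specificity, x$specificity_ci)
  row("PPV", x$ppv, x$ppv_ci)
  row("NPV", x$npv, x$npv_ci)
  cat(sprintf("  %-22s %.2f\n", "Likelihood ratio +", x$plr))
  cat(sprintf("  %-22s %.2f\n", "Likelihood ratio -", x$nlr))
  invisible(x)
}

#' Positive and negative likelihood ratios
#'
#' `PLR = sens / (1 - spec)`; `NLR = (1 - sens) / spec`. A specificity of 1
#' gives an infinite PLR; a specificity of 0 leaves the NLR undefined
#' (`NA`); both are flagged with a warning.
#'
#' @param sensitivity,specificity proportions in `[0, 1]`.
#' @return list with `plr` and `nlr`.
#' @export
likelihood_ratios <- function(sensitivity, specificity) {
  plr <- if (specificity < 1) sensitivity / (1 - specificity) else {
    warning("specificity = 1: PLR is infinite", call. = FALSE)
    Inf
  }
  nlr <- if (specificity > 0) (1 - sensitivity) / specificity else {
    warning("specificity = 0: NLR is undefined", call. = FALSE)
    NA_real_
  }
  list(plr = plr, nlr = nlr)
}

#' Bayesian post-test probability
#'
#' Pre-test odds times the likelihood ratio, converted back to a
#' probability: `post = (odds * LR) / (1 + odds * LR)` with
#' `odds = prev / (1 - prev)`. With the PLR this reproduces the PPV, with
#' the NLR it reproduces `1 - NPV`, exactly, for any 2x2 table.
#'
#' @param prevalence pre-test probability, strictly inside (0, 1).
#' @param likelihood_ratio non-negative likelihood ratio.
#' @return post-test probability.
#' @export
post_test_probability <- function(prevalence, likelihood_ratio) {
  if (any(prevalence <= 0 | prevalence >= 1))
    stop("prevalence must lie strictly inside (0, 1)", call. = FALSE)
  if (any(likelihood_ratio < 0))
    stop("likelihood ratio must be non-negative", call. = FALSE)
  odds <- prevalence / (1 - prevalence) * likelihood_ratio
  odds / (1 + odds)
}

#' ROC curve and AUC
#'
#' AUC equals the Mann-Whitney statistic (ties credited 0.5), with a DeLong
#' 95% confidence interval; the point sequence is the empirical ROC curve.
#' Delegates to \pkg{pROC}.
#'
#' @param scores numeric scores (higher = more diseased).
#' @param labels logical (or 0/1) disease indicator.
#' @param conf confidence level (default 0.95).
#' @return object of class `roc_result`: list with `auc`, `auc_ci`,
#'   `points` (data.frame `fpr`, `sensitivity`), and the underlying
#'   \pkg{pROC} object in `roc`.
#' @export
roc_auc <- function(scores, labels, conf = 0.95) {
  y <- as.logical(labels)
  if (length(unique(y)) < 2)
    stop("labels must contain both classes", call. = FALSE)
  r <- pROC::roc(response = y, predictor = as.numeric(scores),
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  ci <- suppressWarnings(
    as.numeric(pROC::ci.auc(r, conf.level = conf, method = "delong")))
  pts <- data.frame(fpr = 1 - r$specificities, sensitivity = r$sensitivities)
  pts <- pts[order(pts$fpr, pts$sensitivity), ]
  rownames(pts) <- NULL
  structure(list(auc = as.numeric(pROC::auc(r)), auc_ci = ci[c(1, 3)],
                 points = pts, roc = r),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (%.3f-%.3f)\n",
              x$auc, x$auc_ci[1], x$auc_ci[2]))
  invisible(x)
}

new_stat_test <- function(statistic, p_value, method) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 method = method),
            class = "stat_test_result")
}

#' @export
print.stat_test_result <- function(x, ...) {
  cat(sprintf("<stat_test_result> %s: statistic %.4g, p = %.4g\n",
              x$method, x$statistic, x$p_value))
  invisible(x)
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of the AUCs of two scores measured on the same
#' patients, using the structural-components variance of DeLong et al.
#' (via \pkg{pROC}). Identical rankings give a difference of zero and
#' p = 1 (with a warning when the variance of the difference vanishes).
#'
#' @param scores_a,scores_b numeric scores on the same patients.
#' @param labels logical (or 0/1) disease indicator.
#' @return a `stat_test_result` (two-sided z test); also carries
#'   `auc_a`, `auc_b`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels) {
  y <- as.logical(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(y))
    stop("scores and labels must be the same length (paired design)",
         call. = FALSE)
  ra <- pROC::roc(y, as.numeric(scores_a), levels = c(FALSE, TRUE),
                  direction = "<", quiet = TRUE)
  rb <- pROC::roc(y, as.numeric(scores_b), levels = c(FALSE, TRUE),
                  direction = "<", quiet = TRUE)
  tt <- suppressWarnings(pROC::roc.test(ra, rb, method = "delong",
                                        paired = TRUE))
  stat <- as.numeric(tt$statistic); p <- as.numeric(tt$p.value)
  if (!is.finite(stat) || !is.finite(p)) {
    warning("zero variance of the AUC difference; p set to 1",
            call. = FALSE)
    stat <- 0; p <- 1
  }
  out <- new_stat_test(stat, p, "DeLong paired AUC comparison")
  out$auc_a <- as.numeric(pROC::auc(ra))
  out$auc_b <- as.numeric(pROC::auc(rb))
  out
}

# Hanley-McNeil variance of an empirical AUC
.hanley_var <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
      (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
}

#' Hanley-McNeil test for two independent AUCs
#'
#' Unpaired z test on the difference of two AUCs from independent groups,
#' with each variance from the Hanley-McNeil formula.
#'
#' @param auc_a,auc_b the two AUCs.
#' @param n_pos_a,n_neg_a,n_pos_b,n_neg_b class sizes in each group.
#' @return a `stat_test_result` (two-sided z test).
#' @export
hanley_unpaired_test <- function(auc_a, n_pos_a, n_neg_a,
                                 auc_b, n_pos_b, n_neg_b) {
  ns <- c(n_pos_a, n_neg_a, n_pos_b, n_neg_b)
  if (any(ns < 1)) stop("degenerate class counts", call. = FALSE)
  if (any(c(auc_a, auc_b) < 0 | c(auc_a, auc_b) > 1))
    stop("AUCs must lie in [0, 1]", call. = FALSE)
  se <- sqrt(.hanley_var(auc_a, n_pos_a, n_neg_a) +
               .hanley_var(auc_b, n_pos_b, n_neg_b))
  z <- if (se > 0) (auc_a - auc_b) / se else 0
  p <- if (se > 0) 2 * stats::pnorm(-abs(z)) else 1
  new_stat_test(z, p, "Hanley-McNeil unpaired AUC comparison")
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction (df = 1), as used for comparing categorical
#' variables between groups.
#'
#' @param counts 2x2 matrix of counts.
#' @return a `stat_test_result`.
#' @export
chi_square_test <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2)))
    stop("need a 2x2 table of counts", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin in the contingency table", call. = FALSE)
  ct <- stats::chisq.test(counts, correct = FALSE)
  new_stat_test(ct$statistic, ct$p.value,
                "Pearson chi-square (no continuity correction)")
}

#' Standard comparison tests for continuous variables
#'
#' Unpaired equal-variance t test for two groups, one-way ANOVA for three or
#' more, and the Pearson correlation test for paired vectors; thin wrappers
#' over the \pkg{stats} implementations returning the package's uniform
#' test-result object.
#'
#' @param x,y numeric vectors (paired for `method = "pearson"`; the two
#'   groups for `method = "t"`).
#' @param groups a list of numeric vectors for `method = "anova"`.
#' @param method `"t"`, `"anova"` or `"pearson"`.
#' @return a `stat_test_result`; for Pearson the estimate is carried in
#'   `$estimate`.
#' @export
summary_tests <- function(x = NULL, y = NULL, groups = NULL,
                          method = c("t", "anova", "pearson")) {
  method <- match.arg(method)
  if (method == "t") {
    if (length(x) < 2 || length(y) < 2)
      stop("need >= 2 observations per group", call. = FALSE)
    if (stats::sd(c(x, y)) == 0) stop("zero variance", call. = FALSE)
    tt <- stats::t.test(x, y, var.equal = TRUE)
    new_stat_test(tt$statistic, tt$p.value, "Unpaired t test (equal variance)")
  } else if (method == "anova") {
    if (is.null(groups) || length(groups) < 2)
      stop("need a list of >= 2 groups", call. = FALSE)
    if (any(lengths(groups) < 2))
      stop("need >= 2 observations per group", call. = FALSE)
    v <- unlist(groups)
    g <- factor(rep(seq_along(groups), lengths(groups)))
    if (stats::sd(v) == 0) stop("zero variance", call. = FALSE)
    an <- stats::anova(stats::aov(v ~ g))
    new_stat_test(an[["F value"]][1], an[["Pr(>F)"]][1], "One-way ANOVA")
  } else {
    if (length(x) != length(y) || length(x) < 3)
      stop("need paired vectors of length >= 3", call. = FALSE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("zero variance", call. = FALSE)
    ct <- stats::cor.test(x, y, method = "pearson")
    out <- new_stat_test(ct$statistic, ct$p.value, "Pearson correlation")
    out$estimate <- unname(ct$estimate)
    out
  }
}

#' Diagnostic performance within sub-groups
#'
#' Applies the pooled evaluation machinery ([diagnostic_summary()] at the
#' score > 20 rule, plus [roc_auc()]) within each level of a stratifying
#' variable. Strata with only one disease class keep their 2x2 metrics but
#' have no AUC (`NA`); empty strata are skipped with a warning.
#'
#' @param cohort data.frame with `cad_score` and `disease_level`.
#' @param stratifier name of the stratifying column, or a vector of stratum
#'   labels.
#' @param threshold positivity threshold on the score (default 20,
#'   positive = above).
#' @return named list (one element per stratum): list with `n`, `summary`
#'   (a `diagnostic_summary`) and `auc` / `auc_ci`.
#' @export
stratified_performance <- function(cohort, stratifier, threshold = 20) {
  strata <- if (is.character(stratifier) && length(stratifier) == 1 &&
                stratifier %in% names(cohort)) cohort[[stratifier]]
  else rep_len(stratifier, nrow(cohort))
  out <- list()
  for (s in unique(as.character(strata))) {
    sel <- as.character(strata) == s
    if (!any(sel)) { warning("empty stratum ", s, call. = FALSE); next }
    sub <- cohort[sel, , drop = FALSE]
    truth <- sub$disease_level == "significant_cad"
    pred <- sub$cad_score > threshold
    entry <- list(n = nrow(sub))
    both <- length(unique(truth)) == 2
    entry$summary <- if (both)
      diagnostic_summary(confusion_matrix(pred, truth)) else NULL
    if (both) {
      rr <- roc_auc(sub$cad_score, truth)
      entry$auc <- rr$auc; entry$auc_ci <- rr$auc_ci
    } else {
      # mirror single-class strata: specificity still defined when only
      # non-diseased patients are present
      entry$auc <- NA_real_; entry$auc_ci <- c(NA_real_, NA_real_)
      if (!any(truth))
        entry$specificity <- mean(!pred)
    }
    out[[s]] <- entry
  }
  out
}
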