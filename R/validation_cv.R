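#' Rank-based AUC (Mann-Whitney)
#'
#' Fast tie-aware AUC used inside the cross-validation loop; identical to
#' the trapezoidal ROC area with ties credited 0.5.
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1) class indicator.
#' @return the AUC.
#' @export
auc_mw <- function(scores, labels) {
  y <- as.logical(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("need both classes", call. = FALSE)
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified fold assignment: within each class, a random permutation dealt
# round-robin over folds, so fold sizes differ by at most one per class;
# folds == n degenerates to leave-one-out (one patient per fold)
.stratified_folds <- function(y, folds) {
  n <- length(y)
  if (folds == n) return(sample.int(n))
  f <- integer(n)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    f[idx[sample.int(length(idx))]] <-
      rep_len(sample.int(folds), length(idx))
  }
  f
}

#' Repeated stratified cross-validation of the score pipeline
#'
#' Quantifies overfitting of the two trainable stages: in each fold the
#' shrinkage LDA and the logistic fusion are refit on the training folds
#' only, and out-of-fold linear predictors are scored. Per repeat, the
#' out-of-fold scores of all folds are pooled into one AUC (the alternative
#' of averaging per-fold AUCs is available via `pool = FALSE`). The
#' resubstitution AUC (fit and evaluate on everything) is computed for
#' comparison; its excess over the mean cross-validated AUC measures
#' optimism.
#'
#' @param features numeric feature matrix (rows = patients).
#' @param age,sex,hypertension clinical covariates.
#' @param labels logical (or 0/1) significant-CAD indicator.
#' @param folds number of folds (default 10); `folds = n` gives
#'   leave-one-out.
#' @param repeats number of repeats (default 50).
#' @param seed integer seed; repeat `r` uses `seed + r`, so results are
#'   reproducible and repeats are independent.
#' @param pool pool out-of-fold scores before the per-repeat AUC (default
#'   `TRUE`).
#' @param shrinkage LDA shrinkage passed to [fit_lda()].
#' @return object of class `cv_result`: list with `auc_per_repeat`,
#'   `fold_auc` (repeats x folds matrix, `NA` off-diagonal for pooled
#'   single-class folds), `mean_cv_auc`, `resub_auc`, `optimism`,
#'   `oof_scores` (patients x repeats), `redraws`.
#' @export
repeated_cv <- function(features, age, sex, hypertension, labels,
                        folds = 10, repeats = 50, seed = 1, pool = TRUE,
                        shrinkage = 0.1) {
  X <- as.matrix(features)
  y <- as.logical(labels)
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (min(table(y)) < 2) stop("need >= 2 patients per class", call. = FALSE)
  male <- encode_male(sex)

  fit_score <- function(train, test) {
    ld <- fit_lda(X[train, , drop = FALSE], y[train], shrinkage = shrinkage)
    ac_tr <- acoustic_score(X[train, , drop = FALSE], ld)
    lg <- suppressWarnings(
      fit_logistic(ac_tr, age[train], male[train], hypertension[train],
                   y[train]))
    ac_te <- acoustic_score(X[test, , drop = FALSE], ld)
    linear_predictor(lg, ac_te, age[test], male[test], hypertension[test])
  }

  resub <- fit_score(seq_len(n), seq_len(n))
  resub_auc <- auc_mw(resub, y)

  auc_per_repeat <- numeric(repeats)
  fold_auc <- matrix(NA_real_, repeats, folds)
  oof <- matrix(NA_real_, n, repeats)
  redraws <- 0L
  for (r in seq_len(repeats)) {
    with_seed(seed + r, {
      repeat {
        f <- .stratified_folds(y, folds)
        ok <- all(vapply(seq_len(folds), function(k)
          length(unique(y[f != k])) == 2, logical(1)))
        if (ok) break
        redraws <- redraws + 1L
      }
      for (k in seq_len(folds)) {
        test <- which(f == k)
        lp <- fit_score(which(f != k), test)
        oof[test, r] <- lp
        if (length(unique(y[test])) == 2)
          fold_auc[r, k] <- auc_mw(lp, y[test])
      }
    })
    auc_per_repeat[r] <- if (pool) auc_mw(oof[, r], y)
    else mean(fold_auc[r, ], na.rm = TRUE)
  }
  structure(list(auc_per_repeat = auc_per_repeat, fold_auc = fold_auc,
                 mean_cv_auc = mean(auc_per_repeat), resub_auc = resub_auc,
                 optimism = resub_auc - mean(auc_per_repeat),
                 oof_scores = oof, folds = folds, repeats = repeats,
                 pool = pool, redraws = redraws),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %dx %d-fold: mean CV AUC %.3f, resubstitution %.3f (optimism %.3f)\n",
    x$repeats, x$folds, x$mean_cv_auc, x$resub_auc, x$optimism))
  invisible(x)
}

#' Write a cross-validation summary
#'
#' JSON summary plus an optional per-fold CSV table.
#'
#' @param cv a `cv_result`.
#' @param json_path,csv_path output paths (`NULL` to skip either).
#' @return invisibly, the summary list.
#' @export
write_cv_summary <- function(cv, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(cv, "cv_result"))
  summary <- list(repeats = cv$repeats, folds = cv$folds, pool = cv$pool,
                  mean_cv_auc = cv$mean_cv_auc, resub_auc = cv$resub_auc,
                  optimism = cv$optimism,
                  auc_per_repeat = cv$auc_per_repeat)
  if (!is.null(json_path))
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path)) {
    tab <- data.frame(repeat_ = rep(seq_len(cv$repeats), each = cv$folds),
                      fold = rep(seq_len(cv$folds), cv$repeats),
                      auc = as.vector(t(cv$fold_auc)))
    utils::write.csv(tab, csv_path, row.names = FALSE)
  }
  invisible(summary)
}
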