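#' Simulate, QC and featurise the recordings of a cohort
#'
#' Runs the acoustic front end for every patient: phonocardiogram
#' simulation, quality control, segmentation (either the envelope-based
#' detector or the generator's ground-truth annotations) and feature
#' extraction. Patients failing QC get `NA` features and an exclusion
#' reason, mirroring how a recording device rejects arrhythmic or noisy
#' recordings before scoring.
#'
#' @param cohort a cohort `data.frame`.
#' @param config the [cohort_config()] used to generate it.
#' @param segmentation `"auto"` (detector) or `"oracle"` (ground-truth
#'   annotations).
#' @param qc apply [quality_check()] (default `TRUE`).
#' @return list with `features` (n x 8 matrix, `NA` rows for excluded
#'   patients), `qc_reason` (character per patient, `"ok"` if scored),
#'   `murmur_rms` (simulated per-patient murmur amplitude, for diagnostics).
#' @export
cohort_acoustics <- function(cohort, config,
                             segmentation = c("auto", "oracle"), qc = TRUE) {
  segmentation <- match.arg(segmentation)
  n <- nrow(cohort)
  feats <- matrix(NA_real_, n, 8,
                  dimnames = list(cohort$patient_id, acoustic_feature_names()))
  reason <- rep("ok", n)
  murmur <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    rec <- simulate_pcg(cohort[i, ], config)
    murmur[i] <- rec$annotations$murmur_rms
    seg <- if (segmentation == "oracle") segmentation_from_annotations(rec)
    else tryCatch(segment_heart_sounds(rec), error = function(e) NULL)
    if (is.null(seg)) { reason[i] <- "noisy_or_weak"; next }
    if (qc) {
      v <- quality_check(rec, min_duration = min(30, config$duration),
                         segmentation = seg)
      if (!v$passed) { reason[i] <- v$reason; next }
    }
    feats[i, ] <- tryCatch(extract_features(rec, seg),
                           error = function(e) rep(NA_real_, 8))
    if (anyNA(feats[i, ])) reason[i] <- "noisy_or_weak"
  }
  list(features = feats, qc_reason = reason, murmur_rms = murmur)
}

#' Run the full study simulation end to end
#'
#' Executes every stage in order: cohort generation, phonocardiogram
#' simulation, QC and segmentation, feature extraction, LDA and logistic
#' fits, score calibration and scoring, pre-test probability and banding,
#' the reclassification analysis (restricted to symptomatic patients),
#' diagnostic evaluation of the score at the > 20 rule, and repeated
#' cross-validation of the trainable stages. Optionally writes the whole
#' report bundle to `outdir`.
#'
#' @param config a [cohort_config()]; its `seed` drives every stage.
#' @param ptp a [ptp_model()].
#' @param segmentation `"auto"` or `"oracle"` (see [cohort_acoustics()]).
#' @param reclassify_symptomatic_only restrict the reclassification analysis
#'   to patients referred with symptoms (default `TRUE`; asymptomatic
#'   screening participants are not reclassified).
#' @param cv_repeats,cv_folds cross-validation plan (default 50 x 10-fold;
#'   `cv_repeats = 0` skips the CV stage).
#' @param outdir output directory (`NULL` = no files written).
#' @return object of class `cad_analysis`: list with `cohort` (scored),
#'   `included`, `qc_exclusions`, `model`, `evaluation` (confusion,
#'   summary, ROC), `reclassification`, `cv`, `config`.
#' @export
run_full_analysis <- function(config, ptp = ptp_model(),
                              segmentation = c("auto", "oracle"),
                              reclassify_symptomatic_only = TRUE,
                              cv_repeats = 50, cv_folds = 10,
                              outdir = NULL) {
  segmentation <- match.arg(segmentation)
  t0 <- proc.time()[3]
  stage <- function(name) message(sprintf("[%s] %.1f s", name,
                                          proc.time()[3] - t0))
  cohort <- generate_cohort(config)
  stage("cohort")
  ac <- cohort_acoustics(cohort, config, segmentation = segmentation)
  stage("acoustics")
  inc <- ac$qc_reason == "ok"
  if (sum(inc) < 50)
    stop("pipeline failure at scoring: fewer than 50 patients passed QC",
         call. = FALSE)
  X <- ac$features[inc, , drop = FALSE]
  y <- cohort$disease_level[inc] == "significant_cad"

  lda <- fit_lda(X, y)
  ac_score <- acoustic_score(X, lda)
  lg <- fit_logistic(ac_score, cohort$age[inc], cohort$sex[inc],
                     cohort$hypertension[inc], y)
  lp <- linear_predictor(lg, ac_score, cohort$age[inc], cohort$sex[inc],
                         cohort$hypertension[inc])
  anchors <- calibrate_scale(lp, y)
  model <- cad_score_model(lda, lg, anchors)
  cohort$cad_score[inc] <-
    as.integer(pmin(pmax(floor(score_map(lp, anchors) + 0.5), 0), 99))
  stage("scoring")

  cohort$ptp <- compute_ptp(ptp, cohort$age, cohort$sex, cohort$symptom)

  rc_sel <- inc & (!reclassify_symptomatic_only | cohort$symptom != "none")
  reclass <- reclassification_table(cohort[rc_sel, , drop = FALSE])
  stage("reclassification")

  truth <- cohort$disease_level[inc] == "significant_cad"
  cm <- confusion_matrix(cohort$cad_score[inc] > model$threshold, truth)
  evaluation <- list(
    confusion = cm,
    summary = diagnostic_summary(cm),
    roc = roc_auc(cohort$cad_score[inc], truth))
  stage("evaluation")

  cv <- NULL
  if (cv_repeats > 0) {
    cv_seed <- if (is.null(config$seed)) 1L else config$seed + 1000L
    cv <- repeated_cv(X, cohort$age[inc], cohort$sex[inc],
                      cohort$hypertension[inc], y,
                      folds = cv_folds, repeats = cv_repeats, seed = cv_seed)
    stage("cross-validation")
  }

  qc_tab <- table(factor(ac$qc_reason[!inc],
                         levels = c("arrhythmia", "noisy_or_weak",
                                    "too_short")))
  out <- structure(list(cohort = cohort, included = inc,
                        qc_exclusions = qc_tab, model = model,
                        evaluation = evaluation, reclassification = reclass,
                        cv = cv, config = config),
                   class = "cad_analysis")
  if (!is.null(outdir)) write_analysis_bundle(out, outdir)
  out
}

#' @export
print.cad_analysis <- function(x, ...) {
  cat(sprintf("<cad_analysis> n = %d (%d scored, %d QC-excluded)\n",
              nrow(x$cohort), sum(x$included), sum(!x$included)))
  cat(sprintf("  CAD-score AUC %.3f (%.3f-%.3f)\n",
              x$evaluation$roc$auc, x$evaluation$roc$auc_ci[1],
              x$evaluation$roc$auc_ci[2]))
  cat(sprintf("  NRI %.3f\n", x$reclassification$nri))
  if (!is.null(x$cv))
    cat(sprintf("  CV AUC %.3f (resubstitution %.3f)\n",
                x$cv$mean_cv_auc, x$cv$resub_auc))
  invisible(x)
}

#' Write the report bundle of a full analysis
#'
#' Cohort CSV, model JSON, a Table-2 style evaluation report (JSON +
#' Markdown), the pre/post reclassification table (JSON + text) and the CV
#' summary.
#'
#' @param analysis a `cad_analysis`.
#' @param outdir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_analysis_bundle <- function(analysis, outdir) {
  stopifnot(inherits(analysis, "cad_analysis"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  write_cohort_csv(analysis$cohort, p("cohort.csv"))
  write_cad_model(analysis$model, p("model.json"))
  s <- analysis$evaluation$summary
  report <- list(
    n_scored = sum(analysis$included),
    qc_excluded = as.list(analysis$qc_exclusions),
    auc = analysis$evaluation$roc$auc,
    auc_ci = analysis$evaluation$roc$auc_ci,
    sensitivity = s$sensitivity, sensitivity_ci = s$sensitivity_ci,
    specificity = s$specificity, specificity_ci = s$specificity_ci,
    ppv = s$ppv, ppv_ci = s$ppv_ci, npv = s$npv, npv_ci = s$npv_ci,
    plr = s$plr, nlr = s$nlr, prevalence = s$prevalence,
    counts = as.list(s$counts))
  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = NA)
  writeLines(report_markdown(s, analysis$evaluation$roc), p("report.md"))
  rc <- analysis$reclassification
  jsonlite::write_json(list(pre = as.list(rc$pre), post = as.list(rc$post),
                            down_events = rc$down_events,
                            down_nonevents = rc$down_nonevents,
                            events = rc$events, nonevents = rc$nonevents,
                            nri = rc$nri),
                       p("reclassification.json"), auto_unbox = TRUE,
                       digits = NA)
  writeLines(format_reclassification(rc), p("reclassification.txt"))
  if (!is.null(analysis$cv))
    write_cv_summary(analysis$cv, p("cv.json"), p("cv.csv"))
  invisible(list.files(outdir, full.names = TRUE))
}

#' Markdown evaluation table
#'
#' @param s a `diagnostic_summary`.
#' @param roc optional `roc_result`.
#' @return character vector of Markdown lines.
#' @export
report_markdown <- function(s, roc = NULL) {
  pc <- function(v) sprintf("%.1f%%", 100 * v)
  ci <- function(v) sprintf("(%s-%s)", pc(v[1]), pc(v[2]))
  lines <- c("| Metric | Value |", "|---|---|",
             sprintf("| N: Other | %d |", s$counts["tn"] + s$counts["fp"]),
             sprintf("| N: Significant-CAD | %d |",
                     s$counts["tp"] + s$counts["fn"]),
             sprintf("| Prevalence of CAD | %s |", pc(s$prevalence)))
  if (!is.null(roc))
    lines <- c(lines, sprintf("| AUC | %.3f (%.3f-%.3f) |", roc$auc,
                              roc$auc_ci[1], roc$auc_ci[2]))
  c(lines,
    sprintf("| True negative | %d |", s$counts["tn"]),
    sprintf("| False negative | %d |", s$counts["fn"]),
    sprintf("| False positive | %d |", s$counts["fp"]),
    sprintf("| True positive | %d |", s$counts["tp"]),
    sprintf("| Negative predictive value | %s %s |", pc(s$npv), ci(s$npv_ci)),
    sprintf("| Positive predictive value | %s %s |", pc(s$ppv), ci(s$ppv_ci)),
    sprintf("| Sensitivity | %s %s |", pc(s$sensitivity),
            ci(s$sensitivity_ci)),
    sprintf("| Specificity | %s %s |", pc(s$specificity),
            ci(s$specificity_ci)),
    sprintf("| Likelihood ratio positive | %.2f |", s$plr),
    sprintf("| Likelihood ratio negative | %.2f |", s$nlr))
}

#' Full evaluation report from 2x2 counts alone
#'
#' The counts-driven path: reproduces every metric a diagnostic-performance
#' table derives from its printed true/false positive/negative counts —
#' sensitivity, specificity, predictive values with exact confidence
#' intervals, likelihood ratios, and the Bayesian post-test probabilities
#' after a positive and after a negative test. Shares its implementation
#' with the simulation-driven path ([diagnostic_summary()],
#' [likelihood_ratios()], [post_test_probability()]).
#'
#' @param tp,fn,tn,fp the 2x2 counts.
#' @return object of class `counts_report`: the `diagnostic_summary` plus
#'   `post_test_positive` (= PPV) and `post_test_negative` (= 1 - NPV).
#' @export
evaluate_from_counts <- function(tp, fn, tn, fp) {
  cm <- as_confusion_matrix(tp = tp, fn = fn, tn = tn, fp = fp)
  s <- diagnostic_summary(cm)
  out <- s
  out$post_test_positive <- post_test_probability(s$prevalence, s$plr)
  out$post_test_negative <- post_test_probability(s$prevalence, s$nlr)
  class(out) <- c("counts_report", "diagnostic_summary")
  out
}

#' @export
print.counts_report <- function(x, ...) {
  NextMethod()
  cat(sprintf("  %-22s %.1f%%\n", "Post-test P(+)", 100 * x$post_test_positive))
  cat(sprintf("  %-22s %.1f%%\n", "Post-test P(-)", 100 * x$post_test_negative))
  invisible(x)
}
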