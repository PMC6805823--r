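#' Pre-test probability model (updated Diamond-Forrester form)
#'
#' Logistic model of the probability of obstructive CAD from age, sex and
#' chest-pain typicality. The default coefficients are a synthetic stand-in:
#' they were fitted (once, and are frozen here) to the widely published
#' age/sex/symptom pre-test-probability table for stable chest pain
#' (reproducing its 30 cells to within half a percentage point), since the
#' original regression coefficients live in an external publication. Every
#' coefficient is configurable, including a separate one for non-specific
#' symptoms (not a classical Diamond-Forrester category; by default it
#' shares the non-anginal reference) and for asymptomatic patients.
#'
#' @param intercept,age,male logistic coefficients (age per year, male = 1).
#' @param symptom named coefficients for `typical`, `atypical`,
#'   `non_specific` and `none` (relative to the non-anginal reference).
#' @return object of class `ptp_model`.
#' @export
ptp_model <- function(intercept = -4.3669, age = 0.0428, male = 1.3343,
                      symptom = c(typical = 1.9078, atypical = 0.6340,
                                  non_specific = 0, none = 0)) {
  need <- c("typical", "atypical", "non_specific", "none")
  if (!all(need %in% names(symptom)))
    stop("`symptom` must name coefficients for: ",
         paste(need, collapse = ", "), call. = FALSE)
  structure(list(intercept = intercept, age = age, male = male,
                 symptom = symptom[need],
                 bands = c(low = 0.15, high = 0.85)),
            class = "ptp_model")
}

#' @export
print.ptp_model <- function(x, ...) {
  cat(sprintf("<ptp_model> logit(p) = %.4f + %.4f*age + %.4f*male + symptom\n",
              x$intercept, x$age, x$male))
  print(round(x$symptom, 4))
  invisible(x)
}

#' Compute the pre-test probability of obstructive CAD
#'
#' Inverse-logit of the configured linear predictor; strictly increasing in
#' age for a positive age coefficient.
#'
#' @param model a [ptp_model()].
#' @param age years.
#' @param sex `"male"`/`"female"` (or male indicator).
#' @param symptom one of `typical`, `atypical`, `non_specific`, `none`.
#' @return probabilities in (0, 1).
#' @export
compute_ptp <- function(model, age, sex, symptom) {
  stopifnot(inherits(model, "ptp_model"))
  symptom <- as.character(symptom)
  bad <- !symptom %in% names(model$symptom)
  if (any(bad))
    stop("unknown symptom category: ",
         paste(unique(symptom[bad]), collapse = ", "), call. = FALSE)
  if (anyNA(c(model$intercept, model$age, model$male, model$symptom)))
    stop("PTP model has missing coefficients", call. = FALSE)
  lp <- model$intercept + model$age * age + model$male * encode_male(sex) +
    unname(model$symptom[symptom])
  stats::plogis(lp)
}

#' Assign the guideline PTP band
#'
#' `low` for PTP < 15%, `high` for PTP > 85%, `intermediate` for 15-85%
#' (both edges inclusive to intermediate).
#'
#' @param ptp probabilities in `[0, 1]`.
#' @return ordered factor with levels `low < intermediate < high`.
#' @export
ptp_band <- function(ptp) {
  if (any(is.na(ptp)) || any(ptp < 0 | ptp > 1))
    stop("ptp must lie in [0, 1]", call. = FALSE)
  out <- ifelse(ptp < 0.15, "low", ifelse(ptp > 0.85, "high", "intermediate"))
  factor(out, levels = c("low", "intermediate", "high"), ordered = TRUE)
}

#' Code the angiographic disease level
#'
#' Three levels: `significant_cad` for a stenosis of at least 50% diameter
#' reduction on invasive angiography (CAG); `non_cad` for a coronary calcium
#' score (CACS) of zero with no stenosis on CT angiography; `mild_cad` for
#' any other evidence of disease (CACS above zero, or a non-obstructive
#' stenosis). Patients with no modality data cannot be classified and return
#' `NA` with a warning.
#'
#' @param cacs coronary artery calcium score (`NA` if not performed).
#' @param cta_stenosis_pct maximal stenosis (%) on CTA (`NA` if not
#'   performed; 0 = no stenosis).
#' @param cag_stenosis_pct maximal stenosis (%) on CAG (`NA` if not
#'   performed).
#' @return character vector over `non_cad`, `mild_cad`, `significant_cad`
#'   (or `NA` where unclassifiable).
#' @export
assign_disease_level <- function(cacs, cta_stenosis_pct, cag_stenosis_pct) {
  n <- max(length(cacs), length(cta_stenosis_pct), length(cag_stenosis_pct))
  cacs <- rep_len(cacs, n)
  cta <- rep_len(cta_stenosis_pct, n)
  cag <- rep_len(cag_stenosis_pct, n)
  out <- rep(NA_character_, n)
  none <- is.na(cacs) & is.na(cta) & is.na(cag)
  sig <- !is.na(cag) & cag >= 50
  non <- !sig & !is.na(cacs) & cacs == 0 & (is.na(cta) | cta == 0)
  out[sig] <- "significant_cad"
  out[non] <- "non_cad"
  out[!sig & !non & !none] <- "mild_cad"
  if (any(none))
    warning(sum(none), " patient(s) unclassifiable: no modality data",
            call. = FALSE)
  out
}

#' Apply the down-only reclassification scheme
#'
#' Patients in the intermediate PTP band with a CAD-score of 20 or below
#' are reclassified to low probability; intermediate patients with a score
#' above 20 stay intermediate; low and high PTP patients pass through
#' unchanged.
#'
#' @param pre pre-test risk class (`low`/`intermediate`/`high`).
#' @param cad_score integer CAD-scores.
#' @return post-test risk classes, same type as [ptp_band()] output.
#' @export
reclassify <- function(pre, cad_score) {
  pre_chr <- as.character(pre)
  out <- ifelse(pre_chr == "intermediate" & cad_score <= 20, "low", pre_chr)
  factor(out, levels = c("low", "intermediate", "high"), ordered = TRUE)
}

#' Tabulate the reclassification of a cohort
#'
#' Computes pre/post risk-class counts and the downward movements split by
#' event status (event = significant-CAD), the inputs to the net
#' reclassification index.
#'
#' @param cohort data.frame with `ptp`, `cad_score` and `disease_level`
#'   filled in for every row.
#' @return object of class `reclassification_result`: list with `pre`,
#'   `post` (named count vectors), `down_events`, `down_nonevents`,
#'   `up_events = 0`, `up_nonevents = 0`, `events`, `nonevents`, `nri`.
#' @export
reclassification_table <- function(cohort) {
  need <- c("ptp", "cad_score", "disease_level")
  bad <- Reduce(`|`, lapply(need, function(cl) is.na(cohort[[cl]])))
  if (any(bad))
    stop("patients with missing ptp/cad_score/disease_level: ",
         paste(utils::head(cohort$patient_id[bad], 10), collapse = ", "),
         if (sum(bad) > 10) ", ..." else "", call. = FALSE)
  pre <- ptp_band(cohort$ptp)
  post <- reclassify(pre, cohort$cad_score)
  event <- cohort$disease_level == "significant_cad"
  moved <- pre == "intermediate" & post == "low"
  res <- reclassification_result(
    down_events = sum(moved & event),
    down_nonevents = sum(moved & !event),
    events = sum(event), nonevents = sum(!event),
    pre = table(pre), post = table(post))
  res
}

#' Build a reclassification result from movement counts
#'
#' The counts-only entry point: useful when the class movements are known
#' (e.g. read off a published pre/post flow diagram) without patient-level
#' data. Only downward movements exist in this scheme, but upward counts are
#' accepted for generality.
#'
#' @param down_events,down_nonevents events / non-events moved from
#'   intermediate to low.
#' @param events,nonevents totals by event status.
#' @param up_events,up_nonevents upward movements (default 0).
#' @param pre,post optional named per-class count vectors.
#' @return a `reclassification_result` (see [reclassification_table()]).
#' @export
reclassification_result <- function(down_events, down_nonevents, events,
                                    nonevents, up_events = 0,
                                    up_nonevents = 0, pre = NULL, post = NULL) {
  res <- structure(list(pre = pre, post = post,
                        down_events = down_events,
                        down_nonevents = down_nonevents,
                        up_events = up_events, up_nonevents = up_nonevents,
                        events = events, nonevents = nonevents),
                   class = "reclassification_result")
  res$nri <- net_reclassification_index(res)
  res
}

#' @export
print.reclassification_result <- function(x, ...) {
  cat("<reclassification_result>\n")
  if (!is.null(x$pre)) {
    m <- rbind(pre = as.numeric(x$pre), post = as.numeric(x$post))
    colnames(m) <- names(x$pre)
    print(m)
  }
  cat(sprintf("moved down: %d events, %d non-events (of %d / %d)\n",
              x$down_events, x$down_nonevents, x$events, x$nonevents))
  cat(sprintf("NRI = %.3f\n", x$nri))
  invisible(x)
}

#' Binary net reclassification index
#'
#' `NRI = (up_events - down_events)/events +
#' (down_nonevents - up_nonevents)/nonevents`. For the down-only scheme the
#' upward terms are zero, so moving non-events down improves the index and
#' moving events down penalises it. Bounded in `[-2, 2]`.
#'
#' @param result a `reclassification_result`.
#' @return the NRI (numeric scalar).
#' @export
net_reclassification_index <- function(result) {
  stopifnot(inherits(result, "reclassification_result"))
  if (result$events <= 0 || result$nonevents <= 0)
    stop("need at least one event and one non-event", call. = FALSE)
  (result$up_events - result$down_events) / result$events +
    (result$down_nonevents - result$up_nonevents) / result$nonevents
}

#' Plain-text pre/post reclassification flow table
#'
#' @param result a `reclassification_result` with per-class counts.
#' @return character vector of lines (invisibly printed).
#' @export
format_reclassification <- function(result) {
  stopifnot(inherits(result, "reclassification_result"))
  lines <- c(
    sprintf("%-14s %8s %8s", "risk class", "pre", "post"),
    sprintf("%-14s %8d %8d", names(result$pre),
            as.integer(result$pre), as.integer(result$post)),
    sprintf("moved down: %d events / %d non-events",
            result$down_events, result$down_nonevents),
    sprintf("NRI = %.3f", result$nri))
  lines
}
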