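#' Configuration for a synthetic CAD cohort
#'
#' Bundles every tunable of the synthetic-data generator: cohort size,
#' disease-level prevalence, covariate distributions, the acoustic murmur
#' effect, noise, arrhythmia rate and the recording protocol. Defaults
#' describe a pooled multi-centre population referred with suspected stable
#' CAD: mean age 58.3 (SD 8.4) years, 52.8% female, 58.5% hypertensive, a
#' 21.8/27.1/28.9/22.2% mix of typical / atypical / non-specific / no
#' symptoms, and a 46.4/44.2/9.4% split over non-CAD / mild-CAD /
#' significant-CAD.
#'
#' Disease level is drawn first from `prevalence`; age, sex and hypertension
#' are then drawn from level-conditional distributions whose mixture
#' reproduces the configured marginals (age via per-level shifts that are
#' re-centred against the prevalence, binary covariates via per-level odds
#' multipliers with the baseline solved numerically), so sicker patients are
#' older, more often male and more often hypertensive without distorting the
#' cohort-level Table-1 style marginals.
#'
#' @param n number of patients (>= 1).
#' @param prevalence probabilities over `(non_cad, mild_cad, significant_cad)`;
#'   must be non-negative and sum to 1 within 1e-9.
#' @param age_mean,age_sd,age_range mean, SD and truncation range (years).
#' @param female_frac,hypertension_frac,diabetes_frac marginal fractions.
#' @param symptom_mix probabilities over
#'   `(typical, atypical, non_specific, none)`.
#' @param bmi_mean,bmi_sd body-mass index distribution (kg/m^2).
#' @param age_level_shift per-level additive age shifts (years), re-centred
#'   internally so the marginal mean is preserved.
#' @param male_odds_mult,hypertension_odds_mult per-level odds multipliers.
#' @param murmur_scale reference RMS amplitude of the diastolic murmur for a
#'   significant-CAD patient (arbitrary units against an S1 amplitude of 1).
#' @param murmur_level_mult per-level multipliers of `murmur_scale`
#'   (dimensionless SNR multipliers).
#' @param murmur_sd_log SD of the per-patient lognormal murmur amplitude
#'   spread (log scale).
#' @param murmur_band murmur frequency band (Hz).
#' @param noise_level RMS of additive broadband noise.
#' @param arrhythmia_frac fraction of patients simulated with an irregular
#'   rhythm (RR coefficient of variation about 0.25).
#' @param sampling_rate sampling rate in Hz.
#' @param duration main recording length in seconds.
#' @param pretest_duration pre-test (sound-check) segment length in seconds.
#' @param heart_rate_mean,heart_rate_sd,heart_rate_range per-patient heart
#'   rate distribution (bpm), truncated normal.
#' @param seed integer seed making cohort and waveform generation
#'   reproducible; `NULL` uses the current RNG stream.
#' @return an object of class `cohort_config` (a named list).
#' @seealso [generate_cohort()], [simulate_pcg()]
#' @export
cohort_config <- function(n,
                          prevalence = c(non_cad = 0.464, mild_cad = 0.442,
                                         significant_cad = 0.094),
                          age_mean = 58.3, age_sd = 8.4, age_range = c(20, 86),
                          female_frac = 0.528,
                          hypertension_frac = 0.585,
                          symptom_mix = c(typical = 0.218, atypical = 0.271,
                                          non_specific = 0.289, none = 0.222),
                          bmi_mean = 26.9, bmi_sd = 4.2,
                          diabetes_frac = 0.053,
                          age_level_shift = c(-1.2, 0.8, 2.2),
                          male_odds_mult = c(1, 1.25, 1.9),
                          hypertension_odds_mult = c(1, 1.3, 1.7),
                          murmur_scale = 0.05,
                          murmur_level_mult = c(non_cad = 0.5, mild_cad = 0.72,
                                                significant_cad = 1.0),
                          murmur_sd_log = 0.60,
                          murmur_band = c(200, 500),
                          noise_level = 0.03,
                          arrhythmia_frac = 0.011,
                          sampling_rate = 1000,
                          duration = 150,
                          pretest_duration = 30,
                          heart_rate_mean = 65, heart_rate_sd = 8,
                          heart_rate_range = c(45, 110),
                          seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be a single count >= 1", call. = FALSE)
  prevalence <- unname(prevalence)
  if (length(prevalence) != 3L || any(prevalence < 0) ||
      abs(sum(prevalence) - 1) > 1e-9)
    stop("`prevalence` must be 3 non-negative probabilities summing to 1",
         call. = FALSE)
  if (abs(sum(symptom_mix) - 1) > 1e-9 || any(symptom_mix < 0))
    stop("`symptom_mix` must be 4 non-negative probabilities summing to 1",
         call. = FALSE)
  if (sampling_rate <= 0) stop("`sampling_rate` must be positive", call. = FALSE)
  cfg <- list(n = as.integer(n), prevalence = prevalence,
              age_mean = age_mean, age_sd = age_sd, age_range = age_range,
              female_frac = female_frac,
              hypertension_frac = hypertension_frac,
              symptom_mix = symptom_mix,
              bmi_mean = bmi_mean, bmi_sd = bmi_sd,
              diabetes_frac = diabetes_frac,
              age_level_shift = age_level_shift,
              male_odds_mult = male_odds_mult,
              hypertension_odds_mult = hypertension_odds_mult,
              murmur_scale = murmur_scale,
              murmur_level_mult = unname(murmur_level_mult),
              murmur_sd_log = murmur_sd_log,
              murmur_band = murmur_band,
              noise_level = noise_level,
              arrhythmia_frac = arrhythmia_frac,
              sampling_rate = sampling_rate,
              duration = duration, pretest_duration = pretest_duration,
              heart_rate_mean = heart_rate_mean,
              heart_rate_sd = heart_rate_sd,
              heart_rate_range = heart_rate_range,
              seed = seed)
  class(cfg) <- "cohort_config"
  cfg
}

disease_levels <- function() c("non_cad", "mild_cad", "significant_cad")
symptom_levels <- function() c("typical", "atypical", "non_specific", "none")

# baseline success probability per level for a binary covariate so that the
# prevalence-weighted mixture hits the target marginal, given odds multipliers
.level_probs <- function(target, odds_mult, prevalence) {
  f <- function(logb) {
    b <- exp(logb)
    sum(prevalence * (b * odds_mult) / (1 + b * odds_mult)) - target
  }
  root <- stats::uniroot(f, c(-20, 20), tol = 1e-12)$root
  b <- exp(root)
  (b * odds_mult) / (1 + b * odds_mult)
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic patient cohort
#'
#' Draws `config$n` patients: disease level from the configured prevalence,
#' then covariates from level-conditional distributions that preserve the
#' configured marginals (see [cohort_config()]). The result is the cohort
#' table the rest of the pipeline operates on; `ptp` and `cad_score` start
#' as `NA` and are filled in by [compute_ptp()] and [compute_cad_score()].
#'
#' @param config a [cohort_config()].
#' @return a `data.frame` with columns `patient_id`, `age`, `sex`,
#'   `hypertension`, `symptom`, `bmi`, `diabetes`, `disease_level`, `ptp`,
#'   `cad_score`.
#' @examples
#' cfg <- cohort_config(n = 50, seed = 1)
#' head(generate_cohort(cfg))
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n
    lev <- sample(disease_levels(), n, replace = TRUE, prob = config$prevalence)
    li <- match(lev, disease_levels())

    shift <- config$age_level_shift
    shift <- shift - sum(config$prevalence * shift)  # preserve marginal mean
    age <- rtruncnorm(n, config$age_mean + shift[li], config$age_sd,
                      config$age_range[1], config$age_range[2])

    p_male <- .level_probs(1 - config$female_frac, config$male_odds_mult,
                           config$prevalence)
    sex <- ifelse(stats::runif(n) < p_male[li], "male", "female")
    p_ht <- .level_probs(config$hypertension_frac,
                         config$hypertension_odds_mult, config$prevalence)
    hypertension <- stats::runif(n) < p_ht[li]

    symptom <- sample(symptom_levels(), n, replace = TRUE,
                      prob = config$symptom_mix)
    bmi <- rtruncnorm(n, config$bmi_mean, config$bmi_sd, 15, 50)
    diabetes <- stats::runif(n) < config$diabetes_frac

    data.frame(
      patient_id = sprintf("P%06d", seq_len(n)),
      age = round(age, 1), sex = sex, hypertension = hypertension,
      symptom = symptom, bmi = round(bmi, 1), diabetes = diabetes,
      disease_level = lev, ptp = NA_real_, cad_score = NA_integer_,
      stringsAsFactors = FALSE)
  })
}

#' Baseline characteristics table for a cohort
#'
#' Summarises a cohort the way baseline tables in diagnostic-accuracy studies
#' are laid out: continuous variables as mean +/- SD, categorical variables
#' as count (percent).
#'
#' @param cohort a cohort `data.frame` from [generate_cohort()].
#' @return a `data.frame` with columns `variable`, `summary` (formatted
#'   string), and numeric helper columns `mean`, `sd`, `count`, `percent`.
#' @export
cohort_summary <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0)
    stop("`cohort` must be a non-empty data.frame", call. = FALSE)
  n <- nrow(cohort)
  num_row <- function(name, x) {
    m <- mean(x); s <- stats::sd(x)
    if (is.na(s)) s <- 0
    data.frame(variable = name,
               summary = sprintf("%.1f ± %.1f", m, s),
               mean = m, sd = s, count = NA_real_, percent = NA_real_)
  }
  cnt_row <- function(name, k) {
    data.frame(variable = name,
               summary = sprintf("%d (%.1f%%)", k, 100 * k / n),
               mean = NA_real_, sd = NA_real_, count = k,
               percent = 100 * k / n)
  }
  out <- rbind(
    data.frame(variable = "N", summary = as.character(n), mean = NA_real_,
               sd = NA_real_, count = n, percent = NA_real_),
    cnt_row("Sex (female)", sum(cohort$sex == "female")),
    num_row("Age", cohort$age),
    num_row("BMI", cohort$bmi),
    cnt_row("Hypertension", sum(cohort$hypertension)),
    cnt_row("Diabetes", sum(cohort$diabetes)),
    do.call(rbind, lapply(symptom_levels(), function(s)
      cnt_row(paste0("Symptoms: ", s), sum(cohort$symptom == s)))),
    do.call(rbind, lapply(disease_levels(), function(l)
      cnt_row(paste0("Disease level: ", l), sum(cohort$disease_level == l)))))
  rownames(out) <- NULL
  out
}

#' Read and write cohort tables as CSV
#'
#' One row per patient with the fixed column set `patient_id, age, sex,
#' hypertension, symptom, bmi, diabetes, disease_level, ptp, cad_score`.
#'
#' @param cohort a cohort `data.frame`.
#' @param path file path.
#' @return `read_cohort_csv()` returns the cohort `data.frame`;
#'   `write_cohort_csv()` returns `path` invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  cols <- c("patient_id", "age", "sex", "hypertension", "symptom", "bmi",
            "diabetes", "disease_level", "ptp", "cad_score")
  missing <- setdiff(cols, names(cohort))
  if (length(missing))
    stop("cohort is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  utils::write.csv(cohort[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$hypertension <- as.logical(x$hypertension)
  x$diabetes <- as.logical(x$diabetes)
  x$cad_score <- as.integer(x$cad_score)
  x
}
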