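#' Zero-phase FFT band-pass
#'
#' Brick-wall band selection in the frequency domain with raised-cosine
#' transition edges; exactly zero phase and length preserving. Used by the
#' simulator for murmur-band noise shaping; recordings go through
#' [bandpass_filter()] (Butterworth, zero phase) in the processing pipeline.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param lo,hi band edges (Hz).
#' @param transition transition width (Hz) of the raised-cosine edges.
#' @return filtered signal, same length as `x`.
#' @keywords internal
fft_bandpass <- function(x, fs, lo, hi, transition = 15) {
  n <- length(x)
  # positive-frequency half mask, built only over the band (plus edges)
  half <- numeric(n %/% 2 + 1)
  fpos <- (seq_along(half) - 1) * fs / n
  i_band <- fpos >= lo & fpos <= hi
  half[i_band] <- 1
  i_up <- fpos > (lo - transition) & fpos < lo
  half[i_up] <- 0.5 * (1 - cos(pi * (fpos[i_up] - (lo - transition)) /
                                 transition))
  i_dn <- fpos > hi & fpos < (hi + transition)
  half[i_dn] <- 0.5 * (1 - cos(pi * ((hi + transition) - fpos[i_dn]) /
                                 transition))
  mask <- numeric(n)
  mask[seq_along(half)] <- half
  if (n > 2)  # mirror onto the negative frequencies
    mask[n:(n %/% 2 + 2)] <- half[2:(n - n %/% 2)]
  Re(stats::fft(stats::fft(x) * mask, inverse = TRUE)) / n
}

new_pcg_recording <- function(samples, sampling_rate, annotations = NULL,
                              pretest = NULL) {
  structure(list(samples = samples,
                 sampling_rate = sampling_rate,
                 duration = length(samples) / sampling_rate,
                 annotations = annotations,
                 pretest = pretest),
            class = "pcg_recording")
}

#' @export
print.pcg_recording <- function(x, ...) {
  cat(sprintf("<pcg_recording> %.1f s @ %g Hz (%d samples)%s%s\n",
              x$duration, x$sampling_rate, length(x$samples),
              if (!is.null(x$pretest))
                sprintf(", pre-test %.1f s", length(x$pretest) / x$sampling_rate)
              else "",
              if (!is.null(x$annotations))
                sprintf(", %d annotated beats", length(x$annotations$s1_onset))
              else ""))
  invisible(x)
}

# damped-oscillation heart-sound transient sampled on a fixed grid
.transient <- function(len, fs, freq, tau) {
  tt <- (seq_len(len) - 1) / fs
  exp(-tt / tau) * sin(2 * pi * freq * tt)
}

.simulate_segment <- function(duration, fs, hr, rr_cov, sys_base,
                              murmur_rms, murmur_band, noise_level) {
  n <- round(duration * fs)
  rr <- 60 / hr
  nbeat_max <- ceiling(duration / (rr * 0.6)) + 2
  rr_i <- pmax(rr * (1 + stats::rnorm(nbeat_max, 0, rr_cov)), 0.35)
  s1_on <- 0.2 + cumsum(c(0, rr_i))
  s1_dur <- 0.09; s2_dur <- 0.07
  keep <- s1_on + sys_base + s2_dur + 0.05 < duration
  s1_on <- s1_on[keep]
  nb <- length(s1_on)
  s2_on <- s1_on + sys_base

  x <- stats::rnorm(n, 0, noise_level)
  for (b in seq_len(nb)) {
    i1 <- round(s1_on[b] * fs) + 1
    l1 <- round(s1_dur * fs)
    a1 <- exp(stats::rnorm(1, 0, 0.08))
    x[i1:(i1 + l1 - 1)] <- x[i1:(i1 + l1 - 1)] +
      a1 * .transient(l1, fs, stats::rnorm(1, 30, 1.5), 0.018)
    i2 <- round(s2_on[b] * fs) + 1
    l2 <- round(s2_dur * fs)
    a2 <- 0.65 * a1 * exp(stats::rnorm(1, 0, 0.08))
    x[i2:(i2 + l2 - 1)] <- x[i2:(i2 + l2 - 1)] +
      a2 * .transient(l2, fs, stats::rnorm(1, 55, 2), 0.012)
  }

  if (murmur_rms > 0 && nb > 1) {
    gate <- numeric(n)
    ramp_len <- round(0.01 * fs)
    ramp <- 0.5 * (1 - cos(pi * seq_len(ramp_len) / ramp_len))
    for (b in seq_len(nb - 1)) {
      from <- round((s2_on[b] + s2_dur + 0.01) * fs) + 1
      to <- round((s1_on[b + 1] - 0.01) * fs)
      if (to - from > 2 * ramp_len + 10) {
        gate[from:to] <- 1
        gate[from:(from + ramp_len - 1)] <- ramp
        gate[(to - ramp_len + 1):to] <- rev(ramp)
      }
    }
    m <- fft_bandpass(stats::rnorm(n), fs, murmur_band[1],
                      min(murmur_band[2], fs / 2 * 0.98))
    m <- m / stats::sd(m)
    x <- x + murmur_rms * m * gate
  }

  list(samples = x,
       annotations = list(s1_onset = s1_on, s2_onset = s2_on,
                          s1_dur = s1_dur, s2_dur = s2_dur,
                          heart_rate = hr, systole_dur = sys_base,
                          rr = diff(s1_on)))
}

#' Simulate a phonocardiogram for one patient
#'
#' Produces a heart-sound waveform with per-beat S1/S2 transients (decaying
#' 20-60 Hz oscillations), a heart-rate dependent systolic duration, an
#' additive band-limited (by default 200-500 Hz) diastolic murmur whose RMS
#' scales with the patient's disease level, and broadband measurement noise.
#' The main recording (default 150 s) is preceded by a pre-test sound-check
#' segment (default 30 s) stored in `$pretest`. Ground-truth S1/S2 onset
#' annotations are attached for segmentation benchmarking.
#'
#' The per-patient murmur RMS is
#' `murmur_scale * murmur_level_mult[level] * lognormal(0, murmur_sd_log)`,
#' so murmur energy increases stochastically with disease severity.
#'
#' @param patient a single-row slice of a cohort `data.frame` (needs
#'   `disease_level`; `patient_id` is used to derive a per-patient seed).
#' @param config a [cohort_config()].
#' @param seed optional explicit seed; by default derived from `config$seed`
#'   and the patient's position so each patient has a reproducible waveform.
#' @param arrhythmia force an irregular rhythm (`TRUE`/`FALSE`); by default
#'   drawn with probability `config$arrhythmia_frac`.
#' @param murmur_mult extra multiplier on the murmur RMS (for effect-size
#'   experiments; 0 switches the murmur off).
#' @param include_pretest simulate the pre-test segment (default `TRUE`).
#' @return a `pcg_recording`: list with `samples`, `sampling_rate`,
#'   `duration`, `annotations` (S1/S2 onsets in seconds from recording
#'   start, heart rate, RR series, murmur RMS, arrhythmia flag), `pretest`.
#' @examples
#' cfg <- cohort_config(n = 2, duration = 20, pretest_duration = 5, seed = 3)
#' co <- generate_cohort(cfg)
#' rec <- simulate_pcg(co[1, ], cfg)
#' rec
#' @export
simulate_pcg <- function(patient, config, seed = NULL, arrhythmia = NULL,
                         murmur_mult = 1, include_pretest = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$sampling_rate <= 0)
    stop("sampling rate must be positive", call. = FALSE)
  level <- as.character(patient$disease_level[1])
  if (is.na(level) || !level %in% disease_levels())
    stop("patient must carry a valid `disease_level`", call. = FALSE)
  if (is.null(seed) && !is.null(config$seed)) {
    idx <- suppressWarnings(as.integer(sub("^P", "", patient$patient_id[1])))
    if (is.na(idx)) idx <- 0L
    seed <- patient_seed(config$seed, idx)
  }
  with_seed(seed, {
    fs <- config$sampling_rate
    hr <- rtruncnorm(1, config$heart_rate_mean, config$heart_rate_sd,
                     config$heart_rate_range[1], config$heart_rate_range[2])
    if (is.null(arrhythmia))
      arrhythmia <- stats::runif(1) < config$arrhythmia_frac
    rr_cov <- if (arrhythmia) 0.25 else 0.03
    sys_base <- 0.35 - 0.0012 * (hr - 60)
    li <- match(level, disease_levels())
    murmur_rms <- config$murmur_scale * config$murmur_level_mult[li] *
      exp(stats::rnorm(1, 0, config$murmur_sd_log)) * murmur_mult

    main <- .simulate_segment(config$duration, fs, hr, rr_cov, sys_base,
                              murmur_rms, config$murmur_band,
                              config$noise_level)
    pre <- NULL
    if (include_pretest && config$pretest_duration > 0)
      pre <- .simulate_segment(config$pretest_duration, fs, hr, rr_cov,
                               sys_base, murmur_rms, config$murmur_band,
                               config$noise_level)$samples

    ann <- main$annotations
    ann$arrhythmia <- arrhythmia
    ann$murmur_rms <- murmur_rms
    ann$patient_id <- as.character(patient$patient_id[1])
    new_pcg_recording(main$samples, fs, annotations = ann, pretest = pre)
  })
}
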