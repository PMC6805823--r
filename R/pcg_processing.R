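#' Amplitude envelope via moving-average energy
#'
#' Square-law envelope: square the signal, smooth with a centred moving
#' average (cumulative-sum implementation, O(n)), take the square root.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param window smoothing window (seconds).
#' @return envelope, same length as `x`.
#' @keywords internal
energy_envelope <- function(x, fs, window = 0.04) {
  w <- max(3L, round(window * fs))
  if (w %% 2 == 0) w <- w + 1L
  half <- (w - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x^2))
  out <- numeric(n)
  core <- (half + 1L):(n - half)
  out[core] <- (cs[core + half + 1L] - cs[core - half]) / w
  for (i in seq_len(half)) {  # shrunken windows at the edges
    out[i] <- cs[i + half + 1L] / (i + half)
    out[n - i + 1L] <- (cs[n + 1L] - cs[n - i - half + 1L]) / (i + half)
  }
  sqrt(out)
}

# local maxima of an envelope above an adaptive threshold, with a minimum
# separation; taller peaks win when two candidates are too close
.pick_peaks <- function(env, fs, min_dist = 0.18, thresh_frac = 0.35) {
  d <- diff(env)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (!length(cand)) return(integer())
  # anchor the threshold between the envelope background and the tall
  # (heart-sound) peaks, so a raised noise floor does not admit noise maxima
  bg <- stats::median(env)
  tall <- stats::quantile(env[cand], 0.98, names = FALSE)
  thr <- bg + thresh_frac * (tall - bg)
  cand <- cand[env[cand] >= thr]
  if (!length(cand)) return(integer())
  ord <- cand[order(env[cand], decreasing = TRUE)]
  min_gap <- round(min_dist * fs)
  keep <- logical(length(env))
  taken <- rep(FALSE, length(env))
  for (i in ord) {
    lo <- max(1L, i - min_gap); hi <- min(length(env), i + min_gap)
    if (!any(taken[lo:hi])) { keep[i] <- TRUE; taken[i] <- TRUE }
  }
  sort(which(keep))
}

# refine a peak to its onset: walk back until the envelope drops below
# background + frac * (peak - background). The centred moving-average
# envelope starts rising half a window before the transient, so callers add
# a constant lead correction.
.onset_of <- function(env, peak_idx, bg, frac = 0.15, max_back) {
  target <- bg + frac * (env[peak_idx] - bg)
  lo <- max(1L, peak_idx - max_back)
  seg <- env[lo:peak_idx]
  below <- which(seg < target)
  if (!length(below)) return(lo)
  lo + max(below) - 1L
}

# heart period from the envelope autocorrelation: tallest peak in the
# physiological lag range 0.45-1.5 s
.estimate_rr <- function(env, fs, lag_range = c(0.45, 1.5)) {
  e <- env - mean(env)
  n <- length(e)
  nfft <- stats::nextn(2 * n, 2)
  ac <- Re(stats::fft(Mod(stats::fft(c(e, numeric(nfft - n))))^2,
                      inverse = TRUE))[seq_len(n)]
  lags <- round(lag_range[1] * fs):min(round(lag_range[2] * fs), n - 1)
  lags[which.max(ac[lags + 1L])] / fs
}

# duration-constrained beat decoding: pick the S1 chain as the path through
# the candidate peaks that maximises summed envelope height subject to
# successive S1-S1 gaps near (a small multiple of) the estimated RR, then
# locate S2 as the tallest candidate inside the systolic window after each
# S1. This rejects spurious noise peaks that do not fit the beat grid.
.decode_beats <- function(peaks, env, fs, rr_est) {
  t <- (peaks - 1) / fs
  bg <- stats::median(env)
  h <- env[peaks] - bg
  k <- length(peaks)
  href <- stats::median(h[h > 0])
  dp <- h
  prev <- rep(0L, k)
  for (j in seq_len(k)) {
    lo <- t[j] - 2.6 * rr_est
    cand <- which(t >= lo & t < t[j] - 0.55 * rr_est)
    if (!length(cand)) next
    gap <- t[j] - t[cand]
    mult <- pmax(1, round(gap / rr_est))
    dev <- (gap - mult * rr_est) / rr_est
    score <- dp[cand] - 3 * href * dev^2 - 0.8 * href * (mult - 1)
    best <- which.max(score)
    if (score[best] > 0) { dp[j] <- h[j] + score[best]; prev[j] <- cand[best] }
  }
  end <- which.max(dp)
  chain <- integer()
  while (end != 0L) { chain <- c(end, chain); end <- prev[end] }
  # between consecutive chain peaks, the tallest off-chain peak; its median
  # offset decides whether the chain is S1 (short systolic gap follows) or S2
  ct <- t[chain]
  sec_gap <- rep(NA_real_, length(chain) - 1)
  sec_idx <- rep(NA_integer_, length(chain) - 1)
  for (b in seq_len(length(chain) - 1)) {
    inb <- which(t > ct[b] + 0.12 & t < ct[b + 1] - 0.1)
    if (!length(inb)) next
    sec_idx[b] <- inb[which.max(h[inb])]
    sec_gap[b] <- t[sec_idx[b]] - ct[b]
  }
  gap_ratio <- stats::median(sec_gap / diff(ct), na.rm = TRUE)
  s1 <- if (is.finite(gap_ratio) && gap_ratio > 0.5) {
    # chain caught the S2s: the secondary peaks are the S1s
    sec_idx[!is.na(sec_idx)]
  } else chain
  ct1 <- t[s1]
  s2 <- rep(NA_integer_, length(s1))
  for (b in seq_along(s1)) {
    upper <- if (b < length(s1)) ct1[b + 1] - 0.1 else ct1[b] + 0.6 * rr_est
    inb <- which(t > ct1[b] + 0.12 & t < pmin(ct1[b] + 0.6 * rr_est, upper))
    if (length(inb)) s2[b] <- inb[which.max(h[inb])]
  }
  keep <- !is.na(s2)
  list(s1 = peaks[s1[keep]], s2 = peaks[s2[keep]])
}

# template cross-correlation refinement of transient onsets: the envelope
# averaged over beats suppresses noise; each beat is re-aligned against the
# template, and the onset offset (threshold crossing on the flank) is read
# off the template once, which is far more stable than per-beat crossings
.refine_onsets <- function(env, fs, idx, bg, max_shift = 0.04) {
  W <- round(0.15 * fs)
  n <- length(env)
  safe <- pmin(pmax(idx, W + 1L), n - W)
  L <- 2L * W + 1L
  M <- t(vapply(safe, function(i) env[(i - W):(i + W)], numeric(L)))
  template <- apply(M, 2, stats::median)
  s_max <- round(max_shift * fs)
  shifts <- -s_max:s_max
  core <- (s_max + 1):(L - s_max)
  Tm <- vapply(shifts, function(s) template[core + s], numeric(length(core)))
  scores <- M[, core, drop = FALSE] %*% Tm
  best <- shifts[apply(scores, 1, which.max)]
  # beat[j] ~ template[j + s]  =>  corrected peak position is idx - s
  peak_corr <- idx - as.integer(best)
  onset_local <- .onset_of(template, W + 1L, bg, max_back = round(0.12 * fs))
  peak_corr - (W + 1L - onset_local)
}

#' Sound-quality control of a phonocardiogram
#'
#' Screens a recording before segmentation, mirroring the pre-test
#' sound-check of an automated heart-sound device. The verdict is one of
#' `ok`, `too_short` (below `min_duration`), `noisy_or_weak` (S1/S2
#' peak-to-background envelope ratio below `min_peak_ratio`, or fewer than
#' `min_beats` detectable beats), or `arrhythmia` (coefficient of variation
#' of the detected RR intervals above `max_rr_cov`).
#'
#' @param recording a `pcg_recording`.
#' @param max_rr_cov maximum RR coefficient of variation (default 0.2).
#' @param min_beats minimum number of detectable beats (default 20).
#' @param min_peak_ratio minimum S1 peak-to-background ratio (default 2).
#' @param min_duration minimum recording length in seconds (default 30).
#' @param use_pretest prepend the pre-test segment, when present, to the
#'   signal examined (default `FALSE`: judge the main recording).
#' @param segmentation optional precomputed `segmentation_result` used for
#'   the RR-regularity check; when `NULL` the recording is segmented here.
#' @return a `qc_verdict`: list with `passed` (logical) and `reason`.
#' @export
quality_check <- function(recording, max_rr_cov = 0.2, min_beats = 20,
                          min_peak_ratio = 2, min_duration = 30,
                          use_pretest = FALSE, segmentation = NULL) {
  stopifnot(inherits(recording, "pcg_recording"))
  x <- recording$samples
  if (use_pretest && !is.null(recording$pretest))
    x <- c(recording$pretest, x)
  if (length(x) == 0) stop("empty recording", call. = FALSE)
  fs <- recording$sampling_rate
  verdict <- function(reason)
    structure(list(passed = identical(reason, "ok"), reason = reason),
              class = "qc_verdict")
  if (length(x) / fs < min_duration) return(verdict("too_short"))
  env <- energy_envelope(fft_bandpass(x, fs, 20, min(150, fs / 2 * 0.9)), fs)
  peaks <- .pick_peaks(env, fs)
  bg <- stats::median(env)
  if (length(peaks) < min_beats ||
      stats::median(env[peaks]) / bg < min_peak_ratio)
    return(verdict("noisy_or_weak"))
  seg <- segmentation
  if (is.null(seg)) seg <- try(segment_heart_sounds(recording), silent = TRUE)
  if (inherits(seg, "try-error")) return(verdict("noisy_or_weak"))
  rr <- seg$rr_series
  if (length(rr) >= 5 && stats::sd(rr) / mean(rr) > max_rr_cov)
    return(verdict("arrhythmia"))
  if (length(seg$beats$s1_onset) < min_beats) return(verdict("noisy_or_weak"))
  verdict("ok")
}

#' @export
print.qc_verdict <- function(x, ...) {
  cat(sprintf("<qc_verdict> %s (%s)\n",
              if (x$passed) "PASSED" else "FAILED", x$reason))
  invisible(x)
}

#' Zero-phase Butterworth band-pass of a recording
#'
#' Order-4 Butterworth applied forward and backward (`signal::filtfilt`),
#' giving an effective 8th-order magnitude response with zero group delay,
#' so annotation times stay aligned with the filtered waveform.
#'
#' @param recording a `pcg_recording`.
#' @param low_hz,high_hz band edges; must satisfy
#'   `0 < low_hz < high_hz < fs/2`.
#' @return a `pcg_recording` with filtered samples (annotations preserved).
#' @export
bandpass_filter <- function(recording, low_hz, high_hz) {
  stopifnot(inherits(recording, "pcg_recording"))
  fs <- recording$sampling_rate
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2))
    stop("band must satisfy 0 < low_hz < high_hz < fs/2", call. = FALSE)
  bf <- signal::butter(4, c(low_hz, high_hz) / (fs / 2), type = "pass")
  out <- recording
  out$samples <- signal::filtfilt(bf, recording$samples)
  if (!is.null(out$pretest)) out$pretest <- signal::filtfilt(bf, out$pretest)
  out
}

#' Segment a phonocardiogram into S1, systole, S2 and diastole
#'
#' Envelope-based beat decoding: the square-law energy envelope is peak
#' picked, peaks are labelled S1 or S2 by the short-gap/long-gap alternation
#' of systole versus diastole (at resting heart rates systole is the shorter
#' interval), onsets/offsets are refined by walking the envelope flanks, and
#' beats violating physiological duration windows are dropped. Within each
#' beat the intervals are ordered S1 < systole < S2 < diastole, with
#' diastole running from the S2 offset to the next S1 onset (half-open
#' `[onset, offset)` convention, times in seconds from recording start).
#'
#' @param recording a `pcg_recording` (should have passed [quality_check()]).
#' @param min_beats minimum number of decodable beats (default 5); fewer is
#'   a segmentation failure.
#' @return a `segmentation_result`: list with `beats` (data.frame:
#'   `s1_onset`, `s1_offset`, `s2_onset`, `s2_offset`, `dia_offset`) and
#'   `rr_series` (seconds between successive S1 onsets).
#' @export
segment_heart_sounds <- function(recording, min_beats = 5) {
  stopifnot(inherits(recording, "pcg_recording"))
  x <- recording$samples
  fs <- recording$sampling_rate
  # S1/S2 are low-frequency transients; restricting the envelope to the
  # 20-80 Hz band keeps murmur energy (200-500 Hz) and most broadband noise
  # out of the beat decoder
  env <- energy_envelope(fft_bandpass(x, fs, 20, min(80, fs / 2 * 0.9)), fs)
  peaks <- .pick_peaks(env, fs, min_dist = 0.15, thresh_frac = 0.25)
  if (length(peaks) < 2 * min_beats)
    stop("segmentation failure: fewer than ", min_beats,
         " beats detected", call. = FALSE)
  rr_est <- .estimate_rr(env, fs)
  dec <- .decode_beats(peaks, env, fs, rr_est)
  s1_idx <- dec$s1; s2_idx <- dec$s2
  if (length(s1_idx) < min_beats)
    stop("segmentation failure: fewer than ", min_beats,
         " beats decoded", call. = FALSE)
  bg <- stats::median(env)
  s1_on <- .refine_onsets(env, fs, s1_idx, bg)
  s2_on <- .refine_onsets(env, fs, s2_idx, bg)
  # envelope-lead correction: half the smoothing window plus the transient
  # rise time to its 15% energy point
  corr <- 0.02 + 0.008
  s1_onset <- pmax((s1_on - 1) / fs + corr, 0)
  s2_onset <- pmax((s2_on - 1) / fs + corr, 0)
  s1_offset <- pmin(s1_onset + 0.10, s2_onset - 0.01)
  nb <- length(s1_onset)
  dia_offset <- c(s1_onset[-1], recording$duration)
  s2_offset <- pmin(s2_onset + 0.08, dia_offset - 0.01)
  ok <- s1_offset > s1_onset & s2_onset > s1_offset &
    s2_offset > s2_onset & dia_offset > s2_offset
  # last beat's diastole must not run off the recording
  ok[nb] <- ok[nb] && dia_offset[nb] > s2_offset[nb]
  beats <- data.frame(s1_onset = s1_onset, s1_offset = s1_offset,
                      s2_onset = s2_onset, s2_offset = s2_offset,
                      dia_offset = dia_offset)[ok, , drop = FALSE]
  rownames(beats) <- NULL
  if (nrow(beats) < min_beats)
    stop("segmentation failure: fewer than ", min_beats,
         " valid beats", call. = FALSE)
  structure(list(beats = beats, rr_series = diff(beats$s1_onset)),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d beats, mean RR %.3f s\n",
              nrow(x$beats), mean(x$rr_series)))
  invisible(x)
}

#' Build a segmentation from ground-truth annotations
#'
#' Converts the simulator's per-beat S1/S2 onset annotations into the same
#' `segmentation_result` structure that [segment_heart_sounds()] produces.
#' Used for the oracle (annotation-driven) processing path and for
#' segmentation benchmarking.
#'
#' @param recording an annotated `pcg_recording`.
#' @return a `segmentation_result`.
#' @export
segmentation_from_annotations <- function(recording) {
  ann <- recording$annotations
  if (is.null(ann)) stop("recording carries no annotations", call. = FALSE)
  s1 <- ann$s1_onset; s2 <- ann$s2_onset
  nb <- length(s1)
  dia_offset <- c(s1[-1], recording$duration)
  beats <- data.frame(s1_onset = s1,
                      s1_offset = s1 + ann$s1_dur,
                      s2_onset = s2,
                      s2_offset = s2 + ann$s2_dur,
                      dia_offset = dia_offset)
  ok <- beats$dia_offset > beats$s2_offset + 0.05
  beats <- beats[ok, , drop = FALSE]
  rownames(beats) <- NULL
  structure(list(beats = beats, rr_series = diff(beats$s1_onset)),
            class = "segmentation_result")
}
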