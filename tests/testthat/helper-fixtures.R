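# shared fixtures, built in code and cached for the duration of the run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a small, fast config for waveform-level tests
demo_config <- function(n = 10, duration = 40, seed = 42, ...) {
  cohort_config(n = n, duration = duration, pretest_duration = 10,
                seed = seed, ...)
}

demo_recording <- function() {
  cached("demo_recording", {
    cfg <- demo_config()
    co <- generate_cohort(cfg)
    simulate_pcg(co[1, ], cfg)
  })
}

demo_segmentation <- function() {
  cached("demo_segmentation", segment_heart_sounds(demo_recording()))
}

# band power of a signal via the periodogram (independent oracle for the
# murmur-energy checks)
periodogram_band_power <- function(x, fs, lo, hi) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                          plot = FALSE, detrend = FALSE)
  sum(sp$spec[sp$freq >= lo & sp$freq <= hi])
}

# diastolic samples of an annotated recording
diastolic_samples <- function(rec) {
  ann <- rec$annotations
  fs <- rec$sampling_rate
  idx <- integer()
  for (b in seq_len(length(ann$s1_onset) - 1)) {
    from <- round((ann$s2_onset[b] + ann$s2_dur + 0.02) * fs)
    to <- round((ann$s1_onset[b + 1] - 0.02) * fs)
    if (to > from) idx <- c(idx, from:to)
  }
  rec$samples[idx]
}
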