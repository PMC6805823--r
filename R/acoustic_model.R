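#' Extract the eight-feature acoustic profile of a recording
#'
#' Computes eight acoustic features describing murmur-related properties of
#' the systolic and diastolic periods, each aggregated as the median over
#' beats (robust to occasional mis-segmented beats):
#'
#' \describe{
#'   \item{dia_band_ratio}{log10 ratio of diastolic murmur-band
#'     (default 200-500 Hz) power to total diastolic power.}
#'   \item{sys_band_ratio}{the same ratio for the systolic period.}
#'   \item{dia_spec_entropy}{normalised spectral entropy of the diastolic
#'     spectrum (0 = pure tone, 1 = white).}
#'   \item{dia_pole_freq}{frequency (Hz) of the dominant pole of an AR(4)
#'     model of the diastolic signal (Yule-Walker).}
#'   \item{dia_sys_rms_ratio}{log10 ratio of diastolic to systolic RMS.}
#'   \item{s1_s2_ratio}{log10 ratio of S1 to S2 peak envelope amplitude.}
#'   \item{dia_hf_fraction}{fraction of diastolic power above `hf_cut`
#'     (default 250 Hz).}
#'   \item{dia_power_var}{beat-to-beat variability of diastolic murmur-band
#'     power (IQR / median).}
#' }
#'
#' All eight are ratios or shape measures, so they are invariant to overall
#' amplitude scaling of the recording, and they are computed only from
#' samples inside the designated cardiac intervals.
#'
#' @param recording a `pcg_recording`.
#' @param segmentation a `segmentation_result` with at least 5 beats.
#' @param band murmur band in Hz (default `c(200, 500)`).
#' @param hf_cut high-frequency cut (Hz) for `dia_hf_fraction`.
#' @return named numeric vector of length 8.
#' @export
extract_features <- function(recording, segmentation, band = c(200, 500),
                             hf_cut = 250) {
  stopifnot(inherits(recording, "pcg_recording"),
            inherits(segmentation, "segmentation_result"))
  beats <- segmentation$beats
  if (nrow(beats) < 5)
    stop("need a segmentation with at least 5 beats", call. = FALSE)
  x <- recording$samples
  fs <- recording$sampling_rate
  n <- length(x)
  idx <- function(t) pmin(pmax(round(t * fs) + 1L, 1L), n)
  sys0 <- idx(beats$s1_offset); sys1 <- idx(beats$s2_onset) - 1L
  dia0 <- idx(beats$s2_offset); dia1 <- idx(beats$dia_offset) - 1L
  if (any(sys1 - sys0 < 10) || any(dia1 - dia0 < 10))
    stop("degenerate (near zero-length) systolic or diastolic interval",
         call. = FALSE)

  hi <- min(band[2], fs / 2 * 0.98)
  xb <- fft_bandpass(x, fs, band[1], hi)            # murmur band
  xh <- fft_bandpass(x, fs, hf_cut, fs / 2 * 0.98)  # high-frequency part
  cs_tot <- cumsum(c(0, x^2))
  cs_band <- cumsum(c(0, xb^2))
  cs_hf <- cumsum(c(0, xh^2))
  pow <- function(cs, i0, i1) (cs[i1 + 1L] - cs[i0]) / (i1 - i0 + 1L)

  dia_tot <- pow(cs_tot, dia0, dia1); dia_band <- pow(cs_band, dia0, dia1)
  sys_tot <- pow(cs_tot, sys0, sys1); sys_band <- pow(cs_band, sys0, sys1)
  dia_hf <- pow(cs_hf, dia0, dia1)

  # per-beat diastolic windows on a common length for spectral features
  L <- min(512L, min(dia1 - dia0 + 1L))
  D <- vapply(seq_len(nrow(beats)),
              function(b) x[dia0[b]:(dia0[b] + L - 1L)], numeric(L))
  spec <- Mod(stats::mvfft(D * (0.5 - 0.5 * cos(2 * pi * seq_len(L) / L))))^2
  spec <- spec[2:(L %/% 2), , drop = FALSE]
  p <- sweep(spec, 2, colSums(spec), "/")
  entropy <- -colSums(p * log(pmax(p, 1e-300))) / log(nrow(p))

  # AR(4) Yule-Walker per beat, vectorised autocovariances
  r <- vapply(0:4, function(k)
    colSums(D[1:(L - k), , drop = FALSE] * D[(1 + k):L, , drop = FALSE]) / L,
    numeric(ncol(D)))
  pole_freq <- vapply(seq_len(nrow(beats)), function(b) {
    R <- stats::toeplitz(r[b, 1:4])
    a <- tryCatch(solve(R, r[b, 2:5]), error = function(e) rep(0, 4))
    roots <- polyroot(c(-rev(a), 1))
    dom <- roots[which.max(Mod(roots))]
    abs(Arg(dom)) / (2 * pi) * fs
  }, numeric(1))

  env <- energy_envelope(fft_bandpass(x, fs, 20, min(80, fs / 2 * 0.9)), fs,
                         window = 0.02)
  s1a <- vapply(seq_len(nrow(beats)), function(b)
    max(env[idx(beats$s1_onset[b]):idx(beats$s1_offset[b])]), numeric(1))
  s2a <- vapply(seq_len(nrow(beats)), function(b)
    max(env[idx(beats$s2_onset[b]):idx(beats$s2_offset[b])]), numeric(1))

  out <- c(
    dia_band_ratio = stats::median(log10(dia_band / dia_tot)),
    sys_band_ratio = stats::median(log10(sys_band / sys_tot)),
    dia_spec_entropy = stats::median(entropy),
    dia_pole_freq = stats::median(pole_freq),
    dia_sys_rms_ratio = stats::median(0.5 * log10(dia_tot / sys_tot)),
    s1_s2_ratio = stats::median(log10(s1a / s2a)),
    dia_hf_fraction = stats::median(dia_hf / dia_tot),
    dia_power_var = stats::IQR(dia_band) / stats::median(dia_band))
  if (any(!is.finite(out)))
    stop("non-finite acoustic features (degenerate intervals?)",
         call. = FALSE)
  out
}

#' Feature names of the acoustic profile
#' @return character vector of the 8 feature names, in canonical order.
#' @export
acoustic_feature_names <- function() {
  c("dia_band_ratio", "sys_band_ratio", "dia_spec_entropy", "dia_pole_freq",
    "dia_sys_rms_ratio", "s1_s2_ratio", "dia_hf_fraction", "dia_power_var")
}

#' Fit a two-class shrinkage linear discriminant
#'
#' Fisher discriminant with the pooled within-class covariance shrunk toward
#' its diagonal: `S* = (1 - shrinkage) S + shrinkage diag(S)` (plus a tiny
#' ridge when a feature is constant), so collinear or duplicated features
#' yield finite weights rather than a failure. The projection is oriented so
#' that higher scores point toward the positive class.
#'
#' @param x numeric matrix (rows = recordings, columns = features).
#' @param labels logical or two-level vector; `TRUE` (or the second level)
#'   is the positive class.
#' @param shrinkage shrinkage coefficient in `[0, 1]` (default 0.1).
#' @return an object of class `lda_weights`: list with `weights` (named),
#'   `intercept`, `shrinkage`.
#' @export
fit_lda <- function(x, labels, shrinkage = 0.1) {
  x <- as.matrix(x)
  y <- as.logical(labels)
  if (anyNA(y) || length(unique(y)) < 2)
    stop("labels must contain both classes", call. = FALSE)
  if (min(table(y)) < 2)
    stop("need at least 2 samples per class", call. = FALSE)
  if (nrow(x) != length(y)) stop("dimension mismatch", call. = FALSE)
  mu1 <- colMeans(x[y, , drop = FALSE])
  mu0 <- colMeans(x[!y, , drop = FALSE])
  n1 <- sum(y); n0 <- sum(!y)
  S <- ((n1 - 1) * stats::cov(x[y, , drop = FALSE]) +
          (n0 - 1) * stats::cov(x[!y, , drop = FALSE])) / (n1 + n0 - 2)
  D <- diag(diag(S), ncol(S))
  Sh <- (1 - shrinkage) * S + shrinkage * D
  eps <- 1e-8 * mean(diag(Sh))
  w <- tryCatch(solve(Sh, mu1 - mu0),
                error = function(e)
                  solve(Sh + diag(eps, ncol(Sh)), mu1 - mu0))
  names(w) <- colnames(x)
  structure(list(weights = w,
                 intercept = -sum(w * (mu1 + mu0) / 2),
                 shrinkage = shrinkage),
            class = "lda_weights")
}

#' @export
print.lda_weights <- function(x, ...) {
  cat("<lda_weights> intercept", format(x$intercept, digits = 4),
      "shrinkage", x$shrinkage, "\n")
  print(round(x$weights, 4))
  invisible(x)
}

#' Acoustic score: linear discriminant projection of a feature vector
#'
#' The affine combination `sum(w * f) + intercept`; strictly monotone in
#' every feature with a nonzero weight.
#'
#' @param features named numeric vector of length 8, or a matrix with one
#'   row per recording.
#' @param weights an `lda_weights` object.
#' @return numeric scalar (or vector for matrix input).
#' @export
acoustic_score <- function(features, weights) {
  stopifnot(inherits(weights, "lda_weights"))
  w <- weights$weights
  if (is.matrix(features) || is.data.frame(features)) {
    features <- as.matrix(features)
    if (ncol(features) != length(w)) stop("dimension mismatch", call. = FALSE)
    if (!is.null(colnames(features)) &&
        !identical(colnames(features), names(w)))
      features <- features[, names(w), drop = FALSE]
    drop(features %*% w) + weights$intercept
  } else {
    if (length(features) != length(w)) stop("dimension mismatch", call. = FALSE)
    if (!is.null(names(features)) && !identical(names(features), names(w)))
      features <- features[names(w)]
    sum(features * w) + weights$intercept
  }
}

#' Read and write feature matrices as CSV
#'
#' One row per recording: `patient_id`, the 8 named feature columns, and
#' the class label.
#'
#' @param features matrix or data.frame of features.
#' @param labels class label per row.
#' @param patient_id identifier per row.
#' @param path file path.
#' @return `read_features_csv()` returns a data.frame;
#'   `write_features_csv()` returns `path` invisibly.
#' @export
write_features_csv <- function(features, labels, patient_id, path) {
  df <- data.frame(patient_id = patient_id, as.data.frame(features),
                   label = labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
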