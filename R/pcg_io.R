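#' Read and write phonocardiograms as mono 16-bit PCM WAV
#'
#' Minimal RIFF/WAVE support for the package's recording interchange format:
#' mono, 16-bit PCM. On write, samples are rescaled to 98% full scale and
#' the scale factor is stored in the sidecar annotations (if written), so
#' round-tripping preserves the waveform up to quantisation. Ground-truth
#' annotations travel in a sidecar JSON file (see
#' [write_annotations_json()]).
#'
#' @param recording a `pcg_recording`.
#' @param path file path (`.wav`).
#' @return `read_pcg_wav()` returns a `pcg_recording` (without annotations);
#'   `write_pcg_wav()` returns `path` invisibly.
#' @export
write_pcg_wav <- function(recording, path) {
  stopifnot(inherits(recording, "pcg_recording"))
  x <- recording$samples
  peak <- max(abs(x), 1e-12)
  pcm <- as.integer(round(x / peak * 0.98 * 32767))
  fs <- as.integer(round(recording$sampling_rate))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_pcg_wav
#' @export
read_pcg_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file", call. = FALSE)
  invisible(readBin(con, integer(), 1, size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file", call. = FALSE)
  fs <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L)
        stop("only mono PCM WAV is supported", call. = FALSE)
      fs <- readBin(con, integer(), 1, size = 4, endian = "little")
      invisible(readBin(con, integer(), 1, size = 4, endian = "little"))
      invisible(readBin(con, integer(), 1, size = 2, endian = "little"))
      bits <- readBin(con, integer(), 1, size = 2, endian = "little")
      if (bits != 16L) stop("only 16-bit PCM WAV is supported", call. = FALSE)
    } else if (identical(id, "data")) {
      pcm <- readBin(con, integer(), sz / 2, size = 2, endian = "little")
      samples <- pcm / 32767
    } else {
      invisible(readBin(con, raw(), sz))
    }
    if (!is.null(fs) && !is.null(samples)) break
  }
  if (is.null(fs) || is.null(samples))
    stop("malformed WAV: missing fmt or data chunk", call. = FALSE)
  new_pcg_recording(samples, fs)
}

#' Sidecar JSON for recording annotations and segmentations
#'
#' Annotations (ground-truth S1/S2 onsets and metadata) and segmentation
#' results (per-beat interval records) are serialised as JSON next to the
#' WAV files.
#'
#' @param annotations the `annotations` element of a `pcg_recording`.
#' @param segmentation a `segmentation_result` from
#'   [segment_heart_sounds()].
#' @param path file path (`.json`).
#' @return readers return the deserialised object; writers return `path`
#'   invisibly.
#' @export
write_annotations_json <- function(annotations, path) {
  jsonlite::write_json(annotations, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotations_json
#' @export
read_annotations_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname write_annotations_json
#' @export
write_segmentation_json <- function(segmentation, path) {
  stopifnot(inherits(segmentation, "segmentation_result"))
  jsonlite::write_json(list(beats = segmentation$beats,
                            rr_series = segmentation$rr_series),
                       path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
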