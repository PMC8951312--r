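#' Preprocessing configuration
#'
#' Segmentation and denoising parameters. Recordings are cut into
#' non-overlapping fixed-length windows (10 s by default, at most
#' `n_segments` per recording), then mains interference is removed with a
#' narrow Butterworth band-stop ("notch") and broadband noise with a
#' Butterworth band-pass, both applied forward-backward for zero phase.
#'
#' The notch frequency and band edges are implementation defaults (60 Hz
#' mains, Q = 30; 0.5-50 Hz pass band): standard choices for US-recorded
#' scalp EEG, overridable here.
#'
#' @param segment_length_s Window length in seconds.
#' @param n_segments Maximum number of windows taken per recording.
#' @param notch_freq_hz Mains frequency to suppress.
#' @param notch_q Notch quality factor; the stop band is
#'   `notch_freq_hz / notch_q` wide.
#' @param bandpass_low_hz,bandpass_high_hz Pass-band edges in Hz.
#' @param filter_order Butterworth design order of the band-pass (the
#'   band-stop notch uses a fixed order-2 design).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(segment_length_s = 10,
                              n_segments = 6,
                              notch_freq_hz = 60,
                              notch_q = 30,
                              bandpass_low_hz = 0.5,
                              bandpass_high_hz = 50,
                              filter_order = 4) {
  stopifnot(segment_length_s > 0, n_segments >= 1, notch_q > 0,
            bandpass_low_hz > 0, bandpass_high_hz > bandpass_low_hz,
            filter_order >= 1)
  structure(list(segment_length_s = segment_length_s,
                 n_segments = as.integer(n_segments),
                 notch_freq_hz = notch_freq_hz,
                 notch_q = notch_q,
                 bandpass_low_hz = bandpass_low_hz,
                 bandpass_high_hz = bandpass_high_hz,
                 filter_order = as.integer(filter_order)),
            class = "preprocess_config")
}

#' Cut a recording into fixed-length non-overlapping segments
#'
#' Takes consecutive windows of `segment_length_s` seconds from the start of
#' the recording, up to `n_segments` of them. A partial trailing window is
#' discarded (padding would distort AR estimates at the boundary).
#'
#' @param rec An [eeg_recording()].
#' @param cfg A [preprocess_config()].
#' @return A list of [eeg_recording()] segments inheriting `subject_id` and
#'   `record_id`, with a `segment` field added.
#' @export
segment_recording <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  win <- round(cfg$segment_length_s * rec$sampling_rate_hz)
  n <- ncol(rec$data)
  k <- min(n %/% win, cfg$n_segments)
  if (k < 1) {
    stop(sprintf("recording %s/%d is shorter than one %g s segment",
                 rec$subject_id, rec$record_id, cfg$segment_length_s))
  }
  lapply(seq_len(k), function(i) {
    seg <- eeg_recording(rec$subject_id,
                         rec$data[, ((i - 1) * win + 1):(i * win), drop = FALSE],
                         rec$sampling_rate_hz,
                         channel_names = rec$channel_names,
                         record_id = rec$record_id)
    seg$segment <- i
    seg
  })
}

.filtfilt_rows <- function(filt, X) {
  t(apply(X, 1, function(x) signal::filtfilt(filt, x)))
}

#' Notch (band-stop) filter a recording
#'
#' Order-2 Butterworth band-stop of width `notch_freq_hz / notch_q`, applied
#' forward-backward (zero phase) to every channel.
#'
#' @inheritParams segment_recording
#' @return The filtered [eeg_recording()].
#' @export
notch_filter <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$sampling_rate_hz / 2
  if (cfg$notch_freq_hz >= nyq) stop("notch frequency at or above Nyquist")
  bw <- cfg$notch_freq_hz / cfg$notch_q / 2
  band <- c(max(cfg$notch_freq_hz - bw, 1e-6), min(cfg$notch_freq_hz + bw, nyq * 0.999)) / nyq
  filt <- signal::butter(2, band, type = "stop")
  rec$data <- .filtfilt_rows(filt, rec$data)
  rownames(rec$data) <- rec$channel_names
  rec
}

#' Band-pass filter a recording
#'
#' Butterworth band-pass between `bandpass_low_hz` and `bandpass_high_hz`,
#' applied forward-backward (zero phase) to every channel. DC and
#' out-of-band components are suppressed.
#'
#' @inheritParams segment_recording
#' @return The filtered [eeg_recording()].
#' @export
bandpass_filter <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$sampling_rate_hz / 2
  if (cfg$bandpass_high_hz >= nyq) stop("band edge at or above Nyquist")
  filt <- signal::butter(cfg$filter_order,
                         c(cfg$bandpass_low_hz, cfg$bandpass_high_hz) / nyq,
                         type = "pass")
  rec$data <- .filtfilt_rows(filt, rec$data)
  rownames(rec$data) <- rec$channel_names
  rec
}

#' Full preprocessing pipeline over a cohort
#'
#' segment -> notch -> band-pass, for every recording.
#'
#' @param cohort List of [eeg_recording()] objects.
#' @param cfg A [preprocess_config()].
#' @return A flat list of preprocessed segment recordings.
#' @export
preprocess_cohort <- function(cohort, cfg = preprocess_config()) {
  segs <- unlist(lapply(cohort, segment_recording, cfg = cfg),
                 recursive = FALSE)
  lapply(segs, function(s) bandpass_filter(notch_filter(s, cfg), cfg))
}
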