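## Deterministic substream seeding: one user-facing seed fans out to
## per-(subject, channel, record) streams so that enlarging a cohort never
## perturbs recordings already generated under the same seed.
.substream <- function(seed, ...) {
  ids <- c(...)
  x <- as.double(seed) %% 2147483647
  for (i in ids) {
    x <- (x * 69069 + (i + 1) * 2654435761) %% 2147483647
  }
  as.integer(x)
}

#' Specify a synthetic multi-subject EEG cohort
#'
#' Describes a desk-scale cohort in which a known subset of channels carries
#' subject-specific autoregressive (AR) signatures while the remaining
#' channels carry a cohort-shared AR process plus sensor noise. The planted
#' informative channels make channel-recovery by the wrapper testable
#' without any external recordings.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param n_channels Number of EEG channels per recording.
#' @param informative_channels Integer vector of 1-based channel indices that
#'   carry subject-specific AR signatures. May be empty.
#' @param ar_order_gen Order of the generating AR processes.
#' @param records_per_subject Number of recordings per subject.
#' @param record_duration_s Duration of each recording in seconds.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param noise_sd Standard deviation of additive white sensor noise, in units
#'   of the AR innovation standard deviation (which is 1).
#' @param seed Integer seed; the cohort is a pure function of the spec.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [planted_truth()]
#' @export
#' @examples
#' spec <- cohort_spec(n_subjects = 2, n_channels = 4,
#'                     informative_channels = 1, record_duration_s = 1)
#' cohort <- generate_cohort(spec)
#' dim(cohort[[1]]$data)
cohort_spec <- function(n_subjects = 8,
                        n_channels = 16,
                        informative_channels = c(3, 8, 12),
                        ar_order_gen = 5,
                        records_per_subject = 6,
                        record_duration_s = 10,
                        sampling_rate_hz = 160,
                        noise_sd = 0.5,
                        seed = 1) {
  stopifnot(n_subjects >= 2, n_channels >= 1, sampling_rate_hz > 0,
            records_per_subject >= 1, record_duration_s > 0,
            ar_order_gen >= 1, noise_sd >= 0)
  informative_channels <- sort(unique(as.integer(informative_channels)))
  if (length(informative_channels) &&
      (min(informative_channels) < 1 || max(informative_channels) > n_channels)) {
    stop("informative_channels must lie in 1..n_channels")
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_channels = as.integer(n_channels),
    informative_channels = informative_channels,
    ar_order_gen = as.integer(ar_order_gen),
    records_per_subject = as.integer(records_per_subject),
    record_duration_s = record_duration_s,
    sampling_rate_hz = sampling_rate_hz,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "cohort_spec: %d subjects x %d records, %d channels (%d informative: %s)\n",
    x$n_subjects, x$records_per_subject, x$n_channels,
    length(x$informative_channels),
    paste(x$informative_channels, collapse = ",")))
  cat(sprintf("  %g s @ %g Hz, AR(%d) generators, noise_sd = %g, seed = %d\n",
              x$record_duration_s, x$sampling_rate_hz, x$ar_order_gen,
              x$noise_sd, x$seed))
  invisible(x)
}

#' Construct a single EEG recording object
#'
#' @param subject_id Subject label.
#' @param data Numeric matrix, channels x samples.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param channel_names Optional channel labels; defaults to `Ch01`, ...
#' @param record_id Recording index within the subject.
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(subject_id, data, sampling_rate_hz,
                          channel_names = NULL, record_id = 1L) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("EEG data must be finite")
  if (is.null(channel_names)) {
    channel_names <- sprintf("Ch%02d", seq_len(nrow(data)))
  }
  stopifnot(length(channel_names) == nrow(data), sampling_rate_hz > 0)
  rownames(data) <- channel_names
  structure(list(subject_id = as.character(subject_id),
                 data = data,
                 sampling_rate_hz = sampling_rate_hz,
                 channel_names = channel_names,
                 record_id = as.integer(record_id)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("eeg_recording: subject %s, record %d, %d channels x %d samples @ %g Hz\n",
              x$subject_id, x$record_id, nrow(x$data), ncol(x$data),
              x$sampling_rate_hz))
  invisible(x)
}

## Levinson recursion: map reflection (partial autocorrelation) coefficients
## k_1..k_p, each in (-1, 1), to AR coefficients a such that
## x_t = sum_j a_j x_{t-j} + e_t is stationary by construction.
refl_to_ar <- function(k) {
  a <- numeric(0)
  for (m in seq_along(k)) {
    if (m > 1) a <- a - k[m] * rev(a)
    a <- c(a, k[m])
  }
  a
}

.draw_ar_coefs <- function(order, max_tries = 10L) {
  for (i in seq_len(max_tries)) {
    k <- stats::runif(order, -0.95, 0.95)
    a <- refl_to_ar(k)
    # |k| < 1 guarantees stationarity; the root check guards numerics only
    if (all(Mod(polyroot(c(1, -a))) > 1)) return(a)
  }
  stop("failed to draw stationary AR coefficients")
}

.simulate_ar <- function(a, n, burn = 200L) {
  as.numeric(stats::arima.sim(model = list(ar = a), n = n,
                              n.start = burn + length(a)))
}

#' Generate a synthetic EEG cohort with planted discriminative channels
#'
#' Each informative channel of subject `s` is a realization of a
#' subject-specific stationary AR process whose coefficients are drawn once
#' per (subject, channel) via reflection coefficients in (-0.95, 0.95) mapped
#' through the Levinson recursion (stationary by construction). Every
#' non-informative channel is a realization of one cohort-shared AR process.
#' White sensor noise of standard deviation `noise_sd` is added to every
#' channel. The output is a pure function of the spec (including its seed).
#'
#' @param spec A [cohort_spec()].
#' @return A list of [eeg_recording()] objects, ordered by subject then record
#'   (`n_subjects * records_per_subject` in total).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- round(spec$record_duration_s * spec$sampling_rate_hz)
  if (n <= 10 * spec$ar_order_gen) stop("record too short for the generating AR order")

  set.seed(.substream(spec$seed, 0, 0))
  shared_a <- .draw_ar_coefs(spec$ar_order_gen)

  subj_coefs <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    subj_coefs[[s]] <- lapply(spec$informative_channels, function(ch) {
      set.seed(.substream(spec$seed, s, ch))
      .draw_ar_coefs(spec$ar_order_gen)
    })
  }

  out <- vector("list", spec$n_subjects * spec$records_per_subject)
  idx <- 1L
  for (s in seq_len(spec$n_subjects)) {
    for (r in seq_len(spec$records_per_subject)) {
      X <- matrix(0, spec$n_channels, n)
      for (ch in seq_len(spec$n_channels)) {
        set.seed(.substream(spec$seed, s, ch, 1000L + r))
        pos <- match(ch, spec$informative_channels)
        a <- if (is.na(pos)) shared_a else subj_coefs[[s]][[pos]]
        X[ch, ] <- .simulate_ar(a, n) + spec$noise_sd * stats::rnorm(n)
      }
      out[[idx]] <- eeg_recording(sprintf("S%03d", s), X,
                                  spec$sampling_rate_hz, record_id = r)
      idx <- idx + 1L
    }
  }
  out
}

#' Ground-truth channel mask of a synthetic cohort
#'
#' @param spec A [cohort_spec()].
#' @return Integer 0/1 vector of length `n_channels` with 1 exactly at the
#'   planted informative channels.
#' @export
planted_truth <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  mask <- integer(spec$n_channels)
  mask[spec$informative_channels] <- 1L
  mask
}

#' Write a cohort to a directory of plain-text matrices plus a manifest
#'
#' One tab-separated channels x samples matrix per recording and a
#' `manifest.tsv` (subject_id, record_id, file, sampling_rate_hz, channels).
#'
#' @param cohort List of [eeg_recording()] objects.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(cohort), function(i) {
    rec <- cohort[[i]]
    file <- sprintf("rec_%s_%02d.tsv", rec$subject_id, rec$record_id)
    utils::write.table(rec$data, file.path(dir, file), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    data.frame(subject_id = rec$subject_id, record_id = rec$record_id,
               file = file, sampling_rate_hz = rec$sampling_rate_hz,
               channels = paste(rec$channel_names, collapse = ","),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.tsv`.
#' @return A list of [eeg_recording()] objects.
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    X <- as.matrix(utils::read.table(file.path(dir, m$file), sep = "\t"))
    dimnames(X) <- NULL
    eeg_recording(m$subject_id, X, m$sampling_rate_hz,
                  channel_names = strsplit(m$channels, ",")[[1]],
                  record_id = m$record_id)
  })
}
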