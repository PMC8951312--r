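# Shared fixtures: built in code at test time, small enough to be fast.

# Tiny planted cohort -> preprocessed feature table (cached per session).
small_cohort_spec <- function(n_channels = 8, informative = c(2, 5),
                              n_subjects = 4, seed = 7) {
  cohort_spec(n_subjects = n_subjects, n_channels = n_channels,
              informative_channels = informative, records_per_subject = 6,
              record_duration_s = 10, sampling_rate_hz = 160, seed = seed)
}

small_feature_table <- local({
  cache <- new.env()
  function(spec = small_cohort_spec(), method = "AR5") {
    key <- paste(spec$seed, spec$n_channels, method, spec$n_subjects, sep = "_")
    if (is.null(cache[[key]])) {
      segs <- preprocess_cohort(generate_cohort(spec))
      cache[[key]] <- build_feature_table(segs, feature_config(method))
    }
    cache[[key]]
  }
})

# Toy objectives for the optimizers (percent scale, maximized).
onemax_fitness <- function(mask) 100 * sum(mask) / length(mask)

make_mask <- function(idx, D) {
  m <- integer(D)
  m[idx] <- 1L
  m
}

# Brute-force one-vs-rest confusion tally: the independent oracle for the
# closed-form aggregation in identification_report().
ovr_oracle <- function(truth, pred) {
  if (!is.factor(truth)) truth <- factor(truth)
  pred <- factor(pred, levels = levels(truth))
  TA <- TR <- FA <- FR <- 0L
  for (cl in levels(truth)) {
    for (i in seq_along(truth)) {
      t_is <- truth[i] == cl
      p_is <- pred[i] == cl
      if (t_is && p_is) TA <- TA + 1L
      else if (!t_is && p_is) FA <- FA + 1L
      else if (t_is && !p_is) FR <- FR + 1L
      else TR <- TR + 1L
    }
  }
  list(TA = TA, TR = TR, FA = FA, FR = FR,
       acc = 100 * mean(pred == truth),
       sen = TA / (TA + FR),
       spe = TR / (TR + FA),
       f_score = 2 * TA / (2 * TA + FA + FR))
}

# Sinusoid probe recording for filter tests.
probe_recording <- function(freq_hz, fs = 160, duration_s = 4, amp = 1) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  eeg_recording("probe", matrix(amp * sin(2 * pi * freq_hz * t), nrow = 1), fs)
}

rms <- function(x) sqrt(mean(x^2))
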