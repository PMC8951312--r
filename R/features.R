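## Daubechies-4 analysis filters (8 taps, 4 vanishing moments), orthonormal.
.db4_dec_lo <- c(-0.010597401785069032, 0.0328830116668852,
                 0.030841381835560764, -0.18703481171909309,
                 -0.027983769416859854, 0.6308807679298589,
                 0.7148465705529157, 0.2303778133088965)
.db4_dec_hi <- c(-0.2303778133088965, 0.7148465705529157,
                 -0.6308807679298589, -0.027983769416859854,
                 0.18703481171909309, 0.030841381835560764,
                 -0.0328830116668852, -0.010597401785069032)

#' Feature-extraction configuration
#'
#' Chooses the per-channel feature family: Yule-Walker autoregressive
#' coefficients of order 5, 10 or 20 (`"AR5"`, `"AR10"`, `"AR20"`), or
#' multi-level discrete wavelet sub-band statistics (`"WT"`). The wavelet
#' family, depth and statistics are implementation defaults (Daubechies-4,
#' 4 levels, energy / mean absolute value / standard deviation per sub-band).
#'
#' @param method One of `"AR5"`, `"AR10"`, `"AR20"`, `"WT"`.
#' @param wavelet_name Wavelet family; `"db4"` is the only built-in.
#' @param wavelet_levels Decomposition depth (>= 1).
#' @param wavelet_stats Statistics computed per sub-band, a subset of
#'   `c("energy", "mean_abs", "sd")`.
#' @param aggregate_segments If `TRUE` (default) the per-segment feature
#'   vectors of a recording are averaged element-wise, giving one row per
#'   recording; if `FALSE`, one row per segment.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(method = c("AR5", "AR10", "AR20", "WT"),
                           wavelet_name = "db4",
                           wavelet_levels = 4,
                           wavelet_stats = c("energy", "mean_abs", "sd"),
                           aggregate_segments = TRUE) {
  method <- match.arg(method)
  wavelet_stats <- match.arg(wavelet_stats, several.ok = TRUE)
  if (wavelet_name != "db4") stop("only the db4 wavelet is built in")
  stopifnot(wavelet_levels >= 1)
  ar_order <- switch(method, AR5 = 5L, AR10 = 10L, AR20 = 20L, WT = NA_integer_)
  structure(list(method = method, ar_order = ar_order,
                 wavelet_name = wavelet_name,
                 wavelet_levels = as.integer(wavelet_levels),
                 wavelet_stats = wavelet_stats,
                 aggregate_segments = isTRUE(aggregate_segments)),
            class = "feature_config")
}

#' Yule-Walker autoregressive coefficients of a channel
#'
#' Fits an AR(`order`) model by solving the autocovariance (Yule-Walker)
#' equations and returns the coefficients `a` of
#' `x_t = a_1 x_(t-1) + ... + a_p x_(t-p) + e_t`.
#'
#' @param x Numeric vector, one channel's samples (length > 10 * order).
#' @param order AR model order.
#' @return Numeric vector of length `order`.
#' @export
#' @examples
#' set.seed(1)
#' x <- as.numeric(arima.sim(list(ar = c(0.5, -0.3)), 5000))
#' ar_features(x, 2)  # close to (0.5, -0.3)
ar_features <- function(x, order) {
  stopifnot(is.numeric(x), all(is.finite(x)), order >= 1)
  if (length(x) <= 10 * order) stop("signal too short for AR order")
  if (stats::var(x) == 0) stop("constant signal: autocovariance matrix is singular")
  fit <- stats::ar.yw(x, aic = FALSE, order.max = order, demean = TRUE)
  as.numeric(fit$ar)
}

## Periodized single-level DWT step; matches PyWavelets mode="periodization".
.dwt_step <- function(x, filt) {
  n <- length(x)
  if (n %% 2 == 1) {
    x <- c(x, x[n])
    n <- n + 1L
  }
  L <- length(filt)
  y <- vapply(seq_len(n), function(i) {
    sum(filt * x[((i - seq_len(L)) %% n) + 1])
  }, numeric(1))
  y[((seq(0, n / 2 - 1) * 2 + L / 2) %% n) + 1]
}

#' Multi-level periodized discrete wavelet decomposition
#'
#' @param x Numeric vector (length >= 2^levels).
#' @param levels Decomposition depth.
#' @return Named list `A<levels>`, `D<levels>`, ..., `D1` of coefficient
#'   vectors (approximation band first, then details coarse to fine).
#' @export
dwt_decompose <- function(x, levels) {
  stopifnot(all(is.finite(x)), levels >= 1)
  if (length(x) < 2^levels) stop("signal too short for requested wavelet depth")
  details <- vector("list", levels)
  a <- x
  for (lev in seq_len(levels)) {
    d <- .dwt_step(a, .db4_dec_hi)
    a <- .dwt_step(a, .db4_dec_lo)
    details[[lev]] <- d
  }
  out <- c(list(a), rev(details))
  names(out) <- c(sprintf("A%d", levels), sprintf("D%d", levels:1))
  out
}

.band_stat <- function(coefs, stat) {
  switch(stat,
         energy = sum(coefs^2),
         mean_abs = mean(abs(coefs)),
         sd = stats::sd(coefs))
}

#' Wavelet sub-band statistics of a channel
#'
#' Decomposes the signal to `wavelet_levels` levels (Daubechies-4,
#' periodized) and computes the configured statistics per sub-band, in fixed
#' (band, statistic) order: approximation band first, then detail bands from
#' coarse to fine.
#'
#' @param x Numeric vector, one channel's samples.
#' @param cfg A [feature_config()] (its wavelet fields are used).
#' @return Named numeric vector of length
#'   `(wavelet_levels + 1) * length(wavelet_stats)`.
#' @export
wavelet_features <- function(x, cfg = feature_config("WT")) {
  bands <- dwt_decompose(x, cfg$wavelet_levels)
  out <- unlist(lapply(names(bands), function(b) {
    v <- vapply(cfg$wavelet_stats, .band_stat, numeric(1), coefs = bands[[b]])
    names(v) <- paste(b, cfg$wavelet_stats, sep = "_")
    v
  }))
  out
}

.channel_features <- function(x, cfg) {
  if (cfg$method == "WT") {
    wavelet_features(x, cfg)
  } else {
    v <- ar_features(x, cfg$ar_order)
    names(v) <- sprintf("ar%d", seq_along(v))
    v
  }
}

#' Construct a feature table
#'
#' @param X Numeric matrix, samples x features.
#' @param y Subject label per row.
#' @param channel_of_column Integer vector mapping each column to a channel.
#' @param feature_names Column names.
#' @return An object of class `feature_table` with fields `X`, `y`,
#'   `channel_of_column`, `feature_names`, `n_channels`.
#' @export
feature_table <- function(X, y, channel_of_column, feature_names = colnames(X)) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), ncol(X) == length(channel_of_column),
            all(is.finite(X)))
  blocks <- table(channel_of_column)
  if (length(unique(as.integer(blocks))) != 1) {
    stop("per-channel column blocks must be equal-sized")
  }
  colnames(X) <- feature_names
  structure(list(X = X, y = factor(y),
                 channel_of_column = as.integer(channel_of_column),
                 feature_names = feature_names,
                 n_channels = length(blocks)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features (%d channels x %d), %d subjects\n",
              nrow(x$X), ncol(x$X), x$n_channels,
              ncol(x$X) / x$n_channels, nlevels(x$y)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$X)

## Row subset, keeping factor levels (needed for stratified splits).
ft_rows <- function(table, idx) {
  out <- table
  out$X <- table$X[idx, , drop = FALSE]
  out$y <- table$y[idx]
  out
}

#' Build the channel-blocked feature matrix of a segmented cohort
#'
#' Extracts the configured per-channel features from every segment and lays
#' them out with one contiguous column block per channel. With
#' `aggregate_segments = TRUE` each recording's segment feature vectors are
#' averaged element-wise, giving one row per (subject, recording) — the
#' "mean value of each electrode" aggregation that reduces feature
#' dispersion; otherwise one row per segment.
#'
#' @param segments List of [eeg_recording()] segments (all with the same
#'   channel count and sampling rate), e.g. from [preprocess_cohort()].
#' @param cfg A [feature_config()].
#' @return A [feature_table()].
#' @export
build_feature_table <- function(segments, cfg = feature_config("AR5")) {
  stopifnot(length(segments) >= 1)
  n_ch <- vapply(segments, function(s) nrow(s$data), integer(1))
  if (length(unique(n_ch)) != 1) stop("segments have inconsistent channel counts")
  n_ch <- n_ch[1]

  rows <- lapply(segments, function(seg) {
    unlist(lapply(seq_len(n_ch), function(ch) {
      v <- .channel_features(seg$data[ch, ], cfg)
      names(v) <- paste(seg$channel_names[ch], names(v), sep = "_")
      v
    }))
  })
  X <- do.call(rbind, rows)
  key <- vapply(segments, function(s) paste(s$subject_id, s$record_id, sep = "/"),
                character(1))
  subj <- vapply(segments, function(s) s$subject_id, character(1))

  if (cfg$aggregate_segments) {
    uk <- unique(key)
    X <- do.call(rbind, lapply(uk, function(k) {
      colMeans(X[key == k, , drop = FALSE])
    }))
    y <- subj[match(uk, key)]
  } else {
    y <- subj
  }
  block <- ncol(X) / n_ch
  feature_table(X, y, rep(seq_len(n_ch), each = block),
                feature_names = colnames(X))
}

#' Restrict a feature table to the channels selected by a mask
#'
#' @param table A [feature_table()].
#' @param mask 0/1 vector of length `table$n_channels`; 1 keeps the channel's
#'   column block.
#' @return A [feature_table()] over the selected channels only.
#' @export
apply_mask <- function(table, mask) {
  stopifnot(inherits(table, "feature_table"),
            length(mask) == table$n_channels,
            all(mask %in% c(0, 1)))
  if (sum(mask) == 0) stop("all-zero channel mask: no features to select")
  keep <- table$channel_of_column %in% which(mask == 1)
  feature_table(table$X[, keep, drop = FALSE], table$y,
                table$channel_of_column[keep],
                feature_names = table$feature_names[keep])
}

#' Write / read a feature table as delimited text
#'
#' The header carries the channel map as `#channel_of_column:` and the label
#' vector as a final `subject` column.
#'
#' @param table A [feature_table()].
#' @param path Output file.
#' @return `write_feature_table` invisibly returns `path`;
#'   `read_feature_table` returns the [feature_table()].
#' @export
write_feature_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#channel_of_column: %s",
                     paste(table$channel_of_column, collapse = ",")), con)
  df <- data.frame(subject = as.character(table$y), table$X,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  header <- readLines(path, n = 1)
  map <- as.integer(strsplit(sub("^#channel_of_column:\\s*", "", header), ",")[[1]])
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1,
                          check.names = FALSE)
  feature_table(as.matrix(df[, -1, drop = FALSE]), df$subject, map,
                feature_names = colnames(df)[-1])
}
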