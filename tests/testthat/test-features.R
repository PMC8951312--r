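test_that("Yule-Walker estimates recover generating processes", {
  set.seed(101)
  # white noise has all AR coefficients 0
  coefs <- ar_features(rnorm(10000), 5)
  expect_length(coefs, 5)
  expect_true(all(abs(coefs) < 0.05))

  # AR(2) generator recovery
  x <- as.numeric(arima.sim(list(ar = c(0.5, -0.3)), 10000))
  expect_true(all(abs(ar_features(x, 2) - c(0.5, -0.3)) < 0.05))
})

test_that("ar_features validates its input", {
  expect_error(ar_features(rep(1, 1000), 5), "singular")
  expect_error(ar_features(rnorm(40), 5), "too short")
})

test_that("the periodized db4 decomposition matches the PyWavelets oracle", {
  # frozen from pywt.wavedec(x, "db4", mode="periodization", level=2)
  x <- c(1.788628, 0.43651, 0.096497, -1.863493, -0.277388, -0.354759,
         -0.082741, -0.627001, -0.043818, -0.477218, -1.313865, 0.884622,
         0.881318, 1.709573, 0.050034, -0.404677, -0.54536, -1.546477,
         0.982367, -1.101068, -1.185047, -0.20565, 1.486148, 0.236716,
         -1.023785, -0.712993, 0.625245, -0.160513, -0.768836, -0.230031,
         0.745056, 1.976111)
  A2 <- c(-1.233978162720, 2.472658145334, -0.465539017282, -1.192922498884,
          0.652898670569, 0.205763785856, -1.193077176287, 0.241248753414)
  D2 <- c(0.376351144969, -0.010723801870, 1.694642299964, -1.418489087369,
          -0.941284097304, -1.826763708126, -1.043337124386, 0.941622008752)
  D1 <- c(-0.967881095167, -0.055636498814, -0.493140515230, 0.009190311624,
          1.250526636192, 0.377422931815, -0.002667686256, -0.952699209161,
          -1.224810742154, 0.447314613922, -0.798272407463, 0.307794139781,
          -0.542994677661, 0.279563812362, 0.375197992387, -0.734663533400)
  bands <- dwt_decompose(x, 2)
  expect_equal(bands$A2, A2, tolerance = 1e-9)
  expect_equal(bands$D2, D2, tolerance = 1e-9)
  expect_equal(bands$D1, D1, tolerance = 1e-9)
  # orthonormal periodized transform preserves energy
  expect_equal(sum(unlist(bands)^2), sum(x^2), tolerance = 1e-10)
})

test_that("wavelet features have the documented layout and scaling", {
  cfg <- feature_config("WT")
  zero <- wavelet_features(rep(0, 1600), cfg)
  expect_length(zero, (4 + 1) * 3)
  expect_true(all(zero == 0))

  set.seed(2)
  x <- rnorm(1600)
  f1 <- wavelet_features(x, cfg)
  fc <- wavelet_features(3 * x, cfg)
  energy <- grepl("_energy$", names(f1))
  mean_abs <- grepl("_mean_abs$", names(f1))
  expect_equal(fc[energy], 9 * f1[energy], tolerance = 1e-10)
  expect_equal(fc[mean_abs], 3 * f1[mean_abs], tolerance = 1e-10)

  expect_error(wavelet_features(rnorm(8), cfg), "too short")
})

test_that("AR estimation error decreases with signal length", {
  # consistency on simulated AR(5), 20 seeds
  rmse <- function(n, seed) {
    set.seed(seed)
    a <- c(0.5, -0.3, 0.2, -0.1, 0.05)
    x <- as.numeric(arima.sim(list(ar = a), n))
    sqrt(mean((ar_features(x, 5) - a)^2))
  }
  short <- vapply(1:20, function(s) rmse(1600, s), numeric(1))
  long <- vapply(1:20, function(s) rmse(16000, s), numeric(1))
  expect_lt(mean(long), mean(short))
})

test_that("feature tables have the channel-blocked layout", {
  spec <- cohort_spec(n_subjects = 2, n_channels = 4,
                      informative_channels = 1, records_per_subject = 1,
                      record_duration_s = 60, seed = 9)
  segs <- unlist(lapply(generate_cohort(spec), segment_recording),
                 recursive = FALSE)
  expect_length(segs, 12)  # 2 subjects x 6 segments

  agg <- build_feature_table(segs, feature_config("AR5"))
  expect_equal(dim(agg), c(2, 20))
  expect_equal(agg$n_channels, 4)
  expect_equal(agg$channel_of_column, rep(1:4, each = 5))

  per_seg <- build_feature_table(
    segs, feature_config("AR5", aggregate_segments = FALSE))
  expect_equal(dim(per_seg), c(12, 20))

  # aggregation is the element-wise mean over a record's segments
  rows_s1 <- which(vapply(segs, `[[`, character(1), "subject_id") == "S001")
  manual <- colMeans(per_seg$X[rows_s1, , drop = FALSE])
  expect_equal(unname(agg$X[1, ]), unname(manual), tolerance = 1e-12)
})

test_that("apply_mask restricts to whole channel blocks", {
  tab <- small_feature_table()
  D <- tab$n_channels

  expect_equal(apply_mask(tab, rep(1, D))$X, tab$X)

  one <- apply_mask(tab, make_mask(1, D))
  expect_equal(ncol(one$X), 5)
  expect_true(all(one$channel_of_column == 1))

  three <- apply_mask(tab, make_mask(c(1, 3, 7), D))
  expect_equal(ncol(three$X), 15)
  expect_identical(three$y, tab$y)

  expect_error(apply_mask(tab, rep(0, D)), "all-zero")

  # nested masks compose
  m1 <- make_mask(c(1, 3, 7), D)
  m2 <- make_mask(c(1, 7), D)
  t1 <- apply_mask(tab, m1)
  direct <- apply_mask(tab, m2)
  expect_equal(apply_mask(tab, m2)$X, direct$X)
  expect_true(all(direct$feature_names %in% t1$feature_names))
})

test_that("column blocks partition the feature columns", {
  tab <- small_feature_table()
  blocks <- split(seq_len(ncol(tab$X)), tab$channel_of_column)
  expect_equal(sort(unname(unlist(blocks))), seq_len(ncol(tab$X)))
  expect_equal(length(unique(lengths(blocks))), 1L)
})

test_that("feature tables round-trip through delimited text", {
  tab <- small_feature_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_equal(back$X, tab$X, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(as.character(back$y), as.character(tab$y))
  expect_equal(back$channel_of_column, tab$channel_of_column)
})
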