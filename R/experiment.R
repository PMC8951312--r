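#' Experiment configuration
#'
#' Bundles everything needed to run the full protocol: generate (or load) a
#' cohort, preprocess, extract features, and repeat the
#' split / optimize / retrain / test cycle `n_runs` times with seeds
#' `base_seed + r`. By default each run reshuffles the split; set
#' `fixed_split = TRUE` to reuse the `base_seed` split in every run.
#'
#' @param feature_method `"AR5"`, `"AR10"`, `"AR20"` or `"WT"`.
#' @param optimizer `"fpa"`, `"bhc"` or `"fpa_bhc"`.
#' @param classifier A [classifier_config()].
#' @param n_runs Number of independent runs (25 in the full protocol).
#' @param base_seed Integer; run `r` uses seed `base_seed + r - 1`.
#' @param cohort A [cohort_spec()], or a directory path readable by
#'   [read_cohort()].
#' @param optimizer_control Named list overriding [optimizer_config()]
#'   fields (e.g. `N`, `T`, `bhc_inner_iters`, `max_evals`).
#' @param preprocess A [preprocess_config()].
#' @param split A [split_config()] (its seed is replaced per run).
#' @param fixed_split Reuse one split across runs.
#' @param output_dir Optional directory for per-run and summary artifacts
#'   (delimited text).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(feature_method = "AR5",
                              optimizer = c("fpa_bhc", "fpa", "bhc"),
                              classifier = classifier_config("svm_rbf"),
                              n_runs = 25,
                              base_seed = 1,
                              cohort = cohort_spec(),
                              optimizer_control = list(),
                              preprocess = preprocess_config(),
                              split = split_config(),
                              fixed_split = FALSE,
                              output_dir = NULL) {
  optimizer <- match.arg(optimizer)
  stopifnot(n_runs >= 1)
  structure(list(feature_method = feature_method, optimizer = optimizer,
                 classifier = classifier, n_runs = as.integer(n_runs),
                 base_seed = as.integer(base_seed), cohort = cohort,
                 optimizer_control = optimizer_control,
                 preprocess = preprocess, split = split,
                 fixed_split = isTRUE(fixed_split), output_dir = output_dir),
            class = "experiment_config")
}

.prepare_table <- function(cfg) {
  cohort <- if (inherits(cfg$cohort, "cohort_spec")) {
    generate_cohort(cfg$cohort)
  } else {
    read_cohort(cfg$cohort)
  }
  segs <- preprocess_cohort(cohort, cfg$preprocess)
  build_feature_table(segs, feature_config(cfg$feature_method))
}

.opt_config_for <- function(cfg, D, seed) {
  args <- utils::modifyList(list(D = D, seed = seed), cfg$optimizer_control)
  do.call(optimizer_config, args)
}

.run_optimizer <- function(optimizer, fitness_fn, ocfg) {
  switch(optimizer,
         fpa_bhc = fpa_bhc_optimize(fitness_fn, ocfg),
         fpa = fpa_optimize(fitness_fn, ocfg),
         bhc = bhc_optimize(fitness_fn, ocfg))
}

#' Run the full channel-selection experiment
#'
#' For each run `r`: split the feature table (stratified by subject),
#' build the wrapper objective on (train, validation), search for the best
#' channel mask with the configured optimizer, retrain the classifier on
#' the training set with that mask, and score it once on the held-out test
#' set. Aggregates accuracy, sensitivity, specificity, F-score and the
#' number of selected channels over runs, plus per-channel selection
#' frequencies and convergence curves.
#'
#' @param cfg An [experiment_config()].
#' @return An object of class `experiment_summary`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  table <- .prepare_table(cfg)
  D <- table$n_channels

  runs <- vector("list", cfg$n_runs)
  for (r in seq_len(cfg$n_runs)) {
    seed_r <- cfg$base_seed + r - 1L
    scfg <- cfg$split
    scfg$seed <- if (cfg$fixed_split) cfg$base_seed else seed_r
    parts <- split_table(table, scfg)
    # the optimizer must never see test rows
    stopifnot(sum(parts$index == "test") + sum(parts$index == "train") +
                sum(parts$index == "validation") == nrow(table$X))

    fit_fn <- make_fitness_fn(parts$train, parts$validation, cfg$classifier)
    ocfg <- .opt_config_for(cfg, D, seed_r)
    hist <- tryCatch(.run_optimizer(cfg$optimizer, fit_fn, ocfg),
                     error = function(e) {
                       stop(sprintf("run %d (seed %d) failed: %s", r, seed_r,
                                    conditionMessage(e)))
                     })
    report <- evaluate_mask(hist$best_mask, parts$train, parts$test,
                            cfg$classifier)
    runs[[r]] <- list(seed = seed_r, history = hist, test_report = report,
                      val_fitness = hist$best_fitness)
  }

  metrics <- data.frame(
    run = seq_len(cfg$n_runs),
    seed = vapply(runs, `[[`, numeric(1), "seed"),
    val_acc = vapply(runs, `[[`, numeric(1), "val_fitness"),
    acc = vapply(runs, function(r) r$test_report$acc, numeric(1)),
    sen = vapply(runs, function(r) r$test_report$sen, numeric(1)),
    spe = vapply(runs, function(r) r$test_report$spe, numeric(1)),
    f_score = vapply(runs, function(r) r$test_report$f_score, numeric(1)),
    n_selected = vapply(runs, function(r) r$test_report$n_selected, numeric(1)),
    evaluations = vapply(runs, function(r) r$history$evaluations, numeric(1))
  )
  masks <- do.call(rbind, lapply(runs, function(r) r$history$best_mask))
  curves <- do.call(rbind, lapply(runs, function(r) r$history$best_fitness_per_iter))

  summary <- structure(list(
    config = cfg,
    metrics = metrics,
    mean = colMeans(metrics[c("acc", "sen", "spe", "f_score", "n_selected")]),
    sd = apply(metrics[c("acc", "sen", "spe", "f_score", "n_selected")], 2,
               stats::sd),
    best_masks = masks,
    channel_frequency = colSums(masks),
    convergence = curves
  ), class = "experiment_summary")

  if (!is.null(cfg$output_dir)) write_summary(summary, cfg$output_dir)
  summary
}

#' @export
print.experiment_summary <- function(x, ...) {
  cat(sprintf("experiment_summary: %s features, %s optimizer, %d runs\n",
              x$config$feature_method, x$config$optimizer, x$config$n_runs))
  m <- x$mean; s <- x$sd
  cat(sprintf("  test acc  %.2f%% (sd %.2f)\n", m["acc"], s["acc"]))
  cat(sprintf("  sen %.4f  spe %.4f  F %.4f\n", m["sen"], m["spe"], m["f_score"]))
  cat(sprintf("  channels  %.1f (sd %.1f) of %d\n", m["n_selected"],
              s["n_selected"], ncol(x$best_masks)))
  invisible(x)
}

#' Write experiment artifacts as delimited text
#'
#' Per-run metrics, mask bit-strings, the channel-frequency table and the
#' convergence curves, all reproducible from the config and seed.
#'
#' @param summary An `experiment_summary`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_summary <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(summary$metrics, file.path(dir, "runs.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  writeLines(apply(summary$best_masks, 1, paste, collapse = ""),
             file.path(dir, "best_masks.txt"))
  utils::write.table(
    data.frame(channel = seq_along(summary$channel_frequency),
               count = summary$channel_frequency),
    file.path(dir, "channel_frequency.tsv"), sep = "\t",
    row.names = FALSE, quote = FALSE)
  utils::write.table(summary$convergence, file.path(dir, "convergence.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Per-channel selection frequency across runs
#'
#' Counts, for each channel, the runs whose best mask selects it. The counts
#' sum to the total number of selected channels over runs.
#'
#' @param x An `experiment_summary`, or a list of them (counts are summed).
#' @return Integer vector of per-channel counts.
#' @export
channel_frequency <- function(x) {
  if (inherits(x, "experiment_summary")) return(as.integer(x$channel_frequency))
  stopifnot(length(x) >= 1)
  as.integer(Reduce(`+`, lapply(x, channel_frequency)))
}

#' Compare optimizer arms with paired significance tests
#'
#' Runs (or accepts pre-run) experiment summaries sharing the same data and
#' per-run seeds, then for every pair of arms reports a paired t-test and a
#' Wilcoxon signed-rank test on the per-run test accuracies, with a
#' significance flag at `alpha`. All-zero difference vectors are reported as
#' no significant difference (p = 1).
#'
#' @param arms Named list of [experiment_config()] objects or
#'   `experiment_summary` objects.
#' @param alpha Significance level (default 0.05).
#' @param metric Metrics column compared (default `"acc"`).
#' @return A data frame with one row per pair: means, t and Wilcoxon
#'   statistics, p-values, significance flag and favoured arm.
#' @export
compare_optimizers <- function(arms, alpha = 0.05, metric = "acc") {
  summaries <- lapply(arms, function(a) {
    if (inherits(a, "experiment_summary")) a else run_experiment(a)
  })
  if (is.null(names(summaries)) || any(names(summaries) == "")) {
    names(summaries) <- vapply(summaries, function(s) s$config$optimizer,
                               character(1))
  }
  ns <- vapply(summaries, function(s) nrow(s$metrics), integer(1))
  if (length(unique(ns)) != 1) stop("arms have mismatched n_runs")

  pairs <- utils::combn(names(summaries), 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- summaries[[pr[1]]]$metrics[[metric]]
    b <- summaries[[pr[2]]]$metrics[[metric]]
    d <- a - b
    if (all(d == 0)) {
      tt <- list(statistic = c(t = 0), p.value = 1)
      wt <- list(statistic = c(V = 0), p.value = 1)
    } else if (stats::sd(d) == 0) {
      # perfectly consistent shift: zero-variance differences
      tt <- list(statistic = c(t = sign(mean(d)) * Inf), p.value = 0)
      wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
    } else {
      tt <- stats::t.test(a, b, paired = TRUE)
      wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
    }
    data.frame(arm_a = pr[1], arm_b = pr[2],
               mean_a = mean(a), mean_b = mean(b),
               t_stat = unname(tt$statistic), t_p = tt$p.value,
               w_stat = unname(wt$statistic), wilcox_p = wt$p.value,
               significant = !is.na(wt$p.value) && wt$p.value < alpha,
               favours = if (mean(a) == mean(b)) "tie" else
                 pr[which.max(c(mean(a), mean(b)))],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "summaries") <- summaries
  out
}
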