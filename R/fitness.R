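#' Train/validation/test split configuration
#'
#' The identification protocol partitions the feature-table rows into a
#' training set (fit the classifier), a validation set (the wrapper
#' objective scores candidate channel subsets on it) and a held-out test set
#' (scored once, with the final mask). Default fractions are 50/20/30
#' train/test/validation.
#'
#' @param train_frac,test_frac,val_frac Positive fractions summing to 1.
#' @param seed Integer seed for the (stratified) shuffle.
#' @param stratified Stratify by subject label (default) so every subject is
#'   represented in the training set.
#' @return An object of class `split_config`.
#' @export
split_config <- function(train_frac = 0.5, test_frac = 0.2, val_frac = 0.3,
                         seed = 1, stratified = TRUE) {
  stopifnot(train_frac > 0, test_frac > 0, val_frac > 0)
  if (abs(train_frac + test_frac + val_frac - 1) > 1e-8) {
    stop("split fractions must sum to 1")
  }
  structure(list(train_frac = train_frac, test_frac = test_frac,
                 val_frac = val_frac, seed = as.integer(seed),
                 stratified = isTRUE(stratified)),
            class = "split_config")
}

## Largest-remainder allocation of n items to the three fractions,
## guaranteeing the counts sum to n and train gets at least one item.
.allocate <- function(n, fracs) {
  exact <- n * fracs
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    order_idx <- order(exact - base, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  if (base[1] == 0) {  # train must be non-empty per subject
    donor <- which.max(base[-1]) + 1L
    base[donor] <- base[donor] - 1
    base[1] <- 1
  }
  base
}

#' Split a feature table into train / validation / test sets
#'
#' Disjoint row partitions covering the table, stratified by subject label,
#' deterministic given the seed. Within each subject the counts follow the
#' configured fractions by largest remainder.
#'
#' @param table A [feature_table()].
#' @param cfg A [split_config()].
#' @return A list with elements `train`, `validation`, `test`
#'   ([feature_table()] objects) and `index` (the per-row assignment).
#' @export
split_table <- function(table, cfg = split_config()) {
  stopifnot(inherits(table, "feature_table"))
  n <- nrow(table$X)
  assign <- character(n)
  fracs <- c(cfg$train_frac, cfg$val_frac, cfg$test_frac)
  set.seed(cfg$seed)
  groups <- if (cfg$stratified) split(seq_len(n), table$y) else list(seq_len(n))
  for (idx in groups) {
    if (cfg$stratified && length(idx) < 2) {
      stop("stratified split needs >= 2 samples per subject")
    }
    idx <- idx[sample.int(length(idx))]
    counts <- .allocate(length(idx), fracs)
    assign[idx] <- rep(c("train", "validation", "test"), counts)
  }
  list(train = ft_rows(table, which(assign == "train")),
       validation = ft_rows(table, which(assign == "validation")),
       test = ft_rows(table, which(assign == "test")),
       index = assign)
}

## Column standardization with training statistics only (constant columns
## are left centred with unit divisor).
.standardize <- function(train_X, eval_X) {
  mu <- colMeans(train_X)
  sdv <- apply(train_X, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(train = scale(train_X, center = mu, scale = sdv),
       eval = scale(eval_X, center = mu, scale = sdv))
}

#' Score a channel mask with a trained classifier
#'
#' Restricts the training and evaluation tables to the masked channels,
#' standardizes features with training-set statistics, trains the
#' classifier, predicts the evaluation set, and aggregates one-vs-rest
#' confusion counts over the subject classes: `TA` (true acceptances, the
#' correctly identified samples), `TR` (true rejections), `FA` (false
#' acceptances) and `FR` (false rejections) are the sums of per-class TP,
#' TN, FP and FN. The reported `acc` is the identification rate
#' `100 * TA / n` — the accept/reject accuracy of the per-sample
#' identification decisions — while `sen = TA/(TA+FR)`,
#' `spe = TR/(TR+FA)` and `f_score = 2TA/(2TA+FA+FR)` come from the summed
#' one-vs-rest counts.
#'
#' @param mask 0/1 channel vector with at least one 1.
#' @param train,eval_set [feature_table()] objects sharing the label set.
#' @param clf A [classifier_config()].
#' @return An object of class `fitness_report`.
#' @export
evaluate_mask <- function(mask, train, eval_set, clf = classifier_config()) {
  if (sum(mask) == 0) stop("all-zero channel mask")
  tr <- apply_mask(train, mask)
  ev <- apply_mask(eval_set, mask)
  std <- .standardize(tr$X, ev$X)
  fit <- tryCatch(train_classifier(clf, std$train, tr$y),
                  error = function(e) {
                    stop(sprintf("classifier '%s' failed: %s", clf$kind,
                                 conditionMessage(e)))
                  })
  pred <- predict_classifier(fit, std$eval)
  truth <- factor(ev$y, levels = fit$levels)
  rep <- identification_report(truth, pred)
  rep$n_selected <- sum(mask)
  rep$mask <- as.integer(mask)
  rep
}

#' Identification metrics from truth and predicted labels
#'
#' Sums one-vs-rest confusion counts over the classes: `TA` (sum of
#' per-class true positives, i.e. the correctly identified samples), `TR`
#' (true negatives), `FA` (false positives), `FR` (false negatives). The
#' closed forms are `TA = tp`, `FA = FR = n - tp`,
#' `TR = (C - 2) n + tp` for `C` classes and `tp` correct predictions.
#' `acc` is the identification rate `100 * tp / n`; `sen`, `spe` and
#' `f_score` derive from the summed counts.
#'
#' @param truth,pred Factors on the same level set.
#' @return An object of class `fitness_report` (without mask fields).
#' @export
identification_report <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  if (!is.factor(truth)) truth <- factor(truth)  # keep supplied level sets
  pred <- factor(pred, levels = levels(truth))
  n <- length(truth)
  C <- nlevels(truth)
  tp <- sum(pred == truth, na.rm = TRUE)
  TA <- tp
  FA <- n - tp
  FR <- n - tp
  TR <- (C - 2L) * n + tp
  structure(list(TA = TA, TR = TR, FA = FA, FR = FR,
                 acc = 100 * tp / n,
                 sen = TA / (TA + FR),
                 spe = if (TR + FA > 0) TR / (TR + FA) else NA_real_,
                 f_score = 2 * TA / (2 * TA + FA + FR),
                 n_selected = NA_integer_, mask = NULL),
            class = "fitness_report")
}

#' @export
print.fitness_report <- function(x, ...) {
  cat(sprintf("fitness_report: acc %.2f%% | sen %.4f spe %.4f F %.4f | %d channels\n",
              x$acc, x$sen, x$spe, x$f_score, x$n_selected))
  cat(sprintf("  counts TA=%d TR=%d FA=%d FR=%d | mask %s\n",
              x$TA, x$TR, x$FA, x$FR, paste(x$mask, collapse = "")))
  invisible(x)
}

#' Build the wrapper objective over channel masks
#'
#' Returns a memoized function `f(mask) -> validation accuracy (percent)`
#' closing over a fixed (train, validation, classifier) context — the
#' objective the optimizers maximize. Identical masks hit the cache and do
#' not retrain.
#'
#' @param train,validation [feature_table()] objects.
#' @param clf A [classifier_config()].
#' @return A function of a 0/1 mask returning percent accuracy, with
#'   attribute access via [fitness_evals()].
#' @export
make_fitness_fn <- function(train, validation, clf = classifier_config()) {
  cache <- new.env(parent = emptyenv())
  evals <- 0L
  fn <- function(mask) {
    key <- paste(as.integer(mask), collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    evals <<- evals + 1L
    val <- evaluate_mask(mask, train, validation, clf)$acc
    cache[[key]] <- val
    val
  }
  class(fn) <- c("fitness_fn", "function")
  fn
}

#' Number of distinct (non-cached) objective evaluations performed
#'
#' @param fn A function returned by [make_fitness_fn()].
#' @return Integer count of cache misses.
#' @export
fitness_evals <- function(fn) environment(fn)$evals
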