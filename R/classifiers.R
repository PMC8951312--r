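#' Classifier configuration for the wrapper fitness
#'
#' Seven classifier families are available to guide (or score) the channel
#' search. Defaults mirror common identification-pipeline settings: RBF-SVM
#' with `C = 1e11`, `gamma = 0.01`; fine kNN (`k = 1`, Euclidean); a
#' single-hidden-layer neural network of width 32; a CART tree. Features are
#' always standardized with training-set statistics before fitting (see
#' [evaluate_mask()]), so the SVM is run unscaled internally.
#'
#' @param kind One of `"svm_rbf"`, `"svm_linear"`, `"lda"`, `"knn"`, `"ann"`,
#'   `"naive_bayes"`, `"tree"`.
#' @param C SVM regularization weight.
#' @param gamma RBF kernel width.
#' @param k Neighbour count for kNN.
#' @param hidden Hidden-layer width for the neural network.
#' @param learning_rate Weight-decay surrogate for the neural network fit.
#' @param confidence_factor Complexity parameter for tree pruning.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(kind = c("svm_rbf", "svm_linear", "lda", "knn",
                                       "ann", "naive_bayes", "tree"),
                              C = 1e11, gamma = 0.01, k = 1L,
                              hidden = 32L, learning_rate = 0.3,
                              confidence_factor = 0.25) {
  kind <- match.arg(kind)
  structure(list(kind = kind, C = C, gamma = gamma, k = as.integer(k),
                 hidden = as.integer(hidden), learning_rate = learning_rate,
                 confidence_factor = confidence_factor),
            class = "classifier_config")
}

## Train on standardized features; returns an object predict_classifier()
## understands. kNN is lazy and just stores its training set.
train_classifier <- function(cfg, X, y) {
  y <- factor(y)
  model <- switch(cfg$kind,
    svm_rbf = e1071::svm(X, y, kernel = "radial", cost = cfg$C,
                         gamma = cfg$gamma, scale = FALSE),
    svm_linear = e1071::svm(X, y, kernel = "linear", cost = cfg$C,
                            scale = FALSE),
    lda = suppressWarnings(MASS::lda(X, grouping = y, tol = 1e-10)),
    knn = list(X = X, y = y, k = cfg$k),
    ann = {
      nnet::nnet(X, stats::model.matrix(~ y - 1), size = cfg$hidden,
                 maxit = 200, decay = 1e-4, trace = FALSE,
                 MaxNWts = 1e5, softmax = TRUE)
    },
    naive_bayes = e1071::naiveBayes(X, y),
    tree = rpart::rpart(y ~ ., data = data.frame(y = y, X, check.names = FALSE),
                        method = "class",
                        control = rpart::rpart.control(cp = cfg$confidence_factor / 25,
                                                       minsplit = 4))
  )
  structure(list(kind = cfg$kind, model = model, levels = levels(y)),
            class = "eeg_classifier")
}

predict_classifier <- function(fit, X) {
  pred <- switch(fit$kind,
    svm_rbf = ,
    svm_linear = as.character(predict(fit$model, X)),
    lda = as.character(predict(fit$model, X)$class),
    knn = as.character(class::knn(fit$model$X, X, fit$model$y, k = fit$model$k)),
    ann = {
      p <- predict(fit$model, X)
      sub("^y", "", colnames(p)[max.col(p, ties.method = "first")])
    },
    naive_bayes = as.character(predict(fit$model, X)),
    tree = as.character(predict(fit$model,
                                data.frame(X, check.names = FALSE),
                                type = "class"))
  )
  factor(pred, levels = fit$levels)
}
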