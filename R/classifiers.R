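#' Classifier specification
#'
#' Names one of the five supported classifier families and its
#' hyperparameters. The reference classifier is the multilayer perceptron
#' with six hidden layers of 100 units and L2 penalty 0.01; the other
#' families run through their established implementations with those
#' packages' defaults, which are echoed into every cross-validation report:
#' \describe{
#'   \item{`mlp`}{the package's own [mlp_fit()].}
#'   \item{`svm`}{[e1071::svm()] (radial kernel).}
#'   \item{`rf`}{[randomForest::randomForest()].}
#'   \item{`dt`}{[rpart::rpart()] classification tree.}
#'   \item{`extratrees`}{[ranger::ranger()] with
#'     `splitrule = "extratrees"`.}
#' }
#'
#' @param kind One of `"mlp"`, `"svm"`, `"rf"`, `"dt"`, `"extratrees"`.
#' @param ... Hyperparameter overrides passed to the underlying fit
#'   function (for `"mlp"`, arguments of [mlp_fit()]).
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(kind = c("mlp", "svm", "rf", "dt", "extratrees"),
                            ...) {
  kind <- match.arg(kind)
  structure(list(kind = kind, hyperparams = list(...)),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  hp <- if (length(x$hyperparams) == 0L) "defaults" else
    paste(names(x$hyperparams), vapply(x$hyperparams, format, character(1)),
          sep = "=", collapse = ", ")
  cat(sprintf("classifier_spec: %s (%s)\n", x$kind, hp))
  invisible(x)
}

#' Fit / predict a specified classifier
#'
#' Thin dispatch layer so cross-validation treats all families uniformly.
#' Class predictions threshold the positive-class score at 0.5 where the
#' family exposes scores.
#'
#' @param spec A [classifier_spec()].
#' @param x Numeric training matrix.
#' @param y Integer 0/1 labels.
#' @param seed Integer seed set before fitting (stochastic families).
#' @return A `fitted_classifier` wrapper.
#' @export
fit_classifier <- function(spec, x, y, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  yf <- factor(y, levels = c(0L, 1L))
  hp <- spec$hyperparams
  fit <- switch(spec$kind,
    mlp = do.call(mlp_fit, c(list(x = x, y = y), hp)),
    svm = do.call(e1071::svm, c(list(x = x, y = yf), hp)),
    rf = do.call(randomForest::randomForest, c(list(x = x, y = yf), hp)),
    dt = {
      df <- data.frame(x, check.names = FALSE)
      df$.label <- yf
      do.call(rpart::rpart,
              c(list(formula = .label ~ ., data = df, method = "class"), hp))
    },
    extratrees = {
      df <- data.frame(x, check.names = FALSE)
      df$.label <- yf
      do.call(ranger::ranger,
              c(list(formula = .label ~ ., data = df,
                     splitrule = "extratrees",
                     seed = if (is.null(seed)) 1L else seed), hp))
    })
  structure(list(kind = spec$kind, fit = fit,
                 feature_names = colnames(x)),
            class = "fitted_classifier")
}

#' @rdname fit_classifier
#' @param model A `fitted_classifier`.
#' @param newdata Numeric matrix to score.
#' @return Integer 0/1 predictions.
#' @export
predict_classifier <- function(model, newdata) {
  switch(model$kind,
    mlp = predict(model$fit, newdata, type = "class"),
    svm = as.integer(as.character(predict(model$fit, newdata))),
    rf = as.integer(as.character(predict(model$fit, newdata))),
    dt = {
      df <- data.frame(newdata, check.names = FALSE)
      prob <- predict(model$fit, df)[, "1"]
      as.integer(prob >= 0.5)
    },
    extratrees = {
      df <- data.frame(newdata, check.names = FALSE)
      as.integer(as.character(predict(model$fit, df)$predictions))
    })
}
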