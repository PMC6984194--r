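# Pairwise probabilistic classifiers, cross-validated training accuracies,
# and chance-level tests.

#' Train a regularized logistic classifier on a class pair
#'
#' L2-penalized binomial log-likelihood, maximized by Newton iterations to a
#' gradient max-norm below `tol`. Features are standardized internally
#' (mean/SD stored with the model); the intercept is not penalized. With the
#' default `l2_lambda = 1` the fit is defined even under perfect separation.
#'
#' @param features Numeric trial x feature matrix (finite values).
#' @param labels Per-trial labels; exactly two classes, >= 2 trials each.
#' @param positive Label treated as the positive class (probability
#'   reported); defaults to the first label level encountered.
#' @param l2_lambda Regularization strength on standardized coefficients.
#' @param tol Gradient max-norm convergence tolerance.
#' @return An object of class `pairwise_classifier` with `weights` (on the
#'   standardized scale), `bias`, `center`, `scale`, `class_pair`,
#'   `l2_lambda`.
#' @export
train_pairwise <- function(features, labels, positive = NULL, l2_lambda = 1,
                           tol = 1e-8) {
  features <- as.matrix(features)
  if (!all(is.finite(features))) {
    abort_validation("`features` must be finite")
  }
  classes <- unique(labels)
  if (length(classes) != 2L) {
    abort_validation("`labels` must contain exactly two classes")
  }
  if (is.null(positive)) positive <- classes[1]
  if (!positive %in% classes) {
    abort_validation("`positive` must be one of the two class labels")
  }
  if (min(table(labels)) < 2) {
    abort_validation("each class needs at least 2 samples")
  }
  check_scalar(l2_lambda, "l2_lambda", lower = 0)
  y <- as.numeric(labels == positive)
  center <- colMeans(features)
  scl <- apply(features, 2, sd)
  scl[scl < 1e-12] <- 1
  x <- sweep(sweep(features, 2, center), 2, scl, "/")
  p <- ncol(x)
  beta <- rep(0, p + 1)                  # bias first
  xb <- cbind(1, x)
  pen <- c(0, rep(l2_lambda, p))
  for (iter in seq_len(100)) {
    eta <- drop(xb %*% beta)
    mu <- 1 / (1 + exp(-eta))
    grad <- drop(crossprod(xb, y - mu)) - pen * beta
    if (max(abs(grad)) < tol) break
    wgt <- pmax(mu * (1 - mu), 1e-10)
    hess <- crossprod(xb * wgt, xb) + diag(pen + 1e-12, p + 1)
    step <- solve(hess, grad)
    # damped Newton: halve until the penalized log-likelihood improves
    obj <- function(b) {
      e <- drop(xb %*% b)
      sum(y * e - log1p(exp(e))) - sum(pen * b^2) / 2
    }
    f0 <- obj(beta)
    alpha <- 1
    while (obj(beta + alpha * step) < f0 && alpha > 1e-6) alpha <- alpha / 2
    beta <- beta + alpha * step
  }
  structure(list(weights = beta[-1], bias = beta[1], center = center,
                 scale = scl, l2_lambda = l2_lambda,
                 class_pair = c(positive, setdiff(classes, positive))),
            class = "pairwise_classifier")
}

#' @export
print.pairwise_classifier <- function(x, ...) {
  cat(sprintf("<pairwise_classifier> p(%s) vs %s, %d features, lambda = %g\n",
              x$class_pair[1], x$class_pair[2], length(x$weights),
              x$l2_lambda))
  invisible(x)
}

#' Predict positive-class probabilities
#'
#' @param object A [train_pairwise()] classifier.
#' @param newdata Feature matrix on the original (unstandardized) scale.
#' @param ... Unused.
#' @return Numeric vector of `p(positive class)` in `[0, 1]`.
#' @export
predict.pairwise_classifier <- function(object, newdata, ...) {
  x <- sweep(sweep(as.matrix(newdata), 2, object$center), 2, object$scale, "/")
  drop(1 / (1 + exp(-(object$bias + x %*% object$weights))))
}

#' Hard class decision
#'
#' Ties at p = 0.5 classify as the negative class (deterministic,
#' conservative).
#' @param clf A [train_pairwise()] classifier.
#' @param newdata Feature matrix.
#' @return Character vector of predicted labels.
#' @export
classify_pairwise <- function(clf, newdata) {
  p <- predict(clf, newdata)
  ifelse(p > 0.5, clf$class_pair[1], clf$class_pair[2])
}

# Fit CSP + component selection + classifier for one class pair.
fit_pair_pipeline <- function(epochs, pair, l2_lambda = 1, shrinkage = 0,
                              plausibility = TRUE) {
  ep_a <- subset_epochs(epochs, which(epochs$labels == pair[1]))
  ep_b <- subset_epochs(epochs, which(epochs$labels == pair[2]))
  csp <- fit_csp(ep_a, ep_b, shrinkage = shrinkage)
  if (plausibility) csp <- select_plausible_components(csp)
  both <- subset_epochs(epochs, which(epochs$labels %in% pair))
  feats <- logvar_features(both, csp)
  clf <- train_pairwise(feats, both$labels, positive = pair[1],
                        l2_lambda = l2_lambda)
  list(csp = csp, clf = clf)
}

#' Train the three-classifier bank
#'
#' Trains the flexion-vs-extension (`ef`), flexion-vs-rest-open (`of`) and
#' extension-vs-rest-closed (`ce`) classifiers on a labelled training epoch
#' set, each with its own CSP model and plausibility-selected components.
#' The positive class of `ef` and `of` is flexion; of `ce`, extension.
#'
#' @param epochs A training [epoch_set()] with the four class labels.
#' @param l2_lambda Regularization strength.
#' @param thresholds Per-classifier decision thresholds in (0, 1); scalar
#'   or named vector `c(ef=, of=, ce=)` (default 0.7 each).
#' @param shrinkage Covariance shrinkage passed to [fit_csp()].
#' @param plausibility Apply [select_plausible_components()]?
#' @return An object of class `classifier_bank`.
#' @export
train_classifier_bank <- function(epochs, l2_lambda = 1, thresholds = 0.7,
                                  shrinkage = 0, plausibility = TRUE) {
  if (length(thresholds) == 1L) {
    thresholds <- c(ef = thresholds, of = thresholds, ce = thresholds)
  }
  check_probability(thresholds, "thresholds")
  if (any(thresholds <= 0 | thresholds >= 1)) {
    abort_validation("`thresholds` must lie strictly inside (0, 1)")
  }
  pairs <- list(ef = c("flexion", "extension"),
                of = c("flexion", "rest_open"),
                ce = c("extension", "rest_closed"))
  fits <- lapply(pairs, function(p) {
    fit_pair_pipeline(epochs, p, l2_lambda = l2_lambda,
                      shrinkage = shrinkage, plausibility = plausibility)
  })
  structure(list(ef = fits$ef, of = fits$of, ce = fits$ce,
                 thresholds = thresholds[c("ef", "of", "ce")]),
            class = "classifier_bank")
}

#' @export
print.classifier_bank <- function(x, ...) {
  cat("<classifier_bank>\n")
  cat(sprintf("  Y_EF: flexion vs extension    (theta = %.2f)\n", x$thresholds["ef"]))
  cat(sprintf("  Y_OF: flexion vs rest_open    (theta = %.2f)\n", x$thresholds["of"]))
  cat(sprintf("  Y_CE: extension vs rest_closed (theta = %.2f)\n", x$thresholds["ce"]))
  invisible(x)
}

#' Five-fold block-wise cross-validated accuracy
#'
#' Trials of the class pair are split into `k` contiguous temporal blocks by
#' run, so paired trials from one run never straddle folds. Per fold, the
#' CSP model, component selection and classifier are fit on the training
#' blocks only and evaluated on the held-out block; the mean of the per-fold
#' accuracies is returned — no information leaks from test to train.
#'
#' @param epochs A labelled [epoch_set()] with per-trial `run` metadata.
#' @param class_pair Character pair, e.g. `c("flexion", "rest_open")`; the
#'   first element is the positive class.
#' @param k Number of folds (>= 2, <= number of runs).
#' @param l2_lambda,shrinkage,plausibility Passed to the per-fold pipeline.
#' @return Mean held-out accuracy in `[0, 1]`, with per-fold accuracies and
#'   the held-out trial count as attributes `folds` and `n_trials`.
#' @export
blockwise_cv_accuracy <- function(epochs, class_pair, k = 5, l2_lambda = 1,
                                  shrinkage = 0, plausibility = TRUE) {
  check_scalar(k, "k", lower = 2, integerish = TRUE)
  idx <- which(epochs$labels %in% class_pair)
  if (length(idx) == 0) abort_validation("no trials of the requested classes")
  sub <- subset_epochs(epochs, idx)
  if (is.null(sub$meta) || !"run" %in% names(sub$meta)) {
    abort_validation("`epochs` must carry per-trial `run` metadata")
  }
  runs <- sort(unique(sub$meta$run))
  if (k > length(runs)) {
    abort_validation("k exceeds the number of available blocks (runs)")
  }
  fold_of_run <- setNames(ceiling(seq_along(runs) / (length(runs) / k)), runs)
  fold <- fold_of_run[as.character(sub$meta$run)]
  accs <- numeric(k)
  n_test <- 0L
  for (f in seq_len(k)) {
    train <- subset_epochs(sub, which(fold != f))
    test <- subset_epochs(sub, which(fold == f))
    if (any(table(factor(train$labels, levels = class_pair)) < 2) ||
        n_trials(test) == 0) {
      abort_validation("fold without enough trials per class; reduce k")
    }
    fit <- fit_pair_pipeline(train, class_pair, l2_lambda = l2_lambda,
                             shrinkage = shrinkage,
                             plausibility = plausibility)
    feats <- logvar_features(test, fit$csp)
    pred <- classify_pairwise(fit$clf, feats)
    accs[f] <- mean(pred == test$labels)
    n_test <- n_test + n_trials(test)
  }
  out <- mean(accs)
  attr(out, "folds") <- accs
  attr(out, "n_trials") <- n_test
  out
}

#' Binomial chance level for classification accuracy
#'
#' Smallest accuracy whose correct-trial count has an upper-tail probability
#' below `alpha` under Binomial(n, 1/n_classes): the minimum accuracy that
#' counts as above chance.
#'
#' @param n_trials Number of classified trials (>= 1).
#' @param n_classes Number of classes (default 2).
#' @param alpha Significance level in (0, 1).
#' @return Threshold accuracy `k*/n` in `(0, 1]`.
#' @export
binomial_chance_level <- function(n_trials, n_classes = 2, alpha = 0.05) {
  check_scalar(n_trials, "n_trials", lower = 1, integerish = TRUE)
  check_scalar(n_classes, "n_classes", lower = 2, integerish = TRUE)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort_validation("`alpha` must lie in (0, 1)")
  }
  # smallest k with P(X >= k) < alpha <=> P(X > k - 1) < alpha; capped at
  # a perfect score when even that is not nominally significant (very
  # small n), so the threshold is always an attainable accuracy
  k_star <- qbinom(alpha, n_trials, 1 / n_classes, lower.tail = FALSE) + 1
  min(k_star, n_trials) / n_trials
}

#' Wilson confidence interval and above-chance test for an accuracy
#'
#' Wilson score interval at level `1 - alpha`; the accuracy is judged above
#' chance when the interval's lower bound exceeds `1/n_classes`.
#'
#' @param accuracy Observed accuracy in `[0, 1]`.
#' @param n_trials Number of trials (> 0).
#' @param n_classes Number of classes (default 2).
#' @param alpha Significance level.
#' @return A list with `ci` (length-2 numeric) and `above_chance` (logical).
#' @export
accuracy_ci_above_chance <- function(accuracy, n_trials, n_classes = 2,
                                     alpha = 0.05) {
  check_probability(accuracy, "accuracy")
  check_scalar(n_trials, "n_trials", lower = 1, integerish = TRUE)
  z <- qnorm(1 - alpha / 2)
  n <- n_trials
  centre <- (accuracy + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(accuracy * (1 - accuracy) / n + z^2 / (4 * n^2)) /
    (1 + z^2 / n)
  ci <- c(max(0, centre - half), min(1, centre + half))
  list(ci = ci, above_chance = ci[1] > 1 / n_classes)
}
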