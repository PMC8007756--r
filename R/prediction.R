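# Model fitting and discrimination evaluation for the feasibility harness:
# lasso logistic regression (glmnet), gradient boosting (xgboost) and random
# forest (ranger), trained on 25% of the data with five-fold CV for
# hyper-parameters and evaluated on the held-out 75% by AUC (DeLong CI) and
# AUPRC (step-wise average precision).

auc_of <- function(scores, labels) {
  as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}

#' Area under the precision-recall curve
#'
#' Step-wise average precision: the mean of the precision values at the rank
#' of each positive, equivalently the area under the precision-recall step
#' function. Ties in the score are broken by averaging over a fixed order.
#'
#' @param scores Numeric risk scores.
#' @param labels 0/1 outcome labels.
#' @return AUPRC in \[0, 1\].
#' @export
average_precision <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  if (sum(y) == 0) return(0)
  prec <- cumsum(y) / seq_along(y)
  sum(prec * y) / sum(y)
}

cv_folds_of <- function(n, k, seed) {
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

fit_lasso <- function(x_tr, y_tr, x_te, cv_folds, seed) {
  foldid <- cv_folds_of(length(y_tr), cv_folds, seed)
  fit <- glmnet::cv.glmnet(x_tr, y_tr, family = "binomial",
                           foldid = foldid, type.measure = "auc")
  co <- as.matrix(stats::coef(fit, s = "lambda.min"))[-1, 1]
  list(scores = as.numeric(stats::predict(fit, x_te, s = "lambda.min",
                                          type = "response")),
       importance = abs(co),
       hyper = list(lambda = fit$lambda.min),
       importance_metric = "absolute lasso coefficient")
}

fit_rf <- function(x_tr, y_tr, x_te, cv_folds, seed) {
  p <- ncol(x_tr)
  grid <- unique(pmax(1, c(floor(sqrt(p)), floor(p / 3))))
  foldid <- cv_folds_of(length(y_tr), cv_folds, seed)
  cv_auc <- vapply(grid, function(mtry) {
    mean(vapply(seq_len(cv_folds), function(k) {
      tr <- foldid != k
      if (length(unique(y_tr[tr])) < 2 || length(unique(y_tr[!tr])) < 2) {
        return(0.5)
      }
      f <- ranger::ranger(x = x_tr[tr, , drop = FALSE],
                          y = factor(y_tr[tr]), probability = TRUE,
                          num.trees = 300, mtry = mtry, seed = seed,
                          num.threads = 1)
      pr <- stats::predict(f, x_tr[!tr, , drop = FALSE],
                           num.threads = 1)$predictions[, "1"]
      auc_of(pr, y_tr[!tr])
    }, numeric(1)))
  }, numeric(1))
  best <- grid[which.max(cv_auc)]
  fit <- ranger::ranger(x = x_tr, y = factor(y_tr), probability = TRUE,
                        num.trees = 500, mtry = best, seed = seed,
                        importance = "impurity", num.threads = 1)
  list(scores = stats::predict(fit, x_te,
                               num.threads = 1)$predictions[, "1"],
       importance = fit$variable.importance,
       hyper = list(mtry = best, num_trees = 500),
       importance_metric = "impurity (Gini) importance")
}

fit_gbm <- function(x_tr, y_tr, x_te, cv_folds, seed) {
  grid <- expand.grid(max_depth = c(2, 3), eta = c(0.1, 0.3))
  foldid <- cv_folds_of(length(y_tr), cv_folds, seed)
  train_one <- function(x, y, g) {
    set.seed(seed)
    xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = grid$max_depth[g], eta = grid$eta[g],
                    nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(x, label = y), nrounds = 60, verbose = 0)
  }
  cv_auc <- vapply(seq_len(nrow(grid)), function(g) {
    mean(vapply(seq_len(cv_folds), function(k) {
      tr <- foldid != k
      if (length(unique(y_tr[tr])) < 2 || length(unique(y_tr[!tr])) < 2) {
        return(0.5)
      }
      f <- train_one(x_tr[tr, , drop = FALSE], y_tr[tr], g)
      auc_of(stats::predict(f, xgboost::xgb.DMatrix(
        x_tr[!tr, , drop = FALSE])), y_tr[!tr])
    }, numeric(1)))
  }, numeric(1))
  g <- which.max(cv_auc)
  fit <- train_one(x_tr, y_tr, g)
  imp <- xgboost::xgb.importance(model = fit)
  imp_vec <- stats::setNames(rep(0, ncol(x_tr)), colnames(x_tr))
  imp_vec[imp$Feature] <- imp$Gain
  list(scores = stats::predict(fit, xgboost::xgb.DMatrix(x_te)),
       importance = imp_vec,
       hyper = list(max_depth = grid$max_depth[g], eta = grid$eta[g],
                    nrounds = 60),
       importance_metric = "gradient-boosting gain")
}

#' Fit a prediction model and evaluate discrimination
#'
#' Splits the cohort into 25% training / 75% testing (the feasibility
#' design), chooses hyper-parameters by `cv_folds`-fold cross-validation on
#' the training set only, and reports test-set AUC with a DeLong 95% CI and
#' AUPRC. Deterministic given `seed`.
#'
#' @param covariates A `psg_covariates` from [extract_covariates()], or a
#'   bare numeric matrix.
#' @param labels 0/1 outcome labels (defaults to the `label` column of the
#'   covariate entries).
#' @param model `"lasso_logistic"`, `"gradient_boosting"` or
#'   `"random_forest"`.
#' @param train_fraction Fraction used for training (default 0.25).
#' @param cv_folds Cross-validation folds on the training set (default 5).
#' @param seed Integer seed controlling the split, folds and model RNG.
#' @return A `psg_prediction` object; see [glance.psg_prediction()] /
#'   [tidy.psg_prediction()].
#' @export
fit_and_evaluate <- function(covariates, labels = NULL,
                             model = c("lasso_logistic", "gradient_boosting",
                                       "random_forest"),
                             train_fraction = 0.25, cv_folds = 5, seed = 1) {
  model <- match.arg(model)
  if (inherits(covariates, "psg_covariates")) {
    x <- covariates$x
    labels <- labels %||% covariates$entries$label
    setting <- covariates$setting
  } else {
    x <- covariates
    setting <- NA_character_
  }
  if (is.null(labels)) {
    abort_sleepcdm("labels are required", "sleepcdm_config_error")
  }
  y <- as.integer(labels)
  n <- length(y)
  set.seed(seed)
  idx_tr <- sort(sample(n, round(train_fraction * n)))
  idx_te <- setdiff(seq_len(n), idx_tr)
  if (length(unique(y[idx_tr])) < 2 || length(unique(y[idx_te])) < 2) {
    abort_sleepcdm("degenerate split: a partition contains a single class",
                   "sleepcdm_degenerate_split")
  }
  x_tr <- x[idx_tr, , drop = FALSE]
  x_te <- x[idx_te, , drop = FALSE]
  fit <- switch(model,
                lasso_logistic = fit_lasso(x_tr, y[idx_tr], x_te, cv_folds, seed),
                random_forest = fit_rf(x_tr, y[idx_tr], x_te, cv_folds, seed),
                gradient_boosting = fit_gbm(x_tr, y[idx_tr], x_te, cv_folds,
                                            seed))
  roc <- pROC::roc(y[idx_te], fit$scores, quiet = TRUE, direction = "<",
                   levels = c(0, 1))
  ci <- as.numeric(pROC::ci.auc(roc, method = "delong"))
  structure(list(
    model = model, setting = setting, seed = seed,
    auc = as.numeric(pROC::auc(roc)), auc_ci = c(ci[1], ci[3]),
    ci_method = "delong",
    auprc = average_precision(fit$scores, y[idx_te]),
    n_test = length(idx_te), n_outcome_test = sum(y[idx_te]),
    outcome_rate_test = round_half_up(100 * mean(y[idx_te]), 2),
    hyper = fit$hyper, importance_metric = fit$importance_metric,
    importance = tibble::tibble(covariate = names(fit$importance) %||%
                                  colnames(x),
                                importance = as.numeric(fit$importance)),
    test_scores = as.numeric(fit$scores), test_labels = y[idx_te],
    x_test = x_te
  ), class = "psg_prediction")
}

#' Top covariates by importance with per-group test means
#'
#' Ranks covariates by model importance (descending, ties broken by
#' covariate name) and attaches the covariate means in the test-set outcome
#' and non-outcome groups.
#'
#' @param result A `psg_prediction`.
#' @param top_k Number of covariates to return (default 20; larger than the
#'   covariate count returns all; 0 returns an empty table).
#' @return Tibble `rank`, `covariate`, `importance`, `mean_with_outcome`,
#'   `mean_without_outcome`.
#' @export
rank_importances <- function(result, top_k = 20) {
  stopifnot(inherits(result, "psg_prediction"))
  imp <- result$importance |>
    dplyr::arrange(dplyr::desc(.data$importance), .data$covariate)
  top_k <- min(top_k, nrow(imp))
  imp <- imp[seq_len(top_k), , drop = FALSE]
  if (top_k == 0) {
    return(tibble::tibble(rank = integer(0), covariate = character(0),
                          importance = numeric(0),
                          mean_with_outcome = numeric(0),
                          mean_without_outcome = numeric(0)))
  }
  pos <- result$test_labels == 1
  m1 <- colMeans(result$x_test[pos, imp$covariate, drop = FALSE])
  m0 <- colMeans(result$x_test[!pos, imp$covariate, drop = FALSE])
  tibble::tibble(rank = seq_len(top_k), covariate = imp$covariate,
                 importance = imp$importance,
                 mean_with_outcome = as.numeric(m1),
                 mean_without_outcome = as.numeric(m0))
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Glance at a fitted feasibility model
#'
#' One-row summary in the layout of the usual performance table: covariate
#' setting, model, test target size, test outcome count and rate, AUC with
#' its 95% CI, and AUPRC.
#'
#' @param x A `psg_prediction`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance psg_prediction
#' @export
glance.psg_prediction <- function(x, ...) {
  tibble::tibble(setting = x$setting, model = x$model,
                 n_test = x$n_test, n_outcome_test = x$n_outcome_test,
                 outcome_rate = x$outcome_rate_test,
                 auc = x$auc, auc_lo = x$auc_ci[1], auc_hi = x$auc_ci[2],
                 auprc = x$auprc)
}

#' Tidy covariate importances
#'
#' @param x A `psg_prediction`.
#' @param ... Unused.
#' @return Tibble `covariate`, `importance`, sorted descending.
#' @method tidy psg_prediction
#' @export
tidy.psg_prediction <- function(x, ...) {
  dplyr::arrange(x$importance, dplyr::desc(.data$importance),
                 .data$covariate)
}

#' ROC curve of a fitted feasibility model
#'
#' @param object A `psg_prediction`.
#' @param ... Unused.
#' @return A ggplot ROC curve annotated with the AUC.
#' @method autoplot psg_prediction
#' @export
autoplot.psg_prediction <- function(object, ...) {
  ord <- order(object$test_scores, decreasing = TRUE)
  y <- object$test_labels[ord]
  df <- tibble::tibble(tpr = c(0, cumsum(y) / sum(y)),
                       fpr = c(0, cumsum(1 - y) / sum(1 - y)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey") +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("%s (%s): AUC %.3f (%.3f-%.3f)", object$model,
                      object$setting, object$auc, object$auc_ci[1],
                      object$auc_ci[2])) +
    ggplot2::theme_minimal()
}

#' @export
print.psg_prediction <- function(x, ...) {
  cat(sprintf(
    "<psg_prediction> %s, setting=%s\n  test n=%d, outcomes=%d (%.2f%%)\n  AUC %.3f (95%% CI %.3f-%.3f, %s), AUPRC %.3f\n",
    x$model, x$setting, x$n_test, x$n_outcome_test, x$outcome_rate_test,
    x$auc, x$auc_ci[1], x$auc_ci[2], x$ci_method, x$auprc))
  invisible(x)
}
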