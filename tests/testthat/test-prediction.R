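test_that("perfectly separable data reach AUC 1", {
  set.seed(4)
  y <- rep(c(0L, 1L), each = 200)
  x <- cbind(signal = y * 10 + runif(400), noise = rnorm(400))
  # pROC warns that the CI of a perfect ROC curve is degenerate; expected here
  fit <- suppressWarnings(
    fit_and_evaluate(x, y, model = "lasso_logistic", seed = 2))
  expect_equal(fit$auc, 1)
  expect_equal(fit$auprc, 1)
})

test_that("fits are deterministic given the seed", {
  set.seed(8)
  y <- rbinom(300, 1, 0.3)
  x <- cbind(a = rnorm(300) + y, b = rnorm(300), c = rnorm(300))
  for (m in c("lasso_logistic", "random_forest", "gradient_boosting")) {
    f1 <- fit_and_evaluate(x, y, model = m, seed = 7)
    f2 <- fit_and_evaluate(x, y, model = m, seed = 7)
    expect_identical(f1$auc, f2$auc, label = m)
    expect_identical(f1$importance, f2$importance, label = m)
  }
})

test_that("single-class partitions raise a degenerate-split error", {
  x <- cbind(a = rnorm(50))
  expect_error(fit_and_evaluate(x, rep(0L, 50), model = "lasso_logistic"),
               class = "sleepcdm_degenerate_split")
})

test_that("metrics land in their ranges with a sane CI", {
  set.seed(5)
  y <- rbinom(400, 1, 0.25)
  x <- cbind(a = rnorm(400) + 0.8 * y, b = rnorm(400))
  fit <- fit_and_evaluate(x, y, model = "gradient_boosting", seed = 3)
  expect_true(fit$auc >= 0 && fit$auc <= 1)
  expect_true(fit$auprc >= 0 && fit$auprc <= 1)
  expect_true(fit$auc_ci[1] <= fit$auc && fit$auc <= fit$auc_ci[2])
  expect_equal(fit$ci_method, "delong")
  g <- glance(fit)
  expect_equal(g$n_test, 300)
  expect_equal(g$auc, fit$auc)
})

test_that("average precision matches a direct enumeration", {
  # hand-computable case: scores rank y = (1,0,1); AP = (1/1 + 2/3)/2
  expect_equal(average_precision(c(3, 2, 1), c(1, 0, 1)), (1 + 2 / 3) / 2)
  expect_equal(average_precision(c(1, 2, 3), c(0, 0, 1)), 1)
  expect_equal(average_precision(c(3, 2, 1), c(0, 0, 0)), 0)
})

test_that("importance ranking breaks ties by name and honours top_k", {
  fake <- structure(list(
    importance = tibble::tibble(covariate = c("b_cov", "a_cov", "c_cov"),
                                importance = c(0.5, 0.5, 0.1)),
    test_labels = c(1L, 0L),
    x_test = matrix(c(1, 2, 3, 4, 5, 6), nrow = 2,
                    dimnames = list(NULL, c("a_cov", "b_cov", "c_cov")))),
    class = "psg_prediction")
  r <- rank_importances(fake, top_k = 2)
  expect_equal(r$covariate, c("a_cov", "b_cov"))
  expect_equal(r$mean_with_outcome, c(1, 3))
  expect_equal(r$mean_without_outcome, c(2, 4))
  expect_equal(nrow(rank_importances(fake, top_k = 0)), 0L)
  expect_equal(nrow(rank_importances(fake, top_k = 99)), 3L)
})

test_that("a dominant planted AHI effect puts an AHI covariate first", {
  p <- demo_pipeline(n = 2000, seed = 3)
  coh <- build_target_cohort(p$cdm)
  lab <- label_outcomes(coh$entries, outcome_definition(),
                        p$cdm$condition_occurrence)
  cv <- suppressMessages(
    extract_covariates(lab, p$cdm, p$vocab, covariate_settings("psg_only")))
  ahi_col <- grep("Apnea hypopnea index", colnames(cv$x), value = TRUE)[1]
  set.seed(10)
  y <- rbinom(nrow(cv$x), 1, stats::plogis(-2 + 0.12 * (cv$x[, ahi_col] - 20)))
  hits <- vapply(1:10, function(s) {
    fit <- fit_and_evaluate(cv$x, y, model = "random_forest", seed = s)
    top <- rank_importances(fit, 1)$covariate
    grepl("AHI|Apnea hypopnea", top)
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})
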