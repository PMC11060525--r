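test_that("confusion matrix and APC follow their definitions", {
  perfect <- confusion_and_apc(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(unname(diag(perfect$normalized)), rep(1, 3))
  expect_equal(perfect$apc, 1)

  ## recalls 0.8 and 0.6 average to 0.7
  truth <- rep(c("a", "b"), each = 10)
  pred <- c(rep("a", 8), rep("b", 2), rep("b", 6), rep("a", 4))
  res <- confusion_and_apc(pred, truth)
  expect_equal(unname(res$per_class_recall), c(0.8, 0.6))
  expect_equal(res$apc, 0.7)

  ## a class with zero truth items is excluded and flagged
  res2 <- confusion_and_apc(c("a", "b"), c("a", "a"),
                            labels = c("a", "b", "ghost"))
  expect_equal(res2$empty_classes, c("b", "ghost"))
  expect_equal(res2$apc, 0.5)   # only class a contributes
  expect_error(confusion_and_apc(c("a"), c("zz"), labels = c("a", "b")),
               "zz")
})

test_that("under-threshold rate counts abstentions", {
  mk <- function(abst) structure(list(final_label = "x", abstained = abst,
                                      abstention_level = NA_integer_,
                                      confidence = 1,
                                      path = data.frame(confidence = 1)),
                                 class = "prediction")
  preds <- c(replicate(2, mk(TRUE), simplify = FALSE),
             replicate(48, mk(FALSE), simplify = FALSE))
  expect_equal(under_threshold_rate(preds), 0.04)
  expect_equal(under_threshold_rate(replicate(5, mk(FALSE),
                                              simplify = FALSE)), 0)
  expect_equal(under_threshold_rate(replicate(5, mk(TRUE),
                                              simplify = FALSE)), 1)
})

test_that("agreement regression handles exact and offset series", {
  x <- seq(0.1, 0.9, length.out = 10)
  ref <- data.frame(a = x, b = x^2)
  ## identical series: slope 1, R2 1, RMSE 0, decisive p
  ## exact fits trigger base R's perfect-fit note; that is the point here
  res <- suppressWarnings(class_agreement_regression(ref, ref))
  expect_equal(res$slope, c(1, 1), tolerance = 1e-12)
  expect_equal(res$r_squared, c(1, 1), tolerance = 1e-12)
  expect_equal(res$rmse, c(0, 0), tolerance = 1e-10)
  expect_true(all(res$p_value < 1e-10))
  ## constant offset is absorbed by the intercept
  shifted <- data.frame(a = x + 0.3, b = x^2 + 0.3)
  res2 <- suppressWarnings(class_agreement_regression(ref, shifted))
  expect_equal(res2$slope, c(1, 1), tolerance = 1e-12)
  expect_equal(res2$intercept, c(0.3, 0.3), tolerance = 1e-12)
  expect_equal(res2$rmse, c(0, 0), tolerance = 1e-10)
  ## zero-variance reference: flagged, not NaN
  flat <- data.frame(a = rep(0.5, 10))
  res3 <- class_agreement_regression(flat, data.frame(a = x))
  expect_false(res3$fitted)
  expect_true(is.na(res3$p_value))
})

test_that("regression statistics agree with closed-form OLS to 1e-10", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    x <- runif(n); y <- 0.4 * x + rnorm(n, sd = 0.2)
    res <- class_agreement_regression(data.frame(k = x), data.frame(k = y))
    ## closed forms
    sxx <- sum((x - mean(x))^2)
    beta <- sum((x - mean(x)) * (y - mean(y))) / sxx
    alpha <- mean(y) - beta * mean(x)
    resid <- y - alpha - beta * x
    sigma2 <- sum(resid^2) / (n - 2)
    tstat <- beta / sqrt(sigma2 / sxx)
    pval <- 2 * stats::pt(-abs(tstat), n - 2)
    r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
    expect_equal(res$slope, beta, tolerance = 1e-10)
    expect_equal(res$intercept, alpha, tolerance = 1e-10)
    expect_equal(res$p_value, pval, tolerance = 1e-10)
    expect_equal(res$r_squared, r2, tolerance = 1e-10)
    expect_equal(res$rmse, sqrt(mean(resid^2)), tolerance = 1e-10)
  }
})

test_that("difference-based RMSE option measures series disagreement", {
  x <- seq(0, 1, length.out = 8)
  res <- suppressWarnings(
    class_agreement_regression(data.frame(a = x), data.frame(a = x + 0.2),
                               rmse = "difference"))
  expect_equal(res$rmse, 0.2, tolerance = 1e-10)
})

test_that("count_proportions normalizes over the requested denominator", {
  counts <- data.frame(sample_id = c("s1", "s2"), depth_cm = c(1, 2),
                       A = c(30, 0), B = c(10, 50), NPP = c(60, 50),
                       marker_count = c(5, 5), volume_cm3 = 1)
  p <- count_proportions(counts)
  expect_equal(p$A, c(0.3, 0))
  expect_equal(p$A + p$B + p$NPP, c(1, 1))
  p2 <- count_proportions(counts, classes = c("A", "B"),
                          denominator = c("A", "B"))
  expect_equal(p2$A, c(0.75, 0))
})
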