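test_that("metrics match hand-derivable cases", {
  perfect <- sba_metrics(c(1, 2, 3), c(1, 2, 3), p = 1)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$mpe, 0)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$r2_adj, 1)

  # errors (1, -1): Sum|e| = 2, Sum y = 6, TSS = 2
  m <- sba_metrics(c(2, 4), c(1, 5), p = 1)
  expect_equal(m$mae, 1, tolerance = 1e-10)
  expect_equal(m$mpe, 100 * 2 / 6, tolerance = 1e-10)
  expect_equal(m$rmse, 1, tolerance = 1e-10)
  expect_equal(m$r2, 0, tolerance = 1e-10)

  # engineered R2 = 0.9 at n = 10, p = 3: adj = 1 - (9/7) * 0.1
  y <- as.numeric(1:10)
  tss <- sum((y - mean(y))^2)
  e <- rep(c(1, -1), 5) * sqrt(0.1 * tss / 10)
  m2 <- sba_metrics(y, y - e, p = 3)
  expect_equal(m2$r2, 0.9, tolerance = 1e-10)
  expect_equal(m2$r2_adj, 1 - (9 / 7) * 0.1, tolerance = 1e-10)
  expect_equal(m2$r2_adj, 0.87142857142857, tolerance = 1e-10)
})

test_that("metrics agree with a naive loop-based oracle", {
  loop_metrics <- function(y, yhat, p) {
    n <- length(y)
    sae <- 0; sse <- 0
    for (i in seq_len(n)) {
      sae <- sae + abs(y[i] - yhat[i])
      sse <- sse + (y[i] - yhat[i])^2
    }
    ybar <- sum(y) / n
    tss <- 0
    for (i in seq_len(n)) tss <- tss + (y[i] - ybar)^2
    r2 <- 1 - sse / tss
    list(mae = sae / n, mpe = sae / sum(y) * 100, rmse = sqrt(sse / n),
         r2 = r2, r2_adj = 1 - (n - 1) / (n - p) * (1 - r2))
  }
  set.seed(101)
  for (case in 1:50) {
    n <- sample(5:60, 1)
    y <- runif(n, 1, 30)
    yhat <- y + rnorm(n)
    p <- sample(2:5, 1)
    m <- sba_metrics(y, yhat, p)
    o <- loop_metrics(y, yhat, p)
    for (k in names(o)) expect_equal(m[[k]], o[[k]], tolerance = 1e-12)
  }
})

test_that("degenerate inputs are flagged rather than raised", {
  flat <- sba_metrics(c(2, 2, 2), c(1, 2, 3), p = 1)
  expect_true(is.na(flat$r2))
  expect_true("r2_undefined" %in% flat$flags)
})

test_that("percent change reproduces the published comparison arithmetic", {
  expect_equal(round(percent_change(1.776, 1.170), 2), 34.12)
  expect_equal(round(percent_change(1.354, 0.481), 2), 64.48)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(0, 1), "positive")
})

test_that("fold assignment partitions with near-equal sizes, reproducibly", {
  f <- cv_folds(58, 10, seed = 99)
  expect_identical(sort(unique(f)), 1:10)
  expect_identical(as.vector(table(factor(f, levels = 1:10))),
                   c(rep(6L, 8), rep(5L, 2)))
  expect_identical(f, cv_folds(58, 10, seed = 99))
  expect_false(identical(f, cv_folds(58, 10, seed = 100)))
  expect_error(cv_folds(5, 10, seed = 1), "at least")
})

test_that("noiseless cross-validation reproduces the training fit", {
  sim <- sba_simulate(sba_sim_config(n_plots = 40, seed = 71,
                                     sigma_P = 0, sigma_B = 0))
  fit <- sba_nls("M1", sim$table, stratum = "B", seed = 1)
  cv <- sba_cv(fit, k = 10, seed = 5)
  expect_length(cv$failed_folds, 0)
  expect_lt(abs(cv$pooled$rmse - fit$metrics$rmse), 1e-6)
  # same seed reproduces the assignment
  cv2 <- sba_cv(fit, k = 10, seed = 5)
  expect_identical(cv$fold_assignments, cv2$fold_assignments)
})

test_that("system cross-validation pools out-of-fold metrics per stratum", {
  sim <- sba_simulate(sba_sim_config(n_plots = 60, seed = 73,
                                     sigma_P = 0.4, sigma_B = 0.3))
  fit <- sba_nsur(c(P = "M6", B = "M1"), sim$table,
                  start = list(P = truth_nsur_P, B = truth_nsur_B))
  cv <- sba_cv(fit, k = 5, seed = 9)
  expect_named(cv$pooled, c("P", "B", "t"))
  for (s in c("P", "B", "t"))
    expect_s3_class(cv$pooled[[s]], "sba_metrics")
  # out-of-sample error at least as large as in-sample, up to noise
  expect_gt(cv$pooled$t$rmse, 0)
})

test_that("the method-comparison table has the documented sign convention", {
  cmp <- sba_compare_methods(sba_reference_metrics())
  row <- cmp[cmp$method == "NSUR" & cmp$stratum == "t", ]
  expect_gt(row$rmse_decrease, 0)   # NSUR reduced the total RMSE
  expect_gt(row$r2_increase, 0)     # and increased R2
})
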