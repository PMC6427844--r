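test_that("rate baseline predicts smoothed block means, constant in position", {
  train <- as_meth_dataset(tibble::tibble(
    cell = "a", region = "r1", pos = c(-0.5, 0, 0.5),
    state = c(1L, 1L, 0L)
  ), cells = "a", regions = c("r1", "r2"))
  fit <- fit_rate_baseline(train)
  expect_equal(fit$block$rate_raw, 2 / 3)
  expect_equal(fit$block$rate, 2.5 / 4) # (s + 0.5) / (n + 1)
  test <- as_meth_dataset(tibble::tibble(
    cell = "a", region = c("r1", "r1", "r2"), pos = c(-0.9, 0.9, 0),
    state = c(0L, 1L, 1L)
  ), cells = "a", regions = c("r1", "r2"))
  preds <- impute_dataset(fit, test)
  expect_equal(preds$prob[1], preds$prob[2]) # position-independent
  expect_equal(preds$prob[1], 0.625)
  expect_equal(preds$prob[3], 2.5 / 4) # uncovered region -> cell mean
  # an all-zero block binarises to 0
  train0 <- as_meth_dataset(tibble::tibble(
    cell = "a", region = "r1", pos = c(-0.5, 0.5), state = c(0L, 0L)
  ))
  p0 <- impute_dataset(fit_rate_baseline(train0),
                       as_meth_dataset(tibble::tibble(
                         cell = "a", region = "r1", pos = 0, state = 1L)))
  expect_lt(p0$prob, 0.5)
  expect_equal(p0$pred_state, 0L)
})

test_that("rate-constrained mixture fits flat profiles", {
  sim <- rate_structured_sim(seed = 3)
  fit <- fit_methmix_rate(sim$data, k = 4, n_init = 1, seed = 1,
                          max_iter = 100)
  expect_equal(fit$basis$D, 1L)
  p <- predict_cpgs(fit, fit$cells[1], fit$regions[1], c(-0.9, 0, 0.9))
  expect_equal(p$prob, rep(p$prob[1], 3)) # flat within a region
  expect_gte(adjusted_rand_index(fit$hard_labels,
                                 sim$truth$labels$label), 0.95)
})

test_that("M-value transform matches its closed form and inverts", {
  expect_equal(m_value(0.5), 0)
  expect_equal(m_value(0), log2(0.01 / 1.01))
  expect_equal(m_value(1), log2(1.01 / 0.01))
  r <- seq(0, 1, 0.05)
  expect_equal(m_value(r), -m_value(1 - r)) # antisymmetry
  expect_true(all(diff(m_value(r)) > 0)) # strictly increasing
  expect_equal(inv_m_value(m_value(r)), r, tolerance = 1e-12)
  expect_error(m_value(1.2), "\\[0, 1\\]")
})

test_that("GMM EM is monotone, recovers blobs, and K=1 gives column means", {
  set.seed(42)
  X <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 6), 30))
  em <- methmix:::gmm_em(X, 2, seed = 1)
  ll <- em$loglik_trace
  expect_true(all(diff(ll) > -1e-8 * abs(ll[-1])))
  labels <- max.col(em$resp)
  expect_equal(adjusted_rand_index(labels, rep(1:2, each = 30)), 1)
  em1 <- methmix:::gmm_em(X, 1, seed = 1)
  expect_equal(as.numeric(em1$means), colMeans(X), tolerance = 1e-10)
})

test_that("GMM on M-values clusters rate-structured data like the rate mixture", {
  sim <- rate_structured_sim(n_cells = 40, n_regions = 10, seed = 12)
  gmm <- fit_gmm_mvalues(sim$data, k = 2, seed = 1)
  expect_gte(adjusted_rand_index(gmm$hard_labels,
                                 sim$truth$labels$label), 0.95)
  expect_error(fit_gmm_mvalues(sim$data, k = 99), "components")
  # imputation is a responsibility-weighted mixture of cluster rates
  parts <- split_train_test(sim$data, 0.5, seed = 2)
  gmm2 <- fit_gmm_mvalues(parts$train, k = 2, seed = 1)
  preds <- impute_dataset(gmm2, parts$test)
  expect_equal(nrow(preds), nrow(parts$test))
  expect_true(all(preds$prob > 0 & preds$prob < 1))
  # PCA variant runs and clusters comparably
  gmm_pca <- fit_gmm_mvalues(sim$data, k = 2, seed = 1, n_pcs = 5)
  expect_gte(adjusted_rand_index(gmm_pca$hard_labels, gmm$hard_labels),
             0.9)
})

test_that("independent probit MAP matches direct optimisation of the objective", {
  basis <- rbf_basis(2)
  set.seed(7)
  tau0 <- 0.1
  for (rep_i in 1:3) {
    n <- 8
    pos <- sort(runif(n, -1, 1))
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) == 1) y[1] <- 1 - y[1]
    train <- as_meth_dataset(tibble::tibble(
      cell = "a", region = "r1", pos = pos, state = as.integer(y)
    ))
    fit <- fit_independent_profiles(train, basis, tau0 = tau0,
                                    max_iter = 5000, tol = 1e-12)
    H <- design_matrix(pos, basis)
    s <- 2 * y - 1
    negobj <- function(w) {
      -(sum(pnorm(s * (H %*% w), log.p = TRUE)) - tau0 / 2 * sum(w^2))
    }
    opt <- optim(rep(0, basis$D), negobj, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-14))
    expect_equal(as.numeric(fit$weights), opt$par, tolerance = 1e-4)
  }
})

test_that("independent profiles behave sensibly in degenerate blocks", {
  # all-methylated block: probability above 0.5 everywhere
  train <- as_meth_dataset(tibble::tibble(
    cell = "a", region = "r1", pos = c(-0.5, 0, 0.5), state = c(1L, 1L, 1L)
  ))
  fit <- fit_independent_profiles(train, rbf_basis(2))
  test <- as_meth_dataset(tibble::tibble(
    cell = "a", region = "r1", pos = seq(-0.9, 0.9, 0.3),
    state = rep(1L, 7)
  ))
  expect_true(all(impute_dataset(fit, test)$prob > 0.5))
  # intercept-only: the MAP rate is shrunk from the raw rate toward 1/2
  tr <- as_meth_dataset(tibble::tibble(
    cell = "a", region = "r1", pos = c(-0.5, 0, 0.5),
    state = c(1L, 1L, 0L)
  ))
  f0 <- fit_independent_profiles(tr, rbf_basis(0), tau0 = 0.5)
  p <- pnorm(f0$weights[1, 1])
  expect_gt(p, 0.5)
  expect_lt(p, 2 / 3)
})
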