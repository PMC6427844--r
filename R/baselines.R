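#' Per-cell per-region methylation rate baseline
#'
#' The simplest imputation strategy: predict every CpG in a (cell, region)
#' block with the block's mean training state, smoothed with a half
#' pseudo-count (`(s + 0.5) / (n + 1)`) so degenerate all-0/all-1 blocks
#' keep probabilities strictly inside (0, 1). Blocks unseen during training
#' fall back to the cell's global smoothed mean.
#'
#' @param train A methylome dataset tibble.
#' @return A `rate_baseline` object.
#' @export
fit_rate_baseline <- function(train) {
  block <- train |>
    dplyr::group_by(.data$cell, .data$region) |>
    dplyr::summarise(n = dplyr::n(), s = sum(.data$state),
                     .groups = "drop") |>
    dplyr::mutate(rate_raw = .data$s / .data$n,
                  rate = (.data$s + 0.5) / (.data$n + 1))
  cell_mean <- train |>
    dplyr::group_by(.data$cell) |>
    dplyr::summarise(n = dplyr::n(), s = sum(.data$state),
                     .groups = "drop") |>
    dplyr::mutate(rate = (.data$s + 0.5) / (.data$n + 1))
  structure(list(block = block, cell_mean = cell_mean),
            class = "rate_baseline")
}

#' @rdname fit_rate_baseline
#' @inheritParams impute_dataset
#' @export
impute_dataset.rate_baseline <- function(fit, test,
                                         weights = NULL, threshold = 0.5) {
  pred <- test |>
    dplyr::left_join(dplyr::select(fit$block, "cell", "region",
                                   block_rate = "rate"),
                     by = c("cell", "region")) |>
    dplyr::left_join(dplyr::select(fit$cell_mean, "cell",
                                   cell_rate = "rate"),
                     by = "cell") |>
    dplyr::mutate(prob = dplyr::coalesce(.data$block_rate, .data$cell_rate,
                                         0.5))
  tibble::tibble(cell = pred$cell, region = pred$region, pos = pred$pos,
                 prob = pred$prob,
                 pred_state = as.integer(pred$prob > threshold),
                 true_state = as.integer(pred$state))
}

#' Rate-only mixture model
#'
#' The full mixture model constrained to constant (intercept-only)
#' profiles: information is still shared across cells through the
#' clustering, but not across neighbouring CpGs. Equivalent to
#' `fit_methmix(..., basis = rbf_basis(0))`.
#'
#' @inheritParams fit_methmix
#' @return A `methmix_fit` with `basis$D == 1`.
#' @export
fit_methmix_rate <- function(data, k = 10, prior = prior_config("broad"),
                             max_iter = 400, tol = 1e-5, n_init = 3,
                             seed = 1) {
  fit_methmix(data, k = k, basis = rbf_basis(0), prior = prior,
              max_iter = max_iter, tol = tol, n_init = n_init, seed = seed)
}

#' M-value transform of a methylation rate
#'
#' `m_value(r) = log2((r + 0.01) / (1 - r + 0.01))`: the offset log-ratio
#' transform bringing rates in `[0, 1]` closer to Gaussian.
#' `inv_m_value()` is its exact inverse (clamped to `[0, 1]`).
#'
#' @param rate Numeric vector in `[0, 1]`.
#' @return Numeric vector of M-values in
#'   `[log2(0.01 / 1.01), log2(1.01 / 0.01)]`.
#' @examples
#' m_value(0.5) # 0
#' @export
m_value <- function(rate) {
  if (any(rate < 0 | rate > 1)) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  log2((rate + 0.01) / (1 - rate + 0.01))
}

#' @rdname m_value
#' @param m Numeric vector of M-values.
#' @export
inv_m_value <- function(m) {
  pmin(pmax((1.01 * 2^m - 0.01) / (1 + 2^m), 0), 1)
}

#' Gaussian mixture model on per-region average M-values
#'
#' Builds the N x M matrix of per-(cell, region) mean methylation rates,
#' transforms it to M-values, fills missing entries with column means, and
#' fits a K-component diagonal-covariance Gaussian mixture by EM.
#' Clustering is the argmax of the responsibilities. Imputation for a
#' (cell, region) is the responsibility-weighted mixture of the cluster
#' mean rates (cluster mean M-values mapped back through the inverse
#' transform), constant in position.
#'
#' @param train A methylome dataset tibble.
#' @param k Number of Gaussian components.
#' @param seed Seed for the k-means initialisation.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   tolerance.
#' @param n_pcs If non-NULL, project the M-value matrix onto this many
#'   principal components before EM (clustering only; imputation still uses
#'   the original-space cluster rates).
#' @return A `gmm_mvalues` fit with responsibilities, component parameters
#'   and the log-likelihood trace.
#' @export
fit_gmm_mvalues <- function(train, k = 10, seed = 1, max_iter = 200,
                            tol = 1e-6, n_pcs = NULL) {
  cells <- dataset_cells(train)
  regions <- dataset_regions(train)
  N <- length(cells)
  if (k > N) stop("more mixture components than cells", call. = FALSE)
  block <- train |>
    dplyr::group_by(.data$cell, .data$region) |>
    dplyr::summarise(rate = mean(.data$state), .groups = "drop")
  X <- matrix(NA_real_, N, length(regions),
              dimnames = list(cells, regions))
  X[cbind(match(block$cell, cells), match(block$region, regions))] <-
    m_value(block$rate)
  X <- apply(X, 2, function(col) {
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    col
  })
  X[is.nan(X)] <- 0 # regions unobserved in every cell

  Xfit <- X
  if (!is.null(n_pcs)) {
    n_pcs <- min(n_pcs, ncol(X), N - 1)
    Xfit <- stats::prcomp(X, center = TRUE)$x[, seq_len(n_pcs),
                                              drop = FALSE]
  }
  em <- gmm_em(Xfit, k, seed = seed, max_iter = max_iter, tol = tol)

  # cluster mean rates in the original space, for imputation
  rk <- em$resp
  nk <- pmax(colSums(rk), 1e-12)
  mean_m <- t(rk) %*% X / nk # k x M cluster mean M-values
  structure(
    list(k = k, resp = rk, weights = em$weights, means = em$means,
         vars = em$vars, loglik_trace = em$loglik_trace,
         hard_labels = max.col(rk, ties.method = "first"),
         cluster_rates = inv_m_value(mean_m),
         cells = cells, regions = regions, n_pcs = n_pcs),
    class = "gmm_mvalues"
  )
}

# Diagonal-covariance Gaussian mixture EM. Returns responsibilities,
# weights, means (k x p), vars (k x p) and the (non-decreasing)
# log-likelihood trace.
gmm_em <- function(X, k, seed = 1, max_iter = 200, tol = 1e-6,
                   var_floor = 1e-6) {
  N <- nrow(X); p <- ncol(X)
  set.seed(as.integer(seed))
  km <- tryCatch(stats::kmeans(X, centers = k, nstart = 5, iter.max = 50),
                 error = function(e) NULL)
  if (!is.null(km)) {
    mu <- km$centers
    assign0 <- km$cluster
  } else {
    mu <- X[sample.int(N, k), , drop = FALSE]
    assign0 <- sample.int(k, N, replace = TRUE)
  }
  w <- tabulate(assign0, k) / N
  w <- pmax(w, 1e-8); w <- w / sum(w)
  v <- matrix(pmax(apply(X, 2, stats::var), var_floor), k, p, byrow = TRUE)
  if (any(is.na(v))) v[] <- 1

  loglik <- numeric(0)
  resp <- matrix(1 / k, N, k)
  for (it in seq_len(max_iter)) {
    # E-step
    lp <- matrix(0, N, k)
    for (j in seq_len(k)) {
      lp[, j] <- log(w[j]) - 0.5 * sum(log(2 * pi * v[j, ])) -
        0.5 * colSums((t(X) - mu[j, ])^2 / v[j, ])
    }
    mx <- apply(lp, 1, max)
    ll <- sum(mx + log(rowSums(exp(lp - mx))))
    resp <- exp(lp - mx)
    resp <- resp / rowSums(resp)
    loglik[it] <- ll
    if (it > 1 && abs(ll - loglik[it - 1]) < tol * abs(ll)) break
    # M-step
    nk <- pmax(colSums(resp), 1e-10)
    w <- nk / N
    mu <- t(resp) %*% X / nk
    for (j in seq_len(k)) {
      v[j, ] <- pmax(colSums(resp[, j] * (X - matrix(mu[j, ], N, p,
                                                     byrow = TRUE))^2) /
                       nk[j], var_floor)
    }
  }
  list(resp = resp, weights = w, means = mu, vars = v,
       loglik_trace = loglik)
}

#' @rdname fit_gmm_mvalues
#' @inheritParams impute_dataset
#' @export
impute_dataset.gmm_mvalues <- function(fit, test, weights = NULL,
                                       threshold = 0.5) {
  ci <- match(test$cell, fit$cells)
  mi <- match(test$region, fit$regions)
  if (anyNA(ci) || anyNA(mi)) {
    stop("test cells/regions not present in the GMM fit", call. = FALSE)
  }
  p <- numeric(nrow(test))
  for (j in seq_len(fit$k)) {
    p <- p + fit$resp[ci, j] * fit$cluster_rates[j, mi]
  }
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  tibble::tibble(cell = test$cell, region = test$region, pos = test$pos,
                 prob = p, pred_state = as.integer(p > threshold),
                 true_state = as.integer(test$state))
}

#' Independently fitted probit methylation profiles
#'
#' The local-smoothing-only comparator: each (cell, region) block gets its
#' own probit basis regression with a fixed ridge prior `N(0, tau0^-1 I)`,
#' fitted to its MAP estimate by iterating the probit augmentation (expected
#' latent Gaussians, then a ridge solve). Information is shared across
#' neighbouring CpGs within the block but not across cells.
#'
#' @param train A methylome dataset tibble.
#' @param basis An [rbf_basis()].
#' @param tau0 Prior precision of the weights (default 0.1).
#' @param max_iter,tol Iteration cap and convergence tolerance on the
#'   weight change; blocks that fail to converge keep the last iterate with
#'   a warning.
#' @return An `independent_profiles` fit holding one weight vector per
#'   observed (cell, region) block.
#' @export
fit_independent_profiles <- function(train, basis = rbf_basis(4),
                                     tau0 = 0.1, max_iter = 300,
                                     tol = 1e-5) {
  stopifnot(nrow(train) > 0)
  flat <- flatten_dataset(train, basis)
  key <- paste(train$cell, train$region, sep = "\r")
  blocks <- split(seq_len(nrow(train)), key)
  n_fail <- 0L
  W <- matrix(NA_real_, length(blocks), flat$D)
  for (b in seq_along(blocks)) {
    idx <- blocks[[b]]
    H <- flat$H[idx, , drop = FALSE]
    y <- flat$y[idx]
    A <- crossprod(H)
    diag(A) <- diag(A) + tau0
    Ainv <- chol2inv(chol(A))
    w <- rep(0, flat$D)
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      ez <- truncnorm_moments(as.numeric(H %*% w), y)$ez
      w_new <- as.numeric(Ainv %*% crossprod(H, ez))
      if (max(abs(w_new - w)) < tol) {
        w <- w_new
        ok <- TRUE
        break
      }
      w <- w_new
    }
    if (!ok) n_fail <- n_fail + 1L
    W[b, ] <- w
  }
  if (n_fail > 0) {
    warning(n_fail, " block(s) did not converge; last iterate kept",
            call. = FALSE)
  }
  keys <- names(blocks)
  sep_pos <- regexpr("\r", keys, fixed = TRUE)
  structure(
    list(weights = W,
         cell = substr(keys, 1, sep_pos - 1),
         region = substr(keys, sep_pos + 1, nchar(keys)),
         basis = basis, tau0 = tau0,
         cells = flat$cells, regions = flat$regions),
    class = "independent_profiles"
  )
}

#' @rdname fit_independent_profiles
#' @inheritParams impute_dataset
#' @export
impute_dataset.independent_profiles <- function(fit, test, weights = NULL,
                                                threshold = 0.5) {
  key <- paste(test$cell, test$region, sep = "\r")
  fit_key <- paste(fit$cell, fit$region, sep = "\r")
  bi <- match(key, fit_key)
  H <- design_matrix(test$pos, fit$basis)
  eta <- rowSums(H * fit$weights[ifelse(is.na(bi), 1L, bi), ,
                                 drop = FALSE])
  p <- stats::pnorm(eta)
  p[is.na(bi)] <- 0.5 # block never observed in training: no information
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  tibble::tibble(cell = test$cell, region = test$region, pos = test$pos,
                 prob = p, pred_state = as.integer(p > threshold),
                 true_state = as.integer(test$state))
}
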