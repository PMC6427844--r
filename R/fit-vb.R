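#' Prior configuration for the methylome mixture model
#'
#' The model places a symmetric Dirichlet prior on the mixing proportions
#' (concentration `delta0` per component), a zero-mean isotropic Gaussian
#' prior on each region's profile weights with cluster-specific precision
#' `tau_k`, and a Gamma(`alpha0`, `beta0`) prior on each `tau_k`.
#'
#' Two named presets are provided. `"broad"` (`delta0 = 0.5`) is weakly
#' informative; `"shrinkage"` (`delta0 = 1e-6`) puts negligible prior mass
#' on each component so that components must earn their occupancy from the
#' data, encouraging more aggressive pruning of redundant clusters.
#'
#' @param delta0 Dirichlet concentration per component, or the string
#'   `"broad"` / `"shrinkage"`.
#' @param alpha0,beta0 Shape and rate of the Gamma prior on the weight
#'   precisions.
#' @return A `prior_config` list with elements `delta0`, `alpha0`, `beta0`.
#' @export
prior_config <- function(delta0 = "broad", alpha0 = 0.5, beta0 = 10) {
  if (is.character(delta0)) {
    delta0 <- switch(match.arg(delta0, c("broad", "shrinkage")),
                     broad = 0.5, shrinkage = 1e-6)
  }
  stopifnot(delta0 > 0, alpha0 > 0, beta0 > 0)
  structure(list(delta0 = delta0, alpha0 = alpha0, beta0 = beta0),
            class = "prior_config")
}

# ---------------------------------------------------------------------------
# Internal flat representation: all observed CpGs in long vectors, plus the
# design matrix, its packed outer products for fast quadratic forms, and
# per-(cell, region) block indexing with the constant sufficient statistic
# G_nm = sum_i x_i x_i' (packed). The likelihood terms of every factor
# update depend on the data only through G_nm and b_nm = sum_i E[z_i] x_i,
# so the expensive sums run over blocks, not CpGs.
flatten_dataset <- function(data, basis) {
  cells <- dataset_cells(data)
  regions <- dataset_regions(data)
  if (nrow(data) == 0) stop("dataset contains no observed CpGs",
                            call. = FALSE)
  cell_idx <- match(data$cell, cells)
  region_idx <- match(data$region, regions)
  if (anyNA(cell_idx) || anyNA(region_idx)) {
    stop("dataset rows refer to cells/regions outside the declared universe",
         call. = FALSE)
  }
  ord <- order(cell_idx, region_idx)
  cell_idx <- cell_idx[ord]
  region_idx <- region_idx[ord]
  pos <- data$pos[ord]
  y <- as.numeric(data$state)[ord]

  H <- design_matrix(pos, basis)
  D <- ncol(H)
  pair_j <- rep(seq_len(D), times = D:1)
  pair_l <- unlist(lapply(seq_len(D), function(j) j:D))
  Hout <- H[, pair_j, drop = FALSE] * H[, pair_l, drop = FALSE]
  mult <- ifelse(pair_j == pair_l, 1, 2)

  new_block <- c(TRUE, diff(cell_idx) != 0 | diff(region_idx) != 0)
  block_id <- cumsum(new_block)
  block_cell <- cell_idx[new_block]
  block_region <- region_idx[new_block]
  Gpack <- rowsum(Hout, block_id, reorder = FALSE)

  list(
    N = length(cells), M = length(regions), D = D,
    cells = cells, regions = regions,
    cell_idx = cell_idx, region_idx = region_idx,
    y = y, H = H, Hout = Hout,
    pair_j = pair_j, pair_l = pair_l, mult = mult,
    block_id = block_id, block_cell = block_cell,
    block_region = block_region, n_blocks = length(block_cell),
    Gpack = Gpack,
    n_obs = nrow(data)
  )
}

# unpack a packed symmetric matrix (length D(D+1)/2) into D x D
unpack_sym <- function(p, pair_j, pair_l, D) {
  A <- matrix(0, D, D)
  A[cbind(pair_j, pair_l)] <- p
  A[cbind(pair_l, pair_j)] <- p
  A
}

pack_sym <- function(A, pair_j, pair_l) A[cbind(pair_j, pair_l)]

# per-(cell, region) expected log-Gaussian data terms under each cluster,
# up to the k-constant -(E[z^2] + ln 2*pi)/2 per CpG:
#   LL_block,k = b_nm' lambda_mk - G_nm : (lambda lambda' + S)_mk / 2
block_loglik <- function(flat, Bmat, Lambda, Spack) {
  K <- length(Lambda)
  ll <- matrix(0, flat$n_blocks, K)
  for (k in seq_len(K)) {
    lam_b <- Lambda[[k]][flat$block_region, , drop = FALSE]
    lin <- rowSums(Bmat * lam_b)
    Apack <- (Spack[[k]][flat$block_region, , drop = FALSE] +
                lam_b[, flat$pair_j, drop = FALSE] *
                lam_b[, flat$pair_l, drop = FALSE])
    quad <- rowSums(flat$Gpack * Apack *
                      rep(flat$mult, each = flat$n_blocks))
    ll[, k] <- lin - 0.5 * quad
  }
  ll
}

# initial variational state given starting responsibilities
init_state <- function(flat, K, prior, r) {
  M <- flat$M; D <- flat$D
  delta <- prior$delta0 + colSums(r)
  list(
    K = K,
    r = r,
    delta = delta,
    Lambda = replicate(K, matrix(0, M, D), simplify = FALSE),
    Spack = replicate(K, {
      p <- matrix(0, M, length(flat$pair_j))
      p[, flat$pair_j == flat$pair_l] <- 1
      p
    }, simplify = FALSE),
    logdetS = matrix(0, M, K),
    trS = matrix(D, M, K),
    wsq = matrix(D, M, K), # E[w'w] = lambda'lambda + tr(S)
    g_alpha = rep(prior$alpha0, K),
    g_beta = rep(prior$beta0, K),
    mu = NULL, ez = NULL, ez2 = NULL,
    elbo = -Inf
  )
}

# One full coordinate-ascent sweep in the fixed order
# q(Z) -> q(W) -> q(tau) -> q(C) -> q(pi), followed by the ELBO of the
# resulting state.
cavi_sweep <- function(state, flat, prior) {
  K <- state$K; M <- flat$M; D <- flat$D

  # ---- q(Z): unit-variance truncated Gaussians at the responsibility-
  # weighted predictor. The mixed weights are formed per block first.
  wbar <- matrix(0, flat$n_blocks, D)
  for (k in seq_len(K)) {
    wbar <- wbar + state$r[flat$block_cell, k] *
      state$Lambda[[k]][flat$block_region, , drop = FALSE]
  }
  mu <- rowSums(flat$H * wbar[flat$block_id, , drop = FALSE])
  mom <- truncnorm_moments(mu, flat$y)
  state$mu <- mu; state$ez <- mom$ez; state$ez2 <- mom$ez2

  # per-block linear statistic b_nm = sum_i E[z_i] x_i
  Bmat <- rowsum(flat$H * mom$ez, flat$block_id, reorder = FALSE)

  # ---- q(W): Gaussian, precision E[tau_k] I + sum_n r_nk X'X
  e_tau <- state$g_alpha / state$g_beta
  for (k in seq_len(K)) {
    w_k <- state$r[flat$block_cell, k]
    Gp <- rowsum_full(flat$Gpack * w_k, flat$block_region, M)
    Bp <- rowsum_full(Bmat * w_k, flat$block_region, M)
    for (m in seq_len(M)) {
      G <- unpack_sym(Gp[m, ], flat$pair_j, flat$pair_l, D)
      diag(G) <- diag(G) + e_tau[k]
      ch <- chol(G)
      Sm <- chol2inv(ch)
      lam <- Sm %*% Bp[m, ]
      state$Lambda[[k]][m, ] <- lam
      state$Spack[[k]][m, ] <- pack_sym(Sm, flat$pair_j, flat$pair_l)
      state$logdetS[m, k] <- -2 * sum(log(diag(ch)))
      state$trS[m, k] <- sum(diag(Sm))
      state$wsq[m, k] <- sum(lam^2) + state$trS[m, k]
    }
  }

  # ---- q(tau): Gamma
  state$g_alpha <- rep(prior$alpha0 + M * D / 2, K)
  state$g_beta <- prior$beta0 + colSums(state$wsq) / 2

  # ---- q(C): categorical from the expected log joint of each cell's
  # data, dropping terms constant in k (restored in the ELBO)
  ll <- block_loglik(flat, Bmat, state$Lambda, state$Spack)
  LL <- rowsum_full(ll, flat$block_cell, flat$N) # N x K
  e_lnpi <- digamma(state$delta) - digamma(sum(state$delta))
  lr <- sweep(LL, 2, e_lnpi, "+")
  lr <- lr - apply(lr, 1, max)
  r <- exp(lr)
  r <- r / rowSums(r)
  state$r <- r

  # ---- q(pi): Dirichlet
  state$delta <- prior$delta0 + colSums(r)

  state$LL <- LL
  state$elbo <- cavi_elbo(state, flat, prior)
  state
}

# rowsum() that keeps absent groups as zero rows, in index order
rowsum_full <- function(x, idx, n) {
  out <- matrix(0, n, ncol(x))
  rs <- rowsum(x, idx)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# Evidence lower bound of the current state (all factors as stored).
cavi_elbo <- function(state, flat, prior) {
  K <- state$K; M <- flat$M; D <- flat$D; N <- flat$N
  e_lnpi <- digamma(state$delta) - digamma(sum(state$delta))
  e_tau <- state$g_alpha / state$g_beta
  e_lntau <- digamma(state$g_alpha) - log(state$g_beta)

  # data + augmented-variable terms
  s <- 2 * flat$y - 1
  t_z <- sum(0.5 * state$mu^2 - state$mu * state$ez +
               stats::pnorm(s * state$mu, log.p = TRUE)) +
    sum(state$r * state$LL)

  # cluster assignment terms (0 * log 0 := 0)
  rl <- state$r * log(pmax(state$r, .Machine$double.xmin))
  rl[state$r == 0] <- 0
  t_c <- sum(sweep(state$r, 2, e_lnpi, "*")) - sum(rl)

  # weight terms
  t_w <- sum(
    rep(D / 2 * e_lntau, each = M) - 0.5 * sweep(state$wsq, 2, e_tau, "*") +
      0.5 * state$logdetS + D / 2
  )

  # mixing proportion terms
  d0 <- prior$delta0
  t_pi <- lgamma(K * d0) - K * lgamma(d0) -
    lgamma(sum(state$delta)) + sum(lgamma(state$delta)) +
    sum((d0 - state$delta) * e_lnpi)

  # precision terms
  t_tau <- sum(
    prior$alpha0 * log(prior$beta0) - lgamma(prior$alpha0) +
      (prior$alpha0 - 1) * e_lntau - prior$beta0 * e_tau -
      (state$g_alpha * log(state$g_beta) - lgamma(state$g_alpha) +
         (state$g_alpha - 1) * e_lntau - state$g_alpha)
  )

  elbo <- t_z + t_c + t_w + t_pi + t_tau
  if (!is.finite(elbo)) stop("non-finite ELBO", call. = FALSE)
  elbo
}

# k-means (or random) starting responsibilities on the N x M matrix of
# per-region mean rates, missing entries filled with the region mean
initial_responsibilities <- function(data, flat, K, method = c("kmeans",
                                                               "random")) {
  method <- match.arg(method)
  N <- flat$N; K <- as.integer(K)
  if (method == "random") {
    r <- matrix(stats::rgamma(N * K, 1, 1), N, K)
    return(r / rowSums(r))
  }
  rates <- matrix(NA_real_, N, flat$M)
  agg <- rowsum(cbind(flat$y, 1), flat$region_idx + (flat$cell_idx - 1) *
                  (flat$M + 1L))
  idx <- as.integer(rownames(agg))
  ri <- (idx - 1L) %% (flat$M + 1L) + 1L
  ci <- (idx - 1L) %/% (flat$M + 1L) + 1L
  rates[cbind(ci, ri)] <- agg[, 1] / agg[, 2]
  col_means <- colMeans(rates, na.rm = TRUE)
  col_means[is.nan(col_means)] <- 0.5
  for (j in seq_len(ncol(rates))) {
    rates[is.na(rates[, j]), j] <- col_means[j]
  }
  km <- tryCatch(
    stats::kmeans(rates, centers = K, nstart = 5, iter.max = 50),
    error = function(e) NULL
  )
  if (is.null(km)) {
    return(initial_responsibilities(data, flat, K, "random"))
  }
  onehot <- matrix(0, N, K)
  onehot[cbind(seq_len(N), km$cluster)] <- 1
  # deliberately soft: hard initial assignments lock the optimisation into
  # split-cluster local optima before redundant components can merge
  0.3 * onehot + 0.7 / K
}

#' Fit the methylome mixture model by variational inference
#'
#' Cells are clustered genome-wide by a finite Dirichlet mixture whose
#' components are per-region probit profiles over a shared basis; missing
#' states can then be imputed from the posterior predictive (see
#' [impute_dataset()]). Inference is mean-field coordinate-ascent
#' variational Bayes (CAVI) with probit data augmentation; the factors are
#' updated in the fixed order q(Z), q(W), q(tau), q(C), q(pi) and the
#' evidence lower bound (ELBO) is monitored every sweep. Components that
#' end up with no cells assigned are pruned diagnostically (reported, not
#' deleted), so fitting with a generous `k` performs automatic model
#' selection.
#'
#' @param data A methylome dataset tibble (`cell`, `region`, `pos`,
#'   `state`), typically the training half of [split_train_test()].
#' @param k Number of mixture components to start from (upper bound on the
#'   number of sub-populations).
#' @param basis An [rbf_basis()]; `rbf_basis(0)` constrains all profiles to
#'   constants, turning the model into its rate-only variant.
#' @param prior A [prior_config()] or one of `"broad"`, `"shrinkage"`.
#' @param max_iter Maximum CAVI sweeps (default 400).
#' @param tol Relative ELBO change declaring convergence (default 1e-5).
#' @param n_init Number of restarts (first from k-means on per-region mean
#'   rates, the rest random); the fit with the highest final ELBO is
#'   returned, ties broken by the lowest restart index.
#' @param seed Integer seed governing initialisation.
#' @param verbose Print the ELBO every sweep.
#' @return A `methmix_fit` object with elements `r` (N x k
#'   responsibilities), `delta`, `Lambda`, `Spack` and friends
#'   (per-cluster weight posteriors), `g_alpha`/`g_beta` (precision
#'   posteriors), `elbo_trace`, `hard_labels`, `effective_k`, `converged`,
#'   `n_iter`, plus the `basis`, `prior` and indexing metadata needed for
#'   prediction.
#' @examples
#' sim <- simulate_dataset(sim_config(n_cells = 30, n_regions = 5,
#'                                    cpgs_per_region = 20, seed = 1))
#' fit <- fit_methmix(sim$data, k = 4, max_iter = 50, n_init = 1, seed = 1)
#' glance(fit)
#' @export
fit_methmix <- function(data, k = 10, basis = rbf_basis(4),
                        prior = prior_config("broad"), max_iter = 400,
                        tol = 1e-5, n_init = 3, seed = 1, verbose = FALSE) {
  if (k < 1 || k != round(k)) stop("`k` must be a positive integer",
                                   call. = FALSE)
  if (is.character(prior)) prior <- prior_config(prior)
  stopifnot(inherits(prior, "prior_config"))
  flat <- flatten_dataset(data, basis)

  set.seed(as.integer(seed))
  restart_seeds <- sample.int(.Machine$integer.max, n_init)
  best <- NULL
  for (i in seq_len(n_init)) {
    set.seed(restart_seeds[i])
    r0 <- initial_responsibilities(
      data, flat, k, method = if (i == 1) "kmeans" else "random"
    )
    state <- init_state(flat, as.integer(k), prior, r0)
    trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      prev <- state$elbo
      state <- cavi_sweep(state, flat, prior)
      trace[it] <- state$elbo
      if (verbose) {
        message(sprintf("restart %d sweep %3d ELBO %.6f", i, it,
                        state$elbo))
      }
      if (is.finite(prev) &&
          abs(state$elbo - prev) < tol * abs(state$elbo)) {
        converged <- TRUE
        break
      }
    }
    if (is.null(best) || state$elbo > best$state$elbo) {
      best <- list(state = state, trace = trace, converged = converged,
                   restart = i)
    }
  }

  state <- best$state
  hard <- max.col(state$r, ties.method = "first")
  fit <- structure(
    list(
      k = as.integer(k),
      r = state$r,
      delta = state$delta,
      Lambda = state$Lambda,
      Spack = state$Spack,
      logdetS = state$logdetS,
      trS = state$trS,
      g_alpha = state$g_alpha,
      g_beta = state$g_beta,
      elbo = state$elbo,
      elbo_trace = best$trace,
      hard_labels = hard,
      effective_k = NA_integer_,
      converged = best$converged,
      n_iter = length(best$trace),
      restart = best$restart,
      cells = flat$cells,
      regions = flat$regions,
      pair_j = flat$pair_j,
      pair_l = flat$pair_l,
      basis = basis,
      prior = prior,
      n_obs = flat$n_obs
    ),
    class = "methmix_fit"
  )
  fit$effective_k <- effective_clusters(fit)
  fit
}

#' Count mixture components with real support
#'
#' Variational optimisation of an over-specified mixture empties redundant
#' components; this reports how many remain occupied. A component counts as
#' occupied when its expected number of assigned cells `sum_n r_nk`
#' exceeds `min_cells` (default: one cell-equivalent). Pruning is
#' diagnostic only — no component is removed from the fit.
#'
#' @param fit A `methmix_fit`.
#' @param min_cells Occupancy threshold in cell-equivalents.
#' @return Integer count of occupied components.
#' @export
effective_clusters <- function(fit, min_cells = 1) {
  stopifnot(inherits(fit, "methmix_fit"))
  sum(colSums(fit$r) > min_cells)
}

#' @export
print.methmix_fit <- function(x, ...) {
  cat(sprintf(
    "<methmix_fit> %d cells, %d regions, k = %d (effective %d)\n",
    length(x$cells), length(x$regions), x$k, x$effective_k
  ))
  cat(sprintf("  ELBO %.3f after %d sweeps (%s), basis D = %d\n",
              x$elbo, x$n_iter,
              if (x$converged) "converged" else "max_iter reached",
              x$basis$D))
  invisible(x)
}
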