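#' Gibbs sampling for the methylome mixture model
#'
#' Samples the same joint model as [fit_methmix()] by blocked Gibbs: the
#' augmented Gaussians from their truncated-normal full conditionals, the
#' profile weights from their Gaussian conjugate updates (falling back to
#' the prior for empty clusters), the cluster precisions from their Gamma
#' conditionals, the cell assignments from the probit likelihood of each
#' cell under each cluster's current weights, and the mixing proportions
#' from the Dirichlet conditional. Used as a correctness oracle for the
#' variational fit and for scalability comparisons; the variational engine
#' is the recommended one for large data.
#'
#' @inheritParams fit_methmix
#' @param n_iter Total Gibbs iterations (default 3000).
#' @param burn_in Discarded initial iterations (default `n_iter / 2`).
#' @param thin Keep every `thin`-th draw after burn-in (default 5).
#' @param store_weights Keep the thinned weight draws (an
#'   `draws x M x k x D` array); disable for large models.
#' @return A `methmix_gibbs` object with matrices `labels` (draws x N),
#'   `pi`, `tau` (draws x k), optionally `weights`, plus the run
#'   configuration.
#' @export
fit_methmix_gibbs <- function(data, k = 3, basis = rbf_basis(4),
                              prior = prior_config("broad"), n_iter = 3000,
                              burn_in = floor(n_iter / 2), thin = 5,
                              seed = 1, store_weights = TRUE) {
  if (k < 1 || k != round(k)) stop("`k` must be a positive integer",
                                   call. = FALSE)
  if (is.character(prior)) prior <- prior_config(prior)
  flat <- flatten_dataset(data, basis)
  N <- flat$N; M <- flat$M; D <- flat$D
  set.seed(as.integer(seed))

  keep <- seq(burn_in + thin, n_iter, by = thin)
  n_keep <- length(keep)
  out_labels <- matrix(NA_integer_, n_keep, N)
  out_pi <- matrix(NA_real_, n_keep, k)
  out_tau <- matrix(NA_real_, n_keep, k)
  out_w <- if (store_weights) array(NA_real_, c(n_keep, M, k, D)) else NULL

  # initial values from the priors / a random partition
  c_n <- sample.int(k, N, replace = TRUE)
  tau <- stats::rgamma(k, prior$alpha0, prior$beta0)
  W <- replicate(k, matrix(0, M, D), simplify = FALSE)
  pi_k <- as.numeric(rdirichlet1(rep(prior$delta0, k)))
  s <- 2 * flat$y - 1

  keep_i <- 0L
  for (it in seq_len(n_iter)) {
    # -- z | c, w: truncated normals, sign matched to y --------------------
    mu <- rowSums(flat$H * W_rows(W, flat, c_n))
    z <- rtruncnorm_sign(mu, s)

    # -- w_mk | z, c, tau: Gaussian conjugate ------------------------------
    for (kk in seq_len(k)) {
      in_k <- c_n[flat$cell_idx] == kk
      if (any(in_k)) {
        Gp <- rowsum_full(flat$Hout[in_k, , drop = FALSE],
                          flat$region_idx[in_k], M)
        Bp <- rowsum_full(flat$H[in_k, , drop = FALSE] * z[in_k],
                          flat$region_idx[in_k], M)
      } else {
        Gp <- matrix(0, M, length(flat$pair_j))
        Bp <- matrix(0, M, D)
      }
      for (m in seq_len(M)) {
        G <- unpack_sym(Gp[m, ], flat$pair_j, flat$pair_l, D)
        diag(G) <- diag(G) + tau[kk]
        ch <- chol(G)
        mean_w <- backsolve(ch, backsolve(ch, Bp[m, ], transpose = TRUE))
        W[[kk]][m, ] <- mean_w + backsolve(ch, stats::rnorm(D))
      }
    }

    # -- tau_k | W: Gamma ---------------------------------------------------
    wsq <- vapply(W, function(w) sum(w^2), numeric(1))
    tau <- stats::rgamma(k, prior$alpha0 + M * D / 2,
                         prior$beta0 + wsq / 2)

    # -- c_n | y, W, pi: categorical from the probit likelihood ------------
    ll <- matrix(0, flat$n_obs, k)
    for (kk in seq_len(k)) {
      eta <- rowSums(flat$H * W[[kk]][flat$region_idx, , drop = FALSE])
      ll[, kk] <- stats::pnorm(s * eta, log.p = TRUE)
    }
    LL <- rowsum_full(ll, flat$cell_idx, N)
    lp <- sweep(LL, 2, log(pi_k), "+")
    lp <- lp - apply(lp, 1, max)
    p <- exp(lp); p <- p / rowSums(p)
    u <- stats::runif(N)
    c_n <- max.col(u < t(apply(p, 1, cumsum)), ties.method = "first")

    # -- pi | c: Dirichlet --------------------------------------------------
    pi_k <- as.numeric(rdirichlet1(prior$delta0 + tabulate(c_n, k)))

    if (it > burn_in && (it - burn_in) %% thin == 0) {
      keep_i <- keep_i + 1L
      out_labels[keep_i, ] <- c_n
      out_pi[keep_i, ] <- pi_k
      out_tau[keep_i, ] <- tau
      if (store_weights) {
        for (kk in seq_len(k)) out_w[keep_i, , kk, ] <- W[[kk]]
      }
    }
  }

  structure(
    list(k = as.integer(k), labels = out_labels, pi = out_pi,
         tau = out_tau, weights = out_w,
         n_iter = n_iter, burn_in = burn_in, thin = thin, seed = seed,
         cells = flat$cells, regions = flat$regions, basis = basis,
         prior = prior),
    class = "methmix_gibbs"
  )
}

# rows of the assigned cluster's weight matrix for every CpG
W_rows <- function(W, flat, c_n) {
  out <- matrix(0, flat$n_obs, flat$D)
  for (kk in seq_along(W)) {
    sel <- c_n[flat$cell_idx] == kk
    if (any(sel)) out[sel, ] <- W[[kk]][flat$region_idx[sel], ,
                                        drop = FALSE]
  }
  out
}

# one Dirichlet draw via normalised Gammas
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), alpha, 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

# z ~ N(mu, 1) truncated to sign(z) == s, via log-scale inverse-CDF so the
# far tail stays finite
rtruncnorm_sign <- function(mu, s) {
  u <- stats::runif(length(mu))
  # by reflection, |z| = s*mu - qnorm(u * Phi(s*mu)) on the matched side;
  # the CDF product is kept on the log scale so far-tail draws stay finite
  lq <- log(u) + stats::pnorm(s * mu, log.p = TRUE)
  s * (s * mu - stats::qnorm(lq, log.p = TRUE))
}

#' @export
print.methmix_gibbs <- function(x, ...) {
  cat(sprintf(
    "<methmix_gibbs> %d cells, %d regions, k = %d; %d draws (%d iterations, burn-in %d, thin %d)\n",
    length(x$cells), length(x$regions), x$k, nrow(x$labels), x$n_iter,
    x$burn_in, x$thin
  ))
  invisible(x)
}

#' Posterior-mode labels from a Gibbs run
#'
#' Relabels each stored draw against the last draw by greedy matching of
#' the confusion matrix, then returns the per-cell majority label. The
#' adjusted Rand index is invariant to relabelling; this is only needed
#' when a single representative partition is required.
#'
#' @param fit A `methmix_gibbs`.
#' @return Integer vector of length N.
#' @export
gibbs_map_labels <- function(fit) {
  stopifnot(inherits(fit, "methmix_gibbs"))
  ref <- fit$labels[nrow(fit$labels), ]
  k <- fit$k
  counts <- matrix(0L, ncol(fit$labels), k)
  for (d in seq_len(nrow(fit$labels))) {
    lab <- fit$labels[d, ]
    conf <- table(factor(lab, levels = seq_len(k)),
                  factor(ref, levels = seq_len(k)))
    perm <- integer(k)
    free_to <- rep(TRUE, k)
    for (j in order(-apply(conf, 1, max))) {
      best <- which.max(ifelse(free_to, conf[j, ], -1))
      perm[j] <- best
      free_to[best] <- FALSE
    }
    relab <- perm[lab]
    counts[cbind(seq_along(relab), relab)] <-
      counts[cbind(seq_along(relab), relab)] + 1L
  }
  max.col(counts, ties.method = "first")
}
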