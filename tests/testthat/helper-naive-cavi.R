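# An independent, deliberately naive coordinate-ascent implementation of the
# variational updates, written with explicit loops and dense matrices. Used
# as an oracle: on tiny instances the package's vectorised sweep must
# reproduce these factor parameters and ELBO values.

naive_design <- function(pos, basis) {
  H <- matrix(1, length(pos), basis$n_rbf + 1)
  for (j in seq_len(basis$n_rbf)) {
    H[, j + 1] <- exp(-basis$gamma * (pos - basis$centers[j])^2)
  }
  H
}

# data: list per cell of list per region of list(pos, y); absent = NULL
naive_setup <- function(dataset, basis) {
  cells <- attr(dataset, "cells")
  regions <- attr(dataset, "regions")
  blocks <- vector("list", length(cells))
  for (n in seq_along(cells)) {
    blocks[[n]] <- vector("list", length(regions))
    for (m in seq_along(regions)) {
      rows <- dataset$cell == cells[n] & dataset$region == regions[m]
      if (any(rows)) {
        blocks[[n]][[m]] <- list(
          H = naive_design(dataset$pos[rows], basis),
          y = as.numeric(dataset$state[rows])
        )
      }
    }
  }
  list(blocks = blocks, N = length(cells), M = length(regions),
       D = basis$n_rbf + 1)
}

naive_trunc_moments <- function(mu, y) {
  if (y == 1) {
    ez <- mu + dnorm(mu) / pnorm(mu)
  } else {
    ez <- mu - dnorm(mu) / pnorm(-mu)
  }
  c(ez, 1 + mu * ez)
}

naive_init <- function(setup, K, prior, r0) {
  list(
    r = r0,
    delta = prior$delta0 + colSums(r0),
    Lambda = lapply(seq_len(K), function(k) matrix(0, setup$M, setup$D)),
    S = lapply(seq_len(K), function(k) {
      lapply(seq_len(setup$M), function(m) diag(setup$D))
    }),
    g_alpha = rep(prior$alpha0, K),
    g_beta = rep(prior$beta0, K),
    ez = NULL, mu = NULL
  )
}

naive_sweep <- function(state, setup, K, prior) {
  N <- setup$N; M <- setup$M; D <- setup$D
  # q(Z)
  ez <- mu_all <- vector("list", N)
  for (n in seq_len(N)) {
    ez[[n]] <- mu_all[[n]] <- vector("list", M)
    for (m in seq_len(M)) {
      b <- setup$blocks[[n]][[m]]
      if (is.null(b)) next
      I <- length(b$y)
      ez_nm <- mu_nm <- ez2_nm <- numeric(I)
      for (i in seq_len(I)) {
        mu <- 0
        for (k in seq_len(K)) {
          mu <- mu + state$r[n, k] * sum(b$H[i, ] * state$Lambda[[k]][m, ])
        }
        mom <- naive_trunc_moments(mu, b$y[i])
        mu_nm[i] <- mu; ez_nm[i] <- mom[1]; ez2_nm[i] <- mom[2]
      }
      ez[[n]][[m]] <- list(ez = ez_nm, ez2 = ez2_nm)
      mu_all[[n]][[m]] <- mu_nm
    }
  }
  state$ez <- ez; state$mu <- mu_all
  # q(W)
  for (k in seq_len(K)) {
    e_tau <- state$g_alpha[k] / state$g_beta[k]
    for (m in seq_len(M)) {
      G <- diag(e_tau, D)
      bvec <- rep(0, D)
      for (n in seq_len(N)) {
        b <- setup$blocks[[n]][[m]]
        if (is.null(b)) next
        G <- G + state$r[n, k] * (t(b$H) %*% b$H)
        bvec <- bvec + state$r[n, k] * as.numeric(t(b$H) %*% ez[[n]][[m]]$ez)
      }
      S <- solve(G)
      state$S[[k]][[m]] <- S
      state$Lambda[[k]][m, ] <- as.numeric(S %*% bvec)
    }
  }
  # q(tau)
  for (k in seq_len(K)) {
    wsq <- 0
    for (m in seq_len(M)) {
      wsq <- wsq + sum(state$Lambda[[k]][m, ]^2) +
        sum(diag(state$S[[k]][[m]]))
    }
    state$g_alpha[k] <- prior$alpha0 + M * D / 2
    state$g_beta[k] <- prior$beta0 + wsq / 2
  }
  # q(C)
  e_lnpi <- digamma(state$delta) - digamma(sum(state$delta))
  LL <- matrix(0, N, K)
  for (n in seq_len(N)) {
    for (k in seq_len(K)) {
      acc <- 0
      for (m in seq_len(M)) {
        b <- setup$blocks[[n]][[m]]
        if (is.null(b)) next
        lam <- state$Lambda[[k]][m, ]
        S <- state$S[[k]][[m]]
        for (i in seq_along(b$y)) {
          x <- b$H[i, ]
          acc <- acc + ez[[n]][[m]]$ez[i] * sum(x * lam) -
            0.5 * (sum(x * lam)^2 + as.numeric(t(x) %*% S %*% x))
        }
      }
      LL[n, k] <- acc
    }
  }
  lr <- sweep(LL, 2, e_lnpi, "+")
  lr <- lr - apply(lr, 1, max)
  r <- exp(lr) / rowSums(exp(lr))
  state$r <- r
  state$LL <- LL
  # q(pi)
  state$delta <- prior$delta0 + colSums(r)
  state$elbo <- naive_elbo(state, setup, K, prior)
  state
}

naive_elbo <- function(state, setup, K, prior) {
  N <- setup$N; M <- setup$M; D <- setup$D
  e_lnpi <- digamma(state$delta) - digamma(sum(state$delta))
  e_tau <- state$g_alpha / state$g_beta
  e_lntau <- digamma(state$g_alpha) - log(state$g_beta)
  t_z <- 0
  for (n in seq_len(N)) {
    for (m in seq_len(M)) {
      b <- setup$blocks[[n]][[m]]
      if (is.null(b)) next
      for (i in seq_along(b$y)) {
        mu <- state$mu[[n]][[m]][i]
        ez <- state$ez[[n]][[m]]$ez[i]
        s <- if (b$y[i] == 1) 1 else -1
        t_z <- t_z + 0.5 * mu^2 - mu * ez + pnorm(s * mu, log.p = TRUE)
      }
    }
  }
  t_z <- t_z + sum(state$r * state$LL)
  rl <- ifelse(state$r > 0, state$r * log(state$r), 0)
  t_c <- sum(sweep(state$r, 2, e_lnpi, "*")) - sum(rl)
  t_w <- 0
  for (k in seq_len(K)) {
    for (m in seq_len(M)) {
      wsq <- sum(state$Lambda[[k]][m, ]^2) + sum(diag(state$S[[k]][[m]]))
      t_w <- t_w + D / 2 * e_lntau[k] - 0.5 * e_tau[k] * wsq +
        0.5 * determinant(state$S[[k]][[m]])$modulus + D / 2
    }
  }
  d0 <- prior$delta0
  t_pi <- lgamma(K * d0) - K * lgamma(d0) - lgamma(sum(state$delta)) +
    sum(lgamma(state$delta)) + sum((d0 - state$delta) * e_lnpi)
  t_tau <- sum(prior$alpha0 * log(prior$beta0) - lgamma(prior$alpha0) +
                 (prior$alpha0 - 1) * e_lntau - prior$beta0 * e_tau -
                 (state$g_alpha * log(state$g_beta) - lgamma(state$g_alpha) +
                    (state$g_alpha - 1) * e_lntau - state$g_alpha))
  as.numeric(t_z + t_c + t_w + t_pi + t_tau)
}
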