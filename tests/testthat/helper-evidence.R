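# Brute-force log evidence ln p(Y | X) for a tiny intercept-only (D = 1)
# two-component model with one region, via enumeration over cluster
# assignments and nested numerical integration over the weight and its
# Gamma-distributed precision. The Dirichlet-multinomial assignment
# probability is available in closed form.

# p(Y_S) for the CpG states of the cells assigned to one component:
# int Gamma(tau | a0, b0) int N(w | 0, 1/tau) prod_i Phi(s_i * w) dw dtau
component_evidence <- function(signs, alpha0, beta0) {
  if (length(signs) == 0) return(1)
  inner <- function(tau) {
    vapply(tau, function(tt) {
      f <- function(w) {
        lik <- vapply(w, function(ww) {
          exp(sum(pnorm(signs * ww, log.p = TRUE)))
        }, numeric(1))
        dnorm(w, 0, sqrt(1 / tt)) * lik
      }
      stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
    }, numeric(1))
  }
  f_tau <- function(tau) dgamma(tau, alpha0, beta0) * inner(tau)
  stats::integrate(f_tau, 0, Inf, rel.tol = 1e-9)$value
}

# log p(Y) for N cells (each a vector of +-1 signs at intercept-only
# covariates), K components, symmetric Dirichlet delta0
brute_force_log_evidence <- function(sign_list, K, prior) {
  N <- length(sign_list)
  assignments <- as.matrix(expand.grid(rep(list(seq_len(K)), N)))
  total <- 0
  for (a in seq_len(nrow(assignments))) {
    cvec <- assignments[a, ]
    counts <- tabulate(cvec, K)
    log_p_c <- lgamma(K * prior$delta0) - lgamma(K * prior$delta0 + N) +
      sum(lgamma(prior$delta0 + counts) - lgamma(prior$delta0))
    log_lik <- 0
    for (k in seq_len(K)) {
      signs <- unlist(sign_list[cvec == k])
      log_lik <- log_lik + log(component_evidence(signs, prior$alpha0,
                                                  prior$beta0))
    }
    total <- total + exp(log_p_c + log_lik)
  }
  log(total)
}
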