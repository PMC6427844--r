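# Correctness of the coordinate-ascent variational inference engine.

test_that("vectorised sweep reproduces a naive loop-based implementation", {
  set.seed(11)
  sim <- tiny_sim(n_cells = 6, n_regions = 3, seed = 5)
  basis <- rbf_basis(2)
  prior <- prior_config("broad")
  K <- 2
  flat <- methmix:::flatten_dataset(sim$data, basis)
  setup <- naive_setup(sim$data, basis)
  r0 <- matrix(rgamma(6 * K, 1), 6, K)
  r0 <- r0 / rowSums(r0)

  state <- methmix:::init_state(flat, K, prior, r0)
  nstate <- naive_init(setup, K, prior, r0)
  for (sweep_i in 1:4) {
    state <- methmix:::cavi_sweep(state, flat, prior)
    nstate <- naive_sweep(nstate, setup, K, prior)
    expect_equal(state$r, nstate$r, tolerance = 1e-8)
    expect_equal(state$delta, nstate$delta, tolerance = 1e-8)
    for (k in seq_len(K)) {
      expect_equal(state$Lambda[[k]], nstate$Lambda[[k]], tolerance = 1e-8)
    }
    expect_equal(state$g_beta, nstate$g_beta, tolerance = 1e-8)
    expect_equal(state$elbo, nstate$elbo, tolerance = 1e-8)
  }
})

test_that("ELBO never exceeds the brute-force evidence on a tiny instance", {
  # 2 cells, 1 region, intercept-only basis, K = 2, 2 CpGs per cell
  dataset <- as_meth_dataset(tibble::tibble(
    cell = rep(c("a", "b"), each = 2),
    region = "r1",
    pos = rep(c(-0.3, 0.4), 2),
    state = c(1L, 1L, 0L, 1L)
  ))
  prior <- prior_config(delta0 = 0.5, alpha0 = 1.5, beta0 = 2)
  log_evidence <- brute_force_log_evidence(
    list(c(1, 1), c(-1, 1)), K = 2, prior = prior
  )
  fit <- fit_methmix(dataset, k = 2, basis = rbf_basis(0), prior = prior,
                     n_init = 3, seed = 1, tol = 1e-10, max_iter = 500)
  expect_lt(fit$elbo, log_evidence)
  # the bound should also be reasonably tight here
  expect_gt(fit$elbo, log_evidence - 1.5)
})

test_that("ELBO is non-decreasing across sweeps and conserves Dirichlet mass", {
  sim <- tiny_sim(n_cells = 20, n_regions = 4, seed = 8)
  prior <- prior_config("broad")
  K <- 3
  flat <- methmix:::flatten_dataset(sim$data, rbf_basis(4))
  set.seed(2)
  r0 <- methmix:::initial_responsibilities(sim$data, flat, K, "random")
  state <- methmix:::init_state(flat, K, prior, r0)
  elbos <- numeric(25)
  for (i in seq_along(elbos)) {
    state <- methmix:::cavi_sweep(state, flat, prior)
    elbos[i] <- state$elbo
    expect_equal(rowSums(state$r), rep(1, flat$N), tolerance = 1e-8)
    expect_equal(sum(state$delta), K * prior$delta0 + flat$N,
                 tolerance = 1e-8)
  }
  expect_true(all(diff(elbos) > -1e-6 * abs(elbos[-1])))
})

test_that("a converged state is a fixed point of the sweep", {
  sim <- tiny_sim(n_cells = 10, n_regions = 3, seed = 3)
  prior <- prior_config("broad")
  flat <- methmix:::flatten_dataset(sim$data, rbf_basis(2))
  set.seed(4)
  r0 <- methmix:::initial_responsibilities(sim$data, flat, 2, "kmeans")
  state <- methmix:::init_state(flat, 2, prior, r0)
  for (i in 1:2000) {
    prev <- state$elbo
    state <- methmix:::cavi_sweep(state, flat, prior)
    if (is.finite(prev) && abs(state$elbo - prev) < 1e-14 * abs(prev)) break
  }
  again <- methmix:::cavi_sweep(state, flat, prior)
  expect_equal(again$r, state$r, tolerance = 1e-6)
  expect_equal(again$Lambda, state$Lambda, tolerance = 1e-6)
  expect_equal(again$elbo, state$elbo, tolerance = 1e-10)
})

test_that("the ELBO is invariant under component relabelling", {
  sim <- tiny_sim(n_cells = 12, n_regions = 3, seed = 6)
  prior <- prior_config("broad")
  K <- 3
  flat <- methmix:::flatten_dataset(sim$data, rbf_basis(2))
  set.seed(5)
  r0 <- methmix:::initial_responsibilities(sim$data, flat, K, "random")
  state <- methmix:::init_state(flat, K, prior, r0)
  for (i in 1:5) state <- methmix:::cavi_sweep(state, flat, prior)
  perm <- c(3, 1, 2)
  pstate <- state
  pstate$r <- state$r[, perm]
  pstate$delta <- state$delta[perm]
  pstate$Lambda <- state$Lambda[perm]
  pstate$Spack <- state$Spack[perm]
  pstate$logdetS <- state$logdetS[, perm]
  pstate$trS <- state$trS[, perm]
  pstate$wsq <- state$wsq[, perm]
  pstate$g_alpha <- state$g_alpha[perm]
  pstate$g_beta <- state$g_beta[perm]
  pstate$LL <- state$LL[, perm]
  expect_equal(methmix:::cavi_elbo(pstate, flat, prior), state$elbo,
               tolerance = 1e-10)
})

test_that("cluster recovery and diagnostic pruning work on simulated data", {
  sim <- tiny_sim(n_cells = 80, n_regions = 15, seed = 21)
  fit <- fit_methmix(sim$data, k = 8, n_init = 2, seed = 1)
  expect_equal(fit$effective_k, 4L)
  expect_gte(adjusted_rand_index(fit$hard_labels, sim$truth$labels$label),
             0.95)
  expect_true(fit$converged)
  # occupancy counting conventions
  r_onehot <- matrix(0, 10, 3)
  r_onehot[, 2] <- 1
  mock <- structure(list(r = r_onehot), class = "methmix_fit")
  expect_equal(effective_clusters(mock), 1L)
  r_unif <- matrix(1 / 3, 10, 3)
  mock$r <- r_unif
  expect_equal(effective_clusters(mock), 3L)
})

test_that("restarts pick the highest-ELBO solution deterministically", {
  sim <- tiny_sim(n_cells = 20, n_regions = 4, seed = 13)
  f1 <- fit_methmix(sim$data, k = 3, n_init = 2, seed = 7, max_iter = 60)
  f2 <- fit_methmix(sim$data, k = 3, n_init = 2, seed = 7, max_iter = 60)
  expect_identical(f1$elbo, f2$elbo)
  expect_identical(f1$r, f2$r)
  expect_error(fit_methmix(sim$data, k = 0), "positive")
})
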