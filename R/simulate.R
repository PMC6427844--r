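#' Configuration for the synthetic single-cell methylome generator
#'
#' The generator emulates a single-cell bisulfite experiment with known
#' sub-population structure: `n_clusters` groups of cells in fixed
#' proportions, each region carrying a latent methylation profile drawn
#' from a small set of prototypes. A `dissimilarity` fraction of regions
#' have their prototypes re-drawn independently per cluster, so clusters
#' differ there; the remaining regions share one prototype across clusters.
#' Binary CpG states are Bernoulli draws from the profile with Gaussian
#' noise added to the success probability, mimicking bisulfite conversion
#' error.
#'
#' @param n_cells Number of cells N (default 200).
#' @param n_regions Number of genomic regions M (default 100).
#' @param n_clusters Number of cell sub-populations K (default 4).
#' @param proportions Sub-population proportions, length `n_clusters`
#'   summing to 1 (default 40/25/20/15%).
#' @param dissimilarity Fraction of regions whose profiles differ between
#'   clusters, in `[0, 1]` (default 0.5).
#' @param coverage Expected fraction of a region's CpG grid observed per
#'   cell (default 0.4).
#' @param cpgs_per_region Maximal CpG count per region (default 50).
#' @param noise_sd Standard deviation of the Gaussian noise added to each
#'   CpG's success probability (default 0.05).
#' @param seed Integer seed.
#' @param multinomial_labels If TRUE cluster sizes are drawn multinomially
#'   instead of the default exact block counts.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cells = 200, n_regions = 100, n_clusters = 4,
                       proportions = c(0.40, 0.25, 0.20, 0.15),
                       dissimilarity = 0.5, coverage = 0.4,
                       cpgs_per_region = 50, noise_sd = 0.05, seed = 1,
                       multinomial_labels = FALSE) {
  stopifnot(n_cells >= 1, n_regions >= 1, n_clusters >= 1,
            length(proportions) == n_clusters,
            abs(sum(proportions) - 1) < 1e-8,
            dissimilarity >= 0, dissimilarity <= 1,
            coverage > 0, coverage <= 1,
            cpgs_per_region >= 1, noise_sd >= 0)
  structure(
    list(n_cells = as.integer(n_cells), n_regions = as.integer(n_regions),
         n_clusters = as.integer(n_clusters),
         proportions = as.numeric(proportions),
         dissimilarity = dissimilarity, coverage = coverage,
         cpgs_per_region = as.integer(cpgs_per_region),
         noise_sd = noise_sd, seed = as.integer(seed),
         multinomial_labels = isTRUE(multinomial_labels)),
    class = "sim_config"
  )
}

#' Prototype methylation profiles
#'
#' Five qualitatively distinct latent profiles — flat-high, flat-low,
#' rising, falling, and dip-at-centre — expressed as weight vectors in the
#' given basis. Each target shape is projected onto the basis by least
#' squares on the probit scale over a dense grid, so the same shapes are
#' available for any basis with at least two bumps. User-supplied weight
#' matrices can be passed to [simulate_dataset()] instead.
#'
#' @param basis An [rbf_basis()] with `n_rbf >= 2`.
#' @param n_prototypes Number of prototypes (currently the built-in five).
#' @return A numeric matrix, one prototype per row, `basis$D` columns.
#' @export
make_prototypes <- function(basis, n_prototypes = 5) {
  stopifnot(inherits(basis, "rbf_basis"))
  if (basis$n_rbf < 2) {
    stop("need at least 2 RBFs to express non-flat prototypes",
         call. = FALSE)
  }
  if (n_prototypes != 5) {
    stop("only the 5 built-in prototypes are available; pass a weight ",
         "matrix to simulate_dataset() for custom profiles", call. = FALSE)
  }
  shapes <- list(
    flat_high = function(x) rep(0.90, length(x)),
    flat_low  = function(x) rep(0.08, length(x)),
    rising    = function(x) 0.10 + 0.80 * stats::pnorm(2.5 * x),
    falling   = function(x) 0.90 - 0.80 * stats::pnorm(2.5 * x),
    dip       = function(x) 0.85 - 0.80 * exp(-4 * x^2)
  )
  grid <- seq(basis$domain[1], basis$domain[2], length.out = 101)
  H <- design_matrix(grid, basis)
  W <- t(vapply(shapes, function(f) {
    target <- stats::qnorm(pmin(pmax(f(grid), 1e-4), 1 - 1e-4))
    stats::lsfit(H, target, intercept = FALSE)$coefficients
  }, numeric(basis$D)))
  rownames(W) <- names(shapes)
  W
}

#' Evaluate a profile (methylation probability) from basis weights
#'
#' @param positions Scaled positions in the basis domain.
#' @param w Weight vector of length `basis$D`.
#' @param basis An [rbf_basis()].
#' @return `pnorm(design_matrix(positions) %*% w)` as a numeric vector.
#' @export
profile_probability <- function(positions, w, basis) {
  as.numeric(stats::pnorm(design_matrix(positions, basis) %*% w))
}

#' Simulate a clustered single-cell methylome dataset
#'
#' See [sim_config()] for the generative mechanics. Cluster labels use
#' exact block counts (`round(p_k * N)`, remainder to the largest cluster)
#' and are then shuffled, so the stated proportions are reproduced exactly.
#'
#' @param config A [sim_config()].
#' @param basis An [rbf_basis()] (default `rbf_basis(4)`).
#' @param prototypes Optional weight matrix (rows = prototypes) overriding
#'   [make_prototypes()].
#' @return A list with elements:
#'   * `data`: a methylome dataset tibble (`cell`, `region`, `pos`,
#'     `state`),
#'   * `truth`: a list with `labels` (tibble `cell`, `label`),
#'     `profile_assignment` (M x K matrix of prototype row indices) and
#'     `prototypes` (the weight matrix),
#'   * `config`, `basis`.
#' @export
simulate_dataset <- function(config = sim_config(), basis = rbf_basis(4),
                             prototypes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  W <- prototypes %||% make_prototypes(basis)
  stopifnot(ncol(W) == basis$D, nrow(W) >= 1)
  n_proto <- nrow(W)
  N <- config$n_cells; M <- config$n_regions; K <- config$n_clusters

  set.seed(config$seed)
  # -- cluster labels ------------------------------------------------------
  if (config$multinomial_labels) {
    labels <- sample.int(K, N, replace = TRUE, prob = config$proportions)
  } else {
    counts <- round(config$proportions * N)
    counts[which.max(counts)] <- counts[which.max(counts)] + (N - sum(counts))
    labels <- sample(rep.int(seq_len(K), counts))
  }

  # -- region prototype assignment ----------------------------------------
  base_proto <- sample.int(n_proto, M, replace = TRUE)
  assignment <- matrix(base_proto, nrow = M, ncol = K)
  n_diff <- ceiling(config$dissimilarity * M)
  diff_regions <- if (n_diff > 0) sample.int(M, n_diff) else integer(0)
  for (m in diff_regions) {
    assignment[m, ] <- sample.int(n_proto, K, replace = TRUE)
  }

  # -- observations --------------------------------------------------------
  counts_nm <- matrix(
    stats::rbinom(N * M, config$cpgs_per_region, config$coverage),
    nrow = N, ncol = M
  )
  total <- sum(counts_nm)
  cell_idx <- rep(rep(seq_len(N), times = M), times = as.vector(counts_nm))
  region_idx <- rep(rep(seq_len(M), each = N), times = as.vector(counts_nm))
  # note: as.vector(counts_nm) runs column-major, i.e. region-major blocks
  pos <- stats::runif(total, -1, 1)
  H <- design_matrix(pos, basis)
  proto_idx <- assignment[cbind(region_idx, labels[cell_idx])]
  eta <- rowSums(H * W[proto_idx, , drop = FALSE])
  prob <- stats::pnorm(eta)
  if (config$noise_sd > 0) {
    prob <- prob + stats::rnorm(total, 0, config$noise_sd)
  }
  prob <- pmin(pmax(prob, 1e-6), 1 - 1e-6)
  state <- stats::rbinom(total, 1L, prob)

  cell_ids <- sprintf("cell_%03d", seq_len(N))
  region_ids <- sprintf("region_%03d", seq_len(M))
  data <- tibble::tibble(
    cell = cell_ids[cell_idx],
    region = region_ids[region_idx],
    pos = pos,
    state = as.integer(state)
  ) |>
    dplyr::arrange(.data$cell, .data$region, .data$pos)
  data <- as_meth_dataset(data, cells = cell_ids, regions = region_ids)

  truth <- list(
    labels = tibble::tibble(cell = cell_ids, label = labels),
    profile_assignment = assignment,
    prototypes = W
  )
  list(data = data, truth = truth, config = config, basis = basis)
}

#' Grids of simulated datasets along one experimental axis
#'
#' Reproduces the simulation-study designs: 11 datasets varying cluster
#' dissimilarity from 0 to 1, or grids over the number of cells or the CpG
#' coverage. Exactly one axis may be varied; per-dataset seeds are derived
#' from the base seed plus the grid index.
#'
#' @param base A [sim_config()] providing the non-varied settings.
#' @param vary A named list with exactly one element: `dissimilarity`,
#'   `n_cells` or `coverage`, giving the grid values.
#' @param basis An [rbf_basis()].
#' @return A tibble with columns `axis`, `value`, and list-columns
#'   `config`, `data`, `truth`.
#' @export
experiment_grid <- function(base = sim_config(),
                            vary = list(dissimilarity = seq(0, 1, by = 0.1)),
                            basis = rbf_basis(4)) {
  stopifnot(length(vary) == 1,
            names(vary) %in% c("dissimilarity", "n_cells", "coverage"))
  axis <- names(vary)
  values <- vary[[1]]
  sims <- purrr::imap(values, function(v, i) {
    cfg <- unclass(base)
    cfg[[axis]] <- v
    cfg$seed <- base$seed + i
    cfg <- do.call(sim_config, cfg)
    sim <- simulate_dataset(cfg, basis)
    list(config = cfg, data = sim$data, truth = sim$truth)
  })
  tibble::tibble(
    axis = axis,
    value = as.numeric(values),
    config = purrr::map(sims, "config"),
    data = purrr::map(sims, "data"),
    truth = purrr::map(sims, "truth")
  )
}
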