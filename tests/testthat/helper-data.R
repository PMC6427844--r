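# Small datasets shared across test files. Everything is generated in code;
# sizes are kept tiny so the whole suite stays fast.

tiny_sim <- function(n_cells = 30, n_regions = 6, seed = 42, ...) {
  simulate_dataset(sim_config(n_cells = n_cells, n_regions = n_regions,
                              cpgs_per_region = 25, seed = seed, ...))
}

# a hand-built dataset: 2 cells x 2 regions with fixed CpGs
handmade_dataset <- function() {
  as_meth_dataset(tibble::tibble(
    cell = rep(c("a", "b"), each = 6),
    region = rep(rep(c("r1", "r2"), each = 3), 2),
    pos = rep(c(-0.5, 0, 0.5), 4),
    state = c(1L, 1L, 0L, 0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L, 1L)
  ))
}

# two-cluster data where profiles are flat (rate-only structure): cluster 1
# hyper-methylated, cluster 2 hypo-methylated
rate_structured_sim <- function(n_cells = 40, n_regions = 8, seed = 7) {
  basis <- rbf_basis(4)
  W <- make_prototypes(basis)[c("flat_high", "flat_low"), ]
  simulate_dataset(
    sim_config(n_cells = n_cells, n_regions = n_regions, n_clusters = 2,
               proportions = c(0.5, 0.5), dissimilarity = 1,
               cpgs_per_region = 25, noise_sd = 0, seed = seed),
    basis, prototypes = W
  )
}

write_tsv_lines <- function(lines, file = tempfile(fileext = ".tsv")) {
  writeLines(lines, file)
  file
}
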