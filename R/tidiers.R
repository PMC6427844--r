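#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a variational mixture fit
#'
#' One row per (cell, cluster) with the posterior responsibility, plus the
#' hard label for convenience.
#'
#' @param x A `methmix_fit`.
#' @param ... Unused.
#' @return A tibble `cell`, `cluster`, `responsibility`, `hard_label`.
#' @export
tidy.methmix_fit <- function(x, ...) {
  tibble::tibble(
    cell = rep(x$cells, times = x$k),
    cluster = rep(seq_len(x$k), each = length(x$cells)),
    responsibility = as.numeric(x$r),
    hard_label = rep(x$hard_labels, times = x$k)
  ) |>
    dplyr::arrange(.data$cell, .data$cluster)
}

#' @rdname tidy.methmix_fit
#' @export
glance.methmix_fit <- function(x, ...) {
  tibble::tibble(
    n_cells = length(x$cells),
    n_regions = length(x$regions),
    n_cpgs = x$n_obs,
    k = x$k,
    effective_k = x$effective_k,
    elbo = x$elbo,
    n_iter = x$n_iter,
    converged = x$converged,
    basis_d = x$basis$D
  )
}

#' Tidy a Gibbs run
#'
#' Posterior draws of the mixing proportions and precisions in long form.
#'
#' @param x A `methmix_gibbs`.
#' @param ... Unused.
#' @return A tibble `draw`, `cluster`, `pi`, `tau`.
#' @export
tidy.methmix_gibbs <- function(x, ...) {
  n_draws <- nrow(x$pi)
  tibble::tibble(
    draw = rep(seq_len(n_draws), times = x$k),
    cluster = rep(seq_len(x$k), each = n_draws),
    pi = as.numeric(x$pi),
    tau = as.numeric(x$tau)
  )
}

#' @rdname tidy.methmix_gibbs
#' @export
glance.methmix_gibbs <- function(x, ...) {
  tibble::tibble(
    n_cells = length(x$cells),
    n_regions = length(x$regions),
    k = x$k,
    n_draws = nrow(x$labels),
    n_iter = x$n_iter,
    burn_in = x$burn_in,
    thin = x$thin
  )
}

#' Serialise a fit to a plain-text archive
#'
#' Writes every array of the variational state plus the basis, prior and
#' run metadata to a single JSON file; [read_methmix_fit()] reconstructs a
#' fit whose predictions are identical to the original's.
#'
#' @param fit A `methmix_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_methmix_fit <- function(fit, path) {
  stopifnot(inherits(fit, "methmix_fit"))
  obj <- unclass(fit)
  obj$basis <- basis_to_list(fit$basis)
  obj$prior <- unclass(fit$prior)
  obj$r <- as.data.frame(fit$r)
  obj$Lambda <- lapply(fit$Lambda, as.data.frame)
  obj$Spack <- lapply(fit$Spack, as.data.frame)
  obj$logdetS <- as.data.frame(fit$logdetS)
  obj$trS <- as.data.frame(fit$trS)
  # I(17) significant digits: doubles survive the text round-trip exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_methmix_fit
#' @export
read_methmix_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$basis <- basis_from_list(obj$basis)
  obj$prior <- structure(obj$prior, class = "prior_config")
  obj$r <- as.matrix(obj$r)
  dimnames(obj$r) <- NULL
  obj$Lambda <- lapply(obj$Lambda, function(d) unname(as.matrix(d)))
  obj$Spack <- lapply(obj$Spack, function(d) unname(as.matrix(d)))
  obj$logdetS <- unname(as.matrix(obj$logdetS))
  obj$trS <- unname(as.matrix(obj$trS))
  structure(obj, class = "methmix_fit")
}
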