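#' Radial basis function representation of CpG positions
#'
#' Methylation profiles are modelled as probit-linear functions of a fixed
#' basis expansion of the (scaled) CpG coordinate. The basis consists of an
#' intercept column plus `n_rbf` Gaussian bumps with evenly spaced centres,
#' so the design dimension is `D = n_rbf + 1`. With `n_rbf = 0` every profile
#' collapses to a constant, i.e. a per-region methylation rate.
#'
#' Centres are placed at the interior points of an `(n_rbf + 1)`-way even
#' partition of the domain, and the width parameter `gamma` is chosen so that
#' adjacent bumps overlap at about half of their peak value
#' (`gamma = 1 / (2 s^2)` with `s` the centre spacing). Both can be
#' overridden.
#'
#' @param n_rbf Number of radial basis functions (>= 0).
#' @param domain Numeric length-2 vector, the interval positions live on.
#'   Positions are expected pre-scaled to this interval (default `[-1, 1]`).
#' @param gamma Optional positive width override (inverse squared
#'   length-scale shared by all bumps).
#' @param centers Optional strictly increasing vector of centres overriding
#'   the even placement; its length defines `n_rbf`.
#'
#' @return An object of class `rbf_basis`: a list with elements `n_rbf`,
#'   `centers`, `gamma`, `domain` and `D`.
#' @examples
#' rbf_basis(4)
#' rbf_basis(0) # intercept-only: the "rate" configuration
#' @export
rbf_basis <- function(n_rbf = 4, domain = c(-1, 1), gamma = NULL,
                      centers = NULL) {
  if (!is.null(centers)) {
    stopifnot(is.numeric(centers), !is.unsorted(centers, strictly = TRUE))
    n_rbf <- length(centers)
  }
  if (length(n_rbf) != 1 || is.na(n_rbf) || n_rbf < 0 ||
      n_rbf != round(n_rbf)) {
    stop("`n_rbf` must be a single non-negative integer", call. = FALSE)
  }
  n_rbf <- as.integer(n_rbf)
  stopifnot(length(domain) == 2, domain[1] < domain[2])
  if (is.null(centers)) {
    # interior points of an (n_rbf + 1)-way even partition of the domain
    centers <- if (n_rbf > 0) {
      domain[1] + diff(domain) * seq_len(n_rbf) / (n_rbf + 1)
    } else {
      numeric(0)
    }
  }
  if (is.null(gamma)) {
    gamma <- if (n_rbf >= 2) {
      s <- centers[2] - centers[1]
      1 / (2 * s^2)
    } else if (n_rbf == 1) {
      # lone bump: use the half-domain as its length-scale
      1 / (2 * (diff(domain) / 2)^2)
    } else {
      NA_real_
    }
  }
  if (n_rbf > 0 && (!is.numeric(gamma) || gamma <= 0)) {
    stop("`gamma` must be a positive number", call. = FALSE)
  }
  structure(
    list(n_rbf = n_rbf, centers = as.numeric(centers),
         gamma = as.numeric(gamma), domain = as.numeric(domain),
         D = n_rbf + 1L),
    class = "rbf_basis"
  )
}

#' @export
print.rbf_basis <- function(x, ...) {
  cat(sprintf("<rbf_basis> D = %d (intercept + %d RBFs)\n", x$D, x$n_rbf))
  if (x$n_rbf > 0) {
    cat("  centers:", paste(signif(x$centers, 4), collapse = ", "), "\n")
    cat("  gamma:  ", signif(x$gamma, 6), "\n")
  }
  invisible(x)
}

#' Evaluate the basis design matrix
#'
#' @param positions Numeric vector of scaled positions inside the basis
#'   domain.
#' @param basis An [rbf_basis()] object.
#' @return A `length(positions) x D` matrix; first column all ones, column
#'   `j + 1` equals `exp(-gamma * (x - center_j)^2)`.
#' @examples
#' H <- design_matrix(c(-0.5, 0, 0.5), rbf_basis(3))
#' @export
design_matrix <- function(positions, basis) {
  stopifnot(inherits(basis, "rbf_basis"), is.numeric(positions))
  eps <- 1e-9 # guard against representation error at the boundary
  if (length(positions) &&
      (min(positions) < basis$domain[1] - eps ||
       max(positions) > basis$domain[2] + eps)) {
    stop("positions outside the basis domain [",
         basis$domain[1], ", ", basis$domain[2],
         "]; check the upstream coordinate scaling", call. = FALSE)
  }
  n <- length(positions)
  H <- matrix(1, nrow = n, ncol = basis$D)
  for (j in seq_len(basis$n_rbf)) {
    H[, j + 1L] <- exp(-basis$gamma * (positions - basis$centers[j])^2)
  }
  colnames(H) <- c("intercept",
                   if (basis$n_rbf > 0) paste0("rbf", seq_len(basis$n_rbf)))
  H
}

#' Serialise / deserialise a basis configuration
#'
#' Round-trips through a plain list so run configs written as JSON or YAML
#' reproduce the exact basis.
#'
#' @param basis An [rbf_basis()] object.
#' @return `basis_to_list()` returns a plain list; `basis_from_list()` the
#'   reconstructed `rbf_basis`.
#' @keywords internal
#' @export
basis_to_list <- function(basis) {
  unclass(basis)[c("n_rbf", "centers", "gamma", "domain")]
}

#' @rdname basis_to_list
#' @param x A list as produced by `basis_to_list()`.
#' @export
basis_from_list <- function(x) {
  rbf_basis(n_rbf = x$n_rbf, domain = x$domain,
            gamma = if (x$n_rbf > 0) x$gamma else NULL,
            centers = if (x$n_rbf > 0) x$centers else NULL)
}
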