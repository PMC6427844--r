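#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the ELBO trace of a variational fit
#'
#' @param object A `methmix_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.methmix_fit <- function(object, ...) {
  d <- tibble::tibble(sweep = seq_along(object$elbo_trace),
                      elbo = object$elbo_trace)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sweep, y = .data$elbo)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "CAVI sweep", y = "ELBO",
                  title = "Evidence lower bound trace") +
    ggplot2::theme_minimal()
}

#' Plot posterior methylation profiles per cluster
#'
#' Draws each occupied cluster's posterior mean methylation profile (with a
#' pointwise predictive band from the weight posterior) over a grid of
#' scaled positions for the chosen regions.
#'
#' @param fit A `methmix_fit`.
#' @param regions Region identifiers to show (default: the first 4).
#' @param grid_size Number of grid points per region.
#' @param min_cells Occupancy threshold below which a cluster is omitted.
#' @return A ggplot, faceted by region.
#' @export
plot_profiles <- function(fit, regions = NULL, grid_size = 101,
                          min_cells = 1) {
  stopifnot(inherits(fit, "methmix_fit"))
  regions <- regions %||% utils::head(fit$regions, 4)
  occupied <- which(colSums(fit$r) > min_cells)
  grid <- seq(-1, 1, length.out = grid_size)
  H <- design_matrix(grid, fit$basis)
  mult <- 2 - (fit$pair_j == fit$pair_l)
  Hout <- H[, fit$pair_j, drop = FALSE] * H[, fit$pair_l, drop = FALSE]
  d <- purrr::map_dfr(regions, function(rg) {
    m <- match(rg, fit$regions)
    if (is.na(m)) stop("unknown region: ", rg, call. = FALSE)
    purrr::map_dfr(occupied, function(k) {
      eta <- as.numeric(H %*% fit$Lambda[[k]][m, ])
      quad <- as.numeric(Hout %*% (fit$Spack[[k]][m, ] * mult))
      tibble::tibble(
        region = rg, cluster = factor(k), pos = grid,
        prob = stats::pnorm(eta / sqrt(1 + quad)),
        lower = stats::pnorm((eta - 2 * sqrt(quad)) / sqrt(1 + quad)),
        upper = stats::pnorm((eta + 2 * sqrt(quad)) / sqrt(1 + quad))
      )
    })
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$prob,
                                  colour = .data$cluster,
                                  fill = .data$cluster)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~region) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "scaled position", y = "methylation probability") +
    ggplot2::theme_minimal()
}

#' Plot a precision-recall curve
#'
#' @param predictions Output of [impute_dataset()].
#' @return A ggplot.
#' @export
plot_pr_curve <- function(predictions) {
  curve <- precision_recall_curve(predictions$prob, predictions$true_state)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$recall,
                                      y = .data$precision)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "recall", y = "precision") +
    ggplot2::theme_minimal()
}
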