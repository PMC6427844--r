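#' Predict methylation probabilities at arbitrary CpG positions
#'
#' The posterior predictive probability of methylation at position `x` in
#' region `m` is a mixture over clusters of probit predictions that
#' integrate over the Gaussian weight posterior:
#' `p(y = 1) = sum_k w_k * Phi(h(x)' lambda_mk / sqrt(1 + h(x)' S_mk h(x)))`.
#'
#' For a cell seen during training the mixture weights default to that
#' cell's responsibilities (its cluster assignment was inferred from its
#' training CpGs); for an unseen cell (`cell = "new"` or
#' `weights = "prior"`), the posterior mixing proportions
#' `delta_k / sum_j delta_j` are used.
#'
#' @param fit A `methmix_fit`.
#' @param cell A cell identifier from the training set, or `"new"`.
#' @param region A region identifier from the training set.
#' @param positions Scaled positions in `[-1, 1]`.
#' @param weights `"responsibility"` (default for training cells) or
#'   `"prior"`.
#' @return A tibble with columns `cell`, `region`, `pos`, `prob`,
#'   `pred_state`. Probabilities are clamped to `(1e-10, 1 - 1e-10)` so
#'   downstream log-metrics stay finite.
#' @export
predict_cpgs <- function(fit, cell, region, positions,
                         weights = c("responsibility", "prior")) {
  stopifnot(inherits(fit, "methmix_fit"))
  weights <- match.arg(weights)
  m <- match(region, fit$regions)
  if (is.na(m)) stop("unknown region: ", region, call. = FALSE)
  if (identical(cell, "new")) weights <- "prior"
  w <- if (weights == "prior") {
    fit$delta / sum(fit$delta)
  } else {
    n <- match(cell, fit$cells)
    if (is.na(n)) {
      stop("unknown cell '", cell, "'; use cell = \"new\" for unseen cells",
           call. = FALSE)
    }
    fit$r[n, ]
  }
  H <- design_matrix(positions, fit$basis)
  mult <- 2 - (fit$pair_j == fit$pair_l)
  Hout <- H[, fit$pair_j, drop = FALSE] * H[, fit$pair_l, drop = FALSE]
  p <- numeric(length(positions))
  for (k in seq_len(fit$k)) {
    eta <- as.numeric(H %*% fit$Lambda[[k]][m, ])
    quad <- as.numeric(Hout %*% (fit$Spack[[k]][m, ] * mult))
    p <- p + w[k] * stats::pnorm(eta / sqrt(1 + quad))
  }
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  tibble::tibble(cell = as.character(cell), region = as.character(region),
                 pos = as.numeric(positions), prob = p,
                 pred_state = as.integer(p > 0.5))
}

#' Impute all held-out CpGs of a test dataset
#'
#' Applies the posterior predictive of [predict_cpgs()] to every row of a
#' held-out methylome dataset, carrying the true states for evaluation.
#' Every test CpG receives exactly one prediction.
#'
#' @param fit A `methmix_fit` (or a baseline fit providing the same
#'   interface).
#' @param test A methylome dataset tibble whose regions are a subset of the
#'   fit's regions.
#' @param weights `"responsibility"` (default) or `"prior"` cluster
#'   weights; see [predict_cpgs()].
#' @param threshold Binarisation threshold (default 0.5).
#' @return A tibble `cell`, `region`, `pos`, `prob`, `pred_state`,
#'   `true_state` with one row per test CpG.
#' @export
impute_dataset <- function(fit, test,
                           weights = c("responsibility", "prior"),
                           threshold = 0.5) {
  UseMethod("impute_dataset")
}

#' @export
impute_dataset.methmix_fit <- function(fit, test,
                                       weights = c("responsibility",
                                                   "prior"),
                                       threshold = 0.5) {
  weights <- match.arg(weights)
  if (nrow(test) == 0) {
    return(tibble::tibble(cell = character(), region = character(),
                          pos = double(), prob = double(),
                          pred_state = integer(), true_state = integer()))
  }
  region_idx <- match(test$region, fit$regions)
  if (anyNA(region_idx)) {
    stop("test regions not present in the fit: ",
         paste(utils::head(unique(test$region[is.na(region_idx)]), 3),
               collapse = ", "), call. = FALSE)
  }
  cell_idx <- match(test$cell, fit$cells)
  if (weights == "responsibility" && anyNA(cell_idx)) {
    stop("test cells not present in the fit; use weights = \"prior\"",
         call. = FALSE)
  }
  W <- if (weights == "prior") {
    matrix(fit$delta / sum(fit$delta), nrow(test), fit$k, byrow = TRUE)
  } else {
    fit$r[cell_idx, , drop = FALSE]
  }
  H <- design_matrix(test$pos, fit$basis)
  mult <- 2 - (fit$pair_j == fit$pair_l)
  Hout <- H[, fit$pair_j, drop = FALSE] * H[, fit$pair_l, drop = FALSE]
  HoutM <- Hout * rep(mult, each = nrow(test))
  p <- numeric(nrow(test))
  for (k in seq_len(fit$k)) {
    eta <- rowSums(H * fit$Lambda[[k]][region_idx, , drop = FALSE])
    quad <- rowSums(HoutM * fit$Spack[[k]][region_idx, , drop = FALSE])
    p <- p + W[, k] * stats::pnorm(eta / sqrt(1 + quad))
  }
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  tibble::tibble(cell = test$cell, region = test$region, pos = test$pos,
                 prob = p, pred_state = as.integer(p > threshold),
                 true_state = as.integer(test$state))
}

#' Export predictions and metrics
#'
#' Writes a prediction table as tab-separated values together with a JSON
#' sidecar of summary metrics.
#'
#' @param predictions Output of [impute_dataset()].
#' @param path Output TSV path; the sidecar is written next to it as
#'   `<path>.metrics.json`.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  readr::write_tsv(predictions, path, progress = FALSE)
  metrics <- evaluate_imputation(predictions)
  jsonlite::write_json(as.list(metrics),
                       paste0(path, ".metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
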