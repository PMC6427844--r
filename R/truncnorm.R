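#' Moments of the augmented truncated-normal variable
#'
#' The probit likelihood is handled by augmentation with a latent Gaussian
#' `z ~ N(mu, 1)` whose sign generates the binary observation. Conditioned
#' on the observed state, `z` follows a unit-variance normal truncated to
#' `(0, Inf)` when `y = 1` and `(-Inf, 0]` when `y = 0`. This returns its
#' first two moments, computed with log-scale Mills ratios so the result is
#' accurate for `|mu|` well beyond 30.
#'
#' For `y = 1`: `E[z] = mu + phi(mu)/Phi(mu)`; for `y = 0`:
#' `E[z] = mu - phi(mu)/Phi(-mu)`. In both cases
#' `E[z^2] = 1 + mu * E[z]`.
#'
#' @param mu Numeric vector of untruncated means.
#' @param y Binary vector (recycled) of observed states.
#' @return A list with numeric vectors `ez` and `ez2`.
#' @examples
#' truncnorm_moments(0, 1)$ez # sqrt(2/pi)
#' @export
truncnorm_moments <- function(mu, y) {
  stopifnot(all(is.finite(mu)), all(y %in% c(0, 1)))
  y <- rep_len(y, length(mu))
  s <- 2 * y - 1 # +1 when truncated to positive z, -1 otherwise
  # Mills ratio phi(s*mu)/Phi(s*mu) on the log scale
  mills <- exp(stats::dnorm(s * mu, log = TRUE) -
                 stats::pnorm(s * mu, log.p = TRUE))
  ez <- mu + s * mills
  list(ez = ez, ez2 = 1 + mu * ez)
}
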