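#' Heavy-tailed Levy-flight step vector
#'
#' Draws `dim` independent heavy-tailed step lengths scaled by `alpha`,
#' using Mantegna's algorithm with stability index `beta = lambda`:
#' `step = alpha * u / |v|^(1/beta)` with `u ~ N(0, sigma_u^2)`,
#' `v ~ N(0, 1)` and
#' `sigma_u = [Gamma(1+beta) sin(pi beta / 2) /
#'             (Gamma((1+beta)/2) beta 2^((beta-1)/2))]^(1/beta)`.
#' The resulting |step| distribution has a power-law tail with tail index
#' `beta`, mixing many small moves with rare long jumps.  Mantegna's
#' construction is defined for stability index below 2; exponents at or
#' above 2 (finite-variance regime) are clamped to 1.99 with a warning.
#'
#' @param lambda tail exponent, in the open interval (1, 3); default 1.5.
#' @param alpha nonnegative step scale; `alpha = 0` gives an exactly zero
#'   vector (the random stream is still advanced, preserving determinism of
#'   surrounding code).
#' @param dim number of components.
#' @return numeric vector of length `dim`.
#' @examples
#' set.seed(1); levy_step(1.5, 1, 5)
#' @export
levy_step <- function(lambda = 1.5, alpha = 1, dim = 1L) {
  if (!is.finite(lambda) || lambda <= 1 || lambda >= 3) {
    stop("lambda must lie in the open interval (1, 3)", call. = FALSE)
  }
  if (!is.finite(alpha) || alpha < 0) {
    stop("alpha must be a nonnegative finite number", call. = FALSE)
  }
  beta <- lambda
  if (beta >= 2) {
    warning("lambda >= 2: clamping Mantegna stability index to 1.99",
            call. = FALSE)
    beta <- 1.99
  }
  sigma_u <- (gamma(1 + beta) * sin(pi * beta / 2) /
                (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  u <- stats::rnorm(dim, sd = sigma_u)
  v <- stats::rnorm(dim)
  alpha * u / abs(v)^(1 / beta)
}
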