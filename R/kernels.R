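#' Full-conditional sampling kernels
#'
#' Single draws from the fully conditional posterior distributions used by the
#' Gibbs samplers. The compiled sweep in [run_snp_blup()] and [run_grouped()]
#' implements the same conditionals; these R versions are the documented
#' reference and are convenient for validation work.
#'
#' * `sample_mu()`: the general mean, `N(mean(offsets), sigma_e2 / n)` where
#'   `offsets` are `y_i - sum_j x_ij beta_j`.
#' * `sample_beta_j()`: one marker effect, `N(rhs / C, sigma_e2 / C)` with
#'   `C = x_j'x_j + sigma_e2 / sigma_j2` and `rhs = x_j' r`, where the partial
#'   residual r is `y - mu - sum_{l != j} x_l beta_l`.
#' * `sample_sigma_k2()`: a group variance, scaled-inverse-chi-square with
#'   scale `(sum(beta_k^2) + scale * df) / (n_k + df)` and `n_k + df` degrees
#'   of freedom; draws are floored at `1e-12`.
#' * `sample_sigma_e2()`: the residual variance; with the default flat prior
#'   (`prior_df = -2`, `prior_scale = 0`) this is the
#'   scaled-inverse-chi-square draw `SSE / chisq(n - 2)`.
#' * `sample_scale()`: the prior scale hyperparameter,
#'   `Gamma(shape = g * df / 2 + 1, rate = (df / 2) * sum(1 / sigma_k2))`
#'   under the uniform(>0) prior on the scale (the printed scale parameter
#'   `2 / (df * sum(1 / sigma_k2))` is the reciprocal of this rate).
#'
#' @param offsets numeric vector `y_i - sum_j x_ij beta_j`.
#' @param sigma_e2 residual variance.
#' @name conditionals
#' @return A single numeric draw.
NULL

#' @rdname conditionals
#' @export
sample_mu <- function(offsets, sigma_e2) {
  n <- length(offsets)
  stopifnot(n >= 1, sigma_e2 > 0)
  rnorm(1L, mean(offsets), sqrt(sigma_e2 / n))
}

#' @rdname conditionals
#' @param x_j genotype column for marker j (centered).
#' @param partial_residual `y - mu - sum_{l != j} x_l beta_l`.
#' @param sigma_j2 prior variance of the marker's group.
#' @export
sample_beta_j <- function(x_j, partial_residual, sigma_e2, sigma_j2) {
  stopifnot(length(x_j) == length(partial_residual),
            sigma_e2 > 0, sigma_j2 > 0, is.finite(sigma_j2))
  C <- sum(x_j^2) + sigma_e2 / sigma_j2
  rnorm(1L, sum(x_j * partial_residual) / C, sqrt(sigma_e2 / C))
}

#' @rdname conditionals
#' @param beta_k effects of the markers in the group.
#' @param scale prior scale hyperparameter (>= 0).
#' @param df prior degrees of freedom (>= 0).
#' @export
sample_sigma_k2 <- function(beta_k, scale, df) {
  n_k <- length(beta_k)
  stopifnot(n_k >= 1, scale >= 0, df >= 0)
  max((sum(beta_k^2) + scale * df) / rchisq(1L, n_k + df), 1e-12)
}

#' @rdname conditionals
#' @param sse residual sum of squares `sum((y - mu - X beta)^2)`.
#' @param n number of records.
#' @param prior_df,prior_scale scaled-inverse-chi-square prior parameters for
#'   the residual variance; the defaults (`-2`, `0`) reproduce the flat-prior
#'   conditional with `n - 2` degrees of freedom.
#' @export
sample_sigma_e2 <- function(sse, n, prior_df = -2, prior_scale = 0) {
  stopifnot(n + prior_df > 0, sse >= 0)
  max((sse + prior_scale * prior_df) / rchisq(1L, n + prior_df), 1e-12)
}

#' @rdname conditionals
#' @param sigma_k2 vector of current group variances.
#' @param g number of groups (defaults to `length(sigma_k2)`).
#' @param shape0,rate0 Gamma prior parameters for the scale; the defaults
#'   (`1`, `0`) are the uniform(>0) prior.
#' @export
sample_scale <- function(sigma_k2, df, g = length(sigma_k2),
                         shape0 = 1, rate0 = 0) {
  if (df <= 0) stop("the scale conditional requires df > 0; freeze the scale when df = 0")
  stopifnot(all(sigma_k2 > 0))
  stats::rgamma(1L, shape = g * df / 2 + shape0,
                rate = rate0 + (df / 2) * sum(1 / sigma_k2))
}
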