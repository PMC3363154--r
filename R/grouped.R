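#' Fit the grouped-variance model by Gibbs sampling
#'
#' Step two of the two-step procedure: the same additive genomic model as
#' SNP-BLUP, but each marker effect `beta_jk` is shrunk with the variance of
#' its group, `beta_jk ~ N(0, sigma_k2)`. The group variances share a
#' scaled-inverse-chi-square prior `sigma_k2 ~ inv-chi2(scale, df)`: `df` is a
#' fixed hyperparameter, while the scale is either fixed or treated as a model
#' parameter with a uniform(>0) prior and sampled from its Gamma full
#' conditional `Gamma(g*df/2 + 1, rate = (df/2) * sum(1/sigma_k2))`. Setting
#' `df = 0`, `scale = 0` gives the Jeffreys (non-informative) prior per group;
#' estimating the scale then has a flat likelihood, so `df = 0` with
#' `scale = "estimate"` is rejected at configuration time.
#'
#' Per iteration the sampler draws the general mean, each marker effect
#' (single-site), each group variance from
#' scaled-inv-chi2(`(sum_k beta^2 + scale*df)/(n_k + df)`, `n_k + df`), the
#' residual variance from scaled-inv-chi2(`SSE/(n-2)`, `n-2`), and the scale.
#' Groups are updated in index order and markers within group in rank order,
#' so runs are reproducible for a given seed.
#'
#' At every saved iteration the genomic heritability is
#' `V_g / (V_g + sigma_e2)` with `V_g` the empirical variance of the genetic
#' values, and the per-group heritabilities allocate between-group covariance
#' proportionally: `h2_k = cov(g_k, g) / (V_g + sigma_e2)`, so the `h2_k` sum
#' to the total exactly.
#'
#' @inheritParams run_snp_blup
#' @param groups a [assign_groups()] result covering every marker of
#'   `genotypes` (a marker without a group is an error).
#' @param df fixed prior degrees of freedom, `>= 0`.
#' @param scale either a fixed non-negative number or `"estimate"`.
#' @return An object of classes `grouped_fit`, `gibbs_fit`; as
#'   [run_snp_blup()] plus per-group columns `sigma_k2_<k>` / `h2_k_<k>` in
#'   `$samples`, the `groups` assignment, and the posterior-mean `scale` when
#'   estimated.
#' @seealso [run_snp_blup()], [assign_groups()], [predict_pbv()]
#' @export
run_grouped <- function(genotypes, phenotypes, groups, df = 0, scale = 0,
                        chain = chain_config(), save_beta = FALSE,
                        check_every = 0L) {
  stopifnot(inherits(chain, "chain_config"), inherits(groups, "group_assignment"))
  if (!genotypes$centered)
    stop("genotypes must be centered; see center_genotypes()")
  if (df < 0) stop("`df` must be >= 0")
  estimate_scale <- identical(scale, "estimate")
  if (estimate_scale) {
    if (df == 0)
      stop("scale cannot be estimated with df = 0 (flat likelihood); fix the scale")
    scale0 <- 1
  } else {
    if (!is.numeric(scale) || length(scale) != 1L || scale < 0)
      stop("`scale` must be a non-negative number or \"estimate\"")
    scale0 <- scale
  }
  y <- align_geno_pheno(genotypes, phenotypes)
  ids <- marker_ids(genotypes)
  miss <- setdiff(ids, groups$marker_id)
  if (length(miss) > 0L)
    stop("markers without a group: ", paste(utils::head(miss, 5L), collapse = ", "))
  group_of <- groups$group[match(ids, groups$marker_id)]
  ngroups <- max(group_of)

  res <- run_gibbs(genotypes, y, group = group_of, ngroups = ngroups,
                   df = df, scale = scale0, estimate_scale = estimate_scale,
                   chain = chain, save_beta = save_beta,
                   check_every = check_every)
  samples <- build_samples_tibble(res, ngroups, estimate_scale,
                                  seq_len(ngroups))
  structure(
    list(samples = samples,
         beta = stats::setNames(res$beta_mean, ids),
         beta_samples = if (save_beta) res$beta_samples else NULL,
         allele_freq = genotypes$allele_freq,
         centers = genotypes$centers,
         groups = groups, group_of = stats::setNames(group_of, ids),
         df = df, scale_policy = if (estimate_scale) "estimate" else "fixed",
         mu = mean(samples$mu), sigma_e2 = mean(samples$sigma_e2),
         scale = if (estimate_scale) mean(samples$scale) else scale0,
         h2 = mean(samples$h2),
         h2_k = colMeans(res$h2_k),
         sigma_k2 = colMeans(res$sigma_k2),
         max_resid_drift = res$max_resid_drift,
         chain = chain, model = "grouped"),
    class = c("grouped_fit", "gibbs_fit"))
}

#' @export
print.grouped_fit <- function(x, ...) {
  g <- length(x$h2_k)
  cat(sprintf("<grouped_fit> %d markers in %d groups, df = %g, scale %s\n",
              length(x$beta), g, x$df,
              if (x$scale_policy == "estimate")
                sprintf("estimated (post. mean %.3g)", x$scale)
              else sprintf("fixed at %g", x$scale)))
  cat(sprintf("  posterior means: h2 = %.3f (group 1: %.3f), sigma_e2 = %.3f\n",
              x$h2, x$h2_k[1L], x$sigma_e2))
  invisible(x)
}

#' Predict breeding values from fitted marker effects
#'
#' The predicted breeding value of an animal is the sum of its centered
#' dosages weighted by the posterior-mean allele substitution effects,
#' `PBV_i = sum_j x_ij * beta_j`. The general mean is a fixed effect and is
#' excluded. New animals must be centered with the training column means: an
#' uncentered matrix is centered here at the fit's stored centers; a centered
#' one is used as-is (it is the caller's responsibility that the centering
#' matches).
#'
#' @param fit a `gibbs_fit` from [run_snp_blup()] or [run_grouped()].
#' @param genotypes a [geno_matrix()] carrying exactly the markers of the fit
#'   (a mismatch is an error naming the missing markers).
#' @return Named numeric vector of predicted breeding values.
#' @export
predict_pbv <- function(fit, genotypes) {
  stopifnot(inherits(fit, "gibbs_fit"), inherits(genotypes, "geno_matrix"))
  miss <- setdiff(names(fit$beta), marker_ids(genotypes))
  if (length(miss) > 0L)
    stop("genotypes lack fitted markers: ",
         paste(utils::head(miss, 5L), collapse = ", "),
         if (length(miss) > 5L) sprintf(" (+%d more)", length(miss) - 5L) else "")
  g <- subset_markers(genotypes, names(fit$beta))
  if (!g$centered) {
    if (is.null(fit$centers)) stop("fit carries no training centers")
    g <- center_genotypes(g, at = fit$centers)
  }
  drop(g$dosages %*% fit$beta)
}

#' @export
predict.gibbs_fit <- function(object, genotypes, ...) {
  predict_pbv(object, genotypes)
}
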