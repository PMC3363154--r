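#' MCMC chain configuration
#'
#' Defaults follow the sampling protocol used throughout the analyses: a chain
#' of 50,000 iterations, the first 20,000 discarded as burn-in, and every 30th
#' subsequent sample saved, giving 1,000 saved samples.
#'
#' @param n_iter total chain length.
#' @param burn_in iterations discarded before saving.
#' @param thin keep every `thin`-th post-burn-in sample.
#' @param seed integer RNG seed.
#' @return A list of class `chain_config`; `n_saved` is the number of samples
#'   that will be kept, `floor((n_iter - burn_in) / thin)`.
#' @export
chain_config <- function(n_iter = 50000, burn_in = 20000, thin = 30, seed = 1) {
  stopifnot(n_iter >= 1, burn_in >= 0, burn_in < n_iter, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 n_saved = (as.integer(n_iter) - as.integer(burn_in)) %/%
                   as.integer(thin)),
            class = "chain_config")
}

#' @export
print.chain_config <- function(x, ...) {
  cat(sprintf("<chain_config> %d iterations, burn-in %d, thin %d (%d saved), seed %d\n",
              x$n_iter, x$burn_in, x$thin, x$n_saved, x$seed))
  invisible(x)
}

align_geno_pheno <- function(genotypes, phenotypes) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  phenotypes <- as_phenotypes(phenotypes)
  ids <- animal_ids(genotypes)
  miss <- setdiff(ids, phenotypes$id)
  if (length(miss) > 0L)
    stop("animals without phenotype: ", paste(utils::head(miss, 5L), collapse = ", "))
  y <- phenotypes$value[match(ids, phenotypes$id)]
  if (anyNA(y)) stop("missing phenotype values")
  y
}

# shared driver around the compiled sweep
run_gibbs <- function(genotypes, y, group, ngroups, df, scale, estimate_scale,
                      chain, update_sigma_k = TRUE, update_sigma_e = TRUE,
                      sigma_k2_init = NULL, sigma_e2_init = NULL,
                      save_beta = FALSE, check_every = 0L,
                      e_df = -2, e_scale = 0, scale_shape0 = 1, scale_rate0 = 0) {
  X <- genotypes$dosages
  n <- nrow(X); q <- ncol(X)
  if (n < 3L) stop("need at least 3 animals")
  if (q < 3L) stop("need at least 3 markers")
  # initialization: neutral equal split of the phenotypic variance (floored
  # so that degenerate constant phenotypes still start from a proper state)
  vy <- max(var(y), 1e-8)
  if (is.null(sigma_e2_init)) sigma_e2_init <- 0.5 * vy
  if (is.null(sigma_k2_init)) {
    sum2pq <- sum(2 * genotypes$allele_freq * (1 - genotypes$allele_freq))
    sigma_k2_init <- rep(0.5 * vy / max(sum2pq, 1e-12), ngroups)
  }
  if (sigma_e2_init <= 0) stop("initial residual variance must be positive")
  set.seed(chain$seed)
  res <- gibbs_core(X, y, as.integer(group), as.integer(ngroups),
                    as.numeric(df), as.numeric(scale), isTRUE(estimate_scale),
                    as.numeric(e_df), as.numeric(e_scale),
                    as.numeric(scale_shape0), as.numeric(scale_rate0),
                    chain$n_iter, chain$burn_in, chain$thin,
                    mean(y), numeric(q), as.numeric(sigma_k2_init),
                    as.numeric(sigma_e2_init),
                    isTRUE(update_sigma_k), isTRUE(update_sigma_e),
                    isTRUE(save_beta), as.integer(check_every))
  res
}

build_samples_tibble <- function(res, ngroups, estimate_scale, group_labels) {
  n_save <- res$n_saved
  out <- tibble::tibble(iteration = seq_len(n_save),
                        mu = res$mu, sigma_e2 = res$sigma_e2)
  if (estimate_scale) out$scale <- res$scale
  out$h2 <- res$h2
  sk <- res$sigma_k2; hk <- res$h2_k
  colnames(sk) <- paste0("sigma_k2_", group_labels)
  colnames(hk) <- paste0("h2_k_", group_labels)
  if (ngroups > 1L) {
    out <- dplyr::bind_cols(out, tibble::as_tibble(sk), tibble::as_tibble(hk))
  } else {
    out$sigma_beta2 <- sk[, 1L]
  }
  out
}

#' Fit SNP-BLUP by Gibbs sampling
#'
#' Step one of the two-step procedure: the additive genomic model
#' `y_i = mu + sum_j x_ij beta_j + e_i` with a single shrinkage variance
#' common to all marker effects, `beta ~ N(0, I sigma_beta2)`, and flat priors
#' on both variances. Each iteration sweeps the general mean, every marker
#' effect (single-site, with an incrementally maintained residual), then draws
#' `sigma_beta2` from scaled-inv-chi2(`sum(beta^2)/(q-2)`, `q-2`) and
#' `sigma_e2` from scaled-inv-chi2(`SSE/(n-2)`, `n-2`).
#'
#' The per-iteration heritability is `V_g / (V_g + sigma_e2)` where `V_g` is
#' the empirical variance over the training animals of the genetic values
#' `g_i = sum_j x_ij beta_j` at the current state.
#'
#' @param genotypes a centered [geno_matrix()].
#' @param phenotypes tibble/data frame with columns `id`, `value`; every
#'   genotyped animal must have a phenotype.
#' @param chain a [chain_config()].
#' @param fix_variances optional list with elements `sigma_beta2` and
#'   `sigma_e2`; when supplied, variance updates are disabled and the sampler
#'   runs at these fixed values (useful for conjugate checks).
#' @param save_beta keep per-iteration marker-effect samples (memory heavy);
#'   posterior means are always kept.
#' @param check_every recompute the residual from scratch every this many
#'   iterations and track the maximum drift (0 = off).
#' @return An object of classes `snp_blup_fit`, `gibbs_fit`: a list with
#'   `samples` (tibble of saved draws), `beta` (named posterior-mean effects),
#'   `allele_freq`, `centers`, posterior means (`mu`, `sigma_e2`, `h2`,
#'   `sigma_beta2`), and the chain configuration.
#' @seealso [run_grouped()], [predict_pbv()], [tidy.gibbs_fit()]
#' @export
run_snp_blup <- function(genotypes, phenotypes, chain = chain_config(),
                         fix_variances = NULL, save_beta = FALSE,
                         check_every = 0L) {
  stopifnot(inherits(chain, "chain_config"))
  if (!genotypes$centered)
    stop("genotypes must be centered; see center_genotypes()")
  y <- align_geno_pheno(genotypes, phenotypes)
  q <- ncol(genotypes$dosages)
  fixed <- !is.null(fix_variances)
  res <- run_gibbs(
    genotypes, y, group = rep(1L, q), ngroups = 1L,
    df = -2, scale = 0, estimate_scale = FALSE, chain = chain,
    update_sigma_k = !fixed, update_sigma_e = !fixed,
    sigma_k2_init = if (fixed) fix_variances$sigma_beta2 else NULL,
    sigma_e2_init = if (fixed) fix_variances$sigma_e2 else NULL,
    save_beta = save_beta, check_every = check_every)
  samples <- build_samples_tibble(res, 1L, FALSE, "1")
  structure(
    list(samples = samples,
         beta = stats::setNames(res$beta_mean, marker_ids(genotypes)),
         beta_samples = if (save_beta) res$beta_samples else NULL,
         allele_freq = genotypes$allele_freq,
         centers = genotypes$centers,
         mu = mean(samples$mu), sigma_e2 = mean(samples$sigma_e2),
         sigma_beta2 = mean(samples$sigma_beta2), h2 = mean(samples$h2),
         max_resid_drift = res$max_resid_drift,
         chain = chain, model = "snp_blup"),
    class = c("snp_blup_fit", "gibbs_fit"))
}

#' @export
print.snp_blup_fit <- function(x, ...) {
  cat(sprintf("<snp_blup_fit> %d markers, %d saved samples\n",
              length(x$beta), nrow(x$samples)))
  cat(sprintf("  posterior means: h2 = %.3f, sigma_e2 = %.3f, sigma_beta2 = %.3g\n",
              x$h2, x$sigma_e2, x$sigma_beta2))
  invisible(x)
}
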