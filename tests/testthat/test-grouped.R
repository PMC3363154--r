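# reference all-R Gibbs sweep built from the documented kernels; used as an
# independent implementation of the grouped sampler on tiny instances
gibbs_reference <- function(X, y, group, df, scale, n_iter, burn_in, seed,
                            e_df = -2, e_scale = 0, snp_blup_var = FALSE) {
  set.seed(seed)
  n <- nrow(X); q <- ncol(X); gG <- max(group)
  mu <- mean(y)
  beta <- numeric(q)
  sk <- rep(var(y) / 2, gG)
  se <- var(y) / 2
  keep_beta <- matrix(0, n_iter - burn_in, q)
  keep_h2 <- numeric(n_iter - burn_in)
  r <- y - mu
  for (it in seq_len(n_iter)) {
    mu_new <- sample_mu(y - drop(X %*% beta), se)
    r <- r - (mu_new - mu)
    mu <- mu_new
    for (j in seq_len(q)) {
      r <- r + X[, j] * beta[j]
      beta[j] <- sample_beta_j(X[, j], r, se, sk[group[j]])
      r <- r - X[, j] * beta[j]
    }
    for (k in seq_len(gG)) {
      bk <- beta[group == k]
      sk[k] <- if (snp_blup_var)
        # common-variance flat-prior conditional: sum(beta^2)/chisq(q - 2)
        sample_sigma_e2(sum(bk^2), length(bk))
      else sample_sigma_k2(bk, scale, df)
    }
    se <- sample_sigma_e2(sum(r^2), n, e_df, e_scale)
    if (it > burn_in) {
      keep_beta[it - burn_in, ] <- beta
      vg <- var(drop(X %*% beta))
      keep_h2[it - burn_in] <- vg / (vg + se)
    }
  }
  list(beta = colMeans(keep_beta), beta_samples = keep_beta, h2 = keep_h2)
}

test_that("the compiled sweep agrees with an all-R kernel implementation", {
  inst <- make_regression(n = 25, q = 6, seed = 31)
  group <- rep(1:2, each = 3)
  grp <- assign_groups(setNames(c(6:4, 3:1), paste0("M", 1:6)), 3)
  fit <- run_grouped(inst$g, inst$phen, grp, df = 2, scale = 0.1,
                     chain = chain_config(8000, 2000, 1, seed = 3),
                     save_beta = TRUE)
  ref <- gibbs_reference(inst$X, inst$y, group, df = 2, scale = 0.1,
                         n_iter = 8000, burn_in = 2000, seed = 4)
  for (j in 1:6) {
    tol <- 3 * sqrt(mc_se(fit$beta_samples[, j])^2 + mc_se(ref$beta_samples[, j])^2)
    expect_lt(abs(fit$beta[[j]] - ref$beta[j]), tol)
  }
  tol_h2 <- 3 * sqrt(mc_se(fit$samples$h2)^2 + mc_se(ref$h2)^2)
  expect_lt(abs(fit$h2 - mean(ref$h2)), tol_h2)
})

test_that("one group with matched conditionals reduces to SNP-BLUP", {
  # model reduction oracle: the grouped model with a single group coincides
  # with SNP-BLUP up to the common-variance conditional's df convention
  # (q - 2 under the flat prior vs n_k under the Jeffreys prior). The R
  # reference with the matched flat-prior conditional must agree with
  # run_snp_blup; the public grouped fit (df = 0) agrees up to the small df
  # offset, tested at q large enough that it is negligible.
  # dense signal keeps the common variance well identified, so neither prior
  # convention can collapse the chain toward the variance floor
  set.seed(17)
  n <- 40; q <- 30
  X <- scale(matrix(rnorm(n * q), n, q,
                    dimnames = list(paste0("A", 1:n), paste0("M", 1:q))),
             scale = FALSE)
  attr(X, "scaled:center") <- NULL
  y <- drop(X %*% rnorm(q, 0, 0.4)) + rnorm(n) + 2
  inst <- list(
    g = geno_matrix(X, allele_freq = rep(0.5, q), centered = TRUE,
                    centers = rep(1, q)),
    phen = tibble::tibble(id = rownames(X), value = y),
    X = X, y = y)
  ch <- chain_config(9000, 2000, 1, seed = 6)
  fs <- run_snp_blup(inst$g, inst$phen, ch, save_beta = TRUE)
  ref <- gibbs_reference(inst$X, inst$y, rep(1L, 30), df = 0, scale = 0,
                         n_iter = 9000, burn_in = 2000, seed = 7,
                         snp_blup_var = TRUE)
  for (j in seq(1, 30, by = 4)) {
    tol <- 3 * sqrt(mc_se(fs$beta_samples[, j])^2 + mc_se(ref$beta_samples[, j])^2)
    expect_lt(abs(fs$beta[[j]] - ref$beta[j]), tol)
  }
  tol_h2 <- 3 * sqrt(mc_se(fs$samples$h2)^2 + mc_se(ref$h2)^2)
  expect_lt(abs(fs$h2 - mean(ref$h2)), tol_h2)

  grp <- assign_groups(setNames(rep(1, 30), paste0("M", 1:30)), 40)
  fg <- run_grouped(inst$g, inst$phen, grp, df = 0, scale = 0, chain = ch,
                    save_beta = TRUE)
  tol_h2g <- 3 * sqrt(mc_se(fg$samples$h2)^2 + mc_se(fs$samples$h2)^2) + 0.01
  expect_lt(abs(fg$h2 - fs$h2), tol_h2g)
})

test_that("permuting markers within a group leaves the posterior unchanged", {
  inst <- make_regression(n = 25, q = 6, seed = 23)
  sc <- setNames(c(6:1), paste0("M", 1:6))
  grp <- assign_groups(sc, 3)
  ch <- chain_config(6000, 1000, 1, seed = 8)
  f1 <- run_grouped(inst$g, inst$phen, grp, df = 0, scale = 0, chain = ch)
  # swap two markers inside group 1 (ranks 2 and 3) in the genotype order
  perm <- c("M2", "M1", "M3", "M4", "M5", "M6")
  g2 <- subset_markers(inst$g, perm)
  f2 <- run_grouped(g2, inst$phen, grp, df = 0, scale = 0,
                    chain = chain_config(6000, 1000, 1, seed = 88))
  tol <- 3 * sqrt(mc_se(f1$samples$h2)^2 + mc_se(f2$samples$h2)^2) + 0.005
  expect_lt(abs(f1$h2 - f2$h2), tol)
  expect_lt(abs(f1$sigma_e2 - f2$sigma_e2),
            3 * sqrt(mc_se(f1$samples$sigma_e2)^2 + mc_se(f2$samples$sigma_e2)^2) + 0.01)
})

test_that("scale estimation follows its configuration rules", {
  inst <- make_regression(n = 20, q = 6, seed = 41)
  grp <- assign_groups(setNames(6:1, paste0("M", 1:6)), 3)
  expect_error(run_grouped(inst$g, inst$phen, grp, df = 0, scale = "estimate",
                           chain = chain_config(100, 10, 1)),
               "df = 0")
  expect_error(run_grouped(inst$g, inst$phen, grp, df = -1, scale = 0,
                           chain = chain_config(100, 10, 1)),
               ">= 0")
  fit <- run_grouped(inst$g, inst$phen, grp, df = 5, scale = "estimate",
                     chain = chain_config(500, 100, 1, seed = 2))
  expect_true("scale" %in% names(fit$samples))
  expect_true(all(fit$samples$scale > 0))
  # a marker missing from the assignment is an error
  grp_bad <- assign_groups(setNames(5:1, paste0("M", 1:5)), 3)
  expect_error(run_grouped(inst$g, inst$phen, grp_bad, df = 0, scale = 0,
                           chain = chain_config(100, 10, 1)),
               "without a group")
})

test_that("per-group heritabilities sum to the total in every saved sample", {
  inst <- make_regression(n = 30, q = 9, seed = 51)
  grp <- assign_groups(setNames(9:1, paste0("M", 1:9)), 3)
  fit <- run_grouped(inst$g, inst$phen, grp, df = 0, scale = 0,
                     chain = chain_config(800, 200, 2, seed = 3))
  hk <- as.matrix(fit$samples[, grep("^h2_k_", names(fit$samples))])
  expect_equal(rowSums(hk), fit$samples$h2, tolerance = 1e-9)
})

test_that("predicted breeding values follow the fitted effects", {
  inst <- make_regression(n = 20, q = 5, seed = 61)
  fit <- run_snp_blup(inst$g, inst$phen, chain_config(500, 100, 1, seed = 1))
  # beta all zero -> PBV all zero
  fit0 <- fit
  fit0$beta[] <- 0
  expect_equal(unname(predict_pbv(fit0, inst$g)), rep(0, 20))
  # one marker with effect 1 on centered dosages [-1, 0, 1]
  fit1 <- fit
  fit1$beta <- c(M1 = 1)
  gm <- geno_matrix(matrix(c(-1, 0, 1), 3, 1,
                           dimnames = list(paste0("N", 1:3), "M1")),
                    allele_freq = 0.5, centered = TRUE)
  expect_equal(unname(predict_pbv(fit1, gm)), c(-1, 0, 1))
  # training animals: PBV equals X beta used in the h2 computation
  expect_equal(predict_pbv(fit, inst$g), drop(inst$X %*% fit$beta),
               ignore_attr = TRUE)
  # marker mismatch errors
  g_less <- subset_markers(inst$g, c("M1", "M2", "M3"))
  expect_error(predict_pbv(fit, g_less), "lack fitted markers")
  # uncentered prediction data is centered with the stored training centers
  raw <- geno_matrix(matrix(rep(0:2, 5), 3, 5,
                            dimnames = list(paste0("N", 1:3), paste0("M", 1:5))))
  pb <- predict_pbv(fit, raw)
  expect_equal(unname(pb),
               drop(sweep(raw$dosages, 2, fit$centers, "-") %*% fit$beta),
               ignore_attr = TRUE)
})
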