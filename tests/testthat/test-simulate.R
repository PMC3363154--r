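test_that("simulator is deterministic and hits the target heritability", {
  sim1 <- simulate_dataset(n_founders = 5, n_dams = 50, progeny_per_dam = 4,
                           q_markers = 400, seed = 11)
  sim2 <- simulate_dataset(n_founders = 5, n_dams = 50, progeny_per_dam = 4,
                           q_markers = 400, seed = 11)
  expect_identical(sim1$genotypes$dosages, sim2$genotypes$dosages)
  expect_identical(sim1$phenotypes$value, sim2$phenotypes$value)
  expect_identical(sim1$true_bv, sim2$true_bv)

  # realized h2 within +-0.05 of the target at n >= 1000
  sim <- simulate_dataset(n_founders = 10, n_dams = 100, progeny_per_dam = 10,
                          q_markers = 500, h2_target = 0.30, seed = 4)
  h2_real <- var(sim$true_bv) / var(sim$phenotypes$value)
  expect_gt(h2_real, 0.25)
  expect_lt(h2_real, 0.35)
})

test_that("no QTL means no genetic signal", {
  sim <- simulate_dataset(n_founders = 3, n_dams = 10, progeny_per_dam = 3,
                          q_markers = 50, n_qtl = 0, seed = 2)
  expect_true(all(sim$true_bv == 0))
  expect_equal(nrow(sim$qtl), 0)
})

test_that("realized h2 is monotone in the target", {
  h2s <- vapply(c(0.1, 0.3, 0.5), function(h2)
    {
      sim <- simulate_dataset(n_founders = 5, n_dams = 60, progeny_per_dam = 5,
                              q_markers = 300, h2_target = h2, seed = 8)
      var(sim$true_bv) / var(sim$phenotypes$value)
    }, 0)
  expect_true(all(diff(h2s) > 0))
})

test_that("founder allele frequencies respect the requested range and HWE", {
  sim <- simulate_dataset(n_founders = 30, n_dams = 300, progeny_per_dam = 2,
                          q_markers = 200, founder_maf_range = c(0.2, 0.4),
                          seed = 6)
  # progeny frequencies drift around founder frequencies; all should stay
  # comfortably inside (0.05, 0.55) for this range
  expect_true(all(sim$genotypes$allele_freq > 0.05 &
                    sim$genotypes$allele_freq < 0.55))
  # heterozygosity near 2p(1-p) on average (HWE within sampling noise)
  p <- sim$genotypes$allele_freq
  het <- colMeans(sim$genotypes$dosages == 1)
  expect_equal(mean(het), mean(2 * p * (1 - p)), tolerance = 0.02)
})

test_that("pedigree structure gives sibs the expected genomic relationship", {
  sim <- simulate_dataset(n_founders = 4, n_dams = 24, progeny_per_dam = 5,
                          q_markers = 1200, seed = 9)
  d <- sim$genotypes$dosages
  d <- d[, apply(d, 2, sd) > 0, drop = FALSE]  # drop markers fixed by drift
  Z <- scale(d)
  Grel <- tcrossprod(Z) / ncol(Z)
  ped <- sim$pedigree
  prog <- ped[ped$dam != "0", ]
  # mean genomic relationship of full sibs ~ 0.5
  fs <- do.call(rbind, lapply(split(prog$id, prog$dam), function(ids)
    t(combn(ids, 2))))
  fs_rel <- Grel[cbind(fs[, 1], fs[, 2])]
  other <- Grel[prog$id, prog$id]
  same_dam <- outer(prog$dam, prog$dam, "==")
  same_sire <- outer(prog$sire, prog$sire, "==")
  un <- other[!same_dam & !same_sire & upper.tri(other)]
  hs <- other[!same_dam & same_sire & upper.tri(other)]
  # sample-frequency centering shifts the whole G by the population mean
  # relationship, so compare against the unrelated baseline
  expect_equal(mean(fs_rel) - mean(un), 0.5, tolerance = 0.06)
  expect_equal(mean(hs) - mean(un), 0.25, tolerance = 0.05)
})

test_that("QTL are members of the marker panel and effects reproduce true_bv", {
  sim <- simulate_dataset(n_founders = 3, n_dams = 20, progeny_per_dam = 4,
                          q_markers = 100, n_qtl = 8, seed = 13)
  expect_true(all(sim$qtl$marker_id %in% marker_ids(sim$genotypes)))
  g <- drop(sim$genotypes$dosages[, sim$qtl$marker_id] %*% sim$qtl$effect)
  expect_equal(unname(g), unname(sim$true_bv))
})

test_that("true_accuracy is a Pearson correlation with id alignment", {
  x <- setNames(rnorm(50), paste0("P", 1:50))
  expect_equal(true_accuracy(x, x), 1)
  expect_equal(true_accuracy(x, -x), -1)
  expect_equal(true_accuracy(unname(x), unname(rev(x))),
               cor(unname(x), unname(rev(x))))
  # named vectors align on ids regardless of order
  expect_equal(true_accuracy(x, rev(x)), 1)
  expect_error(true_accuracy(x, setNames(rep(1, 50), names(x))), "zero variance")
  expect_error(true_accuracy(x[1:2], x[1:2]), "at least 3")
})

test_that("noise of equal variance halves the squared accuracy", {
  set.seed(42)
  n <- 1e5
  bv <- rnorm(n)
  pbv <- bv + rnorm(n)
  expect_equal(true_accuracy(pbv, bv), 1 / sqrt(2), tolerance = 0.01)
})
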