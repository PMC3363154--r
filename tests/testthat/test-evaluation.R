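test_that("last progeny per dam is held out, one per dam, deterministically", {
  ped <- tibble::tibble(
    id = c("S1", "D1", "D2", "P1", "P2", "P3", "P4", "P5", "P6"),
    sire = c("0", "0", "0", rep("S1", 6)),
    dam = c("0", "0", "0", "D1", "D1", "D1", "D2", "D2", "D2"))
  sp <- holdout_last_progeny_per_dam(ped, paste0("P", 1:6))
  expect_equal(sp$validation_ids, c("P3", "P6"))
  expect_equal(sp$train_ids, c("P1", "P2", "P4", "P5"))
  # deterministic re-run
  sp2 <- holdout_last_progeny_per_dam(ped, paste0("P", 1:6))
  expect_identical(sp, sp2)
  # a dam with a single eligible progeny contributes it to validation
  sp3 <- holdout_last_progeny_per_dam(ped, c("P1", "P2", "P3", "P4"))
  expect_equal(sp3$validation_ids, c("P3", "P4"))
  # ineligible animals never appear in either set
  expect_false(any(c("S1", "D1", "D2", "P5", "P6") %in%
                     unlist(sp3[c("train_ids", "validation_ids")])))
  expect_error(holdout_last_progeny_per_dam(ped, character(0)), "missing|no dams")
})

test_that("simulator defaults produce one validation animal per dam", {
  sim <- simulate_dataset(n_founders = 4, n_dams = 30, progeny_per_dam = 3,
                          q_markers = 20, seed = 44)
  sp <- holdout_last_progeny_per_dam(sim$pedigree, animal_ids(sim$genotypes))
  expect_length(sp$validation_ids, 30)
  expect_length(sp$train_ids, 60)
  # the validation animal is the last-recorded progeny of its dam
  ped <- sim$pedigree
  dams <- ped$dam[match(sp$validation_ids, ped$id)]
  expect_equal(sort(dams), sort(unique(ped$dam[ped$dam != "0"])))
})

test_that("an explicit validation list overrides the last-progeny rule", {
  sim <- simulate_dataset(n_founders = 3, n_dams = 10, progeny_per_dam = 3,
                          q_markers = 20, seed = 45)
  ids <- animal_ids(sim$genotypes)
  sp <- holdout_last_progeny_per_dam(sim$pedigree, ids,
                                     validation_ids = ids[1:5])
  expect_equal(sp$validation_ids, ids[1:5])
  expect_error(holdout_last_progeny_per_dam(sim$pedigree, ids,
                                            validation_ids = "nope"),
               "subset")
})

test_that("heritability report summarizes totals and groups consistently", {
  inst <- make_regression(n = 30, q = 6, seed = 71)
  grp <- assign_groups(setNames(6:1, paste0("M", 1:6)), 3)
  fit <- run_grouped(inst$g, inst$phen, grp, df = 0, scale = 0,
                     chain = chain_config(600, 100, 1, seed = 4))
  rep_ <- heritability_report(fit)
  expect_equal(rep_$component, c("total", "group_1", "group_2"))
  expect_equal(rep_$mean[1], fit$h2)
  # groups sum to the total (means of an exact per-iteration identity)
  expect_equal(sum(rep_$mean[-1]), rep_$mean[1], tolerance = 1e-9)
  expect_true(all(rep_$lower <= rep_$mean & rep_$mean <= rep_$upper))
  # degenerate: identical samples give a zero-width interval
  fit2 <- fit
  fit2$samples$h2[] <- 0.3
  r2 <- heritability_report(fit2)
  expect_equal(r2$mean[1], 0.3)
  expect_equal(r2$lower[1], r2$upper[1])
})

test_that("accuracy_table aligns ids and detects null predictors", {
  set.seed(9)
  truth <- setNames(rnorm(1000), paste0("P", 1:1000))
  good <- truth + rnorm(1000, 0, 0.5)
  noise <- setNames(rnorm(1000), names(truth))
  tab <- accuracy_table(list(good = good, noise = noise),
                        list(true_bv = truth))
  expect_equal(tab$method, c("good", "noise"))
  expect_equal(tab$accuracy[1], cor(good, truth))
  expect_lt(abs(tab$accuracy[2]), 3 / sqrt(1000))
  # perfect self-accuracy; affine invariance of the Pearson correlation
  tab2 <- accuracy_table(list(self = truth, shifted = 2 * truth + 5),
                         list(true_bv = truth))
  expect_equal(tab2$accuracy, c(1, 1))
  expect_error(accuracy_table(list(a = truth[1:5]),
                              list(t = unname(truth[1:4]))), "length mismatch")
})

test_that("progeny means average the progeny breeding values per parent", {
  ped <- tibble::tibble(
    id = c("S", "D1", "D2", "P1", "P2", "P3"),
    sire = c("0", "0", "0", "S", "S", "S"),
    dam = c("0", "0", "0", "D1", "D1", "D2"))
  bv <- c(P1 = 1, P2 = 3, P3 = 10)
  pm <- progeny_mean_bv(ped, bv)
  expect_equal(pm[["D1"]], 2)
  expect_equal(pm[["D2"]], 10)
  expect_equal(pm[["S"]], mean(c(1, 3, 10)))
  expect_equal(progeny_mean_bv(ped, bv, min_progeny = 2)[["S"]], 14 / 3)
  expect_false("D2" %in% names(progeny_mean_bv(ped, bv, min_progeny = 2)))
})
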