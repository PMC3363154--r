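#' Simulate a dam-family genomic dataset
#'
#' Generates a two-generation pedigree — unrelated founder sires and dams,
#' full-sib families nested within sires — and drops genes through it to
#' produce a dense biallelic SNP panel in which a small number of markers are
#' causative QTL with large additive effects. The design mirrors a typical
#' genomic-selection study population: every progeny is genotyped and
#' phenotyped; founders are neither. Dams are assigned to sires in equal-size
#' blocks, so the progeny form `n_dams` full-sib families nested in
#' `n_founders` half-sib sire families.
#'
#' Founder genotypes are drawn in Hardy-Weinberg proportions with
#' counted-allele frequencies uniform on `founder_maf_range`. Loci are
#' unlinked: each progeny receives, per locus, one allele from each parent
#' with transmission probability `dosage/2`. QTL effects start as standard
#' normal draws and are rescaled so the empirical variance of the true
#' breeding values over the progeny equals `h2_target`; residuals are
#' N(0, 1 - h2_target), so the realized narrow-sense heritability matches the
#' target up to the sampling noise of the residual draw. The trait mean is 0.
#'
#' @param n_founders number of founder sires (default 20).
#' @param n_dams number of founder dams (default 200).
#' @param progeny_per_dam progeny per dam, at least 2 (default 10).
#' @param q_markers number of SNP markers (default 2000).
#' @param n_qtl number of causative QTL among the markers (default 8).
#' @param h2_target narrow-sense heritability of the trait in (0, 1)
#'   (default 0.30).
#' @param founder_maf_range range of founder counted-allele frequencies
#'   (default `c(0.05, 0.5)`).
#' @param seed integer RNG seed; the output is deterministic given the seed.
#' @return A list of class `sim_output` with elements `genotypes` (a
#'   [geno_matrix()] of the progeny), `phenotypes` (tibble `id`, `value`),
#'   `pedigree` ([as_pedigree()] tibble covering founders and progeny),
#'   `true_bv` (named vector over progeny), `qtl` (tibble `marker_id`,
#'   `effect`), and the call's configuration.
#' @export
simulate_dataset <- function(n_founders = 20, n_dams = 200,
                             progeny_per_dam = 10, q_markers = 2000,
                             n_qtl = 8, h2_target = 0.30,
                             founder_maf_range = c(0.05, 0.5), seed = 1) {
  stopifnot(n_founders >= 1, n_dams >= 1, q_markers >= 1)
  if (progeny_per_dam < 2) stop("`progeny_per_dam` must be at least 2")
  if (n_qtl < 0 || n_qtl > q_markers) stop("`n_qtl` must be in [0, q_markers]")
  if (n_qtl > 0 && (h2_target <= 0 || h2_target >= 1))
    stop("`h2_target` must be in (0, 1)")
  if (n_qtl == 0 && (h2_target < 0 || h2_target >= 1))
    stop("`h2_target` must be in [0, 1)")
  stopifnot(length(founder_maf_range) == 2,
            founder_maf_range[1] > 0, founder_maf_range[2] <= 0.5,
            founder_maf_range[1] <= founder_maf_range[2])
  set.seed(as.integer(seed))

  n_prog <- n_dams * progeny_per_dam
  sire_ids <- sprintf("S%03d", seq_len(n_founders))
  dam_ids <- sprintf("D%04d", seq_len(n_dams))
  prog_ids <- sprintf("P%05d", seq_len(n_prog))
  marker_names <- sprintf("M%05d", seq_len(q_markers))

  # mating design: dams in equal blocks per sire; progeny ordered by dam
  sire_of_dam <- sire_ids[ceiling(seq_len(n_dams) / (n_dams / n_founders))]
  dam_of_prog <- rep(dam_ids, each = progeny_per_dam)
  sire_of_prog <- rep(sire_of_dam, each = progeny_per_dam)

  ped <- tibble::tibble(
    id = c(sire_ids, dam_ids, prog_ids),
    sire = c(rep("0", n_founders + n_dams), sire_of_prog),
    dam = c(rep("0", n_founders + n_dams), dam_of_prog))
  ped <- as_pedigree(ped)

  # founder genotypes: Hardy-Weinberg at uniform frequencies
  p <- runif(q_markers, founder_maf_range[1], founder_maf_range[2])
  founders <- matrix(rbinom((n_founders + n_dams) * q_markers, 2L,
                            rep(p, each = n_founders + n_dams)),
                     nrow = n_founders + n_dams, ncol = q_markers,
                     dimnames = list(c(sire_ids, dam_ids), marker_names))

  # gene dropping, unlinked loci: transmitted allele ~ Bernoulli(dosage/2)
  sire_dose <- founders[sire_of_prog, , drop = FALSE]
  dam_dose <- founders[dam_of_prog, , drop = FALSE]
  prog <- matrix(rbinom(length(sire_dose), 1L, sire_dose / 2) +
                   rbinom(length(dam_dose), 1L, dam_dose / 2),
                 nrow = n_prog, ncol = q_markers,
                 dimnames = list(prog_ids, marker_names))
  storage.mode(prog) <- "double"

  # QTL: uniform choice among markers, normal effects rescaled so that the
  # empirical additive variance over the progeny equals h2_target
  true_bv <- stats::setNames(numeric(n_prog), prog_ids)
  qtl <- tibble::tibble(marker_id = character(0), effect = numeric(0))
  if (n_qtl > 0) {
    qtl_idx <- sort(sample.int(q_markers, n_qtl))
    a <- rnorm(n_qtl)
    g <- drop(prog[, qtl_idx, drop = FALSE] %*% a)
    vg <- var(g)
    if (vg <= 0) stop("degenerate QTL draw: zero additive variance")
    a <- a * sqrt(h2_target / vg)
    true_bv[] <- g * sqrt(h2_target / vg)
    qtl <- tibble::tibble(marker_id = marker_names[qtl_idx], effect = a)
  }
  e <- rnorm(n_prog, 0, sqrt(1 - h2_target))
  y <- true_bv + e
  if (var(y) <= 0) stop("degenerate simulation: zero phenotypic variance")

  structure(
    list(genotypes = geno_matrix(prog),
         phenotypes = tibble::tibble(id = prog_ids, value = unname(y)),
         pedigree = ped,
         true_bv = true_bv,
         qtl = qtl,
         config = list(n_founders = n_founders, n_dams = n_dams,
                       progeny_per_dam = progeny_per_dam,
                       q_markers = q_markers, n_qtl = n_qtl,
                       h2_target = h2_target,
                       founder_maf_range = founder_maf_range, seed = seed)),
    class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<sim_output> %d progeny (%d dams x %d), %d markers, ",
                     "%d QTL, target h2 = %.2f, seed %d\n"),
              nrow(x$genotypes$dosages), cfg$n_dams, cfg$progeny_per_dam,
              cfg$q_markers, cfg$n_qtl, cfg$h2_target, cfg$seed))
  invisible(x)
}

#' Correlation between predicted and true breeding values
#'
#' Pearson correlation between a vector of predicted breeding values and the
#' matching true genetic values — the accuracy measure of genomic prediction.
#' When both vectors are named they are aligned on their names first.
#'
#' @param pbv numeric vector of predictions.
#' @param true_bv numeric vector of true breeding values.
#' @return Pearson correlation (scalar).
#' @export
true_accuracy <- function(pbv, true_bv) {
  if (!is.null(names(pbv)) && !is.null(names(true_bv))) {
    common <- intersect(names(pbv), names(true_bv))
    if (length(common) == 0L) stop("no shared animal ids")
    pbv <- pbv[common]
    true_bv <- true_bv[common]
  }
  if (length(pbv) != length(true_bv)) stop("length mismatch")
  if (length(pbv) < 3L) stop("need at least 3 animals")
  if (sd(pbv) == 0 || sd(true_bv) == 0)
    stop("zero variance in predictions or true values")
  cor(pbv, true_bv)
}
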