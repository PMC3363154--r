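#' Run the full two-step analysis on files
#'
#' File-level driver wiring the stages end to end: read genotypes, phenotypes
#' and pedigree; MAF-filter; build the family-based validation split; center
#' the training genotypes; fit SNP-BLUP (step 1); rank and group markers by
#' explained variance; fit the grouped model (step 2, optionally on a reduced
#' top-`select_top_k` panel re-ranked from the step-2 effects); predict
#' breeding values for the validation animals from markers and from the
#' pedigree baseline; write every declared artifact plus a `manifest.json`
#' recording the configuration, seed and per-stage wall time.
#'
#' @param genotypes,phenotypes,pedigree input file paths (formats as in
#'   [read_genotypes()], [read_phenotypes()], [read_pedigree()]).
#' @param out_dir output directory (created if needed).
#' @param maf_threshold MAF filter threshold (default 0.01).
#' @param group_size markers per group (default 150).
#' @param df prior degrees of freedom for the group variances (default 0).
#' @param scale fixed prior scale or `"estimate"` (default 0).
#' @param select_top_k optional panel reduction: refit on the `k` markers
#'   with the largest step-2 effects (default `NULL` = keep all markers).
#' @param chain a [chain_config()]; its seed drives every sampler.
#' @param truth optional path to a truth CSV (`animal_id`, `true_bv`) for an
#'   accuracy table.
#' @return Invisibly, a list with the fitted objects, the split, the accuracy
#'   table (when truth is given) and the manifest. Side effect: files under
#'   `out_dir` (`groups.csv`, `effects_*.csv`, `posterior_*.csv`,
#'   `pbv_*.csv`, `accuracy.csv`, `manifest.json`).
#' @export
run_two_step <- function(genotypes, phenotypes, pedigree, out_dir,
                         maf_threshold = 0.01, group_size = 150,
                         df = 0, scale = 0, select_top_k = NULL,
                         chain = chain_config(), truth = NULL) {
  stopifnot(inherits(chain, "chain_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  stages <- list()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    stages[[name]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }

  geno <- read_genotypes(genotypes)
  phen <- read_phenotypes(phenotypes)
  ped <- read_pedigree(pedigree)
  tick("read")

  geno <- filter_maf(geno, maf_threshold)
  eligible <- intersect(animal_ids(geno), phen$id)
  split <- holdout_last_progeny_per_dam(ped, eligible)
  train_geno_raw <- subset_animals(geno, split$train_ids)
  train_geno <- center_genotypes(train_geno_raw)
  train_phen <- phen[phen$id %in% split$train_ids, ]
  val_geno <- subset_animals(geno, split$validation_ids)
  tick("filter_split")

  fit1 <- run_snp_blup(train_geno, train_phen, chain = chain)
  write_posterior(fit1, file.path(out_dir, "posterior_snp_blup.csv"))
  write_effects(fit1, file.path(out_dir, "effects_snp_blup.csv"))
  tick("snp_blup")

  scores1 <- tidy(fit1)
  groups <- assign_groups(
    stats::setNames(scores1$explained_variance, scores1$marker_id),
    group_size = group_size)
  write_groups(groups, file.path(out_dir, "groups.csv"))
  fit2 <- run_grouped(train_geno, train_phen, groups, df = df, scale = scale,
                      chain = chain)
  tick("grouped")

  if (!is.null(select_top_k)) {
    # reduced panels keep the largest effects from the step-2 model and are
    # re-grouped before refitting
    scores2 <- tidy(fit2)
    keep <- select_top(stats::setNames(scores2$explained_variance,
                                       scores2$marker_id), select_top_k)
    sub_geno <- center_genotypes(subset_markers(train_geno_raw, keep))
    sub_scores <- scores2$explained_variance[match(keep, scores2$marker_id)]
    groups <- assign_groups(stats::setNames(sub_scores, keep), group_size)
    write_groups(groups, file.path(out_dir, "groups_selected.csv"))
    fit2 <- run_grouped(sub_geno, train_phen, groups, df = df, scale = scale,
                        chain = chain)
    tick("grouped_selected")
  }
  write_posterior(fit2, file.path(out_dir, "posterior_grouped.csv"))
  write_effects(fit2, file.path(out_dir, "effects_grouped.csv"))

  pbv <- list(snp_blup = predict_pbv(fit1, val_geno),
              grouped = predict_pbv(fit2, val_geno))
  fit_ped <- fit_animal_model(ped, phen[phen$id %in% split$train_ids, ],
                              h2 = "reml")
  pbv$blup <- pbv_animal_model(fit_ped, split$validation_ids)
  for (nm in names(pbv))
    write_pbv(pbv[[nm]], file.path(out_dir, paste0("pbv_", nm, ".csv")))
  tick("predict")

  acc <- NULL
  if (!is.null(truth)) {
    tb <- utils::read.csv(truth, stringsAsFactors = FALSE)
    tv <- stats::setNames(tb[[2L]], as.character(tb[[1L]]))
    acc <- accuracy_table(pbv, list(true_bv = tv[split$validation_ids]))
    write_csv_precise(acc, file.path(out_dir, "accuracy.csv"))
  }
  tick("evaluate")

  manifest <- list(
    package_version = as.character(utils::packageVersion("snpgroups")),
    seed = chain$seed,
    chain = unclass(chain)[c("n_iter", "burn_in", "thin")],
    maf_threshold = maf_threshold, group_size = group_size,
    df = df, scale = if (identical(scale, "estimate")) "estimate" else scale,
    select_top_k = select_top_k,
    n_train = length(split$train_ids),
    n_validation = length(split$validation_ids),
    n_markers = ncol(train_geno$dosages),
    stage_seconds = stages)
  writeLines(manifest_json(manifest), file.path(out_dir, "manifest.json"))

  invisible(list(snp_blup = fit1, grouped = fit2, animal_model = fit_ped,
                 split = split, groups = groups, pbv = pbv, accuracy = acc,
                 manifest = manifest))
}

#' Subset a genotype matrix to a set of animals
#' @param g a [geno_matrix()].
#' @param ids animal ids to keep (order preserved as given).
#' @return A [geno_matrix()]; allele frequencies are recomputed for the
#'   subset when `g` is uncentered, since they describe the data held.
#' @export
subset_animals <- function(g, ids) {
  stopifnot(inherits(g, "geno_matrix"))
  miss <- setdiff(ids, animal_ids(g))
  if (length(miss) > 0L)
    stop("animals not in genotype matrix: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  d <- g$dosages[ids, , drop = FALSE]
  if (g$centered)
    geno_matrix(d, allele_freq = g$allele_freq, centered = TRUE,
                centers = g$centers)
  else
    geno_matrix(d)
}

# minimal JSON writer for the manifest (flat lists of scalars / named lists)
manifest_json <- function(x, indent = 0) {
  pad <- strrep("  ", indent)
  enc <- function(v) {
    if (is.null(v)) return("null")
    if (is.character(v)) return(sprintf("\"%s\"", v))
    if (is.logical(v)) return(tolower(as.character(v)))
    format(v, digits = 15, scientific = FALSE, trim = TRUE)
  }
  items <- vapply(names(x), function(nm) {
    v <- x[[nm]]
    body <- if (is.list(v)) manifest_json(v, indent + 1)
            else if (length(v) > 1)
              paste0("[", paste(vapply(v, enc, ""), collapse = ", "), "]")
            else enc(v)
    sprintf("%s  \"%s\": %s", pad, nm, body)
  }, "")
  paste0("{\n", paste(items, collapse = ",\n"), "\n", pad, "}")
}
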