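#' Family-based validation split
#'
#' Implements the hold-out design used for model validation: from each dam
#' with at least one eligible progeny (eligible = both genotyped and
#' phenotyped), the progeny appearing last in pedigree record order is set
#' aside for validation; every other eligible animal trains the model. "Last"
#' in record order stands in for the youngest progeny; pass `validation_ids`
#' to override with an explicit list.
#'
#' @param ped a pedigree accepted by [as_pedigree()].
#' @param eligible_ids character vector of animals with both genotype and
#'   phenotype records.
#' @param validation_ids optional explicit validation set (subset of
#'   `eligible_ids`); skips the last-progeny rule.
#' @return A list of class `validation_split` with `train_ids` and
#'   `validation_ids`, disjoint and in pedigree order.
#' @export
holdout_last_progeny_per_dam <- function(ped, eligible_ids,
                                         validation_ids = NULL) {
  ped <- as_pedigree(ped)
  eligible_ids <- as.character(eligible_ids)
  miss <- setdiff(eligible_ids, ped$id)
  if (length(miss) > 0L)
    stop("eligible animals missing from pedigree: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  eligible_ids <- ped$id[ped$id %in% eligible_ids]  # pedigree order
  if (is.null(validation_ids)) {
    rows <- ped[ped$id %in% eligible_ids & ped$dam != "0", ]
    if (nrow(rows) == 0L) stop("no dams with eligible progeny")
    last <- vapply(split(rows$id, rows$dam), function(x) x[length(x)], "")
    validation_ids <- ped$id[ped$id %in% last]
  } else {
    validation_ids <- as.character(validation_ids)
    if (!all(validation_ids %in% eligible_ids))
      stop("`validation_ids` must be a subset of `eligible_ids`")
    validation_ids <- ped$id[ped$id %in% validation_ids]
  }
  structure(list(train_ids = setdiff(eligible_ids, validation_ids),
                 validation_ids = validation_ids),
            class = "validation_split")
}

#' @export
print.validation_split <- function(x, ...) {
  cat(sprintf("<validation_split> %d training, %d validation animals\n",
              length(x$train_ids), length(x$validation_ids)))
  invisible(x)
}

#' Posterior heritability report
#'
#' Posterior means and central 95% credible intervals for the total genomic
#' heritability and, for grouped fits, each per-group heritability `h2_k`
#' (group 1 first). Because the per-group values allocate between-group
#' covariance proportionally, they sum to the total in every saved iteration.
#'
#' @param fit a `gibbs_fit` from [run_snp_blup()] or [run_grouped()].
#' @param level credible-interval mass (default 0.95).
#' @return A tibble with columns `component` (`"total"`, `"group_1"`, ...),
#'   `mean`, `lower`, `upper`.
#' @export
heritability_report <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "gibbs_fit"))
  s <- fit$samples
  if (nrow(s) == 0L) stop("fit has no saved samples")
  a <- (1 - level) / 2
  grp_cols <- names(s)[grepl("^h2_k_", names(s))]
  cols <- c(stats::setNames("h2", "total"),
            stats::setNames(grp_cols, sub("^h2_k_", "group_", grp_cols)))
  tibble::tibble(
    component = names(cols),
    mean = unname(vapply(cols, function(cn) mean(s[[cn]]), 0)),
    lower = unname(vapply(cols, function(cn) unname(quantile(s[[cn]], a)), 0)),
    upper = unname(vapply(cols, function(cn) unname(quantile(s[[cn]], 1 - a)), 0)))
}

#' Accuracy table for competing predictors
#'
#' Pearson correlations between each set of predicted breeding values and one
#' or more reference vectors (true genetic values, progeny means, ...), the
#' comparison underlying accuracy tables in genomic-prediction studies. All
#' vectors are aligned on animal ids when named; unnamed vectors must already
#' be aligned and of equal length.
#'
#' @param pbv named list of numeric prediction vectors (one per method).
#' @param reference a numeric reference vector, or a named list of them.
#' @return A tibble with columns `method`, `reference`, `accuracy`, `n`.
#' @export
accuracy_table <- function(pbv, reference) {
  if (!is.list(pbv)) pbv <- list(pbv = pbv)
  if (is.null(names(pbv)) || any(names(pbv) == ""))
    names(pbv) <- paste0("method_", seq_along(pbv))
  if (!is.list(reference)) reference <- list(reference = reference)
  if (is.null(names(reference)) || any(names(reference) == ""))
    names(reference) <- paste0("reference_", seq_along(reference))
  rows <- lapply(names(pbv), function(m) {
    lapply(names(reference), function(r) {
      x <- pbv[[m]]; y <- reference[[r]]
      if (!is.null(names(x)) && !is.null(names(y))) {
        common <- intersect(names(x), names(y))
        if (length(common) == 0L) stop("no shared ids between '", m, "' and '", r, "'")
        x <- x[common]; y <- y[common]
      }
      if (length(x) != length(y))
        stop("length mismatch between '", m, "' and '", r, "'")
      tibble::tibble(method = m, reference = r,
                     accuracy = cor(x, y), n = length(x))
    })
  })
  dplyr::bind_rows(unlist(rows, recursive = FALSE))
}

#' Expected genetic value of each dam's progeny
#'
#' For validation against progeny performance rather than true breeding
#' values: the mean true (or predicted) breeding value of each animal's
#' progeny, returned for animals with at least `min_progeny` progeny.
#'
#' @param ped a pedigree accepted by [as_pedigree()].
#' @param bv named numeric vector of breeding values of the progeny.
#' @param min_progeny minimum progeny count (default 1).
#' @return Named numeric vector of progeny-mean values, named by parent id.
#' @export
progeny_mean_bv <- function(ped, bv, min_progeny = 1) {
  ped <- as_pedigree(ped)
  rows <- ped[ped$id %in% names(bv) & (ped$sire != "0" | ped$dam != "0"), ]
  parents <- c(stats::setNames(rows$sire, rows$id), stats::setNames(rows$dam, rows$id))
  parents <- parents[parents != "0"]
  vals <- tapply(bv[names(parents)], parents, mean)
  cnt <- table(parents)
  out <- vals[cnt >= min_progeny]
  stats::setNames(as.numeric(out), names(out))
}
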