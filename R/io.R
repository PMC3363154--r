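#' Read and write phenotype tables
#'
#' Phenotypes are stored as a two-column CSV (`id,value`). Ids must be unique.
#'
#' @param path file path.
#' @return A tibble with columns `id` (character) and `value` (numeric).
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c("character", "numeric"))
  names(tab) <- c("id", "value")
  as_phenotypes(tab)
}

#' @rdname read_phenotypes
#' @param phen a phenotype tibble/data frame with columns `id`, `value`.
#' @export
write_phenotypes <- function(phen, path) {
  phen <- as_phenotypes(phen)
  utils::write.csv(phen, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

as_phenotypes <- function(phen) {
  phen <- tibble::as_tibble(phen)
  if (!all(c("id", "value") %in% names(phen)))
    stop("phenotypes need columns `id` and `value`")
  phen$id <- as.character(phen$id)
  if (anyDuplicated(phen$id)) stop("duplicate animal ids in phenotypes")
  if (!is.numeric(phen$value)) stop("phenotype `value` must be numeric")
  phen[, c("id", "value")]
}

#' Read and write pedigrees
#'
#' Pedigrees are three-column CSVs (`id,sire,dam`), one row per individual,
#' with `"0"` (or empty) marking an unknown parent. Rows must be ordered so
#' that every parent appears before its offspring; this is validated on read
#' and construction.
#'
#' @param path file path.
#' @return A tibble of class `pedigree` with character columns `id`, `sire`,
#'   `dam` (`"0"` = unknown).
#' @export
read_pedigree <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  names(tab) <- c("id", "sire", "dam")
  as_pedigree(tab)
}

#' @rdname read_pedigree
#' @param ped a pedigree tibble/data frame with columns `id`, `sire`, `dam`.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.csv(as_pedigree(ped)[, c("id", "sire", "dam")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_pedigree
#' @export
as_pedigree <- function(ped) {
  ped <- tibble::as_tibble(ped)
  if (!all(c("id", "sire", "dam") %in% names(ped)))
    stop("pedigree needs columns `id`, `sire`, `dam`")
  for (cn in c("id", "sire", "dam")) {
    ped[[cn]] <- as.character(ped[[cn]])
    ped[[cn]][is.na(ped[[cn]]) | ped[[cn]] == ""] <- "0"
  }
  if (any(ped$id == "0")) stop("'0' is reserved for unknown parents")
  if (anyDuplicated(ped$id)) stop("duplicate ids in pedigree")
  seen <- character(0)
  for (i in seq_len(nrow(ped))) {
    if (ped$sire[i] == ped$id[i] || ped$dam[i] == ped$id[i])
      stop(sprintf("individual '%s' is its own parent", ped$id[i]))
    for (par in c(ped$sire[i], ped$dam[i])) {
      if (par != "0" && !(par %in% seen))
        stop(sprintf("parent '%s' of '%s' does not precede it in the pedigree",
                     par, ped$id[i]))
    }
    seen <- c(seen, ped$id[i])
  }
  class(ped) <- c("pedigree", class(ped))
  ped
}

ped_parent_index <- function(ped) {
  # 1-based indices into pedigree order; 0 = unknown
  idx <- stats::setNames(seq_len(nrow(ped)), ped$id)
  s <- ifelse(ped$sire == "0", 0L, idx[ped$sire])
  d <- ifelse(ped$dam == "0", 0L, idx[ped$dam])
  list(sire = unname(as.integer(s)), dam = unname(as.integer(d)))
}

#' Write fit outputs to CSV
#'
#' `write_posterior()` stores the saved per-iteration samples of a Gibbs fit
#' (columns: `iteration`, `mu`, `sigma_e2`, `scale` where sampled, `h2`, and
#' per-group `sigma_k2_*` / `h2_k_*`); `write_effects()` stores the per-marker
#' posterior summary (`marker_id`, `group`, `posterior_mean_beta`,
#' `explained_variance`); `write_pbv()` stores predicted breeding values
#' (`animal_id`, `pbv`); `write_groups()` stores a group assignment
#' (`marker_id`, `rank`, `group`). All round-trip through `read.csv` at full
#' stored precision (15 significant digits).
#'
#' @param fit a fitted object from [run_snp_blup()] or [run_grouped()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_posterior <- function(fit, path) {
  stopifnot(inherits(fit, "gibbs_fit"))
  write_csv_precise(fit$samples, path)
}

#' @rdname write_posterior
#' @export
write_effects <- function(fit, path) {
  stopifnot(inherits(fit, "gibbs_fit"))
  write_csv_precise(tidy(fit), path)
}

#' @rdname write_posterior
#' @param pbv named numeric vector of predicted breeding values.
#' @export
write_pbv <- function(pbv, path) {
  write_csv_precise(tibble::tibble(animal_id = names(pbv), pbv = unname(pbv)),
                    path)
}

#' @rdname write_posterior
#' @param groups a [group_assignment] tibble from [assign_groups()].
#' @export
write_groups <- function(groups, path) {
  stopifnot(inherits(groups, "group_assignment"))
  write_csv_precise(groups[, c("marker_id", "rank", "group")], path)
}

#' @rdname write_posterior
#' @export
read_pbv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c("character", "numeric"))
  stats::setNames(tab$pbv, tab$animal_id)
}

#' @rdname write_posterior
#' @export
read_groups <- function(path) {
  tab <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  tab$marker_id <- as.character(tab$marker_id)
  class(tab) <- c("group_assignment", class(tab))
  tab
}

write_csv_precise <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  for (cn in names(df)[num]) df[[cn]] <- sprintf("%.15g", df[[cn]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
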