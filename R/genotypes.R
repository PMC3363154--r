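#' Genotype matrix container
#'
#' A `geno_matrix` holds an animals-by-markers allele dosage matrix together
#' with the per-marker counted-allele frequencies and a centering flag. Dosages
#' are coded 0/1/2 (copies of the counted allele) before centering. The allele
#' frequency of marker j is the column mean dosage divided by 2, always
#' computed on the uncentered matrix; it is the frequency of the counted
#' allele, not forced to be the minor allele (everything downstream uses
#' p(1-p), which is symmetric in p).
#'
#' @param dosages numeric matrix, animals in rows, markers in columns, with
#'   dimnames giving animal and marker ids. Values in `{0, 1, 2}` or, after
#'   mean imputation, column means.
#' @param allele_freq optional numeric vector of counted-allele frequencies;
#'   computed from `dosages` when missing.
#' @param centered logical; `TRUE` once [center_genotypes()] has been applied.
#' @param centers numeric vector of the column means subtracted at centering
#'   time (`2 * allele_freq` of the data the centering was derived from).
#' @return An object of class `geno_matrix`.
#' @seealso [read_genotypes()], [filter_maf()], [center_genotypes()]
#' @export
geno_matrix <- function(dosages, allele_freq = NULL, centered = FALSE,
                        centers = NULL) {
  if (!is.matrix(dosages) || !is.numeric(dosages))
    stop("`dosages` must be a numeric matrix")
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("A", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("M", seq_len(ncol(dosages)))
  if (anyDuplicated(rownames(dosages))) stop("duplicate animal ids")
  if (anyDuplicated(colnames(dosages))) stop("duplicate marker ids")
  if (is.null(allele_freq)) {
    if (centered) stop("`allele_freq` is required for pre-centered dosages")
    allele_freq <- colMeans(dosages) / 2
  }
  if (length(allele_freq) != ncol(dosages))
    stop("`allele_freq` length does not match the number of markers")
  structure(
    list(dosages = dosages,
         allele_freq = stats::setNames(as.numeric(allele_freq), colnames(dosages)),
         centered = isTRUE(centered),
         centers = centers),
    class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d animals x %d markers (%s)\n",
              nrow(x$dosages), ncol(x$dosages),
              if (x$centered) "centered" else "uncentered"))
  removed <- attr(x, "removed")
  if (!is.null(removed))
    cat(sprintf("  %d markers removed by MAF filter\n", length(removed)))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Animal and marker identifiers of a genotype matrix
#' @param g a [geno_matrix()].
#' @return Character vector of ids.
#' @export
animal_ids <- function(g) rownames(g$dosages)

#' @rdname animal_ids
#' @export
marker_ids <- function(g) colnames(g$dosages)

#' Minor allele frequencies
#'
#' @param g a [geno_matrix()].
#' @return Named numeric vector `min(p, 1 - p)` per marker.
#' @export
maf <- function(g) pmin(g$allele_freq, 1 - g$allele_freq)

#' Read a genotype matrix from disk
#'
#' Two dialects are supported. `"matrix"` is delimited text (comma or tab,
#' auto-detected) with a header row of marker ids and a first column of animal
#' ids; cells must be 0, 1, 2 or NA. `"vcf"` is a standard VCF v4.x file whose
#' biallelic sites are converted to counts of the first ALT allele;
#' multi-allelic records are skipped with a warning. Missing cells are imputed
#' to the column mean dosage at load time, so that centered columns are
#' exactly mean zero.
#'
#' @param path file path.
#' @param format `"auto"` (by file extension), `"matrix"` or `"vcf"`.
#' @return An uncentered [geno_matrix()] with allele frequencies populated.
#' @export
read_genotypes <- function(path, format = c("auto", "matrix", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "matrix"
  if (format == "vcf") return(read_genotypes_vcf(path))

  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  ids <- tab[[1L]]
  raw <- as.matrix(tab[, -1L, drop = FALSE])
  m <- raw
  marker_names <- colnames(m)
  suppressWarnings(storage.mode(m) <- "double")
  na_ok <- is.na(raw) | toupper(trimws(raw)) %in% c("NA", "")
  bad <- (is.na(m) & !na_ok) | (!is.na(m) & !(m %in% c(0, 1, 2)))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid genotype at animal '%s', marker '%s' (must be 0, 1, 2 or NA)",
                 ids[idx[1L]], marker_names[idx[2L]]))
  }
  rownames(m) <- ids
  impute_and_wrap(m)
}

impute_and_wrap <- function(m) {
  if (anyNA(m)) {
    for (j in which(colSums(is.na(m)) > 0L)) {
      obs <- m[, j][!is.na(m[, j])]
      if (length(obs) == 0L) stop("marker '", colnames(m)[j], "' is entirely missing")
      m[is.na(m[, j]), j] <- mean(obs)
    }
  }
  geno_matrix(m)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF import requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt) | is.na(alt) | alt == "."
  if (any(multi)) {
    warning(sprintf("skipping %d non-biallelic VCF record(s)", sum(multi)))
    v <- v[!multi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || ncol(gt) == 0L) stop("VCF has no genotype columns")
  dose <- apply(gt, c(1, 2), function(s) {
    if (is.na(s)) return(NA_real_)
    alleles <- strsplit(s, "[/|]")[[1L]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles == "1")
  })
  ids <- vcfR::getID(v)
  if (any(is.na(ids)))
    ids[is.na(ids)] <- paste0(vcfR::getCHROM(v)[is.na(ids)], "_",
                              vcfR::getPOS(v)[is.na(ids)])
  rownames(dose) <- ids
  impute_and_wrap(t(dose))
}

#' Filter markers on minor allele frequency
#'
#' Keeps marker j iff `min(p_j, 1 - p_j) > threshold` — a strict inequality,
#' so a marker sitting exactly at the threshold is removed. The ids of removed
#' markers are attached as the `"removed"` attribute of the result.
#'
#' @param g an uncentered [geno_matrix()].
#' @param threshold MAF threshold in `[0, 0.5)`; default 0.01.
#' @return The filtered [geno_matrix()]; `attr(, "removed")` holds the removed
#'   marker ids (possibly empty).
#' @export
filter_maf <- function(g, threshold = 0.01) {
  stopifnot(inherits(g, "geno_matrix"))
  if (g$centered) stop("filter_maf() expects an uncentered genotype matrix")
  if (threshold < 0 || threshold >= 0.5) stop("`threshold` must be in [0, 0.5)")
  keep <- maf(g) > threshold
  if (!any(keep)) stop("MAF filter removed every marker")
  out <- geno_matrix(g$dosages[, keep, drop = FALSE],
                     allele_freq = g$allele_freq[keep])
  attr(out, "removed") <- marker_ids(g)[!keep]
  out
}

#' Center genotype columns
#'
#' Subtracts the column mean from each dosage column so every column has mean
#' zero (the coding the regression models expect). When predicting for new
#' animals, pass the training-column means via `at` so the new dosages are
#' expressed on the training scale.
#'
#' @param g an uncentered [geno_matrix()].
#' @param at optional numeric vector of centers (training column means, i.e.
#'   `2 * p_train`), named by marker id; defaults to the column means of `g`.
#' @return A centered [geno_matrix()]; `allele_freq` is unchanged and the
#'   applied centers are stored in `$centers`.
#' @export
center_genotypes <- function(g, at = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  if (g$centered) stop("genotype matrix is already centered")
  if (is.null(at)) {
    at <- colMeans(g$dosages)
  } else {
    if (!is.null(names(at))) {
      miss <- setdiff(marker_ids(g), names(at))
      if (length(miss) > 0L)
        stop("no centers for markers: ", paste(utils::head(miss, 5L), collapse = ", "))
      at <- at[marker_ids(g)]
    }
    if (length(at) != ncol(g$dosages)) stop("`at` has the wrong length")
  }
  geno_matrix(sweep(g$dosages, 2L, at, "-"),
              allele_freq = g$allele_freq, centered = TRUE,
              centers = stats::setNames(as.numeric(at), marker_ids(g)))
}

#' Write a genotype matrix to delimited text
#'
#' @param g a [geno_matrix()] (uncentered dosages are written as stored).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "geno_matrix"))
  df <- data.frame(id = animal_ids(g), g$dosages, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
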