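#' Variance explained by a marker
#'
#' The population variance attributed to a marker with counted-allele
#' frequency `p` and allele substitution effect `beta`, computed as
#' `p * (1 - p) * beta^2`. This is the ranking score of the two-step
#' procedure; the conventional additive-variance expression carries an extra
#' factor 2 (`factor2 = TRUE`), which changes no ranks.
#'
#' @param p allele frequency (vector), in `[0, 1]`.
#' @param beta allele substitution effect (vector).
#' @param factor2 multiply by 2 to get the conventional additive variance.
#' @return Numeric vector of scores.
#' @export
explained_variance <- function(p, beta, factor2 = FALSE) {
  stopifnot(all(p >= 0 & p <= 1), length(p) == length(beta))
  (if (factor2) 2 else 1) * p * (1 - p) * beta^2
}

#' Group markers by ranked explained variance
#'
#' Sorts markers by score in decreasing order (ties broken by original input
#' position, so the result is deterministic) and chunks the ranking into
#' consecutive groups of `group_size`: group 1 holds the top-ranked markers.
#' If the marker count is not a multiple of `group_size` the final remainder
#' block forms its own, smaller group, so every marker belongs to exactly one
#' group.
#'
#' @param scores numeric vector of per-marker scores, named by marker id, or a
#'   data frame with columns `marker_id` and `score` (a [tidy.gibbs_fit()]
#'   result with its `explained_variance` column renamed works directly).
#' @param group_size markers per group (default 150).
#' @return A tibble of class `group_assignment` in rank order with columns
#'   `marker_id`, `score`, `rank`, `group`; `attr(, "group_sizes")` holds the
#'   per-group counts `n_k`.
#' @export
assign_groups <- function(scores, group_size = 150) {
  scores <- as_score_vector(scores)
  if (length(scores) == 0L) stop("no markers to group")
  stopifnot(group_size >= 1)
  ord <- order(-scores, seq_along(scores))
  q <- length(scores)
  grp <- ceiling(seq_len(q) / group_size)
  out <- tibble::tibble(marker_id = names(scores)[ord],
                        score = unname(scores[ord]),
                        rank = seq_len(q),
                        group = as.integer(grp))
  attr(out, "group_sizes") <- as.integer(table(grp))
  class(out) <- c("group_assignment", class(out))
  out
}

as_score_vector <- function(scores) {
  if (is.data.frame(scores)) {
    if (!all(c("marker_id", "score") %in% names(scores)))
      stop("score data frame needs columns `marker_id` and `score`")
    scores <- stats::setNames(scores$score, scores$marker_id)
  }
  if (length(scores) == 0L) stop("no markers to group or select")
  if (is.null(names(scores)))
    names(scores) <- paste0("M", seq_along(scores))
  scores
}

#' @export
print.group_assignment <- function(x, ...) {
  sizes <- attr(x, "group_sizes")
  cat(sprintf("<group_assignment> %d markers in %d groups (sizes: %s)\n",
              nrow(x), length(sizes),
              paste(utils::head(sizes, 12L), collapse = ", ")))
  invisible(x)
}

#' Group sizes of an assignment
#' @param groups a [assign_groups()] result.
#' @return Integer vector `n_k`, one entry per group.
#' @export
group_sizes <- function(groups) {
  stopifnot(inherits(groups, "group_assignment"))
  sizes <- attr(groups, "group_sizes")
  if (is.null(sizes)) sizes <- as.integer(table(groups$group))
  sizes
}

#' Select the top-scoring markers
#'
#' Returns the `k` markers with the largest scores, in rank order, with the
#' same deterministic tie-breaking as [assign_groups()] (ties go to the
#' earlier input position). Used to build the reduced panels that keep only
#' the markers with the largest effects.
#'
#' @inheritParams assign_groups
#' @param k number of markers to keep.
#' @return Character vector of marker ids in rank order.
#' @export
select_top <- function(scores, k) {
  scores <- as_score_vector(scores)
  if (k <= 0) stop("`k` must be positive")
  if (k > length(scores)) stop("`k` exceeds the number of scored markers")
  ord <- order(-scores, seq_along(scores))
  names(scores)[ord][seq_len(k)]
}

#' Subset a genotype matrix to a marker list
#'
#' @param g a [geno_matrix()].
#' @param markers character vector of marker ids (order preserved).
#' @return A [geno_matrix()] restricted to `markers`.
#' @export
subset_markers <- function(g, markers) {
  stopifnot(inherits(g, "geno_matrix"))
  miss <- setdiff(markers, marker_ids(g))
  if (length(miss) > 0L)
    stop("markers not in genotype matrix: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  geno_matrix(g$dosages[, markers, drop = FALSE],
              allele_freq = g$allele_freq[markers],
              centered = g$centered,
              centers = if (!is.null(g$centers)) g$centers[markers] else NULL)
}
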