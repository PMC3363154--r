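#' Tidy a Gibbs fit into a per-marker tibble
#'
#' One row per marker with the posterior-mean allele substitution effect, the
#' marker's group (1 for SNP-BLUP fits), and the variance it explains,
#' `p(1-p) * beta^2`.
#'
#' @param x a `gibbs_fit` from [run_snp_blup()] or [run_grouped()].
#' @param ... unused.
#' @return A tibble with columns `marker_id`, `group`, `posterior_mean_beta`,
#'   `explained_variance`.
#' @export
tidy.gibbs_fit <- function(x, ...) {
  grp <- if (!is.null(x$group_of)) unname(x$group_of) else rep(1L, length(x$beta))
  tibble::tibble(
    marker_id = names(x$beta),
    group = as.integer(grp),
    posterior_mean_beta = unname(x$beta),
    explained_variance = unname(explained_variance(x$allele_freq[names(x$beta)],
                                                   x$beta)))
}

#' One-row summary of a Gibbs fit
#'
#' @param x a `gibbs_fit`.
#' @param ... unused.
#' @return A tibble with the model label, posterior-mean heritability and
#'   variance components, chain bookkeeping, and problem sizes.
#' @export
glance.gibbs_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    h2 = x$h2,
    sigma_e2 = x$sigma_e2,
    scale = if (!is.null(x$scale)) x$scale else NA_real_,
    df = if (!is.null(x$df)) x$df else NA_real_,
    n_markers = length(x$beta),
    n_groups = if (!is.null(x$h2_k)) length(x$h2_k) else 1L,
    n_saved = nrow(x$samples))
}

#' @rdname tidy.gibbs_fit
#' @export
tidy.animal_model_fit <- function(x, ...) x$bv

#' @rdname glance.gibbs_fit
#' @export
glance.animal_model_fit <- function(x, ...) {
  tibble::tibble(model = paste0("animal_blup_", x$method),
                 h2 = x$h2, sigma_a2 = x$sigma_a2, sigma_e2 = x$sigma_e2,
                 mu = x$mu, n_records = x$n_records, n_iter = x$n_iter)
}

#' Plot the per-group heritability profile
#'
#' Bar chart of the posterior-mean heritability attributed to each marker
#' group (group 1 = largest-effect markers), with 95% credible intervals —
#' the standard display of how prior degrees of freedom redistribute the
#' genomic variance across groups.
#'
#' @param fit a `grouped_fit`, or a named list of them to overlay (e.g. one
#'   fit per prior df).
#' @return A ggplot object.
#' @export
plot_group_h2 <- function(fit) {
  fits <- if (inherits(fit, "gibbs_fit")) list(fit = fit) else fit
  stopifnot(all(vapply(fits, inherits, TRUE, "gibbs_fit")))
  if (is.null(names(fits))) names(fits) <- paste0("fit_", seq_along(fits))
  dat <- dplyr::bind_rows(lapply(names(fits), function(nm) {
    rep_ <- heritability_report(fits[[nm]])
    rep_ <- rep_[rep_$component != "total", ]
    rep_$group <- as.integer(sub("^group_", "", rep_$component))
    rep_$fit <- nm
    rep_
  }))
  if (nrow(dat) == 0L) stop("no per-group heritabilities to plot")
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$group), y = .data$mean,
                                    fill = .data$fit)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                           position = ggplot2::position_dodge(width = 0.8),
                           width = 0.25, linewidth = 0.3) +
    ggplot2::labs(x = "marker group (1 = largest effects)",
                  y = expression(h[k]^2), fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_group_h2
#' @param object a `grouped_fit`.
#' @param ... unused.
#' @export
autoplot.grouped_fit <- function(object, ...) plot_group_h2(object)

#' Trace plot of saved variance samples
#'
#' @param fit a `gibbs_fit`.
#' @param pars columns of `fit$samples` to show (default: the scalar variance
#'   parameters present).
#' @return A ggplot object.
#' @export
plot_trace <- function(fit, pars = NULL) {
  stopifnot(inherits(fit, "gibbs_fit"))
  if (is.null(pars))
    pars <- intersect(c("mu", "sigma_e2", "sigma_beta2", "scale", "h2"),
                      names(fit$samples))
  long <- tidyr::pivot_longer(fit$samples[, c("iteration", pars)],
                              -"iteration", names_to = "parameter")
  ggplot2::ggplot(long, ggplot2::aes(.data$iteration, .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "saved sample", y = NULL) +
    ggplot2::theme_minimal()
}
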