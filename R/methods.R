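## broom-style accessors and ggplot2 displays

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname tidy.twin_fit
#' @export
glance.twin_fit <- function(x, ...) {
  tibble(loglik = x$loglik, npar = x$npar, n_pairs_used = x$n_pairs_used,
         converged = x$converged, gradient_norm = x$gradient_norm,
         aic = -2 * x$loglik + 2 * x$npar,
         bic = -2 * x$loglik + log(x$n_pairs_used) * x$npar)
}

#' Tidy a FIML twin-model fit
#'
#' `tidy()` returns one row per estimated parameter; `glance()` a one-row fit
#' summary (log-likelihood, parameter count, information criteria,
#' convergence).
#'
#' @param x A `twin_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.twin_fit <- function(x, ...) {
  tibble(term = names(x$par), estimate = as.numeric(x$par))
}

#' @export
tidy.sex_moderation_test <- function(x, ...) x$table

#' @export
tidy.cfa_fit <- function(x, ...) {
  lo <- x$loadings
  out <- tibble(term = paste0("loading_", rownames(lo)),
                estimate = lo[cbind(seq_len(nrow(lo)), max.col(abs(lo)))])
  bind_rows(out, tibble(term = "factor_correlation",
                        estimate = x$factor_correlation))
}

#' @export
tidy.boxcox_result <- function(x, ...) {
  tibble(term = c("lambda", "loglik", "scale_factor"),
         estimate = c(x$lambda, x$loglik_at_lambda, x$scale_factor))
}

#' Plot an ADE decomposition
#'
#' Stacked bars of the standardized a2, d2 and e2 shares per phenotype.
#'
#' @param object An `ade_decomposition` from [decompose_ade()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ade_decomposition <- function(object, ...) {
  df <- object$components %>%
    tidyr::pivot_longer(c("a2", "d2", "e2"), names_to = "component",
                        values_to = "share") %>%
    mutate(component = factor(.data$component, levels = c("e2", "d2", "a2"),
                              labels = c("E", "D", "A")),
           phenotype = factor(.data$phenotype, levels = object$phenotypes))
  ggplot2::ggplot(df, ggplot2::aes(x = phenotype, y = share, fill = component)) +
    ggplot2::geom_col() +
    ggplot2::labs(y = "standardized variance share", x = NULL,
                  title = "ADE decomposition (rater variance excluded)") +
    ggplot2::theme_minimal()
}

#' Heatmap of a correlation matrix
#'
#' @param mat Correlation matrix (e.g. `corr_ad` from [decompose_ade()]).
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_correlation_matrix <- function(mat, title = NULL) {
  ph <- rownames(mat) %||% paste0("P", seq_len(nrow(mat)))
  df <- tidyr::expand_grid(row_ph = ph, col_ph = ph) %>%
    mutate(value = as.vector(t(mat)),
           row_ph = factor(.data$row_ph, levels = rev(ph)),
           col_ph = factor(.data$col_ph, levels = ph))
  ggplot2::ggplot(df, ggplot2::aes(x = col_ph, y = row_ph, fill = value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$value)), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, title = title) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.twin_fit <- function(object, ...) {
  if (!inherits(object$estimates, "ade_parameters"))
    stop_twinade("autoplot is available for Cholesky ADE fits; use tidy() otherwise")
  autoplot.ade_decomposition(decompose_ade(object$estimates))
}
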