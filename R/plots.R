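#' Heat-map of a 2D free-energy landscape
#'
#' @param object A [pmf_2d()] grid.
#' @param ... Unused.
#' @return A ggplot object (free energy in kcal/mol; undefined bins blank).
#' @export
autoplot.pmf_grid <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df[!is.na(df$G), ],
                  ggplot2::aes(x = .data$cv1, y = .data$cv2, fill = .data$G)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "G (kcal/mol)", direction = -1) +
    ggplot2::labs(x = "CV 1 (Å)", y = "CV 2 (Å)",
                  title = "Free-energy landscape") +
    ggplot2::theme_minimal()
}

#' Heat-map of a dynamic cross-correlation matrix
#'
#' @param object A [dccm()] matrix, optionally masked with [mask_dccm()]
#'   (masked entries render white).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dccm <- function(object, ...) {
  m <- unclass(object)
  df <- tibble(i = rep(seq_len(nrow(m)), times = ncol(m)),
               j = rep(seq_len(ncol(m)), each = nrow(m)),
               c = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j, fill = .data$c)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(name = expression(C[ij]), limits = c(-1, 1),
                                  low = "blue", mid = "white", high = "red",
                                  na.value = "white") +
    ggplot2::labs(x = "Residue", y = "Residue",
                  title = "Dynamic cross-correlation matrix") +
    ggplot2::theme_minimal()
}

#' Bar chart of MM/PBSA components
#'
#' @param object A [mmpbsa_binding()] report.
#' @param ... Unused.
#' @return A ggplot object with mean +/- sd per component.
#' @export
autoplot.binding_report <- function(object, ...) {
  s <- object$summary
  s$component <- factor(s$component, levels = s$component)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$component, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.3) +
    ggplot2::labs(x = NULL, y = "Energy (kcal/mol)",
                  title = "MM/PBSA binding components") +
    ggplot2::theme_minimal()
}

#' RMSF profile plot
#'
#' @param rmsf_tbl Output of [rmsf()].
#' @return A ggplot object.
#' @export
plot_rmsf <- function(rmsf_tbl) {
  ggplot2::ggplot(rmsf_tbl, ggplot2::aes(x = .data$resid, y = .data$rmsf)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Residue", y = "RMSF (Å)") +
    ggplot2::theme_minimal()
}
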