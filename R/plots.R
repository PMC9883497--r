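#' Kaplan-Meier curves of the optimal dichotomization
#'
#' Step curves for the low/high marker groups at the scan's optimal cutoff,
#' annotated with the naive log-rank p value.
#'
#' @param x an `nfyar_cutoff` object.
#' @return a ggplot object.
#' @export
plot_km_curves <- function(x) {
  stopifnot(inherits(x, "nfyar_cutoff"))
  km <- dplyr::bind_rows(
    tibble::tibble(time = 0, survival = 1,
                   group = unique(x$km$group)),
    x$km[, c("time", "survival", "group")]
  )
  ggplot2::ggplot(km, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "time", y = "progression-free survival",
      title = sprintf("Optimal cutoff %.3g (log-rank p = %.2g)",
                      x$cutoff, x$p_value),
      colour = "marker group") +
    ggplot2::theme_minimal()
}

#' Scale-free fit and connectivity across candidate powers
#'
#' @param sft result of [pick_soft_threshold()].
#' @return a ggplot object (signed R^2 and mean connectivity vs power).
#' @export
plot_soft_threshold <- function(sft) {
  tab <- sft$table |>
    tidyr::pivot_longer(c("sft_r_squared", "mean_connectivity"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$power, y = .data$value)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::geom_vline(xintercept = sft$suggested_power, linetype = 2) +
    ggplot2::labs(x = "soft-thresholding power", y = NULL) +
    ggplot2::theme_minimal()
}

#' Module sizes of a partition
#'
#' @param object an `nfyar_modules` object.
#' @param ... unused.
#' @return a ggplot bar chart of module sizes (module 0 = unassigned).
#' @export
autoplot.nfyar_modules <- function(object, ...) {
  tab <- tidy(object) |>
    dplyr::count(.data$module, name = "n_genes") |>
    dplyr::mutate(module = factor(.data$module))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$module, y = .data$n_genes,
                                    fill = .data$module == "0")) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey70", `FALSE` = "steelblue")) +
    ggplot2::labs(x = "module (0 = unassigned)", y = "genes") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Stacked mean cell-type composition across strata
#'
#' @param stratum_means output of [average_by_stratum()].
#' @return a ggplot stacked bar chart.
#' @export
plot_strata <- function(stratum_means) {
  long <- tidyr::pivot_longer(stratum_means, -"stratum",
                              names_to = "cell_type",
                              values_to = "mean_proportion")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$stratum),
                                     y = .data$mean_proportion,
                                     fill = .data$cell_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "stratum", y = "mean proportion", fill = "cell type") +
    ggplot2::theme_minimal()
}

#' Significance grid of the cross-cohort RBP screen
#'
#' Tile plot of per-cohort significance flags (up / down / none) for the
#' top-ranked RBPs, mirroring the usual presentation of pan-cancer screens.
#'
#' @param ranking an `nfyar_rbp_ranking` object.
#' @param which `"up"` or `"down"` table.
#' @return a ggplot object.
#' @export
plot_rbp_grid <- function(ranking, which = c("up", "down")) {
  which <- match.arg(which)
  stopifnot(inherits(ranking, "nfyar_rbp_ranking"))
  top <- ranking[[which]]$rbp
  flags <- ranking$flags |>
    dplyr::filter(.data$rbp %in% top) |>
    dplyr::mutate(rbp = factor(.data$rbp, levels = rev(top)),
                  state = factor(.data$flag, levels = c(1, 0, -1),
                                 labels = c("up", "ns", "down")))
  ggplot2::ggplot(flags, ggplot2::aes(x = .data$cohort, y = .data$rbp,
                                      fill = .data$state)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(up = "darkgreen", ns = "grey90",
                                          down = "firebrick")) +
    ggplot2::labs(x = "cohort", y = "RBP", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
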