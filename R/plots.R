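# ggplot2 views of the result types.

#' Plot driver scores as a gene-by-patient heat map
#'
#' Shows the propagated score of the `n_genes` highest-scoring genes
#' (by cohort mean) across all patients.
#'
#' @param object A `driver_scores` tibble from [propagate()].
#' @param n_genes Number of genes to display (default 25).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.driver_scores <- function(object, n_genes = 25L, ...) {
  means <- dplyr::summarise(dplyr::group_by(object, .data$gene),
                            mean_score = mean(.data$score), .groups = "drop")
  keep <- head(dplyr::arrange(means, dplyr::desc(.data$mean_score),
                              .data$gene)$gene, n_genes)
  dat <- dplyr::filter(object, .data$gene %in% keep)
  dat$gene <- factor(dat$gene, levels = rev(keep))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$patient, y = .data$gene,
                                    fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "score") +
    ggplot2::labs(x = "patient", y = NULL,
                  title = "Propagated driver scores") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 7))
}

#' Plot cohort recurrence of candidate drivers
#'
#' Bar chart of the fraction of patients carrying each gene in their
#' per-patient top list, with the recurrence threshold marked; genes
#' above the line are the cohort drivers.
#'
#' @param object A `driver_calls` object from [call_drivers()].
#' @param n_genes Number of most recurrent genes to display (default 30).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.driver_calls <- function(object, n_genes = 30L, ...) {
  dat <- head(object$recurrence_counts, n_genes)
  dat$gene <- factor(dat$gene, levels = rev(dat$gene))
  dat$called <- dat$fraction > object$recurrence
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$fraction, y = .data$gene,
                                    fill = .data$called)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = object$recurrence, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#D55E00", `FALSE` = "grey70"),
                               name = "cohort driver") +
    ggplot2::labs(x = paste0("fraction of patients (top ", object$top_n, ")"),
                  y = NULL, title = "Candidate-driver recurrence") +
    ggplot2::theme_minimal()
}

#' Plot the size of each patient's personalized network
#'
#' @param run A `driver_run` object from [run_pipeline()].
#' @return A ggplot object: edges and matched genes per patient.
#' @export
plot_network_sizes <- function(run) {
  stopifnot(inherits(run, "driver_run"))
  dat <- tidyr::pivot_longer(tidy(run), cols = -"patient",
                             names_to = "quantity", values_to = "count")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$patient, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Personalized network and matching sizes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 7))
}
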