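#' Drift landscape of a call set
#'
#' Scatter of each tested probe's grade-correlation rho against its
#' extreme-grade |Delta-Beta| effect, called grade-CpGs highlighted and the
#' effect threshold drawn.
#'
#' @param object A `grade_cpg_calls` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.grade_cpg_calls <- function(object, ...) {
  rec <- object$records
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$rho, y = .data$extreme_effect,
                                    colour = .data$is_grade_cpg)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = object$config$effect_delta_beta,
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 name = "grade-CpG") +
    ggplot2::labs(x = "Spearman rho (Delta-M vs grade)",
                  y = "|mean Delta-Beta VII - III|")
}

#' Heatmap of a Ward bicluster
#'
#' Delta-Beta heatmap with probes and donors in dendrogram leaf order and
#' donors annotated by their 2-cluster label.
#'
#' @param object A `ward_bicluster` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ward_bicluster <- function(object, ...) {
  m <- object$matrix[object$row_order, object$col_order, drop = FALSE]
  df <- as_tibble(m, rownames = "probe_id") %>%
    tidyr::pivot_longer(-"probe_id", names_to = "donor_id",
                        values_to = "delta") %>%
    mutate(probe_id = factor(.data$probe_id, levels = rev(object$row_order)),
           donor_id = factor(.data$donor_id, levels = object$col_order))
  ggplot2::ggplot(df, ggplot2::aes(.data$donor_id, .data$probe_id,
                                   fill = .data$delta)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", name = "Delta-Beta") +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank()) +
    ggplot2::labs(x = "donor", y = "probe")
}

#' Direction and strata composition of a call set
#'
#' Bar chart of hyper/hypo direction counts, optionally faceted by baseline
#' methylation stratum of the normal tissue.
#'
#' @param calls A `grade_cpg_calls` object.
#' @param beta Optional Beta matrix to derive baseline N strata.
#' @param cohort Cohort tibble (required with `beta`).
#' @return A ggplot.
#' @export
plot_direction <- function(calls, beta = NULL, cohort = NULL) {
  rec <- filter(calls$records, .data$is_grade_cpg)
  if (!is.null(beta) && !is.null(cohort)) {
    pairs <- cohort_pairs(cohort)
    mat <- beta_as_matrix(beta)
    mn <- rowMeans(mat[, pairs$sample_N, drop = FALSE])
    rec <- mutate(rec, stratum = baseline_strata(
      mn[match(.data$probe_id, rownames(mat))], calls$config))
  }
  p <- ggplot2::ggplot(rec, ggplot2::aes(x = .data$direction,
                                         fill = .data$direction)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = NULL, y = "grade-CpGs") +
    ggplot2::guides(fill = "none")
  if ("stratum" %in% names(rec)) p <- p + ggplot2::facet_wrap(~stratum)
  p
}
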