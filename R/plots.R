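#' Probe-level scan plot
#'
#' -log10 of the HEIDI-penalized SMR p by probe position, faceted by
#' chromosome, with the suggestive line at 1/m.
#'
#' @param records SMR records from [run_smr()].
#' @param m_tests Number of tests for the suggestive line (default: number
#'   of records).
#' @return A ggplot object.
#' @export
plot_smr_scan <- function(records, m_tests = nrow(records)) {
  df <- dplyr::mutate(records,
                      mlogp = -log10(.data$p_smr_adj),
                      heidi_low = !is.na(.data$p_heidi) & .data$p_heidi < 0.01)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$probe_pos / 1e6, y = .data$mlogp,
                                   colour = .data$heidi_low)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(1 / max(m_tests, 1)),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "firebrick"),
                                 name = "HEIDI p < 0.01") +
    ggplot2::labs(x = "probe position (Mb)",
                  y = expression(-log[10] ~ "adjusted SMR p")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a concordance fit
#'
#' Pattern weights as a bar chart (`type = "weights"`), or the distribution
#' of per-study marginal posteriors (`type = "pp"`).
#'
#' @param object A `pattern_fit`.
#' @param type `"weights"` or `"pp"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pattern_fit <- function(object, type = c("weights", "pp"), ...) {
  type <- match.arg(type)
  if (type == "weights") {
    df <- tidy(object)
    ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$pattern, -.data$weight),
                                     y = .data$weight)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = "association pattern", y = "estimated weight") +
      ggplot2::theme_minimal()
  } else {
    df <- tidyr::pivot_longer(
      tibble::as_tibble(object$PP, .name_repair = ~object$studies),
      dplyr::all_of(object$studies), names_to = "study", values_to = "PP")
    ggplot2::ggplot(df, ggplot2::aes(x = .data$PP)) +
      ggplot2::geom_histogram(bins = 50, fill = "steelblue") +
      ggplot2::geom_vline(xintercept = 0.95, linetype = "dashed") +
      ggplot2::facet_wrap(~study) +
      ggplot2::labs(x = "marginal posterior probability of association",
                    y = "genes") +
      ggplot2::theme_minimal()
  }
}

#' Enrichment bar plot
#'
#' -log10 q by gene set, sets at q < threshold highlighted.
#'
#' @param enrichment Tibble from [run_enrichment()].
#' @param q_threshold Significance threshold (default 0.05).
#' @param top Show at most this many sets (smallest q).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, q_threshold = 0.05, top = 20) {
  df <- utils::head(dplyr::arrange(enrichment, .data$q), top)
  df$significant <- df$q < q_threshold
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$set_name, -.data$q),
                                   y = -log10(.data$q), fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(q_threshold), linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                               name = sprintf("q < %.2g", q_threshold)) +
    ggplot2::labs(x = NULL, y = expression(-log[10] ~ q)) +
    ggplot2::theme_minimal()
}
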