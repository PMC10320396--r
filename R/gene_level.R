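#' HEIDI-penalized SMR p-value
#'
#' Combines the SMR and HEIDI p-values into a single adjusted p-value:
#' `p_adj = min(1, p_smr / min(p_heidi / floor, 1))`. The SMR p is left
#' untouched when the HEIDI p is at or above the floor (default 0.01), and
#' penalized by the amount the HEIDI p falls below it. This soft penalty is
#' used instead of a hard HEIDI filter because LD-reference misalignment can
#' deflate HEIDI p-values at genuine signals. A missing HEIDI p (test not
#' run) applies no penalty.
#'
#' @param p_smr SMR p-value(s) in (0, 1].
#' @param p_heidi HEIDI p-value(s) in (0, 1], or `NA`.
#' @param floor Penalty floor (default 0.01).
#' @return Adjusted p-value(s), capped at 1.
#' @examples
#' adjust_for_heidi(1e-8, 5.94e-4)  # penalized by 0.0594
#' adjust_for_heidi(1e-8, 0.5)      # untouched
#' @export
adjust_for_heidi <- function(p_smr, p_heidi, floor = 0.01) {
  stopifnot(all(p_smr > 0 & p_smr <= 1, na.rm = TRUE), floor > 0)
  divisor <- ifelse(is.na(p_heidi), 1, pmin(p_heidi / floor, 1))
  pmin(1, p_smr / divisor)
}

#' Cauchy (ACAT) combination of p-values
#'
#' `T = sum(w_i * tan((0.5 - p_i) * pi))` with weights summing to 1; the
#' combined p is the standard Cauchy upper tail `0.5 - atan(T) / pi`. The
#' null distribution of T is standard Cauchy regardless of dependence among
#' the inputs, which is what makes the combination valid for correlated
#' probe-level p-values. Inputs below 1e-300 use the tail expansion
#' `w_i / (p_i * pi)`; inputs equal to 1 are clipped just below 1; very
#' large T uses the reciprocal tail so the result never underflows to 0.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param weights Optional non-negative weights (normalized internally;
#'   default equal).
#' @return A single combined p-value in (0, 1).
#' @export
cauchy_combine <- function(p, weights = NULL) {
  if (length(p) == 0) stop_format("cauchy_combine: empty p-value list")
  if (any(!is.finite(p)) || any(p <= 0 | p > 1))
    stop_format("cauchy_combine: p-values must lie in (0, 1]")
  w <- weights %||% rep(1, length(p))
  if (length(w) != length(p) || any(w < 0) || sum(w) == 0)
    stop_format("cauchy_combine: invalid weights")
  w <- w / sum(w)
  p <- pmin(p, 1 - 1e-15)
  terms <- ifelse(p < 1e-300, w / (p * pi), w * tan((0.5 - p) * pi))
  T_stat <- sum(terms)
  if (T_stat > 1e10) return(max(1 / (pi * T_stat), 1e-300))
  out <- 0.5 - atan(T_stat) / pi
  min(max(out, 1e-300), 1 - 1e-16)
}

#' Combine probe-level adjusted p-values to one p per gene
#'
#' Probes without a gene symbol are dropped; genes with a single probe keep
#' that probe's p; genes with several probes get the Cauchy combination.
#'
#' @param records Tibble of SMR records (needs `gene` and `p_smr_adj`), e.g.
#'   from [run_smr()].
#' @param study Study label (trait x tissue x paradigm) stamped on the
#'   output.
#' @return Tibble with one row per gene: `gene, study, p_combined, n_probes`.
#' @export
combine_by_gene <- function(records, study = "study") {
  mapped <- dplyr::filter(records, !is.na(.data$gene), .data$gene != "")
  out <- dplyr::summarise(dplyr::group_by(mapped, .data$gene),
                          p_combined = cauchy_combine(.data$p_smr_adj),
                          n_probes = dplyr::n(), .groups = "drop")
  dplyr::arrange(tibble::add_column(out, study = study, .after = "gene"),
                 .data$p_combined)
}

#' Suggestive and Bonferroni significance flags
#'
#' Suggestive means `p < 1/m` (the level crossed once per scan by chance);
#' Bonferroni means `p < alpha/m`. Both are strict inequalities; `m` is the
#' per-study number of tests (probes tested for probe-level flags, mapped
#' genes for gene-level flags).
#'
#' @param gene_stats Tibble with a p-value column named `p_combined` (or
#'   pass any tibble and name the column via `p_col`).
#' @param m_tests Number of tests in this study (>= 1).
#' @param alpha Family-wise error rate for the Bonferroni flag.
#' @param p_col Name of the p-value column.
#' @return The input with logical columns `suggestive` and `bonferroni`
#'   added; `m_tests` is recorded as an attribute.
#' @export
threshold_flags <- function(gene_stats, m_tests, alpha = 0.05, p_col = "p_combined") {
  stopifnot(m_tests >= 1)
  p <- gene_stats[[p_col]]
  gene_stats$suggestive <- p < 1 / m_tests
  gene_stats$bonferroni <- p < alpha / m_tests
  attr(gene_stats, "m_tests") <- m_tests
  gene_stats
}
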