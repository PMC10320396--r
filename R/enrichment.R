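#' Remove genes in the MHC region
#'
#' The major histocompatibility complex (chromosome 6, 25-35 Mb on GRCh37)
#' has such extreme LD that association signals there cannot be attributed
#' to individual genes; it is excluded before enrichment. The interval is
#' half-open `[start, end)` for determinism at the boundary. Genes without
#' coordinates in the annotation are kept (and reported via the
#' `n_no_coords` attribute).
#'
#' @param genes Character vector of gene symbols.
#' @param annot Tibble `gene, chrom, start` (e.g. [read_gene_annot()]).
#' @param chrom,start,end Region to excise (defaults: chr6 25-35 Mb).
#' @return Filtered gene vector with attributes `n_removed`, `n_no_coords`.
#' @export
filter_mhc <- function(genes, annot, chrom = "6", start = 25e6, end = 35e6) {
  idx <- match(genes, annot$gene)
  no_coords <- is.na(idx)
  in_mhc <- !no_coords &
    annot$chrom[idx] == chrom &
    annot$start[idx] >= start & annot$start[idx] < end
  out <- genes[!in_mhc]
  attr(out, "n_removed") <- sum(in_mhc)
  attr(out, "n_no_coords") <- sum(no_coords)
  out
}

#' Hypergeometric gene-set over-representation test
#'
#' Upper-tail hypergeometric probability `P(X >= k)` of observing `k`
#' query genes inside a set of size `K` when `n` genes are drawn from a
#' universe of size `N`. The universe may be an explicit gene list (query
#' and set are intersected with it; query genes outside it are dropped with
#' a warning) or just its size.
#'
#' @param query Character vector of query genes.
#' @param gene_set Character vector of set members.
#' @param universe Either a character vector (explicit universe) or a single
#'   number (universe size; query and set assumed within it).
#' @param set_name Label for the output row.
#' @return One-row tibble: `set_name, k, n_query, K_set, N_universe, p,
#'   overlap_genes` (list-column).
#' @export
hypergeom_test <- function(query, gene_set, universe = 54619, set_name = "set") {
  query <- unique(query)
  gene_set <- unique(gene_set)
  if (is.character(universe)) {
    universe <- unique(universe)
    dropped <- setdiff(query, universe)
    if (length(dropped) > 0)
      warning(length(dropped), " query gene(s) outside the universe dropped",
              call. = FALSE)
    query <- intersect(query, universe)
    gene_set <- intersect(gene_set, universe)
    N <- length(universe)
  } else {
    N <- as.integer(universe)
  }
  if (length(query) == 0) stop_format("hypergeom_test: empty query after filtering")
  overlap <- intersect(query, gene_set)
  k <- length(overlap)
  K <- length(gene_set)
  n <- length(query)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tibble::tibble(set_name = set_name, k = k, n_query = n, K_set = K,
                 N_universe = N, p = p, overlap_genes = list(overlap))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' @param p Non-empty numeric vector of p-values.
#' @return q-values in the input order (`stats::p.adjust` step-up method).
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) stop_format("bh_fdr: empty p-value list")
  stats::p.adjust(p, method = "BH")
}

#' Gene-set enrichment of a suggestive gene list
#'
#' Runs [hypergeom_test()] for every set in a GMT collection against a
#' fixed universe, optionally excising the MHC region from the query first,
#' and BH-adjusts across sets.
#'
#' @param query Character vector of (suggestive) gene symbols.
#' @param gene_sets Tibble from [read_gmt()] (columns `set_name`, `genes`).
#' @param universe Explicit universe gene vector or its size (default
#'   54,619, covering coding and non-coding genes).
#' @param annot Optional gene annotation for the MHC filter.
#' @param exclude_mhc Apply [filter_mhc()] to the query first?
#' @return Tibble of enrichment records sorted by p, with `q` (BH) added.
#' @export
run_enrichment <- function(query, gene_sets, universe = 54619, annot = NULL,
                           exclude_mhc = FALSE) {
  if (exclude_mhc) {
    if (is.null(annot)) stop_format("exclude_mhc = TRUE requires a gene annotation")
    query <- filter_mhc(query, annot)
    if (is.character(universe)) universe <- filter_mhc(universe, annot)
  }
  rows <- purrr::map2(gene_sets$genes, gene_sets$set_name,
                      function(g, nm) hypergeom_test(query, g, universe, set_name = nm))
  out <- dplyr::bind_rows(rows)
  out$q <- bh_fdr(out$p)
  dplyr::arrange(dplyr::relocate(out, "q", .after = "p"), .data$p)
}
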