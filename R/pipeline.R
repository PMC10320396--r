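#' Run one study's full XWAS scan from a config
#'
#' Reads the GWAS table, xQTL dataset and LD panel named in the config,
#' runs the per-probe SMR/HEIDI scan, the HEIDI-penalized adjustment, the
#' gene-level Cauchy combination and significance flags, and (when a GMT
#' file is configured) gene-set enrichment of the suggestive genes. All
#' intermediate tables are written to `out_dir` so each stage can be
#' inspected and re-used; a run log records the count at every filter step.
#' Outputs are deterministic: re-running the same config reproduces the
#' files byte for byte.
#'
#' @param config A named list or the path of a flat YAML file with fields
#'   `study`, `gwas`, `xqtl_effects`, `xqtl_annot`, `panel`, `out_dir`, and
#'   optionally `gene_annot`, `gmt`, `universe`, `exclude_mhc`,
#'   `is_case_control`, `effect_is_or`, `alpha`, plus any [smr_config()]
#'   field under the same name.
#' @return List (invisibly returns paths as attribute): `smr` (probe-level
#'   records), `genes` (gene-level stats with flags), `enrichment` (or
#'   `NULL`), `counts`.
#' @export
run_xwas <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  required <- c("gwas", "xqtl_effects", "xqtl_annot", "panel", "out_dir")
  missing_f <- setdiff(required, names(cfg))
  if (length(missing_f) > 0)
    stop_format("run_xwas config is missing field(s): %s",
                paste(missing_f, collapse = ", "))
  for (f in c("gwas", "xqtl_effects", "xqtl_annot", "panel", "gene_annot", "gmt")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop_format("run_xwas: configured %s file does not exist: %s", f, cfg[[f]])
  }
  sc_fields <- intersect(names(cfg), names(formals(smr_config)))
  sc <- do.call(smr_config, cfg[sc_fields])
  study <- cfg$study %||% "study"
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  gwas <- read_gwas_table(cfg$gwas,
                          is_case_control = isTRUE(cfg$is_case_control),
                          effect_is_or = isTRUE(cfg$effect_is_or))
  xqtl <- read_xqtl_dataset(cfg$xqtl_effects, cfg$xqtl_annot)
  panel <- read_genotype_panel(cfg$panel)

  smr <- run_smr(xqtl, gwas, panel, sc)
  counts <- attr(smr, "counts")
  smr_path <- file.path(cfg$out_dir, "smr_probes.tsv")
  write_results_table(smr, smr_path)

  m_probes <- nrow(smr)
  genes <- combine_by_gene(smr, study = study)
  m_genes <- nrow(genes)
  genes <- threshold_flags(genes, m_tests = max(m_genes, 1L),
                           alpha = cfg$alpha %||% 0.05)
  gene_path <- file.path(cfg$out_dir, "gene_level.tsv")
  gene_lines <- c(sprintf("# study=%s n_probes_tested=%d n_genes=%d", study,
                          m_probes, m_genes),
                  readr::format_tsv(genes))
  writeLines(sub("\n$", "", gene_lines), gene_path)

  enr <- NULL
  if (!is.null(cfg$gmt) && m_genes > 0) {
    annot <- if (!is.null(cfg$gene_annot)) read_gene_annot(cfg$gene_annot) else NULL
    sugg <- genes$gene[genes$suggestive]
    if (length(sugg) > 0) {
      universe <- cfg$universe %||% 54619
      enr <- run_enrichment(sugg, read_gmt(cfg$gmt), universe = universe,
                            annot = annot, exclude_mhc = isTRUE(cfg$exclude_mhc))
      enr_flat <- dplyr::mutate(enr, overlap_genes = vapply(
        .data$overlap_genes, paste, character(1), collapse = ","))
      readr::write_tsv(enr_flat, file.path(cfg$out_dir, "enrichment.tsv"),
                       progress = FALSE)
    }
  }

  log_lines <- c(sprintf("study\t%s", study),
                 sprintf("%s\t%d", names(counts), counts),
                 sprintf("genes_mapped\t%d", m_genes),
                 sprintf("genes_suggestive\t%d", sum(genes$suggestive)),
                 sprintf("genes_bonferroni\t%d", sum(genes$bonferroni)))
  writeLines(log_lines, file.path(cfg$out_dir, "run_log.tsv"))

  out <- list(smr = smr, genes = genes, enrichment = enr, counts = counts)
  attr(out, "paths") <- list(smr = smr_path, genes = gene_path,
                             log = file.path(cfg$out_dir, "run_log.tsv"))
  invisible(out)
}

# read a gene-level TSV written by run_xwas (skips the comment header)
read_gene_level <- function(path) {
  readr::read_tsv(path, comment = "#", progress = FALSE, show_col_types = FALSE,
                  col_types = readr::cols(gene = "c", study = "c",
                                          p_combined = "d", n_probes = "i",
                                          suggestive = "l", bonferroni = "l"))
}

#' Joint concordance across completed XWAS runs
#'
#' Intersects gene symbols across the per-study gene-level tables, fits the
#' pattern-posterior concordance model on the shared genes, and writes the
#' per-gene posterior table plus the PP-threshold call set. At least two
#' studies and 100 shared genes are required (the mixture densities cannot
#' be estimated from less).
#'
#' @param gene_tables List of gene-level tibbles (from [run_xwas()] results
#'   or [combine_by_gene()]) or paths to `gene_level.tsv` files.
#' @param out_dir Optional output directory for the TSVs.
#' @param alt_props,pp_threshold,tol,max_iter Model controls (see
#'   [fit_concordance()]).
#' @param sweep_grid Optional `alt_props` grid; when given, the sensitivity
#'   sweep is run and returned (and written) as well.
#' @return List: `fit` (a `pattern_fit`), `pp` (tibble gene x per-study PP,
#'   best pattern and its posterior), `significant`, and optionally `sweep`.
#' @export
run_concordance <- function(gene_tables, out_dir = NULL, alt_props = 1e-3,
                            pp_threshold = 0.95, tol = 1e-6, max_iter = 1000L,
                            sweep_grid = NULL) {
  if (is.character(gene_tables)) gene_tables <- lapply(gene_tables, read_gene_level)
  J <- length(gene_tables)
  if (J < 2) stop_format("run_concordance: need at least 2 studies, got %d", J)
  studies <- vapply(gene_tables, function(g) g$study[1], character(1))
  shared <- Reduce(intersect, lapply(gene_tables, function(g) g$gene))
  if (length(shared) < 100)
    stop_format("run_concordance: only %d genes shared across studies (>= 100 needed for density estimation)",
                length(shared))
  P <- vapply(gene_tables, function(g) g$p_combined[match(shared, g$gene)],
              numeric(length(shared)))
  rownames(P) <- shared
  colnames(P) <- studies
  fit <- fit_concordance(P, genes = shared, studies = studies,
                         alt_props = alt_props, tol = tol, max_iter = max_iter)
  best <- max.col(fit$posterior, ties.method = "first")
  pp <- tibble::as_tibble(fit$PP)
  names(pp) <- paste0("PP_", studies)
  pp <- tibble::add_column(pp, gene = shared, .before = 1)
  pp$best_pattern <- pattern_labels(fit$patterns)[best]
  pp$best_posterior <- fit$posterior[cbind(seq_along(best), best)]
  sig <- significant_concordance(fit, pp_threshold)
  out <- list(fit = fit, pp = pp, significant = sig)
  if (!is.null(sweep_grid))
    out$sweep <- sweep_alt_props(P, grid = sweep_grid, genes = shared,
                                 studies = studies, pp_threshold = pp_threshold,
                                 tol = tol, max_iter = max_iter)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(pp, file.path(out_dir, "concordance_pp.tsv"), progress = FALSE)
    readr::write_tsv(sig, file.path(out_dir, "concordance_significant.tsv"),
                     progress = FALSE)
    if (!is.null(out$sweep))
      readr::write_tsv(out$sweep, file.path(out_dir, "alt_props_sweep.tsv"),
                       progress = FALSE)
  }
  out
}
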