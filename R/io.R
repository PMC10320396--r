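#' Read a GWAS summary-statistics table (COJO `.ma` dialect)
#'
#' Parses a whitespace- or tab-delimited file with header
#' `SNP A1 A2 freq b se p N` into a tibble of per-SNP association records.
#' For case-control traits whose effect column holds odds ratios, set
#' `effect_is_or = TRUE`: the effect is log-transformed (`beta = ln(OR)`)
#' and the `se` column is taken to already be the standard error of
#' `ln(OR)` (the usual convention for summary statistics released with OR
#' and the SE of its logarithm).
#'
#' @param path Path to the summary-statistics file.
#' @param is_case_control Logical; marks the trait as binary. Carried as the
#'   `case_control` attribute of the result, for bookkeeping only.
#' @param effect_is_or Logical; if `TRUE` the `b` column is an odds ratio and
#'   is replaced by its natural logarithm.
#' @return A tibble with columns `snp, a1, a2, freq, beta, se, p, n` and
#'   attribute `case_control`. Alleles are uppercased. `n` may be `NA`.
#' @examples
#' f <- tempfile()
#' writeLines(c("SNP A1 A2 freq b se p N",
#'              "rs1 A G 0.30 0.1 0.02 5e-7 10000"), f)
#' read_gwas_table(f)
#' @export
read_gwas_table <- function(path, is_case_control = FALSE, effect_is_or = FALSE) {
  tab <- readr::read_table(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  names(tab) <- tolower(names(tab))
  required <- c("snp", "a1", "a2", "freq", "b", "se", "p")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0)
    stop_format("GWAS file %s is missing required column(s): %s",
                path, paste(missing_cols, collapse = ", "))
  out <- tibble::tibble(
    snp  = tab$snp,
    a1   = toupper(tab$a1),
    a2   = toupper(tab$a2),
    freq = as.numeric(tab$freq),
    beta = as.numeric(tab$b),
    se   = as.numeric(tab$se),
    p    = as.numeric(tab$p),
    n    = if ("n" %in% names(tab)) suppressWarnings(as.numeric(tab$n)) else NA_real_
  )
  if (anyDuplicated(out$snp))
    stop_format("duplicate SNP id(s) in %s: %s", path,
                paste(unique(out$snp[duplicated(out$snp)]), collapse = ", "))
  validate_assoc(out, path)
  if (effect_is_or) {
    if (any(out$beta <= 0))
      stop_format("effect_is_or = TRUE but non-positive OR found in %s", path)
    out$beta <- log(out$beta)
  }
  attr(out, "case_control") <- isTRUE(is_case_control)
  out
}

validate_assoc <- function(tab, path) {
  bad <- function(msg) stop_format("invalid values in %s: %s", path, msg)
  if (any(!is.finite(tab$se)) || any(tab$se <= 0)) bad("se must be finite and > 0")
  if (any(!is.finite(tab$p)) || any(tab$p <= 0 | tab$p > 1)) bad("p must lie in (0, 1]")
  if (any(!is.finite(tab$freq)) || any(tab$freq < 0 | tab$freq > 1)) bad("freq must lie in [0, 1]")
  if (any(tab$a1 == tab$a2)) bad("a1 and a2 must differ")
  invisible(tab)
}

#' Read a cis-xQTL dataset (flat-text effect file + probe annotation)
#'
#' The flat-text dialect replaces the binary `.besd` trio: a probe annotation
#' TSV (`probe_id, gene, chrom, probe_pos, paradigm`) and an effect TSV
#' (`probe_id, snp, chrom, pos, a1, a2, freq, beta, se, p`). Probes with no
#' effect rows are retained and flagged unusable.
#'
#' @param esd_path Path to the per-SNP effect TSV.
#' @param probe_annot_path Path to the probe annotation TSV.
#' @return An object of class `xqtl_dataset`: a list with tibbles `probes`
#'   (annotation plus `n_snps` and `usable`) and `effects` (one row per
#'   probe-SNP pair).
#' @export
read_xqtl_dataset <- function(esd_path, probe_annot_path) {
  probes <- readr::read_tsv(probe_annot_path,
                            col_types = readr::cols(.default = readr::col_character()),
                            progress = FALSE, show_col_types = FALSE)
  names(probes) <- tolower(names(probes))
  req_p <- c("probe_id", "gene", "chrom", "probe_pos", "paradigm")
  if (length(setdiff(req_p, names(probes))) > 0)
    stop_format("probe annotation %s must have columns %s", probe_annot_path,
                paste(req_p, collapse = ", "))
  probes <- tibble::tibble(
    probe_id = as.character(probes$probe_id),
    gene = as.character(probes$gene),
    chrom = as.character(probes$chrom),
    probe_pos = as.integer(probes$probe_pos),
    paradigm = as.character(probes$paradigm)
  )
  if (anyDuplicated(probes$probe_id))
    stop_format("duplicate probe_id in %s", probe_annot_path)
  if (any(probes$probe_pos <= 0, na.rm = TRUE))
    stop_format("probe_pos must be positive in %s", probe_annot_path)

  eff <- readr::read_tsv(esd_path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  names(eff) <- tolower(names(eff))
  req_e <- c("probe_id", "snp", "chrom", "pos", "a1", "a2", "freq", "beta", "se", "p")
  if (length(setdiff(req_e, names(eff))) > 0)
    stop_format("xQTL effect file %s must have columns %s", esd_path,
                paste(req_e, collapse = ", "))
  effects <- tibble::tibble(
    probe_id = eff$probe_id,
    snp = eff$snp,
    chrom = as.character(eff$chrom),
    pos = as.integer(eff$pos),
    a1 = toupper(eff$a1),
    a2 = toupper(eff$a2),
    freq = as.numeric(eff$freq),
    beta = as.numeric(eff$beta),
    se = as.numeric(eff$se),
    p = as.numeric(eff$p)
  )
  unknown <- setdiff(unique(effects$probe_id), probes$probe_id)
  if (length(unknown) > 0)
    stop_format("effect rows reference probe(s) absent from the annotation: %s",
                paste(unknown, collapse = ", "))
  if (nrow(effects) > 0) {
    if (anyDuplicated(effects[, c("probe_id", "snp")]))
      stop_format("duplicate (probe_id, snp) pair in %s", esd_path)
    validate_assoc(effects, esd_path)
  }
  counts <- table(factor(effects$probe_id, levels = probes$probe_id))
  probes$n_snps <- as.integer(counts)
  probes$usable <- probes$n_snps > 0L
  structure(list(probes = probes, effects = effects), class = "xqtl_dataset")
}

#' @export
print.xqtl_dataset <- function(x, ...) {
  cat(sprintf("<xqtl_dataset> %d probes (%d usable), %d effect rows\n",
              nrow(x$probes), sum(x$probes$usable), nrow(x$effects)))
  invisible(x)
}

#' Read an LD reference panel from a dosage TSV
#'
#' The file carries five metadata rows (`snp`, `chrom`, `pos`, `a1`, `a2`;
#' one column per SNP after the row label) followed by one row per reference
#' individual holding additive dosages in `[0, 2]`. Monomorphic SNPs (zero
#' dosage variance) are flagged; their LD correlation is undefined.
#'
#' @param path Path to the dosage TSV.
#' @return An object of class `genotype_panel`: list with `snps` (tibble
#'   `snp, chrom, pos, a1, a2, freq, monomorphic`; `freq` is the a1 dosage
#'   frequency) and `dosages` (n_ref x m numeric matrix, columns named by SNP).
#' @export
read_genotype_panel <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7)
    stop_format("panel file %s too short: need 5 metadata rows and >= 2 individuals", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  labels <- vapply(fields[1:5], `[[`, character(1), 1L)
  if (!identical(tolower(labels), c("snp", "chrom", "pos", "a1", "a2")))
    stop_format("panel file %s must start with metadata rows snp/chrom/pos/a1/a2", path)
  meta <- lapply(fields[1:5], function(f) f[-1])
  m <- length(meta[[1]])
  body <- fields[-(1:5)]
  n_ref <- length(body)
  if (n_ref < 2) stop_format("panel %s has fewer than 2 reference individuals", path)
  dos <- matrix(NA_real_, nrow = n_ref, ncol = m)
  for (i in seq_len(n_ref)) {
    row <- body[[i]]
    if (length(row) != m + 1L)
      stop_format("panel %s: individual row %d has %d fields, expected %d",
                  path, i, length(row), m + 1L)
    dos[i, ] <- as.numeric(row[-1])
  }
  build_genotype_panel(dos,
                       snp = meta[[1]], chrom = meta[[2]],
                       pos = as.integer(meta[[3]]),
                       a1 = toupper(meta[[4]]), a2 = toupper(meta[[5]]))
}

# construct + validate the panel container (also used by the simulator)
build_genotype_panel <- function(dosages, snp, chrom, pos, a1, a2) {
  if (any(!is.finite(dosages)) || any(dosages < 0 | dosages > 2))
    stop_format("panel dosages must lie in [0, 2]")
  if (nrow(dosages) < 2) stop_format("panel needs at least 2 individuals")
  if (anyDuplicated(snp)) stop_format("duplicate SNP id in panel")
  colnames(dosages) <- snp
  v <- apply(dosages, 2L, stats::var)
  snps <- tibble::tibble(
    snp = snp, chrom = as.character(chrom), pos = as.integer(pos),
    a1 = a1, a2 = a2,
    freq = unname(colMeans(dosages)) / 2,
    monomorphic = unname(v == 0)
  )
  structure(list(snps = snps, dosages = dosages), class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d individuals x %d SNPs (%d monomorphic)\n",
              nrow(x$dosages), ncol(x$dosages), sum(x$snps$monomorphic)))
  invisible(x)
}

#' Pairwise LD correlation from a genotype panel
#'
#' Pearson correlation of reference dosages for the requested SNPs, with `NA`
#' for pairs involving a monomorphic SNP. `flip` reverses the dosage
#' orientation (`2 - dosage`) of selected SNPs so that correlations refer to
#' a chosen effect allele.
#'
#' @param panel A `genotype_panel`.
#' @param snps Character vector of SNP ids (default: all).
#' @param flip Logical vector parallel to `snps`; `TRUE` entries are computed
#'   on `2 - dosage`.
#' @return Symmetric correlation matrix with unit diagonal on non-flagged SNPs.
#' @export
panel_cor <- function(panel, snps = NULL, flip = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  snps <- snps %||% panel$snps$snp
  idx <- match(snps, panel$snps$snp)
  if (anyNA(idx)) stop_format("SNP(s) absent from panel: %s",
                              paste(snps[is.na(idx)], collapse = ", "))
  d <- panel$dosages[, idx, drop = FALSE]
  if (!is.null(flip)) d[, flip] <- 2 - d[, flip, drop = FALSE]
  mono <- panel$snps$monomorphic[idx]
  r <- suppressWarnings(stats::cor(d))
  r[mono, ] <- NA_real_
  r[, mono] <- NA_real_
  diag(r)[!mono] <- 1
  dimnames(r) <- list(snps, snps)
  r
}

results_columns <- c("probeID", "ProbeChr", "Gene", "Probe_bp", "topSNP",
                     "A1", "A2", "Freq", "b_GWAS", "se_GWAS", "p_GWAS",
                     "b_eQTL", "se_eQTL", "p_eQTL", "b_SMR", "se_SMR",
                     "p_SMR", "p_HEIDI", "nsnp_HEIDI", "p_SMR_adj")

# internal column names corresponding to results_columns, in order
record_columns <- c("probe_id", "chrom", "gene", "probe_pos", "top_snp",
                    "a1", "a2", "freq", "b_gwas", "se_gwas", "p_gwas",
                    "b_xqtl", "se_xqtl", "p_xqtl", "b_smr", "se_smr",
                    "p_smr", "p_heidi", "nsnp_heidi", "p_smr_adj")

#' Write / read the per-probe SMR results table
#'
#' Writes one row per probe in the conventional SMR output layout
#' (`probeID ... p_SMR, p_HEIDI, nsnp_HEIDI, p_SMR_adj`), tab-delimited with
#' `NA` for missing values. Numeric fields are rendered with 12 significant
#' digits so that a write-read round trip reproduces values to that
#' precision.
#'
#' @param records Tibble of per-probe records as produced by [run_smr()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  stopifnot(all(record_columns %in% names(records)))
  out <- records[, record_columns]
  fmt <- function(x) {
    if (is.numeric(x) && !is.integer(x)) ifelse(is.na(x), "NA", sprintf("%.12g", x))
    else ifelse(is.na(x), "NA", as.character(x))
  }
  cells <- vapply(out, fmt, character(nrow(out)))
  if (nrow(out) == 1L) cells <- matrix(cells, nrow = 1L)
  lines <- c(paste(results_columns, collapse = "\t"),
             apply(cells, 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  tab <- readr::read_tsv(path, na = "NA", progress = FALSE, show_col_types = FALSE,
                         col_types = readr::cols(
                           probeID = "c", ProbeChr = "c", Gene = "c", Probe_bp = "i",
                           topSNP = "c", A1 = "c", A2 = "c", .default = "d",
                           nsnp_HEIDI = "i"))
  if (!identical(names(tab), results_columns))
    stop_format("%s is not a results table (unexpected columns)", path)
  names(tab) <- record_columns
  tab
}

#' Read gene sets in GMT format
#'
#' One set per line: set name, description, then member gene symbols,
#' tab-separated.
#'
#' @param path Path to a `.gmt` file.
#' @return Tibble with columns `set_name`, `description` and list-column
#'   `genes`.
#' @export
read_gmt <- function(path) {
  fields <- strsplit(readLines(path), "\t", fixed = TRUE)
  fields <- fields[lengths(fields) > 0]
  if (any(lengths(fields) < 3))
    stop_format("GMT %s: every line needs name, description and >= 1 gene", path)
  tibble::tibble(
    set_name = vapply(fields, `[[`, character(1), 1L),
    description = vapply(fields, `[[`, character(1), 2L),
    genes = lapply(fields, function(f) unique(f[-(1:2)]))
  )
}

#' Read a gene annotation table (gene, chrom, start position)
#'
#' @param path TSV with columns `gene, chrom, start`.
#' @return Tibble `gene, chrom, start`.
#' @export
read_gene_annot <- function(path) {
  tab <- readr::read_tsv(path, col_types = "cci", progress = FALSE, show_col_types = FALSE)
  names(tab) <- tolower(names(tab))
  if (length(setdiff(c("gene", "chrom", "start"), names(tab))) > 0)
    stop_format("gene annotation %s must have columns gene, chrom, start", path)
  tab[, c("gene", "chrom", "start")]
}
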