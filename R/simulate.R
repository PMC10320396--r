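#' Scenario specification for a synthetic cis region
#'
#' Describes one probe's cis region under a known causal structure. The
#' latent genotype model is AR(1): haplotype alleles are thresholded
#' standard normals with first-order autocorrelation `ld_rho`, so the true
#' dosage LD is available in closed form. Phenotypes are standardized to
#' unit variance, so effects are in per-SD units. Scenarios:
#' \describe{
#'   \item{causal}{`x = b_zx z_c + e`, `y = b_xy x + e`; one shared causal
#'     variant, HEIDI should not reject.}
#'   \item{pleiotropy}{as causal plus a direct SNP-on-trait effect
#'     `direct_zy` at the same variant.}
#'   \item{linkage}{distinct causal variants for x and y in LD
#'     `linkage_r`; the SMR signal is spurious and HEIDI should reject.}
#'   \item{null}{`y` unaffected (`b_zy = 0` everywhere).}
#' }
#'
#' @param scenario One of `"causal"`, `"pleiotropy"`, `"linkage"`, `"null"`.
#' @param m_snps SNPs in the region.
#' @param maf_range Minor-allele-frequency range (uniform draw).
#' @param ld_rho Latent AR(1) correlation between adjacent SNPs.
#' @param b_xy_true Causal effect of the molecular level on the trait.
#' @param b_zx_causal xQTL effect of the causal variant (per-SD).
#' @param direct_zy Pleiotropic direct SNP-on-trait effect.
#' @param linkage_r Target dosage LD between the two causal variants in the
#'   linkage scenario.
#' @param b_zy_linkage SNP-on-trait effect at the second causal variant.
#' @param n_xqtl,n_gwas,n_ref Sample sizes of the xQTL study, the GWAS and
#'   the LD reference panel.
#' @param seed Master seed for this region.
#' @return List of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario = c("causal", "pleiotropy", "linkage", "null"),
                          m_snps = 20L, maf_range = c(0.1, 0.5), ld_rho = 0.8,
                          b_xy_true = 0.3, b_zx_causal = 0.5, direct_zy = 0.1,
                          linkage_r = 0.6, b_zy_linkage = b_xy_true * b_zx_causal,
                          n_xqtl = 30000L, n_gwas = 100000L, n_ref = 500L,
                          seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(m_snps >= 3, maf_range[1] > 0.01, maf_range[2] <= 0.5,
            abs(ld_rho) < 1, n_ref >= 50, n_xqtl >= 10, n_gwas >= 10)
  structure(list(scenario = scenario, m_snps = as.integer(m_snps),
                 maf_range = maf_range, ld_rho = ld_rho, b_xy_true = b_xy_true,
                 b_zx_causal = b_zx_causal, direct_zy = direct_zy,
                 linkage_r = linkage_r, b_zy_linkage = b_zy_linkage,
                 n_xqtl = as.integer(n_xqtl), n_gwas = as.integer(n_gwas),
                 n_ref = as.integer(n_ref), seed = as.integer(seed)),
            class = "scenario_spec")
}

# standard bivariate normal CDF P(U1 < a, U2 < b; r), vectorized over r;
# composite Simpson on the outer integral (smooth integrand, 201 nodes)
bvnorm_cdf <- function(a, b, r) {
  if (r == 0) return(stats::pnorm(a) * stats::pnorm(b))
  if (abs(r) >= 1 - 1e-12) {
    if (r > 0) return(stats::pnorm(min(a, b)))
    return(max(0, stats::pnorm(a) + stats::pnorm(b) - 1))
  }
  lo <- -8.5
  if (a <= lo) return(0)
  n <- 200L
  u <- seq(lo, a, length.out = n + 1L)
  h <- (a - lo) / n
  f <- stats::dnorm(u) * stats::pnorm((b - r * u) / sqrt(1 - r^2))
  w <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
  sum(w * f) * h / 3
}

# analytic dosage correlation between two thresholded-latent SNPs
dosage_cor_analytic <- function(maf_i, maf_j, r_latent) {
  ti <- stats::qnorm(maf_i); tj <- stats::qnorm(maf_j)
  p11 <- bvnorm_cdf(ti, tj, r_latent)
  (p11 - maf_i * maf_j) / sqrt(maf_i * (1 - maf_i) * maf_j * (1 - maf_j))
}

# full analytic dosage LD matrix for an AR(1) latent region
ld_true_matrix <- function(mafs, ld_rho) {
  m <- length(mafs)
  R <- diag(1, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    R[i, j] <- R[j, i] <- dosage_cor_analytic(mafs[i], mafs[j], ld_rho^(j - i))
  }
  R
}

# haplotype dosages: n individuals x m SNPs from the thresholded AR(1) model
draw_dosages <- function(n, mafs, ld_rho) {
  m <- length(mafs)
  cuts <- stats::qnorm(mafs)
  hap <- function() {
    u <- matrix(stats::rnorm(n * m), n, m)
    if (m > 1 && ld_rho != 0) {
      for (j in 2:m) u[, j] <- ld_rho * u[, j - 1] + sqrt(1 - ld_rho^2) * u[, j]
    }
    sweep(u, 2L, cuts, `<`) + 0
  }
  hap() + hap()
}

# non-ambiguous allele pairs for simulated SNPs
allele_pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                      c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))

#' Simulate an LD reference panel
#'
#' Samples `n_ref` diploid individuals from the thresholded AR(1) latent
#' model and returns both the sampled panel and the analytic dosage
#' correlation implied by the model (the ground truth the empirical LD
#' estimates).
#'
#' @param spec A [scenario_spec()].
#' @param snp_ids,chrom,pos Optional SNP metadata (defaults generated).
#' @param mafs Optional per-SNP minor-allele frequencies (default: uniform
#'   draw within `spec$maf_range` under `spec$seed`).
#' @return List: `panel` (a `genotype_panel`), `ld_true` (m x m matrix),
#'   `mafs`, `alleles` (m x 2).
#' @export
make_ld_panel <- function(spec, snp_ids = NULL, chrom = "1", pos = NULL,
                          mafs = NULL) {
  m <- spec$m_snps
  with_seed(child_seed(spec$seed, 1L), {
    mafs <- mafs %||% stats::runif(m, spec$maf_range[1], spec$maf_range[2])
    alleles <- allele_pairs[sample(nrow(allele_pairs), m, replace = TRUE), , drop = FALSE]
    dos <- draw_dosages(spec$n_ref, mafs, spec$ld_rho)
  })
  snp_ids <- snp_ids %||% paste0("rs", seq_len(m))
  pos <- pos %||% as.integer(1e6 + seq_len(m) * 5000L)
  panel <- build_genotype_panel(dos, snp = snp_ids, chrom = rep(chrom, m),
                                pos = pos, a1 = alleles[, 1], a2 = alleles[, 2])
  list(panel = panel, ld_true = ld_true_matrix(mafs, spec$ld_rho),
       mafs = mafs, alleles = alleles)
}

# joint (per standardized genotype) effect vectors for a scenario
scenario_effects <- function(spec, ld_true) {
  m <- spec$m_snps
  c1 <- as.integer(ceiling(m / 2))
  beta_x <- numeric(m); beta_y <- numeric(m)
  beta_x[c1] <- spec$b_zx_causal
  c2 <- NA_integer_
  if (spec$scenario == "causal") {
    beta_y[c1] <- spec$b_xy_true * spec$b_zx_causal
  } else if (spec$scenario == "pleiotropy") {
    beta_y[c1] <- spec$b_xy_true * spec$b_zx_causal + spec$direct_zy
  } else if (spec$scenario == "linkage") {
    cand <- setdiff(seq_len(m), c1)
    c2 <- cand[which.min(abs(ld_true[c1, cand] - spec$linkage_r))]
    beta_y[c2] <- spec$b_zy_linkage
  }
  list(beta_x = beta_x, beta_y = beta_y, causal_x = c1, causal_y = c2)
}

#' Simulate GWAS and xQTL summary statistics for one cis region
#'
#' Two fidelities. The fast path draws the per-SNP marginal estimates
#' directly from their large-sample distribution
#' `beta_hat ~ N(R beta_joint, R / n)` (standardized genotypes and
#' phenotypes, residual variance ~ 1), which is what makes thousands of
#' regions cheap. The slow path simulates individual-level genotypes and
#' phenotypes and runs per-SNP least squares; it serves as the oracle the
#' fast path is validated against.
#'
#' @param spec A [scenario_spec()].
#' @param probe_id,gene Probe labels stamped on the xQTL rows.
#' @param chrom Chromosome label.
#' @param probe_pos Probe position (default: region midpoint).
#' @param method `"fast"` (multivariate-normal summary draw) or `"slow"`
#'   (individual-level simulation + per-SNP OLS).
#' @param scramble Randomly swap allele orientation per SNP independently
#'   in the GWAS slice and the panel (exercises harmonization; on by
#'   default).
#' @param genome Optional precomputed output of [make_ld_panel()] for this
#'   region, so several studies can share one set of SNPs, frequencies and
#'   LD while drawing independent noise.
#' @return List: `xqtl` (effect-row tibble), `gwas` (tibble in
#'   [read_gwas_table()] layout), `panel` (a `genotype_panel`), `ld_true`,
#'   and `truth` (scenario, b_xy_true, causal SNP ids).
#' @export
simulate_summary_region <- function(spec, probe_id = "probe1", gene = "GENE1",
                                    chrom = "1", probe_pos = NULL,
                                    method = c("fast", "slow"), scramble = TRUE,
                                    genome = NULL) {
  method <- match.arg(method)
  m <- spec$m_snps
  snp_ids <- paste0(probe_id, "_rs", seq_len(m))
  pos <- as.integer(1e6 + seq_len(m) * 5000L)
  probe_pos <- probe_pos %||% pos[ceiling(m / 2)]
  lp <- genome %||% make_ld_panel(spec, snp_ids = snp_ids, chrom = chrom, pos = pos)
  snp_ids <- lp$panel$snps$snp
  pos <- lp$panel$snps$pos
  R <- lp$ld_true
  eff <- scenario_effects(spec, R)

  sim_one <- if (method == "fast") {
    function(beta, n, seed) {
      with_seed(seed, {
        mu <- as.vector(R %*% beta)
        L <- chol(R + diag(1e-10, m))
        bhat <- mu + as.vector(crossprod(L, stats::rnorm(m))) / sqrt(n)
        se <- rep(1 / sqrt(n), m)
        list(b = bhat, se = se, p = 2 * stats::pnorm(-abs(bhat / se)))
      })
    }
  } else {
    function(beta, n, seed) {
      with_seed(seed, {
        D <- draw_dosages(n, lp$mafs, spec$ld_rho)
        Dz <- scale(D)
        sig2 <- max(0.05, 1 - as.numeric(crossprod(beta, R %*% beta)))
        y <- as.vector(Dz %*% beta) + stats::rnorm(n, sd = sqrt(sig2))
        y <- as.vector(scale(y))
        b <- as.vector(crossprod(Dz, y)) / (n - 1)
        # per-SNP simple regression on standardized genotype
        se <- sqrt(pmax(1 - b^2, 1e-12) / (n - 2))
        list(b = b, se = se, p = 2 * stats::pnorm(-abs(b / se)))
      })
    }
  }
  sx <- sim_one(eff$beta_x, spec$n_xqtl, child_seed(spec$seed, 2L))
  sy <- sim_one(eff$beta_y, spec$n_gwas, child_seed(spec$seed, 3L))
  sy$p <- pmax(sy$p, 1e-300); sx$p <- pmax(sx$p, 1e-300)

  a1 <- lp$alleles[, 1]; a2 <- lp$alleles[, 2]
  freq <- lp$mafs
  xqtl <- tibble::tibble(probe_id = probe_id, snp = snp_ids, chrom = chrom,
                         pos = pos, a1 = a1, a2 = a2, freq = freq,
                         beta = sx$b, se = sx$se, p = sx$p)
  gwas <- tibble::tibble(snp = snp_ids, a1 = a1, a2 = a2, freq = freq,
                         beta = sy$b, se = sy$se, p = sy$p,
                         n = as.numeric(spec$n_gwas))
  panel <- lp$panel
  if (scramble) {
    with_seed(child_seed(spec$seed, 4L), {
      gw_flip <- stats::runif(m) < 0.5
      pan_flip <- stats::runif(m) < 0.5
    })
    gwas[gw_flip, c("a1", "a2")] <- gwas[gw_flip, c("a2", "a1")]
    gwas$beta[gw_flip] <- -gwas$beta[gw_flip]
    gwas$freq[gw_flip] <- 1 - gwas$freq[gw_flip]
    panel$snps[pan_flip, c("a1", "a2")] <- panel$snps[pan_flip, c("a2", "a1")]
    panel$dosages[, pan_flip] <- 2 - panel$dosages[, pan_flip, drop = FALSE]
    panel$snps$freq[pan_flip] <- 1 - panel$snps$freq[pan_flip]
  }
  truth <- list(scenario = spec$scenario, b_xy_true = spec$b_xy_true,
                causal_x_snp = snp_ids[eff$causal_x],
                causal_y_snp = if (is.na(eff$causal_y)) NA_character_
                               else snp_ids[eff$causal_y])
  list(xqtl = xqtl, gwas = gwas, panel = panel, ld_true = R,
       probe = tibble::tibble(probe_id = probe_id, gene = gene, chrom = chrom,
                              probe_pos = probe_pos, paradigm = "expression"),
       truth = truth)
}

#' Simulate a multi-study gene-level p-value matrix
#'
#' Each gene is assigned one of the 2^J binary association patterns with the
#' given probabilities. Null entries get Uniform(0,1) p-values; associated
#' entries get `p = exp(-t/2)` with `t ~ a_true * chisq_2` (the scaled
#' alternative the concordance model assumes).
#'
#' @param G Number of genes.
#' @param J Number of studies (<= 8).
#' @param pattern_probs Length-2^J probability vector over patterns, in
#'   [pattern_matrix()] order (pattern 1 = all-null).
#' @param alt_scale Per-study alternative scale(s) > 1 (recycled).
#' @param seed Seed.
#' @return List: `P` (G x J matrix), `genes`, `truth` (tibble with the true
#'   pattern index and per-study association flags).
#' @export
simulate_pattern_pvalues <- function(G, J, pattern_probs, alt_scale = 10,
                                     seed = 1L) {
  Q <- pattern_matrix(J)
  K <- nrow(Q)
  stopifnot(length(pattern_probs) == K, abs(sum(pattern_probs) - 1) < 1e-8)
  alt_scale <- rep_len(alt_scale, J)
  with_seed(seed, {
    pat <- sample.int(K, G, replace = TRUE, prob = pattern_probs)
    P <- matrix(stats::runif(G * J), G, J)
    for (j in seq_len(J)) {
      alt <- Q[pat, j] == 1L
      n_alt <- sum(alt)
      if (n_alt > 0) {
        t <- alt_scale[j] * stats::rchisq(n_alt, df = 2)
        P[alt, j] <- pmax(exp(-t / 2), 1e-300)
      }
    }
  })
  genes <- sprintf("gene%05d", seq_len(G))
  rownames(P) <- genes
  colnames(P) <- paste0("study", seq_len(J))
  truth <- tibble::tibble(gene = genes, pattern = pat)
  for (j in seq_len(J)) truth[[paste0("assoc_study", j)]] <- Q[pat, j] == 1L
  list(P = P, genes = genes, truth = truth)
}

# write a genotype_panel in the dosage-TSV dialect read_genotype_panel expects
write_genotype_panel <- function(panel, path) {
  s <- panel$snps
  meta <- c(paste(c("snp", s$snp), collapse = "\t"),
            paste(c("chrom", s$chrom), collapse = "\t"),
            paste(c("pos", s$pos), collapse = "\t"),
            paste(c("a1", s$a1), collapse = "\t"),
            paste(c("a2", s$a2), collapse = "\t"))
  body <- vapply(seq_len(nrow(panel$dosages)), function(i) {
    paste(c(paste0("ind", i), format(panel$dosages[i, ], trim = TRUE)), collapse = "\t")
  }, character(1))
  writeLines(c(meta, body), path)
  invisible(path)
}

#' Write a complete synthetic input bundle with ground truth
#'
#' Emits everything one end-to-end run needs, in exactly the dialects the
#' readers expect: per-study GWAS `.ma` files and xQTL effect files, one
#' probe annotation, one shared LD panel TSV, a gene annotation, a GMT file
#' with one planted enriched set among random sets, per-study run-config
#' YAMLs, and a `truth.json` manifest recording every probe's scenario and
#' the planted items. Probes are split across causal / linkage / null
#' scenarios; all studies share genes and scenario labels (so causal genes
#' are shared signals) but have independently re-simulated noise.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_probes Total probes.
#' @param scenario_counts Named counts for `causal`, `linkage`, `null`
#'   (must sum to `n_probes`).
#' @param studies Character vector of study labels (J >= 2).
#' @param seed Master seed; all child seeds derive from it by counter.
#' @param base_spec Template [scenario_spec()] whose sizes/effects apply to
#'   every region.
#' @param universe_size Gene universe for enrichment.
#' @param n_random_sets Random gene sets written alongside the planted set.
#' @return Invisibly, a list of file paths plus the truth manifest.
#' @export
write_fixture_set <- function(out_dir,
                              n_probes = 200L,
                              scenario_counts = c(causal = 100L, linkage = 50L, null = 50L),
                              studies = c("traitA_blood_twas", "traitA_brain_twas",
                                          "traitA_blood_mwas"),
                              seed = 1L,
                              base_spec = scenario_spec(seed = seed),
                              universe_size = 10000L,
                              n_random_sets = 19L) {
  stopifnot(sum(scenario_counts) == n_probes, length(studies) >= 2)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scen <- rep(names(scenario_counts), scenario_counts)
  J <- length(studies)

  genes <- sprintf("G%05d", seq_len(universe_size))
  probe_genes <- genes[seq_len(n_probes)]
  chroms <- as.character(rep_len(setdiff(1:22, 6), universe_size))
  gene_annot <- tibble::tibble(gene = genes, chrom = chroms,
                               start = as.integer(1e6 + (seq_len(universe_size) %/% 21) * 2000L))

  probes <- tibble::tibble(probe_id = sprintf("P%04d", seq_len(n_probes)),
                           gene = probe_genes,
                           chrom = gene_annot$chrom[seq_len(n_probes)],
                           probe_pos = NA_integer_,
                           paradigm = "expression")

  panel_blocks <- vector("list", n_probes)
  xqtl_rows <- rep(list(vector("list", n_probes)), J)
  gwas_rows <- rep(list(vector("list", n_probes)), J)
  truth_probes <- vector("list", n_probes)
  for (i in seq_len(n_probes)) {
    sp0 <- base_spec
    sp0$scenario <- scen[i]
    sp0$seed <- child_seed(seed, i * 64L)
    genome <- make_ld_panel(sp0,
                            snp_ids = paste0(probes$probe_id[i], "_rs",
                                             seq_len(sp0$m_snps)),
                            chrom = probes$chrom[i])
    for (s in seq_len(J)) {
      sp <- sp0
      sp$seed <- child_seed(seed, i * 64L + s)
      region <- simulate_summary_region(sp, probe_id = probes$probe_id[i],
                                        gene = probes$gene[i],
                                        chrom = probes$chrom[i],
                                        genome = genome)
      if (s == 1L) {
        panel_blocks[[i]] <- region$panel
        probes$probe_pos[i] <- region$probe$probe_pos
        truth_probes[[i]] <- region$truth
      }
      xqtl_rows[[s]][[i]] <- region$xqtl
      gwas_rows[[s]][[i]] <- region$gwas
    }
  }

  panel <- structure(list(
    snps = dplyr::bind_rows(lapply(panel_blocks, function(p) p$snps)),
    dosages = do.call(cbind, lapply(panel_blocks, function(p) p$dosages))
  ), class = "genotype_panel")
  panel_path <- file.path(out_dir, "panel.tsv")
  write_genotype_panel(panel, panel_path)

  annot_path <- file.path(out_dir, "probes.tsv")
  readr::write_tsv(probes[, c("probe_id", "gene", "chrom", "probe_pos", "paradigm")],
                   annot_path, progress = FALSE)
  gene_annot_path <- file.path(out_dir, "genes.tsv")
  readr::write_tsv(gene_annot, gene_annot_path, progress = FALSE)

  study_files <- list()
  for (s in seq_len(J)) {
    gw <- dplyr::bind_rows(gwas_rows[[s]])
    ma_path <- file.path(out_dir, paste0("gwas_", studies[s], ".ma"))
    ma <- tibble::tibble(SNP = gw$snp, A1 = gw$a1, A2 = gw$a2,
                         freq = sprintf("%.6g", gw$freq),
                         b = sprintf("%.10g", gw$beta),
                         se = sprintf("%.10g", gw$se),
                         p = sprintf("%.6g", gw$p), N = gw$n)
    readr::write_delim(ma, ma_path, delim = " ", progress = FALSE)
    xq <- dplyr::bind_rows(xqtl_rows[[s]])
    esd_path <- file.path(out_dir, paste0("xqtl_", studies[s], ".tsv"))
    readr::write_tsv(xq, esd_path, progress = FALSE)
    cfg_path <- file.path(out_dir, paste0("config_", studies[s], ".yaml"))
    yaml::write_yaml(list(study = studies[s], gwas = ma_path,
                          xqtl_effects = esd_path, xqtl_annot = annot_path,
                          panel = panel_path, gene_annot = gene_annot_path,
                          gmt = file.path(out_dir, "sets.gmt"),
                          universe = universe_size, exclude_mhc = TRUE,
                          out_dir = file.path(out_dir, paste0("out_", studies[s]))),
                     cfg_path)
    study_files[[studies[s]]] <- list(gwas = ma_path, xqtl = esd_path,
                                      config = cfg_path)
  }

  # gene sets: one planted set enriched in causal genes + random sets
  causal_genes <- probe_genes[scen == "causal"]
  with_seed(child_seed(seed, 7L), {
    n_in <- min(20L, length(causal_genes))
    planted <- c(sample(causal_genes, n_in),
                 sample(setdiff(genes, probe_genes), 30L - n_in))
    random_sets <- lapply(seq_len(n_random_sets),
                          function(k) sample(genes, 30L))
  })
  gmt_path <- file.path(out_dir, "sets.gmt")
  gmt_lines <- c(paste(c("planted_set", "planted enriched set", planted), collapse = "\t"),
                 vapply(seq_len(n_random_sets), function(k) {
                   paste(c(sprintf("random_set_%02d", k), "random set", random_sets[[k]]),
                         collapse = "\t")
                 }, character(1)))
  writeLines(gmt_lines, gmt_path)

  truth <- list(seed = seed, studies = studies,
                scenario = stats::setNames(scen, probes$probe_id),
                probe_gene = stats::setNames(probe_genes, probes$probe_id),
                b_xy_true = base_spec$b_xy_true,
                planted_set = "planted_set",
                planted_shared_gene = probe_genes[which(scen == "causal")[1]],
                universe_size = universe_size)
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(dir = out_dir, panel = panel_path, probe_annot = annot_path,
                 gene_annot = gene_annot_path, gmt = gmt_path,
                 truth = truth_path, studies = study_files,
                 truth_manifest = truth))
}
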