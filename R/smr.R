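#' Analysis settings for the per-probe SMR/HEIDI scan
#'
#' Defaults follow standard practice for cis summary-data Mendelian
#' randomization: instruments are cis SNPs (within 2 Mb of the probe) with
#' xQTL p < 5e-8; the HEIDI instrument set admits SNPs with xQTL p < 1.57e-3,
#' prunes LD r^2 > 0.9 and < 0.05 against the top SNP, and runs only with 3
#' to 20 instruments besides the top SNP capped at 20; SNPs whose allele
#' frequency disagrees by more than 15 percentage points between any two
#' input sources are dropped during harmonization.
#'
#' @param cis_window_bp Cis window around the probe position, base pairs.
#' @param instrument_p Top-instrument xQTL p-value threshold.
#' @param heidi_select_p xQTL p-value threshold for admitting SNPs to the
#'   HEIDI instrument set.
#' @param heidi_min,heidi_max Minimum / maximum size of the HEIDI instrument
#'   set (excluding the top SNP).
#' @param prune_r2_high,prune_r2_low LD r^2 pruning bounds against the top SNP.
#' @param freq_mismatch Maximum tolerated allele-frequency difference between
#'   any two of GWAS, xQTL and reference panel.
#' @param heidi_adjust_floor HEIDI p-value below which the SMR p-value is
#'   penalized (see [adjust_for_heidi()]).
#' @param heidi_tail Weighted-chi-square tail method for the HEIDI p-value:
#'   `"saddlepoint"` (default), `"satterthwaite"` or `"montecarlo"` (see
#'   [weighted_chisq_tail()]).
#' @param heidi_mc_draws Draws for the Monte-Carlo tail.
#' @param heidi_mc_seed Fixed seed for the Monte-Carlo tail (private stream).
#' @param ridge Diagonal ridge added to the HEIDI difference covariance.
#' @return A list of class `smr_config`.
#' @export
smr_config <- function(cis_window_bp = 2e6,
                       instrument_p = 5e-8,
                       heidi_select_p = 1.57e-3,
                       heidi_min = 3L,
                       heidi_max = 20L,
                       prune_r2_high = 0.9,
                       prune_r2_low = 0.05,
                       freq_mismatch = 0.15,
                       heidi_adjust_floor = 0.01,
                       heidi_tail = c("saddlepoint", "satterthwaite", "montecarlo"),
                       heidi_mc_draws = 1e5,
                       heidi_mc_seed = 20240801L,
                       ridge = 1e-8) {
  heidi_tail <- match.arg(heidi_tail)
  stopifnot(prune_r2_low > 0, prune_r2_low < prune_r2_high, prune_r2_high <= 1,
            heidi_min >= 3, heidi_max >= heidi_min, cis_window_bp > 0,
            freq_mismatch > 0, heidi_adjust_floor > 0)
  structure(list(cis_window_bp = cis_window_bp, instrument_p = instrument_p,
                 heidi_select_p = heidi_select_p, heidi_min = as.integer(heidi_min),
                 heidi_max = as.integer(heidi_max), prune_r2_high = prune_r2_high,
                 prune_r2_low = prune_r2_low, freq_mismatch = freq_mismatch,
                 heidi_adjust_floor = heidi_adjust_floor, heidi_tail = heidi_tail,
                 heidi_mc_draws = heidi_mc_draws, heidi_mc_seed = heidi_mc_seed,
                 ridge = ridge),
            class = "smr_config")
}

strand_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize a probe's cis region across GWAS, xQTL and LD panel
#'
#' Restricts to SNPs within the cis window that are present in all three
#' sources, re-orients every record to the xQTL effect allele (swapped
#' alleles flip the sign of beta and replace freq by 1 - freq), drops
#' strand-ambiguous (A/T, C/G) SNPs, SNPs whose allele pair disagrees across
#' sources, monomorphic panel SNPs, and SNPs with an allele-frequency
#' mismatch above `config$freq_mismatch` between any two sources. The LD
#' matrix is the panel dosage correlation over the survivors, oriented to
#' the same effect allele.
#'
#' @param probe One row of an `xqtl_dataset` probe table (needs `probe_id`,
#'   `chrom`, `probe_pos`, `gene`).
#' @param gwas Tibble from [read_gwas_table()].
#' @param xqtl_effects Effect rows (tibble) for this probe, or a full effects
#'   table that will be filtered on `probe_id`.
#' @param panel A `genotype_panel`.
#' @param config An `smr_config`.
#' @return List of class `aligned_region` with `probe`, `snps` (tibble with
#'   `snp, pos, b_zx, se_zx, p_zx, b_zy, se_zy, p_zy, freq_xqtl, freq_gwas,
#'   freq_ref`), `ld` (correlation matrix) and `counts` (named integer vector
#'   of filter-step drop counts). An empty region is a valid result.
#' @export
harmonize_region <- function(probe, gwas, xqtl_effects, panel, config = smr_config()) {
  eff <- xqtl_effects
  if ("probe_id" %in% names(eff)) eff <- eff[eff$probe_id == probe$probe_id, ]
  counts <- c(n_cis = 0L, not_in_gwas = 0L, not_in_panel = 0L,
              allele_mismatch = 0L, strand_ambiguous = 0L, monomorphic = 0L,
              freq_mismatch = 0L, kept = 0L)

  eff <- eff[eff$chrom == probe$chrom &
               abs(eff$pos - probe$probe_pos) <= config$cis_window_bp, ]
  counts["n_cis"] <- nrow(eff)
  empty <- function() structure(list(probe = probe,
                                     snps = tibble::tibble(snp = character()),
                                     ld = matrix(numeric(), 0, 0),
                                     counts = counts),
                                class = "aligned_region")
  if (nrow(eff) == 0) return(empty())

  gi <- match(eff$snp, gwas$snp)
  counts["not_in_gwas"] <- sum(is.na(gi))
  keep <- !is.na(gi)
  eff <- eff[keep, ]; gi <- gi[keep]
  pi_ <- match(eff$snp, panel$snps$snp)
  counts["not_in_panel"] <- sum(is.na(pi_))
  keep <- !is.na(pi_)
  eff <- eff[keep, ]; gi <- gi[keep]; pi_ <- pi_[keep]
  if (nrow(eff) == 0) return(empty())

  amb <- strand_ambiguous(eff$a1, eff$a2)
  counts["strand_ambiguous"] <- sum(amb)
  eff <- eff[!amb, ]; gi <- gi[!amb]; pi_ <- pi_[!amb]
  if (nrow(eff) == 0) return(empty())

  g <- gwas[gi, ]
  pan <- panel$snps[pi_, ]
  g_same <- g$a1 == eff$a1 & g$a2 == eff$a2
  g_swap <- g$a1 == eff$a2 & g$a2 == eff$a1
  p_same <- pan$a1 == eff$a1 & pan$a2 == eff$a2
  p_swap <- pan$a1 == eff$a2 & pan$a2 == eff$a1
  ok <- (g_same | g_swap) & (p_same | p_swap)
  counts["allele_mismatch"] <- sum(!ok)
  eff <- eff[ok, ]; g <- g[ok, ]; pan <- pan[ok, ]
  g_swap <- g_swap[ok]; p_swap <- p_swap[ok]
  if (nrow(eff) == 0) return(empty())

  b_zy <- ifelse(g_swap, -g$beta, g$beta)
  freq_gwas <- ifelse(g_swap, 1 - g$freq, g$freq)
  freq_ref <- ifelse(p_swap, 1 - pan$freq, pan$freq)

  mono <- pan$monomorphic
  counts["monomorphic"] <- sum(mono)
  keep <- !mono
  eff <- eff[keep, ]; g <- g[keep, ]
  b_zy <- b_zy[keep]; freq_gwas <- freq_gwas[keep]; freq_ref <- freq_ref[keep]
  p_swap <- p_swap[keep]
  if (nrow(eff) == 0) return(empty())

  fdiff <- pmax(abs(eff$freq - freq_gwas),
                abs(eff$freq - freq_ref),
                abs(freq_gwas - freq_ref))
  fbad <- fdiff > config$freq_mismatch
  counts["freq_mismatch"] <- sum(fbad)
  keep <- !fbad
  eff <- eff[keep, ]; g <- g[keep, ]
  b_zy <- b_zy[keep]; freq_gwas <- freq_gwas[keep]; freq_ref <- freq_ref[keep]
  p_swap <- p_swap[keep]
  counts["kept"] <- nrow(eff)
  if (nrow(eff) == 0) return(empty())

  snps <- tibble::tibble(
    snp = eff$snp, pos = eff$pos, a1 = eff$a1, a2 = eff$a2,
    b_zx = eff$beta, se_zx = eff$se, p_zx = eff$p,
    b_zy = b_zy, se_zy = g$se, p_zy = g$p,
    freq_xqtl = eff$freq, freq_gwas = freq_gwas, freq_ref = freq_ref
  )
  ld <- panel_cor(panel, snps$snp, flip = p_swap)
  structure(list(probe = probe, snps = snps, ld = ld, counts = counts),
            class = "aligned_region")
}

#' @export
print.aligned_region <- function(x, ...) {
  cat(sprintf("<aligned_region> probe %s: %d SNPs retained\n",
              x$probe$probe_id, nrow(x$snps)))
  invisible(x)
}

#' Pick the top cis instrument in an aligned region
#'
#' The SNP with smallest xQTL p-value, if it passes the instrument
#' threshold. Ties are broken deterministically: larger |z_zx|, then smaller
#' position.
#'
#' @inheritParams select_heidi_snps
#' @return Integer row index into `region$snps`, or `NA` when no SNP passes.
#' @export
select_top_instrument <- function(region, config = smr_config()) {
  s <- region$snps
  if (nrow(s) == 0) return(NA_integer_)
  ord <- order(s$p_zx, -abs(s$b_zx / s$se_zx), s$pos)
  top <- ord[1L]
  if (s$p_zx[top] < config$instrument_p) top else NA_integer_
}

#' Wald ratio estimate of the mediator-to-trait effect
#'
#' `b_xy = b_zy / b_zx` with first-order (delta-method) standard error
#' `se_xy = |b_xy| * sqrt(se_zy^2/b_zy^2 + se_zx^2/b_zx^2)`. When `b_zy = 0`
#' the estimate is 0 with `se_xy = se_zy / |b_zx|` (the delta limit).
#'
#' @param b_zx,se_zx SNP effect on the molecular level and its SE.
#' @param b_zy,se_zy SNP effect on the trait and its SE.
#' @return List with `b_xy` and `se_xy` (vectorized).
#' @export
wald_ratio <- function(b_zx, se_zx, b_zy, se_zy) {
  if (any(b_zx == 0)) stop_format("wald_ratio: b_zx must be non-zero (undefined instrument)")
  b_xy <- b_zy / b_zx
  se_xy <- ifelse(b_zy == 0,
                  se_zy / abs(b_zx),
                  abs(b_xy) * sqrt(se_zy^2 / b_zy^2 + se_zx^2 / b_zx^2))
  list(b_xy = b_xy, se_xy = se_xy)
}

#' The SMR test statistic and p-value
#'
#' `T_SMR = z_zx^2 z_zy^2 / (z_zx^2 + z_zy^2)`, compared to the upper tail
#' of a 1-df chi-square. Symmetric in its arguments and bounded above by
#' `min(z_zx^2, z_zy^2)`.
#'
#' @param z_zx,z_zy Z-scores of the xQTL and GWAS associations at the
#'   instrument.
#' @return List with `t_smr` and `p_smr` (vectorized).
#' @export
smr_test <- function(z_zx, z_zy) {
  stopifnot(all(is.finite(z_zx)), all(is.finite(z_zy)), all(z_zx != 0))
  t_smr <- (z_zx^2 * z_zy^2) / (z_zx^2 + z_zy^2)
  # clamp: the chi-square tail underflows to 0 for extreme statistics
  p <- pmax(stats::pchisq(t_smr, df = 1, lower.tail = FALSE), 1e-300)
  list(t_smr = t_smr, p_smr = p)
}

#' Select the HEIDI instrument set
#'
#' Candidates are cis SNPs (excluding the top instrument) with xQTL
#' p < `heidi_select_p`. SNPs in too-strong (`r^2 > prune_r2_high`) or
#' too-weak (`r^2 < prune_r2_low`) LD with the top SNP are removed; among
#' remaining near-duplicate pairs (`r^2 > prune_r2_high` with each other)
#' the smaller xQTL p wins; at most `heidi_max` SNPs are kept (smallest p).
#' Fewer than `heidi_min` survivors means HEIDI is not run.
#'
#' @param region An `aligned_region`.
#' @param top Index of the top instrument (from [select_top_instrument()]).
#' @param config An `smr_config`.
#' @return Integer vector of row indices (possibly empty).
#' @export
select_heidi_snps <- function(region, top, config = smr_config()) {
  s <- region$snps
  r2_top <- region$ld[, top]^2
  cand <- which(seq_len(nrow(s)) != top &
                  s$p_zx < config$heidi_select_p &
                  r2_top <= config$prune_r2_high &
                  r2_top >= config$prune_r2_low)
  if (length(cand) == 0) return(integer())
  cand <- cand[order(s$p_zx[cand], -abs(s$b_zx[cand] / s$se_zx[cand]), s$pos[cand])]
  kept <- integer()
  for (i in cand) {
    if (length(kept) >= config$heidi_max) break
    if (all(region$ld[i, kept]^2 <= config$prune_r2_high)) kept <- c(kept, i)
  }
  if (length(kept) < config$heidi_min) return(integer())
  kept
}

#' The HEIDI heterogeneity test
#'
#' Tests whether Wald ratios at LD-linked instruments are consistent with a
#' single shared causal variant. For each instrument i, the ratio
#' `b_i = b_zy_i / b_zx_i` has delta-method variance
#' `(se_zy_i^2 + b_i^2 se_zx_i^2) / b_zx_i^2` and covariance
#' `r_ij (se_zy_i se_zy_j + b_i b_j se_zx_i se_zx_j) / (b_zx_i b_zx_j)`
#' (GWAS and xQTL cohorts are assumed non-overlapping, so no cross-cohort
#' term). The statistic is the sum of squared standardized differences
#' `d_i = b_i - b_top`; its null distribution is a weighted sum of 1-df
#' chi-squares with weights the eigenvalues of the correlation matrix of d,
#' evaluated by [weighted_chisq_tail()] with the method named in
#' `config$heidi_tail` (saddlepoint by default).
#'
#' @inheritParams select_heidi_snps
#' @param snp_set Indices from [select_heidi_snps()].
#' @return List `t_heidi`, `p_heidi` (`NA` on a numerically degenerate
#'   covariance), `nsnp` (instrument count including the top SNP).
#' @export
heidi_test <- function(region, top, snp_set, config = smr_config()) {
  stopifnot(length(snp_set) >= 1, !top %in% snp_set)
  idx <- c(top, snp_set)
  s <- region$snps[idx, ]
  R <- region$ld[idx, idx, drop = FALSE]
  b <- s$b_zy / s$b_zx
  # delta-method covariance of the ratio estimates
  V <- R * (outer(s$se_zy, s$se_zy) + outer(b, b) * outer(s$se_zx, s$se_zx)) /
    outer(s$b_zx, s$b_zx)
  m <- length(snp_set)
  d <- b[-1L] - b[1L]
  Cd <- V[-1L, -1L, drop = FALSE] -
    matrix(V[-1L, 1L], m, m) - matrix(V[1L, -1L], m, m, byrow = TRUE) + V[1L, 1L]
  Cd <- Cd + diag(config$ridge, m)
  vd <- diag(Cd)
  bad <- list(t_heidi = NA_real_, p_heidi = NA_real_, nsnp = m + 1L)
  if (any(!is.finite(vd)) || any(vd <= 0)) return(bad)
  z <- d / sqrt(vd)
  t_heidi <- sum(z^2)
  Corr <- stats::cov2cor(Cd)
  lambda <- tryCatch(eigen(Corr, symmetric = TRUE, only.values = TRUE)$values,
                     error = function(e) NULL)
  if (is.null(lambda) || any(!is.finite(lambda))) return(bad)
  lambda <- pmax(lambda, 0)
  if (sum(lambda) <= 0) return(bad)
  p <- weighted_chisq_tail(t_heidi, lambda, method = config$heidi_tail,
                           mc_draws = config$heidi_mc_draws,
                           mc_seed = config$heidi_mc_seed)
  list(t_heidi = t_heidi, p_heidi = p, nsnp = m + 1L)
}

#' Upper tail of a weighted sum of 1-df chi-squares
#'
#' `P(sum_k lambda_k chisq_1 > t)` by one of three routes: the
#' Lugannani-Rice saddlepoint approximation (default; deterministic and
#' accurate far into the tail), Satterthwaite two-moment matching (scale
#' `a = sum(lambda^2)/sum(lambda)`, dof `nu = sum(lambda)^2/sum(lambda^2)`;
#' cheap but anti-conservative below p ~ 1e-2 when the weights are spread),
#' or Monte-Carlo with an add-one correction.
#'
#' @param t Observed statistic (scalar).
#' @param lambda Non-negative weights.
#' @param method `"saddlepoint"`, `"satterthwaite"` or `"montecarlo"`.
#' @param mc_draws,mc_seed Monte-Carlo controls.
#' @return Tail probability in (0, 1].
#' @export
weighted_chisq_tail <- function(t, lambda,
                                method = c("saddlepoint", "satterthwaite", "montecarlo"),
                                mc_draws = 1e5, mc_seed = 20240801L) {
  method <- match.arg(method)
  switch(method,
         saddlepoint = saddlepoint_tail(t, lambda),
         satterthwaite = satterthwaite_tail(t, lambda),
         montecarlo = mc_weighted_chisq_tail(t, lambda, mc_draws, mc_seed))
}

# Lugannani-Rice saddlepoint tail for sum(lambda_k chisq_1); falls back to
# two-moment matching in the immediate neighbourhood of the mean, where the
# saddlepoint formula is singular (p ~ 0.5 there, so accuracy is uncritical)
saddlepoint_tail <- function(t, lambda) {
  lambda <- lambda[lambda > 1e-12]
  if (length(lambda) == 0) return(1)
  s1 <- sum(lambda)
  if (t <= 0) return(1)
  # (near-)equal weights: the exact chi-square tail, which two-moment
  # matching reproduces, beats the saddlepoint approximation
  if (diff(range(lambda)) < 1e-9 * mean(lambda))
    return(satterthwaite_tail(t, lambda))
  if (abs(t - s1) < 1e-6 * s1) return(satterthwaite_tail(t, lambda))
  up <- 1 / (2 * max(lambda))
  Kp <- function(s) sum(lambda / (1 - 2 * s * lambda))
  lo <- -1e4 / s1
  if (Kp(lo) > t) return(satterthwaite_tail(t, lambda))
  sh <- stats::uniroot(function(s) Kp(s) - t, c(lo, up * (1 - 1e-12)),
                       tol = .Machine$double.eps^0.5)$root
  K <- -0.5 * sum(log1p(-2 * sh * lambda))
  Kpp <- 2 * sum(lambda^2 / (1 - 2 * sh * lambda)^2)
  w <- sign(sh) * sqrt(max(2 * (sh * t - K), 0))
  v <- sh * sqrt(Kpp)
  if (abs(w) < 1e-8 || abs(v) < 1e-12) return(satterthwaite_tail(t, lambda))
  p <- stats::pnorm(w + log(v / w) / w, lower.tail = FALSE)
  min(max(p, 1e-300), 1)
}

# two-moment (Satterthwaite) upper tail of sum(lambda_k * chisq_1)
satterthwaite_tail <- function(t, lambda) {
  s1 <- sum(lambda); s2 <- sum(lambda^2)
  if (s2 == 0) return(1)
  a <- s2 / s1
  nu <- s1^2 / s2
  pmax(stats::pchisq(t / a, df = nu, lower.tail = FALSE), 1e-300)
}

# Monte-Carlo upper tail with add-one correction, on a private RNG stream
mc_weighted_chisq_tail <- function(t, lambda, draws = 1e5, seed = 20240801L) {
  with_seed(seed, {
    sims <- as.vector(matrix(stats::rchisq(draws * length(lambda), df = 1),
                             nrow = draws) %*% lambda)
    (1 + sum(sims >= t)) / (1 + draws)
  })
}

#' Run the full per-probe analysis
#'
#' Composes harmonization, top-instrument selection, the Wald-ratio/SMR
#' test, HEIDI instrument selection and test, and the HEIDI-penalized
#' adjustment into one record. Probes with no passing instrument yield
#' `NULL`.
#'
#' @inheritParams harmonize_region
#' @return One-row tibble (an SMR record) or `NULL`.
#' @export
run_probe <- function(probe, gwas, xqtl_effects, panel, config = smr_config()) {
  region <- harmonize_region(probe, gwas, xqtl_effects, panel, config)
  probe_record(region, config)
}

# per-probe record from an already-harmonized region (NULL if no instrument)
probe_record <- function(region, config = smr_config()) {
  probe <- region$probe
  top <- select_top_instrument(region, config)
  if (is.na(top)) return(NULL)
  s <- region$snps[top, ]
  wr <- wald_ratio(s$b_zx, s$se_zx, s$b_zy, s$se_zy)
  smr <- smr_test(s$b_zx / s$se_zx, s$b_zy / s$se_zy)
  hs <- select_heidi_snps(region, top, config)
  if (length(hs) > 0) {
    h <- heidi_test(region, top, hs, config)
    p_heidi <- h$p_heidi
    nsnp <- if (is.na(h$p_heidi)) NA_integer_ else h$nsnp
  } else {
    p_heidi <- NA_real_
    nsnp <- NA_integer_
  }
  tibble::tibble(
    probe_id = probe$probe_id, chrom = probe$chrom,
    gene = probe$gene, probe_pos = as.integer(probe$probe_pos),
    top_snp = s$snp, a1 = s$a1, a2 = s$a2, freq = s$freq_xqtl,
    b_gwas = s$b_zy, se_gwas = s$se_zy, p_gwas = s$p_zy,
    b_xqtl = s$b_zx, se_xqtl = s$se_zx, p_xqtl = s$p_zx,
    b_smr = wr$b_xy, se_smr = wr$se_xy, p_smr = smr$p_smr,
    p_heidi = p_heidi, nsnp_heidi = nsnp,
    p_smr_adj = adjust_for_heidi(smr$p_smr, p_heidi, config$heidi_adjust_floor)
  )
}

#' Per-probe SMR/HEIDI scan over an xQTL dataset
#'
#' Applies [run_probe()] to every usable probe and stacks the records.
#' Filter-step counters (summed over probes, plus probes without an
#' instrument) are attached as attribute `counts`.
#'
#' @param xqtl An `xqtl_dataset`.
#' @param gwas Tibble from [read_gwas_table()].
#' @param panel A `genotype_panel`.
#' @param config An `smr_config`.
#' @return Tibble of SMR records (zero rows if nothing passes), with
#'   attribute `counts`.
#' @export
run_smr <- function(xqtl, gwas, panel, config = smr_config()) {
  probes <- xqtl$probes[xqtl$probes$usable, ]
  eff_split <- split(xqtl$effects, xqtl$effects$probe_id)
  totals <- NULL
  no_instrument <- 0L
  heidi_skipped <- 0L
  recs <- vector("list", nrow(probes))
  for (i in seq_len(nrow(probes))) {
    probe <- probes[i, ]
    region_eff <- eff_split[[probe$probe_id]]
    region <- harmonize_region(probe, gwas, region_eff, panel, config)
    totals <- if (is.null(totals)) region$counts else totals + region$counts
    rec <- probe_record(region, config)
    if (is.null(rec)) { no_instrument <- no_instrument + 1L; next }
    if (is.na(rec$p_heidi)) heidi_skipped <- heidi_skipped + 1L
    recs[[i]] <- rec
  }
  out <- dplyr::bind_rows(recs)
  counts <- c(totals %||% integer(), probes_no_instrument = no_instrument,
              probes_heidi_skipped = heidi_skipped,
              probes_tested = nrow(out))
  attr(out, "counts") <- counts
  out
}
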