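test_that("harmonization aligns alleles, drops ambiguous and mismatched SNPs", {
  sp <- scenario_spec("causal", seed = 5)
  r <- simulate_summary_region(sp, scramble = FALSE)
  # swap one GWAS record's alleles by hand: harmonization must flip it back
  gwas2 <- r$gwas
  gwas2[3, c("a1", "a2")] <- gwas2[3, c("a2", "a1")]
  gwas2$beta[3] <- -gwas2$beta[3]
  gwas2$freq[3] <- 1 - gwas2$freq[3]
  reg0 <- harmonize_region(r$probe, r$gwas, r$xqtl, r$panel)
  reg1 <- harmonize_region(r$probe, gwas2, r$xqtl, r$panel)
  expect_equal(reg1$snps, reg0$snps)
  expect_equal(reg1$ld, reg0$ld)

  # frequency mismatch beyond 15 points is dropped (|0.10 - 0.30| = 0.20)
  gwas3 <- r$gwas
  gwas3$freq[4] <- ifelse(r$xqtl$freq[4] > 0.5, r$xqtl$freq[4] - 0.2,
                          r$xqtl$freq[4] + 0.2)
  reg3 <- harmonize_region(r$probe, gwas3, r$xqtl, r$panel)
  expect_equal(nrow(reg3$snps), nrow(reg0$snps) - 1L)
  expect_false(r$xqtl$snp[4] %in% reg3$snps$snp)
  expect_equal(unname(reg3$counts["freq_mismatch"]), 1L)

  # strand-ambiguous SNP dropped regardless of frequency agreement
  xq4 <- r$xqtl
  xq4$a1[5] <- "A"; xq4$a2[5] <- "T"
  gw4 <- r$gwas
  gw4$a1[5] <- "A"; gw4$a2[5] <- "T"
  pan4 <- r$panel
  pan4$snps$a1[5] <- "A"; pan4$snps$a2[5] <- "T"
  reg4 <- harmonize_region(r$probe, gw4, xq4, pan4)
  expect_false(r$xqtl$snp[5] %in% reg4$snps$snp)
  expect_equal(unname(reg4$counts["strand_ambiguous"]), 1L)

  # cis-window restriction
  probe_far <- r$probe
  probe_far$probe_pos <- r$probe$probe_pos + 5e6
  reg5 <- harmonize_region(probe_far, r$gwas, r$xqtl, r$panel)
  expect_equal(nrow(reg5$snps), 0L)
})

test_that("top-instrument selection applies the threshold and tie-breaks", {
  reg <- make_region(b_zx = c(0.1, 0.2, 0.3), se_zx = c(0.01, 0.01, 0.01),
                     b_zy = c(0, 0, 0), se_zy = rep(0.01, 3),
                     p_zx = c(1e-7, 1e-9, 1e-6))
  expect_equal(select_top_instrument(reg), 2L)
  # nothing passes the genome-wide threshold
  reg2 <- make_region(b_zx = c(0.1, 0.2), se_zx = c(0.01, 0.01),
                      b_zy = c(0, 0), se_zy = rep(0.01, 2),
                      p_zx = c(1e-6, 5e-8))
  expect_true(is.na(select_top_instrument(reg2)))
  # exact p tie: larger |z| wins
  reg3 <- make_region(b_zx = c(0.059, 0.061), se_zx = c(0.01, 0.01),
                      b_zy = c(0, 0), se_zy = rep(0.01, 2),
                      p_zx = c(1e-9, 1e-9))
  expect_equal(select_top_instrument(reg3), 2L)
  # full tie: smaller position wins
  reg4 <- make_region(b_zx = c(0.06, 0.06), se_zx = c(0.01, 0.01),
                      b_zy = c(0, 0), se_zy = rep(0.01, 2),
                      p_zx = c(1e-9, 1e-9), pos = c(2000L, 1000L))
  expect_equal(select_top_instrument(reg4), 2L)
})

test_that("Wald ratio arithmetic matches the delta formula and its MC oracle", {
  wr <- wald_ratio(0.5, 0.05, 0.1, 0.02)
  expect_equal(wr$b_xy, 0.2)
  expect_equal(wr$se_xy, 0.2 * sqrt((0.02 / 0.1)^2 + (0.05 / 0.5)^2))
  # zero-numerator convention
  wr0 <- wald_ratio(1, 0.1, 0, 0.02)
  expect_equal(wr0$b_xy, 0)
  expect_equal(wr0$se_xy, 0.02)
  expect_error(wald_ratio(0, 0.1, 0.1, 0.02), "b_zx")

  # sampling oracle: empirical SD of the ratio over 1e6 draws within 5%
  # of the first-order SE
  set.seed(21)
  bzx <- rnorm(1e6, 0.5, 0.05)
  bzy <- rnorm(1e6, 0.1, 0.02)
  expect_lt(abs(sd(bzy / bzx) / wr$se_xy - 1), 0.05)
})

test_that("SMR statistic: bounds, symmetry, monotonicity, chi-square tail", {
  expect_equal(smr_test(3, 0)$t_smr, 0)
  expect_equal(smr_test(3, 0)$p_smr, 1)
  z <- 4.2
  expect_equal(smr_test(z, z)$t_smr, z^2 / 2)
  s <- smr_test(10, 4)
  expect_equal(s$t_smr, 1600 / 116)
  expect_equal(s$p_smr, 2.04084e-4, tolerance = 1e-5)
  # symmetry and upper bound over a grid
  for (zz in list(c(2, 7), c(-3, 1.5), c(5, 5))) {
    expect_equal(smr_test(zz[1], zz[2])$t_smr, smr_test(zz[2], zz[1])$t_smr)
    expect_lte(smr_test(zz[1], zz[2])$t_smr, min(zz^2))
  }
  # monotone increasing in |z_zy| for fixed z_zx
  ts <- vapply(seq(0, 6, by = 0.5), function(zy) smr_test(3, zy)$t_smr, 1)
  expect_true(all(diff(ts) > 0))
})

test_that("HEIDI instrument selection enforces LD pruning and size bounds", {
  m <- 30
  ld <- outer(1:m, 1:m, function(i, j) 0.6^abs(i - j))
  reg <- make_region(b_zx = rep(0.5, m), se_zx = rep(0.01, m),
                     b_zy = rep(0.1, m), se_zy = rep(0.01, m), ld = ld,
                     p_zx = c(1e-20, rep(1e-4, m - 1)))
  top <- select_top_instrument(reg)
  expect_equal(top, 1L)
  sel <- select_heidi_snps(reg, top)
  # near-duplicates of the top (r^2 > 0.9) and near-independent SNPs
  # (r^2 < 0.05) are both excluded
  r2 <- ld[, top]^2
  expect_true(all(r2[sel] <= 0.9 & r2[sel] >= 0.05))
  expect_lte(length(sel), 20L)

  # p-value gate: SNPs at or above 1.57e-3 never enter
  reg2 <- reg
  reg2$snps$p_zx[-1] <- 1.57e-3
  expect_length(select_heidi_snps(reg2, 1L), 0L)

  # fewer than 3 survivors: HEIDI skipped
  reg3 <- make_region(b_zx = rep(0.5, 3), se_zx = rep(0.01, 3),
                      b_zy = rep(0.1, 3), se_zy = rep(0.01, 3),
                      ld = outer(1:3, 1:3, function(i, j) 0.6^abs(i - j)),
                      p_zx = c(1e-20, 1e-4, 1e-4))
  expect_length(select_heidi_snps(reg3, 1L), 0L)

  # cap at 20: with >20 admissible SNPs the 20 smallest p survive
  ld_w <- matrix(0.3, m, m); diag(ld_w) <- 1
  regw <- make_region(b_zx = rep(0.5, m), se_zx = rep(0.01, m),
                      b_zy = rep(0.1, m), se_zy = rep(0.01, m), ld = ld_w,
                      p_zx = c(1e-20, seq(1e-6, 1e-3, length.out = m - 1)))
  selw <- select_heidi_snps(regw, 1L)
  expect_length(selw, 20L)
  expect_equal(sort(selw), 2:21)
})

test_that("HEIDI covariance matches an independent re-derivation and the
           uncorrelated case collapses to the plain chi-square tail", {
  set.seed(31)
  m <- 8
  ld <- outer(1:m, 1:m, function(i, j) 0.7^abs(i - j))
  reg <- make_region(b_zx = runif(m, 0.3, 0.6), se_zx = runif(m, 0.008, 0.012),
                     b_zy = runif(m, 0.05, 0.15), se_zy = runif(m, 0.008, 0.012),
                     ld = ld, p_zx = c(1e-20, rep(1e-5, m - 1)))
  top <- 1L
  sel <- 2:m
  h <- heidi_test(reg, top, sel)
  o <- oracle_heidi_cov(reg, top, sel)
  z <- o$d / sqrt(diag(o$Cd) + 1e-8)
  expect_equal(h$t_heidi, sum(z^2), tolerance = 1e-6)
  expect_equal(h$nsnp, m)

  # identical ratios: T = 0, p = 1
  reg0 <- make_region(b_zx = rep(0.5, 5), se_zx = rep(0.01, 5),
                      b_zy = rep(0.1, 5), se_zy = rep(0.01, 5),
                      ld = diag(5), p_zx = c(1e-20, rep(1e-5, 4)))
  h0 <- heidi_test(reg0, 1L, 2:5)
  expect_equal(h0$t_heidi, 0)
  expect_equal(h0$p_heidi, 1)

  # uncorrelated instruments with a precisely-measured top ratio: the
  # null distribution is an exact chi-square with |set| df
  mm <- 6
  regI <- make_region(b_zx = c(10, runif(mm - 1, 0.4, 0.6)),
                      se_zx = c(1e-9, rep(0.01, mm - 1)),
                      b_zy = c(2, runif(mm - 1, 0.05, 0.3)),
                      se_zy = c(1e-9, rep(0.01, mm - 1)),
                      ld = diag(mm), p_zx = c(1e-300, rep(1e-5, mm - 1)))
  hI <- heidi_test(regI, 1L, 2:mm)
  expect_equal(hI$p_heidi,
               pchisq(hI$t_heidi, df = mm - 1, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("deterministic HEIDI tail tracks a weighted chi-square MC oracle", {
  # 6 random AR(1)-plus-common-component spectra, tail checked at several
  # depths against direct simulation of sum(lambda chisq_1)
  set.seed(88)
  for (k in 1:6) {
    m <- sample(4:12, 1)
    rho <- runif(1, 0.3, 0.9)
    cc <- runif(1, 0, 0.7)
    R <- (1 - cc) * outer(1:m, 1:m, function(i, j) rho^abs(i - j)) + cc
    lam <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    sims <- as.vector(matrix(rchisq(2e5 * m, 1), 2e5) %*% lam)
    for (target in c(1e-3, 1e-2, 0.2)) {
      t_obs <- unname(quantile(sims, 1 - target))
      p_mc <- (1 + sum(sims >= t_obs)) / (1 + 2e5)
      p_det <- weighted_chisq_tail(t_obs, lam, method = "saddlepoint")
      expect_lt(abs(log(p_det / p_mc)), log(1.5))
    }
  }
  # the Monte-Carlo route agrees with its own definition and is reproducible
  lam <- c(2, 1, 0.5)
  p1 <- weighted_chisq_tail(4, lam, method = "montecarlo", mc_draws = 2e4)
  p2 <- weighted_chisq_tail(4, lam, method = "montecarlo", mc_draws = 2e4)
  expect_identical(p1, p2)
})

test_that("run_probe composes the stages and honors boundaries", {
  sp <- scenario_spec("causal", seed = 17)
  r <- simulate_summary_region(sp)
  rec <- run_probe(r$probe, r$gwas, r$xqtl, r$panel)
  expect_s3_class(rec, "tbl_df")
  expect_equal(rec$top_snp, r$truth$causal_x_snp)
  expect_lt(rec$p_smr, 1e-4)
  expect_equal(rec$p_smr_adj,
               adjust_for_heidi(rec$p_smr, rec$p_heidi))

  # no instrument at 5e-8: no record
  xq <- r$xqtl
  xq$p <- pmax(xq$p, 1e-6)
  expect_null(run_probe(r$probe, r$gwas, xq, r$panel))
})

test_that("allele-flip invariance: flipping any one input leaves records unchanged", {
  sp <- scenario_spec("causal", seed = 23)
  r <- simulate_summary_region(sp, scramble = FALSE)
  base <- run_probe(r$probe, r$gwas, r$xqtl, r$panel)
  flip_rows <- c(2L, 7L, 13L)

  gw <- r$gwas
  gw[flip_rows, c("a1", "a2")] <- gw[flip_rows, c("a2", "a1")]
  gw$beta[flip_rows] <- -gw$beta[flip_rows]
  gw$freq[flip_rows] <- 1 - gw$freq[flip_rows]
  expect_equal(run_probe(r$probe, gw, r$xqtl, r$panel), base)

  pan <- r$panel
  pan$snps[flip_rows, c("a1", "a2")] <- pan$snps[flip_rows, c("a2", "a1")]
  pan$dosages[, flip_rows] <- 2 - pan$dosages[, flip_rows]
  pan$snps$freq[flip_rows] <- 1 - pan$snps$freq[flip_rows]
  expect_equal(run_probe(r$probe, r$gwas, r$xqtl, pan), base)

  # flipping the xQTL flips the reference allele, so the SMR effect changes
  # sign at the flipped top SNP but every p-value is invariant
  xq <- r$xqtl
  top_row <- match(base$top_snp, xq$snp)
  xq[top_row, c("a1", "a2")] <- xq[top_row, c("a2", "a1")]
  xq$beta[top_row] <- -xq$beta[top_row]
  xq$freq[top_row] <- 1 - xq$freq[top_row]
  flipped <- run_probe(r$probe, r$gwas, xq, r$panel)
  # the ratio is invariant under relabeling (numerator and denominator both
  # flip); the reported alleles and frequency reflect the new labels
  expect_equal(flipped$b_smr, base$b_smr)
  expect_equal(flipped$p_smr, base$p_smr)
  expect_equal(flipped$p_heidi, base$p_heidi)
  expect_equal(flipped$a1, base$a2)
  expect_equal(flipped$freq, 1 - base$freq)
})

test_that("probe with exactly 3 admissible HEIDI SNPs still runs HEIDI", {
  ld <- outer(1:4, 1:4, function(i, j) 0.8^abs(i - j))
  reg <- make_region(b_zx = rep(0.5, 4), se_zx = rep(0.01, 4),
                     b_zy = rep(0.1, 4) + c(0, 1e-3, -1e-3, 2e-3),
                     se_zy = rep(0.01, 4), ld = ld,
                     p_zx = c(1e-20, rep(1e-5, 3)))
  sel <- select_heidi_snps(reg, 1L)
  expect_length(sel, 3L)
  h <- heidi_test(reg, 1L, sel)
  expect_equal(h$nsnp, 4L)
  expect_false(is.na(h$p_heidi))
})
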