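test_that("LD panel generator: independence, analytic truth, determinism", {
  # rho = 0: off-diagonal empirical correlations hover near zero
  sp0 <- scenario_spec(m_snps = 10L, ld_rho = 0, n_ref = 1000L, seed = 4)
  lp0 <- make_ld_panel(sp0)
  r0 <- panel_cor(lp0$panel)
  off <- abs(r0[upper.tri(r0)])
  expect_lt(mean(off), 0.05)
  expect_true(all(abs(lp0$ld_true[upper.tri(lp0$ld_true)]) < 1e-12))

  # strong LD: empirical r close to the analytic dosage correlation
  sp9 <- scenario_spec(m_snps = 6L, ld_rho = 0.9, n_ref = 2000L, seed = 5,
                       maf_range = c(0.28, 0.32))
  lp9 <- make_ld_panel(sp9)
  r9 <- panel_cor(lp9$panel)
  for (j in 1:5)
    expect_lt(abs(r9[j, j + 1] - lp9$ld_true[j, j + 1]), 0.1)
  # analytic correlation is below the latent rho (thresholding attenuates)
  expect_lt(lp9$ld_true[1, 2], 0.9)
  expect_gt(lp9$ld_true[1, 2], 0.6)

  # byte-identical regeneration under the same seed
  lp9b <- make_ld_panel(sp9)
  expect_identical(lp9$panel$dosages, lp9b$panel$dosages)
})

test_that("null-scenario summary statistics give uniform GWAS p-values", {
  ps <- unlist(lapply(1:300, function(i) {
    sp <- scenario_spec("null", m_snps = 5L, ld_rho = 0, seed = 5000 + i)
    simulate_summary_region(sp)$gwas$p
  }))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("fast and slow simulation paths agree in distribution", {
  # top-SNP xQTL effect estimates from both fidelities, 120 seeds each:
  # same mean within Monte-Carlo error and same spread (KS test)
  n <- 5000L
  grab <- function(method, seeds) {
    vapply(seeds, function(s) {
      sp <- scenario_spec("causal", m_snps = 6L, n_xqtl = n, n_gwas = n,
                          seed = s, n_ref = 50L)
      r <- simulate_summary_region(sp, method = method, scramble = FALSE)
      r$xqtl$beta[match(r$truth$causal_x_snp, r$xqtl$snp)]
    }, numeric(1))
  }
  fast <- grab("fast", 1:120)
  slow <- grab("slow", 201:320)
  se_mc <- sqrt(var(fast) / 120 + var(slow) / 120)
  expect_lt(abs(mean(fast) - mean(slow)), 2.5 * se_mc)
  ks <- suppressWarnings(ks.test(fast, slow))
  expect_gt(ks$p.value, 0.01)
})

test_that("causal regions yield genome-wide instruments at realistic power", {
  hits <- vapply(1:100, function(i) {
    sp <- scenario_spec("causal", seed = 7000 + i)
    r <- simulate_summary_region(sp)
    min(r$xqtl$p) < 5e-8
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("pattern p-value generator honors its labels and seed", {
  sim0 <- simulate_pattern_pvalues(1e4, 2, c(1, 0, 0, 0), seed = 8)
  expect_equal(mean(sim0$P), 0.5, tolerance = 0.01)
  sim1 <- simulate_pattern_pvalues(5e3, 2, c(0.98, 0, 0, 0.02), alt_scale = 10,
                                   seed = 9)
  assoc <- sim1$truth$assoc_study1
  # closed-form median of the associated p-values: exp(-scale * log(2)) = 2^-10
  expect_lt(abs(log(median(sim1$P[assoc, 1]) / 2^-10)), log(1.25))
  expect_identical(simulate_pattern_pvalues(5e3, 2, c(0.98, 0, 0, 0.02),
                                            alt_scale = 10, seed = 9)$P,
                   sim1$P)
})

test_that("fixture bundle is complete, self-consistent and deterministic", {
  dir1 <- withr::local_tempdir()
  fx <- write_fixture_set(dir1, n_probes = 12L,
                          scenario_counts = c(causal = 6L, linkage = 3L, null = 3L),
                          studies = c("s1", "s2"), seed = 5,
                          universe_size = 500L, n_random_sets = 3L)
  # the bundle reads back through the standard readers
  gw <- read_gwas_table(fx$studies$s1$gwas)
  xq <- read_xqtl_dataset(fx$studies$s1$xqtl, fx$probe_annot)
  pan <- read_genotype_panel(fx$panel)
  expect_equal(nrow(xq$probes), 12L)
  expect_equal(ncol(pan$dosages), nrow(gw))
  expect_true(all(xq$effects$snp %in% gw$snp))
  truth <- jsonlite::read_json(fx$truth, simplifyVector = TRUE)
  expect_equal(sum(truth$scenario == "causal"), 6L)
  gmt <- read_gmt(fx$gmt)
  expect_true("planted_set" %in% gmt$set_name)

  # regenerating under the same seed gives byte-identical files
  dir2 <- withr::local_tempdir()
  fx2 <- write_fixture_set(dir2, n_probes = 12L,
                           scenario_counts = c(causal = 6L, linkage = 3L, null = 3L),
                           studies = c("s1", "s2"), seed = 5,
                           universe_size = 500L, n_random_sets = 3L)
  for (f in c("panel.tsv", "probes.tsv", "sets.gmt", "gwas_s1.ma", "xqtl_s2.tsv"))
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)))
})
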