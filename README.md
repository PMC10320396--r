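# xwasmr

Molecular-trait-wide association scans (TWAS / PWAS / MWAS) from summary
statistics, for statistical geneticists integrating GWAS with cis-xQTL
reference data. Given per-SNP effects from a trait GWAS, per-SNP cis
effects on molecular probes (transcripts, proteins, CpG sites), and a
reference genotype panel for LD, `xwasmr` runs the full chain:

1. **SMR** — per probe, the Wald ratio `b_xy = b_zy / b_zx` at the top cis
   instrument (xQTL `p < 5e-8` within 2 Mb), tested with
   `T_SMR = z_zx² z_zy² / (z_zx² + z_zy²)` against a 1-df chi-square.
2. **HEIDI** — heterogeneity in dependent instruments: do Wald ratios at
   3–20 LD-linked instruments agree with one shared causal variant, or do
   they betray linkage of distinct variants? The null is a weighted sum of
   1-df chi-squares (weights = eigenvalues of the difference-correlation
   matrix), evaluated by a saddlepoint approximation.
3. **HEIDI-penalized p-values** —
   `p'_SMR = min(1, p_SMR / min(p_HEIDI / 0.01, 1))`: no penalty when
   HEIDI shows no heterogeneity, a smooth demotion as it does.
4. **Gene level** — Cauchy (ACAT) combination of probe p-values per gene
   (valid under arbitrary probe correlation), with suggestive (`p < 1/m`)
   and Bonferroni (`p < 0.05/m`) flags.
5. **Multi-study concordance** — a 2^J-pattern mixture model over J
   studies (traits × tissues × paradigms) fit by EM; genes are called per
   study at marginal posterior probability PP > 0.95.
6. **Enrichment** — hypergeometric gene-set tests against a 54,619-gene
   universe, MHC (chr6:25–35 Mb) excluded, BH-FDR at q < 0.05.

A synthetic-data module generates complete input bundles (GWAS `.ma`,
flat-text xQTL effects, dosage panel, gene sets) under causal, pleiotropy,
linkage and null scenarios with AR(1) LD and known ground truth, so every
stage is validated end to end without any external data.

## Worked example

```r
library(xwasmr)

# one causal cis region: true effect b_xy = 0.3, xQTL n = 30,000, GWAS n = 100,000
sp <- scenario_spec("causal", seed = 42)
r  <- simulate_summary_region(sp)
run_probe(r$probe, r$gwas, r$xqtl, r$panel)
#> # A tibble: 1 × 20
#>   probe_id top_snp     b_smr  se_smr  p_smr p_heidi nsnp_heidi p_smr_adj
#>   <chr>    <chr>       <dbl>   <dbl>  <dbl>   <dbl>      <int>     <dbl>
#> 1 probe1   probe1_rs10 0.301 0.00727 1e-300   0.239         12    1e-300
```

The estimate recovers the true 0.3; HEIDI (12 instruments, p = 0.24) sees
no heterogeneity, so the adjusted p equals the SMR p. A linkage region —
distinct causal variants for expression and trait at LD r ≈ 0.6 — from the
same seed gives:

```r
sp2 <- scenario_spec("linkage", seed = 42)
r2  <- simulate_summary_region(sp2)
run_probe(r2$probe, r2$gwas, r2$xqtl, r2$panel)
#>   b_smr     p_smr  p_heidi p_smr_adj
#>   0.170 3.85e-143 1.35e-89  2.85e-56
```

The SMR p alone looks spectacular, but HEIDI rejects (p ≈ 1e-89) and the
penalty demotes the signal by 87 orders of magnitude — exactly the
linkage artifact the test exists to catch.

A full multi-study run from files:

```r
fx   <- write_fixture_set("sim", seed = 1)          # 200 probes × 3 studies
res  <- lapply(fx$studies, \(s) run_xwas(s$config)) # scan + genes + enrichment
conc <- run_concordance(lapply(res, `[[`, "genes"), out_dir = "sim/conc")
significant_concordance(conc$fit)                   # gene/study calls, PP > 0.95
```

`run_xwas()` writes `smr_probes.tsv`, `gene_level.tsv`, `enrichment.tsv`
and a `run_log.tsv` counting every harmonization filter step; outputs are
byte-identical under a fixed master seed. A thin CLI over the same
functions lives at `inst/cli/xwasmr.R` (subcommands `simulate`, `xwas`,
`concord`, `enrich`).

## File formats

- **GWAS**: COJO-style `.ma` text — `SNP A1 A2 freq b se p N`; for
  case-control traits read with `effect_is_or = TRUE` to log-transform
  odds ratios.
- **xQTL**: two TSVs — probe annotation
  (`probe_id gene chrom probe_pos paradigm`) and per-SNP effects
  (`probe_id snp chrom pos a1 a2 freq beta se p`). A documented flat-text
  stand-in for binary xQTL stores.
- **LD panel**: dosage TSV — five metadata rows (`snp/chrom/pos/a1/a2`),
  then one row of `[0,2]` dosages per reference individual.
- **Gene sets**: standard GMT. **Outputs**: TSV throughout; the fixture
  generator also writes a `truth.json` manifest (scenario per probe,
  planted set, planted shared gene, seed).

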