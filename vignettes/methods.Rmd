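---
title: "Models and methods behind xwasmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind xwasmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xwasmr)
```

`xwasmr` asks, for each molecular probe (a transcript, protein or CpG site),
whether its level mediates genetic risk for a trait, using only summary
statistics: per-SNP effects from a GWAS of the trait and from a cis-xQTL
study of the probe, plus a reference genotype panel for linkage
disequilibrium (LD). This vignette records the models, the parameter
choices, the numerical decisions, and what the synthetic-data validation
does and does not establish.

## The per-probe causal test

For the top cis instrument (the SNP with smallest xQTL p-value, required to
pass $p < 5\times10^{-8}$ within 2 Mb of the probe), the Wald ratio

$$\hat b_{xy} = \hat b_{zy} / \hat b_{zx}$$

estimates the effect of the molecular level on the trait, with the
first-order delta-method standard error
$\mathrm{se}_{xy} = |\hat b_{xy}|\sqrt{\mathrm{se}_{zy}^2/\hat b_{zy}^2 +
\mathrm{se}_{zx}^2/\hat b_{zx}^2}$. The test statistic

$$T_{\mathrm{SMR}} = \frac{z_{zx}^2 z_{zy}^2}{z_{zx}^2 + z_{zy}^2}$$

is compared to a 1-df chi-square upper tail. It is symmetric in the two
z-scores and bounded by the weaker of the two associations, so a probe can
never be declared causal on the strength of only one side.

A small SMR p is consistent with causality or pleiotropy, but also with
*linkage*: two distinct causal variants, one for the molecular level and
one for the trait, in LD with each other. The HEIDI test discriminates
these by checking whether the Wald ratios at multiple LD-linked instruments
are homogeneous. For instruments $i$ in moderate LD with the top SNP
(xQTL $p < 1.57\times10^{-3}$, $0.05 \le r^2 \le 0.9$, between 3 and 20 of
them), the differences $d_i = \hat b_i - \hat b_{\mathrm{top}}$ have a
delta-method covariance assembled from the two sets of standard errors and
the reference-panel LD correlations (the GWAS and xQTL cohorts are treated
as non-overlapping, so there is no cross-cohort covariance term — the
standard two-sample design). The statistic $\sum_i d_i^2/\mathrm{Var}(d_i)$
is distributed under the single-variant null as a weighted sum of 1-df
chi-squares with weights the eigenvalues of the correlation matrix of $d$.

**Tail evaluation.** The weighted-chi-square tail is evaluated by a
Lugannani–Rice saddlepoint approximation by default. We initially used
Satterthwaite two-moment matching, but against a $10^6$-draw Monte-Carlo
oracle it proved anti-conservative by up to a factor of five at
$p \sim 10^{-3}$ on realistic eigenvalue spectra, which distorts exactly
the p-values the HEIDI penalty (below) cares about. The saddlepoint stays
within a factor ~1.2 of the oracle across the spectra we generate, is
deterministic, and needs no integration tuning; when all eigenvalues are
(near-)equal it hands over to the exact chi-square tail, and a
Monte-Carlo route (fixed private seed) remains available via
`smr_config(heidi_tail = )`.

**Harmonization.** All effects are re-oriented to the xQTL effect allele;
swapped alleles flip the effect sign and frequency. Strand-ambiguous (A/T,
C/G) SNPs are dropped unconditionally — frequency-based resolution is
unreliable near MAF 0.5. SNPs whose allele frequency disagrees by more than
15 percentage points between any two sources, SNPs absent from any source,
and monomorphic panel SNPs are dropped, each under a named counter that the
pipeline writes to its run log. Multi-allelic records (duplicate SNP ids)
are rejected at parse time rather than guessed at. Coordinates are 1-based;
all inputs are assumed on one genome build.

## From probes to genes

Rather than discarding probes with HEIDI $p < 0.01$, the SMR p-value is
*penalized*:

$$p'_{\mathrm{SMR}} = \min\!\left(1,\;
  \frac{p_{\mathrm{SMR}}}{\min(p_{\mathrm{HEIDI}}/0.01,\,1)}\right).$$

The penalty is the identity when HEIDI shows no heterogeneity
($p_{\mathrm{HEIDI}} \ge 0.01$) and grows smoothly as heterogeneity
evidence accumulates. A hard filter would silently delete genuine signals
whose HEIDI p is deflated by LD-reference mismatch; the soft penalty keeps
them visible, merely demoted. Two boundary conventions are ours: the
quotient is capped at 1 (the raw formula can exceed it), and a probe whose
HEIDI test never ran (fewer than 3 admissible instruments) is not
penalized, with `nsnp_heidi = NA` kept in the record so users can filter.

Probe-level adjusted p-values are combined per gene by the Cauchy (ACAT)
rule $T = \sum_i w_i \tan((0.5-p_i)\pi)$ with equal weights, whose null
distribution is standard Cauchy *regardless of dependence* between probes —
exactly what correlated cis probes require. Tiny inputs use the tail
expansion $w_i/(p_i \pi)$ and the result is floored at $10^{-300}$, so no
underflow can produce a zero p-value. Probes not mapped to a gene symbol
are dropped before combination.

Two significance flags are attached per study: *suggestive*, $p < 1/m$
(crossed once per scan by chance), and *Bonferroni*, $p < 0.05/m$. Both
phrasings of $m$ (probes tested vs genes mapped) are defensible; the
gene-level table uses the number of mapped genes and records both counts in
its header so either convention can be reconstructed.

## Multi-study concordance

Gene-level p-values from $J$ studies (trait × tissue × paradigm) are
analyzed jointly. Statistics $t = -2\ln p$ are chi-square with 2 df under
the null; alternatives are modeled as a scaled chi-square with per-study
scale $a_j$ estimated as the mean of the top $\lceil \alpha G\rceil$
statistics divided by 2 (floored just above 1), where $\alpha$ is the prior
alternative proportion `alt_props`. Each gene carries a posterior over all
$2^J$ binary association patterns, fit by EM on the pattern weights
$\pi_k$; conditional on the pattern, studies are treated as independent.
Between-study correlation from sample overlap is *not* modeled — a known
limitation; the validation simulations generate independent studies, so
they cannot detect miscalibration caused by overlap in real data.

The marginal posterior probability $PP_{ij}$ that gene $i$ is associated in
study $j$ sums the posterior over patterns with a 1 in position $j$; calls
use $PP > 0.95$. The default `alt_props` is $10^{-3}$, a deliberately
sparse prior appropriate for real scans where only a small fraction of
genes carry signal; because calls grow with `alt_props`,
`sweep_alt_props()` exposes the sensitivity explicitly rather than hiding
the choice. For *parameter-recovery* validation the fitting prior is set to
the generator's true marginal alternative fraction: with the recovery
generator's ~6% alternative fraction per study, fitting at $10^{-3}$
mis-estimates the alternative scale (the top-20 tail mean lands near 50
when the truth is 10) and the weight error triples; that is a
misspecification phenomenon, not a defect of the EM, and conflating the
two would make the recovery check meaningless. Everything runs in log
space with log-sum-exp; the EM is deterministic, initialized at 0.9 mass
on the all-null pattern, converged when $\max_k |\Delta\pi_k| < 10^{-6}$,
and its observed-data log-likelihood is asserted non-decreasing in tests.

## Gene-set enrichment

Suggestive gene lists are tested for over-representation in gene sets by
the upper-tail hypergeometric probability against a universe of 54,619
coding and non-coding genes by default (configurable, or an explicit gene
list). Genes in the MHC region — chromosome 6, 25–35 Mb, where extreme LD
makes gene attribution meaningless — are excised first; the interval is
half-open $[25\,\mathrm{Mb}, 35\,\mathrm{Mb})$ for a deterministic
boundary. Benjamini–Hochberg adjustment across sets yields q-values,
thresholded at $q < 0.05$.

## The synthetic-data generator

Validation needs inputs whose truth is known. Haplotypes are thresholded
AR(1) latent Gaussians: adjacent SNPs have latent correlation `ld_rho`
(default 0.8) and MAFs drawn uniformly on [0.1, 0.5], so the true dosage
correlation is available in closed form via the Gaussian-copula rectangle
probability — no external reference data needed, and the empirical panel
LD can be tested against an analytic target. Phenotypes are standardized,
so effects are per-SD units. Four scenarios per region: *causal*
($y = b_{xy} x + e$, one shared variant, default $b_{xy} = 0.3$,
$b_{zx} = 0.5$), *pleiotropy* (plus a direct variant-on-trait effect),
*linkage* (distinct causal variants for $x$ and $y$ at dosage LD ~0.6) and
*null*. Default sample sizes — 30,000 for the xQTL study, 100,000 for the
GWAS, 500 reference individuals — match the scale of modern blood eQTL
meta-analyses and psychiatric GWAS, and make the top instrument essentially
always genome-wide significant, as it is for strong cis-eQTLs.

Summary statistics are drawn two ways. The *fast path* samples marginal
estimates directly from their large-sample distribution
$\hat\beta \sim N(R\beta,\, R/n)$; the *slow path* simulates individuals
and runs per-SNP least squares. The slow path is the oracle: the two are
required to agree in distribution, and every large simulation uses the
fast path. Allele orientations are randomly scrambled between sources so
harmonization is exercised on every run, and all seeds derive from one
master seed by a counter scheme, making every artifact byte-reproducible.

What the generator does *not* emulate: realistic human LD maps, imputation
noise, population stratification, case-control ascertainment, or overlap
between cohorts. Green validation therefore demonstrates internal
statistical correctness — calibration, power, recovery, FDR control under
the stated models — not robustness to those real-data complications.

## Validation protocol and problem sizes

The acceptance checks run at these sizes, chosen to pin down each rate
while keeping a full run in minutes on one CPU: 2,000 null regions for SMR
type-I error (rejection at $\alpha=0.05$ expected in [0.035, 0.065]); 500
causal regions for median-effect recovery (±10%) and 95% CI coverage
([0.92, 0.98]); 500 regions each for HEIDI level (≤ 0.03 at $\alpha=0.01$
under causality) and power (≥ 0.5 under linkage); 20 random AR(1)
eigenvalue spectra against a $10^6$-draw tail oracle (factor 1.5); $10^4$
adjustment-grid points; $10^4$ Cauchy combinations for the uniformity KS
test; $G = 2\times10^4$, $J = 3$ for concordance recovery (weights within
±0.02, call precision ≥ 0.90); 100 null enrichment scans for FDR control;
and a 200-probe, 3-study end-to-end bundle with one planted shared gene
(recovered at $PP > 0.95$ everywhere) and one planted gene set (recovered
at $q < 0.05$), byte-identical across reruns.

```{r example, eval = FALSE}
# a single causal region, end to end
sp <- scenario_spec("causal", seed = 42)
r <- simulate_summary_region(sp)
run_probe(r$probe, r$gwas, r$xqtl, r$panel)
```

## Known limitations

Single-SNP instruments only (no multi-SNP SMR extension); cis analysis
only; no colocalization method beyond HEIDI; no modeling of study overlap
in the concordance step; the alternative-scale estimator is biased upward
by extreme null order statistics when `alt_props` understates the true
alternative fraction; and binary-format references (PLINK bed, binary xQTL
stores) are out of scope — all interchange is documented flat text.
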