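---
title: "Cross-ancestry mQTL sharing: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-ancestry mQTL sharing: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: the models and their assumptions, the parameters that matter
(with units and defaults), what the synthetic-data generator does and does
not emulate, and the design decisions taken where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The scientific question

DNA methylation at a CpG probe is a quantitative molecular trait with
unusually large *cis* genetic effects, which makes it a tractable model
system for asking how much of the genetic control of complex traits is
shared between ancestries. Given per-cohort *cis*-mQTL summary statistics
from two ancestry groups, the pipeline answers three questions: (i) are
the same loci associated in both groups, and when lead SNPs differ, is
that a different causal variant or merely different tagging under
different LD? (ii) how correlated are the underlying effect sizes once
estimation noise is removed? (iii) what does a second ancestry buy for
fine-mapping resolution and for detecting ancestry-specific
trait-methylation pleiotropy?

## Association model

Methylation is pre-corrected per probe by fixed-effects least squares on
sex, age, age², cell proportions and batch indicators, then
rank-inverse-normal transformed (Blom offset `c = 3/8`, i.e.
`qnorm((rank − 3/8)/(n + 1/4))`, average ranks for ties). The scan is
per-SNP simple OLS with intercept, t-based two-sided p-values (n − 2 df);
missing dosages are mean-imputed per SNP. Within ancestry, cohorts are
pooled by fixed-effects IVW meta-analysis with normal-approximation
p-values.

Two thresholds recur everywhere and are config entries, never constants
in stage code: the stringent significance level `p_sig = 1e-10` (a 0.05
Bonferroni bound for ~probes × ~2000 independent SNPs per 2 Mb window)
and the replication level `p_rep = 1e-6`.

Design choices here:

* *Fixed batch columns instead of a mixed model.* Real protocols fit
  random slide/row effects; with balanced synthetic batches the BLUP and
  fixed-effect residuals agree to numerical noise, and the fixed-effects
  route keeps the stage dependency-free. Divergence documented, not
  hidden: residuals are asserted orthogonal to every retained design
  column at 1e-8.
* *Plain OLS, unrelated individuals.* Family cohorts (sparse-GRM mixed
  models) are out of scope; the simulator only emits unrelated samples.
* *Exact (enumeration) Hardy–Weinberg test* rather than chi-square —
  robust at low counts; the QC order of precedence is missingness, info
  score, HWE, MAF, each SNP logged with its first failing reason.

## Effect-size correlation r_b

The Pearson correlation of estimated lead-SNP effects is attenuated by
sampling error. The method-of-moments estimator used here subtracts the
mean squared standard error from each observed effect variance:

    r_b = cov(b1, b2) / sqrt((var(b1) − mean(se1²)) (var(b2) − mean(se2²)))

with zero covariance correction because the datasets are
sample-independent, and a delete-one jackknife SE. Two guardrails: if a
corrected variance goes non-positive the estimator refuses ("effects
indistinguishable from noise"); if the correction overshoots |r_b| > 1
(noise-free degenerate inputs) the estimate is clipped to ±1 with a
warning. Lead SNPs are ascertained **only** in the discovery dataset —
ascertaining on the joint minimum p would bias r_b upward.

## Sharing hierarchy and heterogeneity

Stringent-set probes (both ancestries p < 1e-10 at their own lead) are
classified top-down, first rule wins: same lead + same harmonized sign;
lead–lead r² > 0.8 in *either* reference panel; LD-block overlap (blocks =
SNPs at r² > 0.8 with the lead, each built in its own ancestry panel);
lead of one ancestry among the other's conditionally independent signals;
block overlap with such a signal; else unexplained. Choices:

* Same-lead pairs with *opposite* signs fall through to the LD rules
  rather than being declared shared — they can still be rescued by LD
  evidence, and a sign flip at the same SNP is not by itself evidence of
  sharing.
* Block-overlap uses the either-panel (OR) rule; the block search radius
  is the probe's cis window (no separate radius is defined anywhere
  else).
* Ancestry-specific probes are dropped from the specific sets (flag kept)
  when they share the lead SNP across ancestries or are stringently
  significant in an individual cohort of the alternate ancestry — both
  indicate a power artefact, not specificity. The exclusions are applied
  *before* reporting set sizes, and both pre- and post-exclusion counts
  are logged.
* AF heterogeneity: the lead's minor AF in the alternate panel, flagged
  rare below 0.01; lead–lead LD bucketed at r² 0.2/0.8, "incalculable"
  when the lead is monomorphic or absent in the alternate-ancestry panel.

## Conditional analysis

Standardized z-score COJO: `z_cond(t|C) = (z_t − R_tC R_CC⁻¹ z_C) /
√(1 − R_tC R_CC⁻¹ R_Ct)` with a 1e-6 ridge on `R_CC`, targets skipped as
collinear when the conditional variance drops below 1e-4. Stepwise
selection starts at the lead SNP, adds the smallest conditional p while it
stays below 1e-10 and reference r² with the selected set stays below 0.9;
ties break by SNP id, making the procedure invariant to input order. The
full allele-frequency/variance bookkeeping of genotype-based COJO
implementations collapses to this form when per-SNP n is constant, which
holds for the synthetic cohorts. Conditioning is restricted to the cis
window: the 10 Mb LD window of the real protocol cannot bind when no
tested SNP lies outside ±1 Mb. A warning fires when the reference panel
has fewer than 20× the selected-set size samples.

## Fine mapping

The number of causal signals is fixed at one, so the sum-of-single-effects
machinery collapses exactly to Wakefield approximate Bayes factors:

    log ABF = ½ log(se²/(se² + W)) + z² W / (2 (se² + W))

Per SNP, BFs are averaged over a prior effect-variance grid
`W ∈ {0.01, 0.05, 0.1, 0.2, 0.4}` (standardized-phenotype scale) — grid
averaging avoids a per-locus optimization and is standard practice — and
normalized to PIPs under a uniform causal prior over the window. The 95%
credible set is the smallest descending-PIP prefix reaching 0.95, exact
PIP ties broken by genomic position. Cross-ancestry mapping multiplies
per-population grid-averaged BFs (independent samples, shared causal
position, population-specific effect sizes); a SNP absent in one
population contributes BF = 1 there. Probes sharing a lead SNP are
deduplicated to the smallest-p probe before mapping, and a BED region
mask (e.g. MHC) is supported. Oversized sets are excluded when the size
exceeds mean + 3·IQR within a mode (strict inequality, so a zero IQR
keeps sizes equal to the mean); "size" here is credible-set size since
the signal count is pinned to one — the alternative reading (signal
count) is degenerate under this model.

The sample-size experiment simulates, for each n in an ascending grid, a
fresh cohort and one phenotype per probe with the probe's causal SNP as
causal, scans, fine-maps, and records set sizes; with `n_eas > 0` it adds
an EAS cohort at each grid point and computes cross-ancestry sets,
quantifying whether diversity beats raw sample size. Sizes below 50 are
refused (sets are meaningless at that power).

## SMR and HEIDI

`T_SMR = z_zx² z_zy²/(z_zx² + z_zy²) ~ χ²₁`; `b_xy = b_zy/b_zx` with
delta-method SE; instruments with `z_zx² < 10` draw a weak-instrument
warning. HEIDI tests whether `b_xy` is constant across SNPs in LD with
the instrument (r² in (0.05, 0.9), exposure p < 1.57e-3, at most 20
SNPs — SMR-software conventions, all exposed in the config): deviations
`d_i = b_xy(i) − b_xy(top)` get a delta-method covariance with cross-SNP
correlation from the reference panel, and the correlated chi-square sum
is referred to a Satterthwaite two-moment approximation — chosen over an
eigen-decomposition of the covariance for simplicity; the calibration
tests bound its type-I error at the 0.01 level by 0.03. The SMR
significance default is `p_smr < 1e-7` (Bonferroni for the probe count);
`1e-6` is available as the alternative preset since both conventions
circulate. Ancestry-specific probes are excluded from SMR when the
alternate ancestry's GWAS has any `p < 5e-8` SNP inside the probe's cis
window, so surviving pleiotropic signals are genuinely ancestry-specific.
When fewer than three eligible SNPs remain, HEIDI returns NA with a
reason and the SMR call stands unfiltered.

## The synthetic world

The generator emulates exactly the features the pipeline must be
sensitive to, with these defaults:

| parameter | default | meaning |
|---|---|---|
| `fst` | 0.1 | Balding–Nichols divergence; EUR–EAS genome-wide F_ST is ~0.1 |
| `ancestral_af_range` | (0.05, 0.95) | uniform ancestral AFs, common-variant regime |
| `rho_eur`, `rho_eas` | 0.9 | latent AR(1) LD within 10-SNP blocks |
| `eas_block_shift` | 5 | EAS block boundaries rotated half a block — creates ancestry-specific tagging |
| `rho_b` | 0.9 | cross-population causal-effect correlation |
| `prop_private` | 0.2 | probes with an effect in one population only |
| `b_sd` | 0.5 | causal effect SD, phenotype-SD units per allele (the large-effect mQTL regime) |
| cis window | 1 Mb real scale; 12–25 kb on the compressed synthetic chromosome (1 kb SNP spacing) |

Haplotypes are thresholded latent AR(1) Gaussians: marginal AFs are exact,
but **thresholding attenuates LD** — latent rho 0.9 yields adjacent
genotype r² ≈ 0.51 (the tests verify this against a numeric-integration
oracle), and rho 0.99 ≈ 0.85. LD-block tests are calibrated to realized,
not latent, correlation. Not emulated: coalescent genealogies,
recombination-map structure, imputation uncertainty (the info score is a
column set to 1.0, only exercised by QC), relatedness, and probe-level
array artefacts. A green suite therefore establishes the statistical
machinery — calibration, recovery, ordering of methods — not realism of
any particular locus.

Two scenario choices in the acceptance suite were made once, on
realism grounds, and not revisited: the two-causal conditional-analysis
scenario draws causal SNPs at panel MAF ≥ 0.1 (a MAF ~0.01 causal SNP
cannot reach p < 1e-10 at n = 2000 — a power fact that the real protocol
avoids by AF filtering); the HEIDI linkage scenario uses a trait effect
of 0.3 per allele so the outcome association is genome-wide significant,
the only regime in which SMR is actually invoked.

## Numerical details

* PIP normalization uses log-sum-exp; sums asserted to 1 ± 1e-8.
* HWE: probabilities normalized in log space; two-sided tail includes
  configurations with probability ≤ observed + 1e-12 (float guard).
* IVW meta of a partition equals meta of the whole (tested).
* Lead-SNP tie-break cascade: min p → max |z| → min distance to probe →
  min position; fully deterministic.
* Strand-ambiguous SNPs (A/T, C/G) are resolved by allele frequency only
  when reference MAF < 0.4, else dropped.
* The pipeline config is a JSON document (no YAML parser in the
  dependency budget); outputs embed the seed and an FNV-1a config hash,
  and identical config + seed reproduces outputs byte-for-byte.

## Known limitations

Single-causal fine mapping by construction (no multi-signal credible
sets); no sample-overlap correction in r_b (cohorts assumed disjoint); no
trans-QTLs; family data unsupported; EAS conditional analysis is
implemented but the default configuration runs conditional selection for
EUR only, mirroring the reference-panel-size asymmetry of real data.
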