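# mqtlshare

Tools for asking how much of the genetic control of DNA methylation is
shared between ancestries, using only cohort-level *cis*-mQTL summary
statistics plus reference-panel LD — and for quantifying what
cross-ancestry data buys in fine-mapping resolution.

The package is aimed at statistical geneticists working with methylation
QTL (mQTL) studies across populations (e.g. European and East Asian
cohorts). Everything runs on a bundled two-population simulator with known
ground truth, so the full pipeline is testable on a laptop without any
genotype downloads.

## What it implements

For each cohort, methylation values are residualized on covariates (sex,
age, age², cell proportions, batch), rank-inverse-normal transformed, and
regressed on every SNP within ±1 Mb of the probe (simple OLS per SNP).
Cohort results are combined within ancestry by fixed-effects
inverse-variance-weighted (IVW) meta-analysis:

    w_i = 1/se_i²,  b_meta = Σ w_i b_i / Σ w_i,  se_meta = (Σ w_i)^(-1/2)

Downstream stages, all from summary statistics + a reference panel:

- **r_b** — the correlation of *true* effect sizes between two datasets,
  de-attenuated by subtracting sampling-error variance:
  `r_b = cov(b1,b2) / √[(var(b1) − mean(se1²))(var(b2) − mean(se2²))]`,
  with delete-one jackknife standard errors. Lead SNPs are always
  ascertained in the discovery dataset only.
- **Sharing classification** — probes significant at p < 1e-10 in both
  ancestries are classified hierarchically: same lead SNP (matching
  direction) → lead SNPs in strong LD (r² > 0.8 in either panel) →
  overlapping LD blocks → EAS lead among EUR conditionally independent
  signals → block overlap with a conditional signal → unexplained.
  Ancestry-specific sets (p < 1e-10 in one ancestry, p > 1e-6 in the
  other) get allele-frequency-heterogeneity summaries (rare in the
  alternate ancestry: MAF < 0.01; lead–lead LD buckets at r² 0.2/0.8).
- **COJO** — stepwise approximate conditional analysis from z-scores and a
  reference LD correlation matrix, conditional p < 1e-10, collinearity cap
  r² < 0.9.
- **Fine mapping** — single-causal-variant Wakefield approximate Bayes
  factors, `log ABF = ½ log(se²/(se²+W)) + z²W/(2(se²+W))`, averaged over
  a prior-variance grid; PIPs normalized over the cis window; 95% credible
  sets; cross-ancestry mapping multiplies per-population Bayes factors
  under a shared causal position with population-specific effects. A
  sample-size experiment quantifies credible-set shrinkage from extra
  same-ancestry samples versus an extra ancestry.
- **SMR + HEIDI** — `T_SMR = z_zx² z_zy² / (z_zx² + z_zy²) ~ χ²₁` tests
  whether a SNP's trait effect is mediated by methylation
  (`b_xy = b_zy/b_zx`); HEIDI compares `b_xy` across LD-linked SNPs to
  separate a single shared causal variant from linkage.
- **Simulator** — Balding–Nichols allele-frequency divergence
  (`f_pop ~ Beta(f(1−F)/F, (1−f)(1−F)/F)`), LD from thresholded latent
  AR(1) Gaussian haplotypes with population-rotated block boundaries,
  causal effect pairs bivariate normal with correlation `rho_b`, and
  optionally population-private effects.

## Worked example

```r
library(mqtlshare)
cfg <- default_config(outdir = tempfile("demo_"), seed = 1L)
cfg$cohorts <- data.frame(name = c("eur1", "eur2", "eas1"),
                          pop = c("EUR", "EUR", "EAS"),
                          n = c(350L, 350L, 350L))
cfg$sim$n_probes <- 100L; cfg$sim$n_snps <- 400L
cfg$sim$rho_eur <- 0.95; cfg$sim$rho_eas <- 0.95; cfg$sim$fst <- 0.15
res <- run_pipeline(cfg)
table(res$sets$label)
res$rb[1:3, 1:5]
res$finemap[, .(mean_size = round(mean(size), 2)), by = mode]
```

prints (seed 1):

```
EAS_SPECIFIC EUR_SPECIFIC        OTHER    STRINGENT
           1           12           75           12

   discovery replication        rb          se n_pairs
1:      eur1        eur2 0.9980018 0.005486242      33
2:      eur1        eas1 0.9115895 0.031545555      33
3:      eur2        eur1 1.0000000 0.003336319      32

     mode mean_size
1:    EUR         1
2:    EAS         1
3:  CROSS         1
```

Reading this: 12 probes are stringently significant in both ancestries
(all of them classified `SAME_LEAD_SAME_DIRECTION` at this small scale —
with n = 700 per ancestry and strong simulated effects, both ancestries'
scans land on the causal SNP itself); 13 probes are ancestry-specific,
dominated by EUR because two of the three cohorts are European.
Within-ancestry effect-size correlation is ~1.00 while the cross-ancestry
estimate (~0.91) reflects the simulated `rho_b = 0.9`, despite per-lead
noise — the naive Pearson correlation would sit well below it. Credible
sets collapse to a single SNP at this power; the cross-ancestry gain is
visible at larger window/LD settings (see the vignette and
`sample_size_experiment()`).

## Command line

`mqtl_cli()` exposes verbs (`simulate`, `qc`, `scan`, `meta`, `rb`,
`classify`, `cojo`, `finemap`, `all`) plus `--config <json>`,
`--seed <int>`, `--out <dir>`; every output file records the seed and a
config hash, and identical configs yield byte-identical outputs.
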