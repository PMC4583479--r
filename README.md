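# finemapsim

Simulation-based evaluation of Bayesian GWAS fine-mapping for
statistical geneticists: how reliably do approximate-Bayes-factor (ABF)
credible sets localize the causal variant at a case-control association
locus, and how does that reliability degrade under real study designs —
array genotyping with imputation and QC, per-cohort genotype failure,
trans-ethnic meta-analysis, functional priors, and multiple causal
variants?

## The method being evaluated

For each variant at a locus, with estimated log odds ratio `beta`,
standard error `sqrt(V)` and `Z = beta/sqrt(V)`, the Wakefield
approximate Bayes factor for association is

    log ABF = 0.5 * log(1 - r) + Z^2 * r / 2,      r = W / (V + W)

(the normal–normal marginal likelihood ratio; `W` is the prior variance
of the log odds ratio under association, default 0.04 — a 95% belief
that the relative risk is below 1.5). Under a single-causal-variant
assumption the posterior for variant `j` is `w_j ABF_j / sum_k w_k ABF_k`
with optional prior weights `w`, and the **95% (99%) credible set** is
the smallest posterior-sorted set of variants holding 95% (99%) of the
mass. The package evaluates these sets — coverage of the causal variant,
set sizes, success rate (fewer than 10 variants) — against `r^2`-threshold
comparator sets, across a grid of risk-allele frequencies and odds
ratios, by simulating the entire pipeline:

1. synthetic phased haplotype panels with human-like LD block structure
   (one or two populations diverged by Balding–Nichols drift);
2. ten case-control cohorts of 1,000/1,000 resampled from the panel
   under an additive disease model (prevalence 0.55%);
3. per-variant additive logistic regression and fixed-effects
   inverse-variance meta-analysis;
4. optionally: array downsampling, panel-based imputation with INFO
   scores, and the `INFO > 0.4`, `MAF >= 1%` filters;
5. ABF fine-mapping and scoring.

Everything is seeded and deterministic; see the methods vignette
(`vignettes/finemapping-evaluation.Rmd`) for the models, parameter
choices and limitations.

## A worked example

```r
library(finemapsim)
cfg <- grid_config(replicates = 20, raf_levels = 0.1, or_levels = 1.2,
                   scenarios = c("gold", "gwas"),
                   panel = list(target_density = 500),
                   array_density_per_mb = 140, seed = 1)
res <- run_grid(cfg)
res$summary[, c("raf", "or", "scenario", "coverage95", "median_size95",
                "p90_size95", "rank1_rate", "power")]
```

which prints

```
  raf  or scenario coverage95 median_size95 p90_size95 rank1_rate power
1 0.1 1.2     gold          1             5         12       0.30 0.586
2 0.1 1.2     gwas          1             5         12       0.65 0.586
```

Read: at risk-allele frequency 10% and odds ratio 1.2 (58.6% analytic
power at genome-wide significance for the 10,000-case meta-analysis),
the 95% credible sets contained the causal variant in all 20 replicate
regions, with a median set of 5 variants and a 90th centile of 12, both
on full sequence data ("gold") and after array downsampling, imputation
and QC ("gwas"). Rates at 20 replicates carry Monte-Carlo noise of
roughly ±10 percentage points (the rank-1 rates here differ only by
chance); the calibration runs below use 100 replicates per setting and a
full RAF × OR grid.

Published summary statistics (tab-delimited `SNPID CHR POS EA NEA EAF
BETA SE Z N_EFF N_STUDIES`) can be fine-mapped directly:

```r
fm <- finemap_summary_file("locus_stats.tsv", W = 0.04)
head(fm$table)       # per-variant posterior, cumulative, in_95/in_99
```

A thin command-line wrapper with `simulate-panel`, `run-grid` and
`finemap-summary` subcommands is installed at `inst/cli/finemapsim`.

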