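---
title: "Evaluating Bayesian fine-mapping by simulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating Bayesian fine-mapping by simulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question

A genome-wide association signal rarely identifies its causal variant:
linkage disequilibrium (LD) spreads the association over tens to hundreds of
correlated variants. One widely used refinement is the approximate-Bayes-
factor (ABF) credible set: convert each variant's association summary
statistic into a Bayes factor for association, normalize across the locus
under a single-causal-variant assumption, and report the smallest set of
variants holding 95% (or 99%) of the posterior mass. `finemapsim` measures,
by simulation, how well that procedure localizes causal variants in
case-control studies — its coverage (does the set contain the causal
variant at the advertised rate?), its resolution (how small are the sets?),
and how both degrade under realistic study designs: array genotyping with
imputation, genotype failure, trans-ethnic meta-analysis, functional
priors, and multiple causal variants.

# The statistical core

For a variant with estimated log odds ratio $\hat\beta$ and standard error
$\sqrt{V}$, the Wakefield approximate Bayes factor compares the marginal
likelihood of $\hat\beta$ under association (prior $\beta \sim N(0, W)$)
with the null:

$$\log \mathrm{ABF} = \tfrac12\log(1-r) + \tfrac{Z^2 r}{2},
\qquad r = \frac{W}{V+W},\ Z = \hat\beta/\sqrt{V}.$$

This is exactly $\log\left[N(\hat\beta; 0, V+W)/N(\hat\beta; 0,
V)\right]$, and the implementation is tested against that density ratio to
$10^{-10}$ relative error. The orientation is association-positive: larger
means more evidence for association. Posteriors are
$w_j\,\mathrm{ABF}_j/\sum_k w_k\,\mathrm{ABF}_k$ with optional prior
weights $w_j$ (e.g. 10 on coding variants), computed by log-sum-exp so
$|Z|$ up to several hundred cannot underflow. Credible sets are the
smallest posterior-sorted prefix reaching the level, with ties broken by
descending $|Z|$ then ascending position.

The prior variance default is $W = 0.04$: a prior standard deviation of
$0.2$ on the log odds ratio encodes a 95% belief that the relative risk
under association is below 1.5 ($\log(1.5)/1.96 \approx 0.207$). Some
descriptions of this calibration print $W = 0.4$; that value is
inconsistent with the stated belief statement, but it is one configuration
key away (`W = 0.4`) for anyone wishing to reproduce it.

Variants with missing genotype data in some cohorts are put on a common
footing before ABF computation by rescaling variance to the maximum
observed effective sample size, $V' = V \cdot n_{\mathrm{eff}}/n_{\max}$
with $n_{\mathrm{eff}} = 4/(1/n_{\mathrm{case}} + 1/n_{\mathrm{ctrl}})$;
variants observed at less than 70% of $n_{\max}$ are excluded from the
posterior normalization rather than rescaled (configurable via
`min_fraction`).

# The synthetic haplotype panel

Real evaluations of this kind resample reference haplotypes (e.g. 1000
Genomes CEU/YRI). `finemapsim` instead *generates* panels with a blockwise
haplotype model chosen for desk-scale speed and direct control over LD:

* the region (1 Mb by default) is cut into blocks with exponential lengths
  (mean `block_length_mean`, default 40 kb);
* each block carries `haplotypes_per_block` (default 12) block-haplotypes.
  The first block's frequencies are a symmetric Dirichlet draw
  (`dirichlet_alpha = 0.65`) and subsequent blocks follow a Dirichlet
  random walk (`block_freq_drift = 45`), so the haplotype composition
  changes gradually along the region as real genealogies do;
* each panel haplotype follows a Markov chain across blocks: its
  block-haplotype choice is retained across a boundary with probability
  `inter_block_correlation` (default 0.85), else redrawn. The chain is
  implemented by quantile coupling — a shared latent uniform retained
  across boundaries — so the marginal distribution in every block is exact,
  and fresh uniforms are drawn stratified, so realized haplotype counts
  track the model frequencies with sub-binomial noise;
* variant alleles are carried by *clades* of a single random binary
  genealogy over the block-haplotype labels, the carrier structure that a
  mutation on a haplotype tree produces. Target minor-allele frequencies
  are drawn from a density $\propto 1/p$ on $[0.01, 0.5]$ (the common
  variant spectrum, truncated at 1% because downstream QC discards rarer
  variants), and each variant adopts the clade whose frequency best matches
  its target, with near-ties randomized.

The clade restriction matters. A first implementation allowed arbitrary
label subsets as carrier sets; the resulting patterns were so diverse that
a third of untyped common variants could not be linearly predicted from
array variants — unlike real human data, where most common variants have
near-perfect proxies (which is why array-plus-imputation designs work at
all). With clade-carried alleles on a slowly drifting composition, the panel
reproduces the empirical signatures the simulation depends on: at 28%
array density, most common variants are well imputable (about 8% of
MAF ~5% variants and 5% of MAF ~10% variants fall below the INFO 0.4 QC
threshold, against roughly 2-5% for real dense arrays), the folded
frequency spectrum is bottom-heavy, and mean $r^2$ between common
variants is ~0.26 at 50 kb and ~0.07 at 200 kb. These input-side
statistics — not any downstream performance number — are what the
defaults were calibrated against. The remaining known gap to real data
is the array model itself: a random MAF-weighted subset rather than a
designed tagging array, so a few percent of low-frequency variants
(including, occasionally, a simulated causal variant) remain untagged
and are removed by QC slightly more often than in a real pipeline.

The second population (`derive_diverged_panel`) redraws each block's
frequency vector from a Dirichlet with concentration $(1-F)/F$ times the
source frequencies — the Balding–Nichols model, giving
$\mathrm{Var}(p'-p) = F\,p(1-p)$ exactly at the block level (tested by
simulation) — and subdivides blocks by `recomb_scale` (default 2) to
shorten LD, emulating the reduced LD of African-ancestry panels. The
defaults $F = 0.15$ and `recomb_scale = 2` are conventions for a
EUR-vs-AFR-like contrast; no quantitative CEU/YRI target was available, so
both are exposed in the configuration. Every source variant remains in the
derived panel, possibly near-monomorphic — exactly the situation that
makes trans-ethnic fine-mapping informative (and occasionally harmful,
when the risk allele is rare in the second population).

Coordinates are 0-based internally and 1-based in VCF output. Panels round
trip exactly through phased VCF (`write_panel_vcf`/`read_panel_vcf`);
unphased or multiallelic records are rejected with their position. A panel
read from VCF carries no generative block model, so it supports LD lookup
and fine-mapping but not cohort simulation.

# Disease model and cohort simulation

One or two causal variants receive allelic odds ratios; genotype
penetrances are $f_g = f_0\,\mathrm{OR}^g$ (multiplicative across loci on
the odds scale, i.e. log-additive), with $f_0$ solved in closed form from
the prevalence constraint $\sum_g P(g) f_g = K$ (default $K = 0.55\%$,
an ankylosing-spondylitis-like prevalence; the residual is checked to
$10^{-10}$). Cohorts are sampled retrospectively and genotype-first: a
case draws its causal genotype from $P(g\,|\,\mathrm{case}) \propto
P(g) f_g$, a control from $P(g\,|\,\mathrm{control}) \propto P(g)(1-f_g)$.
At $K = 0.55\%$, prevalence rejection sampling would need ~180 population
draws per case; genotype-first sampling is exact under the model and
cheap. Controls are unaffected individuals rather than population
samples — at sub-percent prevalence the difference is negligible, but it
is stated for reproducibility.

Given its causal genotype, an individual's two haplotypes are block
mosaics of panel haplotypes anchored at the causal variant's block (the
anchor is drawn from the panel haplotypes carrying the required allele)
and re-switched to a random panel haplotype at block boundaries at a rate
of one expected switch per 400 kb — the Li–Stephens rate of copying a
200-haplotype panel ($4 N_e r/H$ with $N_e = 10^4$, $r = 1.2\times
10^{-8}$ per bp). This preserves local LD while preventing cohort
individuals from being verbatim panel copies; a faster switch rate would
give study samples systematically shorter LD than the panel, which (unlike
in real cohorts imputed from a population-matched reference) would
artificially destroy imputability. With two
causal variants, the anchor carries both required alleles and the chain is
re-anchored at the second causal block in the (rare) event that switching
broke the required allele; the small LD distortion this causes between the
two causal blocks is accepted.

# Association, meta-analysis, imputation, QC

Per-variant association is maximum-likelihood additive logistic regression
(Newton–Raphson, tolerance $10^{-8}$, 25 iterations maximum), with Wald
$\hat\beta$ and standard error — Wald rather than score statistics
because the ABF consumes $\hat\beta$ and $V$; at these sample sizes the
difference is negligible. Hard-called variants are fitted on their 2x3
genotype-by-status table (the sufficient statistics); imputed variants are
fitted on per-individual expected dosages, with the iterations warm-started
from a fit on dosages aggregated to a 1/64 grid and finished exactly (the
fixed point of the exact iterations is the exact-data maximum likelihood
estimate; agreement with `stats::glm` is at the $10^{-10}$ level). Monomorphic and non-converged (separated) variants are flagged
and omitted, not reported as numbers. Ten cohorts of 1,000 cases and 1,000
controls are combined by fixed-effects inverse-variance meta-analysis; no
genomic control or heterogeneity statistics are applied.

The array ("GWAS") scenario restricts each cohort to an array mask drawn
at a target density with probability proportional to MAF (commercial
arrays favour common variants), and imputes the rest from the panel with a
deliberately simplified engine: for each untyped variant, a
ridge-regularized linear regression (k = 30 nearest typed variants, ridge
$10^{-4}$) of its panel alleles on the typed panel alleles, applied to
study dosages and clipped to $[0,2]$. The regression is fitted on panel
covariances shrunk by the mosaic decay factor $e^{-d/L}$ (L = the
simulator's switch scale), i.e. on the LD the study individuals actually
carry; fitting on raw panel LD would over-weight distant proxies and turn
the dosage-variance INFO into an inflated, dishonest accuracy measure. This replaces per-individual
hidden-Markov haplotype imputation — the largest methodological
substitution in the package: one regression per region instead of one HMM
per individual, with near-identical expected dosages for common variants.
INFO is the dosage-variance ratio $\mathrm{Var}(\hat d)/(2\hat p(1-\hat
p))$ (MaCH-style) rather than the IMPUTE measure; both are ~1 for
well-imputed and ~0 for uninformative variants, and only behaviour around
the 0.4 threshold matters here. QC retains variants with INFO strictly
above 0.4 and MAF at least 1%. The INFO filter is applied per study (a
study does not contribute a variant whose INFO in that study is at or
below threshold), and a variant leaves the region only when no study
retains it; in trans-ethnic runs each cohort is imputed from its own
population's panel and meta-analysis merges on variant id.

The "GWAS with failure" scenario additionally removes all genotypes of a
random 5% of array variants per cohort — the literal per-cohort procedure;
across 20 cohorts this yields roughly 5% missing samples for an affected
variant. (An alternative reading of the design — a ~0.25% per-variant
missingness budget across all samples — is expressible through
`failure_fraction`, but the literal procedure is the default.)

# Scoring and power

Each replicate is scored by: causal coverage of the 95%/99% sets; set
sizes (medians and 90th centiles by the nearest-rank convention, stated
because centile conventions differ); success (set smaller than 10
variants, strictly); the causal variant's rank by $|Z|$; the four-way
classification (causal singleton / causal in a set under 10 / small set
without causal / 10 or larger); and $r^2$-threshold comparator sets
(all variants with panel $r^2$ to the lead above 0.5, 0.8 or 0.9).
Replicates whose causal variant is removed by QC are counted as
not covered (conservative) and excluded from rank statistics; both
tallies are reported.

Analytic power uses the closed-form two-sample allele-frequency z-test at
$\alpha = 5\times10^{-8}$ (two-sided, genome-wide; the convention when no
level is stated): expected case allele frequency from the penetrance
model, control frequency at the population value, standard error under
the alternative. Control frequencies computed among unaffected individuals
are available as an option; the population-control convention reproduces
the reference 58.5% power at RAF 10%, OR 1.2, 10,000/10,000 almost
exactly, and is the default.

# The experiment grid

`run_grid` crosses RAF $\{0.05, 0.1, 0.2, 0.5\}$ with OR
$\{1.0, 1.1, 1.2, 1.5\}$ (1.0 is the null model) and runs replicate
regions with a fresh panel each (mirroring a design with many distinct
genomic regions; a shared-panel mode would be faster but is deliberately
not the default). Scenarios share the simulated cohorts within a
replicate, so gold vs array comparisons are paired. Every replicate's seed
derives deterministically from (master seed, setting, replicate); records
are written one file per setting and reruns over an existing output
directory skip completed replicates and reproduce the summary
byte-identically.

Problem sizes in the package's own test and acceptance runs: the coverage
grid uses panels of ~500 common variants per 1 Mb (the low end of the
500-1000 range appropriate for these calibration quantities, which are
density-robust) with 100 replicates per setting; the flat-posterior
analysis uses full-density panels (~3000 variants/Mb). Credible-set *size*
statistics scale with panel density — and in this substrate posterior
concentration saturates at high density because pattern capacity is
bounded by blocks x distinct clades — so size-scale experiments (the
functional-prior fold) are run at the density whose uniform-prior baseline
resolution matches the reference analysis: ~1000 variants/Mb, where the
median 95% set at RAF 10%/OR 1.2 is ~15 variants. All runs use 100
replicates per setting.

# Known limitations

* The panel generator is a phenomenological LD model, not a population-
  genetic simulator: no recombination-map structure, no indels or
  multiallelics, no rare variants, no selection. Passing calibration tests
  on it shows the *procedure* is correctly implemented and calibrated on a
  human-like LD substrate; absolute resolution numbers (set sizes, rank-1
  rates) transfer to real data only qualitatively.
* Imputation is a linear panel-LD predictor, not an HMM; its INFO
  distribution was matched to realistic array designs, but per-individual
  error patterns differ from IMPUTE-style engines.
* Single-causal posteriors are used even in the two-causal design (that is
  the point of that experiment); no conditional analysis or stochastic
  search is included.
* No covariates, stratification confounding, X chromosome, or gene-gene
  interaction.

# A minimal run

```{r, eval = FALSE}
library(finemapsim)
cfg <- grid_config(replicates = 20, raf_levels = 0.1, or_levels = 1.2,
                   scenarios = c("gold", "gwas"),
                   panel = list(target_density = 500),
                   array_density_per_mb = 140, seed = 1)
res <- run_grid(cfg)
res$summary[, c("raf", "or", "scenario", "coverage95", "median_size95",
                "rank1_rate", "power")]
```

Published summary statistics can be fine-mapped directly:

```{r, eval = FALSE}
fm <- finemap_summary_file("locus_stats.tsv", W = 0.04)
head(fm$table)
```
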