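---
title: "Methods: two-stage TWAS with imputed gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage TWAS with imputed gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grextwas)
```

## The problem

Mapping the genetics of complex quantitative traits (here: dairy lactation
traits such as 305-day milk yield or milk solids) by single-SNP GWAS needs
sample sizes that small livestock holdings rarely provide. A
transcriptome-wide association study (TWAS) trades the per-SNP test for a
per-gene test: it first learns, on a small reference panel with both
genotypes and expression, how cis-SNPs predict each gene's expression, then
imputes that genetically regulated expression (GReX) into a larger genotyped
cohort and tests the imputed expression against the trait. Because a gene's
test aggregates many small cis effects, TWAS can recover signals that are
individually invisible to GWAS, and it runs orders of magnitude fewer tests.

`grextwas` implements the full two-stage pipeline at desk scale: genotype
QC, expression normalization and confounder residualization, cis-eQTL weight
training by two models, GReX imputation, covariate-adjusted GWAS and TWAS
scans with multiple-testing control, and comparison reporting. A
synthetic-data module generates genotype-expression-phenotype datasets with
known architecture so every stage is testable without external data.

## Models

### Stage 1: cis-eQTL weights

For gene $g$ with normalized, confounder-residualized expression
$E_g$ and cis-genotype matrix $X$ (minor-allele dosages of the SNPs within
gene body $\pm$ 1 Mb, boundaries inclusive),

$$E_g = X w + \varepsilon, \qquad \varepsilon \sim N(0, \sigma^2_\varepsilon I).$$

Only additive cis effects are modeled. Two estimators of $w$ are provided:

* **Elastic net** (`fit_enet()`): minimizes
  $\tfrac{1}{2n}\lVert E_g - \beta_0 - Xw\rVert^2 +
  \lambda\left[\tfrac{1-\alpha}{2}\lVert w\rVert_2^2 + \alpha\lVert w\rVert_1\right]$
  via glmnet, with $\lambda$ chosen by n-fold cross-validation on a
  log-spaced grid and $\alpha$ either fixed at 0.5 or grid-searched over
  $0.1,\dots,0.9$.
* **Dirichlet-process regression** (`fit_dpr()`): a nonparametric Bayesian
  shrinkage model, $w_j \sim \sum_{k=1}^{K} \pi_k N(0, v_k)$, with a
  truncated stick-breaking Dirichlet-process prior (concentration 1) on the
  mixture weights and inverse-gamma base measures on the component and
  residual variances. Posterior means are computed by coordinate-ascent
  variational inference: Gaussian-mixture factors per weight, multinomial
  responsibilities per assignment, Beta factors for the stick proportions,
  and MAP updates for the variances. Variational inference (rather than
  MCMC) keeps the fit deterministic given a seed and fast at desk scale.

Training accuracy is reported as squared Pearson correlation between
expression and predictions, either in-sample from a fit on all samples
("without CV") or from seeded out-of-fold predictions ("fivefold CV");
the weights themselves always come from the all-sample fit. The phrase
"without cross validation" is sometimes described alongside a rotational
leave-two-out scheme; both readings exist, fit-on-all is the implemented
default and leave-two-out is available as `evaluate_cv(mode = "loto")`.
A gene counts as *imputable* when at least one trained weight exceeds
$10^{-8}$ in absolute value — the accounting under which the DPR, whose
posterior means are never exactly zero, covers more genes than the elastic
net, which frequently shrinks an 8-sample fit to the null model.

### Stage 2: imputation and association

GReX is imputed into the test panel as
$\widehat{GReX} = X_{test}\hat w$ (`impute_grex()`), with test-panel missing
dosages mean-imputed. Association uses identity-link linear models:

* GWAS, per SNP $x$:
  $y = \beta_0 + x\beta_1 + C_1\beta_2 + C_2\beta_3 + \mathrm{AFC}\,\beta_4 +
  \mathrm{bwt}\,\beta_5 + e$, two-sided t-test of $H_0\!: \beta_1 = 0$.
* TWAS, per gene: $y = \eta C + \beta\,\widehat{GReX} + e$, same covariates,
  t-test of $H_0\!: \beta = 0$.

$C_1, C_2$ are the first two classical (Torgerson) MDS coordinates of the
pairwise identity-by-state distance $1 - \mathrm{IBS}(i,j)$, computed from
the GWAS-QC'd variant set (`compute_ibs_mds()`); age at first calving and
birth weight are fixed covariates. The Wald test uses the t distribution on
$n - q$ residual degrees of freedom (the reference distribution is an
implementation choice; at the pipeline's sample sizes it is mildly more
conservative than the normal). Bonferroni thresholds are $\alpha/m$;
Benjamini-Hochberg adjustment (`bh_adjust()`) delegates to
`stats::p.adjust`. Genomic inflation is summarized as
$\lambda_{GC} = \mathrm{median}(\chi^2_{1,obs})/0.4549$.

## Quality-control profiles

| profile | call rate | HWE exact p | MAF | LD |
|---|---|---|---|---|
| `set1` (TWAS) | > 0.95 | $\ge 10^{-4}$ | $\ge 0.01$ | — |
| `set2` (GWAS) | > 0.95 | $\ge 10^{-4}$ | $\ge 0.05$ | prune $r^2 > 0.8$ |
| `twas_train` (per-gene) | missing $\le 0.2$ | $\ge 10^{-4}$ | $\ge 0.01$ | — |

Conventions worth stating: call rate is strictly greater-than (a variant at
exactly 95% fails); HWE and MAF boundaries pass (source descriptions of the
MAF rules mix inclusive and exclusive phrasing; one inclusive convention is
used everywhere). MAF filtering precedes LD pruning — the order is a
package decision, not an external fact. The HWE test is the exact
conditional test computed by the standard recurrence over heterozygote
counts, without mid-p correction, with $p = 1$ for monomorphic sites. LD
pruning is greedy over sliding windows (defaults 50 variants, step 5; only
the $r^2$ threshold is externally specified), dropping the lower-MAF member
of each offending pair with deterministic tie-breaks. The X chromosome is
treated as diploid like the autosomes; no dosage-compensation rule is
applied. Indels and multi-allelic sites are excluded at VCF parse time.

Minor-allele coding is fixed per variant from the reference panel's
observed allele frequency (ties at 0.5 keep the ALT allele); a test panel
read from VCF can be harmonized to the reference coding with
`match_minor_coding()`, which the pipeline does so that trained weights
transfer correctly.

## Expression preparation

`normalize_expression()` implements median-of-ratios size factors (computed
on genes with all-positive counts) followed by `log2(count/sf + 1)` — a
documented substitute for a regularized-log transform that preserves the
property stage 1 needs, approximately homoskedastic continuous expression.
A pre-normalized matrix can be supplied instead. `residualize()` removes
production-level (high/low yield, indicator-coded) and collection-batch
effects by per-gene least squares; residuals have zero mean and are
orthogonal to every factor column, and rank-deficient factor designs drop
redundant columns.

## The synthetic-data generator

`sim_config()` + `simulate_panel()` / `simulate_expression()` /
`simulate_phenotypes()` emulate the study structure: biallelic SNPs drawn
as two independent allele draws (Hardy-Weinberg proportions) at
frequencies uniform on `maf_range`, laid out so each gene's $\pm$ 1 Mb cis
window holds `snps_per_gene` variants (windows disjoint by default on 1-2
synthetic chromosomes; an overlap mode exists for stress tests);
independent missingness; per-gene expression $Xw + \varepsilon$ with the
genetic variance fraction rescaled to `he2` and `round(pi_causal *
snps_per_gene)` causal SNPs; per-gene, per-batch expression shifts; and
test-panel phenotypes
$y = \sum_g \beta_g\,GReX_g + b_{AFC}\,\mathrm{AFC} + b_{bwt}\,\mathrm{bwt} + N(0,
\sigma^2)$. Phenotypes are generated for test samples only, mirroring the
8-reference / 136-test design. Defaults are chosen once to mirror the study
conditions: `n_ref = 8`, `n_test = 136`, `he2 = 0.12` (the middle of the
0.04-0.2 expression-heritability range that motivates small-panel TWAS),
`pi_causal = 0.2`, 2% missingness, and AFC $\sim N(40, 5^2)$ months /
birth weight $\sim N(31, 3^2)$ kg, typical of riverine dairy buffalo. Trait
heritability and effect sizes are not externally specified; they are
config-exposed, not asserted as biological truth.

What the generator does **not** emulate: linkage disequilibrium between
sites (variants are independent given their frequencies), minor-allele
frequency spectra skewed by ascertainment, population stratification,
non-additive (dominance/epistatic) genetic effects, count-level expression
noise, and cross-assembly variant-calling artifacts. Passing tests
therefore demonstrate correctness of the pipeline's statistics under its
own model assumptions, not robustness to every property of real ddRAD/RNAseq
data.

## Numerical choices and degenerate inputs

* DPR: truncation `K = 4`, `tol = 1e-4` on the relative change of the
  monitored evidence lower bound, `max_iter = 1000`, seeded responsibility
  initialization; hitting `max_iter` returns weights flagged
  `converged = FALSE`. At `K = 1` the update equations are exactly
  Gauss-Seidel on the ridge normal equations, so the fit matches closed-form
  ridge at the fitted variance ratio (a test asserts this to $10^{-4}$).
  Because the hyperpriors are fixed, exact invariance to duplicating all
  samples holds only where the likelihood dominates the prior; in
  low-information regimes duplication mildly reduces shrinkage.
* Elastic net: columns standardized internally, weights returned on dosage
  scale; with fewer samples than folds the fold count drops to n with a
  warning; `lambda = 0` reproduces OLS to $10^{-8}$ on well-conditioned
  designs.
* Zero-variance cases: constant SNPs and constant GReX columns are flagged
  with $p = 1$ rather than dropped; zero-variance CV predictions give a
  training R-squared of 0, flagged; all-missing variants fail call-rate
  filters.
* Degenerate correlations in LD pruning are treated as $r^2 = 0$; all
  pruning and extreme-weight tie-breaks resolve toward the earlier genomic
  position, making every step deterministic.
* p-values from the scans are clamped into `(.Machine$double.xmin, 1]` so
  downstream $-\log_{10}$ and BH steps are well defined.

## Reporting conventions

`top_hits()` annotates each top unit with genes whose flanked interval
(gene body $\pm$ 20 kb, 1-based inclusive) covers the unit position. BH
adjustment over the full test family is the default; an opt-in
`bh_scope = "top"` reproduces the within-top-10 adjustment convention some
reports use (statistically nonstandard, so not the default).
`twas_hit_window_genes()` screens gene midpoints within $\pm$ 1.5 Mb of a
TWAS peak's midpoint, boundary inclusive, same chromosome — the
neighborhoods exported for external pathway enrichment (enrichment itself
is out of scope; it depends on an online service and database versions).
`shared_gene_counts()` reports exclusive Venn-region cardinalities.

## Problem sizes used in tests and the acceptance script

The validation suite runs the oracle-equivalence checks exhaustively for
all genotype configurations with up to 80 samples (sampled configurations
up to 200), parameter recovery on a 400-sample / 30-SNP panel at
`he2 = 0.3`, null calibration with 300 samples and 1,000 units, the
DPR-vs-elastic-net gene-coverage comparison on 200 genes at the study's
8-sample reference size, and the TWAS-vs-GWAS power comparison over 20
replicates (one causal gene, 20 cis-SNPs, `he2 = 0.2`, 5% of trait variance
through GReX, 200 reference / 400 test samples, stratification covariates
from a genome-wide background marker panel). These sizes make every
property measurable in minutes on one CPU while keeping each estimate's
sampling error well inside the asserted bands.

## Known limitations

* The 8-sample reference regime is fundamentally noise-limited; in-sample
  training R-squared there is optimistic (the suite demonstrates this
  rather than hides it), and cross-validated R-squared at n = 8 is nearly
  uninformative.
* No mixed-model/kinship correction: both scans are fixed-effect
  regressions with MDS components, as in the design this package follows.
* No summary-statistic or cross-tissue TWAS modes; no LD-aware weight
  training (sites are modeled jointly but the simulator generates
  independent sites).
* The exact regularized-log normalization of counts is delegated to
  external tools; the built-in normalization is a documented approximation.
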