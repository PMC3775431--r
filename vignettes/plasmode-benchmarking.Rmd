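---
title: "Benchmarking RNA-seq differential-expression tests with simulations and plasmodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking RNA-seq differential-expression tests with simulations and plasmodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmodeBench)
```

## The problem

Choosing a statistical test for RNA-seq differential expression (DE) is
hard to do on real data alone, because the true status of every gene is
unknown. `plasmodeBench` builds datasets where the truth *is* known, in
two complementary ways, and scores testing procedures against that truth
for type-I error calibration and power:

* **Parametric simulation.** Counts are drawn from an over-dispersed
  (lognormal-)Poisson process whose parameters come from a pool estimated
  on, or emulating, pilot data.
* **Plasmode construction.** A real (or synthetic stand-in) base dataset
  is reshuffled and relabelled, optionally with effects spiked in by
  binomial thinning, so the empirical count distribution and gene-gene
  correlations are preserved while the null/alternative status of every
  gene is known by construction.

The testing engines being compared are re-implemented inside the package
rather than called from external tools, so that every modelling choice is
explicit and auditable: negative binomial (NB) GLM likelihood-ratio tests
under two dispersion-sharing policies, and Gaussian F-tests on
transformed counts with tabulated or permutation p-values.

## The count model behind the simulator

For gene $g$, treatment group $i$ and biological sample $j$,

$$ y_{gij} \sim \mathrm{Poisson}(\lambda_{gij}), \qquad
   \log \lambda_{gij} = O_{ij} + \mu_{gi} + e_{gij}, \qquad
   e_{gij} \sim N(0, \sigma^2_g), $$

where $O_{ij}$ is the known log library size. The Normal random effect on
the log rate makes the marginal distribution a lognormal-Poisson mixture:
over-dispersed relative to Poisson
($\mathrm{Var} = m + (e^{\sigma^2} - 1)m^2$ for marginal mean
$m = e^{O + \mu + \sigma^2/2}$), but deliberately *not* negative binomial
— so neither family of tests is simulated under its own model. Technical
replicates of a biological sample share one realized $e_{gij}$ and differ
only in independent Poisson noise: they add depth, not biological
information. A dataset has $T$ genes and $2nr$ columns ($n$ biological
times $r$ technical replicates per group); the replication grid crosses
$n \in \{3, 5, 10\}$ with $r \in \{1, 3, 5\}$, and the DE fraction
defaults to $p_0 = 0.1$ with exactly $\lfloor p_0 T \rfloor$ genes
assigned to the alternative set $S_1$ (a fixed count, not a Bernoulli
draw, so the $\#S_0/\#S_1$ denominators used in evaluation are
deterministic). For null genes, both group means are replaced by their
average $(\mu_1 + \mu_2)/2$ — preserving the gene's overall abundance
rather than copying one group's mean, since only the *difference* must
vanish.

### Parameter estimation by moment matching

`estimate_parameters()` recovers $(\mu_{1}, \mu_{2}, \sigma^2)$ per gene
from a pilot dataset by closed-form moment matching on offset-corrected
rates $z_j = y_j / e^{O_j}$: the group mean $\hat m_i$ estimates
$e^{\mu_i + \sigma^2/2}$; the excess of $\mathrm{var}(z)$ over the
Poisson contribution $\hat m_i\,\overline{e^{-O}}$ estimates
$\hat m_i^2(e^{\sigma^2} - 1)$; pooling the excess across groups with
group-size weights gives $\hat\sigma^2$ and hence $\hat\mu_i$. This is a
deliberate design choice over a generalized linear mixed-model fit: it is
closed-form, dependency-free, and for benchmarking purposes only the
induced distribution of $(\mu, \sigma^2)$ across the pool matters, not
per-gene efficiency. Genes with a zero mean rate in any group are dropped
(their $\mu_i$ is undefined on the log scale). The estimator's bias and
variance vanish as replication grows; the tests verify recovery to
within 0.05 at $n = 200$.

### Offsets

The simulated library-size scheme is configurable because the study
conditions do not pin it down: the default draws lognormal library sizes
with a coefficient of variation of 0.2 around a target depth of
$2\times 10^7$ reads, typical of bulk RNA-seq; `"equal"` gives constant
offsets. The rate computation refuses to exponentiate arguments above 700
(the IEEE double ceiling) and names the offending gene rather than
saturating silently.

## Plasmode generators

**Null plasmodes** (`make_null_plasmodes()`) assume the base samples are
exchangeable — a property the analyst must justify, e.g. by
multidimensional-scaling inspection, not something the package tests.
Each plasmode draws $t \cdot r$ distinct base columns without
replacement, copies them bit-for-bit and assigns arbitrary pseudo-group
labels. Every gene is truly null, yet all distributional quirks and
gene-gene correlations of the base data survive. The default
configuration (10 plasmodes, 2 groups of 10 from a 21-sample base)
mirrors the canonical null-plasmode design for a structureless human
expression dataset.

**DE plasmodes** (`make_de_plasmodes()`) handle a base with treatment and
block structure. A high-confidence effect set $G$ is first selected with
the package's own NB LRT engine (treatment + block, tagwise dispersions)
at a Benjamini-Hochberg q-value cutoff, default $q \le 0.01$ — BH because
it is the standard FDR procedure, and a small cutoff because $G$ should
contain only confidently non-null genes. Each plasmode then:

1. randomly partitions the samples *within each block* into two balanced
   pseudo-treatment groups (odd-sized blocks alternate which side takes
   the extra sample), respecting the restricted randomization that a
   strong block effect demands;
2. picks $\mathrm{round}(\pi T)$ genes at random (default $\pi = 0.2$);
3. imposes an effect $\beta$ on each by **binomial thinning**: the
   pseudo-group on the down side of the effect has its counts replaced by
   $\mathrm{Binomial}(y, e^{-|\beta|})$ draws. Thinning preserves
   integer counts and the mean-variance character of count data, which
   multiply-and-round would distort.

Two readings of "effects taken from $G$" are both implemented:
`sampled_from_G` (default) spikes arbitrary genes with effects drawn with
replacement from $G$'s estimated log fold changes, which lets any gene
carry a realistic effect size; `own_effect_G_only` spikes members of $G$
with their own estimates. The default follows the resampling scheme of
earlier plasmode work in microarrays; the alternative is a stricter
reading and is available as a configuration switch. Each plasmode draws
its own partition independently, including which base samples are left
unused.

## Preprocessing

All engines see the same preprocessing, in this order:

1. `collapse_technical()` — technical replicates are summed into their
   biological sample (they only add depth).
2. `filter_cpm()` — keep genes with $\ge 2$ counts-per-million in at
   least as many libraries as biological replicates per group, computed
   on **raw** library sizes (filtering precedes normalization).
3. Normalization: `tmm_factors()` (trimmed mean of M-values; 30% trimmed
   from each tail by log-ratio, 5% from each tail by abundance, inverse
   approximate-variance weights, 75th-percentile reference — the
   published method's defaults) feeds the NB-tagwise and Gaussian
   engines as log effective library sizes;
   `size_factors_median_ratio()` feeds the NB-trend engine.
4. `log2_cpm()` — $\log_2((y + 0.5)/(\widehat N + 1) \times 10^6)$ with
   effective library size $\widehat N$; the 0.5 prior and the +1 keep
   the transform finite for all counts and reproduce the conventional
   log-CPM used by Gaussian modelling of counts. Precision (mean–
   variance) weights are deliberately out of scope: the Gaussian engines
   consume plain log2-CPM values.

## Testing engines

All engines test the treatment term; with more than one block level the
block enters both full and reduced models as a fixed effect, with
first-level-baseline treatment-contrast coding.

**NB GLM LRT.** `fit_nb_glm()` maximizes the NB log-likelihood with log
link at fixed dispersion $\phi$ (variance $\mu + \phi\mu^2$; $\phi = 0$
is Poisson) by iteratively reweighted least squares, converging when the
relative deviance change falls below $10^{-8}$ (50-iteration cap;
non-convergence flags the gene rather than erroring). The LRT statistic
is the deviance difference referred to $\chi^2$ with the rank
difference as degrees of freedom. Two dispersion policies mimic the two
count-model tools being benchmarked:

* `tagwise_shrunk` maximizes per gene the Cox-Reid adjusted profile
  likelihood (APL) plus $w_0$ times the average APL across genes —
  shrinkage toward a common value with a prior weight of $w_0 = 10$
  gene-equivalents, the historical default of the tool this policy
  mirrors. The APL is evaluated on a 15-point logarithmic grid over
  $[10^{-6}, 10]$ and the per-gene maximizer interpolated
  quadratically; the grid keeps the whole-matrix fit vectorized.
* `trend_max` uses per-gene method-of-moments estimates
  $\max(0, (s^2 - \bar y)/\bar y^2)$ on size-factor-scaled counts,
  pooled within conditions, fits the hyperbolic trend
  $\phi(\mu) = a_0 + a_1/\mu$ by least squares over genes with positive
  estimates, and takes the per-gene *maximum* of estimate and trend —
  the conservative sharing rule characteristic of the second tool.

**Gaussian F-tests.** `fit_gaussian()` runs gene-wise OLS on log2-CPM.
`f_statistics()` produces the ordinary per-gene F (`F1`) and the
moderated `Fs`, whose residual variance is shrunk across genes by a
positive-part James-Stein pull of log variances toward their mean, with
sampling variance $V = \psi'(d/2)$ (trigamma; the variance of the log of
a scaled $\chi^2_d$). P-values come either from the F table
(`tabulated_pvalues()`; moderation changes the statistic, not the
reference) or from `permutation_pvalues()`: whole-sample label
permutations (within blocks when the design is blocked, matching the
restricted randomization), 100 by default, with the null pooled across
genes and the add-one rule
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + \text{pool size})$.
With add-one, zero p-values cannot occur; the evaluation module still
implements the replace-zeros-by-minimum rule because engine-agnostic
input may contain them. When the design admits fewer distinct label
splits than requested, the package enumerates all of them exhaustively
(excluding the observed split from the pool, which reproduces the
classical exact permutation p-value) and warns.

## Evaluation

`confusion_at()` applies the inclusive declaration rule $p \le \alpha$
(inclusive so that permutation-granularity atoms land on the curve) and
asserts the confusion-table identities on every call. `roc_curve()`
sweeps all distinct p-values by default; `type1_curve()` reports the
rejection rate among true-null genes over a 30-point log-spaced grid on
$[10^{-4}, 10^{-1}]$, the region where count-model miscalibration
concentrates; `qq_uniform()` pairs sorted null p-values with $i/(m+1)$
uniform quantiles on the $-\log_{10}$ scale. No multiple-testing
correction is applied anywhere in evaluation — the object of study is the
raw p-value distribution itself (BH appears only inside
`select_effect_set()`). `aggregate_curves()` keeps every per-dataset
curve because the spread across plasmodes is itself a finding, and adds a
pointwise mean on the union grid by step interpolation.

## Synthetic base fixtures

`make_exchangeable_base()` and `make_blocked_base()` provide offline
stand-ins for the two kinds of real base data the plasmode generators
expect: a structureless 21-sample dataset, and a two-group (10 + 11)
dataset spread over 3 blocks with planted effects. Their distributions
are declared defaults — NB counts, lognormal abundances
($\ln \mathrm{CPM} \sim N(\ln 50, 1.5^2)$), gamma dispersions (mean
0.15), lognormal library sizes ($10^7$, CV 0.3), planted absolute
effects $0.5 + \Gamma(4, 4)$ with random sign on 20% of genes, and
per-(gene, block) shifts with SD 0.3 — **not** fits to any published
dataset; real base data can always be supplied through `read_counts()`.
`make_parameter_pool()` similarly declares the simulator's default pool:
$\delta$ from an equal mixture of $N(0, 0.5^2)$ and $N(0, 1^2)$ (many
small effects, some large) and $\sigma^2 \sim \Gamma(2, \text{mean }
0.1)$, i.e. mild-to-moderate biological over-dispersion.

Because the fixtures are NB with modest dispersion and no outlying
genes, passing tests on them demonstrate correct machinery and the
qualitative calibration ordering, not performance on any particular real
dataset — real RNA-seq has heavier tails, correlated genes (which only
the plasmode path preserves), and composition effects stronger than the
fixtures plant.

## Numerical choices and degenerate inputs

* IRLS linear predictors are clamped to $\pm 700$ and fitted means
  floored at $10^{-8}$, so all-zero genes fit cleanly (deviance 0).
* Deviance differences are floored at 0 before the $\chi^2$ tail.
* Dispersion search is confined to $[10^{-6}, 10]$; values at the lower
  boundary are numerically Poisson.
* TMM falls back to factor 1 (with a warning) when trimming removes
  every gene; factors are rescaled to geometric mean 1.
* Ties in permutation pools are counted exactly (no epsilon comparisons)
  via order statistics on negated values.
* Fractional counts are rejected, never rounded; thinning is the only
  sanctioned way to scale counts down.
* Seeds: every stochastic entry point takes a `seed`; pipeline stages
  derive labelled sub-seeds (`derive_seed()`) from the master seed, so
  any stage can be reproduced in isolation. All derived seeds stay below
  $2^{31}$.

## Problem sizes

The shipped test-and-verification workloads use scaled-down sizes chosen
as the smallest that make the statistical assertions sharp: parameter
recovery at $n = 200$ replicates; dispersion recovery at 2000 genes,
5 per group; the replication of the simulation study's type-I ordering
at $K = 50$ datasets of $T = 2000$ genes with $n = 3$, $r = 1$; and the
acceptance script's plasmode studies at 2000-3000 genes. The full-scale
conditions ($K = 1000$, $T = 5000$) are a matter of configuration, not
code.

## Limitations

* The moment-matching estimator is less efficient than a likelihood fit
  at very small $n$; it is intended for pools estimated on well-replicated
  pilot data.
* Exchangeability of a null-plasmode base is assumed, not tested.
* Spiking supports two treatment groups only; multi-group thinning is
  out of scope.
* The Gaussian engines consume unweighted log2-CPM; precision-weighted
  variants are deliberately excluded from the comparison.
* FDR procedures are not compared; BH is used only to pick the spike-in
  effect set.

## A minimal run

```{r example, eval = FALSE}
pool <- make_parameter_pool(seed = 1)
cfg <- sim_config(T = 2000, K = 5, n = 3, r = 1, p0 = 0.1, seed = 1)
st <- sample_truth(pool, cfg$T, cfg$p0, seed = 2)
ds <- simulate_dataset(cfg, st, seed = 3)
flt <- filter_cpm(ds$counts, cfg$n)
design <- ds$design[match(colnames(flt$counts), ds$design$sample_id), ]
rt <- run_de_methods(flt$counts, design,
                     methods = c("nb-lrt-tagwise", "gauss-F1-perm"),
                     seed = 4)
tt <- ds$truth[ds$truth$gene_id %in% rownames(flt$counts), ]
type1_curve(rt[rt$method == "nb-lrt-tagwise", ], tt, nominal = 0.001)
```
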