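---
title: "Methods: Y-STR descent clusters, TMRCA dating and haplogroup population structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Y-STR descent clusters, TMRCA dating and haplogroup population structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ystr)
```

## Scope and model

`ystr` analyses paternal population structure from the two marker systems of
a standard Y-chromosome survey: biallelic SNPs, which place each chromosome
in a haplogroup (a clade of the Y phylogeny), and Y-STR loci, whose integer
repeat counts mutate at roughly `2e-3` per locus per generation and therefore
resolve events on historical timescales — clan founders, medieval
expansions, recent migrations.

Two layers of analysis are covered.

**Haplogroup-frequency structure.** Populations are summarised as frequency
vectors over haplogroups. Between-population divergence uses Nei's standard
genetic distance $D = -\ln\left(J_{xy}/\sqrt{J_x J_y}\right)$ with
$J_{xy} = \sum_i x_i y_i$; ordination uses metric MDS (classical start,
SMACOF stress majorization) and covariance PCA; hypothesis tests are a
three-level AMOVA (within populations / among populations within groups /
among groups) under alternative grouping schemes, and a Mantel permutation
test of genetic against great-circle geographic distance.

**STR descent clusters.** 15-locus haplotypes (the Yfiler panel minus the
multi-copy DYS385a/b, with DYS389b = DYS389II − DYS389I) are compared by
step distance $\sum_\ell |a_\ell - b_\ell|$, the natural metric under the
single-step mutation model (SMM). Modal haplotypes (identical profiles
carried by more than 10 samples), their related haplotypes (same
haplogroup, within 4 steps, i.e. "fewer than 5"), median-joining networks,
population-enriched clade delineation and founder-based dating with the rho
statistic and the ASD estimator complete the workflow:

$$\hat t_{\rho} = \frac{\rho}{L\,\mu}\,g, \qquad
  \hat t_{ASD} = \frac{1}{\mu}\Big(\frac{1}{nL}\sum_i\sum_\ell
  (a_{i\ell}-f_\ell)^2\Big)\,g,$$

with $\rho$ the mean step distance to the founder $f$, $L = 15$ loci,
$\mu = 2.1\times10^{-3}$ mutations/locus/generation (the "genealogical"
rate) and $g = 30$ years per male generation.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `mu` | 2.1e-3 | mutations/locus/generation | genealogical Y-STR rate, consistent with sequence-based calibration for clusters younger than ~30 kyr |
| `g` | 30 | years/generation | standard male generation interval |
| modal threshold | 10 | carriers | a profile is "modal" when carried by *more than* 10 samples |
| related radius | 4 | steps | "fewer than 5 mutational steps"; ~2 kyr of expected divergence at these rates |
| enrichment threshold | 0.5 | fraction | a network zone counts as population-specific when most of its samples come from the seed population |
| distance cap | 4 | steps | "very distant haplotypes are ignored" during clade attribution; defaults to the related radius |
| AMOVA/Mantel permutations | 9999 | — | p-value resolution ~1e-4; seed mandatory |

## Synthetic data: what it emulates, what it does not

Real genotype tables for the motivating survey are not publicly deposited,
so the package ships a generator that reproduces the *statistical structure
the analysis assumes*, with recorded truth:

* `simulate_clan()` grows haplotypes from a founder under the symmetric
  single-step SMM. In **star** mode each sampled lineage accrues, per locus,
  Poisson(`mu * depth`) mutations of ±1 repeat — this is the exact null
  model of the rho/ASD estimators and supports non-integer depths (needed
  for printed ages like 800 y = 26.67 generations). In **galton_watson**
  mode lineages branch per generation with Poisson offspring, conditioned
  on survival, giving correlated (shared-branch) genealogies. Repeat counts
  are floored at 5 (a downward step at the floor is applied upward);
  at the simulated depths this is astronomically rare and does not bias the
  estimators measurably.
* `simulate_populations()` draws group mean haplogroup frequencies from a
  Dirichlet around a base vector (mass = `concentration`; ≥ 1e6 is treated
  as the exact-base null), population frequencies from a Dirichlet around
  the group mean (`pop_concentration = 100`, moderate drift between
  neighbouring populations), individuals multinomially, and coordinates
  uniformly in a box spanning the Amu Darya/Syr Darya region, optionally
  segregated by group to create a genuine Mantel signal.

Not emulated: effective population size and coalescent depth structure,
locus-specific mutation rates, multi-step mutations, migration, and any
linkage between haplogroup frequencies and STR profiles across populations.
A green recovery test therefore establishes that the estimators and their
implementation are correct *under the stated model*, not that the model
captures every feature of real Transoxianan data.

## The rho homoplasy bias, and why one acceptance criterion stays red

rho measures the *net* repeat displacement per locus, $|M - N|$ for $M$
upward and $N$ downward mutations. Whenever two mutations cancel
($\min(M,N) > 0$), rho undercounts: with $M,N \sim$ Poisson$(\lambda/2)$,
$E|M-N| = \lambda - 2E[\min(M,N)] < \lambda$. At the recovery
configurations this exact (Skellam) deficit is ~2% at 600 y, ~3.7% at
1100 y and ~4.7% at 1400 y. The recovery criterion demands the
500-replicate mean within 3 standard errors of the true age; those standard
errors (10–19 y) are *smaller* than the bias for the three larger/deeper
configurations, so the rho half of the criterion fails by mathematics, not
by defect — the test is kept, red, as an honest statement about the
estimator (this is the same systematic bias that motivates reporting ASD
alongside rho in practice). ASD uses squared displacement, for which
$E[(M-N)^2] = \lambda$ exactly, and passes every configuration. The
acceptance *report* values land within ~5% of the printed ages.

## Numerical and design choices

* **Median-joining, not Reduced-Median**: the RM variant is defined for
  binary characters; multi-allelic STR profiles call for MJ, which is also
  what haplotype-network figures in this literature display. Medians
  (per-locus majority of linked triplets) are added greedily while they
  reduce the minimum-spanning-tree cost of the node set, then degree-<2
  medians are pruned; `epsilon` (default 0) relaxes the candidate link set.
  All tie-breaks are lexicographic on allele vectors, making the network
  independent of input order.
* **Zone rule**: the published procedure asks for "a zone carrying mostly
  haplotypes from a single population" without quantifying "mostly". The
  zone is grown greedily from the founder; a node joins only if it is
  itself seed-dominated (threshold 0.5, configurable; inferred median
  nodes are neutral) and the cumulative zone enrichment stays above
  threshold. Clade membership then requires the deterministic shortest
  path to the founder to stay inside the zone and within the distance cap.
* **AMOVA distance**: 0/1 on haplogroup assignment, matching an analysis
  of "variation in haplogroup frequencies"; all sums of squares reduce to
  haplogroup counts, which keeps the three permutation tests (populations
  across groups for $\Phi_{CT}$; individuals within groups for
  $\Phi_{SC}$; individuals overall for $\Phi_{ST}$) fast. Negative
  variance components are retained (Arlequin convention), so percentages
  always sum to 100. When every group contains a single population the
  middle level vanishes and $\Phi_{SC}$ is undefined (reported NaN/NA).
* **Mantel sidedness**: reported two-sided; the use case is a near-zero
  correlation where sidedness is immaterial, and two-sided is the safer
  default.
* **MDS**: the source analysis used nonmetric MDS in commercial software;
  metric stress majorization from the deterministic classical start is
  used instead because it is reproducible, and stress here is compared
  qualitatively. Stress-1 is normalised by the input dissimilarities.
  Infinite Nei sentinels (disjoint haplogroup support) are rejected rather
  than imputed.
* **Duplicated DYS19**: haplotypes flagged `dys19_dup` drop DYS19 from any
  pairwise comparison involving them (no per-copy matching); distances are
  rescaled by 15/14 where comparability across mixed sets matters (PD,
  founder distances).
* **Intermediate alleles** (e.g. 23.2) are rejected at parse time, never
  rounded: integer repeat states are an assumption of every step-based
  statistic downstream.
* **Config format**: the pipeline config is JSON (`jsonlite`), not YAML —
  equivalent structure, one fewer dependency.
* **Seeds**: every stochastic function takes a mandatory seed and restores
  the caller's RNG state; the pipeline derives stage seeds as
  `seed + 101 * stage_index` so inserting a stage never perturbs the
  randomness of earlier ones.

## Null calibration

Under the no-structure simulation (group means equal, populations
exchangeable), $\Phi_{CT}$ permutation p-values must be uniform: the suite
checks a 5% rejection rate within 3 binomial standard errors over 400
replicates. The design uses 2 groups × 6 populations, because the
$\Phi_{CT}$ permutation space is the set of group partitions —
$\binom{12}{6}/2 = 462$ here — and a design with few populations per group
would make the permutation distribution too discrete to probe
$\alpha = 0.05$ at all.

## Known limitations

* rho's homoplasy bias is not corrected (no back-mutation correction is
  applied in the published workflow either); ASD is the unbiased companion.
* ASD is reported as a point estimate; only rho carries a standard
  deviation (star formula without a network, Saillard-style branch formula
  with one).
* The marker tree covers only the 35 typed SNPs; untyped ISOGG levels are
  not imputed, and paragroup labels name only markers actually typed
  ancestral.
* Nei distance does not satisfy the triangle inequality; MDS of such
  matrices is an approximation by construction.
* The median-joining implementation targets the data sizes of clan studies
  (hundreds of haplotypes, dozens of distinct profiles); it is not tuned
  for genome-scale inputs.

## A worked example

```{r}
sim <- simulate_clan(n_samples = 67, depth_generations = 20, seed = 42)
founder <- default_founder()
rho_age(sim$haplotypes, founder)
asd_age(sim$haplotypes, founder)
```

The printed ages estimate the configured truth of
`20 * 30 = 600` years from the simulated profiles alone.
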