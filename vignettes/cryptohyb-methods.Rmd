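---
title: "Models and methods behind cryptohyb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cryptohyb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cryptohyb` reimplements, as one tested pipeline, the genetic workflow used
to characterise a pair of sympatric cryptic species from co-dominant
microsatellite genotypes, a short mitochondrial barcode and two simple
phenotypes. This vignette explains the models, the parameters that matter,
the numerical choices, and what the synthetic-data generator does and does
not emulate.

## The admixture model and its sampler

Nuclear clustering uses the Bayesian admixture model: individual $i$ has an
ancestry vector $q_i$ on the $K$-simplex, and each of its two allele copies
at locus $l$ descends from cluster $k$ with probability $q_{ik}$, carrying
allele $j$ with probability $p_{klj}$. Cluster allele frequencies follow the
correlated-frequency (F-model) prior: $p_{kl} \sim
\mathrm{Dir}(p^A_l (1-F_k)/F_k)$ around an ancestral vector $p^A_l \sim
\mathrm{Dir}(\lambda)$, with one drift coefficient $F_k$ per cluster.
Ancestries have a symmetric Dirichlet prior with a single concentration
$\alpha$ shared by all individuals, $\alpha \sim U(0, 10)$.

`run_admixture()` is a Gibbs sampler: allele-copy origins $Z$ are updated
given $(P, Q)$; $P$ is a conjugate Dirichlet update given $Z$ under the
F-model prior; $p^A_l$ moves by pairwise mass-transfer Metropolis steps and
each $F_k$ by a random-walk Metropolis step under a Gamma prior (mean 0.01,
sd 0.05, the cited program's defaults); $Q$ is a Dirichlet update; $\alpha$
moves by random-walk Metropolis (proposal sd 0.025). Missing genotypes
contribute no likelihood terms, so an individual with no data retains its
prior. Model evidence per run is estimated as
$\widehat{\ln P(D)} = \overline{\ln L} - \mathrm{var}(\ln L)/2$ over the
retained post-burn-in trace.

Two chain presets are provided. `mcmc_config()` defaults to the full
settings of the original analysis (burn-in 300,000, chain 1,000,000);
`desk_mcmc_config()` (burn-in 5,000, chain 20,000, thinning 10) resolves two
sharply differentiated clusters in seconds and is the default of the
pipeline, the test-suite and the acceptance script. The vignette-level
claim that the desk preset suffices rests on the credibility-interval
construction described next.

### Rao-Blackwellised ancestry summaries

Conditionally on the rest of the state, $q_i \sim \mathrm{Dir}(\alpha +
m_i)$ where $m_{ik}$ counts the allele copies of $i$ currently assigned to
cluster $k$. The sampler therefore accumulates the visit histogram of
$m_{ik}$ at every post-burn-in sweep and summarises the marginal posterior
of $q_{ik}$ as the implied mixture of
$\mathrm{Beta}(\alpha + m,\; (K-1)\alpha + M_i - m)$ laws ($M_i$ = number of
scored allele copies). The posterior mean and the 5% and 95% quantiles (the
90% credibility interval used by the relaxed hybrid rule) are computed from
this mixture, whose tails are analytic. Raw sample quantiles at desk-scale
chain lengths underestimate extreme tails noticeably; the mixture bounds are
stable across a five-fold change in chain length, which is why the desk
preset is trusted for threshold work.

### Label alignment and model selection

Independent runs label clusters arbitrarily. `align_runs()` permutes each
run's columns to minimise the summed absolute q-distance to the run with
the highest evidence (exact search over all $K!$ permutations for
$K \le 6$), then averages aligned q matrices and credibility bounds.
`evanno_deltaK()` selects $K$ by the standardized second difference
$\Delta K = |L(K{+}1) - 2L(K) + L(K{-}1)| / \mathrm{sd}(L(K))$ of mean
evidence over runs; a zero standard deviation leaves $\Delta K$ undefined
rather than infinite.

## Hybrid detection

Reference parental pools are the 80 individuals with the highest consensus
q per cluster. `simulate_hybrid_classes()` draws simulants at gamete level
from the pools' empirical allele frequencies: parentals draw both alleles
from one pool, F1s one from each, F2s are unions of two F1 gametes, and
backcrosses an F1 gamete plus a parental gamete. The pooled simulants (300
per class by default) are clustered afresh and the thresholds TP1/TP2 are
the lowest mean q reached by a simulated parent in its own cluster.
Individuals are then classified against the thresholds by their mean q
(conservative) or by the 90%-credibility lower bound of their majority
cluster (relaxed); every conservative hybrid is necessarily a relaxed
hybrid. `misclassification_study()` repeats the few-hybrids scenario (300
parentals per side, 10 F1, 15 backcrosses each) thirty times, clustering
each replicate afresh and applying the fixed thresholds.

In repeated synthetic runs the conservative rule flags no parental
simulants at all, while the relaxed rule flags a small residue (a few per
thousand): under the F-model generator both species share many
intermediate-frequency alleles, so a small fraction of simulated parents
genuinely carry several other-cluster-leaning copies and have wide
posterior tails. With empirical pools of more distinct species this residue
shrinks towards zero; the package reports whatever the data imply rather
than forcing a null.

## Population-genetic estimators

All F-statistics are Weir–Cockerham variance-component estimators:
per-allele components $a$ (among groups), $b$ (among individuals) and $c$
(within individuals), with multilocus $\theta = \sum a / \sum (a+b+c)$ and
$f = 1 - \sum c / \sum(b+c)$; the 95% CI on $\theta$ is a percentile
bootstrap over loci (1000 resamples, seeded). Expected heterozygosity is
Nei's unbiased $\frac{2n}{2n-1}(1 - \sum p^2)$. Permutation tests all use
the includes-observed convention $p = (b+1)/(m+1)$:

* Hardy–Weinberg: the group's allele copies are re-paired at random; since
  allele counts are fixed under this null, the Weir–Cockerham $f$ statistic
  reduces to the heterozygote count, which is what the C++ kernel permutes.
  Two-sided by default, one-sided deficit available. Bonferroni correction
  across locus-by-group tests.
* Linkage disequilibrium: log-likelihood G on the two-locus genotype table,
  permuting one locus within groups.
* Differentiation: pairwise $\theta$ plus an exact-G test on allele counts
  summed over loci, permuting multilocus genotypes between the two groups.
* Sex-biased dispersal: statistic $\theta_F - \theta_M$ over sites, sexes
  permuted within sites, one-sided for the hypothesised dispersing sex
  (dispersers are expected to show the lower $\theta$).

Null alleles are estimated from the heterozygote deficit (Chakraborty's
$(He-Ho)/(He+Ho)$ by default, Brookfield's first estimator as an option)
with an exact one-sided binomial test of the homozygote count against its
Hardy–Weinberg expectation. The pipeline excludes loci with a significant
null-allele signal (p < 0.05) or a Bonferroni-significant Hardy–Weinberg
departure in either cluster, then re-clusters on the retained panel; it
aborts if fewer than five loci survive.

## Mitochondrial barcode

Distances are raw p-distances (proportion of differing sites, pairwise
deletion of anything outside A/C/G/T, so N and gaps never count).
Haplogroups are the single-linkage connected components at distance <=
0.02 — an order of magnitude above typical within-haplogroup barcode
diversity here and well below between-species divergence; the partition can
only split, never merge, as the cutoff decreases. Tree building is
deliberately out of scope: every claim consumed downstream (two
non-overlapping haplogroups, divergence summaries, discordance counts)
depends only on distances. Cyto-nuclear discordance is the cross-table of
nuclear cluster against mitochondrial haplogroup; asymmetric introgression
is flagged when exactly one off-diagonal cell is occupied.

## Phenotypes

`nested_anova()` compares ordinary least-squares fits of nested models.
With the full-model mean square as denominator: the group effect corrected
for sex compares `trait ~ sex` against `trait ~ sex + group` (1 df); any
sex effect compares `trait ~ group` against `trait ~ sex * group` (2 df);
group-specific dimorphism compares the additive against the interaction
model (1 df). Post-hoc Welch t-tests compare the sexes within each group.
The outlier screen flags values below Q1 − 3·IQR within their group — a
reproducible stand-in for the visual screen of aberrantly low call
frequencies; the pipeline applies it to the call-frequency data after
excluding relaxed-rule nuclear hybrids and mtDNA-discordant individuals,
mirroring the study's exclusions.

## The synthetic-data generator

`sim_config()` defaults encode the study design: 325 + 423 individuals, 15
loci with 2–17 alleles, 1.3% missing genotypes, barcodes for a 38 + 42
subsample, mitochondrial introgression probability 0.158 from the B
haplogroup into A-nuclear individuals (none in reverse), barcode divergence
0.057 between and 0.0015/0.0077 within haplogroups, and phenotypes with
dimorphism only where observed (forearm: species B; call frequency: species
A). Differentiation is parameterised by the F-model drift rather than by a
target $\theta$; `calibrate_drift_F()` maps a target to a drift value by
simulation, and the shipped default `drift_F = 0.14` was calibrated that
way for $\theta = 0.139$ (across datasets of this size the realized
multilocus $\theta$ then scatters around 0.139 with an sd of roughly
0.025 — locus sampling noise with 15 loci, matching the width of the
bootstrap CI the estimator itself reports). Phenotype standard deviations
are those implied by reported 95% CIs and sample sizes
($sd = \text{half-width} \cdot \sqrt{n}/1.96$); measured subsample sizes
(172/306 forearms, 62/72 call frequencies, 5 planted low outliers in
species B) mirror the study's data availability. Sexes are drawn 1:1
because per-species sex ratios among genotyped animals are a free
parameter of the design; caves and sessions are sampling labels without
genetic structure, as none was found.

What the generator does **not** emulate: stepwise microsatellite mutation,
linkage, within-species spatial structure, rate heterogeneity along the
barcode, and pedigree depth beyond one generation of hybrid classes.
Passing tests therefore demonstrate that the estimators and the decision
procedure behave correctly under the study's statistical structure, not
that they are robust to, say, severe null-allele loads or isolation by
distance.

## Reproducibility and problem sizes

Every stochastic routine accepts a seed; the pipeline derives per-stage
seeds deterministically from one global seed, so stages can be re-run in
isolation and two runs with the same seed produce identical reports. The
test-suite and the acceptance script run the full design (748 individuals,
15 loci) with the desk MCMC preset, three runs per K for the Evanno scan,
1000 permutations per test and the complete 30-replicate misclassification
study; oracle comparisons (variance components, raw distances, residual
arithmetic) use small fuzzed instances where literal transcriptions of the
published formulas are feasible.
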