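# cryptohyb

Genetic analysis of two sympatric cryptic species from microsatellite
genotypes, a mitochondrial barcode and simple phenotypes — the situation of
mormoopid bat species complexes, where morphologically indistinguishable
lineages co-occur in the same caves and must be told apart (and their
hybrids found) genetically. The package is for population geneticists who
want this classical workflow as scriptable, seeded, testable R functions
rather than a chain of GUI programs (STRUCTURE, CLUMPP, FSTAT,
Micro-Checker).

## What it implements

* **Bayesian admixture clustering** of diploid co-dominant genotypes under
  the correlated-allele-frequency (F-model) prior: a Gibbs sampler (Rcpp)
  over allele-copy origins *Z*, cluster frequencies *P* (Dirichlet updates
  with Metropolis steps for the ancestral frequencies and per-cluster drift
  *F<sub>k</sub>*), ancestries *Q* ~ Dir(α + counts) and the concentration
  α. Per-individual ancestry `q` comes with a 90% credibility interval
  computed from the Rao-Blackwellised Beta-mixture posterior. Multi-run
  label alignment and Evanno's ΔK = |L(K+1) − 2L(K) + L(K−1)| / sd(L(K))
  select and summarise K.
* **Simulation-calibrated hybrid detection**: gamete-level simulation of
  parental, F1, F2 and backcross classes from the 80 highest-q reference
  parents per cluster; thresholds TP1/TP2 = lowest simulated-parental q per
  cluster; conservative (mean q) and relaxed (90%-CI lower bound)
  classification; a 30-replicate parental-misclassification study.
* **Weir–Cockerham F-statistics**: per-allele variance components a, b, c;
  multilocus θ = Σa / Σ(a+b+c) with a bootstrap CI over loci; per-locus
  Na/Ho/He/F<sub>IS</sub> tables; pairwise θ with exact-G permutation
  tests; Hardy–Weinberg and linkage-disequilibrium permutation screens;
  Chakraborty/Brookfield null-allele estimation with exact binomial tests;
  an F<sub>ST</sub>-based sex-biased dispersal randomization test.
* **Mitochondrial barcode**: raw p-distances with pairwise deletion,
  single-linkage haplogroup partition, within/between divergence summaries,
  and cyto-nuclear discordance tables that flag asymmetric introgression.
* **Phenotypes**: nested two-way ANOVA (group effect corrected for sex, any
  sex effect, group-specific dimorphism) with Welch post-hoc tests and an
  IQR-based low-outlier screen.
* **A synthetic-data generator** with ground truth that emulates the study
  design (325 + 423 individuals, 15 loci, θ ≈ 0.139, 1.3% missing data,
  asymmetric mtDNA introgression at 0.158, dimorphic phenotypes), used by
  the tests and the acceptance script.

## Worked example

```r
library(cryptohyb)
ds <- simulate_dataset(sim_config(), seed = 7)   # synthetic two-species study
validate_dataset(ds$genotypes, ds$metadata)
run  <- run_admixture(ds$genotypes, desk_mcmc_config(seed = 7))
cons <- align_runs(list(run))
table(assign_clusters(cons)$cluster)
wc_theta(ds$genotypes, assign_clusters(cons)$cluster, n_boot = 1000, seed = 7)
haplogroup_partition(raw_distance(ds$sequences))
```

```
genotype_matrix: 748 individuals x 15 loci (1.3% missing calls)
validation_report: 748 individuals, 15 loci, amplification 98.7%
  alleles per locus: 3-15; 0 issue(s)

  1   2
423 325
fst_result: theta = 0.1248 [0.0950-0.1649]95% over 15 loci
haplogroup_partition: 2 group(s) at cutoff 0.020; within 0.0018/0.0077; between 0.0565
```

The clustering splits the 748 genotypes into the two simulated species (423
vs 325 individuals, all correctly recovered); the multilocus Weir–Cockerham
θ of 0.125 [0.095–0.165] measures their differentiation (the generator's
design value is 0.139; with 15 loci the realized θ of any one dataset
scatters by about ±0.025, which is exactly what the bootstrap CI reflects);
and the barcode splits into two haplogroups diverging by 5.7% between and
0.2%/0.8% within — the raw material for the cyto-nuclear discordance count.

`run_pipeline(pipeline_config(...))` chains everything — validation, locus
quality screens and exclusion, Evanno scan, consensus clustering, hybrid
thresholds and classification, F-statistics, dispersal tests, haplogroups,
discordance and phenotype ANOVAs — into one reproducible report; a thin CLI
lives at `inst/cli/cryptohyb.R`.

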