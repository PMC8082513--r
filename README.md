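# studbook

Pedigree-based population structure and genetic diversity analysis for
livestock studbooks, with an emphasis on sport-horse populations: closed
registries in which a narrow group of heavily used sires can erode genetic
variation within a few generations. The package is aimed at breed
associations, conservation geneticists and quantitative geneticists who need
the classic herdbook monitoring parameters from nothing but a pedigree table
(animal, sire, dam, sex, birth year, registry label).

## What it computes

Given a pedigree and a *reference population* (the animals whose diversity
is being characterized), `studbook` estimates:

* **Pedigree structure** — founders (animals with both parents unknown),
  non-founders, full-sib groups, longest ancestral path (LAP), and the four
  path generation intervals L (father–son, father–daughter, mother–son,
  mother–daughter) with their pooled total.
* **Pedigree depth/completeness** — equivalent complete generations
  g_e = Σ (1/2)^g over all known-ancestor paths, and the completeness index
  C_p = a_k / Σ_{i=1..5} 2^i over five ancestor generations.
* **Homozygosity** — individual inbreeding coefficients F by the
  Meuwissen–Luo algorithm (linear memory, C++ core; F = diag(A) − 1 of
  Wright's numerator relationship matrix A without building A), the
  individual increase in inbreeding ΔF = 1 − (1 − F)^(1/(t−1)) with t the
  animal's own g_e, the realized effective population size
  Ne = 1 / (2·mean ΔF), and within/between group mean coancestries f
  (numerator relationship = 2f) by memoized kinship recursion.
* **Probability of gene origin** — founder contributions p_i, effective
  number of founders f_e = 1/Σp_i², gene-drop allele retention r_i, founder
  genome equivalent f_ge = 1/Σ(p_i²/r_i), effective number of non-founders
  N_enf = (1/f_ge − 1/f_e)⁻¹, and the diversity measures GD = 1 − 1/(2f_ge)
  and GD* = 1 − 1/(2f_e), whose gap partitions the diversity loss into
  founder-inequality and drift/bottleneck components.
* **Founder decomposition of inbreeding** — each animal's F partitioned by
  the founder from which the identical-by-descent allele pair descends, and
  vf_j, the percentage of the group's mean F attributable to founder j.

A synthetic studbook generator (`simulate_pedigree()`) with overlapping
generations, polygamous sires, dam reuse, breed-lineage labels and
incomplete parent recording makes every estimator testable without
confidential herdbook data.

## Worked example

```r
library(studbook)

ped <- simulate_pedigree(sim_config(
  n_founders = 60, founder_sex_ratio = 0.4, n_years = 6,
  offspring_per_year = 50, n_active_sires = 5, sire_concentration = 0.3,
  missing_parent_rate = 0.05, reference_fraction = 0.5, n_breeds = 3,
  seed = 42))

bundle <- run_analysis(ped, group_by = "birth_year",
                       replicates = 2000, seed = 42)
bundle
```

```
Pedigree structure
  animals: 360 (186 male / 174 female)
  founders: 60   non-founders: 300 (both parents known: 272)
  full-sib groups: 51   LAP: 2 generations   mean max generations: 1.19

Homozygosity by group:
 group   n F_pct pct_inbred mean_coancestry_pct delta_F_pct Ne
  1999  23 0.000    0.00000               6.769       0.000 NA
  ...
  2004  26 3.365   26.92308               4.423       3.365 15
 total 155 0.968    7.74194               1.960       0.968 52

Gene-origin diversity by group:
 group   n f_e f_ge N_enf      GD GD_star loss_total_pct loss_founder_pct
  1999  23   6    6    91 0.91238 0.91787          8.762            8.213
  ...
 total 155  23   22  1029 0.97761 0.97810          2.239            2.190
```

Reading the output: five licensed sires with strongly unequal use per season
push mean inbreeding from 0 to 3.4% across six cohorts, collapse the
realized effective population size to 15 by the last cohort, and compress
360 recorded animals into an effective 23 founders / 22 founder genomes for
the pooled reference; the gap between `loss_total_pct` (1 − GD) and
`loss_founder_pct` (1 − GD*) is the share of diversity lost to drift and
bottlenecks rather than founder inequality. The founder decomposition ranks
the individual founders behind that mean inbreeding:

```r
head(bundle$decomposition$table, 3)
#   founder          p     F_share       vf
# 1  F00036 0.11129032 0.003225806 33.33333
# 2  F00058 0.08064516 0.003225806 33.33333
# 3  F00007 0.04677419 0.001612903 16.66667
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/pedigree-diversity.R`
(`simulate` / `structure` / `analyze` subcommands).

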