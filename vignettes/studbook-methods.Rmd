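---
title: "Pedigree-based diversity estimation in studbook: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree-based diversity estimation in studbook}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(studbook)
```

## The problem

Closed animal registries — sport-horse studbooks being the motivating case —
monitor genetic variation from pedigree data alone. Two families of
parameters dominate that practice. The first is built on identity by
descent: the inbreeding coefficient $F_i$ (probability that an animal's two
alleles at a locus are copies of one ancestral allele), the kinship or
coancestry $f_{ab}$ between animals (numerator relationship $a_{ab} = 2
f_{ab}$), the per-generation rate $\Delta F$ and the realized effective
population size $N_e$. The second is built on the probability of gene
origin: the expected contribution $p_i$ of each founder to the reference
population, the effective number of founders $f_e$, the founder genome
equivalent $f_{ge}$ estimated by gene dropping, the effective number of
non-founders $N_{enf}$, and the heterozygosity-style diversity measures $GD$
and $GD^{*}$. `studbook` implements both families plus a founder
decomposition of mean inbreeding, behind one validated pedigree container.

All estimators assume the pedigree is a directed acyclic graph in which
every animal has at most one recorded sire and dam, founders are unrelated
and non-inbred, and unknown parents are unrelated to everything. These are
the standard assumptions of the numerator relationship matrix; they are
conservative in the sense that missing pedigree can only hide, never
invent, identity by descent (erasing a parent link never increases any
$F_i$ — a property the test suite checks).

## The pedigree container

`pedigree()` validates identifiers (non-empty, unique, no self-parenting),
normalizes the unknown-parent codes `0`, `""` and `"NA"` that coexist in
livestock pedigree files, materializes parents that appear only in
sire/dam columns as founder records (studbook extracts routinely omit
founder rows), and stores animals in a stable parent-first topological
order. Stability means animals not constrained relative to one another keep
their input order, so an already-sorted file round-trips unchanged; the
recursive estimators all rely on the parent-first invariant.
`validate_pedigree()` is deliberately report-only: sex/role conflicts and
cycles are errors, but an offspring recorded in or before a parent's birth
year is only a warning, because historical studbooks contain year typos and
no estimator uses birth years except for grouping and generation intervals.

## Identity-by-descent estimators

**Inbreeding.** $F$ is computed by the Meuwissen–Luo ancestor-tracing
algorithm (C++ core): for animal $i$, path coefficients $L_j$ are
accumulated over its ancestors and $F_i = \sum_j L_j^2 D_j - 1$, with
Mendelian sampling variance $D_j = 0.5 - 0.25(F_{s(j)} + F_{d(j)})$ (0.75
minus a quarter of the known parent's $F$ when one parent is unknown, 1 for
founders). Memory is linear in pedigree size; a 12,860-animal simulated
studbook runs in well under a second. The independent cross-check in the
tests is the tabular relationship matrix (`relationship_matrix()`), a
different algorithm whose diagonal minus one must agree to $10^{-12}$.

**Kinship.** Pairwise kinship uses the classic recursion
$f_{ab} = \tfrac12\,(f_{a,s(b)} + f_{a,d(b)})$, recursing on the pair member
that appears *later* in topological order — the tie-break that guarantees
termination — with $f_{aa} = (1 + F_a)/2$ and memoization of every evaluated
pair. Group means therefore never materialize the full matrix. Two
within-group conventions are exposed: the default excludes self-pairs
(matching the between-group convention, where groups must be disjoint);
`include_self = TRUE` uses the matrix-mean convention (every ordered pair,
self included), since published "total coancestry" figures are not always
explicit about which convention they used.

**Rates and $N_e$.** $\Delta F_i = 1 - (1 - F_i)^{1/(t_i - 1)}$ uses each
animal's *own* equivalent complete generations $t_i$, not a group mean:
the quantity is an individual increase in inbreeding, and using individual
depth prevents shallow pedigrees from diluting deep ones. For $t_i \le 1$
the rate is 0 when $F_i = 0$ and `NaN` (undefined) otherwise; undefined
rates are dropped from group means. $N_e = 1/(2\,\overline{\Delta F})$ is
computed on the proportion scale and only rounded for display, so the
identity $N_e \times 2 \overline{\Delta F} = 1$ holds exactly on the stored
values.

## Probability of gene origin

**Contributions.** Each reference animal's genome is propagated backward,
halving at every parent link. Mass reaching a founder accumulates into
$p_i$; mass reaching an unknown parent of a non-founder accumulates into a
*phantom* residual, so $\sum_i p_i + \mathrm{residual} = 1$ identically.
$f_e = 1/\sum p_i^2$ is computed over true founders with $p$ renormalized
by $1 - \mathrm{residual}$; treating every unknown-parent slot as a distinct
founder would make $f_e$ grow with pedigree incompleteness, which is the
opposite of what a completeness-corrected diversity parameter should do.

**Gene dropping.** Every replicate assigns two unique alleles per founder
and transmits one allele from each parent down the ordered pedigree with
probability 1/2. $r_i$ is the mean fraction (0, 1/2 or 1 per replicate) of
founder $i$'s two alleles surviving among the reference animals — allele
*survival*, not allele frequency, which is the construction under which
$f_{ge} = 1/\sum(p_i^2/r_i)$ is the founder genome equivalent. Defaults:
10,000 replicates, explicit integer seed, Monte-Carlo standard errors always
reported. The test oracle is exact enumeration of all $2^m$ transmission
patterns on toy pedigrees ($m \le 14$ meioses); at 20,000 replicates the
estimate must sit within 0.01 of the enumerated truth.

**Diversity identities.** $GD = 1 - 1/(2 f_{ge})$, $GD^{*} = 1 - 1/(2 f_e)$,
$N_{enf} = (1/f_{ge} - 1/f_e)^{-1}$. These definitions force
$GD^{*} - GD = 1/(2 N_{enf})$, and that is the identity the package
implements and tests; the variant "$1 - 1/(2N_{enf})$" that sometimes
appears in print is algebraically inconsistent with the other three
definitions (substituting $f_e = f_{ge}$ makes it claim a diversity gap of
1) and is treated as a typesetting artifact. $f_{ge} = f_e$ yields
$N_{enf} = \infty$, reported as such rather than as an error.

## Founder decomposition of mean inbreeding

The decomposition answers "which founders are behind the observed
inbreeding?". Define $F_i^{(j)}$ as the probability that animal $i$'s IBD
allele pair descends from source $j$. It is computed exactly by a
founder-partitioned kinship recursion that mirrors the standard recursion:
for founder $g$, partitioned self-kinship is $1/2$ toward $g$ and 0
elsewhere; for non-founder $a$,
$\phi_j(a,a) = \tfrac12\,(p_j(a) + \phi_j(s(a), d(a)))$ where $p_j(a)$ is
source $j$'s genetic contribution to $a$; and for distinct animals the
recursion halves over the later animal's parents. Sources are the true
founders *plus one phantom per unknown-parent slot*, which makes the
partition conserve exactly: $\sum_j F_i^{(j)} = F_i$ to $10^{-10}$ on every
animal, inbred loops through incompletely recorded ancestors included. The
headline quantity is $vf_j = 100 \cdot \overline{F^{(j)}} / \overline{F}$
over true founders, with the phantom mass reported as a residual
percentage; a Monte-Carlo alternative traces IBD founder origin inside the
gene-drop replicates and must agree with the exact partition within a few
Monte-Carlo standard errors. The component diagnostics exposed alongside
$vf$ are the founder contribution vector ($v$), the Mendelian sampling
variances of all ancestors ($m$) and the expected genetic contribution of
every ancestor, not only founders, to the reference genome ($u$). If the
reference has mean $F = 0$ there is nothing to decompose and $vf$ is
reported as undefined rather than as zeros.

## Structure metrics and conventions

* Equivalent complete generations use the recursion
  $g_e(i) = \sum_{p \in \text{known parents}} (1 + g_e(p))/2$, which equals
  the sum of $(1/2)^g$ over every distinct ancestor *path* (verified against
  brute-force path enumeration). $g_e = 0$ iff both parents are unknown and
  $g_e = d$ on a pedigree complete to depth $d$.
* Completeness $C_p$ defaults to depth 5 (62 ancestor slots); an ancestor
  occupying several slots counts once per slot.
* The mean number of ancestor generations reported by `count_structure()`
  is the mean per-animal *longest* ancestral path (the common
  pedigree-software convention) over a caller-chosen subset, defaulting to
  the whole pedigree.
* Generation intervals are integer birth-year differences (studbook
  extracts carry no birth dates) along the four sex paths; the default
  restricts to offspring that themselves reproduced (the classical
  definition), with `all_offspring` selectable. The pooled total is the
  pair-count-weighted mean; the unweighted four-path mean is also reported
  since both appear in published tables. Pairs missing a birth year are
  dropped and counted. Full-sib groups require both parents known and at
  least two offspring.

## The synthetic studbook generator

`simulate_pedigree()` emulates the features the estimators are sensitive
to: overlapping generations (parents eligible from age 3 to 20, so cohort
animals breed alongside founders), a small licensed-sire pool whose yearly
use weights are drawn once from a symmetric Dirichlet — the
`sire_concentration` knob turns equal use (large values) into one or two
dominant sires (small values) —, dams resting between seasons
(`dam_reuse_rate`), founder-lineage breed labels with geometrically
decaying frequencies and a low cross-breed mating rate (default 10%), and
independent erasure of recorded parent links (`missing_parent_rate`).
Default sizes mirror a championship-scale warmblood studbook: 1,621
founders, thirteen cohorts (1999–2011) of 865 foals, and a reference flag
drawn at 9% per cohort animal so the reference population (~1,050 animals)
spans all cohorts. The `reference_fraction` parameter is interpreted as
that per-animal flag probability rather than as a count of trailing cohorts
flagged wholesale, because reference populations in practice (e.g.
championship participants) are spread across birth years.

What the generator does *not* emulate: deep multi-decade ancestry (its
longest ancestral paths stay far below the 15 generations real studbooks
reach — the `chain15` toy covers that regime), real breed-history migration,
selection on performance, and dataset-specific headline values; passing
tests therefore demonstrate estimator correctness and qualitative dynamics
(bottlenecks raise inbreeding and coancestry; sire-pool enlargement lowers
them), not numerical agreement with any particular breed's statistics.

## Numerical choices and problem sizes

Exact identities are tested at $10^{-12}$ (Meuwissen–Luo vs tabular,
kinship vs the relationship matrix), propagation-based identities at
$10^{-10}$ (partition conservation, mass conservation, recursive vs tabular
group means), and Monte-Carlo results at 3–4 standard errors. Degenerate
inputs have defined behavior rather than errors where a value is
meaningful: empty reference or empty group is an error, $\overline{\Delta F}
= 0$ gives $N_e = \infty$, a singleton group's within-mean coancestry is
`NA`, and mean $F = 0$ makes $vf$ undefined. The test suite runs simulated
pedigrees of 50–400 animals (50 replicates of ~300 animals for the
inbreeding cross-check, 30 paired replicates for the bottleneck trend, 8–20
thousand gene-drop replicates on toys); these sizes were chosen so the
whole suite exercises every code path in seconds while keeping Monte-Carlo
assertions well-powered.

## Known limitations

Pairwise-kinship group means are quadratic in group size and the dense
tabular matrix is quadratic in pedigree size; both are intended for groups
of at most a few thousand animals. The package does not ingest genotypes,
compute marker-based inbreeding or runs of homozygosity, implement optimal
contribution selection, or attempt the "pedigree lines" count that some
legacy reports print without defining.
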