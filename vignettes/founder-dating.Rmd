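---
title: "Founder haplotype analysis and STR-based dating: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Founder haplotype analysis and STR-based dating: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(founderhap)
```

This vignette documents the models and procedures implemented in
`founderhap`, the assumptions behind them, the parameters that matter and
why their defaults were chosen, and the limits of what the package's
validation can show.

## The setting

Machado-Joseph disease (spinocerebellar ataxia type 3) is a dominant
ataxia caused by a CAG-repeat expansion in *ATXN3*. The marker panel
shipped with the package covers 20 SNPs within a few kilobases of the
repeat and 7 flanking microsatellites (STRs); the repeat itself is the
anchor at offset zero, lying between rs10467856 and rs12895357. Because
recombination between such tightly linked markers and the expansion is
rare, the alleles in phase with an expansion are inherited as a block —
the disease haplotype — and their diversity among today's patients
records the history of the founding mutation event.

Two ancestral SNP backgrounds are described for MJD expansions over the
six core SNPs (rs12590497, rs16999141, rs1048755, rs12895357, rs7158733,
rs3092822): the Joseph lineage T-T-A-C-A-C and the Machado lineage
G-C-G-G-C-A. The package classifies observed disease haplotypes against
these references; the extended 20-SNP comparison is available for the
Joseph lineage only, because no extended Machado reference exists for
this marker set and inventing reference alleles would be worse than
declining to compare.

## Phasing

**Segregation phasing.** For each non-founding individual and each
marker, the paternal/maternal assignment of the two alleles is fixed
exactly when Mendelian transmission forces it: the child is homozygous,
or only one parent-of-origin assignment of a heterozygous genotype is
compatible with the parents' genotypes (the classic case being one
homozygous parent). Nothing is ever guessed: markers whose phase is not
forced stay unresolved. The expansion is modelled as a binary
pseudo-marker (`E`/`N`) at the anchor, derived from each individual's
expanded-chromosome count (0, 1, or 2 — a patient homozygous for the
expansion carries 2 and both of their haplotypes are disease
haplotypes). This turns "which haplotype is in phase with the expansion"
into an ordinary phase query with no special-cased logic.

Founders are phased through their transmitted gametes: each child's
resolved paternal (or maternal) alleles reconstruct one gamete of that
parent, assuming no recombination within the panel during the
transmissions observed; gametes that carry the expansion merge into the
founder's disease-side haplotype. Disagreements between gametes on the
same side are recorded as conflicts (they indicate within-family
recombination), and a family's disease haplotype is only reported when
the carriers' expansion-phased haplotypes can be reconciled into at most
as many haplotypes as expanded chromosomes entered the family through
its founders. A child allele absent from both parents is a Mendelian
inconsistency and aborts the family's phasing with a report naming every
offending individual and marker — with curated clinical data this is a
data error to fix, not something to correct silently.

**EM frequency estimation.** For unrelated individuals the package
implements the classic expectation-maximisation estimator of haplotype
frequencies from unphased multilocus genotypes. Each individual's
likelihood sums over the haplotype pairs compatible with their genotype
(missing genotypes are marginalised over the marker's domain);
frequencies are initialised uniformly over every haplotype compatible
with at least one individual, which makes the estimator deterministic —
no random restarts by default, so the configuration seed is inert unless
restarts are requested. The observed-data log-likelihood is
non-decreasing across iterations (a property the tests assert), and
iteration stops when it improves by less than `em_tolerance` (default
1e-8, a scale far below one likelihood unit) or after
`em_max_iterations` (default 1000). Downstream haplotype lists apply the
retention rule strictly: a pair is kept only when its posterior exceeds
0.6 (`>`, not `>=`, following the rule's wording). EM finds local maxima
of a multimodal likelihood; for panels of this size and the sample sizes
involved the likelihood surface is benign, but the estimator is a
deliberate stand-in for full Bayesian phasing, not a replacement.

## Association statistics

The linkage-disequilibrium delta statistic is

$$\delta = \frac{F_d - F_c}{1 - F_c},$$

with $F_d$ and $F_c$ the haplotype (or allele) frequencies on disease
and control chromosomes. It satisfies $\delta(F, F) = 0$ and
$\delta(x, 0) = x$, is strictly increasing in $F_d$, and is reported
signed: the packaged frequency table contains one row (T-T-G-G-A-C)
whose printed value (0.003) disagrees with the formula, which gives a
negative value; the package reports the signed computed value and flags
the discrepancy instead of reproducing it. A second, smaller printing
artefact: for T-T-A-G-A-C the formula applied to the table's 3-decimal
frequencies gives 0.2985 (rounding to 0.299) where the table prints
0.298 — the printed value evidently comes from unrounded source
frequencies, and the package again reports what it computes.
Frequencies are kept at full precision internally and rounded only for
display (3 decimals, matching the tables).

Hardy-Weinberg testing exposes two conventions, because genotype classes
as small as 3 make the chi-square approximation poor and the convention
behind the printed p-values is not stated:

* `exact` (default) — enumerates every heterozygote count compatible
  with the observed allele counts under random union of gametes and sums
  the probabilities of all configurations no more probable than the one
  observed (ties included up to a 1e-7 relative tolerance, so the result
  is bit-reproducible);
* `chi_square_gof` — observed genotype counts against the $p^2, 2pq,
  q^2$ expectations, one degree of freedom, no continuity correction.

For the genotype counts (46, 60, 3) these give p = 0.0014 and p = 0.0015
respectively; the corresponding printed value is 0.007, which matches
neither convention — the reproduction report labels such values
not-reproducible rather than forcing agreement. Monomorphic markers make
the exact test degenerate; it returns p = 1 with a warning. The Fisher
exact test is two-sided by the "sum of tables at most as probable"
convention, computed by hypergeometric enumeration; the case-control
allele test is Pearson's chi-square without continuity correction. No
multiple-testing correction is applied anywhere, matching the analysis
the tables report. Tests cross-check the exact Hardy-Weinberg p-values
against a brute-force enumeration oracle for every genotype table with
up to 20 individuals, and the Fisher p-values against both an
independent tail-sum oracle and `stats::fisher.test`.

## STR distances, ancestors, networks

Two step-distance conventions over 7-locus repeat-count vectors are
first-class:

* `locus_count` — the number of loci whose repeat counts differ;
* `stepwise_sum` — the summed absolute repeat-count difference, i.e.
  the mutation count under a strict single-step mutation model.

Both are metrics. `locus_count` is the default everywhere: calibrated
against the packaged lineage data, mean locus-count steps with standard
STR mutation rates land inside the printed age range, while
`stepwise_sum` dates come out roughly 2–3× older (the exact factor per
lineage is the ratio of the two mean step counts, which the tests pin
down). Counting a locus once regardless of how far it has drifted also
makes the estimate robust to the occasional multi-step mutation.

The ancestral haplotype of a lineage is the locus-wise modal haplotype.
When a locus has tied modal alleles, every combination of tied alleles
is evaluated and the candidate minimising the total step distance to the
sample wins; a residual tie falls to the numerically smallest allele,
locus by locus, and every applied tie-break is reported (lineage A's
(GT)n locus, tied 16 vs 20 with four chromosomes each, is the packaged
example: both candidates give the same total distance and the rule picks
16). For `locus_count` the locus-wise mode provably minimises the total
distance among all haplotypes assembled from observed alleles — a
property the tests verify by exhaustive search on small allele grids.

Networks over distinct haplotypes are minimum-spanning networks:
Kruskal's construction processed in weight levels, keeping every edge of
a level that joins components as they stood before the level — i.e. the
union of all minimum spanning trees — so tied alternative paths are
retained as cycles instead of being broken arbitrarily. Node identity is
the exact 7-tuple (no binning); multiplicities become node sizes; the
modal ancestor is marked, and added as an explicit zero-multiplicity
median node if unobserved. Full median-joining with inferred
intermediate vectors is deliberately out of scope, since no specific
network algorithm is attached to the published figures; topology-level
agreement with them is therefore not claimed. Export goes through
igraph's GraphML and DOT writers.

## Founder dating

With per-locus per-generation mutation probability $\mu$, interval
recombination probability $c$, and $L$ loci, the probability that a
disease haplotype changes in one generation is

$$\varepsilon = 1 - (1 - c)\,(1 - \mu)^{L}.$$

The single-locus case reduces to the classic $1-(1-c)(1-\mu)$; the
multiplicative composition across loci is used because $\lambda$ counts
changes anywhere on the haplotype. After $t$ generations the expected
number of change events per chromosome is $\lambda = \varepsilon t$, so
the age estimate inverts this: $\hat t = \hat\lambda / \varepsilon$
generations, $\hat\lambda$ being the mean step distance from the
inferred ancestor, converted to years by the generation time $g$.

The three rate parameters cannot be estimated from the haplotype data
themselves and are therefore explicit, logged configuration values:

| parameter | default | units | rationale |
|---|---|---|---|
| $\mu$ | 5.6e-4 | mutations/locus/generation | standard dinucleotide-STR rate used across the founder-dating literature |
| $c$ | 0 | recombinations/generation | the panel spans a short, tightly linked interval; recombinant haplotypes in families are flagged and excluded rather than modelled |
| $g$ | 25 | years/generation | conventional human generation time in founder-dating studies |

Age scales almost exactly as $1/\mu$ at $c = 0$ (exactly so for a
single locus; the 7-locus composition deviates by ~0.2% at the default
rate), so the choice of $\mu$ is the dominant systematic: all dates
should be read as conditional on the rate model, which every output
object carries alongside the estimate.

Three caveats are inherent to the estimator and are kept visible rather
than papered over:

* **Saturation.** `locus_count` registers at most one change per locus,
  so $\hat\lambda$ underestimates the change count once $\mu t$ per
  locus approaches 0.1 (old founders); back-mutation of the ±1 process
  adds a smaller underestimate. The simulator's tests demonstrate both
  effects directly.
* **Ancestor inference.** The modal haplotype is itself estimated from
  the sample; the bootstrap re-infers it per resample so that this
  uncertainty is inside the standard error.
* **Counting convention.** Simple mean-step counting reproduces two of
  the four packaged lineage ages within their printed ±SD intervals (A
  and D) but not the other two (B and G), for which the published
  counting convention cannot be recovered; `date_all_lineages()` reports
  the comparison per lineage and the discrepancy is flagged, not
  reconciled. The meaning of the printed ± values (SD, SE, or CI) is
  likewise unstated; the package's own uncertainty is a defined
  quantity: a seeded nonparametric bootstrap SD over chromosomes (1,000
  resamples by default).

Degenerate inputs behave explicitly: $\hat\lambda = 0$ dates to age 0;
$\varepsilon = 0$ with positive diversity is an error ("undefined age")
rather than infinity; a sample of one chromosome cannot be
bootstrapped.

## The simulator: what it emulates, what it does not

`simulate_founder_sample()` generates the exact process the dating model
assumes: a star genealogy in which each sampled chromosome descends
independently from the founder, each locus mutating per generation with
probability $\mu$ by one repeat unit up or down (reflecting floor at one
repeat), and with probability $c$ the segment downstream of a uniform
inter-locus breakpoint replaced from a background haplotype pool — the
simplest mechanism consistent with "reorganisation" of a flanking
haplotype. The truth output records each chromosome's realized mutation
events, recombination events, and the number of generations in which it
changed at all; the expectation of that last count is exactly
$\varepsilon t$, which is the identity the acceptance tests verify at
2,000 chromosomes. Under a fixed seed the simulator is reproducible
(integer repeat arithmetic; one RNG stream consumed in a documented
order, with a binomial-count shortcut used only when $c = 0$, where it
is distributionally exact).

The star genealogy is a deliberate idealisation: real disease
chromosomes share genealogy below the founder, which correlates their
accumulated changes and makes the effective number of independent
lineages smaller than the sample size. Passing recovery tests under the
star model therefore shows the estimator is correct *under its own
assumptions*; it does not bound the extra variance (or the drift of the
modal ancestor) that shared genealogy contributes in real cohorts. The
simulator also excludes multi-step STR mutations, mutation-rate
heterogeneity across loci, CAG-repeat instability, and any demography.

`simulate_family()` draws founder haplotype pairs from a pool and drops
them through two- or three-generation pedigrees without intra-panel
recombination, emitting unphased genotypes plus the phased truth. The
phasing tests use it for round-trip validation: every marker the
segregation phaser resolves must match the simulated truth, and every
trio-forced marker must be resolved.

**Validation problem sizes.** The recovery experiment used by the
acceptance tests runs 200 replicates each at true ages of 100, 300 and
500 generations with 10 chromosomes per replicate — a cohort size
matching the packaged lineages (8–12 chromosomes) — and requires the
pooled median relative error of $\hat t$ across the grid to stay within
25%. At 10 chromosomes and 100 generations the expected total change
count is only about 4, so individual grid points sit close to that
bound by sampling noise alone; the pooled median is the stable summary.
The identity check $E[\lambda] = \varepsilon t$ uses 2,000 chromosomes
at 300 generations against a 3-Monte-Carlo-SE band on realized change
counts.

## Data-table conventions

The packaged transcriptions keep the printed data verbatim, including
their oddities: one family appears under both lineages A and D and is
kept in both with distinct row identifiers (the family counts therefore
sum to 51 against a stated cohort of 50 — both numbers are reported);
one annotated repeat entry ("7 (5)") is stored as primary value 7 with
the 5 in an annotation column that no computation consumes by default.
STR physical offsets come from the kilobase tags in the locus names
(e.g. TAT_223 → 223 kb); the two unlabelled loci, (AAAC)n and (GT)n,
and the four SNPs without sub-kilobase position tags carry order-only
placeholder offsets that preserve the published marker order — offsets
order the panel and place the anchor, and nothing downstream consumes
their magnitudes. Genotype files use a human-editable dialect:
tab-separated, unordered `a/b` cells, `.` for missing; pedigrees use the
six standard PED columns plus an optional expanded-chromosome count.

## Known limitations

* Segregation phasing uses parent-offspring information only; it does
  not exploit more distant relatives, linkage across markers, or
  population haplotype frequencies, and unresolved markers stay `NA`.
* The EM estimator enumerates compatible pairs exhaustively, which is
  exponential in heterozygous/missing sites per individual; it is meant
  for core-haplotype panels (a guard refuses configurations beyond 2e5
  combinations).
* Dating assumes the rate model wholesale; no attempt is made to
  estimate $\mu$, $c$ or $g$ from data, to model coalescent structure,
  or to produce likelihood-based intervals.
* The 20-SNP lineage comparison exists for the Joseph background only.
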