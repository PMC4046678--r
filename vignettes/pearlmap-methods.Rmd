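---
title: "Linkage-map construction from mixed phase-known and phase-unknown pearl-oyster pedigrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linkage-map construction from mixed phase-known and phase-unknown pearl-oyster pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

pearlmap builds dense biallelic SNP linkage maps from the kind of mapping
resource used for the silver-lipped pearl oyster *Pinctada maxima*: a
handful of large full-sib families, most of them three-generation (so that
grandparental genotypes resolve the linkage phase of the mapping parents)
and some two-generation (phase unknown). This vignette explains the models
and the numerical choices; the README shows the worked example.

## The data model

Every computation runs off *informative meioses*. For each (parent,
offspring, marker) where the parent is heterozygous, the transmitted allele
is deduced from the mate and offspring genotypes where possible: a
homozygous offspring always reveals the parent's contribution, a
heterozygous offspring only when the mate is homozygous. Where the parent's
own parents are genotyped and jointly force which allele sits on which
grandparental haplotype, the transmission is *phase-known* and becomes a
grandparental-origin observation; otherwise it enters the likelihood as a
phase-unknown transmission. With the default simulated design
(14 F0, 118 F1, 219 F2 in 6 three-generation plus 2 two-generation
families, founder minor-allele frequencies 0.2-0.5) roughly 100-200
phase-known and 150-250 phase-unknown informative meioses accrue per
marker, comparable to the study design the package emulates.

## Two-point estimation

For a marker pair, phase-known meioses contribute a binomial kernel in the
recombination fraction theta; each phase-unknown parent contributes the
mixture `0.5 * [theta^k (1-theta)^(n-k) + theta^(n-k) (1-theta)^k]` over
its two relative phases, with `k` the mismatch count under an arbitrary
reference phase. The joint likelihood is maximised on [0, 0.5] by golden
section to a 1e-6 tolerance; the LOD is the log10 ratio against
theta = 0.5, where each parent's mixture equals `0.5^n`. Markers with fewer
than 10 informative meioses are excluded before grouping, mirroring the
attrition rule of the study design. The all-pairs scan screens pairs on a
coarse likelihood grid and refines everything above the reporting floor
(default LOD 0.1).

Phase-unknown mixtures rectify sampling noise (both `k` and `n - k` count
as linkage evidence), so their null LOD tail is heavier than the
chi-squared 1-df tail; under the default design the largest spurious
cross-chromosome LOD among ~80,000 pairs sits near 4.4. The grouping
thresholds below are calibrated with that in mind.

## Linkage-group formation

Grouping follows a five-layer relaxation, each layer a 4-tuple of
(minimum link LOD, minimum informative meioses, maximum linked groups,
minimum linkage ratio): (100, 2, 2, 0.9), (50, 1.5, 5, 0.8),
(20, 1, 8, 0.7), (10, 0.5, 10, 0.6), (5, 0.1, 15, 0.5). Within a layer,
unassigned markers join the group holding the largest share of their
qualifying links into groups (the ratio is computed over links into
groups, so a freshly seeded nucleus absorbs its neighbours chainwise);
still-unconnected markers seed new groups by single linkage. Two groups
merge when at least two marker-disjoint links of LOD >= 6 at theta <= 0.25
connect them: fragments of one chromosome bridge at adjacent-pair strength
(tens of LOD), while spurious cross-chromosome pairs stay below LOD 5, and
requiring disjoint support means a single bad pair or one promiscuous
marker can never fuse chromosomes. Groups are numbered by decreasing size.

Haplogroups (LOD >= 3 and theta <= 0.03) are taken as connected components
of the threshold graph, each represented by its most informative member.
On dense maps the components percolate along the chromosome, so the
primary set can be small; ordering handles that gracefully.

## Marker ordering

The multipoint likelihood is a no-interference Markov model along the
order: each gamete contributes, for every pair of consecutive observed
markers, a Bernoulli observation whose probability is the composed
fraction `0.5 * (1 - prod(1 - 2 theta_t))` over the spanned intervals.
Interval fractions are profiled by EM with a closed-form E-step. Two
classes of data enter: pooled spans between phase-resolved markers, and
per-parent phase-mixture classes for adjacent spans (a parent's phase
vector marginalises into independent per-interval flip bits, so this is
exact for completely observed gametes; longer mixture spans are excluded
from estimation because their flip bit absorbs recombinant excess and
biases theta downward). EM fractions are floored at 1e-4 on covered
intervals - zero is an absorbing state of this EM and silently reallocates
recombinants - and intervals with no covering data are flagged and set to
zero.

The order itself is found in three stages:

1. *Skeleton*: classical multidimensional scaling of the pairwise Kosambi
   distance matrix (linked pairs only, unlinked pairs capped) onto one
   axis. This is globally consistent - no reversed or translocated arms -
   with only local noise.
2. *Refinement*: the FLIPS window (all permutations of five consecutive
   markers, sweeps repeated to a fixpoint), single-marker re-insertion
   sweeps restricted to the slots flanking each marker's strongest
   two-point partners (LOD >= 3), and prefix/suffix reversal repair at
   junction-like intervals. Restricting insertion slots matters: the
   phase-mixture likelihood alone cannot veto a long-range misplacement,
   because a junction between distant blocks lets every parent re-fit its
   flip bit there.
3. *Placement support*: each marker, most informative first, is removed
   and re-inserted; the LOD gap between its best and second-best position
   assigns its tier (>= 3 framework, >= 2, >= 1, >= 0.5 most-likely
   position). Markers without a unique position are left unmapped, which
   reproduces the grouped-but-unmapped attrition class of low-information
   markers. Groups of up to seven markers get an exhaustive permutation
   search as the final refinement.

An exact phase-enumeration evaluator (`multipoint_loglik()` with fixed
fractions, up to 12 unresolved heterozygous markers per parent) backs the
oracle tests; the order search itself always uses the profiled kernel.

The double-recombinant audit reconstructs each gamete's origin string
along the final order and flags singleton origin switches. Genuine double
recombinants occur at a rate set by the flanking fractions, so a marker is
re-tested only when its singleton count exceeds a Poisson 99.5% bound on
that expectation; re-tested markers are re-inserted at their best position
and dropped if the excess persists.

## Sex-specific maps, metrics and tests

Sex maps keep the sex-average order fixed and re-profile interval
fractions from dam and sire meioses separately; intervals with fewer than
8 informative meioses for a sex are set to 0 cM and flagged. All distances
use the Kosambi function `d = 25 ln[(1+2 theta)/(1-2 theta)]`. Genome
coverage inflates each group by `(m+1)/(m-1)` and divides observed by
expected totals. Interval summaries report the per-group mean non-zero
interval (group length over non-zero interval count) and aggregate across
groups by the unweighted mean - the convention under which the published
per-group averages reproduce their printed overall mean (2.00 cM),
where the pooled mean would give about 1.7.

The heterochiasmy profile regresses cumulative standardised male position
on cumulative standardised female position within left/middle/right
segments. The published figure's axes are identified by its printed
slopes: the middle (centromeric) slope far below 1 where male
recombination is suppressed, outer slopes far above 1 where it is
inflated; the reverse orientation is also reported
(`slope_female_on_male`), which is the natural reading of a constructed
"female = 2 x male" example. Breakpoints are user-supplied, or chosen by
exhaustive residual-sum-of-squares search as an automatic stand-in for
the by-eye assignment.

Heterogeneity statistics use integer counts from phase-resolved (known
plus anchored) meioses, as the binomial-kernel forms require: the
sex-heterogeneity test is the 1-df likelihood-ratio chi-square
`2 [l(theta_f) + l(theta_m) - l(theta_joint)]`; per-group and genome
scopes sum interval chi-squares with summed df (a 1-df pooled version is
also reported). The family M-test is `2 ln(10) (sum_i Zmax_i -
Zmax_total)` with df = families - 1. Segregation distortion partitions
per-parent G values into total, pooled and heterogeneity components;
multiple testing is controlled by Benjamini-Hochberg step-up, reporting
the realised per-test alpha. The inline formulas behind the published
tests are reconstructed from their cited source; the worked value
chi2 = 6.550 for counts (10/50 vs 2/50) pins the form down.

LD is estimated from unphased genotypes by EM under Hardy-Weinberg
equilibrium (tolerance 1e-8, 200 iterations; the likelihood is unimodal
in the one free haplotype frequency), with `D' = |D|/Dmax` and
`r2 = D^2/(pA pa pB pb)`. Decay is summarised over the distance bins 0,
0-1, 1-2, 2-5, 5-10, 10-20, 20-50 and > 50 cM (bin "0" holds identical
positions; others are left-exclusive), with non-syntenic pairs summarised
as a decile histogram. All related individuals enter by default, as in
the study population; a founders-only mode avoids the family-structure
inflation of LD.

## The simulator

`simulate_dataset()` emulates the study conditions: 14 linkage groups of
48-76 cM; marker positions on a jittered even grid (dense maps have
near-regular spacing, and short intervals keep the simulator's crossover
process close to the Kosambi scale used downstream); female and male
positions derived by strictly monotone warps - a cubic plateau compresses
the male map around the centromere, an arctangent ramp expands the female
map there - scaled to a total female:male length ratio of 1.15; eight
families (six three-generation, two two-generation with
unknown-ancestry parents), 14 F0 + 118 F1 + 219 F2, offspring per family
between 14 and 99, consecutive families sharing a grandparental couple;
missing rate 0.006 (call rate > 99%); optional allele-flip genotyping
error and post-zygotic viability distortion (carriers of a selected
genotype are rejected and redrawn with probability s). Crossovers follow
a Poisson process on the sex-specific map with no interference, so
observed fractions follow the Haldane transform of true distances while
the analysis reports Kosambi distances; on the simulated 2-3 cM spacing
this mismatch is a documented bias of about -2 to -3% in recovered
lengths. Gamete origin strings and founder phases are retained for
audits, so every pipeline stage can be checked against ground truth.

What passing tests show about real data is limited in known ways: founders
carry no linkage disequilibrium, genotyping error is an unstructured
allele flip, marker informativeness varies only through founder allele
frequencies, and there is no crossover interference.

## Problem sizes and known limitations

The shipped tests run the full pipeline at 14 groups x 30 markers with the
complete family design (a few minutes on one core), the exhaustive
ordering oracle on 100 groups of 4-7 markers, and 1,000-replicate null
calibrations of the heterogeneity tests. At 30 markers per group the
per-interval informative meioses are family-clustered - an interval's
deducible subset comes from only a handful of parents - which puts the
standard deviation of a recovered per-group length at roughly 8-10%. Group
recovery, the overall female:male ratio and the centromere/telomere slope
pattern are stable; individual group lengths can deviate beyond 15% on
unlucky draws, and the corresponding acceptance check records exactly
that. Tightening it further would require a joint parent-mate genotype
likelihood over ambiguous calls (a full chromosome-scan HMM), which is
beyond this package's scope.
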