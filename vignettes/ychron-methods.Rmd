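---
title: "ychron: models, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ychron: models, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ychron)
```

## Scope and assumptions

`ychron` analyses variation on the male-specific region of the Y chromosome
(MSY): haploid, nonrecombining, patrilineally inherited. Everything below
rests on three assumptions:

1. every sampled chromosome is related to every other by a single rooted
   genealogy (no recombination);
2. SNP mutations arrive as a Poisson process at a clock-like rate per
   nucleotide per year, and each hits a previously unmutated site
   (infinite sites) except for a small recurrent fraction that the tree
   builder detects and flags;
3. Y-STR alleles evolve by a strict symmetric single-step mutation model
   (SMM): each mutation changes the repeat count by ±1 with equal
   probability.

Violations of (2) — sequencing error, somatic mutation in cell-line DNA,
gene conversion from the X — surface as recurrent sites, branch-length
heterogeneity, or tissue-source effects, and the package ships explicit
tests for each.

## Tree construction

Input is a samples × sites matrix of haploid calls polarized to derived
coding (`polarize()`: outgroup sample, ancestral-allele table, or
ref-is-ancestral; sites whose ancestral state cannot be resolved are flagged
and excluded, never guessed).

A set of sites admits a perfect phylogeny exactly when their derived-carrier
sets form a *laminar family* — pairwise nested or disjoint. `build_tree()`
therefore:

1. groups sites by carrier set and processes the distinct sets in
   decreasing size order (ties by first-seen site order), accepting each set
   that stays laminar with everything accepted so far;
2. builds the rooted tree from the accepted family: each accepted set of
   two or more tips becomes an internal node whose parent is its smallest
   accepted superset; singleton sets become terminal-branch mutations;
   polytomies are retained and identical haplotypes attach to a shared node
   via zero-length branches;
3. places every rejected (recurrent) site on the fixed tree by exact
   two-state small parsimony (Sankoff dynamic programming with unit costs,
   exact on polytomies — `place_recurrent()`).

This replaces heuristic maximum-parsimony tree search: on near-tree-like
haploid data the laminar family determines the topology, and ambiguity is
confined to the flagged recurrent sites. The construction is deterministic.

**Root state and back-mutations.** Parsimony placement leaves the root state
free. When the optimal root state is *derived*, the pattern is consistent
with a gain above the root followed by loss(es) inside the tree; the stem
gain is emitted in the event table (branch `NA`) and the site is flagged as
a possible back-mutation, but the event count reports within-tree state
changes only, so it agrees with exhaustive two-state parsimony. A
consequence worth knowing: a site whose carriers are the exact complement of
a clade counts one event, even though it is not representable on the tree
without the stem gain.

**Tie-breaking.** When several optimal placements exist, the backtrace keeps
the parent's state on ties, which pushes events toward terminal branches;
remaining choices follow the tree traversal order. Event *counts* are
invariant to these choices; event *locations* for recurrent sites are a
convention.

## SNP dating

For a clade with $n$ tips, branches $b$ inside it with mutation count $l_b$
and descendant tips $n_b$:

$$\rho = \frac{1}{n}\sum_b l_b n_b, \qquad
  \sigma = \sqrt{\sum_b l_b \left(\frac{n_b}{n}\right)^2}$$

$\rho$ equals the mean number of mutations from the clade's tips to its
root (the identity is asserted on random genealogies in the test suite);
$\sigma$ is the standard deviation of $\rho$ obtained by treating each
branch's mutation count as Poisson.

$$\mathrm{TMRCA} = \frac{\rho}{\mu L}$$

Defaults (`rate_model()`): $\mu = 1.0\times10^{-9}$ mutations/nt/year with
95% CI $3.0\times10^{-10}$–$2.5\times10^{-9}$, $L = 3{,}724{,}156$ bp, i.e.
one mutation per 268.5 years. The rate CI is propagated by pure inverse-rate
scaling of the point estimate (`rescale_estimate()`); it is *not* combined
with $\sigma$, which is reported separately — the rate uncertainty dominates
and keeping the two sources apart makes tables comparable across studies.
TMRCAs in ka are rounded half-up to 0.1 ka, matching the convention of
printed dating tables; ranges are computed from unrounded values, so
last-digit differences of ±0.1 ka against a table computed from rounded
points are possible.

Generation time (default 30 y) is carried in the rate model but only used
for STR dating; the SNP clock is per year.

## STR dating

Given members of a clade, a root haplotype and a marker subset with $m$
loci:

$$\mathrm{ASD} = \frac{1}{nm}\sum_{i,j} (a_{ij} - r_j)^2, \qquad
  \rho_{\mathrm{STR}} = \frac{1}{nm}\sum_{i,j} |a_{ij} - r_j|$$

Under the unbounded symmetric SMM, $E[\mathrm{ASD}] = \mu_s t$ for *all*
depths, while $\rho_{\mathrm{STR}}$ measures net displacement and
undercounts once back-mutations matter ($\mu_s t \gtrsim 1$); both facts are
verified by Monte-Carlo in the tests. $\rho_{\mathrm{STR}}$ is the
star-genealogy reduction of network-based rho counting; on non-star data it
is an approximation, documented as such.

Roots: the *modal* haplotype is the per-locus mode of the members (ties to
the smallest allele — deterministic); an *ancestral* root is supplied by the
user or taken from simulated truth, never inferred heuristically.

Subsets (`str_subsets()`): `set21` = the full panel minus bilocal DYS385;
`set17` additionally drops the rapidly mutating DYS570/DYS576 and
complex-structure DYS389II/DYS448; `set13` further drops the non-Yfiler
loci DYS481/DYS533/DYS549/DYS643. Bilocal loci are flagged on input and
banned from every dating subset.

Rates: the "evolutionary" regime applies 6.9e-4 mutations/STR/generation at
every locus. The "pedigree" regime needs per-locus father–son rates; only
the bracket of subset means (2.797–4.238e-3) is published, so the shipped
per-locus values are **placeholders** with realistic relative magnitudes
whose subset means fall inside that bracket (set21 3.910e-3, set17
2.965e-3, set13 2.808e-3). Supply measured rates for real data.

`compare_estimates()` joins STR to SNP dates by clade and reports, per
(method, root, subset, regime) cell, the Pearson correlation, the mean
signed relative error and an over/under flag; with fewer than three shared
clades the correlation is reported as undefined.

## Branch-length heterogeneity

`anova_one_way()` compares mean mutations-to-root across tissue sources.
`subsampled_pairwise_test()` implements the protocol for haplogroup
comparisons under unequal sample sizes: for each pair of groups and each of
R = 100 replicates, groups larger than k = 10 are subsampled without
replacement to k (groups at or below k are used whole), a two-sided
Mann-Whitney U test is applied, p-values are Bonferroni-corrected by the
number of pairs actually tested (overridable — the original protocol's
divisor is not recoverable), and a pair is flagged when more than half of
its replicates are significant. The whole protocol is a deterministic
function of its seed.

The Mann-Whitney implementation enumerates the full permutation
distribution of U when $\binom{n_1+n_2}{n_1} \le 2\times10^5$ — correct
under ties, unlike the classical exact null — and otherwise uses the
tie-corrected normal approximation with continuity correction; the
approximation is the default inside the subsampling protocol at k = 10.

## Selection and recurrence

`yates_chi2()` implements $\chi^2 = \sum (\max(|O-E|-0.5,\,0))^2/E$ on 2×2
tables with 1 df. `singleton_enrichment()` builds the table (damaging vs
remainder of the dataset) × (singleton vs not) against a dataset-wide
background and reports direction; Fisher's exact test is available behind a
flag. On the reference counts (background 7,782/13,261 singletons; 17
damaging with 16 singletons; 15 with 13) the Yates test yields p = 0.0065
and p = 0.0524 — the second differs from the printed 0.0527 in the third
significant figure, and no alternative construction we tried (plain
chi-square 0.028, Fisher 0.034) comes closer, so Yates is retained for
both tests. For the cross-study recurrence-rate comparison of 123/13,261
against 4/2,386 the Yates p is 2.29e-4 while the plain chi-square gives
1.40e-4; a printed bound of p < 2e-4 is met only by the uncorrected
variant, so `compare_recurrence_rates()` exposes `correct = FALSE`.

A site is in CpG context when its reference trinucleotide context contains
the site base in a CG pair on either strand (`.CG` or `CG.`); this fixed
convention is applied to recurrence summaries, where methylation-driven
deamination predicts an excess of recurrent events at CpG sites.

## The simulator: what a green test establishes

`simulate_dataset()` draws a genealogy (constant-size coalescent with
effective male population size Ne, a star of fixed depth — useful for
isolating estimator properties from genealogical noise — or a user tree),
then Poisson SNP mutations at $\mu L$ per year per branch, single-step STR
mutations at per-locus per-generation rates, tissue-source labels and
optional cell-line (LCL) somatic singletons on terminal branches. Every
stage is a pure function of (config, seed); stage seeds are derived from
the master seed, and arguments are forced before seeding so nested and
sequential call styles give identical results.

Defaults are the stated world of the reference analysis: rate 1.0e-9/nt/y,
target 3,724,156 bp, generation time 30 y, evolutionary STR rate 6.9e-4,
star depth 125,826 y (the depth at which the expected tip count is 468.6),
tissue composition 152:208:88 LCL:blood:saliva. Where no value is stated we
chose once: Ne = 5,000 males (a conventional order of magnitude for human Y
effective size), STR root allele 14 repeats (mid-range for common Y-STRs),
finite-sites CpG class of 2% of sites at 10× rate (an order-of-magnitude
convention, synthetic only). For the LCL-excess power test the star depth
is 12 ka so that the Poisson background variance does not drown a
3-mutation somatic excess at n = 150 per group; at the full reference depth
that particular test would be underpowered, which is a statement about the
design, not the code.

The generator emulates the *statistical* structure the analyses assume. It
does not emulate: sequencing error, missing data, X-Y gene conversion,
population structure or demography beyond constant size, multi-step or
locus-heterogeneous STR mutation, or length constraints on repeat arrays
(alleles are unbounded; the rare negative excursion is clamped at zero with
a warning). A green test therefore establishes correctness of the
estimators under their own model, plus the specific robustness properties
tested (recurrence detection, somatic-singleton detection), and nothing
more.

## Numerical conventions and degenerate inputs

* ka rounding: half away from zero, 1 decimal.
* Modal-haplotype ties: smallest allele.
* Parsimony ties: root to ancestral state, then keep-parent-state.
* Laminar greedy ties: larger carrier sets first, then input site order.
* Single-tip clades: rho = sigma = 0. Empty member sets, empty matrices,
  all-missing loci, zero rates and inconsistent backgrounds raise typed
  errors (`ychron_error`) rather than propagating NaN.
* VCF: 1-based positions kept unchanged; GT `0`, `1`, `0/0`, `1/1` (and
  phased forms) accepted, anything else is non-haploid; duplicate positions
  are errors; missing calls are errors under `require_complete` (the
  default — high-coverage haploid data should be complete) or drop the site
  otherwise.
* Newick branch lengths are integer mutation counts; per-mutation detail
  travels in a sidecar event table because Newick cannot carry it.

## Known limitations

* The tree builder assumes complete calls at used sites; imputation is out
  of scope.
* Recurrent-site event *locations* (not counts) depend on the documented
  tie rules and may differ from other parsimony implementations.
* STR pedigree rates are placeholders (above).
* The coalescent is single-population, constant-size; no demographic
  inference is attempted.
* p-values from the subsampling protocol are a screening heuristic (the
  flagged proportion is not itself a calibrated p-value); its type-I
  behaviour is characterised empirically in the acceptance suite.
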