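---
title: "Methods: mito-nuclear carriership association and epistasis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mito-nuclear carriership association and epistasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitosyn)
```

## The problem

Mitochondrial DNA is maternally inherited and non-recombining, so its
variation clusters into haplogroups — clades of haplotypes sharing inherited
substitutions. In European populations the common haplogroups H, J, K and U
can be discriminated by a handful of marker SNPs. Because mitochondrial
dysfunction is implicated in neurodegenerative and autoimmune disease, a
natural question in a case-control cohort is twofold: does a haplogroup
itself shift disease risk, and does it interact ("epistasis") with nuclear
susceptibility variants so that joint carriers are at disproportionate risk?

`mitosyn` implements this analysis for individual-level genotype tables:
haplogroup calling, carriership association, exhaustive combination mining,
and two complementary epistasis statistics, together with a simulator and
exact fixture reconstruction so that every stage can be validated without
access to any external cohort.

## Haplogroup assignment

Five haploid marker alleles at rCRS positions 1719, 7028, 9055, 10398 and
12308 are matched against a fixed decision table:

| haplogroup | 1719 | 7028 | 9055 | 10398 | 12308 |
|---|---|---|---|---|---|
| H | G | C | G | A | A |
| J | G | T | G | G | A |
| K | G | T | A | G | G |
| U | G | T | G | A | G |

Any other complete five-tuple is `OTHER`; any missing marker yields
`UNKNOWN`. The four patterns are pairwise distinct and the assignment is a
total function on the $4^5$ complete haplotypes (property-tested by full
enumeration). Two conventions are our own, since marker panels of this kind
cannot resolve every lineage: `OTHER` is retained as a reportable class but
is never an association feature by default, and `UNKNOWN` subjects are
excluded from the denominators of frequency and association tables
(complete-case per feature). Published aggregate tables of this design report
percentages on the full N, which implies complete genotyping; complete-case
handling is the faithful generalization when missingness does occur.

## Carriership association

Features are dominant-style codings: a haplogroup label, carriage of at
least one copy of an allele, or an exact unordered genotype. For each
feature the informative subjects form a 2×2 table
(case/control × carrier/non-carrier) with cells $a, b, c, d$.

* **Fisher exact P**, two-sided by probability ordering: with all margins
  fixed, $P$ is the sum of hypergeometric probabilities of every table whose
  point probability is at most the observed one. Ties are compared with a
  relative tolerance of $10^{-12}$. Probability ordering is the most common
  two-sided convention; since no sidedness is universal, P values feed flags
  and ordering, not effect estimates.
* **Odds ratio and Woolf CI**: $\mathrm{OR} = ad/bc$ and
  $\exp(\ln \mathrm{OR} \pm z\sqrt{1/a+1/b+1/c+1/d})$ with $z = 1.96$. When
  any cell is zero, the Haldane–Anscombe correction adds 0.5 to all four
  cells first and the result is flagged. This log-scale (Woolf) interval,
  not the conditional-MLE interval of `fisher.test()`, is the convention
  that reproduces published carriership tables of this design from their
  printed counts.

Sex stratification partitions subjects with known sex; missing-sex subjects
belong to neither stratum.

## Combination mining

Stochastic multilocus searches (MCMC samplers over allelic combinations) are
unnecessary at this problem size: with a few haplogroups, a few dozen
nuclear features and order ≤ 2, the full search space is a few thousand
tables. `enumerate_combinations()` therefore scores **every** subset of
1..`max_order` features with pairwise distinct loci by joint carriership —
results are exact rather than sampled. Two features at the same locus are
skipped (carrying two alleles of one site is a different hypothesis), joint
status is missing if any component is missing, and output order is
deterministic (descending $|\ln \mathrm{OR}|$, ties lexicographic). Nominal
P values are reported by default, matching the practice of the aggregate
tables this package targets; a Benjamini–Hochberg flag is available and off
by default. `permutation_validate()` supplies an empirical P by shuffling
case/control labels with `+1/(n_perm+1)` smoothing; because the permuted
Fisher P depends on the table only through the case-carrier count, P values
are precomputed over that count's support and looked up per permutation.

## Epistasis: synergy factor and FLINT

For factors A and B the informative subjects form a 2×2×2 table
$n_{sij}$ (status, A-carriage, B-carriage). Stratum odds ratios take double
non-carriers as reference,
$\mathrm{OR}_{ij} = (n_{\mathrm{case},ij}/n_{\mathrm{case},00}) /
(n_{\mathrm{ctrl},ij}/n_{\mathrm{ctrl},00})$, and the **synergy factor** is

$$\mathrm{SF} = \frac{\mathrm{OR}_{11}}{\mathrm{OR}_{10}\,\mathrm{OR}_{01}},$$

the multiplicative-scale interaction: SF > 1 means joint carriers are at
higher odds than the product of single-factor effects predicts. Its CI uses
$\mathrm{Var}(\ln \mathrm{SF}) = \sum 1/n_{sij}$ over all eight working
cells and $z = 1.96$. Small-cell policy: when the minimum cell is below 5
(a tunable threshold), 0.5 is added to all eight cells before both the point
estimate and the variance — a single rule that keeps estimate and variance
internally consistent. The threshold of 5 is the standard sparse-cell
rule-of-thumb for log-odds expansions; setting it to 0 disables correction.

**FLINT** (`flint_exact()`) is the exact conditional test of no three-way
interaction. Holding all three two-way margins (status×A, status×B, A×B)
fixed leaves a one-parameter family of tables indexed by the case
joint-carrier cell $t$; the other seven cells are linear in $t$. Under the
no-interaction null the conditional probability of each feasible table is
proportional to $1/\prod_{sij} n_{sij}!$. The two-sided `p_flint` sums the
normalized probabilities of all tables at most as probable as the observed
one (relative tie tolerance $10^{-12}$); because the scientific hypothesis
is synergy, the one-sided tail toward larger $t$ is reported alongside as
`p_synergy`. Enumeration uses log-factorials with log-sum-exp
normalization — cell counts of a few hundred would overflow naive
factorials — and the normalized distribution sums to 1 within $10^{-9}$
(tested). The reference construction for "exact interaction test in a
2×2×2 table" varies across the literature; this conditional
margin-fixed form is the natural Fisher-style one, and on reconstructed
aggregate tables it agrees closely with published interaction P values for
tables without hidden missingness.

`classify_interaction()` applies the combined criterion: `EPISTATIC` when
`p_flint` < α and the SF CI excludes 1, `SUGGESTIVE` when exactly one
criterion holds, `NOT_SUPPORTED` otherwise.

```{r}
t <- build_2x2x2(study_fixture("CCL5"), "hg:J", "rs2107538:A")
t
synergy_factor(t)[c("sf", "ci_low", "ci_high", "correction_applied")]
flint_exact(t)[c("p_flint", "p_synergy", "n_tables")]
```

## Synthetic cohorts

`generate_cohort()` emulates retrospective (case-control) sampling from a
two-factor odds model. Exposure strata $(i,j)$ have independent population
probabilities from carrier frequencies $p_A, p_B$; disease odds in stratum
$(i,j)$ are $\beta \cdot \mathrm{or10}^i \cdot \mathrm{or01}^j \cdot
\mathrm{sf}^{ij}$. Stratum distributions conditional on status follow by
Bayes' rule and the requested numbers of cases and controls are drawn
multinomially — exact and fast, with no rejection sampling. Because
case-control sampling identifies odds ratios, the estimands
$\mathrm{or10}, \mathrm{or01}, \mathrm{sf}$ are recovered regardless of the
baseline odds $\beta$, which is therefore an inert nuisance default
(0.1). Factor A is realized as haplogroup J (carriers get the J-defining
haplotype; non-carriers draw from a background haplogroup distribution with
H most common, as in European populations), factor B as a nuclear locus
whose carriers are heterozygous with probability `het_fraction` (default
0.85, the Hardy–Weinberg heterozygote share among carriers at a carrier
frequency near 0.37).

Defaults describe a study-like cohort fixed once: 283 cases / 290 controls,
$p_A = 0.10$ (haplogroup-J carriage), $p_B = 0.37$ (a common nuclear
allele), or10 = 1.25, or01 = 0.97, sf = 4.3. What the generator does **not**
emulate: linkage disequilibrium among nuclear loci (each run carries one
locus), heteroplasmy (mtDNA is haploid single-base), population
substructure, genotyping failure (no missingness is simulated), and any
sex×genotype dependence (sex is independent of exposure). Passing tests on
generated data therefore validate the statistical machinery under a clean
multiplicative odds model, not robustness to those real-data complications.

`study_fixture()` is the deterministic counterpart: it rebuilds an
individual-level cohort whose factor carriage reproduces a published
aggregate table exactly, via inclusion–exclusion
(`reconstruct_from_marginals()`: $n_{11} = n_{AB}$, $n_{10} = n_A - n_{AB}$,
$n_{01} = n_B - n_{AB}$, $n_{00} = N - n_A - n_B + n_{AB}$). Joint
sex×genotype counts are not published, so sex is assigned independently of
genotype to match the marginal 198/85 and 197/93 female/male splits;
sex-stratified results on fixtures are consequently not comparable to the
study's stratified figures. Background haplogroups of non-J subjects are
likewise a deterministic filler (the published aggregates constrain only J
carriage), so fixture frequencies of H, K and U are not meaningful.

## Numerical and degenerate-input choices

* Tie comparisons in both exact tests use a relative tolerance of
  $10^{-12}$; enumeration is in log space throughout.
* Zero cells: 2×2 odds ratios apply +0.5 to all four cells only when a zero
  occurs; the 2×2×2 synergy factor applies +0.5 to all eight cells iff the
  minimum cell is below the threshold (default 5). A zero working cell
  surviving the policy (e.g. with correction disabled) raises a degenerate
  error rather than returning infinities.
* Degenerate tables — an empty status group after complete-case filtering —
  raise classed errors (`mitosyn_degenerate_error`); the combination miner
  skips such combinations instead of failing the whole report.
* All randomness (simulation, permutation) flows through an explicit seed
  and restores the caller's RNG state; fixtures use no randomness at all.
* Error classes map to scripting-friendly exit codes in the CLI wrapper:
  config 2, data/format 3, degenerate statistics 4.

## Problem sizes used by the test suite

The suite validates the exact tests against brute-force enumeration oracles
on random tables with N ≤ 60 (where exhaustive enumeration is cheap and
exact), checks FLINT's type-I error on 2,000 simulated null cohorts of
500+500 subjects, recovers a simulated SF of 4.3 within ±15% at
20,000+20,000 subjects (the delta-method SE at that size makes ±15% a
~2 SE band), and verifies stratum-frequency convergence at $10^5$ subjects
per arm. These sizes keep the full suite under a few minutes while leaving
each check well-powered.

## Limitations

* Interaction is assessed on the multiplicative (odds-ratio) scale only; no
  additive-scale measures (RERI/AP/S), no model-based (logistic) interaction,
  and no interactions of order above two.
* No covariate adjustment, Hardy–Weinberg testing, haplotype phasing, or
  genotype-dosage (additive) coding; carriership is the only exposure model.
* The five-marker decision table cannot resolve sub-haplogroups, and
  `OTHER` conflates all remaining lineages.
* The genotype TSV dialect is intentionally minimal; it does not aim at VCF
  generality (two observed alleles per nuclear site, unphased).
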