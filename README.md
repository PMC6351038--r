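# mitosyn

Mito-nuclear association and epistasis analysis for case-control cohorts.

Mitochondrial haplogroups — clades of related mtDNA haplotypes such as H,
J, K and U — can modulate the risk of complex disease, and they may do so
not alone but in interaction with nuclear variants. `mitosyn` implements
the complete analysis chain for studying such mito-nuclear interplay in a
case-control design:

1. **Haplogroup assignment** from five diagnostic mtDNA SNPs (rCRS
   positions 1719, 7028, 9055, 10398, 12308) via a fixed decision table:
   H = (G,C,G,A,A), J = (G,T,G,G,A), K = (G,T,A,G,G), U = (G,T,G,A,G);
   any other complete haplotype is `OTHER`, any missing marker `UNKNOWN`.
2. **Carriership association.** For each feature (haplogroup, allele under
   dominant coding, or exact genotype) a case/control × carrier/non-carrier
   2×2 table, two-sided Fisher exact P (probability ordering), odds ratio
   OR = ad/bc, and a Woolf-type 95% CI
   `exp(ln OR ± 1.96·√(1/a + 1/b + 1/c + 1/d))`, with the Haldane–Anscombe
   +0.5 correction when a cell is zero. Optional sex stratification.
3. **Combination mining.** Exhaustive enumeration of all distinct-locus
   feature combinations up to a chosen order, each scored by joint
   carriership; optional Benjamini–Hochberg adjustment and label-permutation
   validation.
4. **Epistasis assessment** for a pair of factors A, B via the 2×2×2
   disease × carriage-A × carriage-B table:
   - the **synergy factor** SF = OR11/(OR10·OR01), stratum odds ratios
     referenced to double non-carriers, CI from
     `Var(ln SF) = Σ 1/cell` over the eight cells, +0.5 to all cells when
     the smallest is below 5;
   - **FLINT**, an exact conditional test of no three-way interaction:
     with all three two-way margins fixed the table family has one degree
     of freedom, and each table's null probability is ∝ `1/Π cell!`;
   - a combined call: `EPISTATIC` when P_FLINT < α **and** the SF CI
     excludes 1, `SUGGESTIVE` when exactly one criterion holds.
5. **Synthetic data.** A retrospective case-control simulator with
   configurable carrier frequencies, stratum odds ratios and target SF, and
   deterministic fixture cohorts that reproduce a published study's
   aggregate carrier counts exactly at the individual level.

## Worked example

Reconstruct the published 283-case / 290-control cohort for the
haplogroup J + *CCL5* rs2107538\*A pair and run the full pipeline:

```r
library(mitosyn)

cohort <- study_fixture("CCL5")
cohort
#> <mitosyn_cohort> 573 subjects (283 case, 290 control), 1 nuclear loci

associate(cohort, c("hg:J", "rs2107538:A"))
#>       feature n_case_carrier n_case_total n_control_carrier n_control_total
#> 1        hg:J             45          283                25             290
#> 2 rs2107538*A            110          283               105             290
#>   freq_case_pct freq_control_pct   p_fisher odds_ratio    ci_low  ci_high
#> 1      15.90106          8.62069 0.01033724   2.004202 1.1923755 3.368758
#> 2      38.86926         36.20690 0.54608752   1.120286 0.7987024 1.571350

res <- run_pipeline(cohort, c("hg:J", "rs2107538:A"))
res$epistasis[, c("pair", "sf", "sf_ci_low", "sf_ci_high", "p_flint",
                  "classification")]
#>                 pair       sf sf_ci_low sf_ci_high    p_flint classification
#> 1 hg:J + rs2107538*A 4.321322  1.270956   14.69274 0.01476794      EPISTATIC
```

Reading the output: haplogroup J is carried by 15.9% of cases versus 8.6%
of controls (OR 2.00, 95% CI 1.19–3.37), while the CCL5 allele alone shows
no association (OR 1.12). Their joint carriership, however, is strongly
enriched in cases, the synergy factor is 4.32 (computed on +0.5-corrected
cells because only 4 controls carry both factors), its CI excludes 1, and
the exact interaction test rejects the multiplicative null — the pair is
called epistatic. Running the same pipeline on `study_fixture("PVT1")`
gives SF = 3.05 [1.00–9.31] but P_FLINT = 0.084, hence only `SUGGESTIVE`.

A thin command-line wrapper over these functions ships in
`inst/scripts/mitosyn.R` (subcommands `run`, `simulate`,
`call-haplogroups`).

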