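# mirtrio

Comparative molecular-evolution analysis of microRNA precursors across the
human, chimpanzee and orang-utan genomes.

Most human miRNAs are strongly conserved, but the primate lineage has also
gained hundreds of young, primate-specific miRNAs whose hairpins are still
being shaped by selection. `mirtrio` implements the full workflow needed to
ask whether those young miRNAs evolve faster than old ones, and whether any
lineage shows acceleration beyond neutral expectation:

- **Ortholog curation** — reconcile BLAT (PSL) and liftOver (BED) evidence
  per species, resolve a single interval per miRNA
  (`select_best_blat_hit()`, `resolve_orthology()`), drop many-to-one
  assignments (`exclude_many_to_one()`), trim three-way alignments to the
  human precursor with 80% coverage and 20-nt internal-gap filters
  (`trim_and_filter_alignment()`), and discard hairpins whose folding
  minimum free energy falls beyond the 5% right tail of the human MFE
  distribution (`mfe_filter()`). Flanking regions (40 bp a side) are
  extracted and aligned as internal references (`extract_flank_alignment()`),
  and ancestral repeats are curated as neutral references
  (`curate_ancestral_repeats()`).
- **Classification** — four axes per miRNA: clustered (< 10 kb, same
  strand), copy number (family size), conservation (primate-specific vs
  families conserved beyond primates, "ConFam"), and genomic context
  (genic/intergenic with a 50-kb rule).
- **Substitution counting and the relative rate test** — every alignment
  column is oriented into ancestral and derived states using the orang-utan
  allele; branch-specific counts over the effective (gap-free) length give
  per-branch rates. Tajima's relative rate test,
  `chi2 = (m1 - m2)^2 / (m1 + m2)` on 1 df, compares the human and
  chimpanzee branches per miRNA and per concatenated category, with
  bootstrap (B = 100) confidence intervals and a reciprocal
  2.5/97.5-percentile rule for declaring two categories different.
- **Composition effects** — substitutions partitioned by ancestral CpG
  context (CpG>TpG / CpG>CpA with conserved partner base) and by
  weak/strong class; the W>S bias `n_WS / (n_WS + n_SW)` indexes GC-biased
  gene conversion.
- **Acceleration test** — a likelihood-ratio test under a Jukes–Cantor
  star-tree model: the test region shares the neutral reference's branch
  lengths up to one scale factor (null) or additionally a one-sided human
  multiplier `rho >= 1` (alternative); p-values come from the 50:50
  point-mass/chi-square(1) boundary mixture, with the median p over 100
  random references reported.
- **Target enrichment** — one-sided Fisher tests of predicted-target gene
  sets against a gene universe, calibrated by 1,000 permutations of random
  miRNA groups (a term is significant when its permuted p exceeds the
  observed one in > 99% of permutations).
- **Synthetic data** — `simulate_triplets()` generates three-species
  datasets with known per-branch rates, CpG hypermutability, W>S bias,
  cluster/gene layouts and all fixture formats (PSL, BED, GFF3, miFam, MFE
  tables), so every stage is testable without genome downloads.

## Worked example

```r
library(mirtrio)

cfg <- run_config(
  sim = simulation_config(
    n_mirnas = c("primate-specific" = 120L, "ConFam" = 60L), seed = 2L),
  stages = c("simulate", "curate", "classify", "rates"),
  bootstrap_B = 100L, seed = 2L)
report <- run_pipeline(cfg)
print(report)
```

```
pipeline_report: 180 simulated loci
  curation: kept 148 of 180
  category rates:
         axis            level n_mirnas rate_human rate_chimp
 conservation primate-specific       99     0.0053     0.0066
 conservation           ConFam       49     0.0010     0.0025
    clustered    non-clustered      102     0.0033     0.0047
    clustered        clustered       46     0.0053     0.0064
       copies           single       79     0.0047     0.0059
       copies         multiple       69     0.0030     0.0045
      context       intergenic       99     0.0037     0.0055
      context       genic:exon       19     0.0046     0.0065
      context     genic:intron       25     0.0049     0.0039
```

The funnel kept 148 of 180 simulated loci (the rest fail the coverage/gap
filters or the MFE tail rule, as configured). The simulated
primate-specific human-branch rate (0.0056 substitutions/site) is recovered
as 0.0053 with the ConFam category an order of magnitude lower, and the
bootstrap comparison declares the two categories different:

```r
report$category_comparison
#> $verdict  "different"
#> $rate_a   0.00534   $ci_a  0.00391 0.00744   (primate-specific, human)
#> $rate_b   0.00101   $ci_b  0.00025 0.00177   (ConFam, human)
```

A multiple regression of per-miRNA rates on all four axes singles out
conservation as the explanatory variable (estimate 0.0071, p = 0.001 in
this run), and the relative rate test on a printed example count pair gives

```r
tajima_rrt(14, 0)
#>   m1 m2 chi2            p
#> 1 14  0   14 0.0001828106
```

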