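---
title: "Substitution rates in primate miRNA ortholog triplets: models and methods"
author: "mirtrio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Substitution rates in primate miRNA ortholog triplets: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtrio)
```

This vignette is the package's own account of its science: the models and
procedures it implements, the assumptions behind them, the parameters that
matter, what the synthetic-data generator does and does not emulate, and the
numerical choices made where the design was genuinely open.

## The question and the unit of analysis

miRNA precursors are ~70–91 bp hairpin RNAs. Because a precursor is short,
per-locus substitution counts between closely related primates are tiny
(most human–chimp precursor alignments are identical), so the package works
at two levels: per miRNA for screening, and per *category* — concatenations
of all precursors sharing a label — for powered inference. The labels are
four axes: clustering (two or more precursors within 10 kb on the same
strand), copy number (miRNA family size, with families of one and orphans
"single-copy"), conservation (families whose members are all primates, plus
orphan human entries, are "primate-specific"; families with any non-primate
member are "ConFam"), and genomic context (genic by exon/intron/UTR overlap
with exon taking priority at a single shared nucleotide, intergenic beyond
50 kb from a protein-coding gene, and an explicit "unassigned" bucket for
loci within 50 kb but overlapping nothing — the genic/intergenic dichotomy
leaves that zone undefined, and making it explicit keeps context contrasts
clean).

## Ortholog curation

Orthology in the chimpanzee and orang-utan genomes is called from two
independent sources: BLAT hits (PSL) and liftOver projections (BED). Hits
covering less than 80% of the query are discarded; survivors are ranked by
matched length then identity, with a deterministic (chromosome, start)
tie-break flagged as ambiguous. When both sources overlap on the same
strand, the call spans the leftmost start to the rightmost end of the
intersecting set; a liftOver projection alone is accepted (this rescues the
most diverged loci, which are exactly the interesting ones); discordant
sources drop the locus. Groups of human miRNAs resolving to one target
locus (≥ 50% reciprocal overlap — the threshold is our operationalisation,
as "same locus" needs one) are removed entirely, because many-to-one
assignments violate the orthology assumption.

Alignments are trimmed to the columns spanned by the human precursor and
rejected when a non-human row covers < 80% of the human length or the human
row has an internal gap > 20 nt. A folding filter then removes triplets in
which *any* of the three sequences has a minimum free energy above the 95th
percentile (linear-interpolation quantile) of the human reference MFE
distribution — "beyond the 5% right tail" is read in the less-stable
direction, the only reading under which genuine hairpins pass. The
curation order is coverage/gap first, then MFE. Flanking references take
100 bp a side, keep the 40 bp adjacent to the precursor after re-alignment,
and are rejected below 50% aligned coverage of the 80 bp target; ancestral
repeats are kept when they survive reciprocal liftOver in all species, lift
to the same chromosome, and fall in the 70–91 bp band (the interquartile
range of human precursor lengths).

Re-alignment is pluggable: externally aligned triplets can be read with
`read_alignment()`, and the built-in `align_triplet_to_human()` projects
each non-human sequence onto the human row by global pairwise alignment
(Biostrings), dropping insertions relative to human — consistent with the
human-anchored trimming that follows. The filters, not the aligner, are the
scientific content here.

## Counting model and the relative rate test

Each gap- and ambiguity-free column is oriented with the orang-utan allele
as the ancestral state: a human–chimp difference is assigned to the branch
of the species that disagrees with orang-utan; columns with three distinct
alleles are multiallelic and skipped; columns where human and chimp agree
against orang-utan are orang-branch/ancestral changes, tallied only as a
diagnostic. The rate is `m_branch / effective_length`. Reported tables
round half-up to 4 decimals; all arithmetic keeps full precision.

This is a parsimony estimator: a branch-specific change is counted only
when the other two lineages are undisturbed at that site. Coincident hits
on two branches at one site are lost or misassigned, producing a small
downward bias of order the per-site rate of the other branches —
about 2% at neutral primate rates, rising to ~5% for the fastest
category once CpG hypermutability concentrates changes on the same sites in
all lineages. The bootstrap intervals below are wider than this bias at the
study's sample sizes, but it is a known property of the method, visible in
the simulation recovery numbers, and no correction (e.g. Jukes–Cantor) is
applied because the sequences compared are nearly identical.

Tajima's relative rate test uses the chi-square form
`chi2 = (m1 - m2)^2 / (m1 + m2)` on 1 df (`m1 + m2 = 0` gives p = 1). The
form is symmetric in its arguments and its p is monotone in the count
imbalance at fixed total. An exact two-sided binomial version
(`method = "binomial"`, null: each oriented change falls on either branch
with probability 1/2) is provided because published per-miRNA p-values in
this literature are not always consistent with either form; we implement
both and do not attempt to reproduce any specific per-locus value. Batch
runs report nominal and Bonferroni flags (0.05/1214 ≈ 0.000041 at the
study's scale).

Category uncertainty comes from bootstrapping members within each category
(B = 100, resampling to the category's own size) and recomputing the
concatenated rate `sum(m) / sum(L)` — a weighted rate, never a mean of
per-locus rates. Two categories are declared different only when each
observed rate falls outside the other bootstrap's 2.5–97.5 percentile
interval; one-sided exceedance is "not distinguishable".

Seed regions (positions 2–8 of each mature) are mapped through the gapped
human row by coordinate walking and re-counted with the same rules. A
multiple linear regression of per-miRNA rates on indicator variables for
the four axes asks which axis explains rate variance once the others are
controlled; collinear indicators are dropped with a warning.

## Composition: CpG context and GC-biased gene conversion

A branch-specific substitution is CpG-context when the oriented ancestral
dinucleotide is CpG and the change is the deamination transition — C>T at
the C, or G>A at the G (the reverse-strand reading, CpG>CpA) — with the
partner base required to be conserved between human and chimp. Edge
positions without a partner count as non-CpG. Oriented changes are also
classified weak/strong (W = A/T, S = C/G): the W>S bias
`n_WS / (n_WS + n_SW)` indexes GC-biased gene conversion, the
recombination-associated fixation bias that can mimic positive selection.
Per-type (12 ordered ancestor→derived pairs) rates are normalised per
mutational opportunity — the count of gap-free columns whose ancestral base
is the source base — because a per-total-length normalisation would
confound type rates with base composition; the denominators partition the
effective length, and the choice is configurable in the sense that counts
and opportunities are both reported.

## The acceleration likelihood-ratio test

The test asks whether a region evolves faster on the human branch than a
neutral reference. Sites are independent under a Jukes–Cantor model on the
unrooted three-taxon star tree; an alignment is summarised by its five
column-pattern counts (all equal; human, chimp, or orang-utan differing;
all distinct), whose class probabilities are closed-form in the three
branch lengths. `fit_reference()` obtains maximum-likelihood branch
lengths, initialised from the pairwise-distance decomposition
`t_i = (d_ij + d_ik - d_jk) / 2` on JC-corrected distances and refined
numerically.

`lrt_acceleration()` fits reference and test jointly: free reference branch
lengths, one shared scale for the test region (null), plus a one-sided
human multiplier `rho >= 1` (alternative). Re-estimating the reference
under both models is essential for calibration when the reference is only a
few times longer than the test — conditioning on fixed reference estimates
leaks reference sampling noise into the statistic and inflates the type-I
error (we measured ~9.5% at a 2:1 length ratio before adopting the joint
fit, against ~5.5% after). Because `rho = 1` is a boundary, p-values use
the 50:50 mixture of a point mass at zero and chi-square(1). The optimiser
(Nelder–Mead on log-parameters) is restarted from jittered starts keeping
the best likelihood; the model surface is smooth enough that a handful of
restarts suffices, and both the restart count and the number of reference
draws for `median_p_over_references()` (default 100, drawn with
replacement) are arguments. Deceleration (`rho < 1`) is deliberately not in
the alternative: the scientific question is acceleration, and the one-sided
boundary design matches the promoter-scan tradition this test follows.

## Permutation-calibrated enrichment

Predicted targets are filtered (conserved sites always; non-conserved sites
only under a flag and a total context score ≤ −0.4), and each functional
term is tested by a one-sided Fisher exact test (hypergeometric upper tail,
vectorised; cross-checked against `fisher.test` in the test suite). Because
target prediction is biased (gene length, 3'UTR composition), raw Fisher
p-values are calibrated by permutation: B = 1000 re-drawings of k = 10
random miRNAs (or of a matched number of genes — both modes exist because
group-level and per-miRNA analyses permute different units), and a term is
significant when its permuted p strictly exceeds the observed p in more
than ⌈0.99·B⌉ permutations. The strict inequality makes the rule
conservative under ties; the add-one estimator
`(1 + #[p_perm <= p_obs]) / (B + 1)` is reported alongside.

## The synthetic-data generator

`simulate_triplets()` draws, per locus, an ancestor of 70–91 bp (uniform
base composition) plus flanks, and evolves three descendants by independent
per-site Bernoulli substitutions at the configured per-branch rates — no
multiple hits within a branch, which is adequate at rates ≤ 0.02. The
emitted orang-utan row is the ancestor plus its own branch noise, so
multiallelic columns and orientation errors arise naturally. Two
composition dials:

- `cpg_multiplier` (default 10, the order of magnitude of CpG transition
  hypermutability): a *relative risk* at CpG dinucleotide sites,
  renormalised so the configured rate stays the marginal per-site rate —
  otherwise a CpG-rich draw would silently inflate every configured rate by
  ~2x.
- `ws_bias` (default 0.39, the genome-wide weak-to-strong fixation bias in
  human–chimp comparisons): the probability that a change at a weak site
  creates a strong allele (and that a change at a strong site stays
  strong), so on a balanced ancestor the realised W>S fraction equals the
  dial.

Default conditions are the study regime: 840 primate-specific and 374
ConFam loci; precursor branch rates 0.0056/0.0066 (human/chimp,
primate-specific) and 0.0014/0.0022 (ConFam); flank rates 0.0065/0.0070 and
0.0048/0.0052; neutral (ancestral-repeat) rates 0.0053/0.0059; orang-utan
branches ~2.5x the human branch, consistent with the outgroup's divergence;
fabricated hairpin energies N(−37.9, 8) kcal/mol; 40-bp flanks from 100-bp
extractions. The generator also lays loci on synthetic chromosomes (cluster
pairs 3 kb apart, isolated loci 60 kb apart, every third locus inside a
synthetic gene), builds the matching PSL/BED/GFF3/family/MFE fixtures, and
records true per-branch counts for recovery tests. Loci are chunked 250 per
chromosome so coordinates stay in integer range at any size.

What the generator does **not** emulate: indel processes (a flag injects
human-row gap runs only to exercise the gap filter), hairpin
thermodynamics (MFEs are fabricated, so the MFE filter's behaviour on real
structures is untested), context-dependent mutation beyond CpG,
lineage-sorting/polymorphism, and alignment error (default fixtures are
gapless, so passing tests validate the statistics, not an aligner).
Parameter-recovery results on synthetic data therefore show that the
*estimators* are correct under the stated model, not that the model captures
every feature of real primate data.

## Numerical choices and problem sizes

- Quantiles (MFE threshold, bootstrap intervals) use R's default
  linear-interpolation type 7.
- Reported rates round half-up at 4 decimals; internal arithmetic is full
  precision.
- Ties in BLAT ranking break on (chromosome, start) and are flagged.
- Degenerate contingency margins return p = 1 with a warning rather than
  erroring, so batch pipelines survive empty categories.
- All resampling (bootstrap, permutations, reference draws, optimiser
  jitters) is seeded through a single RNG-preserving helper; identical
  configuration and seeds reproduce reports byte-for-byte.
- Validation problem sizes, chosen to exercise the asymptotics the methods
  rely on while staying desk-scale: 20 replicate datasets of 800 + 370 loci
  for rate recovery and category separation; 2,000 equal-rate categories of
  ~2,000 bp for relative-rate-test calibration; 200 replicates at ~5,000 bp
  (tests) against ~10,000 bp references for LRT calibration and power;
  1,000 permutations over 300 terms for enrichment calibration; ~10,000
  fixed changes for W>S bias recovery.

## Known limitations

The substitution model is Jukes–Cantor throughout the likelihood machinery;
transition/transversion asymmetry is handled only descriptively (per-type
tables), not in the LRT. The parsimony counting bias discussed above is
uncorrected by design. The enrichment module is database-agnostic and does
not propagate the GO graph (a gene→term map is taken as given). The
built-in re-aligner projects onto the human sequence and discards
insertions relative to human, so human-deletion loci lose those columns
from every species.
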