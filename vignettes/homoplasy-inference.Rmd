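---
title: "Inferring independent allele emergence with sliding-window phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring independent allele emergence with sliding-window phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homoplasr)
```

## The problem

When the same alternate allele is found in several strains of a wild
microbial panel, three histories can explain it: a single emergence
inherited by descent; repeated, independent emergence of the same
mutation (homoplasy); or an ancestral polymorphism maintained across
lineage splits, most plausibly by balancing selection. Distinguishing
descent from the alternatives requires comparing the variant's
distribution with the strain phylogeny — but in heavily admixed panels
such as wild *S. cerevisiae* there is no single strain phylogeny: each
chromosome segment has its own ancestry, and reading a variant against
the genome-wide tree manufactures spurious "repeated emergence" at
every mosaic boundary.

`homoplasr` addresses this by re-estimating the phylogeny locally, in a
sliding window of variants around each locus, and by counting
emergences with a deliberately conservative reconstruction whose error
direction is known (an underestimate). The package also ships the
simulators needed to calibrate the inference on populations with a
recorded ground truth.

## The model and its assumptions

**Local trees.** For a focal variant, the window is the `W = 500`
variants centred on it, truncated — shifted, kept at full width — at
chromosome ends and never crossing a chromosome boundary (mosaicism is
a per-chromosome phenomenon, so windows spanning two chromosomes would
mix unrelated ancestries). The focal variant is included in its own
window; with hundreds of variants per window its own contribution to
the distances is negligible, and excluding it is available as an
option. Pairwise distances are raw SNP-difference counts over co-called
loci (an option normalises by co-called count; off by default). Trees
are built by neighbor joining — exact on additive distances, fast
enough to rebuild hundreds of thousands of times — with two
determinism guarantees: ties in the join criterion resolve toward the
lowest-sorting strain-name pair, and negative branch-length estimates
are clamped to zero.

**Rooting.** The emergence rules walk a rooted binary tree, and no
outgroup exists inside a window, so each local tree is midpoint-rooted.
Midpoint rooting is the natural choice when rate variation is modest;
its failure mode (root on the wrong long branch) at worst adds a single
spurious event, in keeping with the method's conservative design.

**Emergence counting.** In postorder, every internal node takes a state
in `{0, 1, EVENT}` from its two children: equal genotypes pass through;
opposing genotypes create an EVENT (one counted emergence); an EVENT
child next to a genotype child resolves to the genotype; two EVENT
children merge into one EVENT *without* counting a new event. The rules
are symmetric in reference/alternate, so a "multiple emergence" call
(n ≥ 2 events for a shared variant) does not depend on which allele is
labelled alternate. Two corollaries matter for interpretation:

- Absent (EVENT, EVENT) merges, the count equals the binary Fitch
  small-parsimony change count (verified exhaustively in the tests);
  merges only lower it. The inference therefore *undershoots* true
  homoplasy.
- A variant fixed in all (called) strains reconstructs to the root
  without any event: emergence on the stem lineage is invisible, which
  is correct behaviour for a method that counts emergences *within* the
  panel's history.

**Missing data** is a first-class third state: loci missing in a strain
are excluded pairwise from distances, and missing leaves are pruned —
never imputed — before the reconstruction.

**Clade collapse.** Strain sets too closely related for their internal
phylogeny to be resolved (in wild yeast, a nine-member wine/European
group) can be collapsed to a single pseudo-strain carrying the modal
genotype (ties toward reference), so no events are ever inferred within
the collapsed clade. The collapse is configuration-driven — a strain
list, never hard-coded — and sharing is still counted on the
uncollapsed panel.

## The simulators and what they emulate

`build_admixed_population()` emulates a wild-yeast-like panel: 5
founder lineages with 30,000 private mutations each; 10 mosaics made by
mating two distinct founders with one crossover per chromosome (breakpoint
uniform in physical bp) and keeping one haploid product; then 10,000
further private mutations in each of the 15 strains — 300,000 recorded
mutation events in total on the real 16-chromosome S288C karyotype
(~1.21e7 bp, scalable by a single factor). Mutations are uniform in
position with transitions:transversions = 3:1; a site already carrying
the alternate allele in the same isolate is redrawn (reversion
neglected), while independent hits on the same site in different
lineages are allowed — that *is* homoplasy, and the truth log records
every event so the true count is exact. Recurrent hits are treated as
recurrences of the same alternate allele (genotypes are biallelic 0/1;
allele identity is cosmetic at these densities).

`overlay_balanced_polymorphisms()` adds `round(f_ancestral * N_total)`
loci (N_total = variants already segregating) at fresh positions; each
strain independently draws the alternate with probability
`MAF_balanced`, modelling single-colony sequencing from a population in
which the polymorphism is maintained. Whether balanced loci may
coincide with existing variant positions is a free choice; fresh
positions keep the truth log unambiguous.

`place_neutral_variants_on_tree()` drops variants on branches with
probability proportional to branch length and propagates the alternate
to all descendant leaves — the neutral, selection-free expectation for
sharing and apparent multiple emergence. Variant positions are uniform
on the genome; matching an empirical variant-density profile is out of
scope and noted as a simplification.

`simulate_f6_cross()` models an inbred haploid mapping panel (defaults:
1,125 progeny, 12,054 markers). The cross design is six rounds of
sib-mating: each generation two recombinant haploids are produced from
the current pair and mated; one haploid is retained at the end. This is
a pragmatic stand-in for any "highly inbred F6" design — what matters
for mapping is the progressive shrinkage of linkage blocks, which the
tests verify directly (r² decays with inter-marker distance). Phenotype
= sum of planted effects + per-plate offset + replicate noise, with
replicate noise SD 1 so planted effects are in approximately phenotype-SD
units, and plate effects off by default.

What the simulations do *not* emulate: mutation-rate heterogeneity
along the genome, indels and structural variants, diploidy beyond the
meiosis abstraction, selection during the forward simulation (other
than the balancing overlay), and empirical variant-density profiles.
Passing tests therefore demonstrate correctness of the inference under
the stated generative model, not robustness to every property of real
resequencing data.

## QTL mapping choices

Phenotypes are replicate means, Z-scored across progeny. Forward
selection adds the best partial-F predictor while p ≤ 1e-3 and then
removes terms whose leave-one-out (fitted-last) F-test p exceeds 1e-5 —
incremental sums of squares for selection, leave-one-out for the final
screen, the standard stepwise convention. Plate number and plate
position enter as pseudo-genotype columns that compete in the selection
but are flagged non-genetic and never reported as QTLs. Ties break
toward the lowest genomic coordinate, making the procedure
deterministic and column-order invariant. Variance explained is
reported as incremental SS over total SS.

Fine mapping reconstructs the in-silico reciprocal-hemizygote logic:
for candidate *c* and each nearby alternative *a* (linkage
neighbourhood `r² ≥ 0.5`, overridable in bp), only progeny with
discordant genotypes at *c* and *a* separate the two hypotheses; the
candidate's association with the QTL-residual phenotype is tested in
that subset, and the QTN score is the weakest evidence across
alternatives (−log10 of the largest p). The contract is the *ranking*
and the resolved/unresolved call, not the score's absolute scale: a
locus is resolved only when a unique candidate attains the maximum
score with nominal evidence, and candidate pairs in perfect LD are
unresolvable by construction. The empirical FDR permutes phenotypes
across progeny and re-runs the entire selection.

## Selection tests

The directional test bins within-trait, within-chromosome QTL pairs by
distance in marker units; a pair is coherent when both trait-increasing
alleles descend from the same parent. The per-bin fraction is computed
per trait and averaged (so no single trait dominates), while the
binomial test against 0.5 pools pairs; both the per-trait average and
the pooled fraction are reported because either aggregation is
defensible. The niche test asks, for variants carried by exactly 2 or 3
strains, whether all carriers share one niche label; multiplicities ≥ 4
are excluded because few niches hold that many isolates. Its null
distribution re-places variants neutrally on the strain tree 50 times;
permutation p-values use add-one smoothing, so they are never exactly
zero and are bounded below by 1/(reps+1).

## Numerical and degenerate-input choices

- Window width must be ≥ 4; chromosomes with fewer variants are scanned
  with the whole chromosome as window and flagged low-confidence.
- NJ on all-zero distances (identical strains) is well defined and
  deterministic via the tie rule; midpoint rooting of a zero-diameter
  tree roots at the first leaf's edge.
- Zero-variance phenotypes and all-zero branch-length trees are
  errors, not silent degeneracies.
- Collinear predictors are skipped during selection and dropped (with a
  warning) from the final model.
- All randomness flows through R's RNG; every simulator accepts and
  records a seed, and identical seeds reproduce populations
  bit-for-bit.

## Problem sizes used by the tests

The full study design (15 strains, ~330,000 loci after the balancing
overlay, 500-variant windows, 5 replicates) runs in a few minutes and
is exercised end-to-end by the acceptance checks. Unit and property
tests run the same machinery on proportionally scaled problems — genome
scale 0.05–0.2 with window widths 25–100, chosen to preserve the two
geometric ratios that control inference quality: window span relative
to chromosome length (windows should rarely straddle a mosaic
breakpoint) and informative variants per window. The exhaustive
Fitch-equivalence check covers all rooted binary topologies on 5 and 6
leaves crossed with all binary labelings, plus randomized trees to 10
leaves; beyond 6 leaves exhaustive enumeration grows combinatorially
while adding no new rule interactions, so sampling is used.

## Known limitations

- Homoplasy and balancing selection are not distinguishable per variant
  by this method; only their population-level signatures differ.
- The emergence count is a lower bound; (EVENT, EVENT) merges and
  events hidden inside collapsed clades are never recovered.
- Midpoint rooting can misplace the root in windows with strong rate
  asymmetry, occasionally adding one event.
- No maximum-likelihood or Bayesian tree inference, no bootstrap
  support, no ancestral recombination graphs, no epistasis search or
  kinship correction in mapping.
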