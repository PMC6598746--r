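---
title: "Detecting reticulate symbionts by stepwise multi-gene incongruence analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting reticulate symbionts by stepwise multi-gene incongruence analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloconflict)
```

## The problem

Dinoflagellate symbionts of reef corals are typed by short marker
sequences from three genomes: a slowly evolving mitochondrial gene
(*cob*-like), the multi-copy nuclear ribosomal spacer ITS2, and the
hypervariable non-coding chloroplast region psbA^ncr^. In a strictly
clonal, tree-like history all three markers tell the same story. A sample
whose nuclear marker places it in one lineage while both organellar
markers place it in another is evidence of reticulate evolution —
hybridisation followed by backcrossing, or organelle capture — unless the
discordance can be explained more cheaply by noise (a single aberrant
sequence, parsimony-uninformative private mutations) or by incomplete
lineage sorting (ILS), the persistence of ancestral polymorphism through
lineage splits.

`phyloconflict` implements the stepwise screen this field uses to separate
those explanations, as a tested, reusable pipeline:

1. a **gated incongruence length difference (ILD) test** on the
   three-marker supermatrix (is there *any* incongruence here?);
2. per-locus **ML gene trees** with bootstrap collapse, compared by
   **reciprocal Approximately Unbiased (AU) tests** (which markers
   disagree, and is the disagreement symmetric?);
3. **pairwise ILD tests** at a Bonferroni-corrected level (exactly which
   pair of markers is incongruent?);
4. an **agreement search** that names the taxa no common tree can
   accommodate (who causes it?);
5. **rule-based raw-sequence verification** of each flagged sample
   (is it a hybrid pattern, a divergent sequence, or noise?); and
6. **background amplicon-population profiling** that weighs hybridisation
   against ILS using NGS read counts.

## The tests

### ILD / partition homogeneity

The ILD statistic is the sum over partitions of the maximum-parsimony
(MP) tree length, with gaps coded as a fifth character state. Under the
null hypothesis that all partitions share one history, reassigning columns
to partitions at random (preserving partition sizes, jointly across
partitions) should not change that sum systematically. Significance means
the *defined* partitions are **more parsimonious** (lower summed length)
than random ones, so the p-value counts permutation replicates whose sum
is less than or equal to the observed sum, with the add-one Monte-Carlo
correction: `p = (1 + #{null <= obs}) / (1 + R)`. The add-one correction
keeps `p` in `(0, 1]`; it differs from the uncorrected ratio by at most
`1/(R+1)`.

The test is run in two stages: a screen with 100 replicates and MaxTrees
1,000, and — only when the screening p-value falls below 0.2 — a
confirmatory run with 1,000 replicates and MaxTrees 10,000. Post-hoc
pairwise tests on two markers at a time use a Bonferroni-corrected
`alpha = 0.017` (three tests per site).

The MP engine underneath performs random-sequence-addition starts followed
by NNI hill-climbing with bounded sideways ("plateau") walks; all equally
most-parsimonious trees on the final plateau are kept up to the MaxTrees
cap. Parsimony landscapes are plateau-rich, and pure ascent without
sideways moves stalls measurably often on small noisy alignments. The
swap neighbourhood is NNI rather than the TBR a desktop parsimony program
might use; for the ILD's validity only the *identity* of the search
procedure between observed and permuted partitions matters, and the test
suite verifies that the search attains the exhaustive-search optimum on
random alignments of up to 8 taxa. Scoring is Hartigan's generalisation of
Fitch's algorithm, so multifurcating trees are scored exactly under unit
cost; `N` is fully ambiguous; every `-` is one fifth state regardless of
whether it is terminal or internal (the convention when indel placement is
taken at face value from the alignment).

### Gene trees

Likelihood work treats gaps and `N` as missing data (marginalised) — the
standard ML convention — while the parsimony side keeps the gap as a fifth
state; the two conventions deliberately coexist. Model selection fits
{JC69, K80, HKY85, GTR} × {+/- Γ4} by AICc on a fixed
neighbour-joining (Jukes-Cantor) starting topology, ties resolved toward
the simpler model; with very short alignments the AICc penalty is
undefined for complex candidates and the selection warns. The ML search
alternates branch-length optimisation with NNI accept-if-better moves.
Bootstrap replicates resample columns and use a reduced replicate search
(NJ on the resampled JC distances plus a single parsimony NNI sweep),
after which nodes under 50% support collapse into polytomies. The
hypervariable marker keeps the reduced addition-replicate preset its size
demands.

### Reciprocal AU tests

For each base locus the three focal gene trees are evaluated together
with 100 random trees drawn *uniformly* over unrooted binary labelled
topologies (sequential addition at a uniformly chosen edge — the
equiprobable model; uniformity is verified by a chi-square test over all
15 five-taxon topologies). Branch lengths are re-optimised per candidate
tree on the base alignment: the AU test needs likelihoods on the
evaluation data, and foreign branch lengths would bias against transferred
topologies. Per-site log-likelihoods then drive RELL resampling (no
re-optimisation inside the bootstrap) at ten scales `r = 0.5 ... 1.4`
with 10,000 replicates split evenly.

The AU p-value comes from the multiscale model
`BP(r) = Phi(-(d*sqrt(r) + c/sqrt(r)))` with signed distance `d` and
curvature `c`, and `au_p = 1 - Phi(d - c)`. The curve is fitted by
maximising the exact binomial likelihood of the per-scale win counts,
initialised from the weighted least-squares fit of `qnorm(1 - BP)`. The
exact-likelihood step matters for decisively losing trees: a tree that
wins a handful of resamples only at the smallest scale carries most of its
information in *zero* counts, which a least-squares fit on clamped
proportions cannot use. Curves pinned to one bound with at most two stray
counts short-circuit to that bound with a degeneracy flag. A flat curve at
`BP = 0.5` gives `d = c = 0` and `au_p = 0.5` exactly. The
Shimodaira-Hasegawa test (centered-RELL null of the log-likelihood
deficits) is provided alongside; it is the more conservative test and the
suite checks `p_SH >= p_AU` on simulated site likelihoods.

A marker pair is declared incongruent only on **reciprocal** rejection at
`alpha = 0.05/6` (six comparisons per site; 0.05/6 = 0.00833..., and the
rounded 0.0085 is available as a preset). A rejection is flagged
`resolution_confounded` when the base locus's own tree out-resolves
*every* other focal tree by more than a configurable margin (default 3
internal edges): a hypervariable marker demands a more complex tree than
any other marker can offer, and rejects them regardless of history, so
such rejections do not count as evidence when the pipeline decides whether
to proceed to post-hoc testing.

### Naming the culprits

Taxon-level blame is assigned by minimal-removal agreement search: the
smallest leaf set whose removal makes the two collapsed gene trees
*compatible* (a polytomy counts as compatible with any resolution of it —
soft semantics, matching the support-based collapapse that precedes the
comparison). Subsets up to size 3 are searched exhaustively in
lexicographic order; beyond that a greedy round removes the leaf whose
removal most reduces the count of incompatible split pairs. Robinson-
Foulds distances are reported alongside, and tanglegram leaf orderings
(iterated barycenter crossing reduction) are provided for visual
inspection. This operational definition — "the taxa that cannot be
reconciled" — replaces a full hybridisation-network computation, which is
out of scope.

### Verification rules

Flagged samples are classified against exact-match sequence groups
(clusters of at least two non-flagged samples with identical sequences,
`delta = 0` by default). Group formation masks *noise columns* — columns
whose every minority state occurs in exactly one sample — because
single-sequence polymorphisms cannot define a group; the divergence call
below uses raw (unmasked) distances. The rules fire in order:

1. **divergent_sequence** — at some locus the sample is further from every
   group than the divergence threshold (default: the larger of 10
   mismatches and 5% of the locus length, so ordinary between-type
   distances never register);
2. **uninformative** — every column on which the sample conflicts with its
   organellar type is autapomorphic (a state unique to that sample);
3. **reticulate** — the sample sits in one multi-member group at an
   organellar locus and a *disjoint* multi-member group at the nuclear
   locus, organellar loci tried from the most finely grouped down (a
   near-invariant marker whose single group spans several types cannot
   mask the informative one);
4. **congruent** otherwise.

The multi-member requirement encodes the argument that parental types must
be recovered repeatedly in non-flagged samples before a sample bridging
them counts as a hybrid.

### Hybridisation vs ILS

ILS predicts that the ancestral polymorphism survives *inside* the
population: members of the affected type should carry both nuclear
variants intragenomically, visible as widespread counterpart traces in the
NGS read counts. Hybridisation predicts essentially pure parental
populations, with the counterpart variant absent both from them and from
the flagged sample's own amplicon population. The evidence summary labels
a reticulate sample `hybridisation-favored` when mean counterpart trace
frequency is below 1% in both parental populations and absent from the
flagged sample, `ILS-plausible` when counterpart variants are widespread
(present above trace level in at least 25% of a parental population) or
retained in the flagged sample, and `indeterminate` otherwise or without
read counts. This is a labelled evidence summary, never a statistical
test: the data needed to reject ILS formally (population phasing, many
unlinked nuclear loci) are not available at these marker panels, by
design.

## The synthetic-data generator

Because the workflow's properties can only be demonstrated with known
truth, the generator is first-class, tested code. It emulates the
structure of the real marker panels:

* three loci of 787 / 369 / 531 columns;
* two type radiations ("C1-like", "C3-like") of two types each, five
  samples per type (~21-22 samples per site with one planted hybrid);
* the slow organellar locus nearly invariant (2 diagnostic columns across
  the radiation split, none between sister types);
* the nuclear locus with 4 diagnostic columns between sister types and ~8
  across radiations;
* the hypervariable organellar locus with 64 changed columns across the
  radiation split *including* a 49-column contiguous deletion block
  (gap as fifth state) private to one radiation, plus 8 columns between
  sister types;
* Poisson-distributed private mutations per sample (means 0.05 / 0.15 /
  0.5 per locus, reflecting each marker's variability);
* planted hybrids copying the nuclear consensus of a donor type in the
  opposite radiation while keeping the recipient's organellar sequences;
* optional confounders: a hyper-divergent chloroplast sequence (20% of
  columns mutated) and extra autapomorphic singletons;
* NGS read-count tables (multinomial, 20,000 reads, 95% dominant variant)
  with a zero counterpart weight under hybridisation, and an ILS scenario
  in which every member of the affected type carries 10-40% of the
  counterpart variant intragenomically and a configurable number of
  members are dominance-switched.

What the generator does *not* emulate: recombination within loci,
alignment error, PCR/sequencing error models, rate variation along
branches beyond the fixed divergence counts, and coalescent-exact ILS.
Passing tests therefore demonstrate that the pipeline recovers planted
signal of the documented shape and strength — not performance on any
particular empirical dataset.

## Numerical choices and degenerate inputs

* Monte-Carlo p-values always carry the add-one correction, so `p = 0`
  never occurs.
* RELL tie-splitting is exact (`sum over trees of BP = 1` at every scale).
* Branch-length optimisation is delegated to the likelihood engine's
  cyclic single-branch optimiser with a bounded iteration budget; on data
  with too few distinct sequences for NNI machinery the NJ topology with
  optimised branch lengths stands.
* Saturated JC distances are capped (with a warning); all-identical
  sequences yield a star tree, flagged.
* Ties among equally parsimonious trees are kept in discovery order up to
  MaxTrees; the best length is unaffected by the cap.
* Ties in dominant-variant calls break toward the lexicographically first
  variant label.
* Master seeds fan out to stages through a fixed counter scheme, so every
  stage is independently reproducible and the whole pipeline is
  deterministic given its configuration seed.

## Problem sizes used by the test suite

The suite exercises the pipeline at the generator's default site size
(~21 samples, 1,687 columns) with 20 seeded replicates per condition;
the ILD calibration uses 100 two-locus simulations at 10 taxa with 100
permutation replicates each; AU/SH calibration uses 50 simulated
site-likelihood matrices at a reduced replicate budget (5,000); search
oracles run on 50 random alignments of up to 8 taxa against exhaustive
enumeration. These sizes keep a full run of the suite in the
tens-of-minutes range on one CPU while leaving every statistical check
with usable resolution.

## A worked example

```{r example, eval = FALSE}
library(phyloconflict)

ds  <- simulate_multilocus_dataset(sim_params(), seed = 7)
rc  <- simulate_read_counts(ds$truth, seed = 5)
cfg <- pipeline_config(seed = 11)
rep <- run_site_pipeline(ds$alignments, cfg, read_counts = rc,
                         dataset = "demo")
print(rep)
rep$reticulate_samples          # exactly the planted hybrid
ds$truth[ds$truth$is_hybrid, ]  # ground truth for comparison
```

The `analysis/` directory contains the same workflow as numbered driver
scripts (`01_simulate.R` ... `05_report.R`) that write their tables and
reports under `results/`.

## Known limitations

* The MP search is NNI-based; on large, noisy alignments it can return a
  length above the true optimum. The ILD remains valid because observed
  and permuted partitions share one procedure, but absolute tree lengths
  should not be over-interpreted.
* The AU implementation covers the standard multiscale grid; scale grids
  whose smallest resample would be empty are skipped with a warning.
* The agreement search is exhaustive only up to removal sets of size 3;
  datasets where more taxa must be removed fall back to a greedy search
  that is not guaranteed minimal.
* ILS can be made *plausible* or *disfavoured*, never formally rejected,
  from these inputs.
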