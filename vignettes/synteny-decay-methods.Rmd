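---
title: "Measuring genome-order decay on dated phylogenies with syndecay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring genome-order decay on dated phylogenies with syndecay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syndecay)
```

## The problem

Fungus-farming (attine) ants and their cultivars are a textbook case of
agricultural coevolution, and their genomes rearrange unusually fast: gene
order decays between species at rates exceeding those of other insects.
Quantifying that decay requires a chain of comparative-genomics steps —
one-to-one orthologue inference, syntenic-block detection, conversion of
block coverage into a per-million-year loss rate, mapping of pairwise loss
onto a dated phylogeny — plus supporting statistics for gene-family and
trait comparisons across the tree. `syndecay` implements that chain as
composable, tested R functions, together with a genome-rearrangement
simulator that provides ground-truthed inputs, so every stage can be
validated end to end without access to any particular genome assembly.

## Orthology

One-to-one orthologues are inferred by reciprocal best hits (RBH) from
BLAST-style tabular hit lists: for each query, the best subject is the hit
with maximal bit score among hits with e-value below the cutoff (default
`1e-5`), and a pair is kept only if each member is the other's best hit.
Because the underlying search tools do not guarantee a stable order among
tied hits, ties are broken deterministically (bit score, then e-value,
then subject id); multiple HSPs for one gene pair are collapsed to the
strongest row first. `build_one2one_groups()` assembles multi-species
groups as connected components of the pairwise links, discarding any
component with two genes from one species; by default only components
spanning every species are kept, which is the natural reading of
"one-to-one orthologue groups", and `require_all = FALSE` relaxes it. An
optional alignment-length filter (fraction of the query's longest
alignment) is available but off by default: length cutoffs belong to
family clustering, not to RBH.

## Syntenic blocks and the decay rate

Anchors — orthologue pairs placed at their gene-order indices in the two
genomes — are grouped by scaffold pair and chained greedily left to right.
An anchor joins the current chain iff at most `max_gap = 4` annotated
genes intervene since the previous anchor *in both genomes*; the gap rule
is stated in the literature for "gaps of no more than 4 genes" without
saying in which genome, and symmetric enforcement is the stricter,
deterministic reading. Chains with at least `min_genes = 5` anchors and at
most `max_inversions = 5` inversions are blocks. "Inversions" have no
standard operational definition at block level; we count maximal strictly
descending runs of the partner-genome indices, which is parameter-free and
insensitive to anchor density. The greedy partition is provably the
partition into maximal runs of consecutively joinable anchors, and the
test suite checks it against an exhaustive re-derivation on hundreds of
random instances.

Proportion synteny is anchor-based:
`p_s = (anchors in valid blocks) / (all one-to-one anchors)`. A
length-weighted variant would require base-pair-resolution block
boundaries that gene-order data do not define cleanly. Under an
exponential-decay model of synteny over divergence time `T` (MY), the
implied per-MY loss rate is

\[ r = 1 - p_s^{1/T}. \]

`T` is the age of the pair's most recent common ancestor, the literal
reading of "divergence time"; the tip-to-tip path convention (`2T`) is
available via `t_convention = "path_length"`. `p_s = 0` returns a rate of
1 with a warning; `p_s` above 1 or non-positive `T` are errors.

A property of the 5/4/5 rule worth knowing: inversions confined to the
interior of a long scaffold barely register. Spans of up to
`max_gap + 1` genes stay inside a chain (they only increment the
inversion count), and longer spans split a chain into fragments that are
usually still valid blocks. Measurable synteny loss comes from block
fragments falling below five anchors — which happens readily on
realistically fragmented assemblies with tens of genes per scaffold — and
from translocations that strand short segments elsewhere. Calibration
experiments in this package therefore use fragmented assemblies
(default: 2,000 genes on 100 scaffolds), matching the draft-quality
assemblies of the study system; on a handful of chromosome-length
scaffolds the statistic is intentionally tolerant of local shuffling and
a rate calibration would be flat.

## Mapping loss onto a fixed dated tree

`fit_branch_lengths()` performs Fitch–Margoliash weighted least squares
with a *user-supplied* topology: minimize
\(\sum_{i<j} w_{ij}\,(d_{ij} - \sum_{e \in path(i,j)} b_e)^2\) with
`w = d^-P` (P = 2 by default, the weighting of the classic program; 0 and
1 are available). The path-incidence system is solved directly; with
`nonneg = TRUE` the non-negative solution comes from Lawson–Hanson
active-set iteration, not from truncating an unconstrained fit, because
truncation does not minimize the constrained objective. For a rooted
binary topology the two root-adjacent branches enter every path together
and only their sum is identifiable; the fitted sum is split in proportion
to the branches' time durations and flagged in the output.
`branch_rates()` divides fitted loss by branch duration (MY) to give the
per-branch loss rate; zero-duration branches are reported as `NA` with a
warning.

## Gene-family dynamics at ancestral nodes

A family is *consistently expanded* at an internal node iff its minimum
count over the node's descendant species strictly exceeds its maximum
count elsewhere (and symmetrically for contraction). Strict inequalities
mean ties never count and no family is both. The observed counts are
calibrated by permutation: each permutation shuffles every family's
counts across species independently, which preserves each family's size
spectrum while destroying the phylogenetic association; 5th and 95th
percentiles of the permuted counts (type-7 linear interpolation, for
reproducible envelopes) are reported per node. The alternative of
permuting whole species columns — preserving per-species size profiles —
is available as `mode = "columns"`. The root is rejected: it has no
out-clade.

## Supporting statistics

* `mann_whitney()`: U counted as pairs with `x < y` (+ half-ties),
  reported as `min(U, n1*n2 - U)`; exact two-sided p (doubled exact tail,
  capped at 1) for tie-free samples with `n1 + n2 <= 16`, otherwise a
  tie-corrected normal approximation with continuity correction. The
  exact path is verified against full enumeration of label assignments in
  the tests.
* `kruskal_wallis()`: midrank H with the usual tie-correction divisor and
  a chi-square reference; all-constant data return H = 0, p = 1 by
  convention. For two groups H equals the squared tie-corrected
  Mann–Whitney z, an identity the tests assert.
* `steel_dwass()`: pairwise pooled-midrank z statistics referred to the
  studentized-range distribution with k groups and infinite df. This is
  the large-sample form; output is accompanied by a warning when any
  group has n < 8, where the approximation is rough.
* `binomial_equal_test()`: exact two-sided binomial test at p = 1/2 by
  the minimum-likelihood rule (all outcomes no more likely than the
  observed one), matching the standard implementation at machine
  precision.
* `phylo_anova()`: the classical one-way F, calibrated against a null
  distribution built by simulating Brownian motion on the tree with the
  rate estimated from the data by the GLS closed form with the
  phylogenetic mean (`(x-a)'C^{-1}(x-a)/(n-1)`), recomputing F with the
  same group labels, and taking `p = (1 + #{F_sim >= F_obs}) /
  (n_sim + 1)`. Type-I error is verified at the nominal level in the test
  suite.
* `protein_pi()` / `avg_residue_weight()`: Henderson–Hasselbalch net
  charge over the ionizable groups with the EMBOSS pK table (N-terminus
  8.6, C-terminus 3.6, K 10.8, R 12.5, H 6.5, D 3.9, E 4.1, C 8.5,
  Y 10.1), root-found by bisection on pH 0–14 to |charge| < 1e-6; and
  the mean of standard average residue masses. For a free glycine
  residue the mass is 57.052 Da and a lone alanine has pI 6.1, the
  midpoint of the terminal pKs.

## The simulator: what it emulates and what it does not

`simulate_genomes()` evolves an ancestral gene order down a dated tree.
Event counts per branch are Poisson (rate × branch MY) and events apply
in random order: inversions reverse a segment and flip strands,
translocations move a segment to a uniform position (possibly another
scaffold), losses delete single genes, gains insert novel genes that
never receive similarity hits. Segment spans are geometric with mean 5
genes (truncated at the scaffold end): small rearrangements dominate in
real genomes, and the mean is configurable. Every branch draws from its
own RNG stream derived from the master seed and the branch identity, so
edits elsewhere in a configuration leave a branch's events unchanged, and
identical inputs give byte-identical outputs. Coordinates are re-emitted
as 1-kb genes with 100-bp spacers because only order and strand matter
downstream.

`simulate_hit_table()` gives every surviving orthologue pair a
high-scoring hit in both directions and, with probability `noise` per
orthologous query, one spurious paralog hit with a strictly lower score;
e-values are a fixed decreasing function of bit score. Consequently RBH
recovers the truth map exactly at any noise level — by construction, not
as an empirical observation — which makes the simulator a sharp oracle
for the orthology stage but *not* a test of RBH behaviour under real
paralogy, where best hits can be wrong. Similarly, family counts evolve
by a symmetric ±1 birth–death step process (reflected at zero) with an
optional clade-specific intensity multiplier: a variance-inflation model
of turnover shifts, not a fitted model of any real gene family. Brownian
traits use the exact multivariate-normal representation
(`sigma2 × C` with C the shared-path-length matrix). Passing tests
therefore demonstrate internal consistency of the whole chain under the
model the analysis assumes — exponential decay of synteny, exchangeable
null families, Brownian traits — and nothing about violations of those
assumptions in field data.

## Default conditions and problem sizes

The default pipeline configuration simulates 6 taxa over a 60-MY crown
group, 2,000 genes on 100 scaffolds (about 20 genes per scaffold,
comparable to gene-dense scaffolds of draft insect assemblies), with
rapid rearrangement — 0.5 inversions and 0.1 translocations per MY,
gene loss 2e-4 per gene per MY, gain 0.1 per MY, paralog-hit noise 0.2 —
chosen to emulate the fast genome-order decay that distinguishes
fungus-farming ants from other insects while remaining clearly inside
the regime where `p_s` stays well above zero for all pairs. The test
suite's calibration experiments use two-taxon clades of 2,000 genes at
inversion rates between 0.05 and 0.4 per MY (20 replicates per level),
1,000-family count matrices on 8 taxa with 200-permutation envelopes
over 1,000 simulated datasets, and 500 phylogenetic-ANOVA replicates at
200 simulations each; these sizes give stable Monte-Carlo estimates at
interactive runtimes.

## Numerical choices and degenerate inputs

* Gene order ties (equal starts) break by gene id; duplicate gene ids are
  errors.
* `synteny_proportion()` with zero anchors is an error (0/0), while "no
  blocks" is a legitimate 0.
* The weighted least-squares weight for a zero distance is 1, so
  identical genomes do not produce infinite weights.
* Percentile envelopes use quantile type 7 so envelopes are identical
  across platforms.
* The exact Mann–Whitney path refuses ties rather than silently
  approximating them.
* Bisection for pI always brackets the root because the termini guarantee
  positive charge at pH 0 and negative at pH 14.

## Known limitations

Block detection is greedy without lookahead; the exhaustive cross-check
in the tests covers instances up to 30 genes, not adversarial large
cases. The simulator has no nucleotide sequences, no duplication-aware
gene trees and no whole-genome duplication. Steel–Dwass has no exact
small-sample tables. The family birth–death process is stepwise, not a
continuous-time linear birth–death model. The pipeline is single-run,
single-machine; there is no caching scheduler.
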