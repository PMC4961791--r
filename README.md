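# syndecay

Comparative genomics of gene order on dated phylogenies. `syndecay`
quantifies how quickly genomes lose synteny — conservation of gene order —
between species, the signal that revealed exceptionally fast structural
genome evolution in fungus-farming (attine) ants and their relatives. It
is written for researchers who have per-species gene-position tables and
pairwise similarity searches (or who want to study the behaviour of these
estimators on simulated genomes) and need the whole chain from orthology
to per-branch rearrangement rates as reproducible R functions.

## What it computes

* **One-to-one orthology** by reciprocal best hits from BLAST outfmt-6
  tables (e-value < 1e-5, deterministic tie-breaking), and multi-species
  one-per-species orthologue groups (`rbh_pairs()`,
  `build_one2one_groups()`).
* **Syntenic blocks** between each genome pair: chains of collinear
  orthologue anchors with at least 5 genes, gaps of at most 4 annotated
  genes in either genome, and at most 5 inversions per block
  (`detect_blocks()`).
* **Proportion synteny and its decay rate.** With `p_s` the fraction of
  orthologue anchors inside valid blocks and `T` the pair's divergence
  time (MY), the per-MY synteny-loss rate under exponential decay is

  `r = 1 − p_s^(1/T)`

  (`synteny_proportion()`, `loss_rate()`, `pairwise_loss_matrix()`).
* **Per-branch loss rates** by Fitch–Margoliash weighted least squares of
  the pairwise loss matrix on a *fixed* dated topology (weights `d^-P`,
  P = 2 by default; non-negative branch lengths via active-set NNLS), then
  division by branch durations (`fit_branch_lengths()`,
  `branch_rates()`).
* **Gene-family dynamics**: families consistently expanded or contracted
  at each ancestral node (strict min-in > max-out rule) with 5th/95th
  permutation percentiles (`consistent_dynamics()`,
  `permutation_percentiles()`).
* **Supporting statistics**: exact Mann–Whitney U, tie-corrected
  Kruskal–Wallis, Steel–Dwass all-pairs post-hoc comparisons, the exact
  equal-probability binomial test, simulation-based phylogenetic ANOVA
  under a Brownian-motion null, and pepstats-style protein isoelectric
  points and average residue weights.
* **A genome-rearrangement simulator** (`simulate_tree()`,
  `simulate_genomes()`, `simulate_hit_table()`,
  `simulate_family_counts()`, `simulate_bm_traits()`) that evolves gene
  orders by Poisson-distributed inversions, translocations, gene losses
  and gains along a dated tree and emits annotations, hit tables, family
  counts and traits with known ground truth.

## Worked example

Simulate four genomes diverging for up to 40 MY under rapid
rearrangement, recover orthologues, and map synteny loss onto the tree:

```r
library(syndecay)

tree <- simulate_tree(n_taxa = 4, crown_age = 40, seed = 7)
sim  <- simulate_genomes(tree, sim_config(n_scaffolds = 50, n_genes = 1000,
                                          inversion_rate = 0.5,
                                          translocation_rate = 0.1,
                                          seed = 7))
hits  <- simulate_hit_table(sim$genomes, sim$truth, noise = 0.2, seed = 7)
pairs <- rbh_pairs(hits[["t1__t2"]], hits[["t2__t1"]])
synteny_stats(sim$genomes$t1, sim$genomes$t2, pairs,
              T = mrca_age(tree, "t1", "t2"))
#> synteny_stats: 997/1000 anchors in blocks; p_s = 0.9970; T = 9.98956 MY;
#>   loss rate = 0.00030 /MY
```

997 of the 1,000 one-to-one anchors still sit in valid blocks after ~10 MY
of divergence, so this pair has lost 0.3% of its synteny — an implied
decay rate of 3×10⁻⁴ per MY. Doing this for every pair and fitting the
loss matrix on the dated tree:

```r
pairsets <- list()
sp <- names(sim$genomes)
for (i in 1:3) for (j in (i + 1):4) {
  k <- paste0(sp[i], "__", sp[j])
  pairsets[[k]] <- rbh_pairs(hits[[k]], hits[[paste0(sp[j], "__", sp[i])]])
}
mats <- pairwise_loss_matrix(sim$genomes, pairsets, tree)
fit  <- fit_branch_lengths(tree, mats$loss)
round(branch_rates(fit), 5)
#>   parent child duration    loss root_pair    rate
#> 1      5     6 30.01044 0.02136         1 0.00071
#> 2      6     1  9.98956 0.00098         0 0.00010
#> 3      6     7  0.54082 0.00000         0 0.00000
#> 4      7     2  9.44874 0.00596         0 0.00063
#> 5      7     3  9.44874 0.00204         0 0.00022
#> 6      5     4 40.00000 0.02847         1 0.00071
```

Each row is a branch of the dated tree: `loss` is its fitted share of the
pairwise synteny loss and `rate` the loss per MY (the two root-adjacent
branches are only identifiable as a sum, split by duration and flagged in
`root_pair`). Deeper, longer branches here carry most of the loss, as
expected when rearrangement ticks along at a roughly steady per-MY rate.

The same analysis runs end to end from a single configuration with
`run_pipeline(pipeline_config(seed = 1), "out/")`, which writes
annotations, hit tables, pair sets, PHYLIP loss/rate matrices, the
branch-rate table and a JSON report with provenance headers.

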