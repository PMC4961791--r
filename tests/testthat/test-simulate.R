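test_that("simulated trees are dated, calibrated and reproducible", {
  tr <- simulate_tree(8, 60, seed = 42)
  expect_s3_class(tr, "phylo")
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_true(ape::is.binary(tr))
  expect_equal(max(node_ages(tr)), 60)
  expect_identical(ape::write.tree(tr),
                   ape::write.tree(simulate_tree(8, 60, seed = 42)))
  cherry <- simulate_tree(2, 10, seed = 1)
  expect_equal(sort(cherry$edge.length), c(10, 10))
  expect_error(simulate_tree(1, 10), "n_taxa")
})

test_that("zero-rate genomes are identical to the ancestor", {
  tr <- simulate_tree(4, 30, seed = 3)
  sim <- simulate_genomes(tr, sim_config(3, 120, seed = 5))
  for (sp in names(sim$genomes)) {
    g <- sim$genomes[[sp]]
    expect_equal(nrow(g), 120)
    expect_equal(sub("^t\\d+\\.", "", g$gene_id), sprintf("g%05d", 1:120))
    expect_true(all(g$strand == "+"))
  }
  expect_true(all(!is.na(as.matrix(sim$truth$ortholog_map[-1]))))
  expect_equal(nrow(sim$truth$event_log), 0)
})

test_that("branch event counts follow the Poisson law", {
  tr <- simulate_tree(2, 10, seed = 9)     # two branches of 10 MY
  r <- 0.3
  n_rep <- 1000
  counts <- vapply(seq_len(n_rep), function(i) {
    sim <- simulate_genomes(tr, sim_config(2, 40, inversion_rate = r,
                                           seed = i))
    nrow(sim$truth$event_log)
  }, 1)
  mu <- r * 10 * 2                          # both branches
  se <- sqrt(mu / n_rep)                    # Poisson variance = mean
  expect_lt(abs(mean(counts) - mu), 3 * se)
})

test_that("genome simulation is byte-identical under a fixed seed", {
  tr <- simulate_tree(3, 25, seed = 4)
  cfg <- sim_config(2, 80, inversion_rate = 0.2, translocation_rate = 0.1,
                    gene_loss_rate = 1e-3, gene_gain_rate = 0.1, seed = 77)
  expect_identical(simulate_genomes(tr, cfg), simulate_genomes(tr, cfg))
})

test_that("hit tables are deterministic, anti-monotone and noise-bounded", {
  tr <- simulate_tree(3, 20, seed = 2)
  sim <- simulate_genomes(tr, sim_config(2, 60, inversion_rate = 0.05,
                                         seed = 8))
  h1 <- simulate_hit_table(sim$genomes, sim$truth, noise = 0.5, seed = 13)
  h2 <- simulate_hit_table(sim$genomes, sim$truth, noise = 0.5, seed = 13)
  expect_identical(h1, h2)
  tab <- h1[["t1__t2"]]
  expect_named(tab, c("qseqid", "sseqid", "pident", "length", "mismatch",
                      "gapopen", "qstart", "qend", "sstart", "send",
                      "evalue", "bitscore"))
  expect_lte(cor(tab$bitscore, tab$evalue, method = "spearman"), 0)
  expect_error(simulate_hit_table(sim$genomes, sim$truth, noise = 2),
               "noise")
})

test_that("family counts respect the null and shifted generative regimes", {
  tr <- simulate_tree(6, 40, seed = 21)
  flat <- simulate_family_counts(tr, 50, base_lambda = 0, seed = 3)
  expect_true(all(flat == flat[, 1]))        # no events: root counts only
  expect_identical(simulate_family_counts(tr, 50, 0.1, seed = 3),
                   simulate_family_counts(tr, 50, 0.1, seed = 3))
  node <- ape::getMRCA(tr, c("t1", "t2"))
  shifted <- simulate_family_counts(tr, 1000, base_lambda = 0.05,
                                    shift = list(node = node,
                                                 multiplier = 10),
                                    seed = 10)
  inc <- tr$tip.label[unlist(ape::prop.part(tr)[[
    node - length(tr$tip.label)]])]
  expect_gt(mean(shifted[, intersect(colnames(shifted), inc)]),
            mean(shifted[, setdiff(colnames(shifted), inc)]))
  expect_true(all(shifted >= 0))
})

test_that("Brownian traits have the BM variance and group structure", {
  tr <- simulate_tree(6, 10, seed = 5)
  groups <- setNames(rep(c("g1", "g2"), each = 3), tr$tip.label)
  # deterministic limit: vanishing rate leaves only the group offsets
  tiny <- simulate_bm_traits(tr, 1e-12, groups,
                             group_effects = c(g1 = 0, g2 = 1), seed = 2)
  expect_lt(max(abs(tiny$value[groups == "g1"])), 1e-4)
  expect_lt(max(abs(tiny$value[groups == "g2"] - 1)), 1e-4)
  # tip variance across replicates = sigma2 * root-to-tip length
  sigma2 <- 0.5
  reps <- vapply(seq_len(2000), function(i)
    simulate_bm_traits(tr, sigma2, groups, seed = i)$value[["t1"]], 1)
  expect_lt(abs(var(reps) - sigma2 * 10),
            3 * sigma2 * 10 * sqrt(2 / 1999))  # 3 SE of a variance
  expect_identical(simulate_bm_traits(tr, 1, groups, seed = 7),
                   simulate_bm_traits(tr, 1, groups, seed = 7))
})
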