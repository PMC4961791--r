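test_that("exact Mann-Whitney matches small-sample enumeration", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p.value, 2 / 6)
  r2 <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r2$statistic), 0)
  expect_equal(r2$p.value, 0.1)
  # identical samples: U at its centre, p = 1 (ties -> normal path)
  r3 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(r3$statistic), 9 / 2)
  expect_equal(r3$p.value, 1)
  expect_error(mann_whitney(numeric(), 1:3), "non-empty")
  # enumeration oracle across random tie-free datasets
  withr::with_seed(99, {
    for (i in 1:60) {
      n1 <- sample(2:7, 1); n2 <- sample(2:7, 1)
      v <- sample(1000, n1 + n2)           # tie-free
      x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
      expect_equal(mann_whitney(x, y)$p.value, mwu_enum_p(x, y),
                   tolerance = 1e-12)
    }
  })
  # and agrees with the standard exact implementation
  withr::with_seed(7, {
    x <- rnorm(6); y <- rnorm(5) + 1
    expect_equal(mann_whitney(x, y)$p.value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  })
})

test_that("Kruskal-Wallis H matches hand computation and the base test", {
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  r <- kruskal_wallis(g)
  expect_equal(unname(r$statistic), 12 / 42 * (9 / 2 + 49 / 2 + 121 / 2) - 21,
               tolerance = 1e-12)
  expect_equal(unname(r$statistic), 4.5714, tolerance = 1e-4)
  withr::with_seed(3, {
    gg <- list(rnorm(8), rnorm(7) + 0.5, round(rnorm(9), 1))  # with ties
    base <- stats::kruskal.test(gg)
    mine <- kruskal_wallis(gg)
    expect_equal(unname(mine$statistic), unname(base$statistic),
                 tolerance = 1e-12)
    expect_equal(mine$p.value, base$p.value, tolerance = 1e-12)
  })
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2)))$p.value, 1)
  expect_equal(unname(kruskal_wallis(list(c(2, 2), c(2, 2)))$statistic), 0)
  # two-group identity: H equals the squared tie-corrected MWU z
  withr::with_seed(11, {
    x <- rnorm(9); y <- rnorm(12) + 0.3
    z <- mann_whitney(x, y, method = "normal", correct = FALSE)$z
    expect_equal(unname(kruskal_wallis(list(x, y))$statistic), z^2,
                 tolerance = 1e-9)
  })
})

test_that("Steel-Dwass adjusted p-values behave across separations", {
  same <- list(g1 = 1:10, g2 = 1:10, g3 = 1:10)
  expect_warning(P0 <- steel_dwass(lapply(same, head, 5)), "n < 8")
  P1 <- steel_dwass(same)
  expect_true(all(P1[upper.tri(P1)] > 0.95))
  far <- list(a = 1:8, b = 11:18, c = 21:28)
  P2 <- steel_dwass(far)
  expect_true(all(P2[upper.tri(P2)] < 0.05))
  # multiplicity: adjusted p >= the unadjusted normal-approximation p
  withr::with_seed(5, {
    g <- list(rnorm(9), rnorm(9) + 0.8, rnorm(9))
    P <- steel_dwass(g)
    for (i in 1:2) for (j in (i + 1):3) {
      un <- mann_whitney(g[[i]], g[[j]], method = "normal",
                         correct = FALSE)$p.value
      expect_gte(P[i, j] + 1e-12, un)
    }
  })
  expect_error(steel_dwass(list(1:3, 1:3)), "3 groups")
  expect_error(steel_dwass(list(1, 1:3, 1:4)), "at least 2")
})

test_that("the equal-probability binomial test sums minimum-likelihood tails", {
  expect_equal(binomial_equal_test(3, 13)$p.value, 756 / 8192,
               tolerance = 1e-15)
  expect_equal(binomial_equal_test(0, 20)$p.value, 2 / 2^20,
               tolerance = 1e-15)
  expect_equal(binomial_equal_test(6, 12)$p.value, 1)
  for (k in c(0, 2, 5, 9)) # cross-check against the standard implementation
    expect_equal(binomial_equal_test(k, 17)$p.value,
                 stats::binom.test(k, 17, 0.5)$p.value, tolerance = 1e-12)
  expect_error(binomial_equal_test(5, 4), "k <= n")
})

test_that("phylogenetic ANOVA reproduces the classical F and BM machinery", {
  tr <- simulate_tree(6, 10, seed = 2)
  x <- setNames(c(1, 2, 3, 4, 5, 6), tr$tip.label)
  g <- setNames(rep(c("u", "v"), each = 3), tr$tip.label)
  r <- phylo_anova(tr, x, g, n_sim = 200, seed = 4)
  expect_equal(unname(r$statistic), 13.5, tolerance = 1e-12)
  expect_true(r$p.value > 0 && r$p.value <= 1)
  expect_equal(phylo_anova(tr, x, g, n_sim = 200, seed = 4)$p.value,
               r$p.value)
  # F agrees with the reference implementation on random data
  if (requireNamespace("phytools", quietly = TRUE)) {
    tv <- simulate_bm_traits(tr, 1, g, seed = 12)
    ref <- suppressWarnings(phytools::phylANOVA(
      tr, setNames(as.factor(g[tr$tip.label]), tr$tip.label),
      tv$value[tr$tip.label], nsim = 50, posthoc = FALSE))
    mine <- phylo_anova(tr, tv, n_sim = 200, seed = 1)
    expect_equal(unname(mine$statistic), ref$F, tolerance = 1e-8)
  }
  expect_error(phylo_anova(tr, setNames(rep(1, 6), tr$tip.label), g,
                           n_sim = 200), "zero variance")
  g1 <- setNames(c("u", rep("v", 5)), tr$tip.label)
  expect_error(phylo_anova(tr, x, g1, n_sim = 200), "2 tips")
})

test_that("protein pI and residue weights match the pepstats model", {
  expect_equal(protein_pi("A"), 6.1, tolerance = 1e-4)
  expect_equal(avg_residue_weight("G"), 57.052, tolerance = 0.01)
  expect_equal(avg_residue_weight("GG"), avg_residue_weight("G"))
  # permutation invariance of the mean
  expect_equal(avg_residue_weight("ACDEFG"), avg_residue_weight("GFEDCA"))
  # adding a basic residue raises pI, an acidic one lowers it
  withr::with_seed(8, {
    for (i in 1:20) {
      s <- paste(sample(names(syndecay:::RESIDUE_MASS), 100, TRUE),
                 collapse = "")
      expect_gt(protein_pi(paste0(s, "R")), protein_pi(s))
      expect_lt(protein_pi(paste0(s, "D")), protein_pi(s))
      # bisection really finds a root of the charge curve
      aa <- strsplit(s, "")[[1]]
      expect_lt(abs(syndecay:::protein_charge(aa, protein_pi(s))), 1e-6)
    }
  })
  expect_error(protein_pi("AXZ"), "non-standard")
  expect_equal(protein_pi("AXA", on_invalid = "skip"), protein_pi("AA"))
  expect_error(avg_residue_weight(""), "empty")
})
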