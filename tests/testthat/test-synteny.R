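test_that("order_genes indexes per scaffold by start position", {
  g <- make_annotation(c("x", "y", "z"))
  g$start <- c(500, 100, 300); g$end <- g$start + 50
  o <- order_genes(g)
  expect_equal(o$gene_id[order(o$idx)], c("y", "z", "x"))
  two <- rbind(make_annotation("a", "S1"), make_annotation("b", "S2"))
  oo <- order_genes(two)
  expect_equal(oo$idx, c(0L, 0L))
  g$gene_id <- c("x", "x", "z")
  expect_error(order_genes(g), "duplicate")
})

test_that("block detection applies the 5-gene / 4-gap / 5-inversion rule", {
  ids_a <- sprintf("a%02d", 1:10)
  ids_b <- sprintf("b%02d", 1:10)
  ga <- make_annotation(ids_a); gb <- make_annotation(ids_b)
  pairs <- pair_df(ids_a, ids_b)
  # identical order: one block, all anchors, no inversions
  bl <- detect_blocks(ga, gb, pairs)
  expect_length(bl, 1)
  expect_equal(attr(bl[[1]], "n_anchors"), 10L)
  expect_equal(attr(bl[[1]], "inversions"), 0L)
  # four collinear anchors only: below the five-gene minimum
  expect_length(detect_blocks(ga[1:4, ], gb[1:4, ], pairs[1:4, ]), 0)
  # anchors 4-6 order-reversed in B: one block with inversion count 1
  gb_inv <- make_annotation(ids_b[c(1:3, 6, 5, 4, 7:10)])
  bl2 <- detect_blocks(ga, gb_inv, pairs)
  expect_length(bl2, 1)
  expect_equal(attr(bl2[[1]], "inversions"), 1L)
  expect_equal(attr(bl2[[1]], "n_anchors"), 10L)
  # unknown gene in pairs
  expect_error(detect_blocks(ga, gb, pair_df("a01", "nope")), "absent")
})

test_that("gap rule is enforced symmetrically in both genomes", {
  ids_a <- sprintf("a%02d", 1:12)
  ga <- make_annotation(ids_a)
  # anchors every second gene in A: gaps of 1 intervening gene, fine
  anchor_a <- ids_a[c(1, 3, 5, 7, 9, 11)]
  ids_b <- sprintf("b%02d", 1:6)
  gb <- make_annotation(ids_b)
  expect_length(detect_blocks(ga, gb, pair_df(anchor_a, ids_b)), 1)
  # in B insert 5 non-orthologous genes between anchors 3 and 4: gap 5 > 4
  gb_gap <- make_annotation(c(ids_b[1:3], sprintf("f%d", 1:5), ids_b[4:6]))
  bl <- detect_blocks(ga, gb_gap, pair_df(anchor_a, ids_b))
  expect_length(bl, 0)  # both fragments are below min_genes
  bl2 <- detect_blocks(ga, gb_gap, pair_df(anchor_a, ids_b), min_genes = 3)
  expect_length(bl2, 2)
})

test_that("detect_blocks matches the exhaustive chain oracle", {
  withr::with_seed(424, {
    for (i in 1:120) {
      inst <- random_instance()
      got <- blocks_partition(detect_blocks(inst$ga, inst$gb, inst$pairs,
                                            min_genes = 3))
      want <- oracle_blocks(inst$ga, inst$gb, inst$pairs, min_genes = 3)
      expect_identical(got, want)
    }
  })
})

test_that("proportion synteny and the decay-rate formula behave as stated", {
  ids <- sprintf("g%02d", 1:10)
  ga <- make_annotation(ids); gb <- make_annotation(ids)
  pairs <- pair_df(ids, ids)
  bl <- detect_blocks(ga, gb, pairs)
  expect_equal(synteny_proportion(bl, pairs), 1)
  expect_equal(synteny_proportion(list(), pairs), 0)
  expect_error(synteny_proportion(bl, pairs[0, ]), "undefined")
  expect_equal(loss_rate(1, 37), 0)
  expect_equal(loss_rate(0.81, 2), 0.1)
  expect_equal(loss_rate(0.5, 100), 1 - exp(log(0.5) / 100), tolerance = 1e-14)
  expect_warning(r0 <- loss_rate(0, 10), "p_s = 0")
  expect_equal(r0, 1)
  expect_error(loss_rate(1.2, 10), "p_s")
  expect_error(loss_rate(0.5, 0), "T")
  # monotonicity: decreasing in p_s, decreasing in T
  expect_true(all(diff(loss_rate(seq(0.1, 1, 0.1), 10)) < 0))
  expect_true(all(diff(loss_rate(0.5, c(1, 5, 20, 80))) < 0))
})

test_that("pairwise matrices are symmetric with zero diagonals", {
  tr <- simulate_tree(4, 30, seed = 12)
  sim <- simulate_genomes(tr, sim_config(3, 200, inversion_rate = 0.15,
                                         translocation_rate = 0.05,
                                         seed = 14))
  hits <- simulate_hit_table(sim$genomes, sim$truth, seed = 15)
  sp <- names(sim$genomes)
  pairsets <- list()
  for (i in 1:3) for (j in (i + 1):4) {
    k <- paste0(sp[i], "__", sp[j])
    pairsets[[k]] <- rbh_pairs(hits[[k]], hits[[paste0(sp[j], "__", sp[i])]])
  }
  mats <- pairwise_loss_matrix(sim$genomes, pairsets, tr)
  for (m in mats) {
    expect_equal(m, t(m))
    expect_true(all(abs(diag(m) - diag(m)[1]) < 1e-12))
  }
  expect_equal(unname(diag(mats$loss)), rep(0, 4))
  expect_equal(unname(diag(mats$p_s)), rep(1, 4))
  expect_equal(mats$loss, 1 - mats$p_s)
  # identical genomes everywhere -> zero loss everywhere
  idg <- sim$genomes
  for (s in sp) {
    idg[[s]] <- sim$genomes[[sp[1]]]
    idg[[s]]$gene_id <- sub(paste0("^", sp[1]), s, idg[[s]]$gene_id)
  }
  idpairs <- lapply(pairsets, function(p) NULL)
  for (i in 1:3) for (j in (i + 1):4) {
    k <- paste0(sp[i], "__", sp[j])
    idpairs[[k]] <- pair_df(idg[[sp[i]]]$gene_id, idg[[sp[j]]]$gene_id)
  }
  m0 <- pairwise_loss_matrix(idg, idpairs, tr)
  expect_true(all(m0$loss == 0) && all(m0$rate == 0))
  expect_error(pairwise_loss_matrix(setNames(idg, c("t1", "t2", "t3", "zz")),
                                    idpairs, tr), "missing")
})

test_that("more rearrangement means (weakly) less synteny", {
  tr <- simulate_tree(2, 10, seed = 1)
  mean_ps <- vapply(c(0.05, 0.2, 0.8), function(r) {
    mean(vapply(1:20, function(i) {
      sim <- simulate_genomes(tr, sim_config(3, 300, inversion_rate = r,
                                             seed = 1000 + i))
      om <- sim$truth$ortholog_map
      pairs <- pair_df(om$t1, om$t2)
      synteny_proportion(detect_blocks(sim$genomes$t1, sim$genomes$t2,
                                       pairs), pairs)
    }, 1))
  }, 1)
  expect_true(all(diff(mean_ps) <= 0))
})
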