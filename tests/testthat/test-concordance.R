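test_that("bin proportions count fold-change exceedances per CNA bin", {
  rec <- data.frame(gene_id = sprintf("g%02d", 1:10),
                    log2fc = c(1.5, 2.0, -1.5, 0.2,   # loss bin
                               0.5, -2.0,             # nc bin
                               1.2, 0.0, -0.5, -1.1)) # gain bin
  summ <- data.frame(gene_id = rec$gene_id,
                     bin = rep(c("loss", "nc", "gain"), c(4, 2, 4)))
  tab <- bin_tier_proportions(rec, summ, fc_cut = 1.0)
  expect_equal(tab$prop_up[tab$bin == "loss"], 0.5)   # 2 of 4 above +1
  expect_equal(tab$prop_down[tab$bin == "loss"], 0.25)
  expect_equal(tab$prop_up[tab$bin == "nc"], 0)
  expect_equal(tab$n_down[tab$bin == "gain"], 1L)

  # all fold changes zero -> all proportions zero
  rec0 <- transform(rec, log2fc = 0)
  tab0 <- bin_tier_proportions(rec0, summ)
  expect_true(all(tab0$prop_up == 0 & tab0$prop_down == 0))

  # shuffling gene order leaves the table unchanged
  perm <- sample(nrow(rec))
  expect_equal(bin_tier_proportions(rec[perm, ], summ[sample(nrow(summ)), ]),
               tab)

  # empty bin flagged undefined
  tab2 <- bin_tier_proportions(rec[1:4, ], summ[1:4, ])
  expect_false(tab2$defined[tab2$bin == "gain"])
  expect_true(is.na(tab2$prop_up[tab2$bin == "gain"]))
})

test_that("discordant genes are up-tier genes inside loss regions", {
  rec <- data.frame(
    gene_id = sprintf("g%02d", 1:10),
    log2fc = c(2, 2, 0, -2, 2, 2, 0, 0, 0, 0),
    p_adj = c(1e-6, 1e-6, 0.5, 1e-6, 1e-6, 1e-3, 0.5, 0.5, 0.5, 0.5))
  rec <- classify_tiers(rec)
  regions <- data.frame(cancer_code = "X", chromosome = "chr1",
                        start = 1L, end = 10000L, n_genes = 4L,
                        mean_cna = -0.5, rule = "primary",
                        stringsAsFactors = FALSE)
  regions$genes <- list(sprintf("g%02d", 1:4))
  out <- discordant_genes(rec, regions, "strict")
  # g1, g2 are up_strict inside; g5 up_strict outside -> excluded;
  # g4 down; g6 only relaxed
  expect_setequal(out$genes$gene_id, c("g01", "g02"))
  expect_equal(out$per_region$n_up, 2L)
  expect_equal(out$per_region$fraction_up, 0.5)
  # strict list is a subset of the relaxed list
  out_rel <- discordant_genes(rec, regions, "relaxed")
  expect_true(all(out$genes$gene_id %in% out_rel$genes$gene_id))
  expect_true(all(out_rel$per_region$fraction_up >= 0 &
                    out_rel$per_region$fraction_up <= 1))
})

test_that("sharing histogram counts cancers per gene", {
  lists <- list(A = c("g1", "g2", "g3", "g4", "g5"),
                B = c("g1", "g2", "g3", "g4", "g5"))
  h <- sharing_histogram(lists)
  expect_equal(h$histogram$n_genes[h$histogram$n_cancers == 2], 5L)
  expect_equal(sum(h$histogram$n_genes), 5L)

  lists2 <- list(A = "g1", B = "g2")
  h2 <- sharing_histogram(lists2)
  expect_equal(h2$histogram$n_genes[h2$histogram$n_cancers == 1], 2L)

  set.seed(12)
  pool <- sprintf("g%03d", 1:60)
  rnd <- list(A = sample(pool, 20), B = sample(pool, 25),
              C = sample(pool, 15))
  h3 <- sharing_histogram(rnd)
  # brute-force multiset count
  all_g <- sort(unique(unlist(rnd)))
  counts <- sapply(all_g, function(g) sum(sapply(rnd, function(l) g %in% l)))
  expect_equal(h3$per_gene$n_cancers, unname(counts))
  for (k in 1:3)
    expect_equal(h3$histogram$n_genes[h3$histogram$n_cancers == k],
                 sum(counts == k))

  ann <- data.frame(gene_id = pool,
                    chromosome = rep(c("chr1", "chr2"), each = 30))
  h4 <- sharing_histogram(rnd, ann)
  expect_equal(sum(h4$per_chromosome$n_genes), length(all_g))
  expect_true(all(h4$per_chromosome$shared_fraction >= 0 &
                    h4$per_chromosome$shared_fraction <= 1))

  expect_error(sharing_histogram(list(A = "g1")), ">= 2 cancers")
})

test_that("hypergeometric overlap p matches exhaustive enumeration", {
  # frozen example: N=10, |A|=4, |B|=5, k=3 -> 66/252
  u <- sprintf("u%02d", 1:10)
  t1 <- pairwise_overlap_test(u[1:4], u[c(2, 3, 4, 8, 9)], u, min_list = 1)
  expect_equal(t1$shared, 3L)
  expect_equal(t1$p, 66 / 252, tolerance = 1e-12)
  expect_equal(t1$p, enum_hyper_p(10, 4, 5, 3), tolerance = 1e-12)

  # k = 0 with small lists: p close to 1, never above
  t0 <- pairwise_overlap_test(u[1:2], u[9:10], u, min_list = 1)
  expect_lte(t0$p, 1)
  expect_gt(t0$p, 0.5)

  # degenerate: both lists are the whole universe
  td <- pairwise_overlap_test(u, u, u, min_list = 1)
  expect_equal(td$p, 1)

  # property: random configurations on universes <= 15
  set.seed(19)
  for (i in 1:40) {
    N <- sample(5:15, 1)
    nA <- sample(1:N, 1); nB <- sample(1:N, 1)
    univ <- sprintf("x%02d", 1:N)
    A <- univ[seq_len(nA)]
    B <- sample(univ, nB)
    res <- pairwise_overlap_test(A, B, univ, min_list = 1)
    expect_equal(res$p, enum_hyper_p(N, nA, nB, res$shared),
                 tolerance = 1e-10, info = sprintf("config %d", i))
  }

  expect_error(pairwise_overlap_test(c(u, "zz"), u[1:5], u, min_list = 1),
               "subsets")
  # below min_list: overlap reported but untested
  skip_t <- pairwise_overlap_test(u[1:4], u[1:5], u, min_list = 15)
  expect_false(skip_t$tested)
  expect_true(is.na(skip_t$p))
})

test_that("with a dosage effect and no discordant genes, the loss bin has
           fewer upregulated genes than the nc bin", {
  set.seed(23)
  ups <- replicate(8, {
    seed <- sample.int(1e6, 1)
    cfg <- cohort_config(n_discordant_per_region = 0,
      loss_regions = data.frame(chromosome = "chr1", first_gene = 1,
                                last_gene = 150, mean_cna_target = -0.5))
    coh <- generate_cohort(800, 4, 60, 15, cfg, seed = seed)
    res <- analyze_cohort(coh)
    tab <- bin_tier_proportions(res$records, res$summaries, fc_cut = 1.0)
    c(loss = tab$prop_up[tab$bin == "loss"], nc = tab$prop_up[tab$bin == "nc"])
  })
  expect_lt(mean(ups["loss", ]), mean(ups["nc", ]))
})
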