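test_that("four-bin classes tally by fold-change sign and CE membership", {
  rec <- data.frame(gene_id = sprintf("g%d", 1:8),
                    log2fc = c(2, 1, -1, -2, 0.5, -0.5, 0, 3))
  ce <- c("g1", "g3", "g7")
  out <- four_bin_comparison(rec, ce)
  cls <- out$classes
  # zero log2fc is assigned to the T<N (down) side
  expect_equal(cls$n[cls$class == "CE_up"], 1L)      # g1
  expect_equal(cls$n[cls$class == "CE_down"], 2L)    # g3, g7 (fc 0)
  expect_equal(cls$n[cls$class == "other_up"], 3L)   # g2, g5, g8
  expect_equal(cls$n[cls$class == "other_down"], 2L) # g4, g6
  expect_equal(sum(cls$n), nrow(rec))

  # all genes upregulated: down contrast undefined
  rec_up <- transform(rec, log2fc = abs(log2fc) + 0.1)
  out_up <- four_bin_comparison(rec_up, ce)
  expect_true(is.na(out_up$p_down))
})

test_that("four-bin p-values are calibrated under the null", {
  set.seed(77)
  ps <- replicate(200, {
    rec <- data.frame(gene_id = sprintf("g%02d", 1:40),
                      log2fc = rnorm(40, 0.3, 1))  # CE and other same dist
    four_bin_comparison(rec, sprintf("g%02d", sample(40, 15)))$p_up
  })
  ps <- ps[!is.na(ps)]
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("cumulative CE rank curve and deviation behave at the extremes", {
  # CE genes occupy the top ranks: curve hits 1 at rank |CE|
  rec <- data.frame(gene_id = sprintf("g%02d", 1:10),
                    log2fc = seq(2, -2, length.out = 10))
  ce_top <- sprintf("g%02d", 1:3)
  out <- rank_cumulative(rec, ce_top)
  expect_equal(out$curve$cum_ce_fraction[3], 1)
  expect_true(all(diff(out$curve$cum_ce_fraction) >= 0))
  expect_equal(out$curve$cum_ce_fraction[10], 1)
  # max gap for this configuration: at rank 3, 1 - 3/10
  expect_equal(out$deviation, 1 - 3 / 10)

  # every gene CE: curve equals the diagonal, deviation 0
  out_all <- rank_cumulative(rec, rec$gene_id)
  expect_equal(out_all$deviation, 0)

  # reversing the sort order mirrors the curve (distinct fold changes)
  out_rev <- rank_cumulative(transform(rec, log2fc = -log2fc), ce_top)
  n <- 10; n_ce <- 3
  ce_seen_fwd <- out$curve$cum_ce_fraction * n_ce
  ce_seen_rev <- out_rev$curve$cum_ce_fraction * n_ce
  expect_equal(ce_seen_rev[seq_len(n - 1)],
               n_ce - rev(ce_seen_fwd)[-1])

  expect_error(rank_cumulative(rec, "absent"), "no common-essential")
})

test_that("mean deviation under random CE placement matches enumeration", {
  # exhaustive expectation over all C(10,3) placements of 3 CE among 10
  combos <- combn(10, 3)
  dev_of <- function(pos) {
    cum <- cumsum(seq_len(10) %in% pos) / 3
    max(abs(cum - seq_len(10) / 10))
  }
  expected <- mean(apply(combos, 2, dev_of))
  set.seed(99)
  rec <- data.frame(gene_id = sprintf("g%02d", 1:10),
                    log2fc = seq(2, -2, length.out = 10))
  devs <- replicate(400, {
    ce <- sprintf("g%02d", sample(10, 3))
    rank_cumulative(rec, ce)$deviation
  })
  # sampling error of the mean over 400 draws is ~sd/20
  expect_lt(abs(mean(devs) - expected), 3 * sd(devs) / sqrt(400))
})

test_that("gene-set bin means follow the generator's dosage structure", {
  coh <- small_cohort(seed = 41)
  res <- analyze_cohort(coh)
  # all genes: dosage orders the bin means loss < nc < gain
  all_set <- res$aset$genes
  out_all <- binned_set_log2fc(res$records, res$summaries, all_set, "all")
  m <- out_all$bins[out_all$bins$set == "all", ]
  expect_lt(m$mean_log2fc[m$bin == "loss"], m$mean_log2fc[m$bin == "nc"])
  expect_lt(m$mean_log2fc[m$bin == "nc"], m$mean_log2fc[m$bin == "gain"])

  # planted program-driven set (discordant + up): flat across bins
  prog <- intersect(c(coh$truth$discordant_genes, coh$truth$up_genes),
                    res$aset$genes)
  out_p <- binned_set_log2fc(res$records, res$summaries, prog, "program")
  mp <- out_p$bins[out_p$bins$set == "program" & out_p$bins$n >= 2, ]
  expect_gte(nrow(mp), 2)
  expect_lt(max(mp$mean_log2fc) - min(mp$mean_log2fc), 0.3)

  # cross-module consistency: the all-genes baseline equals bin means
  # recomputed independently from the records/summaries join
  jm <- merge(res$records[, c("gene_id", "log2fc")],
              res$summaries[, c("gene_id", "bin")])
  for (b in c("loss", "nc", "gain"))
    expect_equal(m$mean_log2fc[m$bin == b],
                 mean(jm$log2fc[jm$bin == b]), tolerance = 1e-12)

  # a set missing from a bin is excluded from the gain-vs-loss test
  nc_only <- head(jm$gene_id[jm$bin == "nc"], 5)
  out_nc <- suppressWarnings(
    binned_set_log2fc(res$records, res$summaries, nc_only, "nc_only"))
  expect_true(is.na(out_nc$p_gain_vs_loss))
  expect_false(all(out_nc$bins$in_test[out_nc$bins$set == "nc_only"]))
})

test_that("over-representation analysis matches enumeration and ranks truly
           enriched sets first", {
  # N=20, set of 5, list of 6, overlap 4
  univ <- sprintf("u%02d", 1:20)
  sets <- list(hit = list(name = "hit", description = "", members = univ[1:5]),
               miss = list(name = "miss", description = "", members = univ[11:16]))
  lst <- univ[c(1, 2, 3, 4, 18, 19)]
  out <- ora_enrichment(lst, sets, univ)
  expect_identical(out$set[1], "hit")
  expect_equal(out$overlap[out$set == "hit"], 4L)
  # enumeration oracle: draws of 6 from 20 sharing >= 4 with a 5-gene set
  expect_equal(out$p[out$set == "hit"], enum_hyper_p(20, 5, 6, 4),
               tolerance = 1e-10)

  # a list equal to one set ranks that set first with tiny p
  out2 <- ora_enrichment(univ[1:5], sets, univ)
  expect_identical(out2$set[1], "hit")
  expect_lt(out2$p[1], 1e-3)

  # zero overlap everywhere: adjusted p all 1 within rounding
  out3 <- ora_enrichment(univ[17:20], sets["hit"], univ)
  expect_equal(out3$overlap, 0L)
  expect_gt(out3$p_adj, 0.99)

  # adjusted p monotone in raw p
  set.seed(30)
  many <- lapply(1:12, function(i) list(name = paste0("S", i), description = "",
                                        members = sample(univ, sample(3:8, 1))))
  names(many) <- sapply(many, `[[`, "name")
  out4 <- ora_enrichment(sample(univ, 7), many, univ)
  expect_true(all(diff(out4$p_adj[order(out4$p)]) >= -1e-12))

  # sets disjoint from the universe are skipped
  sets_d <- c(sets, list(gone = list(name = "gone", description = "",
                                     members = c("zz1", "zz2"))))
  expect_false("gone" %in% ora_enrichment(lst, sets_d, univ)$set)
  expect_error(ora_enrichment(c(univ[1], "zz"), sets, univ), "subset")
})
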