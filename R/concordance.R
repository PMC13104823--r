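# Crossing copy-number bins with expression change: bin/tier proportions,
# discordant genes inside loss regions, cross-cancer sharing, and pairwise
# hypergeometric overlap tests.

#' Proportion of up-/downregulated genes per copy-number bin
#'
#' For each copy-number bin (loss / nc / gain) reports the number and
#' fraction of genes whose tumor-minus-normal log2 fold change exceeds
#' `+fc_cut` or falls below `-fc_cut`. The fold-change cut is applied
#' alone (no p-value threshold), matching the genome-wide bin summaries.
#'
#' @param records Output of [differential_expression()].
#' @param summaries Output of [gene_cna_summary()] over the same genes.
#' @param fc_cut Absolute log2 fold-change cut (default 1.0).
#' @return Data.frame with one row per bin: `bin`, `n`, `n_up`, `n_down`,
#'   `prop_up`, `prop_down`, `defined`.
#' @export
bin_tier_proportions <- function(records, summaries, fc_cut = 1.0) {
  m <- merge(records[, c("gene_id", "log2fc")],
             summaries[, c("gene_id", "bin")], by = "gene_id")
  do.call(rbind, lapply(c("loss", "nc", "gain"), function(b) {
    fc <- m$log2fc[!is.na(m$bin) & m$bin == b]
    n <- length(fc)
    data.frame(bin = b, n = n,
               n_up = sum(fc > fc_cut, na.rm = TRUE),
               n_down = sum(fc < -fc_cut, na.rm = TRUE),
               prop_up = if (n) sum(fc > fc_cut, na.rm = TRUE) / n else NA_real_,
               prop_down = if (n) sum(fc < -fc_cut, na.rm = TRUE) / n else NA_real_,
               defined = n > 0, stringsAsFactors = FALSE)
  }))
}

#' Discordant genes: upregulated inside copy-number loss regions
#'
#' Returns the genes of one cancer that sit inside any of its loss regions
#' and meet the upward tier, plus the per-region fraction upregulated.
#'
#' @param records Tiered records from [classify_tiers()] for one cancer.
#' @param regions Region data.frame for that cancer (primary plus any
#'   rescued), with the `genes` list-column.
#' @param tier `"strict"` or `"relaxed"` (see [up_genes_at_tier()]).
#' @return List with `genes` (data.frame `gene_id`, `regions` membership
#'   string) and `per_region` (region rows with `n_up` and
#'   `fraction_up`).
#' @export
discordant_genes <- function(records, regions, tier = c("strict", "relaxed")) {
  tier <- match.arg(tier)
  up <- up_genes_at_tier(records, tier)
  region_label <- function(r) sprintf("%s:%d-%d", r$chromosome, r$start, r$end)
  per_region <- regions
  per_region$n_up <- 0L
  per_region$fraction_up <- NA_real_
  hits <- list()
  if (nrow(regions)) for (k in seq_len(nrow(regions))) {
    rg <- unlist(regions$genes[k])
    inr <- intersect(rg, up)
    per_region$n_up[k] <- length(inr)
    per_region$fraction_up[k] <- length(inr) / length(rg)
    if (length(inr)) hits[[region_label(regions[k, ])]] <- inr
  }
  gene_ids <- unique(unlist(hits))
  membership <- vapply(gene_ids, function(g)
    paste(names(hits)[vapply(hits, function(h) g %in% h, logical(1))],
          collapse = ";"), character(1))
  list(genes = data.frame(gene_id = gene_ids,
                          regions = unname(membership),
                          stringsAsFactors = FALSE),
       per_region = per_region)
}

#' Cross-cancer sharing of discordant genes
#'
#' For every gene discordant in at least one cancer, counts the cancers in
#' which it is discordant; reports the histogram over that count and a
#' per-chromosome rollup with the shared (>= 2 cancers) fraction.
#'
#' @param gene_lists Named list (cancer code -> character vector of
#'   discordant genes).
#' @param annotations Optional probemap data.frame for the per-chromosome
#'   rollup.
#' @return List with `per_gene` (`gene_id`, `n_cancers`, `cancers`),
#'   `histogram` (`n_cancers`, `n_genes`) and, when annotations are given,
#'   `per_chromosome` (`chromosome`, `n_genes`, `n_shared`,
#'   `shared_fraction`).
#' @export
sharing_histogram <- function(gene_lists, annotations = NULL) {
  if (length(gene_lists) < 2) stop("need gene lists from >= 2 cancers")
  all_genes <- sort(unique(unlist(gene_lists)))
  counts <- vapply(all_genes, function(g)
    sum(vapply(gene_lists, function(l) g %in% l, logical(1))), integer(1))
  cancers <- vapply(all_genes, function(g)
    paste(names(gene_lists)[vapply(gene_lists, function(l) g %in% l, logical(1))],
          collapse = ";"), character(1))
  per_gene <- data.frame(gene_id = all_genes, n_cancers = unname(counts),
                         cancers = unname(cancers), stringsAsFactors = FALSE)
  tab <- table(factor(per_gene$n_cancers, levels = seq_len(length(gene_lists))))
  histogram <- data.frame(n_cancers = as.integer(names(tab)),
                          n_genes = as.integer(tab))
  out <- list(per_gene = per_gene, histogram = histogram)
  if (!is.null(annotations)) {
    chrom <- annotations$chromosome[match(per_gene$gene_id, annotations$gene_id)]
    rollup <- do.call(rbind, lapply(split(per_gene, chrom), function(d)
      data.frame(chromosome = chrom[match(d$gene_id[1], per_gene$gene_id)],
                 n_genes = nrow(d), n_shared = sum(d$n_cancers >= 2),
                 shared_fraction = mean(d$n_cancers >= 2),
                 stringsAsFactors = FALSE)))
    if (!is.null(rollup)) {
      rollup <- rollup[order(.chrom_rank(rollup$chromosome)), , drop = FALSE]
      rownames(rollup) <- NULL
    }
    out$per_chromosome <- rollup
  }
  out
}

#' Hypergeometric overlap test between two gene lists
#'
#' Upper-tail hypergeometric probability of observing at least the realized
#' overlap when `|listB|` genes are drawn from a universe containing
#' `|listA|` successes. Applied to upregulated-gene lists of two cancers
#' within a shared loss region, with the universe the expressed genes of
#' that shared region; only tested when both lists hold at least
#' `min_list` genes.
#'
#' @param list_a,list_b Character vectors, subsets of `universe`.
#' @param universe Character vector of background genes.
#' @param min_list Minimum size of both lists for the test (default 15).
#' @return Data.frame (`OverlapTest`): `n_universe`, `n_a`, `n_b`,
#'   `shared`, `tested`, `p`.
#' @export
pairwise_overlap_test <- function(list_a, list_b, universe, min_list = 15L) {
  list_a <- unique(list_a); list_b <- unique(list_b)
  universe <- unique(universe)
  if (length(setdiff(list_a, universe)) || length(setdiff(list_b, universe)))
    stop("gene lists must be subsets of the universe")
  k <- length(intersect(list_a, list_b))
  tested <- length(list_a) >= min_list && length(list_b) >= min_list
  p <- if (tested)
    stats::phyper(k - 1, length(list_a), length(universe) - length(list_a),
                  length(list_b), lower.tail = FALSE)
  else NA_real_
  data.frame(n_universe = length(universe), n_a = length(list_a),
             n_b = length(list_b), shared = k, tested = tested, p = p)
}
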