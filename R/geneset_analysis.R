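# Gene-set comparisons: common-essential four-bin contrasts within loss
# regions, cumulative-rank curves, per-copy-number-bin gene-set log2FC
# summaries, and a local hypergeometric over-representation test.

#' Four-bin common-essential comparison within a region
#'
#' Splits a region's genes by the sign of the tumor-minus-normal log2 fold
#' change (T>N versus T<N, zero assigned to T<N) crossed with membership in
#' the common-essential (CE) set, and t-tests CE versus other within each
#' sign. Contrasts with fewer than two genes in a class are flagged
#' undefined.
#'
#' @param records Differential-expression records restricted to the
#'   region's genes.
#' @param ce_set Character vector of common-essential gene ids.
#' @return List with `classes` (per class n / mean / median / quartiles),
#'   `p_up`, `p_down`.
#' @export
four_bin_comparison <- function(records, ce_set) {
  fc <- records$log2fc
  ok <- !is.na(fc)
  ce <- records$gene_id %in% ce_set
  cls <- ifelse(fc > 0, "up", "down")
  cls <- paste0(ifelse(ce, "CE_", "other_"), cls)
  classes <- do.call(rbind, lapply(
    c("CE_up", "other_up", "CE_down", "other_down"), function(cl) {
      x <- fc[ok & cls == cl]
      data.frame(class = cl, n = length(x),
                 mean = if (length(x)) mean(x) else NA_real_,
                 median = if (length(x)) stats::median(x) else NA_real_,
                 q1 = if (length(x)) unname(stats::quantile(x, 0.25)) else NA_real_,
                 q3 = if (length(x)) unname(stats::quantile(x, 0.75)) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  list(classes = classes,
       p_up = .safe_t_p(fc[ok & cls == "CE_up"], fc[ok & cls == "other_up"]),
       p_down = .safe_t_p(fc[ok & cls == "CE_down"], fc[ok & cls == "other_down"]))
}

#' Cumulative rank curve of common-essential genes in a region
#'
#' Ranks the region's genes from highest to lowest log2 fold change (ties
#' broken by gene id) and accumulates the fraction of the CE set seen up to
#' each rank, against the expected diagonal (rank / n). The deviation
#' statistic is the Kolmogorov-style maximum absolute gap between the
#' observed curve and the diagonal.
#'
#' @param records Differential-expression records restricted to the region.
#' @param ce_set Character vector of common-essential gene ids; must
#'   intersect the region.
#' @return List with `curve` (per rank: `gene_id`, `log2fc`, `is_ce`,
#'   `cum_ce_fraction`, `expected`) and `deviation`.
#' @export
rank_cumulative <- function(records, ce_set) {
  d <- records[!is.na(records$log2fc), , drop = FALSE]
  d <- d[order(-d$log2fc, d$gene_id), , drop = FALSE]
  is_ce <- d$gene_id %in% ce_set
  n_ce <- sum(is_ce)
  if (!n_ce) stop("no common-essential genes in the region")
  n <- nrow(d)
  cum <- cumsum(is_ce) / n_ce
  expected <- seq_len(n) / n
  data_curve <- data.frame(rank = seq_len(n), gene_id = d$gene_id,
                           log2fc = d$log2fc, is_ce = is_ce,
                           cum_ce_fraction = cum, expected = expected,
                           stringsAsFactors = FALSE, row.names = NULL)
  list(curve = data_curve, deviation = max(abs(cum - expected)))
}

#' Mean gene-set log2 fold change by copy-number bin
#'
#' Restricts a gene set to the analyzed genes, reports its mean
#' tumor-minus-normal log2 fold change within each copy-number bin (loss /
#' nc / gain), and t-tests gain versus loss. Bins with fewer than two set
#' members are excluded from the test and flagged. The all-genes baseline
#' is emitted alongside.
#'
#' @param records Genome-wide differential-expression records.
#' @param summaries [gene_cna_summary()] over the same genes.
#' @param gene_set Character vector of set member gene ids.
#' @param set_name Label for the output.
#' @return List with `bins` (per bin and per set/baseline: n, mean
#'   log2fc), `p_gain_vs_loss`, `p_baseline_gain_vs_loss`.
#' @export
binned_set_log2fc <- function(records, summaries, gene_set,
                              set_name = "gene_set") {
  m <- merge(records[, c("gene_id", "log2fc")],
             summaries[, c("gene_id", "bin")], by = "gene_id")
  m <- m[!is.na(m$bin) & !is.na(m$log2fc), , drop = FALSE]
  in_set <- m$gene_id %in% gene_set
  if (length(unique(m$bin[in_set])) < 2)
    warning("gene set intersects fewer than two copy-number bins")
  one <- function(sel, label) do.call(rbind, lapply(c("loss", "nc", "gain"),
    function(b) {
      x <- m$log2fc[sel & m$bin == b]
      data.frame(set = label, bin = b, n = length(x),
                 mean_log2fc = if (length(x)) mean(x) else NA_real_,
                 in_test = length(x) >= 2, stringsAsFactors = FALSE)
    }))
  bins <- rbind(one(in_set, set_name), one(rep(TRUE, nrow(m)), "all_genes"))
  list(bins = bins,
       p_gain_vs_loss = .safe_t_p(m$log2fc[in_set & m$bin == "gain"],
                                  m$log2fc[in_set & m$bin == "loss"]),
       p_baseline_gain_vs_loss = .safe_t_p(m$log2fc[m$bin == "gain"],
                                           m$log2fc[m$bin == "loss"]))
}

#' Local over-representation analysis (hypergeometric)
#'
#' For each gene set, the upper-tail hypergeometric probability of the
#' observed overlap between `gene_list` and the set within `universe`,
#' BH-adjusted across sets and sorted by adjusted p. Sets disjoint from the
#' universe are skipped.
#'
#' @param gene_list Character vector, subset of `universe`.
#' @param gene_sets List of gene sets as from [read_gmt()] (or a named list
#'   of character vectors).
#' @param universe Character vector of background genes.
#' @return Data.frame with `set`, `n_set` (in-universe set size),
#'   `n_list`, `overlap`, `p`, `p_adj`, sorted by `p_adj` then `p`.
#' @export
ora_enrichment <- function(gene_list, gene_sets, universe) {
  universe <- unique(universe)
  gene_list <- unique(gene_list)
  if (length(setdiff(gene_list, universe)))
    stop("gene_list must be a subset of the universe")
  members <- lapply(gene_sets, function(s) if (is.list(s)) s$members else s)
  if (is.null(names(members)) || any(!nzchar(names(members))))
    names(members) <- vapply(gene_sets, function(s)
      if (is.list(s)) s$name else NA_character_, character(1))
  rows <- lapply(names(members), function(nm) {
    in_univ <- intersect(members[[nm]], universe)
    if (!length(in_univ)) return(NULL)
    k <- length(intersect(in_univ, gene_list))
    p <- stats::phyper(k - 1, length(in_univ),
                       length(universe) - length(in_univ),
                       length(gene_list), lower.tail = FALSE)
    data.frame(set = nm, n_set = length(in_univ),
               n_list = length(gene_list), overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set = character(), n_set = integer(),
                      n_list = integer(), overlap = integer(),
                      p = numeric(), p_adj = numeric(),
                      stringsAsFactors = FALSE))
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p_adj, out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
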