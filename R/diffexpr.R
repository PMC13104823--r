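# Per-gene tumor-versus-normal differential expression on log2 matrices,
# Benjamini-Hochberg adjustment, tier classification at two cut-offs, and
# per-gene expression summaries by copy-number class.

.row_stats <- function(m) {
  n <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  mu[n == 0] <- NA_real_
  dev2 <- (m - mu)^2
  v <- rowSums(dev2, na.rm = TRUE) / pmax(n - 1, 1)
  v[n < 2] <- NA_real_
  list(n = n, mean = mu, var = v)
}

#' Tumor-versus-normal differential expression
#'
#' Two-sided two-sample t-test per gene on log2 values (Welch
#' unequal-variance by default; `var_equal = TRUE` restores the pooled
#' test), with `log2fc = mean(tumor) - mean(normal)` and Benjamini-Hochberg
#' adjustment over all tested genes. Genes with fewer than two observations
#' in either group are flagged untested and excluded from the adjustment.
#' Zero-variance genes get p = 1 when the means are equal (the two groups
#' are indistinguishable) and p = 0 when they differ (the t statistic
#' diverges), so they survive downstream bookkeeping with finite values.
#'
#' @param expr_tumor,expr_normal Log2 expression (`OmicsMatrix` or matrix)
#'   sharing one gene list.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return Data.frame of `DiffExprRecord`s: `gene_id`, `n_tumor`,
#'   `n_normal`, `mean_tumor`, `mean_normal`, `log2fc`, `t`, `df`,
#'   `p_value`, `p_adj`, `tested`.
#' @export
differential_expression <- function(expr_tumor, expr_normal, var_equal = FALSE) {
  vt <- .values(expr_tumor)
  vn <- .values(expr_normal)
  if (!identical(rownames(vt), rownames(vn)))
    stop("tumor and normal matrices must share one gene list")
  st <- .row_stats(vt)
  sn <- .row_stats(vn)
  fc <- st$mean - sn$mean
  tested <- st$n >= 2 & sn$n >= 2
  if (var_equal) {
    df <- st$n + sn$n - 2
    sp2 <- ((st$n - 1) * st$var + (sn$n - 1) * sn$var) / df
    se2 <- sp2 * (1 / st$n + 1 / sn$n)
  } else {
    a <- st$var / st$n
    b <- sn$var / sn$n
    se2 <- a + b
    df <- se2^2 / (a^2 / (st$n - 1) + b^2 / (sn$n - 1))
  }
  tstat <- fc / sqrt(se2)
  p <- 2 * stats::pt(-abs(tstat), df)
  degen <- tested & !is.na(se2) & se2 == 0
  p[degen] <- ifelse(fc[degen] == 0, 1, 0)
  tstat[degen] <- ifelse(fc[degen] == 0, 0, Inf * sign(fc[degen]))
  p[!tested] <- NA_real_
  p_adj <- rep(NA_real_, length(p))
  p_adj[tested] <- stats::p.adjust(p[tested], method = "BH")
  data.frame(gene_id = rownames(vt),
             n_tumor = st$n, n_normal = sn$n,
             mean_tumor = st$mean, mean_normal = sn$mean,
             log2fc = fc, t = tstat, df = df,
             p_value = p, p_adj = p_adj, tested = tested,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify differential-expression records into stringency tiers
#'
#' A gene is `up_strict` iff `log2fc > strict[1]` and `p_adj < strict[2]`
#' (defaults 1.0 and 1e-4), `up_relaxed` iff it only meets the relaxed
#' cut-offs (defaults 0.4 and 0.01); `down_*` symmetric with
#' `log2fc < -threshold`. The stored tier is the most stringent met;
#' strict genes satisfy the relaxed cut-offs by construction.
#'
#' @param records Output of [differential_expression()].
#' @param strict,relaxed Numeric `(log2fc_threshold, p_adj_threshold)`.
#' @return `records` with a `tier` factor column (`up_strict`,
#'   `up_relaxed`, `down_strict`, `down_relaxed`, `none`).
#' @export
classify_tiers <- function(records, strict = c(1.0, 1e-4), relaxed = c(0.4, 1e-2)) {
  if (strict[1] < relaxed[1] || strict[2] > relaxed[2])
    stop("strict cut-offs must be at least as stringent as relaxed")
  fc <- records$log2fc
  padj <- records$p_adj
  ok <- !is.na(fc) & !is.na(padj)
  tier <- rep("none", nrow(records))
  tier[ok & fc > relaxed[1] & padj < relaxed[2]] <- "up_relaxed"
  tier[ok & fc > strict[1] & padj < strict[2]] <- "up_strict"
  tier[ok & fc < -relaxed[1] & padj < relaxed[2]] <- "down_relaxed"
  tier[ok & fc < -strict[1] & padj < strict[2]] <- "down_strict"
  records$tier <- factor(tier, levels = c("up_strict", "up_relaxed",
                                          "down_strict", "down_relaxed", "none"))
  records
}

#' Genes at or above a tier in the upward direction
#'
#' @param records Tiered records from [classify_tiers()].
#' @param tier `"strict"` (up_strict only) or `"relaxed"` (up_strict or
#'   up_relaxed).
#' @return Character vector of gene ids.
#' @export
up_genes_at_tier <- function(records, tier = c("strict", "relaxed")) {
  tier <- match.arg(tier)
  keep <- if (tier == "strict") records$tier == "up_strict"
          else records$tier %in% c("up_strict", "up_relaxed")
  records$gene_id[keep]
}

.safe_t_p <- function(x, y) {
  if (sum(!is.na(x)) < 2 || sum(!is.na(y)) < 2) return(NA_real_)
  out <- tryCatch(stats::t.test(x, y)$p.value, error = function(e) {
    mx <- mean(x, na.rm = TRUE); my <- mean(y, na.rm = TRUE)
    if (isTRUE(all.equal(mx, my))) 1 else 0   # zero-variance degenerate
  })
  out
}

#' Expression of one gene by copy-number class
#'
#' Partitions tumor samples by their integer thresholded copy-number call
#' (-2 deep deletion, -1 heterozygous loss, 0 diploid, +1 gain, +2
#' amplification) and summarizes the gene's log2 expression per class and
#' in normals, with t-test p-values for each tumor class versus normal and
#' versus the diploid class. Classes with fewer than two samples get an
#' undefined p for their contrasts.
#'
#' @param expr Log2 expression `OmicsMatrix` covering tumors and normals.
#' @param cna Thresholded copy-number `OmicsMatrix` covering the tumors.
#' @param sample_table Output of [classify_samples()].
#' @param gene Gene identifier present in both matrices.
#' @return List with `groups` (per-class n, median, quartiles, mean) and
#'   `tests` (per-class p versus normal and versus diploid).
#' @export
expression_by_copy_number <- function(expr, cna, sample_table, gene) {
  ve <- .values(expr)
  vc <- .values(cna)
  if (!gene %in% rownames(ve) || !gene %in% rownames(vc))
    stop("gene ", gene, " absent from expression or copy-number matrix")
  tum <- intersect(colnames(ve),
                   intersect(colnames(vc),
                             sample_table$sample_id[sample_table$tissue_class == "tumor"]))
  nor <- intersect(colnames(ve),
                   sample_table$sample_id[sample_table$tissue_class == "normal"])
  calls <- vc[gene, tum]
  e_tum <- ve[gene, tum]
  e_nor <- ve[gene, nor]
  groups <- c(list(normal = e_nor),
              split(e_tum, factor(round(calls), levels = -2:2)))
  names(groups) <- c("normal", "-2", "-1", "0", "+1", "+2")
  summ <- do.call(rbind, lapply(names(groups), function(g) {
    x <- groups[[g]][!is.na(groups[[g]])]
    data.frame(group = g, n = length(x),
               median = if (length(x)) stats::median(x) else NA_real_,
               q1 = if (length(x)) unname(stats::quantile(x, 0.25)) else NA_real_,
               q3 = if (length(x)) unname(stats::quantile(x, 0.75)) else NA_real_,
               mean = if (length(x)) mean(x) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  tumor_classes <- setdiff(names(groups), "normal")
  tests <- do.call(rbind, lapply(tumor_classes, function(g) {
    data.frame(group = g,
               p_vs_normal = .safe_t_p(groups[[g]], e_nor),
               p_vs_diploid = if (g == "0") NA_real_
                              else .safe_t_p(groups[[g]], groups[["0"]]),
               stringsAsFactors = FALSE)
  }))
  list(groups = summ, tests = tests)
}
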