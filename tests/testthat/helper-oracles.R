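# Independent oracles and fixture builders used across the suite. The
# oracles are deliberately naive (exhaustive enumeration, direct formulas)
# and never share code with the implementation they check.

# --- region-calling oracle -------------------------------------------------
# All contiguous windows satisfying (a) mean <= thr, (b) length >= min_genes,
# (c) every element < tol; reduced to maximal windows (no satisfying strict
# superset); overlaps resolved by the published policy (more genes, then
# lower mean, then leftmost).
enum_loss_windows <- function(x, min_genes, thr = -0.4, tol = -0.35) {
  n <- length(x)
  wins <- list()
  for (i in seq_len(n)) for (j in i:n) {
    seg <- x[i:j]
    if (all(seg < tol) && mean(seg) <= thr + 1e-9 && length(seg) >= min_genes)
      wins[[length(wins) + 1]] <- c(i, j)
  }
  if (!length(wins)) return(matrix(integer(0), ncol = 2))
  W <- do.call(rbind, wins)
  maximal <- sapply(seq_len(nrow(W)), function(k)
    !any(W[, 1] <= W[k, 1] & W[, 2] >= W[k, 2] &
           (W[, 1] < W[k, 1] | W[, 2] > W[k, 2])))
  W <- W[maximal, , drop = FALSE]
  W <- W[order(W[, 1]), , drop = FALSE]
  repeat {
    if (nrow(W) < 2) break
    ov <- which(W[-1, 1] <= W[-nrow(W), 2])
    if (!length(ov)) break
    k <- ov[1]
    len1 <- W[k, 2] - W[k, 1] + 1
    len2 <- W[k + 1, 2] - W[k + 1, 1] + 1
    m1 <- mean(x[W[k, 1]:W[k, 2]])
    m2 <- mean(x[W[k + 1, 1]:W[k + 1, 2]])
    drop_row <- if (len1 != len2) (if (len1 > len2) k + 1 else k)
      else if (abs(m1 - m2) > 1e-9) (if (m1 <= m2) k + 1 else k)
      else k + 1
    W <- W[-drop_row, , drop = FALSE]
  }
  unname(W)
}

# Run call_loss_regions on a bare mean-CNA vector laid out on one synthetic
# chromosome; returns (start, end) gene-index pairs of regions with
# n_genes >= min_genes, sorted by start.
call_windows <- function(x, min_genes, thr = -0.4, tol = -0.35) {
  n <- length(x)
  ann <- data.frame(gene_id = sprintf("g%03d", seq_len(n)),
                    chromosome = "chr1", start = seq_len(n) * 1000L,
                    end = seq_len(n) * 1000L + 500L,
                    stringsAsFactors = FALSE)
  summ <- data.frame(gene_id = ann$gene_id, mean_cna = x, n_obs = 10L,
                     bin = "x", excluded = FALSE, stringsAsFactors = FALSE)
  res <- call_loss_regions(summ, ann, "T", min_genes = min_genes,
                           loss_thr = thr, tol = tol)
  reg <- rbind(res$primary, res$candidates)
  reg <- reg[reg$n_genes >= min_genes, , drop = FALSE]
  if (!nrow(reg)) return(matrix(integer(0), ncol = 2))
  W <- t(sapply(reg$genes, function(g) range(match(g, ann$gene_id))))
  unname(W[order(W[, 1]), , drop = FALSE])
}

# --- hypergeometric oracle -------------------------------------------------
# Exhaustive enumeration of all C(N, nB) draws for universes <= 15:
# probability of sharing >= k genes with a fixed success set of size nA.
enum_hyper_p <- function(N, nA, nB, k) {
  draws <- utils::combn(N, nB)
  hits <- colSums(draws <= nA)     # successes are elements 1..nA
  mean(hits >= k)
}

# --- signed-rank oracle ----------------------------------------------------
# Exact two-sided p by enumerating all 2^n sign patterns over the observed
# absolute deviations (midranks for ties), for n <= 12.
enum_signed_rank_p <- function(values, null = 0.5) {
  d <- values[!is.na(values)] - null
  d <- d[d != 0]
  n <- length(d)
  if (!n) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# --- fixtures ---------------------------------------------------------------
rand_matrix <- function(nr, nc, prefix = "S") {
  m <- matrix(round(stats::rnorm(nr * nc, 8, 2), 4), nr, nc)
  dimnames(m) <- list(sprintf("G%03d", seq_len(nr)),
                      sprintf("TCGA-%s-%04d-01", prefix, seq_len(nc)))
  m
}

# A small standard cohort configuration shared by several tests: one 150-gene
# loss region, one 120-gene gain region, discordant and up/down genes at the
# generator defaults.
small_cohort <- function(seed = 7, n_genes = 1000, n_tumors = 100,
                         n_normals = 20, ...) {
  cfg <- cohort_config(
    loss_regions = data.frame(chromosome = "chr1", first_gene = 1,
                              last_gene = 150, mean_cna_target = -0.5),
    gain_regions = data.frame(chromosome = "chr2", first_gene = 1,
                              last_gene = 120, mean_cna_target = 0.5),
    ...)
  generate_cohort(n_genes, 5, n_tumors, n_normals, cfg, seed = seed)
}

# Run the per-cancer core of the pipeline on a generated cohort.
analyze_cohort <- function(cohort, min_genes = 100L) {
  aset <- make_analysis_set(cohort$expr, cohort$cna, cohort$sample_table,
                            cohort$annotations)
  records <- classify_tiers(
    differential_expression(aset$expr_tumor, aset$expr_normal))
  summaries <- gene_cna_summary(aset$cna_tumor)
  regions <- call_loss_regions(summaries, aset$annotations,
                               cohort$sample_table$cancer_code[1],
                               min_genes = min_genes)
  list(aset = aset, records = records, summaries = summaries,
       regions = regions)
}
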