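# Per-gene copy-number summaries and the recurrent loss-region caller.
#
# A loss region is a maximal contiguous run of position-ordered genes such
# that (a) the run's mean per-gene CNA is <= loss_thr (-0.4), (b) it holds
# at least min_genes genes, and (c) no gene inside has mean CNA >= tol
# (-0.35): genes between loss_thr and tol are tolerated only while the run
# mean stays at or below loss_thr. Sub-min_genes runs can be rescued by
# full genomic containment in another cancer's primary region.

.EPS <- 1e-9

#' Per-gene copy-number summary and binning
#'
#' Arithmetic mean of thresholded calls across tumor samples (missing cells
#' excluded), binned as loss (mean < -0.4), gain (mean > +0.4) or nc
#' (no change) with strict inequalities. Genes with no observed calls are
#' flagged `excluded` and ignored by the region caller.
#'
#' @param cna_tumor Thresholded copy-number matrix over tumor samples only.
#' @param loss_thr,gain_thr Bin thresholds.
#' @return Data.frame with `gene_id`, `mean_cna`, `n_obs`, `bin`,
#'   `excluded`.
#' @export
gene_cna_summary <- function(cna_tumor, loss_thr = -0.4, gain_thr = 0.4) {
  v <- .values(cna_tumor)
  n <- rowSums(!is.na(v))
  m <- rowMeans(v, na.rm = TRUE)
  m[n == 0] <- NA_real_
  bin <- rep("nc", nrow(v))
  bin[!is.na(m) & m < loss_thr] <- "loss"
  bin[!is.na(m) & m > gain_thr] <- "gain"
  bin[n == 0] <- NA_character_
  data.frame(gene_id = rownames(v), mean_cna = m, n_obs = n,
             bin = bin, excluded = n == 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

# All maximal contiguous windows of x with mean <= thr and every element
# < tol, as (start, end) index pairs. A window is maximal when no strict
# superset window also satisfies both conditions. Overlapping maximal
# windows (whose union never satisfies the mean rule, else neither would be
# maximal) are resolved by keeping the window with more genes, then the
# lower mean, then the leftmost.
.maximal_windows <- function(x, thr, tol, min_len = 1L) {
  n <- length(x)
  out <- matrix(integer(0), ncol = 2)
  if (!n) return(out)
  allowed <- x < tol                          # strict per-gene ceiling
  runs <- rle(allowed)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (seg in which(runs$values)) {
    lo <- starts[seg]; hi <- ends[seg]
    xs <- x[lo:hi] - thr
    L <- length(xs)
    S <- c(0, cumsum(xs))                     # S[j+1] = sum of first j
    Mr <- rev(cummin(rev(S[-1])))             # Mr[j] = min(S[j+1..L+1])
    cand_i <- integer(0); cand_j <- integer(0)
    for (i in seq_len(L)) {
      v <- S[i] + .EPS
      # largest j with S[j+1] <= v  <=>  largest j with Mr[j] <= v
      j <- findInterval(v, Mr)
      if (j >= i) { cand_i <- c(cand_i, i); cand_j <- c(cand_j, j) }
    }
    keep <- cand_j - cand_i + 1L >= min_len
    cand_i <- cand_i[keep]; cand_j <- cand_j[keep]
    # remove dominated candidates: scan ascending i, keep strictly growing j
    maxj <- -1L; sel <- logical(length(cand_i))
    for (k in seq_along(cand_i)) {
      if (cand_j[k] > maxj) { sel[k] <- TRUE; maxj <- cand_j[k] }
    }
    cand_i <- cand_i[sel]; cand_j <- cand_j[sel]
    # resolve overlaps: prefer more genes, then lower mean, then leftmost
    if (length(cand_i) > 1) {
      repeat {
        ov <- which(cand_i[-1] <= cand_j[-length(cand_j)])
        if (!length(ov)) break
        k <- ov[1]
        m1 <- (S[cand_j[k] + 1] - S[cand_i[k]]) / (cand_j[k] - cand_i[k] + 1)
        m2 <- (S[cand_j[k + 1] + 1] - S[cand_i[k + 1]]) / (cand_j[k + 1] - cand_i[k + 1] + 1)
        len1 <- cand_j[k] - cand_i[k] + 1L
        len2 <- cand_j[k + 1] - cand_i[k + 1] + 1L
        drop <- if (len1 != len2) (if (len1 > len2) k + 1L else k)
                else if (abs(m1 - m2) > .EPS) (if (m1 <= m2) k + 1L else k)
                else k + 1L
        cand_i <- cand_i[-drop]; cand_j <- cand_j[-drop]
        if (length(cand_i) < 2) break
      }
    }
    if (length(cand_i))
      out <- rbind(out, cbind(lo + cand_i - 1L, lo + cand_j - 1L))
  }
  out
}

#' Call recurrent copy-number loss regions on ordered gene summaries
#'
#' Operates on one cancer's per-gene summaries joined with annotations and
#' ordered along chromosomes. Returns qualifying primary regions
#' (`n_genes >= min_genes`) and sub-threshold candidate runs (same mean and
#' tolerance rules but fewer genes), which [rescue_overlapping_regions()]
#' can promote by containment in another cancer's primary region. Genes
#' flagged excluded (all-missing CNA) are removed before calling.
#'
#' @param summaries Output of [gene_cna_summary()].
#' @param annotations Probemap-style data.frame covering the genes.
#' @param cancer_code Cohort label attached to the regions.
#' @param min_genes Minimum genes for a primary region (default 100).
#' @param loss_thr Maximum run mean CNA (default -0.4).
#' @param tol Hard per-gene ceiling: no gene with mean CNA >= `tol`
#'   (default -0.35) is ever inside a region.
#' @return List with `primary` and `candidates`, each a region data.frame
#'   (`cancer_code`, `chromosome`, `start`, `end`, `n_genes`, `mean_cna`,
#'   `rule`, list-column `genes`).
#' @export
call_loss_regions <- function(summaries, annotations, cancer_code = NA_character_,
                              min_genes = 100L, loss_thr = -0.4, tol = -0.35) {
  if (loss_thr >= tol) stop("loss_thr must be below tol")
  df <- merge(summaries[!summaries$excluded, , drop = FALSE],
              annotations[, c("gene_id", "chromosome", "start", "end")],
              by = "gene_id", sort = FALSE)
  if (anyNA(df$chromosome)) stop("every summarized gene needs an annotation")
  df <- df[order(.chrom_rank(df$chromosome), df$chromosome, df$start,
                 df$end, df$gene_id), , drop = FALSE]
  empty <- data.frame(cancer_code = character(), chromosome = character(),
                      start = integer(), end = integer(), n_genes = integer(),
                      mean_cna = numeric(), rule = character(),
                      stringsAsFactors = FALSE)
  empty$genes <- list()
  primary <- empty; candidates <- empty
  for (chr in unique(df$chromosome)) {
    sub <- df[df$chromosome == chr, , drop = FALSE]
    if (is.unsorted(sub$start)) stop("unordered gene positions on ", chr)
    win <- .maximal_windows(sub$mean_cna, loss_thr, tol, min_len = 1L)
    if (!nrow(win)) next
    for (k in seq_len(nrow(win))) {
      i <- win[k, 1]; j <- win[k, 2]
      ng <- j - i + 1L
      reg <- data.frame(cancer_code = cancer_code, chromosome = chr,
                        start = min(sub$start[i:j]), end = max(sub$end[i:j]),
                        n_genes = ng,
                        mean_cna = mean(sub$mean_cna[i:j]),
                        rule = if (ng >= min_genes) "primary" else "candidate",
                        stringsAsFactors = FALSE)
      reg$genes <- list(sub$gene_id[i:j])
      if (ng >= min_genes) primary <- rbind(primary, reg)
      else candidates <- rbind(candidates, reg)
    }
  }
  rownames(primary) <- rownames(candidates) <- NULL
  list(primary = primary, candidates = candidates)
}

#' Promote sub-threshold runs contained in another cancer's primary region
#'
#' A candidate run (mean CNA <= -0.4, every gene below tolerance, but fewer
#' than `min_genes` genes) is promoted to `overlap_rescued` iff its genomic
#' span is fully contained in a primary region called in a different
#' cancer.
#'
#' @param candidates Candidate region data.frame (from
#'   [call_loss_regions()]`$candidates`, possibly row-bound across cancers).
#' @param primaries Primary region data.frame across all cancers.
#' @return The promoted candidates with `rule = "overlap_rescued"` and a
#'   `rescued_by` column naming the containing cancer region.
#' @export
rescue_overlapping_regions <- function(candidates, primaries) {
  if (!nrow(candidates) || !nrow(primaries)) {
    out <- candidates[integer(0), , drop = FALSE]
    out$rescued_by <- character(0)
    return(out)
  }
  keep <- logical(nrow(candidates))
  by_whom <- character(nrow(candidates))
  for (k in seq_len(nrow(candidates))) {
    cand <- candidates[k, ]
    host <- primaries$cancer_code != cand$cancer_code &
      primaries$chromosome == cand$chromosome &
      primaries$start <= cand$start & primaries$end >= cand$end
    if (any(host)) {
      keep[k] <- TRUE
      h <- which(host)[1]
      by_whom[k] <- sprintf("%s:%s:%d-%d", primaries$cancer_code[h],
                            primaries$chromosome[h], primaries$start[h],
                            primaries$end[h])
    }
  }
  out <- candidates[keep, , drop = FALSE]
  out$rule <- rep("overlap_rescued", nrow(out))
  out$rescued_by <- by_whom[keep]
  rownames(out) <- NULL
  out
}

#' Overlap between two regions
#'
#' Interval intersection on genomic spans (1-based inclusive) plus the
#' gene-set intersection. Containment fraction is shared bases over the
#' smaller span; regions on different chromosomes share nothing.
#'
#' @param a,b One-row region data.frames (or lists) with `chromosome`,
#'   `start`, `end` and optionally a `genes` list-column.
#' @return List with `shared_bp`, `containment_fraction`, `shared_genes`.
#' @export
region_overlap <- function(a, b) {
  ga <- if (!is.null(a$genes)) unlist(a$genes) else character()
  gb <- if (!is.null(b$genes)) unlist(b$genes) else character()
  if (a$chromosome != b$chromosome)
    return(list(shared_bp = 0L, containment_fraction = 0,
                shared_genes = character()))
  shared <- max(0L, min(a$end, b$end) - max(a$start, b$start) + 1L)
  smaller <- min(a$end - a$start + 1L, b$end - b$start + 1L)
  list(shared_bp = as.integer(shared),
       containment_fraction = if (smaller > 0) shared / smaller else 0,
       shared_genes = intersect(ga, gb))
}
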