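# Synthetic TCGA-like cohorts with planted ground truth. The generator
# emulates the structure the analysis assumes: paired thresholded-CNA and
# log2 expression matrices over position-ordered genes, copy-neutral
# normals, whole-region heterozygous losses recurring across tumors, a
# dosage effect of copy number on expression, and a planted minority of
# "discordant" genes upregulated despite loss.

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a cohort with a clear dosage effect and a discordant
#' minority: expression changes by `dosage_slope` log2 units per thresholded
#' copy-number unit, per-gene log2 noise has standard deviation `noise_sd`,
#' and planted effect sizes are 1.5 log2 units. Planted regions are given as
#' gene-index spans within a chromosome with a target mean CNA across
#' tumors; the loss is a whole-region heterozygous deletion (-1) carried by
#' a fraction of tumors equal to `-mean_cna_target` (so the per-gene mean
#' across tumors hits the target).
#'
#' @param loss_regions,gain_regions Data.frame (or list of lists) with
#'   columns `chromosome`, `first_gene`, `last_gene` (1-based gene indices
#'   within the chromosome) and `mean_cna_target` (negative for losses,
#'   positive for gains).
#' @param n_discordant_per_region Genes per loss region planted as
#'   upregulated despite loss.
#' @param discordant_effect,up_effect,down_effect Planted tumor-vs-normal
#'   log2 effect sizes; discordant and up genes are program-driven
#'   (copy-number independent), down genes keep their dosage response.
#' @param up_fraction,down_fraction Fractions of genes (outside planted
#'   loss regions) planted as plainly up-/downregulated; counts scale with
#'   `n_genes`.
#' @param dosage_slope Log2 expression change per CNA unit.
#' @param noise_sd Per-gene log2 expression standard deviation (> 0).
#' @param baseline_range Uniform range for expressed-gene baselines (log2).
#' @param low_expr_fraction Fraction of genes planted below the expression
#'   floor (baseline drawn from `low_baseline_range`).
#' @param low_baseline_range Uniform range for below-floor baselines.
#' @param background_rate Rate of sporadic single-gene +/-1 calls outside
#'   planted regions (symmetric).
#' @param cancer_code Cohort label for sample metadata.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(loss_regions = NULL,
                          gain_regions = NULL,
                          n_discordant_per_region = 5L,
                          discordant_effect = 1.5,
                          up_effect = 1.5,
                          down_effect = 1.5,
                          up_fraction = 0.05,
                          down_fraction = 0.05,
                          dosage_slope = 0.5,
                          noise_sd = 0.5,
                          baseline_range = c(3, 12),
                          low_expr_fraction = 0.1,
                          low_baseline_range = c(0.5, 1.8),
                          background_rate = 0.02,
                          cancer_code = "SYN1") {
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  cfg <- list(loss_regions = .as_region_table(loss_regions, "loss"),
              gain_regions = .as_region_table(gain_regions, "gain"),
              n_discordant_per_region = as.integer(n_discordant_per_region),
              discordant_effect = discordant_effect,
              up_effect = up_effect, down_effect = down_effect,
              up_fraction = up_fraction, down_fraction = down_fraction,
              dosage_slope = dosage_slope, noise_sd = noise_sd,
              baseline_range = baseline_range,
              low_expr_fraction = low_expr_fraction,
              low_baseline_range = low_baseline_range,
              background_rate = background_rate,
              cancer_code = cancer_code)
  class(cfg) <- "cohort_config"
  cfg
}

.as_region_table <- function(x, side) {
  if (is.null(x) || (is.data.frame(x) && !nrow(x)))
    return(data.frame(chromosome = character(), first_gene = integer(),
                      last_gene = integer(), mean_cna_target = numeric(),
                      stringsAsFactors = FALSE))
  if (!is.data.frame(x)) x <- do.call(rbind.data.frame, c(x, stringsAsFactors = FALSE))
  need <- c("chromosome", "first_gene", "last_gene", "mean_cna_target")
  if (!all(need %in% names(x)))
    stop("planted regions need columns ", paste(need, collapse = ", "))
  x$first_gene <- as.integer(x$first_gene)
  x$last_gene <- as.integer(x$last_gene)
  if (any(x$first_gene > x$last_gene)) stop("region with first_gene > last_gene")
  if (side == "loss" && any(x$mean_cna_target >= 0))
    stop("loss regions need a negative mean_cna_target")
  if (side == "gain" && any(x$mean_cna_target <= 0))
    stop("gain regions need a positive mean_cna_target")
  if (any(abs(x$mean_cna_target) > 1))
    stop("mean_cna_target must lie in [-1, 1] (single-copy events)")
  x
}

#' Generate a synthetic paired CNA/expression cohort with planted truth
#'
#' Genes are laid out consecutively on `n_chromosomes` chromosomes. Normals
#' are copy-neutral by construction. Within each planted region, a fixed
#' number of tumors (`round(|target| * n_tumors)`, sampled without
#' replacement) carries the whole-region single-copy event, so the realized
#' per-gene mean CNA equals the target up to rounding. Expression is
#' `baseline + dosage_slope * CNA + effect + N(0, noise_sd)`, where
#' `effect` is nonzero only in tumors and only for planted genes; planted
#' discordant and up genes are program-driven (their dosage term is zero,
#' so their tumor/normal difference is independent of copy number - the
#' property that makes a discordant gene upregulated despite loss).
#' Output is deterministic for a fixed seed.
#'
#' @param n_genes,n_chromosomes,n_tumors,n_normals Cohort dimensions
#'   (`n_tumors`, `n_normals >= 2`).
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return List with `expr` and `cna` ([omics_matrix()] objects over tumors
#'   and normals), `annotations` (probemap-style data.frame),
#'   `sample_table`, and `truth` (planted regions with gene ids, discordant
#'   / up / down gene sets, above-floor gene ids, and the generator
#'   parameters).
#' @export
generate_cohort <- function(n_genes, n_chromosomes, n_tumors, n_normals,
                            config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  if (n_tumors < 2 || n_normals < 2) stop("need >= 2 tumors and >= 2 normals")
  set.seed(as.integer(seed))

  chrom_of <- sprintf("chr%d", rep(seq_len(n_chromosomes),
                                   each = ceiling(n_genes / n_chromosomes))[seq_len(n_genes)])
  idx_in_chrom <- stats::ave(seq_len(n_genes), chrom_of, FUN = seq_along)
  genes <- sprintf("G%05d", seq_len(n_genes))
  annotations <- data.frame(gene_id = genes, chromosome = chrom_of,
                            start = idx_in_chrom * 100000L,
                            end = idx_in_chrom * 100000L + 10000L,
                            strand = "+", stringsAsFactors = FALSE)

  region_genes <- function(r) {
    on_chr <- genes[chrom_of == r$chromosome]
    if (r$last_gene > length(on_chr))
      stop("planted region exceeds ", r$chromosome, " (",
           length(on_chr), " genes)")
    on_chr[r$first_gene:r$last_gene]
  }
  all_regions <- rbind(config$loss_regions, config$gain_regions)
  if (nrow(all_regions) > 1) {
    spans <- split(all_regions, seq_len(nrow(all_regions)))
    for (i in seq_along(spans)) for (j in seq_along(spans)) {
      if (i < j && spans[[i]]$chromosome == spans[[j]]$chromosome &&
          spans[[i]]$first_gene <= spans[[j]]$last_gene &&
          spans[[j]]$first_gene <= spans[[i]]$last_gene)
        stop("planted regions overlap on ", spans[[i]]$chromosome)
    }
  }

  tumors <- sprintf("TCGA-SY-%04d-01", seq_len(n_tumors))
  normals <- sprintf("TCGA-SY-%04d-11", n_tumors + seq_len(n_normals))
  samples <- c(tumors, normals)

  cna <- matrix(0, n_genes, n_tumors + n_normals, dimnames = list(genes, samples))
  if (config$background_rate > 0 && n_genes > 0) {
    ncell <- n_genes * n_tumors
    hit <- which(stats::runif(ncell) < config$background_rate)
    if (length(hit))
      cna[, seq_len(n_tumors)][hit] <- sample(c(-1, 1), length(hit), replace = TRUE)
  }
  plant <- function(regions, call) {
    out <- list()
    if (nrow(regions)) for (i in seq_len(nrow(regions))) {
      r <- regions[i, ]
      rg <- region_genes(r)
      k <- round(abs(r$mean_cna_target) * n_tumors)
      carriers <- sample(tumors, k)
      cna[rg, tumors] <<- 0          # planted rows are free of background
      cna[rg, carriers] <<- call
      out[[i]] <- list(chromosome = r$chromosome, genes = rg,
                       mean_cna_target = r$mean_cna_target,
                       carriers = carriers)
    }
    out
  }
  loss_truth <- plant(config$loss_regions, -1)
  gain_truth <- plant(config$gain_regions, +1)

  n_low <- floor(config$low_expr_fraction * n_genes)
  low_genes <- if (n_low > 0) sample(genes, n_low) else character()
  baseline <- stats::runif(n_genes, config$baseline_range[1], config$baseline_range[2])
  names(baseline) <- genes
  baseline[low_genes] <- stats::runif(n_low, config$low_baseline_range[1],
                                      config$low_baseline_range[2])

  loss_gene_pool <- unlist(lapply(loss_truth, `[[`, "genes"))
  discordant <- character()
  if (length(loss_truth) && config$n_discordant_per_region > 0) {
    discordant <- unlist(lapply(loss_truth, function(r) {
      pool <- setdiff(r$genes, low_genes)
      sample(pool, min(config$n_discordant_per_region, length(pool)))
    }))
  }
  de_pool <- setdiff(genes, c(loss_gene_pool, low_genes))
  n_up <- round(config$up_fraction * n_genes)
  n_down <- round(config$down_fraction * n_genes)
  up_genes <- if (n_up > 0) sample(de_pool, min(n_up, length(de_pool))) else character()
  de_pool <- setdiff(de_pool, up_genes)
  down_genes <- if (n_down > 0) sample(de_pool, min(n_down, length(de_pool))) else character()

  effect <- stats::setNames(numeric(n_genes), genes)
  effect[up_genes] <- config$up_effect
  effect[down_genes] <- -config$down_effect
  effect[discordant] <- config$discordant_effect

  # Discordant and planted-up genes emulate program-driven expression: their
  # level is set by the transcriptional effect alone, independent of copy
  # number (no dosage term) - this is what makes them upregulated *despite*
  # loss. All other genes scale with copy number.
  slope <- rep(config$dosage_slope, n_genes)
  names(slope) <- genes
  slope[c(discordant, up_genes)] <- 0

  is_tumor <- rep(c(1, 0), c(n_tumors, n_normals))
  expr <- baseline + slope * cna +
    outer(effect, is_tumor) +
    matrix(stats::rnorm(n_genes * length(samples), 0, config$noise_sd),
           n_genes, length(samples))
  dimnames(expr) <- list(genes, samples)

  sample_table <- classify_samples(samples, cancer_code = config$cancer_code)
  truth <- list(loss_regions = loss_truth, gain_regions = gain_truth,
                discordant_genes = discordant, up_genes = up_genes,
                down_genes = down_genes,
                above_floor_genes = setdiff(genes, low_genes),
                baseline = baseline, effect = effect,
                dosage_slope = config$dosage_slope,
                noise_sd = config$noise_sd, seed = as.integer(seed))
  list(expr = omics_matrix(expr, "expression_log2"),
       cna = omics_matrix(cna, "cna_thresholded"),
       annotations = annotations, sample_table = sample_table, truth = truth)
}

#' Generate a synthetic PCR-tag qPCR experiment
#'
#' Emits per-tumor, per-tag Ct values following the relative-quantification
#' model `Ct_tag - Ct_reference = -log2(proportion / reference_proportion) +
#' noise`, with the time-zero mixture as the reference. A zero true
#' proportion yields a not-detected flag instead of a Ct.
#'
#' @param true_proportions Numeric matrix (tumors x tags; rows sum to 1) of
#'   true tag proportions per tumor. Rownames become tumor ids, colnames tag
#'   names.
#' @param ct_noise_sd Standard deviation of Ct noise (cycles).
#' @param seed Integer seed.
#' @param reference_proportions Tag proportions of the time-zero mix
#'   (default equal).
#' @param site Tumor site label(s) (recycled): `"primary"` or
#'   `"metastasis"`.
#' @param base_ct Ct of an equal-share tag in the reference mix.
#' @return List (`TagExperiment`) with `ct` (data.frame `tumor_id`, `site`,
#'   `tag`, `ct`, `detected`) and `reference` (data.frame `tag`, `ct`).
#' @export
generate_tag_experiment <- function(true_proportions, ct_noise_sd = 0,
                                    seed = 1L, reference_proportions = NULL,
                                    site = "primary", base_ct = 20) {
  p <- as.matrix(true_proportions)
  if (any(p < 0)) stop("proportions must be non-negative")
  if (any(abs(rowSums(p) - 1) > 1e-8))
    stop("per-tumor true proportions must sum to 1")
  n_tags <- ncol(p)
  if (n_tags < 2) stop("need >= 2 tags")
  if (is.null(colnames(p))) colnames(p) <- sprintf("tag%d", seq_len(n_tags))
  if (is.null(rownames(p))) rownames(p) <- sprintf("tumor%02d", seq_len(nrow(p)))
  ref <- if (is.null(reference_proportions)) rep(1 / n_tags, n_tags) else reference_proportions
  if (length(ref) != n_tags || abs(sum(ref) - 1) > 1e-8)
    stop("reference proportions must cover every tag and sum to 1")
  set.seed(as.integer(seed))
  ref_ct <- base_ct - log2(ref * n_tags)
  site <- rep(site, length.out = nrow(p))
  rows <- expand.grid(tag = colnames(p), tumor_id = rownames(p),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- rows[, c("tumor_id", "tag")]
  prop <- p[cbind(rows$tumor_id, rows$tag)]
  refp <- ref[match(rows$tag, colnames(p))]
  refc <- ref_ct[match(rows$tag, colnames(p))]
  noise <- stats::rnorm(nrow(rows), 0, ct_noise_sd)
  detected <- prop > 0
  ct <- ifelse(detected, refc - log2(ifelse(detected, prop, NA) / refp) + noise, NA_real_)
  out <- data.frame(tumor_id = rows$tumor_id,
                    site = site[match(rows$tumor_id, rownames(p))],
                    tag = rows$tag, ct = ct, detected = detected,
                    stringsAsFactors = FALSE)
  list(ct = out, reference = data.frame(tag = colnames(p), ct = ref_ct,
                                        stringsAsFactors = FALSE))
}
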