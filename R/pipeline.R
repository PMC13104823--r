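# Orchestration: per-cancer preprocess -> differential expression -> region
# calling, then cross-cancer rescue, sharing, pairwise overlaps and
# optional gene-set stages, with a deterministic manifest.

#' Build and validate a pipeline run configuration
#'
#' @param cancers Named list (cancer code -> list with `expr` and `cna`,
#'   each an [omics_matrix()] or a TSV path, and optionally `classes`, a
#'   named tumor/normal vector overriding barcode classification).
#' @param probemap Probemap data.frame or path for [read_probemap()].
#' @param floor Expression floor (log2, default 2).
#' @param loss_thr,tol,gain_thr Region-calling thresholds (defaults -0.4,
#'   -0.35, +0.4); must satisfy `loss_thr < tol < 0 < gain_thr`.
#' @param min_genes Minimum genes for a primary region (default 100).
#' @param strict,relaxed Tier cut-offs, see [classify_tiers()].
#' @param fc_cut Fold-change cut for bin proportions (default 1.0).
#' @param min_list Minimum list size for pairwise overlap tests (default 15).
#' @param gene_sets Optional GMT path or list of gene sets.
#' @param ce_genes Optional common-essential list (path or character
#'   vector).
#' @param out_dir Optional output directory for CSV/BED/manifest export.
#' @param seed Integer recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return Validated config list of class `cnd_config`.
#' @export
run_config <- function(cancers, probemap, floor = 2.0, loss_thr = -0.4,
                       tol = -0.35, gain_thr = 0.4, min_genes = 100L,
                       strict = c(1.0, 1e-4), relaxed = c(0.4, 1e-2),
                       fc_cut = 1.0, min_list = 15L, gene_sets = NULL,
                       ce_genes = NULL, out_dir = NULL, seed = 1L) {
  cfg <- list(cancers = cancers, probemap = probemap, floor = floor,
              loss_thr = loss_thr, tol = tol, gain_thr = gain_thr,
              min_genes = as.integer(min_genes), strict = strict,
              relaxed = relaxed, fc_cut = fc_cut,
              min_list = as.integer(min_list), gene_sets = gene_sets,
              ce_genes = ce_genes, out_dir = out_dir,
              seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "cnd_config"
  cfg
}

#' @rdname run_config
#' @param config A config list (before or after [run_config()]).
#' @export
validate_config <- function(config) {
  if (!length(config$cancers)) stop("configure at least one cancer")
  if (is.null(names(config$cancers)) || any(!nzchar(names(config$cancers))))
    stop("'cancers' must be a named list of cancer codes")
  with(config, {
    if (!(loss_thr < tol && tol < 0 && 0 < gain_thr))
      stop("thresholds must satisfy loss_thr < tol < 0 < gain_thr")
    if (min_genes < 1) stop("min_genes must be >= 1")
    if (strict[1] < relaxed[1] || strict[2] > relaxed[2])
      stop("strict tier must be at least as stringent as relaxed")
  })
  for (code in names(config$cancers)) {
    cc <- config$cancers[[code]]
    for (field in c("expr", "cna")) {
      if (is.null(cc[[field]])) stop(code, ": missing '", field, "'")
      if (is.character(cc[[field]]) && !file.exists(cc[[field]]))
        stop(code, ": file not found: ", cc[[field]])
    }
  }
  if (is.character(config$probemap) && !file.exists(config$probemap))
    stop("probemap file not found: ", config$probemap)
  invisible(TRUE)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [run_config()]'s arguments, with per-cancer `expr` /
#' `cna` file paths under a `cancers` mapping. Relative paths are resolved
#' against the YAML file's directory.
#'
#' @param path Path to the YAML file.
#' @return A validated `cnd_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  fix_path <- function(p) {
    if (is.character(p) && !file.exists(p) && file.exists(file.path(base, p)))
      file.path(base, p) else p
  }
  y$cancers <- lapply(y$cancers, function(cc) {
    cc$expr <- fix_path(cc$expr); cc$cna <- fix_path(cc$cna); cc
  })
  for (field in c("probemap", "gene_sets", "ce_genes"))
    if (!is.null(y[[field]])) y[[field]] <- fix_path(y[[field]])
  do.call(run_config, y)
}

.load_inputs <- function(cc, code, probemap) {
  expr <- if (is.character(cc$expr)) read_matrix_tsv(cc$expr, "expression_log2") else cc$expr
  cna <- if (is.character(cc$cna)) read_matrix_tsv(cc$cna, "cna_thresholded") else cc$cna
  st <- classify_samples(union(sample_ids(expr), sample_ids(cna)),
                         classes = cc$classes, cancer_code = code)
  list(expr = expr, cna = cna, sample_table = st)
}

.bind_regions <- function(primary, rescued) {
  if (nrow(primary)) primary$rescued_by <- NA_character_
  else primary$rescued_by <- character(0)
  rbind(primary, rescued)
}

#' Run the full analysis across configured cancers
#'
#' Per cancer: sample matching and tumor/normal split, expression floor,
#' positional ordering, tumor-versus-normal differential expression with
#' tier classification, per-gene copy-number summary and loss-region
#' calling. Across cancers: rescue of sub-threshold runs by containment in
#' another cancer's primary region, discordant-gene identification at both
#' tiers, cross-cancer sharing, pairwise hypergeometric overlap tests on
#' shared regions, and (when gene sets are configured) per-set bin
#' summaries, common-essential four-bin / rank-cumulative comparisons and
#' a local over-representation test. A stage failure aborts with the stage
#' and cancer named. Results are deterministic for fixed inputs.
#'
#' @param config A `cnd_config` from [run_config()] /
#'   [read_run_config()], or a YAML path.
#' @return List with `per_cancer`, `regions`, `discordant_strict`,
#'   `discordant_relaxed`, `sharing`, `overlaps`, `genesets`, `manifest`.
#'   When `config$out_dir` is set, CSV/BED/JSON exports are written there.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  validate_config(config)
  probemap <- if (is.character(config$probemap)) read_probemap(config$probemap)
              else config$probemap
  gene_sets <- if (is.character(config$gene_sets)) read_gmt(config$gene_sets)
               else config$gene_sets
  ce_genes <- if (is.character(config$ce_genes)) read_gene_list(config$ce_genes)
              else config$ce_genes

  stage <- function(name, code, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed for %s: %s", name, code,
                   conditionMessage(e)), call. = FALSE))
  }

  per_cancer <- list()
  for (code in names(config$cancers)) {
    inputs <- stage("ingest", code,
                    .load_inputs(config$cancers[[code]], code, probemap))
    aset <- stage("preprocess", code,
                  make_analysis_set(inputs$expr, inputs$cna,
                                    inputs$sample_table, probemap,
                                    floor = config$floor))
    records <- stage("diffexpr", code, classify_tiers(
      differential_expression(aset$expr_tumor, aset$expr_normal),
      strict = config$strict, relaxed = config$relaxed))
    summaries <- stage("cna_summary", code, gene_cna_summary(
      aset$cna_tumor, loss_thr = config$loss_thr, gain_thr = config$gain_thr))
    regions <- stage("regions", code, call_loss_regions(
      summaries, aset$annotations, cancer_code = code,
      min_genes = config$min_genes, loss_thr = config$loss_thr,
      tol = config$tol))
    bins <- stage("concordance", code,
                  bin_tier_proportions(records, summaries,
                                       fc_cut = config$fc_cut))
    per_cancer[[code]] <- list(analysis_set = aset, records = records,
                               summaries = summaries, regions = regions,
                               bin_proportions = bins)
  }

  primaries <- do.call(rbind, lapply(per_cancer, function(x) x$regions$primary))
  rownames(primaries) <- NULL
  regions_by_cancer <- list()
  disc_strict <- list(); disc_relaxed <- list()
  for (code in names(per_cancer)) {
    rescued <- rescue_overlapping_regions(
      per_cancer[[code]]$regions$candidates, primaries)
    regions_by_cancer[[code]] <- .bind_regions(
      per_cancer[[code]]$regions$primary, rescued)
    disc_strict[[code]] <- discordant_genes(
      per_cancer[[code]]$records, regions_by_cancer[[code]], "strict")
    disc_relaxed[[code]] <- discordant_genes(
      per_cancer[[code]]$records, regions_by_cancer[[code]], "relaxed")
  }
  all_regions <- do.call(rbind, regions_by_cancer)
  rownames(all_regions) <- NULL

  sharing <- NULL
  if (length(per_cancer) >= 2) {
    ann_all <- unique(do.call(rbind, lapply(per_cancer, function(x)
      x$analysis_set$annotations)))
    sharing <- sharing_histogram(
      lapply(disc_strict, function(d) d$genes$gene_id), ann_all)
  }

  overlaps <- .pairwise_region_overlaps(regions_by_cancer, per_cancer, config)

  genesets <- NULL
  if (!is.null(gene_sets) || !is.null(ce_genes))
    genesets <- .geneset_stage(per_cancer, regions_by_cancer, gene_sets,
                               ce_genes, disc_strict)

  manifest <- list(
    package = "cndiscord",
    version = as.character(utils::packageVersion("cndiscord")),
    seed = config$seed,
    config_hash = .config_hash(config),
    cancers = names(per_cancer),
    stages = c("ingest", "preprocess", "diffexpr", "cna_summary",
               "regions", "rescue", "concordance",
               if (!is.null(genesets)) "genesets"),
    counts = lapply(per_cancer, function(x) list(
      genes = length(x$analysis_set$genes),
      tumors = ncol(.values(x$analysis_set$expr_tumor)),
      normals = ncol(.values(x$analysis_set$expr_normal)),
      primary_regions = nrow(x$regions$primary),
      candidate_runs = nrow(x$regions$candidates))))

  result <- list(per_cancer = per_cancer, regions = all_regions,
                 regions_by_cancer = regions_by_cancer,
                 discordant_strict = disc_strict,
                 discordant_relaxed = disc_relaxed,
                 sharing = sharing, overlaps = overlaps,
                 genesets = genesets, manifest = manifest)
  if (!is.null(config$out_dir)) .write_outputs(result, config)
  result
}

.config_hash <- function(config) {
  slim <- config[setdiff(names(config), c("cancers", "probemap",
                                          "gene_sets", "ce_genes",
                                          "out_dir"))]
  slim$cancers <- lapply(config$cancers, function(cc)
    lapply(cc, function(v) if (is.character(v)) v else "in-memory"))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(slim, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

# Pairwise hypergeometric overlap tests for every cross-cancer pair of
# overlapping loss regions. Universe: expressed genes present in both
# regions; lists: relaxed-tier upregulated genes of each cancer inside
# that universe.
.pairwise_region_overlaps <- function(regions_by_cancer, per_cancer, config) {
  codes <- names(regions_by_cancer)
  rows <- list()
  if (length(codes) < 2) return(NULL)
  for (i in seq_along(codes)) for (j in seq_along(codes)) {
    if (i >= j) next
    ra <- regions_by_cancer[[codes[i]]]
    rb <- regions_by_cancer[[codes[j]]]
    if (!nrow(ra) || !nrow(rb)) next
    up_a <- up_genes_at_tier(per_cancer[[codes[i]]]$records, "relaxed")
    up_b <- up_genes_at_tier(per_cancer[[codes[j]]]$records, "relaxed")
    for (a in seq_len(nrow(ra))) for (b in seq_len(nrow(rb))) {
      ov <- region_overlap(ra[a, ], rb[b, ])
      if (!length(ov$shared_genes)) next
      universe <- ov$shared_genes
      test <- pairwise_overlap_test(intersect(up_a, universe),
                                    intersect(up_b, universe),
                                    universe, min_list = config$min_list)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(cancer_a = codes[i], cancer_b = codes[j],
                   chromosome = ra$chromosome[a],
                   start = max(ra$start[a], rb$start[b]),
                   end = min(ra$end[a], rb$end[b]),
                   stringsAsFactors = FALSE),
        test)
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.geneset_stage <- function(per_cancer, regions_by_cancer, gene_sets,
                           ce_genes, disc_strict) {
  out <- list()
  if (!is.null(gene_sets)) {
    out$binned <- do.call(rbind, lapply(names(per_cancer), function(code) {
      do.call(rbind, lapply(gene_sets, function(s) {
        res <- suppressWarnings(binned_set_log2fc(
          per_cancer[[code]]$records, per_cancer[[code]]$summaries,
          if (is.list(s)) s$members else s,
          set_name = if (is.list(s)) s$name else "gene_set"))
        cbind(cancer_code = code,
              res$bins[res$bins$set != "all_genes", , drop = FALSE],
              p_gain_vs_loss = res$p_gain_vs_loss)
      }))
    }))
    universe <- sort(unique(unlist(lapply(per_cancer, function(x)
      x$analysis_set$genes))))
    lst <- intersect(sort(unique(unlist(lapply(disc_strict, function(d)
      d$genes$gene_id)))), universe)
    out$ora <- ora_enrichment(lst, gene_sets, universe)
  }
  if (!is.null(ce_genes)) {
    out$four_bin <- list(); out$rank_cumulative <- list()
    for (code in names(per_cancer)) {
      regs <- regions_by_cancer[[code]]
      if (!nrow(regs)) next
      for (k in seq_len(nrow(regs))) {
        key <- sprintf("%s:%s:%d-%d", code, regs$chromosome[k],
                       regs$start[k], regs$end[k])
        recs <- per_cancer[[code]]$records
        recs <- recs[recs$gene_id %in% unlist(regs$genes[k]), , drop = FALSE]
        if (any(recs$gene_id %in% ce_genes)) {
          out$four_bin[[key]] <- four_bin_comparison(recs, ce_genes)
          out$rank_cumulative[[key]] <- rank_cumulative(recs, ce_genes)
        }
      }
    }
  }
  out
}

.write_outputs <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) utils::write.csv(
    df, file.path(config$out_dir, name), row.names = FALSE)
  for (code in names(result$per_cancer)) {
    pc <- result$per_cancer[[code]]
    wr(pc$records, sprintf("%s_diffexpr.csv", code))
    wr(pc$summaries, sprintf("%s_cna_summary.csv", code))
    wr(pc$bin_proportions, sprintf("%s_bin_proportions.csv", code))
    disc <- result$discordant_strict[[code]]
    wr(disc$genes, sprintf("%s_discordant_strict.csv", code))
  }
  regions_flat <- result$regions
  regions_flat$genes <- vapply(regions_flat$genes, paste, character(1),
                               collapse = ";")
  wr(regions_flat, "regions.csv")
  write_regions_bed(result$regions, file.path(config$out_dir, "regions.bed"))
  if (!is.null(result$sharing)) {
    wr(result$sharing$per_gene, "sharing_per_gene.csv")
    wr(result$sharing$histogram, "sharing_histogram.csv")
  }
  if (!is.null(result$overlaps)) wr(result$overlaps, "pairwise_overlaps.csv")
  writeLines(jsonlite::toJSON(result$manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(config$out_dir, "manifest.json"))
  invisible(NULL)
}
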