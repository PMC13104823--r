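# Sample matching, tumor/normal splitting, expression floor, and
# along-chromosome gene ordering.

#' Classify samples as tumor or normal
#'
#' By default samples are classified from TCGA-style barcodes: the two-digit
#' sample-type code after the participant field maps 01-09 to tumor and
#' 10-19 to normal. An explicit class vector overrides barcode parsing for
#' non-TCGA identifiers.
#'
#' @param ids Character vector of sample identifiers.
#' @param classes Optional character vector (`"tumor"`/`"normal"`), either
#'   named by sample id or positional, overriding barcode parsing.
#' @param cancer_code Cancer cohort label stored alongside each sample.
#' @return A data.frame (`SampleTable`) with columns `sample_id`,
#'   `cancer_code`, `tissue_class`.
#' @examples
#' classify_samples(c("TCGA-AA-0001-01", "TCGA-AA-0001-11"))
#' @export
classify_samples <- function(ids, classes = NULL, cancer_code = NA_character_) {
  if (anyDuplicated(ids))
    stop("duplicate sample identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!is.null(classes)) {
    cls <- if (!is.null(names(classes))) unname(classes[ids]) else classes
    if (length(cls) != length(ids) || anyNA(cls))
      stop("explicit classes must cover every sample id")
    if (!all(cls %in% c("tumor", "normal")))
      stop("classes must be 'tumor' or 'normal'")
  } else {
    code <- suppressWarnings(
      as.integer(sub("^TCGA-[^-]+-[^-]+-(\\d{2}).*$", "\\1", ids)))
    cls <- rep(NA_character_, length(ids))
    cls[!is.na(code) & code >= 1 & code <= 9] <- "tumor"
    cls[!is.na(code) & code >= 10 & code <= 19] <- "normal"
    if (anyNA(cls))
      stop("unclassifiable sample id(s): ",
           paste(utils::head(ids[is.na(cls)], 10), collapse = ", "))
  }
  data.frame(sample_id = ids, cancer_code = cancer_code, tissue_class = cls,
             stringsAsFactors = FALSE)
}

#' Match samples across matrices and split tumor from normal
#'
#' The tumor analysis set is the intersection of tumor samples present in
#' both the expression and copy-number matrices. Normal expression samples
#' are retained separately for the tumor-versus-normal comparison; normals
#' are removed from the copy-number matrix before any averaging.
#'
#' @param expr Expression `OmicsMatrix` (log2).
#' @param cna Thresholded copy-number `OmicsMatrix`.
#' @param sample_table Output of [classify_samples()].
#' @return List with `expr_tumor`, `expr_normal`, `cna_tumor`
#'   (OmicsMatrix views) and the trimmed `sample_table`.
#' @export
match_and_split <- function(expr, cna, sample_table) {
  stopifnot(is.data.frame(sample_table),
            all(c("sample_id", "tissue_class") %in% names(sample_table)))
  tum <- sample_table$sample_id[sample_table$tissue_class == "tumor"]
  nor <- sample_table$sample_id[sample_table$tissue_class == "normal"]
  shared_tum <- intersect(intersect(sample_ids(expr), sample_ids(cna)), tum)
  if (!length(shared_tum))
    stop("no tumor samples shared between expression and copy-number matrices")
  normals <- intersect(sample_ids(expr), nor)
  list(expr_tumor = subset_matrix(expr, samples = shared_tum),
       expr_normal = subset_matrix(expr, samples = normals),
       cna_tumor = subset_matrix(cna, samples = shared_tum),
       sample_table = sample_table[sample_table$sample_id %in%
                                     c(shared_tum, normals), , drop = FALSE])
}

#' Expression floor filter
#'
#' Keeps a gene iff its mean log2 expression is above `floor` in tumor OR in
#' normal ("not above 2 (log2) in either" removes it). Means are arithmetic
#' means of the stored log2 values, missing cells excluded.
#'
#' @param expr_tumor,expr_normal Expression matrices (`OmicsMatrix` or bare
#'   matrix) sharing a gene list.
#' @param floor Log2 threshold (default 2), compared with strict `>`.
#' @return Character vector of retained gene ids, in input order.
#' @export
filter_expression_floor <- function(expr_tumor, expr_normal, floor = 2.0) {
  vt <- .values(expr_tumor)
  vn <- .values(expr_normal)
  genes <- rownames(vt)
  if (!identical(genes, rownames(vn)))
    stop("tumor and normal expression matrices must share one gene list")
  mt <- rowMeans(vt, na.rm = TRUE)
  mn <- rowMeans(vn, na.rm = TRUE)
  keep <- (!is.nan(mt) & mt > floor) | (!is.nan(mn) & mn > floor)
  genes[keep]
}

# chromosome rank for natural ordering: chr1 < ... < chr22 < chrX < chrY < chrM,
# other names after, lexicographically.
.chrom_rank <- function(chrom) {
  base <- sub("^chr", "", chrom, ignore.case = TRUE)
  num <- suppressWarnings(as.numeric(base))
  rank <- ifelse(!is.na(num), num,
                 ifelse(base %in% c("X", "x"), 100,
                        ifelse(base %in% c("Y", "y"), 101,
                               ifelse(base %in% c("M", "MT", "m"), 102, 1000))))
  rank
}

#' Order genes along chromosomes
#'
#' Sorts genes by (chromosome, start, end, gene_id); autosomes order
#' numerically before X, Y and M. Genes without an annotation are dropped
#' with a warning.
#'
#' @param genes Character vector of gene ids.
#' @param annotations Annotation data.frame from [read_probemap()].
#' @return Character vector of the annotated genes in positional order.
#' @export
order_by_position <- function(genes, annotations) {
  ann <- annotations[match(genes, annotations$gene_id), , drop = FALSE]
  lost <- genes[is.na(ann$gene_id)]
  if (length(lost)) {
    warning(length(lost), " gene(s) without annotation dropped: ",
            paste(utils::head(lost, 5), collapse = ", "),
            if (length(lost) > 5) ", ..." else "")
    ann <- ann[!is.na(ann$gene_id), , drop = FALSE]
  }
  ann <- ann[order(.chrom_rank(ann$chromosome), ann$chromosome,
                   ann$start, ann$end, ann$gene_id), , drop = FALSE]
  ann$gene_id
}

#' Build the shared analysis set for one cancer cohort
#'
#' Convenience wrapper chaining [match_and_split()],
#' [filter_expression_floor()] and [order_by_position()]: the result holds
#' tumor expression, normal expression and tumor copy-number views over one
#' filtered, position-ordered gene list (genes present in both matrices,
#' above the expression floor, and annotated).
#'
#' @param expr,cna `OmicsMatrix` inputs.
#' @param sample_table Output of [classify_samples()].
#' @param annotations Probemap data.frame.
#' @param floor Expression floor (log2), see [filter_expression_floor()].
#' @return List (`AnalysisSet`) with `expr_tumor`, `expr_normal`,
#'   `cna_tumor`, `genes`, `annotations`, `sample_table`.
#' @export
make_analysis_set <- function(expr, cna, sample_table, annotations, floor = 2.0) {
  split <- match_and_split(expr, cna, sample_table)
  shared_genes <- intersect(gene_ids(split$expr_tumor), gene_ids(split$cna_tumor))
  et <- subset_matrix(split$expr_tumor, genes = shared_genes)
  en <- subset_matrix(split$expr_normal, genes = shared_genes)
  kept <- filter_expression_floor(et, en, floor = floor)
  ordered <- order_by_position(kept, annotations)
  ann <- annotations[match(ordered, annotations$gene_id), , drop = FALSE]
  rownames(ann) <- NULL
  list(expr_tumor = subset_matrix(split$expr_tumor, genes = ordered),
       expr_normal = subset_matrix(split$expr_normal, genes = ordered),
       cna_tumor = subset_matrix(split$cna_tumor, genes = ordered),
       genes = ordered,
       annotations = ann,
       sample_table = split$sample_table)
}
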