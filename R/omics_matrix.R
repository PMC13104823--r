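#' Gene-by-sample omics matrix
#'
#' Light container for the two matrix dialects the pipeline consumes:
#' log2-scale expression and GISTIC2-thresholded copy-number calls. Gene and
#' sample identifiers are carried as dimnames and must be unique; thresholded
#' copy-number values must lie in `[-2, 2]` (the integer call scale: -2 deep
#' deletion, -1 heterozygous loss, 0 diploid, +1 gain, +2 amplification).
#' Missing cells are `NA` and are excluded from downstream means rather than
#' imputed.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene identifiers),
#'   samples in columns (colnames = sample identifiers).
#' @param kind `"expression_log2"` or `"cna_thresholded"`.
#' @return An object of class `OmicsMatrix`: a list with elements `values`
#'   and `kind`.
#' @examples
#' m <- matrix(0, 1, 1, dimnames = list("TGIF1", "TCGA-AA-0001-01"))
#' omics_matrix(m, "cna_thresholded")
#' @export
omics_matrix <- function(values, kind = c("expression_log2", "cna_thresholded")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("'values' must carry gene and sample identifiers as dimnames")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  storage.mode(values) <- "double"
  if (kind == "cna_thresholded" &&
      any(values < -2 | values > 2, na.rm = TRUE))
    stop("cna_thresholded values must lie in [-2, 2]")
  structure(list(values = values, kind = kind), class = "OmicsMatrix")
}

#' @export
print.OmicsMatrix <- function(x, ...) {
  cat(sprintf("OmicsMatrix [%s]: %d genes x %d samples\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.OmicsMatrix <- function(x) dim(x$values)

#' Gene and sample identifiers of an OmicsMatrix
#' @param x An `OmicsMatrix`.
#' @return Character vector of identifiers.
#' @export
gene_ids <- function(x) rownames(.values(x))

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(.values(x))

# Accept either an OmicsMatrix or a bare matrix throughout the package.
.values <- function(x) {
  if (inherits(x, "OmicsMatrix")) x$values else x
}

#' Subset an OmicsMatrix by genes and/or samples
#'
#' @param x An `OmicsMatrix`.
#' @param genes,samples Character vectors of identifiers to keep (in the
#'   given order); `NULL` keeps all.
#' @return An `OmicsMatrix` of the same kind.
#' @export
subset_matrix <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "OmicsMatrix"))
  v <- x$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing))
      stop("genes absent from matrix: ", paste(utils::head(missing, 5), collapse = ", "))
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(v))
    if (length(missing))
      stop("samples absent from matrix: ", paste(utils::head(missing, 5), collapse = ", "))
    v <- v[, samples, drop = FALSE]
  }
  omics_matrix(v, x$kind)
}
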