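# Readers/writers for the plain-text formats the pipeline touches:
# Xena-style TSV matrices, probemaps, GMT gene sets, gene lists, BED6.
# All rejections are surfaced (error or warning), never silent.

.open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

#' Read a Xena-style gene-by-sample TSV matrix
#'
#' First row is the sample header, first column the gene identifiers,
#' tab-separated. Empty cells are read as missing (`NA`). Files may be
#' gzip-compressed (detected by a `.gz` suffix). Ragged rows and duplicate
#' identifiers are rejected with an informative error.
#'
#' @param path Path to the TSV (optionally `.gz`).
#' @param kind `"expression_log2"` or `"cna_thresholded"`; thresholded
#'   copy-number files are range-checked against `[-2, 2]`.
#' @return An [omics_matrix()].
#' @export
read_matrix_tsv <- function(path, kind = c("expression_log2", "cna_thresholded")) {
  kind <- match.arg(kind)
  con <- .open_text(path)
  on.exit(close(con), add = TRUE)
  nf <- utils::count.fields(con, sep = "\t", quote = "", comment.char = "",
                            blank.lines.skip = FALSE)
  if (!length(nf)) stop("empty matrix file: ", path)
  bad <- which(nf != nf[1])
  if (length(bad))
    stop(sprintf("ragged matrix file %s: line %d has %d fields, expected %d",
                 path, bad[1], nf[bad[1]], nf[1]))
  con2 <- .open_text(path)
  on.exit(close(con2), add = TRUE)
  df <- utils::read.delim(con2, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA", "null"),
                          colClasses = "character")
  if (ncol(df) < 2) stop("matrix file must have a gene column and >=1 sample: ", path)
  genes <- df[[1]]
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers in ", path, ": ",
         paste(utils::head(unique(genes[duplicated(genes)]), 5), collapse = ", "))
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample identifiers in ", path)
  vals <- suppressWarnings(
    vapply(df[-1], as.numeric, numeric(nrow(df)), USE.NAMES = FALSE))
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = nrow(df))
  non_numeric <- is.na(vals) & !is.na(as.matrix(df[-1]))
  if (any(non_numeric))
    stop("non-numeric cell(s) in ", path, " (first at gene ",
         genes[which(rowSums(non_numeric) > 0)[1]], ")")
  dimnames(vals) <- list(genes, samples)
  omics_matrix(vals, kind)
}

#' Write an OmicsMatrix as a Xena-style TSV
#'
#' @param x An `OmicsMatrix` or bare named matrix.
#' @param path Output path (writes gzip if it ends in `.gz`).
#' @param gene_col Header of the gene-identifier column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path, gene_col = "sample") {
  v <- .values(x)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con), add = TRUE)
  writeLines(paste(c(gene_col, colnames(v)), collapse = "\t"), con)
  body <- apply(format(v, trim = TRUE, digits = 15, scientific = FALSE), 1,
                paste, collapse = "\t")
  body[] <- gsub("\\bNA\\b", "", body)
  writeLines(paste(rownames(v), body, sep = "\t"), con)
  invisible(path)
}

#' Read a gene probemap (gene -> chromosome, start, end, strand)
#'
#' Accepts the Xena/gencode probemap dialect (`#id gene chrom chromStart
#' chromEnd strand`) or the equivalent `id gene chromosome start end strand`
#' header. Returns one annotation per gene symbol with 1-based inclusive
#' coordinates. Symbols mapping to several loci on one chromosome are merged
#' to their union span; symbols mapping to more than one chromosome are
#' dropped with a warning (their along-chromosome ordering is ambiguous).
#'
#' @param path Path to the tab-separated probemap.
#' @return A data.frame with columns `gene_id`, `chromosome`, `start`,
#'   `end`, `strand`; dropped multi-chromosome symbols are recorded in the
#'   `"dropped"` attribute.
#' @export
read_probemap <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  names(df) <- sub("^#", "", names(df))
  alias <- c(chrom = "chromosome", chromStart = "start", chromEnd = "end",
             position = "start")
  hit <- names(df) %in% names(alias)
  names(df)[hit] <- alias[names(df)[hit]]
  empty <- data.frame(gene_id = character(), chromosome = character(),
                      start = integer(), end = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(df)) {
    warning("probemap ", path, " contains no rows")
    attr(empty, "dropped") <- character()
    return(empty)
  }
  need <- c("gene", "chromosome", "start", "end")
  if (!all(need %in% names(df)))
    stop("probemap must provide columns ", paste(need, collapse = ", "))
  if (!"strand" %in% names(df)) df$strand <- "unknown"
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  bad <- which(df$start > df$end)
  if (length(bad))
    stop(sprintf("probemap coordinate error: start > end for %s (row %d)",
                 df$gene[bad[1]], bad[1]))
  df$strand <- ifelse(df$strand %in% c("+", "-"), df$strand, "unknown")

  chroms_per_gene <- tapply(df$chromosome, df$gene,
                            function(x) length(unique(x)))
  multi <- names(chroms_per_gene)[chroms_per_gene > 1]
  if (length(multi)) {
    warning(length(multi), " gene symbol(s) map to multiple chromosomes and were dropped: ",
            paste(utils::head(multi, 5), collapse = ", "),
            if (length(multi) > 5) ", ..." else "")
    df <- df[!df$gene %in% multi, , drop = FALSE]
  }
  if (!nrow(df)) {
    attr(empty, "dropped") <- multi
    return(empty)
  }
  # merge duplicate rows of one symbol on a single chromosome to the union span
  o <- order(df$gene)
  df <- df[o, , drop = FALSE]
  first <- !duplicated(df$gene)
  ann <- data.frame(
    gene_id = df$gene[first],
    chromosome = df$chromosome[first],
    start = as.integer(tapply(df$start, df$gene, min)[df$gene[first]]),
    end = as.integer(tapply(df$end, df$gene, max)[df$gene[first]]),
    strand = as.character(tapply(df$strand, df$gene, function(s)
      if (length(unique(s)) == 1L) s[1] else "unknown")[df$gene[first]]),
    stringsAsFactors = FALSE)
  rownames(ann) <- NULL
  attr(ann, "dropped") <- multi
  ann
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then members, tab-separated.
#' Duplicate members within a line are deduplicated with a warning; lines
#' whose member list is empty after deduplication are rejected with a
#' warning. Lines with fewer than three fields are a format error.
#'
#' @param path Path to a GMT file.
#' @return Named list of gene sets, each a list with `name`, `description`
#'   and a character vector `members`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("GMT format error: line %d has %d field(s), expected >= 3",
                   i, length(fields)))
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning(sprintf("GMT line %d (%s): duplicate members deduplicated",
                      i, fields[1]))
      members <- unique(members)
    }
    if (!length(members)) {
      warning(sprintf("GMT line %d (%s) rejected: no members", i, fields[1]))
      next
    }
    sets[[fields[1]]] <- list(name = fields[1], description = fields[2],
                              members = members)
  }
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets List of gene sets as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$name, s$description, s$members), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain one-gene-per-line list (e.g. DepMap common essentials)
#'
#' Blank lines are skipped; an optional single header line can be dropped
#' with `skip`. Entries like `"GENE (1234)"` are trimmed to the symbol.
#'
#' @param path Path to the list.
#' @param skip Number of leading lines to skip.
#' @return Character vector of unique gene symbols.
#' @export
read_gene_list <- function(path, skip = 0L) {
  x <- readLines(path)
  if (skip > 0) x <- x[-seq_len(skip)]
  x <- trimws(x)
  x <- x[nzchar(x)]
  unique(sub("\\s*\\(.*\\)$", "", x))
}

#' Export loss regions as BED6
#'
#' Internal coordinates are 1-based inclusive; BED output is 0-based
#' half-open. Name is `cancer:rule`, score is `round(-100 * mean_cna)`.
#'
#' @param regions Region data.frame (see [call_loss_regions()]): columns
#'   `chromosome`, `start`, `end`, `cancer_code`, `rule`, `mean_cna`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  con <- file(path, "wt")
  on.exit(close(con), add = TRUE)
  writeLines("track name=loss_regions description=\"recurrent copy-number loss regions\"", con)
  if (nrow(regions)) {
    lines <- sprintf("%s\t%d\t%d\t%s:%s\t%d\t.",
                     regions$chromosome,
                     as.integer(regions$start) - 1L,
                     as.integer(regions$end),
                     regions$cancer_code, regions$rule,
                     as.integer(round(-100 * regions$mean_cna)))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a BED6 loss-region export back
#'
#' Inverse of [write_regions_bed()] (round-trip up to the gene list, which
#' BED does not carry). Coordinates are converted back to 1-based inclusive.
#'
#' @param path Path to a BED file written by [write_regions_bed()].
#' @return Data.frame with `chromosome`, `start`, `end`, `cancer_code`,
#'   `rule`, `mean_cna`.
#' @export
read_regions_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (!length(lines))
    return(data.frame(chromosome = character(), start = integer(),
                      end = integer(), cancer_code = character(),
                      rule = character(), mean_cna = numeric(),
                      stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  name <- strsplit(parts[, 4], ":", fixed = TRUE)
  data.frame(chromosome = parts[, 1],
             start = as.integer(parts[, 2]) + 1L,
             end = as.integer(parts[, 3]),
             cancer_code = vapply(name, `[`, character(1), 1),
             rule = vapply(name, `[`, character(1), 2),
             mean_cna = -as.numeric(parts[, 5]) / 100,
             stringsAsFactors = FALSE)
}
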