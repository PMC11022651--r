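# Plain-text readers/writers for the pipeline's interchange formats:
# BED3(+length) fragments, chrom-sizes, BED6 TSS tables, TSV matrices and
# pileups, CSV qPCR wells.

#' Write cfDNA fragments as BED3 plus a length column
#'
#' @param fragments fragment data frame (`chrom, start, end`, 0-based
#'   half-open; `length` recomputed as `end - start`).
#' @param path output path.
#' @export
write_fragments_bed <- function(fragments, path) {
  utils::write.table(
    data.frame(fragments$chrom, fragments$start, fragments$end,
               fragments$end - fragments$start),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3(+) fragment file
#'
#' @param path BED path (tab-separated, no header).
#' @return `fragment_set` data frame `chrom, start, end, length`.
#' @export
read_fragments_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  out <- data.frame(chrom = x[[1]], start = x[[2]], end = x[[3]],
                    length = x[[3]] - x[[2]], stringsAsFactors = FALSE)
  assert_that(all(out$start < out$end), "BED intervals must have start < end")
  class(out) <- c("fragment_set", "data.frame")
  out
}

#' Write / read a two-column chrom-sizes file
#' @param chromosomes named numeric vector of chromosome lengths.
#' @param path file path.
#' @export
write_chrom_sizes <- function(chromosomes, path) {
  utils::write.table(data.frame(names(chromosomes), unname(chromosomes)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_chrom_sizes
#' @export
read_chrom_sizes <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  stats::setNames(x[[2]], x[[1]])
}

#' Write / read a TSS table as BED6
#'
#' The TSS is encoded as a 1-bp interval `[tss, tss + 1)`; the name column is
#' the gene id and the strand column carries orientation.
#'
#' @param tss_table data frame `gene, chrom, tss, strand`.
#' @param path file path.
#' @export
write_tss_bed6 <- function(tss_table, path) {
  utils::write.table(
    data.frame(tss_table$chrom, tss_table$tss, tss_table$tss + 1,
               tss_table$gene, 0L, tss_table$strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_tss_bed6
#' @export
read_tss_bed6 <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  data.frame(gene = x[[4]], chrom = x[[1]], tss = x[[2]], strand = x[[6]],
             stringsAsFactors = FALSE)
}

#' Write / read a tissue-by-gene expression matrix as TSV
#' @param expression tissue x gene matrix.
#' @param path file path.
#' @export
write_expression_tsv <- function(expression, path) {
  utils::write.table(cbind(tissue = rownames(expression), as.data.frame(expression)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  m
}

#' Write / read pileup tables as TSV
#' @param pileups pileup data frame.
#' @param path file path.
#' @export
write_pileups_tsv <- function(pileups, path) {
  utils::write.table(pileups, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pileups_tsv
#' @export
read_pileups_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write / read qPCR well tables as CSV
#' @param wells well data frame.
#' @param path file path.
#' @export
write_qpcr_csv <- function(wells, path) {
  utils::write.csv(wells, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_qpcr_csv
#' @export
read_qpcr_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("known_mass_ng" %in% names(x)) {
    x$known_mass_ng <- suppressWarnings(as.numeric(x$known_mass_ng))
  }
  x
}

#' Write / read per-chromosome count tables as TSV
#' @param chrom_counts `chrom_counts` data frame.
#' @param path file path.
#' @export
write_chrom_counts_tsv <- function(chrom_counts, path) {
  utils::write.table(chrom_counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_chrom_counts_tsv
#' @export
read_chrom_counts <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  attr(out, "total_reads") <- sum(out$count)
  class(out) <- c("chrom_counts", "data.frame")
  out
}

#' Generic TSV writer used for derived result tables
#' @param x data frame.
#' @param path file path.
#' @export
write_result_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
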