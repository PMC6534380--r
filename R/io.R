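# Plain-text readers/writers for the pipeline's interchange formats:
# TSV tables, BED intervals, dosage matrices and a minimal VCF subset.
# All coordinates on disk follow the format's own convention (BED and the
# in-memory representation are 0-based half-open; VCF POS is 1-based).

#' Write a data frame or matrix as TSV
#'
#' @param x data frame or matrix (matrices are written with a leading id
#'   column named by \code{id_col}).
#' @param path output path.
#' @param id_col name for the rownames column when \code{x} is a matrix.
#' @param comment optional comment line(s) written first, prefixed
#'   with \code{"# "}.
#' @export
write_tsv <- function(x, path, id_col = "id", comment = NULL) {
  if (is.matrix(x))
    x <- data.frame(stats::setNames(list(rownames(x)), id_col), x,
                    check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' Comment lines (\code{#}) are skipped.
#' @param path file path.
#' @param id_col if non-NULL, that column becomes rownames and the result
#'   is returned as a numeric matrix.
#' @export
read_tsv <- function(path, id_col = NULL) {
  x <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (!is.null(id_col)) {
    rn <- x[[id_col]]
    x <- as.matrix(x[, setdiff(names(x), id_col), drop = FALSE])
    rownames(x) <- rn
  }
  x
}

#' Write intervals as BED
#'
#' @param x data frame with \code{start}, \code{end} (0-based half-open)
#'   and optionally \code{id} and \code{strand} (written as BED6).
#' @param path output path.
#' @param chrom chromosome name used for every row.
#' @export
write_bed <- function(x, path, chrom = "chr1") {
  bed <- data.frame(chrom = chrom, start = x$start, end = x$end)
  if (!is.null(x$id)) {
    bed$name <- x$id
    bed$score <- 0
    bed$strand <- if (!is.null(x$strand)) x$strand else "."
  }
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of intervals or gene models
#'
#' BED3 gives \code{start}/\code{end}; BED6 additionally \code{id} and
#' \code{strand}.
#' @param path file path.
#' @export
read_bed <- function(path) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(chrom = x[[1]], start = x[[2]], end = x[[3]],
                    stringsAsFactors = FALSE)
  if (ncol(x) >= 6) { out$id <- x[[4]]; out$strand <- x[[6]] }
  out
}

#' Read gene models from a minimal GFF3 subset
#'
#' Keeps rows of the requested feature type, converts 1-based closed GFF
#' coordinates to 0-based half-open, and parses the \code{ID=} attribute.
#' @param path file path.
#' @param feature feature type to keep (default \code{"gene"}).
#' @export
read_genes_gff3 <- function(path, feature = "gene") {
  x <- utils::read.delim(path, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
  x <- x[x[[3]] == feature, ]
  ids <- sub("^.*ID=([^;]+).*$", "\\1", x[[9]])
  data.frame(id = ids, chrom = x[[1]], strand = x[[7]],
             start = x[[4]] - 1L, end = x[[5]],
             stringsAsFactors = FALSE)
}

#' Write / read a genotype dosage matrix (samples x SNPs) as TSV
#' @param dosages samples x SNPs matrix of 0/1/2.
#' @param path file path.
#' @export
write_dosage_tsv <- function(dosages, path)
  write_tsv(dosages, path, id_col = "sample")

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) read_tsv(path, id_col = "sample")

#' Write SNPs and dosages as a minimal VCF
#'
#' Emits CHROM, POS (1-based), ID and per-sample unphased GT fields
#' encoding the dosage (0 -> 0/0, 1 -> 0/1, 2 -> 1/1).
#' @param snps data frame \code{id}, \code{pos} (0-based).
#' @param dosages samples x SNPs matrix.
#' @param path file path.
#' @param chrom chromosome name.
#' @export
write_vcf_minimal <- function(snps, dosages, path, chrom = "chr1") {
  gt <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(dosages)),
                     collapse = "\t")), con)
  for (j in seq_len(nrow(snps))) {
    writeLines(paste(c(chrom, snps$pos[j] + 1L, snps$id[j], "A", "G",
                       ".", "PASS", ".", "GT",
                       gt[dosages[, j] + 1L]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a minimal VCF into SNP positions and a dosage matrix
#'
#' Parses GT (phased or unphased) to alternate-allele dosage.
#' @param path file path.
#' @export
read_vcf_minimal <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  header <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  body <- strsplit(lines[-1], "\t")
  samples <- header[-(1:9)]
  snps <- data.frame(
    id = vapply(body, `[`, "", 3),
    pos = as.integer(vapply(body, `[`, "", 2)) - 1L,
    stringsAsFactors = FALSE)
  dosages <- vapply(body, function(f) {
    gt <- sub(":.*$", "", f[-(1:9)])
    vapply(strsplit(gt, "[/|]"),
           function(a) sum(as.integer(a)), integer(1))
  }, integer(length(samples)))
  if (length(samples) == 1L) dosages <- matrix(dosages, nrow = 1L)
  dimnames(dosages) <- list(samples, snps$id)
  list(snps = snps, dosages = dosages)
}

#' Write every file of a toy genome panel
#'
#' Genes and hotspots as BED, dosages as TSV, SNPs as a minimal VCF,
#' sentinels as a one-column text file.
#' @param panel a [simulate_genome_toy()] panel.
#' @param dir output directory (created if missing).
#' @export
write_genome_toy <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bed(panel$genes, file.path(dir, "genes.bed"))
  write_bed(panel$hotspots, file.path(dir, "hotspots.bed"))
  write_dosage_tsv(panel$dosages, file.path(dir, "dosages.tsv"))
  write_vcf_minimal(panel$snps, panel$dosages, file.path(dir, "snps.vcf"))
  writeLines(panel$sentinels, file.path(dir, "sentinels.txt"))
  invisible(dir)
}
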