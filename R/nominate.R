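#' Squared-correlation linkage disequilibrium between two SNPs
#'
#' Composite LD from unphased genotypes: the squared Pearson correlation of
#' the two allele-dosage vectors. A monomorphic SNP has no defined
#' correlation; the result is then \code{NA} (never silently 0).
#'
#' @param dosages_a,dosages_b numeric vectors of dosages in \{0, 1, 2\},
#'   equal length >= 3.
#' @return r2 in [0, 1], or NA if either SNP is monomorphic.
#' @examples
#' compute_r2(c(0, 0, 1, 1), c(0, 1, 0, 1))  # 0
#' compute_r2(c(0, 1, 2, 1), c(0, 1, 2, 1))  # 1
#' @export
compute_r2 <- function(dosages_a, dosages_b) {
  if (length(dosages_a) != length(dosages_b))
    stop("dosage vectors must have equal length")
  if (length(dosages_a) < 3)
    stop("need at least 3 samples to estimate r2")
  if (length(unique(dosages_a)) < 2 || length(unique(dosages_b)) < 2)
    return(NA_real_)
  stats::cor(dosages_a, dosages_b)^2
}

#' LD block around a sentinel SNP
#'
#' Expands a sentinel SNP to the interval spanning every SNP on the panel
#' whose dosage r2 with the sentinel is at least \code{r2_threshold}. The
#' sentinel itself always belongs to the block. Returned coordinates are
#' 0-based half-open, with end = max SNP position + 1, so a sentinel with
#' no partners gives the single-base interval [pos, pos + 1).
#'
#' @param sentinel SNP id present in \code{panel$snps$id}.
#' @param panel a [simulate_genome_toy()] panel, or any list with
#'   \code{snps} (id, pos) and \code{dosages} (samples x SNPs).
#' @param r2_threshold LD threshold, default 0.8.
#' @return named numeric \code{c(start, end)}.
#' @export
ld_block <- function(sentinel, panel, r2_threshold = 0.8) {
  i <- match(sentinel, panel$snps$id)
  if (is.na(i)) stop("sentinel '", sentinel, "' not on the panel")
  s <- panel$dosages[, i]
  if (length(unique(s)) < 2)
    stop("sentinel '", sentinel, "' is monomorphic; r2 undefined")
  r2 <- vapply(seq_len(ncol(panel$dosages)),
               function(j) compute_r2(s, panel$dosages[, j]), numeric(1))
  keep <- which(!is.na(r2) & r2 >= r2_threshold)
  keep <- union(keep, i)
  pos <- panel$snps$pos[keep]
  c(start = min(pos), end = max(pos) + 1)
}

#' Extend an LD block to the nearest flanking recombination hotspots
#'
#' The extended window runs from the inner edge (end) of the nearest
#' hotspot at or left of the block to the inner edge (start) of the nearest
#' hotspot at or right of it; the hotspot intervals themselves are not
#' included. With no hotspot on a side the window extends to the
#' chromosome boundary (0 or \code{chrom_length}).
#'
#' @param block numeric \code{c(start, end)}, 0-based half-open.
#' @param hotspots data frame with \code{start}, \code{end}, sorted and
#'   non-overlapping.
#' @param chrom_length chromosome length in bp.
#' @return named numeric \code{c(start, end)} containing \code{block}.
#' @export
extend_to_hotspots <- function(block, hotspots, chrom_length) {
  ld_start <- block[[1]]; ld_end <- block[[2]]
  if (ld_start < 0 || ld_end > chrom_length || ld_start >= ld_end)
    stop("block must lie within [0, chrom_length)")
  left <- hotspots$end[hotspots$end <= ld_start]
  right <- hotspots$start[hotspots$start >= ld_end]
  c(start = if (length(left)) max(left) else 0,
    end = if (length(right)) min(right) else chrom_length)
}

# strand-aware regulatory wingspan of a gene, clipped at 0
.wingspan <- function(start, end, strand, up_bp, down_bp, strand_aware) {
  if (!strand_aware || strand == "+")
    c(max(0, start - up_bp), end + down_bp)
  else
    c(max(0, start - down_bp), end + up_bp)
}

#' Nominate candidate genes for a locus window
#'
#' A gene is nominated when its regulatory wingspan -- 110 kb upstream of
#' the transcription start and 40 kb downstream of the transcription end,
#' assigned strand-awareness by default -- overlaps the hotspot-extended
#' locus window. All intervals are 0-based half-open; overlap means a
#' nonempty intersection.
#'
#' @param window numeric \code{c(start, end)}: the extended locus window.
#' @param genes data frame with \code{id}, \code{strand}, \code{start},
#'   \code{end} (txStart < txEnd on the forward strand).
#' @param up_kb,down_kb wingspan reach in kb (defaults 110 and 40).
#' @param strand_aware if FALSE, upstream is always to the left regardless
#'   of strand (the strand-agnostic alternative reading).
#' @return character vector of nominated gene ids (possibly empty).
#' @export
nominate_genes <- function(window, genes, up_kb = 110, down_kb = 40,
                           strand_aware = TRUE) {
  if (nrow(genes) == 0) return(character(0))
  up <- up_kb * 1000; down <- down_kb * 1000
  hit <- vapply(seq_len(nrow(genes)), function(i) {
    w <- .wingspan(genes$start[i], genes$end[i], genes$strand[i],
                   up, down, strand_aware)
    w[1] < window[[2]] && window[[1]] < w[2]
  }, logical(1))
  genes$id[hit]
}

#' Run the full locus-to-gene nomination over a panel
#'
#' For every sentinel SNP: LD block at \code{r2_threshold}, extension to
#' the nearest recombination hotspots, and wingspan-overlap gene
#' nomination. Manual window overrides (e.g. gene deserts expanded by
#' hand) can be supplied per locus and replace the computed extended
#' window.
#'
#' @param panel a [simulate_genome_toy()] panel.
#' @param r2_threshold,up_kb,down_kb,strand_aware passed to the stage
#'   functions.
#' @param overrides optional data frame \code{sentinel}, \code{start},
#'   \code{end} replacing the computed window for listed sentinels.
#' @return a list of class \code{"candidate_gene_set"}: \code{windows}
#'   (one row per locus: sentinel, ld_start, ld_end, ext_start, ext_end,
#'   n_genes), \code{genes} (locus/sentinel to gene id, long), and
#'   \code{summary} (total genes, median genes per locus).
#' @export
nominate_all <- function(panel, r2_threshold = 0.8, up_kb = 110,
                         down_kb = 40, strand_aware = TRUE,
                         overrides = NULL) {
  rows <- list(); gene_rows <- list()
  for (k in seq_along(panel$sentinels)) {
    sn <- panel$sentinels[k]
    blk <- ld_block(sn, panel, r2_threshold)
    ext <- extend_to_hotspots(blk, panel$hotspots, panel$chrom_length)
    if (!is.null(overrides) && sn %in% overrides$sentinel) {
      o <- overrides[overrides$sentinel == sn, ]
      ext <- c(start = o$start[1], end = o$end[1])
    }
    nom <- nominate_genes(ext, panel$genes, up_kb, down_kb, strand_aware)
    rows[[k]] <- data.frame(locus = sprintf("L%03d", k), sentinel = sn,
                            ld_start = blk[[1]], ld_end = blk[[2]],
                            ext_start = ext[[1]], ext_end = ext[[2]],
                            n_genes = length(nom), stringsAsFactors = FALSE)
    if (length(nom))
      gene_rows[[k]] <- data.frame(locus = sprintf("L%03d", k),
                                   sentinel = sn, gene = nom,
                                   stringsAsFactors = FALSE)
  }
  windows <- do.call(rbind, rows)
  genes <- if (length(gene_rows)) do.call(rbind, gene_rows) else
    data.frame(locus = character(0), sentinel = character(0),
               gene = character(0))
  structure(list(windows = windows, genes = genes,
                 summary = list(n_genes = length(unique(genes$gene)),
                                median_genes_per_locus =
                                  stats::median(windows$n_genes))),
            class = "candidate_gene_set")
}

#' @export
print.candidate_gene_set <- function(x, ...) {
  cat("Candidate gene set:", nrow(x$windows), "loci,",
      x$summary$n_genes, "distinct genes",
      sprintf("(median %.1f genes/locus)\n",
              x$summary$median_genes_per_locus))
  invisible(x)
}

#' Compare screen hits with eQTL-based nomination
#'
#' Each LD window is resized symmetrically about its midpoint to a fixed
#' width (default 100 kb, clipped at 0); genes whose bodies overlap a
#' padded window and that carry an eQTL are the eQTL-nominated set. The
#' 2x2 contingency table of hit status against eQTL nomination over the
#' gene universe is tested with a two-sided Fisher exact test.
#'
#' @param windows data frame with \code{ld_start}, \code{ld_end} (one row
#'   per locus), e.g. the \code{windows} of [nominate_all()].
#' @param genes data frame \code{id}, \code{start}, \code{end}.
#' @param hits character vector of hit gene ids.
#' @param eqtl_genes character vector of genes with an eQTL (the universe
#'   of the comparison).
#' @param pad_to_kb fixed window width after padding, in kb.
#' @return list with \code{table} (2x2), \code{p} (Fisher two-sided),
#'   \code{nominated} (gene ids) and \code{padded} (windows).
#' @export
eqtl_window_comparison <- function(windows, genes, hits, eqtl_genes,
                                   pad_to_kb = 100) {
  if (length(eqtl_genes) == 0) stop("empty eQTL gene universe")
  half <- pad_to_kb * 1000 / 2
  mid <- (windows$ld_start + windows$ld_end) / 2
  padded <- data.frame(start = pmax(0, floor(mid - half)),
                       end = floor(mid + half))
  in_window <- vapply(seq_len(nrow(genes)), function(i) {
    any(genes$start[i] < padded$end & padded$start < genes$end[i])
  }, logical(1))
  nominated <- intersect(genes$id[in_window], eqtl_genes)
  universe <- unique(eqtl_genes)
  tab <- table(hit = factor(universe %in% hits, levels = c(TRUE, FALSE)),
               nominated = factor(universe %in% nominated,
                                  levels = c(TRUE, FALSE)))
  list(table = tab, p = stats::fisher.test(tab)$p.value,
       nominated = nominated, padded = padded)
}
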