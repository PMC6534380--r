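# Shared permutation machinery: empirical p with add-one correction,
# ties counted as extreme (conservative).
.perm_p <- function(observed, null, tail) {
  n_extreme <- switch(tail,
    greater = sum(null >= observed),
    less = sum(null <= observed),
    two.sided = sum(abs(null - mean(null)) >= abs(observed - mean(null))))
  list(n_extreme = n_extreme,
       p = (n_extreme + 1) / (length(null) + 1))
}

.perm_result <- function(statistic, observed, null, tail, seed,
                         extra = NULL) {
  pp <- .perm_p(observed, null, tail)
  structure(c(list(statistic = statistic, observed = observed,
                   n_permutations = length(null),
                   n_extreme = pp$n_extreme, p = pp$p, tail = tail,
                   null_mean = mean(null), null_sd = stats::sd(null),
                   seed = seed), extra),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test: %s\n", x$statistic))
  cat(sprintf("  observed = %.4g, null mean = %.4g (sd %.4g)\n",
              x$observed, x$null_mean, x$null_sd))
  cat(sprintf("  p = %.4g (%s tail, %d permutations, add-one estimator)\n",
              x$p, x$tail, x$n_permutations))
  if (!is.null(x$exact_p))
    cat(sprintf("  exact hypergeometric p = %.4g\n", x$exact_p))
  invisible(x)
}

# Drop genes without an annotation from both universe and hits (logged).
.restrict_universe <- function(hits, universe, annotated, what) {
  missing <- setdiff(universe, annotated)
  if (length(missing)) {
    message(length(missing), " gene(s) lack ", what,
            " annotation; dropped from universe and hits")
    universe <- setdiff(universe, missing)
    hits <- setdiff(hits, missing)
  }
  list(hits = hits, universe = universe)
}

#' Score-sum enrichment of a hit set by permutation
#'
#' Tests whether the sum of an annotation score (e.g. an erythroid-cell
#' essentiality score) over the hit genes is extreme relative to
#' identically sized gene sets drawn uniformly without replacement from a
#' universe (the screened library, the genome, or an alternative GWAS
#' panel — the universe argument is the only thing that changes between
#' those comparisons).
#'
#' @param hits character vector of hit gene ids, a subset of the universe.
#' @param scores named numeric vector of scores covering the universe.
#' @param universe character vector of gene ids defining the null.
#' @param n_perm number of permutations (default 1e6).
#' @param tail \code{"greater"} (default), \code{"less"} or
#'   \code{"two.sided"}.
#' @param seed integer seed recorded in the result; NULL leaves the RNG
#'   state untouched.
#' @param missing \code{"drop"} (default): genes lacking a score are
#'   removed from universe and hits; \code{"zero"}: scored as 0.
#' @return a \code{"permutation_result"}: observed statistic, null summary,
#'   number as-or-more extreme, add-one empirical p (never 0), tail, seed.
#' @export
score_sum_enrichment <- function(hits, scores, universe, n_perm = 1e6,
                                 tail = c("greater", "less", "two.sided"),
                                 seed = NULL, missing = c("drop", "zero")) {
  tail <- match.arg(tail); missing <- match.arg(missing)
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe")
  if (missing == "drop") {
    r <- .restrict_universe(hits, universe, names(scores), "score")
    hits <- r$hits; universe <- r$universe
  } else {
    add <- setdiff(universe, names(scores))
    scores <- c(scores, stats::setNames(rep(0, length(add)), add))
  }
  k <- length(hits); n <- length(universe)
  if (k > n) stop("more hits than universe genes")
  if (k == 0) stop("empty hit set after annotation restriction")
  if (!is.null(seed)) set.seed(seed)
  sv <- scores[universe]
  observed <- sum(sv[hits])
  null <- vapply(seq_len(n_perm),
                 function(b) sum(sv[sample.int(n, k)]), numeric(1))
  .perm_result("score sum", observed, null, tail, seed)
}

#' Rank-sum enrichment of a target gene set
#'
#' Ranks all genes of the universe by a score in which smaller is stronger
#' (e.g. the minimum FDR q value from the screen model; average ranks for
#' ties) and compares the rank sum of the target genes — for instance five
#' gold-standard genes with established causal variants — with rank sums
#' of uniformly drawn equally sized gene sets. Low rank sums are
#' extreme, so the tail is \code{"less"}.
#'
#' @param target_genes gene ids whose enrichment is tested.
#' @param gene_ranking named numeric vector over the universe; smaller
#'   values rank first.
#' @param universe gene ids defining the null.
#' @param n_perm number of permutations (default 1e6).
#' @param seed integer seed (see [score_sum_enrichment()]).
#' @return a \code{"permutation_result"}.
#' @export
rank_sum_enrichment <- function(target_genes, gene_ranking, universe,
                                n_perm = 1e6, seed = NULL) {
  if (anyDuplicated(target_genes) || anyDuplicated(universe))
    stop("duplicate gene ids")
  if (!all(target_genes %in% universe))
    stop("target genes must be a subset of the universe")
  r <- .restrict_universe(target_genes, universe, names(gene_ranking),
                          "ranking")
  target_genes <- r$hits; universe <- r$universe
  ranks <- rank(gene_ranking[universe], ties.method = "average")
  names(ranks) <- universe
  k <- length(target_genes); n <- length(universe)
  if (k == 0) stop("empty target set after annotation restriction")
  if (!is.null(seed)) set.seed(seed)
  observed <- sum(ranks[target_genes])
  null <- vapply(seq_len(n_perm),
                 function(b) sum(ranks[sample.int(n, k)]), numeric(1))
  .perm_result("rank sum", observed, null, "less", seed)
}

#' Overlap enrichment of hits with a flagged gene set
#'
#' Tests whether the hit set contains more flagged genes (e.g. genes
#' carrying a fine-mapped coding variant) than equally sized random gene
#' sets. Alongside the permutation p, the exact upper hypergeometric tail
#' \eqn{P(X \ge \mathrm{obs})} with
#' \eqn{X \sim \mathrm{Hypergeom}(|U|, |F|, |H|)} is reported.
#'
#' @param hits,flagged gene id vectors, subsets of the universe.
#' @param universe gene ids defining the null.
#' @param n_perm number of permutations (default 1e5).
#' @param seed integer seed.
#' @return a \code{"permutation_result"} with an extra \code{exact_p}.
#' @export
overlap_enrichment <- function(hits, flagged, universe, n_perm = 1e5,
                               seed = NULL) {
  stopifnot(all(hits %in% universe), all(flagged %in% universe))
  k <- length(hits); n <- length(universe); f <- length(unique(flagged))
  observed <- length(intersect(hits, flagged))
  exact_p <- stats::phyper(observed - 1, f, n - f, k, lower.tail = FALSE)
  if (!is.null(seed)) set.seed(seed)
  is_flagged <- universe %in% flagged
  null <- vapply(seq_len(n_perm),
                 function(b) sum(is_flagged[sample.int(n, k)]), numeric(1))
  .perm_result("flagged-gene overlap", observed, null, "greater", seed,
               extra = list(exact_p = exact_p))
}

#' Stage-specific expression enrichment of a hit set
#'
#' Expression values are z-scored within each gene across stages (sample
#' SD; a gene constant across stages contributes 0 everywhere), so each
#' gene describes only its relative stage preference. Per stage, the sum
#' of z scores over the hit genes is compared with sums over equally sized
#' random draws from the library universe; one upper-tail p per stage.
#'
#' @param hits hit gene ids.
#' @param expression numeric matrix, genes x stages (>= 2 stages), row
#'   names = gene ids.
#' @param universe gene ids defining the null (rows must cover it).
#' @param n_perm number of permutations (default 1e4).
#' @param seed integer seed.
#' @return named list of \code{"permutation_result"}, one per stage.
#' @export
stage_expression_enrichment <- function(hits, expression, universe,
                                        n_perm = 1e4, seed = NULL) {
  if (ncol(expression) < 2) stop("need >= 2 stages")
  r <- .restrict_universe(hits, universe, rownames(expression),
                          "expression")
  hits <- r$hits; universe <- r$universe
  if (length(hits) == 0) stop("empty hit set after annotation restriction")
  x <- expression[universe, , drop = FALSE]
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  z <- (x - mu) / ifelse(sdv == 0, Inf, sdv)   # sd 0 -> z 0
  k <- length(hits); n <- length(universe)
  if (!is.null(seed)) set.seed(seed)
  observed <- colSums(z[hits, , drop = FALSE])
  null <- matrix(NA_real_, n_perm, ncol(z))
  for (b in seq_len(n_perm))
    null[b, ] <- colSums(z[sample.int(n, k), , drop = FALSE])
  out <- lapply(seq_len(ncol(z)), function(s)
    .perm_result(paste0("stage z-score sum [", colnames(z)[s], "]"),
                 observed[s], null[, s], "greater", seed))
  names(out) <- colnames(z)
  out
}
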