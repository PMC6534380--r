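#' Simulation configuration for a pooled shRNA dropout screen
#'
#' Builds and validates the parameter set used by [simulate_screen()]. The
#' defaults describe a desk-scale screen in differentiating erythroid cells:
#' three donor replicates sampled at days 4, 6, 9, 12, 14 and 16, five to
#' seven hairpins per gene, ten percent of genes carrying a true dropout or
#' enrichment effect of 0.15--0.3 log2 units per day.
#'
#' The generative model for hairpin \eqn{h} targeting gene \eqn{g} is
#' \deqn{\log_2 a_{h}(t) = \log_2 a_{h0} + (\gamma_g + \delta_h)(t - t_0) + \epsilon}
#' where \eqn{\gamma_g} is the gene's true per-day slope, \eqn{\delta_h} a
#' hairpin-specific slope deviation (efficiency / off-target drift, constant
#' in time), and \eqn{\epsilon} residual log2 noise. Counts are drawn
#' negative-binomially around \code{depth_per_sample} times the hairpin's
#' relative abundance, via a gamma--Poisson mixture with overdispersion
#' \code{dispersion} (0 degrades to Poisson).
#'
#' @param n_loci number of GWAS loci the gene panel is attributed to.
#' @param n_genes number of screened genes.
#' @param hairpins_per_gene integer range (length-2) of hairpins per gene.
#' @param n_replicates number of donor replicates.
#' @param time_grid strictly increasing measurement days; the first entry is
#'   the baseline day.
#' @param depth_per_sample expected total reads per sample.
#' @param dispersion negative-binomial overdispersion phi >= 0 (variance
#'   = mu + phi * mu^2).
#' @param sigma_hairpin SD of the per-hairpin slope deviation, log2/day.
#' @param sigma_resid residual SD of log2 abundance per observation.
#' @param effect_fraction fraction of genes with a nonzero true slope.
#' @param effect_range length-2 range of |gamma| (log2/day) for effect genes.
#' @param enriched_fraction fraction of effect genes whose slope is
#'   positive (enriched rather than depleted). The default 0 emulates a
#'   pure dropout screen; unbounded exponential growth of enriched
#'   hairpins would otherwise dilute every other hairpin's relative
#'   abundance (counts are compositional).
#' @param baseline_sdlog SD (natural-log scale) of the log-normal baseline
#'   abundances; 0 gives a perfectly uniform library.
#' @param control_genes named integer vector with entries \code{erythroid},
#'   \code{essential} and \code{negcon}: additional control genes appended to
#'   the library (strong depletion, strong depletion, and zero effect
#'   respectively). Defaults to none.
#' @param seed integer seed; every random draw in [simulate_screen()] flows
#'   from it.
#' @return a validated list of class \code{"sim_config"}.
#' @seealso [simulate_screen()], [simulate_genome_toy()],
#'   [simulate_annotations()]
#' @export
sim_config <- function(n_loci = 50, n_genes = 200, hairpins_per_gene = c(5, 7),
                       n_replicates = 3, time_grid = c(4, 6, 9, 12, 14, 16),
                       depth_per_sample = 1e7, dispersion = 0.05,
                       sigma_hairpin = 0.05, sigma_resid = 0.1,
                       effect_fraction = 0.1, effect_range = c(0.15, 0.3),
                       enriched_fraction = 0, baseline_sdlog = 0.8,
                       control_genes = c(erythroid = 0, essential = 0, negcon = 0),
                       seed = 1L) {
  if (length(hairpins_per_gene) == 1L)
    hairpins_per_gene <- rep(hairpins_per_gene, 2L)
  stopifnot(n_loci >= 1, n_genes >= 1, n_replicates >= 1,
            hairpins_per_gene[1] >= 1,
            hairpins_per_gene[2] >= hairpins_per_gene[1])
  if (length(time_grid) < 2 || any(diff(time_grid) <= 0))
    stop("time_grid must be strictly increasing with >= 2 days (first = baseline)")
  if (depth_per_sample <= 0) stop("depth_per_sample must be positive")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (sigma_hairpin < 0 || sigma_resid < 0 || baseline_sdlog < 0)
    stop("all SDs must be >= 0")
  if (effect_fraction < 0 || effect_fraction > 1)
    stop("effect_fraction must lie in [0, 1]")
  if (enriched_fraction < 0 || enriched_fraction > 1)
    stop("enriched_fraction must lie in [0, 1]")
  stopifnot(length(effect_range) == 2, effect_range[1] >= 0,
            effect_range[2] >= effect_range[1])
  ctrl <- c(erythroid = 0, essential = 0, negcon = 0)
  ctrl[names(control_genes)] <- control_genes
  cfg <- list(n_loci = as.integer(n_loci), n_genes = as.integer(n_genes),
              hairpins_per_gene = as.integer(hairpins_per_gene),
              n_replicates = as.integer(n_replicates),
              time_grid = as.numeric(time_grid),
              depth_per_sample = depth_per_sample,
              dispersion = dispersion, sigma_hairpin = sigma_hairpin,
              sigma_resid = sigma_resid, effect_fraction = effect_fraction,
              effect_range = as.numeric(effect_range),
              enriched_fraction = enriched_fraction,
              baseline_sdlog = baseline_sdlog,
              control_genes = as.integer(ctrl), seed = as.integer(seed))
  names(cfg$control_genes) <- names(ctrl)
  class(cfg) <- "sim_config"
  cfg
}

# fixed true slopes for the control categories (log2/day)
.control_slopes <- c(erythroid = -0.25, essential = -0.35, negcon = 0)

#' Simulate a pooled shRNA screen with known ground truth
#'
#' Draws a hairpin-by-sample count matrix under the model described in
#' [sim_config()], together with the hairpin library annotation and the
#' ground truth (true gene slopes, hairpin deviations, realised depths)
#' needed for recovery testing.
#'
#' @param cfg a [sim_config()] object.
#' @return a list with components
#'   \describe{
#'     \item{counts}{integer matrix, hairpins x samples; columns named
#'       \code{"<replicate>_d<day>"}.}
#'     \item{samples}{data frame with \code{sample}, \code{replicate},
#'       \code{day} for each column of \code{counts}.}
#'     \item{library}{data frame \code{hairpin}, \code{gene},
#'       \code{category}, \code{locus}.}
#'     \item{truth}{list with \code{genes} (gene, locus, category, gamma),
#'       \code{hairpins} (hairpin, gene, delta, baseline), \code{depth}
#'       (realised column sums) and the \code{seed} used.}
#'   }
#' @examples
#' sim <- simulate_screen(sim_config(n_genes = 20, depth_per_sample = 1e5,
#'                                   seed = 7))
#' dim(sim$counts)
#' head(sim$truth$genes)
#' @export
simulate_screen <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  t0 <- cfg$time_grid[1]

  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  locus <- sprintf("L%03d", rep_len(seq_len(cfg$n_loci), cfg$n_genes))
  category <- rep("gwas", cfg$n_genes)
  n_eff <- round(cfg$effect_fraction * cfg$n_genes)
  gamma <- numeric(cfg$n_genes)
  if (n_eff > 0) {
    eff <- sample.int(cfg$n_genes, n_eff)
    sign <- ifelse(stats::runif(n_eff) < cfg$enriched_fraction, 1, -1)
    gamma[eff] <- sign *
      stats::runif(n_eff, cfg$effect_range[1], cfg$effect_range[2])
  }
  for (cat in names(.control_slopes)) {
    k <- cfg$control_genes[[cat]]
    if (k > 0) {
      ids <- sprintf("%s%02d", toupper(substr(cat, 1, 3)), seq_len(k))
      gene_ids <- c(gene_ids, ids)
      locus <- c(locus, rep("control", k))
      category <- c(category, rep(cat, k))
      gamma <- c(gamma, rep(.control_slopes[[cat]], k))
    }
  }
  n_genes <- length(gene_ids)

  hpg <- if (cfg$hairpins_per_gene[1] == cfg$hairpins_per_gene[2])
    rep(cfg$hairpins_per_gene[1], n_genes)
  else
    sample(seq(cfg$hairpins_per_gene[1], cfg$hairpins_per_gene[2]),
           n_genes, replace = TRUE)
  gene_of_hp <- rep(gene_ids, hpg)
  H <- length(gene_of_hp)
  hp_ids <- sprintf("%s_sh%d", gene_of_hp,
                    unlist(lapply(hpg, seq_len), use.names = FALSE))
  delta <- stats::rnorm(H, 0, cfg$sigma_hairpin)
  log2_a0 <- stats::rnorm(H, 0, cfg$baseline_sdlog / log(2))
  gamma_of_hp <- gamma[match(gene_of_hp, gene_ids)]

  samples <- expand.grid(day = cfg$time_grid,
                         replicate = sprintf("r%d", seq_len(cfg$n_replicates)),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- samples[, c("replicate", "day")]
  samples$sample <- sprintf("%s_d%g", samples$replicate, samples$day)

  counts <- matrix(0L, nrow = H, ncol = nrow(samples),
                   dimnames = list(hp_ids, samples$sample))
  for (j in seq_len(nrow(samples))) {
    mu_log2 <- log2_a0 + (gamma_of_hp + delta) * (samples$day[j] - t0) +
      stats::rnorm(H, 0, cfg$sigma_resid)
    # stabilise the softmax; only relative abundances matter
    w <- 2^(mu_log2 - max(mu_log2))
    lambda <- cfg$depth_per_sample * w / sum(w)
    if (cfg$dispersion > 0)
      lambda <- lambda * stats::rgamma(H, shape = 1 / cfg$dispersion,
                                       rate = 1 / cfg$dispersion)
    counts[, j] <- stats::rpois(H, lambda)
  }

  list(counts = counts,
       samples = samples[, c("sample", "replicate", "day")],
       library = data.frame(hairpin = hp_ids, gene = gene_of_hp,
                            category = category[match(gene_of_hp, gene_ids)],
                            locus = locus[match(gene_of_hp, gene_ids)],
                            stringsAsFactors = FALSE),
       truth = list(genes = data.frame(gene = gene_ids, locus = locus,
                                       category = category, gamma = gamma,
                                       stringsAsFactors = FALSE),
                    hairpins = data.frame(hairpin = hp_ids, gene = gene_of_hp,
                                          delta = delta,
                                          baseline = 2^log2_a0,
                                          stringsAsFactors = FALSE),
                    depth = colSums(counts), seed = cfg$seed))
}

#' Simulate a toy genome panel with LD blocks, hotspots and genes
#'
#' Builds a single-chromosome panel in which linkage-disequilibrium blocks
#' exist by construction: the SNPs of a block are noisy copies of a shared
#' latent diploid haplotype (per-allele flip probability \code{flip_prob}),
#' and blocks are mutually independent. Recombination hotspots are placed in
#' the gaps between blocks, and genes are scattered around each block so
#' that wingspan nomination has both positive and negative cases.
#' Coordinates are 0-based half-open throughout.
#'
#' @param n_loci number of LD blocks (one sentinel SNP each).
#' @param genes_per_locus genes placed in the neighbourhood of each block.
#' @param n_samples diploid samples in the dosage panel.
#' @param snps_per_block SNPs per block.
#' @param flip_prob per-allele probability that a block SNP differs from the
#'   latent haplotype; 0 gives r2 = 1 within blocks.
#' @param block_span bp spanned by each block's SNPs.
#' @param locus_spacing bp between consecutive block starts.
#' @param seed integer seed.
#' @return a list of class \code{"genome_toy"}: \code{chrom_length},
#'   \code{genes} (id, strand, start, end), \code{hotspots} (start, end),
#'   \code{snps} (id, pos), \code{dosages} (samples x SNPs, values 0/1/2),
#'   \code{sentinels} (one SNP id per block), \code{block_of} (block index
#'   per SNP) and the \code{seed}.
#' @export
simulate_genome_toy <- function(n_loci = 10, genes_per_locus = 4,
                                n_samples = 80, snps_per_block = 8,
                                flip_prob = 0.05, block_span = 2e4,
                                locus_spacing = 4e5, seed = 1L) {
  stopifnot(n_loci >= 1, genes_per_locus >= 0, n_samples >= 3,
            snps_per_block >= 1, flip_prob >= 0, flip_prob <= 1,
            block_span > 0, locus_spacing > block_span)
  set.seed(seed)
  chrom_length <- as.integer(n_loci * locus_spacing + locus_spacing)

  snp_pos <- integer(0); snp_block <- integer(0)
  genes <- list(); hotspots <- list(); sentinels <- character(0)
  dos_cols <- list()
  for (b in seq_len(n_loci)) {
    b_start <- as.integer((b - 1) * locus_spacing + locus_spacing / 2)
    pos <- sort(sample.int(block_span, snps_per_block)) + b_start
    # latent diploid haplotype: redrawn until polymorphic so the sentinel
    # has a defined r2
    repeat {
      hap1 <- stats::rbinom(n_samples, 1, 0.5)
      hap2 <- stats::rbinom(n_samples, 1, 0.5)
      if (length(unique(hap1 + hap2)) >= 2) break
    }
    for (s in seq_len(snps_per_block)) {
      f1 <- stats::rbinom(n_samples, 1, flip_prob)
      f2 <- stats::rbinom(n_samples, 1, flip_prob)
      dos_cols[[length(dos_cols) + 1L]] <-
        abs(hap1 - f1) + abs(hap2 - f2)
    }
    snp_pos <- c(snp_pos, pos)
    snp_block <- c(snp_block, rep(b, snps_per_block))
    sentinels <- c(sentinels,
                   sprintf("rs%d_%d", b, ceiling(snps_per_block / 2)))
    # hotspot in the gap after this block
    hs_start <- b_start + block_span + as.integer(locus_spacing / 10)
    hotspots[[b]] <- c(hs_start, hs_start + 2000L)
    if (genes_per_locus > 0) {
      for (g in seq_len(genes_per_locus)) {
        len <- sample(5000:20000, 1)
        gs <- b_start + sample((-as.integer(locus_spacing / 3)):
                                 as.integer(locus_spacing / 3), 1)
        gs <- max(0L, min(gs, chrom_length - len - 1L))
        genes[[length(genes) + 1L]] <-
          data.frame(id = sprintf("GENE_%d_%d", b, g),
                     strand = sample(c("+", "-"), 1),
                     start = gs, end = gs + len, stringsAsFactors = FALSE)
      }
    }
  }
  snp_ids <- sprintf("rs%d_%s", snp_block,
                     unlist(lapply(table(snp_block), seq_len)))
  dosages <- do.call(cbind, dos_cols)
  colnames(dosages) <- snp_ids
  rownames(dosages) <- sprintf("s%03d", seq_len(n_samples))
  genes <- if (length(genes)) do.call(rbind, genes) else
    data.frame(id = character(0), strand = character(0),
               start = integer(0), end = integer(0))
  hs <- do.call(rbind, hotspots)
  structure(list(chrom_length = chrom_length, genes = genes,
                 hotspots = data.frame(start = hs[, 1], end = hs[, 2]),
                 snps = data.frame(id = snp_ids, pos = snp_pos,
                                   stringsAsFactors = FALSE),
                 dosages = dosages, sentinels = sentinels,
                 block_of = snp_block, seed = as.integer(seed)),
            class = "genome_toy")
}

#' Simulate annotation tables tied to a screen's ground truth
#'
#' Produces the external-validation annotations used by the enrichment
#' stage, constructed so that genes with a true effect are genuinely
#' enriched: essentiality scores rise with |gamma| plus noise, the
#' designated active stage of the expression matrix is upweighted for
#' effect genes, coding-variant flags are drawn at an elevated rate among
#' effect genes, and the gold-standard list is the five genes of largest
#' |gamma| (ties broken by gene id). With all gamma = 0 every annotation is
#' exchangeable across genes, so downstream enrichment p values are uniform.
#'
#' @param truth the \code{truth} component returned by [simulate_screen()].
#' @param n_stages number of differentiation stages (>= 2) in the
#'   expression matrix.
#' @param seed integer seed.
#' @param base_coding_rate,effect_coding_rate coding-variant flag rates for
#'   null and effect genes.
#' @return a list of class \code{"annotation_bundle"}: \code{essentiality}
#'   (named numeric), \code{expression} (gene x stage matrix),
#'   \code{coding_flag} (named 0/1), \code{gold_genes} (5 ids),
#'   \code{active_stage}, \code{universe} (all library genes), \code{seed}.
#' @export
simulate_annotations <- function(truth, n_stages = 5, seed = 1L,
                                 base_coding_rate = 0.05,
                                 effect_coding_rate = 0.15) {
  stopifnot(is.list(truth), nrow(truth$genes) > 0)
  if (n_stages < 2) stop("n_stages must be >= 2")
  set.seed(seed)
  g <- truth$genes
  n <- nrow(g)
  is_eff <- g$gamma != 0

  essentiality <- 2 * abs(g$gamma) + stats::rnorm(n, 0, 0.1)
  names(essentiality) <- g$gene

  expression <- matrix(stats::rnorm(n * n_stages, mean = 5, sd = 1),
                       nrow = n,
                       dimnames = list(g$gene,
                                       sprintf("stage%d", seq_len(n_stages))))
  active_stage <- ceiling(n_stages / 2)
  expression[is_eff, active_stage] <- expression[is_eff, active_stage] + 2

  rate <- ifelse(is_eff, effect_coding_rate, base_coding_rate)
  coding_flag <- stats::rbinom(n, 1, rate)
  names(coding_flag) <- g$gene

  ord <- order(-abs(g$gamma), g$gene)
  gold_genes <- g$gene[ord[seq_len(min(5, n))]]

  structure(list(essentiality = essentiality, expression = expression,
                 coding_flag = coding_flag, gold_genes = gold_genes,
                 active_stage = active_stage, universe = g$gene,
                 seed = as.integer(seed)),
            class = "annotation_bundle")
}
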