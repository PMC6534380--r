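# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: correlations from the raw Pearson sums,
# nomination by explicit per-gene interval arithmetic, BH by the textbook
# step-up recursion, permutation p values by exhaustive enumeration.

# Pearson r^2 from the definitional sums (no stats::cor)
oracle_r2 <- function(a, b) {
  n <- length(a)
  num <- n * sum(a * b) - sum(a) * sum(b)
  den <- (n * sum(a^2) - sum(a)^2) * (n * sum(b^2) - sum(b)^2)
  if (den <= 0) return(NA_real_)
  (num / sqrt(den))^2
}

# brute-force sentinel -> LD block -> hotspot extension -> wingspan overlap
oracle_nominate <- function(panel, sentinel, r2_threshold = 0.8,
                            up = 110000, down = 40000) {
  i <- match(sentinel, panel$snps$id)
  s <- panel$dosages[, i]
  pos_in <- panel$snps$pos[i]
  lo <- pos_in; hi <- pos_in
  for (j in seq_len(ncol(panel$dosages))) {
    r2 <- oracle_r2(s, panel$dosages[, j])
    if (!is.na(r2) && r2 >= r2_threshold) {
      lo <- min(lo, panel$snps$pos[j]); hi <- max(hi, panel$snps$pos[j])
    }
  }
  ld <- c(lo, hi + 1)
  ext_start <- 0; ext_end <- panel$chrom_length
  for (k in seq_len(nrow(panel$hotspots))) {
    hs <- panel$hotspots$start[k]; he <- panel$hotspots$end[k]
    if (he <= ld[1] && he > ext_start) ext_start <- he
    if (hs >= ld[2] && hs < ext_end) ext_end <- hs
  }
  nominated <- character(0)
  g <- panel$genes
  for (k in seq_len(nrow(g))) {
    if (g$strand[k] == "+") {
      ws <- max(0, g$start[k] - up); we <- g$end[k] + down
    } else {
      ws <- max(0, g$start[k] - down); we <- g$end[k] + up
    }
    if (ws < ext_end && ext_start < we)
      nominated <- c(nominated, g$id[k])
  }
  list(ld = ld, ext = c(ext_start, ext_end), genes = sort(nominated))
}

# textbook Benjamini-Hochberg step-up: q_(i) = min_{j >= i} m p_(j) / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, m * p[o[i]] / i)
    q_sorted[i] <- min(running, 1)
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# exact permutation p over all k-subsets of a score vector (tail as given)
oracle_exact_subset_p <- function(values, k, observed, tail) {
  combos <- utils::combn(length(values), k)
  sums <- apply(combos, 2, function(ix) sum(values[ix]))
  n_ext <- if (tail == "greater") sum(sums >= observed) else
    sum(sums <= observed)
  n_ext / ncol(combos)
}

# simulate sigma_hairpin-free fold-change rows for one gene directly (no
# count layer), for model oracles
make_gene_fc <- function(gamma = -0.2, n_hairpins = 6, n_reps = 3,
                         days = c(6, 9, 12, 14, 16), baseline = 4,
                         sigma_hairpin = 0, sigma_resid = 0,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  delta <- stats::rnorm(n_hairpins, 0, sigma_hairpin)
  rows <- expand.grid(hairpin = sprintf("h%d", seq_len(n_hairpins)),
                      replicate = sprintf("r%d", seq_len(n_reps)),
                      day = days, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  rows$elapsed_days <- rows$day - baseline
  hidx <- as.integer(factor(rows$hairpin))
  rows$y <- (gamma + delta[hidx]) * rows$elapsed_days +
    stats::rnorm(nrow(rows), 0, sigma_resid)
  rows$gene <- "G1"
  attr(rows, "baseline_day") <- baseline
  class(rows) <- c("fold_change_table", "data.frame")
  rows
}

# fabricate a screen_lmm-shaped object with prescribed coefficients and
# p values, for exercising the hit-calling gates in isolation
fake_fit <- function(beta, p, days = c(6, 9, 12, 14, 16), baseline = 4,
                     se = NULL) {
  genes <- rownames(beta)
  if (is.null(se)) se <- abs(beta) / 5 + 0.01
  structure(list(beta = beta, se = se, wald = (beta / se)^2, p = p,
                 sigma_h = stats::setNames(rep(0.1, nrow(beta)), genes),
                 sigma_resid = stats::setNames(rep(0.1, nrow(beta)), genes),
                 status = stats::setNames(rep("ok", nrow(beta)), genes),
                 n_hairpins = stats::setNames(rep(6L, nrow(beta)), genes),
                 n_obs = stats::setNames(rep(90L, nrow(beta)), genes),
                 time_grid = c(baseline, days), baseline_day = baseline,
                 days = days, random = "slope",
                 data = data.frame(), fitted = numeric(0)),
            class = "screen_lmm")
}
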