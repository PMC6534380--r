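test_that("dosage r2 matches the Pearson definition and flags monomorphs", {
  expect_equal(compute_r2(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1)
  expect_equal(compute_r2(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  a <- c(0, 1, 2, 2, 0, 1); b <- c(0, 1, 2, 1, 0, 2)
  expect_equal(compute_r2(a, b), oracle_r2(a, b))
  expect_true(is.na(compute_r2(c(1, 1, 1, 1), c(0, 1, 0, 1))))
  expect_error(compute_r2(c(0, 1), c(1, 0)), "3 samples")
  expect_error(compute_r2(c(0, 1, 2), c(1, 0)), "equal length")
})

test_that("LD blocks span exactly the SNPs in LD with the sentinel", {
  # sentinel-only block: no partner SNP reaches the threshold
  panel <- list(
    snps = data.frame(id = c("s1", "s2"), pos = c(100L, 500L)),
    dosages = cbind(s1 = c(0, 1, 2, 1, 0, 2),
                    s2 = c(2, 0, 1, 0, 2, 1)))
  blk <- ld_block("s1", panel, r2_threshold = 0.999)
  expect_equal(unname(blk), c(100, 101))
  # a perfect-copy block of 5 spans first to last position
  d <- c(0, 1, 2, 0, 1, 2, 1, 0)
  panel5 <- list(snps = data.frame(id = paste0("s", 1:5),
                                   pos = c(10L, 30L, 50L, 70L, 90L)),
                 dosages = matrix(rep(d, 5), ncol = 5,
                                  dimnames = list(NULL, paste0("s", 1:5))))
  expect_equal(unname(ld_block("s3", panel5)), c(10, 91))
  # monomorphic sentinel is an error, not a silent zero
  panelm <- list(snps = data.frame(id = "m1", pos = 5L),
                 dosages = cbind(m1 = rep(1, 6)))
  expect_error(ld_block("m1", panelm), "monomorphic")
  expect_error(ld_block("nope", panel), "not on the panel")
})

test_that("hotspot extension lands on the inner hotspot edges", {
  hs <- data.frame(start = c(100, 900), end = c(200, 1000))
  expect_equal(unname(extend_to_hotspots(c(400, 500), hs, 2000)),
               c(200, 900))
  # no hotspot left of the block -> chromosome start
  expect_equal(unname(extend_to_hotspots(c(50, 80), hs, 2000))[1], 0)
  # no hotspot right of the block -> chromosome end
  expect_equal(unname(extend_to_hotspots(c(1500, 1600), hs, 2000))[2], 2000)
  # hotspots immediately flanking: window is exactly the gap
  expect_equal(unname(extend_to_hotspots(c(200, 900), hs, 2000)),
               c(200, 900))
  expect_error(extend_to_hotspots(c(-5, 10), hs, 2000), "within")
})

test_that("wingspan nomination is strand-aware with half-open overlap", {
  win <- c(1e6, 1.2e6)
  genes <- data.frame(
    id = c("inside", "plus_upstream", "minus_upstream", "plus_far"),
    strand = c("+", "+", "-", "+"),
    start = c(1.05e6, win[2] + 105000, win[1] - 105000 - 8000,
              win[2] + 111000),
    end = c(1.06e6, win[2] + 115000, win[1] - 105000, win[2] + 120000))
  nom <- nominate_genes(win, genes)
  expect_true("inside" %in% nom)
  # + strand: txStart 105 kb right of the window is within the 110 kb
  # upstream reach
  expect_true("plus_upstream" %in% nom)
  # - strand gene ending 105 kb left of the window: its upstream reach
  # extends rightwards and covers the window
  expect_true("minus_upstream" %in% nom)
  expect_false("plus_far" %in% nom)
  # the same left-side gene on the + strand only reaches 40 kb downstream
  genes_flip <- genes[3, ]; genes_flip$strand <- "+"
  expect_length(nominate_genes(win, genes_flip), 0)
  # exact boundary: wingspan start == window end gives empty half-open
  # intersection; one bp closer and the gene is nominated
  gb <- data.frame(id = "edge", strand = "+", start = win[2] + 110000,
                   end = win[2] + 112000)
  expect_length(nominate_genes(win, gb), 0)
  gb$start <- gb$start - 1
  expect_equal(nominate_genes(win, gb), "edge")
  # strand-agnostic mode treats upstream as left regardless of strand
  expect_length(nominate_genes(win, genes[3, ], strand_aware = FALSE), 0)
})

test_that("enlarging the wingspan never removes a nominated gene", {
  set.seed(21)
  for (r in 1:20) {
    panel <- simulate_genome_toy(n_loci = 3, genes_per_locus = 5,
                                 n_samples = 40, seed = 100 + r)
    win <- sort(sample.int(panel$chrom_length, 2))
    base <- nominate_genes(win, panel$genes, up_kb = 110, down_kb = 40)
    bigger <- nominate_genes(win, panel$genes, up_kb = 150, down_kb = 80)
    expect_true(all(base %in% bigger))
  }
})

test_that("full nomination agrees with the brute-force oracle", {
  for (r in 1:10) {
    panel <- simulate_genome_toy(n_loci = 4, genes_per_locus = 4,
                                 n_samples = 50, flip_prob = 0.1,
                                 seed = 300 + r)
    nom <- nominate_all(panel)
    for (k in seq_along(panel$sentinels)) {
      o <- oracle_nominate(panel, panel$sentinels[k])
      w <- nom$windows[k, ]
      expect_equal(c(w$ld_start, w$ld_end), o$ld)
      expect_equal(c(w$ext_start, w$ext_end), o$ext)
      got <- sort(nom$genes$gene[nom$genes$locus == w$locus])
      expect_equal(got, o$genes)
      # structural invariants: ext contains ld contains sentinel
      spos <- panel$snps$pos[match(w$sentinel, panel$snps$id)]
      expect_true(w$ext_start <= w$ld_start && w$ld_start <= spos &&
                    spos < w$ld_end && w$ld_end <= w$ext_end)
    }
  }
})

test_that("manual window overrides replace the computed window", {
  panel <- simulate_genome_toy(n_loci = 2, genes_per_locus = 3, seed = 44)
  ov <- data.frame(sentinel = panel$sentinels[1], start = 0,
                   end = panel$chrom_length)
  nom <- nominate_all(panel, overrides = ov)
  # a whole-chromosome override nominates every gene at that locus
  expect_equal(nom$windows$n_genes[1], nrow(panel$genes))
})

test_that("eQTL window comparison builds the right table and Fisher p", {
  # 8-gene universe, 4 hits; padded window captures 3 hits + 1 non-hit
  # -> two-sided Fisher p = 34/70
  win <- data.frame(ld_start = 49000, ld_end = 51000)  # pads to [0,100000)
  genes <- data.frame(
    id = sprintf("g%d", 1:8),
    start = c(1e4, 3e4, 5e4, 7e4, 2e5, 3e5, 4e5, 5e5),
    end = c(1e4, 3e4, 5e4, 7e4, 2e5, 3e5, 4e5, 5e5) + 5000)
  hits <- c("g1", "g2", "g3", "g5")
  out <- eqtl_window_comparison(win, genes, hits,
                                eqtl_genes = genes$id)
  expect_equal(sort(out$nominated), c("g1", "g2", "g3", "g4"))
  expect_equal(as.vector(out$table), c(3, 1, 1, 3))
  expect_equal(out$p, 34 / 70)
  # fully separated balanced table -> p = 2/70
  out2 <- eqtl_window_comparison(win, genes, c("g1", "g2", "g3", "g4"),
                                 eqtl_genes = genes$id)
  expect_equal(out2$p, 2 / 70)
  expect_error(eqtl_window_comparison(win, genes, hits, character(0)),
               "empty")
})

test_that("null-configuration Fisher p values are approximately uniform", {
  set.seed(31)
  ps <- replicate(200, {
    genes <- data.frame(id = sprintf("g%d", 1:40),
                        start = sample.int(5e5, 40))
    genes$end <- genes$start + 5000
    win <- data.frame(ld_start = 2e5, ld_end = 2.1e5)
    hits <- sample(genes$id, 12)          # independent of position
    eqtl_window_comparison(win, genes, hits, genes$id)$p
  })
  # Fisher p is discrete and conservative; demand no inflation and real
  # spread rather than exact uniformity
  expect_lt(mean(ps < 0.05), 0.08)
  expect_gt(mean(ps), 0.4)
})
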