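#' Configuration for an end-to-end pipeline run
#'
#' Collects every parameter of the six pipeline stages into one validated
#' object; the single \code{seed} feeds all of them (stage seeds are
#' derived as small fixed offsets so stages can be rerun in isolation).
#'
#' @param out_dir output directory; created by [run_pipeline()].
#' @param seed master seed for the whole run.
#' @param sim a [sim_config()] (its own seed is overwritten by
#'   \code{seed}).
#' @param r2_threshold,up_kb,down_kb locus-nomination parameters.
#' @param baseline_day,pseudocount preprocessing parameters.
#' @param slope_threshold,q_threshold,slope_mode hit-calling parameters.
#' @param n_perm permutations per enrichment statistic.
#' @param n_stages stages in the simulated expression matrix.
#' @return list of class \code{"run_config"}.
#' @export
run_config <- function(out_dir, seed = 1L, sim = sim_config(seed = seed),
                       r2_threshold = 0.8, up_kb = 110, down_kb = 40,
                       baseline_day = NULL, pseudocount = 1,
                       slope_threshold = 0.1, q_threshold = 0.1,
                       slope_mode = "cumulative", n_perm = 1e4,
                       n_stages = 5) {
  stopifnot(slope_threshold >= 0, q_threshold >= 0, n_perm >= 1)
  sim$seed <- as.integer(seed)
  if (is.null(baseline_day)) baseline_day <- sim$time_grid[1]
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 r2_threshold = r2_threshold, up_kb = up_kb,
                 down_kb = down_kb, baseline_day = baseline_day,
                 pseudocount = pseudocount,
                 slope_threshold = slope_threshold,
                 q_threshold = q_threshold, slope_mode = slope_mode,
                 n_perm = as.integer(n_perm),
                 n_stages = as.integer(n_stages)),
            class = "run_config")
}

# stable id for a run: checksum of the config (seed included, paths
# excluded so the same analysis in another directory matches)
.run_id <- function(cfg) {
  c2 <- cfg; c2$out_dir <- NULL
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(c2), auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}

#' Run the full synthetic-screen pipeline
#'
#' Executes simulate, nominate, preprocess, fit, call-hits and enrich in
#' order, writing each stage's tables (TSV, with a run-id header comment)
#' under \code{cfg$out_dir} plus a JSON run manifest with row counts,
#' file checksums and per-stage wall time. On a stage failure the
#' manifest is still written, recording the failing stage, before the
#' error propagates. Identical config and seed give identical tables.
#'
#' @param cfg a [run_config()].
#' @param progress print stage progress.
#' @return invisibly, a list with the in-memory stage results
#'   (\code{sim}, \code{panel}, \code{nomination}, \code{fc}, \code{qc},
#'   \code{fit}, \code{hits}, \code{enrichment}) and the \code{manifest}.
#' @export
run_pipeline <- function(cfg, progress = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  run_id <- .run_id(cfg)
  manifest <- list(run_id = run_id,
                   package_version =
                     as.character(utils::packageVersion("shrnascreen")),
                   config = unclass(cfg), stages = list())
  res <- list()
  t_all <- proc.time()[["elapsed"]]
  record <- function(stage, t0, rows) {
    manifest$stages[[stage]] <<- list(
      rows = rows, seconds = round(proc.time()[["elapsed"]] - t0, 3))
  }
  fail <- function(stage, e) {
    manifest$error <<- list(stage = stage, message = conditionMessage(e))
    .write_manifest(manifest, cfg$out_dir)
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  }
  stage <- function(name, expr) {
    if (progress) message("stage: ", name)
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) fail(name, e))
    list(out = out, t0 = t0)
  }
  wt <- function(x, file, ...) write_tsv(x, file.path(cfg$out_dir, file),
                                         comment = paste("run", run_id), ...)

  s <- stage("simulate", {
    sim <- simulate_screen(cfg$sim)
    panel <- simulate_genome_toy(n_loci = cfg$sim$n_loci,
                                 seed = cfg$seed + 1L)
    ann <- simulate_annotations(sim$truth, n_stages = cfg$n_stages,
                                seed = cfg$seed + 2L)
    wt(sim$counts, "counts.tsv", id_col = "hairpin")
    wt(sim$library, "library.tsv")
    wt(sim$truth$genes, "truth_genes.tsv")
    wt(sim$truth$hairpins, "truth_hairpins.tsv")
    write_genome_toy(panel, file.path(cfg$out_dir, "genome"))
    list(sim = sim, panel = panel, ann = ann)
  })
  res$sim <- s$out$sim; res$panel <- s$out$panel; ann <- s$out$ann
  record("simulate", s$t0, nrow(res$sim$counts))

  s <- stage("nominate", {
    nom <- nominate_all(res$panel, r2_threshold = cfg$r2_threshold,
                        up_kb = cfg$up_kb, down_kb = cfg$down_kb)
    wt(nom$windows, "locus_windows.tsv")
    wt(nom$genes, "candidate_genes.tsv")
    nom
  })
  res$nomination <- s$out
  record("nominate", s$t0, nrow(res$nomination$windows))

  s <- stage("preprocess", {
    norm <- log2_cpm(res$sim$counts, pseudocount = cfg$pseudocount)
    fc <- fold_change_vs_baseline(norm, res$sim$samples, res$sim$library,
                                  baseline_day = cfg$baseline_day)
    qc <- representation_qc(norm, res$sim$samples, day = cfg$baseline_day)
    wt(as.data.frame(fc), "fold_changes.tsv")
    jsonlite::write_json(qc, file.path(cfg$out_dir, "qc.json"),
                         auto_unbox = TRUE, digits = NA)
    list(fc = fc, qc = qc)
  })
  res$fc <- s$out$fc; res$qc <- s$out$qc
  record("preprocess", s$t0, nrow(res$fc))

  s <- stage("fit", {
    fit <- screen_lmm(res$fc, progress = progress)
    tall <- data.frame(gene = rep(rownames(fit$beta), ncol(fit$beta)),
                       day = rep(fit$days, each = nrow(fit$beta)),
                       beta = as.vector(fit$beta),
                       se = as.vector(fit$se),
                       wald = as.vector(fit$wald),
                       p = as.vector(fit$p), stringsAsFactors = FALSE)
    tall <- tall[order(tall$gene, tall$day), ]
    wt(tall, "model_fits.tsv")
    fit
  })
  res$fit <- s$out
  record("fit", s$t0, nrow(res$fit$beta))

  s <- stage("call-hits", {
    hits <- call_hits(res$fit, slope_threshold = cfg$slope_threshold,
                      q_threshold = cfg$q_threshold,
                      slope_mode = cfg$slope_mode,
                      library = res$sim$library)
    wt(as.data.frame(hits), "hits.tsv")
    ls <- attr(hits, "locus_summary")
    wt(data.frame(locus = names(ls$hits_per_locus),
                  n_hits = as.integer(ls$hits_per_locus)),
       "locus_summary.tsv")
    hits
  })
  res$hits <- s$out
  record("call-hits", s$t0, sum(res$hits$hit))

  s <- stage("enrich", {
    hit_genes <- res$hits$gene[res$hits$hit]
    enr <- list()
    if (length(hit_genes) > 0) {
      enr$essentiality <- score_sum_enrichment(
        hit_genes, ann$essentiality, ann$universe, n_perm = cfg$n_perm,
        seed = cfg$seed + 10L)
      qmin <- stats::setNames(res$hits$q_min, res$hits$gene)
      qmin[is.na(qmin)] <- 1
      enr$gold_rank <- rank_sum_enrichment(
        ann$gold_genes, qmin, ann$universe, n_perm = cfg$n_perm,
        seed = cfg$seed + 11L)
      enr$coding_overlap <- overlap_enrichment(
        hit_genes, names(ann$coding_flag)[ann$coding_flag == 1],
        ann$universe, n_perm = cfg$n_perm, seed = cfg$seed + 12L)
      enr$stages <- stage_expression_enrichment(
        hit_genes, ann$expression, ann$universe,
        n_perm = min(cfg$n_perm, 1e4), seed = cfg$seed + 13L)
    }
    tab <- do.call(rbind, lapply(c(enr[setdiff(names(enr), "stages")],
                                   enr$stages), function(e)
      data.frame(statistic = e$statistic, observed = e$observed,
                 n_permutations = e$n_permutations, p = e$p,
                 tail = e$tail, stringsAsFactors = FALSE)))
    if (!is.null(tab)) wt(tab, "enrichment.tsv")
    enr
  })
  res$enrichment <- s$out
  record("enrich", s$t0, length(res$enrichment))

  manifest$total_seconds <- round(proc.time()[["elapsed"]] - t_all, 3)
  manifest$checksums <- as.list(
    tools::md5sum(sort(list.files(cfg$out_dir, pattern = "\\.(tsv|bed|vcf|txt|json)$",
                                  full.names = TRUE, recursive = TRUE))))
  names(manifest$checksums) <- basename(names(manifest$checksums))
  .write_manifest(manifest, cfg$out_dir)
  res$manifest <- manifest
  invisible(res)
}

.write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
}

#' Human-readable summary of a pipeline run
#'
#' Re-reads the tables written by [run_pipeline()] and reports genes
#' tested, hit counts and directions, loci with at least one hit, the
#' hits-per-locus histogram, the representation QC fraction and the
#' enrichment p values. All numbers are recomputed from the output
#' tables, so the report can be reconciled against them.
#'
#' @param out_dir directory written by [run_pipeline()].
#' @return character vector of report lines, invisibly; printed.
#' @export
summary_report <- function(out_dir) {
  hits <- read_tsv(file.path(out_dir, "hits.tsv"))
  qc <- jsonlite::read_json(file.path(out_dir, "qc.json"),
                            simplifyVector = TRUE)
  lines <- c("shRNA screen pipeline summary",
             sprintf("  genes tested: %d", nrow(hits)),
             sprintf("  hits: %d (%d depleted, %d enriched)",
                     sum(hits$hit),
                     sum(hits$direction == "depleted", na.rm = TRUE),
                     sum(hits$direction == "enriched", na.rm = TRUE)))
  if (!is.null(hits$locus)) {
    per_locus <- table(hits$locus[hits$hit])
    n_loci <- length(unique(hits$locus[!is.na(hits$locus)]))
    lines <- c(lines,
               sprintf("  loci with >= 1 hit: %d of %d",
                       length(per_locus), n_loci))
    if (length(per_locus))
      lines <- c(lines, sprintf("  hits per hit-locus: %s",
                                paste(sprintf("%sx%d", names(table(per_locus)),
                                              as.integer(table(per_locus))),
                                      collapse = ", ")))
  }
  lines <- c(lines,
             sprintf("  representation QC (day %g): %.1f%% of hairpins >= %g log2CPM",
                     qc$day, 100 * qc$fraction, qc$threshold))
  ef <- file.path(out_dir, "enrichment.tsv")
  if (file.exists(ef)) {
    enr <- read_tsv(ef)
    lines <- c(lines, "  enrichment p values:",
               sprintf("    %-40s p = %.4g", enr$statistic, enr$p))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
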