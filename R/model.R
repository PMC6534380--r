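#' Fit the longitudinal mixed model for one gene
#'
#' Fits, to the log2 fold-change observations of a single gene's hairpins,
#' the model
#' \deqn{y = \beta_{day} + b_h \cdot \mathrm{elapsed} + \epsilon,}
#' with one fixed coefficient per post-baseline day (no intercept: y is
#' zero at baseline by construction), a random slope \eqn{b_h \sim N(0,
#' \sigma_h^2)} per hairpin capturing knockdown-efficiency and off-target
#' drift, and i.i.d. residuals. Variance components are estimated by REML
#' (lme4); each coefficient gets a Wald chi-square statistic
#' \eqn{W = (\hat\beta/SE)^2} on 1 df.
#'
#' A fit whose response is exactly collinear with the per-day means (zero
#' residual variance) cannot be handled by the likelihood machinery and is
#' returned as the ordinary least-squares solution with status
#' \code{"degenerate"}. \eqn{\hat\sigma_h^2 = 0} is allowed (the fit then
#' equals OLS per-day means) and reported as status \code{"singular"}.
#' Non-converging fits are retried up to three times from jittered starts
#' and flagged \code{"failed"} if all restarts fail; failed genes are
#' excluded from hit calling, never silently dropped.
#'
#' @param fc rows of a [fold_change_vs_baseline()] table for one gene
#'   (columns \code{hairpin}, \code{day}, \code{elapsed_days}, \code{y}).
#' @param random \code{"slope"} (default): a single random slope on elapsed
#'   days per hairpin; \code{"day"}: independent per-day random effects per
#'   hairpin (diagonal covariance).
#' @return a list with \code{beta}, \code{se}, \code{wald}, \code{p} (one
#'   entry per post-baseline day, named \code{d<day>}), \code{sigma_h},
#'   \code{sigma_resid}, \code{status}, \code{n_hairpins}, \code{n_obs},
#'   \code{days}, and per-observation \code{fitted} values.
#' @export
fit_gene <- function(fc, random = c("slope", "day")) {
  random <- match.arg(random)
  days <- sort(unique(fc$day))
  if (length(unique(fc$hairpin)) < 2 || length(days) < 2)
    stop("need >= 2 hairpins and >= 2 post-baseline days")
  d <- data.frame(y = fc$y, day_f = factor(fc$day, levels = days),
                  el = fc$elapsed_days, hairpin = factor(fc$hairpin))
  nm <- paste0("d", days)

  ols_beta <- tapply(d$y, d$day_f, mean)
  resid_ols <- d$y - ols_beta[as.integer(d$day_f)]

  res <- list(days = days, n_hairpins = nlevels(d$hairpin), n_obs = nrow(d))
  if (max(abs(resid_ols)) < 1e-10) {
    # exact fit: the likelihood surface is flat, return OLS directly
    res$beta <- stats::setNames(as.numeric(ols_beta), nm)
    res$se <- stats::setNames(rep(0, length(days)), nm)
    res$wald <- stats::setNames(rep(Inf, length(days)), nm)
    res$p <- stats::setNames(rep(NA_real_, length(days)), nm)
    res$sigma_h <- 0; res$sigma_resid <- 0
    res$status <- "degenerate"
    res$fitted <- as.numeric(ols_beta[as.integer(d$day_f)])
    return(res)
  }

  form <- if (random == "slope") y ~ 0 + day_f + (0 + el | hairpin)
          else y ~ 0 + day_f + (0 + day_f || hairpin)
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  fit <- NULL
  for (attempt in 0:3) {
    fit <- tryCatch({
      if (attempt == 0)
        lme4::lmer(form, data = d, REML = TRUE, control = ctrl)
      else {
        n_th <- if (random == "slope") 1L else length(days)
        st <- list(theta = abs(stats::rnorm(n_th, 1, 0.5)))
        lme4::lmer(form, data = d, REML = TRUE, control = ctrl, start = st)
      }
    }, error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    res$beta <- stats::setNames(rep(NA_real_, length(days)), nm)
    res$se <- res$wald <- res$p <- res$beta
    res$sigma_h <- NA_real_; res$sigma_resid <- NA_real_
    res$status <- "failed"; res$fitted <- rep(NA_real_, nrow(d))
    return(res)
  }

  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  vc <- lme4::VarCorr(fit)
  sigma_h <- sqrt(sum(unlist(lapply(vc, function(m) sum(diag(m))))))
  res$beta <- stats::setNames(as.numeric(beta), nm)
  res$se <- stats::setNames(as.numeric(se), nm)
  res$wald <- stats::setNames((res$beta / res$se)^2, nm)
  res$p <- stats::setNames(
    stats::pchisq(res$wald, df = 1, lower.tail = FALSE), nm)
  res$sigma_h <- sigma_h
  res$sigma_resid <- stats::sigma(fit)
  res$status <- if (lme4::isSingular(fit, tol = 1e-6)) "singular" else "ok"
  res$fitted <- as.numeric(stats::fitted(fit))
  res
}

#' Fit the screen-wide per-gene mixed models
#'
#' The central fitting function: applies [fit_gene()] to every gene of a
#' fold-change table and collects the per-gene, per-day coefficients,
#' standard errors, Wald chi-square statistics and p values into a single
#' model object. The model is fitted independently per gene; replicates
#' enter as pooled rows, not as averaged counts.
#'
#' @param fc a [fold_change_vs_baseline()] table with a \code{gene} column.
#' @param random random-effect structure, see [fit_gene()].
#' @param progress print a dot every 50 genes.
#' @return an object of class \code{"screen_lmm"} with matrices
#'   \code{beta}, \code{se}, \code{wald}, \code{p} (genes x days),
#'   vectors \code{sigma_h}, \code{sigma_resid}, \code{status},
#'   \code{n_hairpins}, \code{n_obs}, the \code{time_grid} /
#'   \code{baseline_day}, and the input data with fitted values for
#'   residual diagnostics. Methods: \code{print}, \code{summary},
#'   \code{coef}, \code{plot}, \code{fitted}, \code{residuals}.
#' @examples
#' sim <- simulate_screen(sim_config(n_genes = 12, depth_per_sample = 1e5,
#'                                   seed = 3))
#' fc <- fold_change_vs_baseline(log2_cpm(sim$counts), sim$samples,
#'                               sim$library)
#' fit <- screen_lmm(fc)
#' head(coef(fit))
#' @export
screen_lmm <- function(fc, random = c("slope", "day"), progress = FALSE) {
  random <- match.arg(random)
  if (is.null(fc$gene)) stop("fold-change table needs a gene column")
  baseline_day <- attr(fc, "baseline_day")
  if (is.null(baseline_day)) baseline_day <- min(fc$day) - min(fc$elapsed_days)
  genes <- sort(unique(fc$gene))
  days <- sort(unique(fc$day))
  nm <- paste0("d", days)
  G <- length(genes)
  mk <- function() matrix(NA_real_, G, length(days),
                          dimnames = list(genes, nm))
  beta <- mk(); se <- mk(); wald <- mk(); p <- mk()
  sigma_h <- sigma_resid <- stats::setNames(rep(NA_real_, G), genes)
  status <- stats::setNames(character(G), genes)
  n_hp <- n_obs <- stats::setNames(integer(G), genes)
  fitted_all <- rep(NA_real_, nrow(fc))
  idx_by_gene <- split(seq_len(nrow(fc)), fc$gene)
  for (i in seq_len(G)) {
    idx <- idx_by_gene[[genes[i]]]
    f <- fit_gene(fc[idx, ], random = random)
    beta[i, names(f$beta)] <- f$beta
    se[i, names(f$se)] <- f$se
    wald[i, names(f$wald)] <- f$wald
    p[i, names(f$p)] <- f$p
    sigma_h[i] <- f$sigma_h; sigma_resid[i] <- f$sigma_resid
    status[i] <- f$status
    n_hp[i] <- f$n_hairpins; n_obs[i] <- f$n_obs
    fitted_all[idx] <- f$fitted
    if (progress && i %% 50 == 0) cat(".")
  }
  if (progress) cat("\n")
  structure(list(beta = beta, se = se, wald = wald, p = p,
                 sigma_h = sigma_h, sigma_resid = sigma_resid,
                 status = status, n_hairpins = n_hp, n_obs = n_obs,
                 time_grid = c(baseline_day, days),
                 baseline_day = baseline_day, days = days,
                 random = random, data = fc, fitted = fitted_all,
                 call = match.call()),
            class = "screen_lmm")
}

#' @export
print.screen_lmm <- function(x, ...) {
  cat("Per-gene longitudinal mixed model (random hairpin ",
      if (x$random == "slope") "slopes" else "day effects", ")\n", sep = "")
  cat(sprintf("  %d genes, %d observations; days %s (baseline %g)\n",
              nrow(x$beta), length(x$fitted),
              paste(x$days, collapse = ", "), x$baseline_day))
  tab <- table(factor(x$status,
                      c("ok", "singular", "degenerate", "failed")))
  cat("  fit status:",
      paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.screen_lmm <- function(object, ...) object$beta

#' @export
fitted.screen_lmm <- function(object, ...) object$fitted

#' @export
residuals.screen_lmm <- function(object, ...) object$data$y - object$fitted

#' @describeIn screen_lmm volcano-style plot of per-day slope at the
#'   minimum-q day against -log10(q).
#' @param x,object a \code{screen_lmm} object.
#' @param ... unused.
#' @export
plot.screen_lmm <- function(x, ...) {
  s <- summary(x)
  graphics::plot(s$table$slope_best, -log10(s$table$q_min),
                 xlab = "per-day slope at best day (log2FC/day)",
                 ylab = "-log10 q", pch = 16,
                 col = ifelse(s$table$hit, "firebrick", "grey40"), ...)
  graphics::abline(v = c(-s$slope_threshold, s$slope_threshold),
                   h = -log10(s$q_threshold), lty = 2, col = "grey60")
  invisible(s)
}

#' @describeIn screen_lmm Benjamini--Hochberg adjustment across all
#'   gene-day tests, per-day slopes and dual-threshold hit calls.
#' @param slope_threshold,q_threshold hit-calling gates (defaults 0.1).
#' @param slope_mode see [slope_per_day()].
#' @export
summary.screen_lmm <- function(object, slope_threshold = 0.1,
                               q_threshold = 0.1,
                               slope_mode = c("cumulative", "incremental"),
                               ...) {
  slope_mode <- match.arg(slope_mode)
  q <- matrix(bh_fdr(as.vector(object$p)), nrow(object$p),
              dimnames = dimnames(object$p))
  slope <- slope_per_day(object, mode = slope_mode)
  eligible <- object$status != "failed"
  qual <- abs(slope) > slope_threshold & q < q_threshold & eligible
  qual[is.na(qual)] <- FALSE
  hit <- rowSums(qual) > 0
  best_day <- q_min <- slope_best <- rep(NA_real_, nrow(q))
  direction <- rep(NA_character_, nrow(q))
  for (i in seq_len(nrow(q))) {
    cand <- if (hit[i]) which(qual[i, ]) else which(!is.na(q[i, ]))
    if (length(cand) == 0) next
    k <- cand[which.min(q[i, cand])]
    best_day[i] <- object$days[k]
    q_min[i] <- q[i, k]
    slope_best[i] <- slope[i, k]
    if (hit[i]) direction[i] <- if (slope[i, k] < 0) "depleted" else "enriched"
  }
  tab <- data.frame(gene = rownames(q), status = object$status,
                    n_hairpins = object$n_hairpins,
                    best_day = best_day, q_min = q_min,
                    slope_best = slope_best, hit = hit,
                    direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, q = q, slope = slope,
                 slope_threshold = slope_threshold,
                 q_threshold = q_threshold, slope_mode = slope_mode,
                 days = object$days, baseline_day = object$baseline_day),
            class = "summary.screen_lmm")
}

#' @export
print.summary.screen_lmm <- function(x, ...) {
  cat(sprintf(
    "Hit calling: |slope| > %g log2FC/day and q < %g (%s slopes)\n",
    x$slope_threshold, x$q_threshold, x$slope_mode))
  cat(sprintf("  %d of %d genes called (%d depleted, %d enriched)\n",
              sum(x$table$hit), nrow(x$table),
              sum(x$table$direction == "depleted", na.rm = TRUE),
              sum(x$table$direction == "enriched", na.rm = TRUE)))
  invisible(x)
}

#' Per-day slopes from cumulative log2 fold-change coefficients
#'
#' Each fixed-effect coefficient is the cumulative log2 fold change from
#' baseline to its day. \code{"cumulative"} mode (default) divides by the
#' elapsed time, \eqn{\beta_k / (t_k - t_0)}; \code{"incremental"} mode
#' differences consecutive coefficients,
#' \eqn{(\beta_k - \beta_{k-1}) / (t_k - t_{k-1})} with \eqn{\beta_0 = 0}.
#' For a linear trajectory the two agree.
#'
#' @param object a [screen_lmm()] fit, or a numeric matrix/vector of
#'   coefficients (then \code{days} and \code{baseline_day} are required).
#' @param mode \code{"cumulative"} or \code{"incremental"}.
#' @param days,baseline_day time grid when \code{object} is a bare matrix.
#' @return matrix (or vector) of per-day slopes in log2FC/day.
#' @export
slope_per_day <- function(object, mode = c("cumulative", "incremental"),
                          days = NULL, baseline_day = NULL) {
  mode <- match.arg(mode)
  if (inherits(object, "screen_lmm")) {
    beta <- object$beta; days <- object$days
    baseline_day <- object$baseline_day
  } else beta <- object
  drop_out <- is.null(dim(beta))
  if (drop_out) beta <- matrix(beta, nrow = 1)
  stopifnot(length(days) == ncol(beta), !is.null(baseline_day))
  if (mode == "cumulative") {
    out <- sweep(beta, 2, days - baseline_day, "/")
  } else {
    prev <- cbind(0, beta[, -ncol(beta), drop = FALSE])
    out <- sweep(beta - prev, 2, diff(c(baseline_day, days)), "/")
  }
  if (drop_out) out[1, ] else out
}

#' Benjamini--Hochberg adjusted q values
#'
#' Step-up FDR adjustment. Missing (NA/NaN) p values propagate to the
#' output and are excluded from the number of tests m.
#'
#' @param p_values vector of p values in [0, 1] (NA/NaN allowed).
#' @return vector of q values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p values must lie in [0, 1]")
  q <- p_values          # propagates NA/NaN as-is
  q[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  q
}

#' Call screen hits with the dual-threshold rule
#'
#' A gene is a hit when at some post-baseline day its per-day effect
#' magnitude exceeds \code{slope_threshold} (log2 fold change per day)
#' while its BH-adjusted q value is below \code{q_threshold} — requiring
#' both a material and a statistically confident effect. BH adjustment is
#' applied jointly across all gene-day tests in the fit (control genes
#' included). When a library with a \code{locus} column is supplied the
#' result carries a per-locus summary: number of loci with at least one
#' hit and the hits-per-locus histogram.
#'
#' @param object a [screen_lmm()] fit.
#' @param slope_threshold minimum |per-day slope|, default 0.1.
#' @param q_threshold maximum q, default 0.1.
#' @param slope_mode see [slope_per_day()].
#' @param library optional data frame mapping \code{gene} to \code{locus}.
#' @return the gene table (one row per gene: \code{gene}, \code{status},
#'   \code{best_day}, \code{q_min}, \code{slope_best}, \code{hit},
#'   \code{direction}) of class \code{"gene_effects"}, with attributes
#'   \code{locus_summary} (when a library was given), \code{thresholds}
#'   and \code{slope_mode}.
#' @export
call_hits <- function(object, slope_threshold = 0.1, q_threshold = 0.1,
                      slope_mode = c("cumulative", "incremental"),
                      library = NULL) {
  slope_mode <- match.arg(slope_mode)
  s <- summary(object, slope_threshold = slope_threshold,
               q_threshold = q_threshold, slope_mode = slope_mode)
  tab <- s$table
  if (!is.null(library)) {
    map <- unique(library[, c("gene", "locus")])
    tab$locus <- map$locus[match(tab$gene, map$gene)]
    hit_loci <- unique(tab$locus[tab$hit & !is.na(tab$locus)])
    per_locus <- table(factor(tab$locus[tab$hit],
                              levels = sort(unique(map$locus))))
    attr(tab, "locus_summary") <- list(
      n_loci = length(unique(map$locus)),
      n_hit_loci = length(hit_loci),
      hits_per_locus = per_locus,
      histogram = table(per_locus[per_locus > 0]))
  }
  attr(tab, "thresholds") <- c(slope = slope_threshold, q = q_threshold)
  attr(tab, "slope_mode") <- slope_mode
  class(tab) <- c("gene_effects", "data.frame")
  tab
}
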