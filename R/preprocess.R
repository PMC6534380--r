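#' Log2 counts-per-million normalisation
#'
#' Adds a pseudocount to every hairpin count, normalises each sample to
#' counts per million using the library size computed after
#' pseudocounting, and log2-transforms:
#' \deqn{v_{hs} = \log_2\left(\frac{c_{hs} + pc}{\sum_h (c_{hs} + pc)} \times 10^6\right).}
#' By construction \code{sum(2^v)} is exactly 1e6 in every sample.
#'
#' @param counts non-negative matrix, hairpins x samples.
#' @param pseudocount added to every cell before normalisation (default 1).
#' @return matrix of log2 CPM values, same dimnames as \code{counts}.
#' @export
log2_cpm <- function(counts, pseudocount = 1) {
  counts <- as.matrix(counts)
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative with no missing cells")
  x <- counts + pseudocount
  if (any(x < 0)) stop("negative values after pseudocounting")
  lib <- colSums(x)
  if (any(lib == 0))
    stop("all-zero sample with pseudocount 0: CPM undefined for sample(s) ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  log2(sweep(x, 2, lib, "/") * 1e6)
}

#' Log2 fold change of each hairpin versus its baseline sample
#'
#' Converts per-sample log2 CPM into the mixed model's response: for each
#' hairpin and replicate, the log2 CPM at each post-baseline day minus the
#' log2 CPM of the same replicate at the baseline day. Baseline rows are
#' not emitted (their fold change is identically zero).
#'
#' @param norm log2 CPM matrix from [log2_cpm()].
#' @param samples data frame with one row per column of \code{norm}:
#'   \code{sample}, \code{replicate}, \code{day}.
#' @param library optional data frame \code{hairpin}, \code{gene} (and
#'   further columns) used to attach the gene of each hairpin.
#' @param baseline_day day of the reference measurement (default 4).
#' @param min_baseline_log2cpm optional representation filter: hairpins
#'   whose baseline log2 CPM falls below this value are dropped for that
#'   replicate only (with a warning). Default NULL applies no filter;
#'   hairpins with a non-finite baseline (possible at pseudocount 0) are
#'   always dropped per replicate, since y is undefined for them.
#' @return a data frame of class \code{"fold_change_table"} with columns
#'   \code{hairpin}, \code{gene} (if a library was given),
#'   \code{replicate}, \code{day}, \code{elapsed_days}, \code{y}.
#' @export
fold_change_vs_baseline <- function(norm, samples, library = NULL,
                                    baseline_day = 4,
                                    min_baseline_log2cpm = NULL) {
  stopifnot(nrow(samples) == ncol(norm))
  if (!all(c("sample", "replicate", "day") %in% names(samples)))
    stop("samples needs columns sample, replicate, day")
  out <- list()
  for (rep_id in unique(samples$replicate)) {
    idx <- which(samples$replicate == rep_id)
    b <- idx[samples$day[idx] == baseline_day]
    if (length(b) == 0)
      stop("replicate '", rep_id, "' has no baseline day ", baseline_day)
    b <- b[1]
    keep <- is.finite(norm[, b])
    if (!is.null(min_baseline_log2cpm))
      keep <- keep & norm[, b] >= min_baseline_log2cpm
    if (any(!keep))
      warning(sum(!keep), " hairpin(s) dropped for replicate '", rep_id,
              "': baseline missing or below threshold")
    post <- idx[samples$day[idx] != baseline_day]
    for (j in post) {
      out[[length(out) + 1L]] <- data.frame(
        hairpin = rownames(norm)[keep], replicate = rep_id,
        day = samples$day[j],
        elapsed_days = samples$day[j] - baseline_day,
        y = norm[keep, j] - norm[keep, b],
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  fc <- do.call(rbind, out)
  if (!is.null(library))
    fc$gene <- library$gene[match(fc$hairpin, library$hairpin)]
  fc <- fc[order(fc$hairpin, fc$replicate, fc$day), ]
  rownames(fc) <- NULL
  cols <- c("hairpin", if (!is.null(library)) "gene", "replicate", "day",
            "elapsed_days", "y")
  fc <- fc[, cols]
  attr(fc, "baseline_day") <- baseline_day
  class(fc) <- c("fold_change_table", "data.frame")
  fc
}

#' Library representation QC at a given day
#'
#' Fraction of hairpins whose log2 CPM, averaged across replicates at the
#' chosen day, reaches a representation threshold (default 5 log2 CPM),
#' together with per-replicate fractions. A well-represented library has
#' this fraction above 0.95 at the first measured day.
#'
#' @param norm log2 CPM matrix from [log2_cpm()].
#' @param samples sample metadata (see [fold_change_vs_baseline()]).
#' @param day day at which representation is assessed.
#' @param threshold_log2cpm representation threshold (default 5).
#' @return list with \code{fraction}, \code{per_replicate} (named vector),
#'   \code{day} and \code{threshold}.
#' @export
representation_qc <- function(norm, samples, day = 4,
                              threshold_log2cpm = 5) {
  idx <- which(samples$day == day)
  if (length(idx) == 0) stop("day ", day, " not present in samples")
  m <- norm[, idx, drop = FALSE]
  per_rep <- colMeans(m >= threshold_log2cpm)
  names(per_rep) <- samples$replicate[idx]
  list(fraction = mean(rowMeans(m) >= threshold_log2cpm),
       per_replicate = per_rep, day = day,
       threshold = threshold_log2cpm)
}
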