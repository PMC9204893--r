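#' Filter genes by median read count
#'
#' Keeps genes whose per-gene median count across samples is at least
#' `threshold` (default 32, the discovery-cohort rule). Idempotent; samples
#' are untouched.
#'
#' @param counts raw-count [expression_matrix()].
#' @param threshold minimum median count.
#' @return the filtered matrix, still raw counts.
#' @export
filter_by_median_count <- function(counts, threshold = 32) {
  if (value_kind(counts, "raw_counts") != "raw_counts")
    stop("filter_by_median_count requires raw counts")
  med <- apply(as_plain(counts), 1L, stats::median)
  counts[med >= threshold, , drop = FALSE]
}

#' TMM scaling factors and log2 counts-per-million
#'
#' Library-size normalization by trimmed mean of M-values (30% trim on
#' log-ratios, 5% on average abundance; reference sample = the one whose upper
#' quartile is closest to the mean upper quartile), then
#' `log2(CPM + 0.5)` on effective library sizes (library size x factor).
#' Factors are rescaled to geometric mean 1. Scaling-factor estimation is
#' delegated to `edgeR::calcNormFactors`.
#'
#' @param counts raw-count [expression_matrix()] with at least 2 samples.
#' @param prior pseudo-count added to CPM before the log (default 0.5).
#' @return log-normalized [expression_matrix()] with attribute `tmm_factors`.
#' @export
tmm_log_cpm <- function(counts, prior = 0.5) {
  if (value_kind(counts, "raw_counts") != "raw_counts")
    stop("tmm_log_cpm requires raw counts")
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("all-zero sample: ",
                          paste(colnames(counts)[lib == 0], collapse = ", "))
  f <- edgeR::calcNormFactors(as_plain(counts), method = "TMM",
                              logratioTrim = 0.3, sumTrim = 0.05)
  f <- f / exp(mean(log(f)))
  eff <- lib * f
  out <- log2(t(t(as_plain(counts)) / eff) * 1e6 + prior)
  out <- expression_matrix(out, "log_normalized")
  attr(out, "tmm_factors") <- stats::setNames(f, colnames(counts))
  out
}

#' Empirical-Bayes batch adjustment (ComBat)
#'
#' Parametric location/scale adjustment of a log-normalized matrix with batch
#' as the only design term, via `sva::ComBat`. Genes with zero variance within
#' some batch are dropped with a warning (their batch scale is undefined).
#'
#' @param expr log-normalized [expression_matrix()].
#' @param batch batch label per sample (dataset of origin); every batch needs
#'   at least 2 samples.
#' @return adjusted [expression_matrix()], possibly with fewer genes.
#' @export
combat_adjust <- function(expr, batch) {
  if (value_kind(expr) == "raw_counts")
    stop("combat_adjust expects log-scale input")
  batch <- as.character(batch)
  stopifnot(length(batch) == ncol(expr))
  if (length(unique(batch)) < 2L)
    stop("need at least 2 batches")
  if (any(table(batch) < 2L))
    stop("every batch needs at least 2 samples")
  v_by_batch <- vapply(unique(batch), function(b) {
    m <- as_plain(expr)[, batch == b, drop = FALSE]
    apply(m, 1L, stats::var)
  }, numeric(nrow(expr)))
  bad <- rowSums(v_by_batch == 0) > 0
  if (any(bad)) {
    warning(sum(bad), " gene(s) with zero variance in some batch dropped")
    expr <- expr[!bad, , drop = FALSE]
  }
  adj <- sva::ComBat(dat = as_plain(expr), batch = batch,
                     par.prior = TRUE, prior.plots = FALSE)
  out <- expression_matrix(adj, value_kind(expr))
  out
}

#' Combine expression datasets on their common genes with batch adjustment
#'
#' Intersects gene symbols across all inputs (exact symbol match), concatenates
#' samples, and runs [combat_adjust()] once with dataset of origin as batch.
#' Optionally z-scores each gene afterwards.
#'
#' @param matrices list of log-scale [expression_matrix()] objects.
#' @param ids dataset label per matrix (defaults to list names).
#' @param zscore if `TRUE`, per-gene standardization is applied after the
#'   batch adjustment.
#' @return list with `expr` (combined matrix, kind `scaled` when `zscore`
#'   else `log_normalized`), `batch` (dataset label per sample) and
#'   `n_common_genes`.
#' @export
combine_datasets <- function(matrices, ids = names(matrices), zscore = FALSE) {
  stopifnot(length(matrices) >= 2L)
  if (is.null(ids)) ids <- paste0("D", seq_along(matrices))
  common <- Reduce(intersect, lapply(matrices, rownames))
  if (length(common) == 0L) stop("empty gene intersection across datasets")
  mats <- lapply(matrices, function(m) as_plain(m)[common, , drop = FALSE])
  combined <- do.call(cbind, mats)
  colnames(combined) <- make.unique(unlist(lapply(mats, colnames)), sep = "/")
  batch <- rep(ids, vapply(mats, ncol, 1L))
  expr <- combat_adjust(expression_matrix(combined, "log_normalized"), batch)
  if (zscore) {
    z <- t(scale(t(as_plain(expr))))
    expr <- expression_matrix(z, "scaled")
  }
  list(expr = expr, batch = stats::setNames(batch, colnames(expr)),
       n_common_genes = length(common))
}
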