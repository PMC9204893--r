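#' Parametric per-sample gene-set scores
#'
#' Genes are z-scored across samples; a set's score in a sample is the mean
#' z-score of its present genes times `sqrt(n_present)` (a one-sample z
#' statistic, so a set whose genes all sit 1 sd above their gene means in a
#' sample scores `sqrt(n)`). Sets with fewer than `min_genes` present genes
#' are skipped and listed in the `skipped` attribute.
#'
#' @param expr log-normalized (or scaled) [expression_matrix()].
#' @param sets a [gene_set_collection()].
#' @param min_genes minimum present genes per set.
#' @return sets x samples score matrix of class `set_scores` (attribute
#'   `method = "pgsea"`).
#' @export
pgsea_scores <- function(expr, sets, min_genes = 8) {
  if (!length(sets)) stop("empty gene-set collection")
  x <- as_plain(expr)
  mu <- rowMeans(x)
  sd_ <- apply(x, 1L, stats::sd)
  ok <- sd_ > 0
  z <- (x[ok, , drop = FALSE] - mu[ok]) / sd_[ok]
  present <- lapply(sets, function(s) intersect(s, rownames(z)))
  skipped <- names(sets)[lengths(present) < min_genes]
  keep <- setdiff(names(sets), skipped)
  if (!length(keep)) stop("no set has >= min_genes present genes")
  scores <- t(vapply(keep, function(nm) {
    g <- present[[nm]]
    colMeans(z[g, , drop = FALSE]) * sqrt(length(g))
  }, numeric(ncol(z))))
  dimnames(scores) <- list(keep, colnames(expr))
  structure(scores, method = "pgsea", skipped = skipped,
            class = c("set_scores", "matrix", "array"))
}

# per-gene CDF statistic across samples
ecdf_stat <- function(x, kernel) {
  if (kernel == "rank_ecdf") {
    t(apply(x, 1L, function(r) rank(r, ties.method = "average") / length(r)))
  } else {
    # Gaussian-kernel CDF estimate, bandwidth sd/4 (floor for flat genes)
    t(apply(x, 1L, function(r) {
      h <- max(stats::sd(r) / 4, 1e-8)
      colMeans(stats::pnorm(outer(r, r, function(a, b) (b - a) / h)))
    }))
  }
}

#' Rank-based per-sample gene-set variation scores
#'
#' Each gene's expression is converted to a relative rank statistic across
#' samples by the chosen cumulative-density estimate (`gaussian_ecdf`:
#' Gaussian-kernel CDF; `rank_ecdf`: empirical ranks). Per sample, genes are
#' ordered by the centered statistic and a Kolmogorov-Smirnov-like random walk
#' is taken: set genes step up by their `|statistic|^tau` (normalized over the
#' set), others step down by `1/(n - m)`. The score is the sum of the maximum
#' positive and maximum negative deviation of the walk, hence in `[-1, 1]`;
#' a set concentrated at the top of a sample's ranking scores near +1, its
#' complement near -1.
#'
#' @param expr [expression_matrix()] with >= 3 samples.
#' @param sets a [gene_set_collection()].
#' @param tau rank-weight exponent.
#' @param kernel `"gaussian_ecdf"` or `"rank_ecdf"`.
#' @param min_genes sets with fewer present genes are skipped.
#' @return sets x samples matrix of class `set_scores` (attribute
#'   `method = "gsva"`).
#' @export
gsva_scores <- function(expr, sets, tau = 1,
                        kernel = c("gaussian_ecdf", "rank_ecdf"),
                        min_genes = 1) {
  kernel <- match.arg(kernel)
  if (ncol(expr) < 3L) stop("need >= 3 samples")
  x <- as_plain(expr)
  stat <- ecdf_stat(x, kernel) - 0.5
  rownames(stat) <- rownames(x)
  n <- nrow(stat)
  present <- lapply(sets, function(s) intersect(s, rownames(stat)))
  keep <- names(sets)[lengths(present) >= max(min_genes, 1L) &
                        lengths(present) < n]
  if (!length(keep)) stop("no scorable gene set")
  scores <- matrix(0, length(keep), ncol(x),
                   dimnames = list(keep, colnames(x)))
  for (j in seq_len(ncol(x))) {
    sj <- stat[, j]
    ord <- order(-sj, rownames(stat))
    genes_ord <- rownames(stat)[ord]
    w_all <- abs(sj[ord])^tau
    for (nm in keep) {
      inset <- genes_ord %in% present[[nm]]
      m <- sum(inset)
      wset <- w_all * inset
      denom <- sum(wset)
      if (denom == 0) { scores[nm, j] <- 0; next }
      steps <- ifelse(inset, wset / denom, -1 / (n - m))
      walk <- cumsum(steps)
      scores[nm, j] <- max(c(0, walk)) + min(c(0, walk))
    }
  }
  structure(scores, method = "gsva",
            class = c("set_scores", "matrix", "array"))
}

#' Filter gene sets against a signature
#'
#' Keeps sets that share at least `ceiling(min_frac * |signature|)` genes with
#' the signature and have strictly fewer than `max_size` genes.
#'
#' @param sets a [gene_set_collection()].
#' @param signature a `signature_spec` (or character vector of genes).
#' @param min_frac minimum shared fraction of the signature.
#' @param max_size strict upper bound on set size.
#' @return list with `sets` (the filtered collection) and `report`
#'   (data.frame: set, size, overlap, pass, reason).
#' @export
filter_sets <- function(sets, signature, min_frac = 0.05, max_size = 600) {
  sig <- if (inherits(signature, "signature_spec")) signature$genes
         else as.character(signature)
  if (!length(sig)) stop("empty signature")
  need <- ceiling(min_frac * length(sig))
  size <- lengths(sets)
  overlap <- vapply(sets, function(s) length(intersect(s, sig)), 0L)
  pass <- overlap >= need & size < max_size
  reason <- rep("", length(sets))
  reason[overlap < need] <- sprintf("overlap %d < %d", overlap[overlap < need],
                                    need)
  too_big <- size >= max_size
  reason[too_big] <- paste0(reason[too_big],
                            ifelse(nzchar(reason[too_big]), "; ", ""),
                            sprintf("size %d >= %d", size[too_big], max_size))
  report <- data.frame(set = names(sets), size = size, overlap = overlap,
                       pass = pass, reason = reason, row.names = NULL)
  kept <- sets[pass]
  out_sets <- if (length(kept))
    gene_set_collection(kept, attr(sets, "collection_name")) else list()
  list(sets = out_sets, report = report, overlap_threshold = need)
}

#' Jaccard dissimilarity and hierarchical clustering of gene sets
#'
#' `d(A, B) = 1 - |intersect| / |union|`, clustered with complete linkage.
#' Sets are ordered by name first so that distance ties resolve
#' deterministically.
#'
#' @param sets a [gene_set_collection()] with >= 2 sets.
#' @return list with `dissimilarity` (matrix) and `hclust` (the dendrogram).
#' @export
jaccard_cluster <- function(sets) {
  stopifnot(length(sets) >= 2L)
  sets <- sets[order(names(sets))]
  n <- length(sets)
  d <- matrix(0, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- sets[[i]]; b <- sets[[j]]
    d[i, j] <- d[j, i] <- 1 - length(intersect(a, b)) / length(union(a, b))
  }
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  list(dissimilarity = d, hclust = hc)
}

#' Group-difference tests on per-sample set scores
#'
#' Per set, a Welch two-sample test of the scores between the two groups,
#' Bonferroni-adjusted across the tested sets; the fold-change measure is the
#' difference of group mean scores (first level minus second). Sets with
#' degenerate variance fall back to exact equality (p = 1 when the group means
#' are equal, else p = 0).
#'
#' @param scores a `set_scores` matrix (sets x samples).
#' @param groups two-level label per sample.
#' @param fc_threshold absolute mean-difference threshold for the `pass` flag.
#' @param alpha significance level on the Bonferroni-adjusted p.
#' @return `data.frame`: set, mean_diff, pvalue, bonferroni, bh, pass.
#' @export
test_set_scores <- function(scores, groups, fc_threshold = 5.0, alpha = 0.05) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2L, ncol(scores) == length(groups))
  if (any(table(groups) < 3L)) stop("need >= 3 samples per group")
  ia <- groups == levels(groups)[1L]
  res <- t(apply(scores, 1L, function(s) {
    a <- s[ia]; b <- s[!ia]
    diff <- mean(a) - mean(b)
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      p <- if (abs(diff) < 1e-12) 1 else 0
    } else {
      p <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
    }
    c(diff, p)
  }))
  out <- data.frame(set = rownames(scores), mean_diff = res[, 1L],
                    pvalue = res[, 2L],
                    bonferroni = pmin(1, res[, 2L] * nrow(scores)),
                    bh = stats::p.adjust(res[, 2L], "BH"), row.names = NULL)
  out$pass <- out$bonferroni <= alpha & abs(out$mean_diff) > fc_threshold
  out
}

#' Median set scores per group (immunogram table)
#'
#' Per-group median score for each requested set plus their difference, ready
#' for radial/bar plotting elsewhere.
#'
#' @param scores a `set_scores` matrix.
#' @param groups label per sample.
#' @param sets_subset set names to report (default all rows).
#' @return `data.frame`: set, one median column per group, diff (first group
#'   minus second).
#' @export
immunogram_table <- function(scores, groups, sets_subset = rownames(scores)) {
  stopifnot(all(sets_subset %in% rownames(scores)))
  groups <- factor(groups)
  med <- vapply(levels(groups), function(g)
    apply(scores[sets_subset, groups == g, drop = FALSE], 1L, stats::median),
    numeric(length(sets_subset)))
  med <- matrix(med, nrow = length(sets_subset),
                dimnames = list(sets_subset, levels(groups)))
  out <- data.frame(set = sets_subset, med, check.names = FALSE,
                    row.names = NULL)
  if (nlevels(groups) == 2L) out$diff <- med[, 1L] - med[, 2L]
  out
}
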