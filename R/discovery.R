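#' Genes correlated with an anchor gene
#'
#' Ranks all other genes by absolute correlation with the anchor's expression
#' across samples and returns those passing an `|r|` cutoff, or the strongest
#' `top_n`. Output is sorted by `|r|` descending, ties broken by symbol order.
#'
#' @param expr log-normalized [expression_matrix()].
#' @param anchor anchor gene symbol (e.g. `"AR"`); must be present.
#' @param method `"pearson"` or `"spearman"`.
#' @param threshold minimum `|r|` (used when `top_n` is `NULL`).
#' @param top_n if given, return exactly the `top_n` highest-`|r|` genes.
#' @return character vector of gene symbols with attribute `r` (signed
#'   correlations).
#' @export
select_anchor_correlated <- function(expr, anchor = "AR",
                                     method = c("pearson", "spearman"),
                                     threshold = 0.5, top_n = NULL) {
  method <- match.arg(method)
  if (!anchor %in% rownames(expr))
    stop("anchor gene ", anchor, " not present")
  x <- as_plain(expr)
  r <- suppressWarnings(
    stats::cor(x[anchor, ], t(x[rownames(x) != anchor, , drop = FALSE]),
               method = method))[1L, ]
  r[is.na(r)] <- 0
  ord <- order(-abs(r), names(r))
  r <- r[ord]
  keep <- if (is.null(top_n)) which(abs(r) >= threshold)
          else seq_len(min(top_n, length(r)))
  structure(names(r)[keep], r = r[keep])
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums((x - x[rep(centers[1L], n), , drop = FALSE])^2)
  for (i in seq_len(k - 1L)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[i + 1L] <- sample.int(n, 1L, prob = p)
    d2 <- pmin(d2, rowSums((x - x[rep(centers[i + 1L], n), , drop = FALSE])^2))
  }
  x[centers, , drop = FALSE]
}

#' Scan cluster numbers by k-means and average silhouette width
#'
#' Samples are clustered on the z-scored gene subset (genes standardized
#' across samples, Euclidean distance) with k-means under k-means++ seeding
#' and `n_init` restarts per k. The best k maximizes the average silhouette
#' width; ties go to the smaller k.
#'
#' @param expr log-normalized [expression_matrix()].
#' @param genes gene subset to cluster on (default: all genes).
#' @param k_min,k_max range of cluster numbers scanned.
#' @param n_init random restarts per k.
#' @param seed RNG seed for the restarts.
#' @return list of class `cluster_scan`: `k`, `avg_sil_width`, `best_k`,
#'   `labels` (samples x k matrix), `cluster_sil` (per-cluster average widths
#'   at each k).
#' @export
scan_kmeans <- function(expr, genes = rownames(expr), k_min = 2, k_max = 10,
                        n_init = 50, seed = 1) {
  if (ncol(expr) <= k_max)
    stop("k_max must be smaller than the number of samples")
  restore <- local_seed(seed); on.exit(restore())
  x <- as_plain(expr)[genes, , drop = FALSE]
  sds <- apply(x, 1L, stats::sd)
  if (all(sds == 0)) stop("zero-variance input")
  x <- x[sds > 0, , drop = FALSE]
  pts <- t((x - rowMeans(x)) / apply(x, 1L, stats::sd))
  d <- stats::dist(pts)
  ks <- k_min:k_max
  labels <- matrix(NA_integer_, ncol(expr), length(ks),
                   dimnames = list(colnames(expr), paste0("k", ks)))
  asw <- numeric(length(ks))
  cluster_sil <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    best <- NULL
    for (rep in seq_len(n_init)) {
      fit <- suppressWarnings(
        stats::kmeans(pts, centers = kmeanspp_centers(pts, k),
                      iter.max = 100))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    labels[, i] <- best$cluster
    sil <- cluster::silhouette(best$cluster, d)
    asw[i] <- mean(sil[, "sil_width"])
    cluster_sil[[i]] <- tapply(sil[, "sil_width"], sil[, "cluster"], mean)
  }
  best_k <- ks[which.max(asw)]  # which.max takes the first, i.e. smaller k
  structure(list(k = ks, avg_sil_width = stats::setNames(asw, paste0("k", ks)),
                 best_k = best_k, labels = labels,
                 cluster_sil = stats::setNames(cluster_sil, paste0("k", ks))),
            class = "cluster_scan")
}

#' @export
print.cluster_scan <- function(x, ...) {
  cat("k-means / silhouette scan\n")
  print(round(x$avg_sil_width, 3))
  cat("best k:", x$best_k, "\n")
  invisible(x)
}

#' Explained-variance fractions of the principal components
#'
#' PCA of samples on the gene-centered expression submatrix; returns the
#' fraction of variance carried by each component (fractions sum to 1).
#'
#' @param expr [expression_matrix()].
#' @param genes gene subset (default all).
#' @return numeric vector of fractions.
#' @export
pca_variance <- function(expr, genes = rownames(expr)) {
  x <- t(as_plain(expr)[genes, , drop = FALSE])
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  v / sum(v)
}

# conditional (count-sum) NB log-likelihood of one group with equalized
# library sizes, dropping phi-free terms; y may be non-integer pseudo-counts
cond_ll_group <- function(y, r) {
  n <- length(y)
  z <- sum(y)
  sum(lgamma(y + r)) - n * lgamma(r) + lgamma(n * r) - lgamma(z + n * r)
}

cond_ll_gene <- function(y1, y2, phi) {
  r <- 1 / phi
  cond_ll_group(y1, r) + cond_ll_group(y2, r)
}

# two-sided exact NB test: condition the group-1 sum on the total, sum the
# probabilities of outcomes no more likely than the observed one
nb_exact_pvalue <- function(z1, z2, n1, n2, phi) {
  r <- max(1 / max(phi, 1e-8), 1e-8)
  r1 <- n1 * r; r2 <- n2 * r
  t_tot <- z1 + z2
  a <- 0:t_tot
  logp <- lgamma(a + r1) - lgamma(a + 1) + lgamma(t_tot - a + r2) -
    lgamma(t_tot - a + 1)
  logp <- logp - max(logp)
  p <- exp(logp); p <- p / sum(p)
  sum(p[p <= p[z1 + 1L] * (1 + 1e-8)])
}

#' Negative-binomial exact differential expression test
#'
#' Small-sample count DE between two groups: TMM effective library sizes are
#' equalized to their geometric mean by rescaling to pseudo-counts, a common
#' dispersion is estimated by maximizing the conditional (count-sum)
#' likelihood summed over genes, tagwise dispersions are shrunk toward it by
#' weighted likelihood (`prior_df` prior degrees of freedom), and each gene is
#' tested by the exact conditional distribution of the group-A pseudo-count
#' sum given the total. Fold changes use a 0.125 prior count per library.
#'
#' @param counts raw-count [expression_matrix()], already filtered.
#' @param labels two-level group factor over samples. The reported log2 fold
#'   change is second level versus first.
#' @param prior_df prior degrees of freedom for the tagwise shrinkage.
#' @param prior_count prior count per library for fold-change stability.
#' @return `data.frame` of class `de_result`: `gene`, `log2fc`, `pvalue`,
#'   `bonferroni`, `bh`, `mean_a`, `mean_b`, `dispersion`, plus attribute
#'   `common_dispersion`.
#' @export
nb_exact_de <- function(counts, labels, prior_df = 10, prior_count = 0.125) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
  if (any(table(labels) < 2L)) stop("both groups need >= 2 samples")
  stopifnot(length(labels) == ncol(counts))
  x <- as_plain(counts)
  lib <- colSums(x)
  f <- edgeR::calcNormFactors(x, method = "TMM")
  eff <- lib * f
  N <- exp(mean(log(eff)))
  pseudo <- t(t(x) * (N / eff))  # equalized libraries
  ia <- labels == levels(labels)[1L]
  ib <- !ia
  n1 <- sum(ia); n2 <- sum(ib)

  ll_all <- function(phi)
    sum(vapply(seq_len(nrow(pseudo)), function(g)
      cond_ll_gene(pseudo[g, ia], pseudo[g, ib], phi), 0))
  common <- stats::optimize(function(lp) -ll_all(exp(lp)),
                            interval = c(log(1e-4), log(4)))$minimum
  common_phi <- exp(common)

  n_genes <- nrow(pseudo)
  # weighted-likelihood tagwise shrinkage toward the common value
  prior_n <- prior_df / max(n1 + n2 - 2L, 1L)
  ll_bar <- function(phi) ll_all(phi) / n_genes
  grid <- exp(seq(log(1e-4), log(4), length.out = 25))
  bar_on_grid <- vapply(grid, ll_bar, 0)
  disp <- vapply(seq_len(n_genes), function(g) {
    obj <- vapply(seq_along(grid), function(i)
      cond_ll_gene(pseudo[g, ia], pseudo[g, ib], grid[i]) +
        prior_n * bar_on_grid[i], 0)
    grid[which.max(obj)]
  }, 0)

  z1 <- round(rowSums(pseudo[, ia, drop = FALSE]))
  z2 <- round(rowSums(pseudo[, ib, drop = FALSE]))
  pval <- vapply(seq_len(n_genes), function(g)
    nb_exact_pvalue(z1[g], z2[g], n1, n2, disp[g]), 0)
  pval <- pmin(pval, 1)

  mean_a <- rowMeans(pseudo[, ia, drop = FALSE])
  mean_b <- rowMeans(pseudo[, ib, drop = FALSE])
  log2fc <- log2((mean_b + prior_count) / (mean_a + prior_count))
  out <- data.frame(gene = rownames(x), log2fc = log2fc, pvalue = pval,
                    bonferroni = pmin(1, pval * n_genes),
                    bh = stats::p.adjust(pval, "BH"),
                    mean_a = mean_a, mean_b = mean_b, dispersion = disp,
                    row.names = NULL)
  attr(out, "common_dispersion") <- common_phi
  attr(out, "groups") <- levels(labels)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Assemble a signature gene list from a differential-expression result
#'
#' Keeps genes with `|log2fc|` strictly above `min_abs_log2fc` and adjusted
#' p-value at most `alpha`. Genes are ordered by absolute fold change
#' (descending), ties by symbol.
#'
#' @param de a `de_result` from [nb_exact_de()].
#' @param min_abs_log2fc fold-change threshold (strict).
#' @param alpha significance level on the adjusted p-value.
#' @param correction `"bonferroni"` or `"bh"`.
#' @param provenance free-form provenance record stored with the signature.
#' @return list of class `signature_spec` with `genes`, `thresholds`,
#'   `provenance`.
#' @export
build_signature <- function(de, min_abs_log2fc = 2, alpha = 0.05,
                            correction = c("bonferroni", "bh"),
                            provenance = list()) {
  correction <- match.arg(correction)
  padj <- de[[correction]]
  keep <- abs(de$log2fc) > min_abs_log2fc & padj <= alpha
  if (!any(keep)) warning("no genes pass the signature thresholds")
  sub <- de[keep, , drop = FALSE]
  sub <- sub[order(-abs(sub$log2fc), sub$gene), , drop = FALSE]
  structure(list(genes = sub$gene,
                 thresholds = list(min_abs_log2fc = min_abs_log2fc,
                                   alpha = alpha, correction = correction),
                 provenance = provenance),
            class = "signature_spec")
}

#' @export
print.signature_spec <- function(x, ...) {
  cat(sprintf("signature_spec: %d genes (|log2FC| > %g, %s p <= %g)\n",
              length(x$genes), x$thresholds$min_abs_log2fc,
              x$thresholds$correction, x$thresholds$alpha))
  invisible(x)
}
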