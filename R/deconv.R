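#' Balanced single-cell reference: k nearest neighbors per type centroid
#'
#' For each cell type, computes the type centroid in the chosen space (the
#' provided 2-D embedding, or the top principal components of log-normalized
#' expression) and keeps the k same-type cells nearest to it (Euclidean
#' distance, ties broken by cell id order). The output always has exactly
#' `k * n_types` cells, so rare and abundant types contribute equally to the
#' signature.
#'
#' @param sc raw-count [expression_matrix()], cells as columns.
#' @param cell_types type label per cell.
#' @param k neighbors kept per type; every type needs at least `k` cells.
#' @param embedding optional cells x 2 coordinate matrix; when `NULL`, the top
#'   `n_pcs` PCs of log1p counts-per-10k are used.
#' @param n_pcs principal components for the expression-space fallback.
#' @return character vector of selected cell ids.
#' @export
build_balanced_reference <- function(sc, cell_types, k = 80, embedding = NULL,
                                     n_pcs = 20) {
  cell_types <- as.character(cell_types)
  stopifnot(length(cell_types) == ncol(sc))
  sizes <- table(cell_types)
  if (any(sizes < k))
    stop("type(s) with fewer than k cells: ",
         paste(names(sizes)[sizes < k], collapse = ", "))
  ids <- colnames(sc)
  if (is.null(embedding)) {
    cp10k <- t(t(as_plain(sc)) / pmax(colSums(sc), 1)) * 1e4
    x <- log1p(t(cp10k))
    keep <- apply(x, 2L, stats::sd) > 0
    pc <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = FALSE,
                        rank. = min(n_pcs, ncol(sc) - 1L))
    space <- pc$x
  } else {
    stopifnot(nrow(embedding) == ncol(sc))
    space <- as.matrix(embedding)
  }
  rownames(space) <- ids
  selected <- character(0)
  for (tp in sort(unique(cell_types))) {
    members <- ids[cell_types == tp]
    pts <- space[members, , drop = FALSE]
    centroid <- colMeans(pts)
    d <- sqrt(rowSums((pts - matrix(centroid, nrow(pts), ncol(pts),
                                    byrow = TRUE))^2))
    ord <- order(d, members)
    selected <- c(selected, members[ord][seq_len(k)])
  }
  selected
}

# Michaelis-Menten dropout reference curve: zhat(mu) = K / (mu + K)
fit_dropout_curve <- function(mu, z) {
  sse <- function(K) sum((z - K / (mu + K))^2)
  stats::optimize(sse, interval = c(1e-6, 1e3))$minimum
}

#' Select genes by excess dropout at high mean expression
#'
#' Computes, per gene, the mean expression `mu_g = log1p(mean count)` and the
#' dropout fraction `z_g` (share of zero cells), fits the reference curve
#' `zhat(mu) = K / (mu + K)` by least squares, and keeps genes with
#' `mu_g >= a` and `z_g >= min(1, b * zhat(mu_g))` — i.e. genes that stay
#' frequently zero despite a high mean, the informative regime for
#' deconvolution references. With `target_n`, the genes passing the mean gate
#' are ranked by dropout excess `z_g - zhat(mu_g)` and the top `target_n`
#' returned.
#'
#' @param sc raw-count [expression_matrix()], cells as columns.
#' @param a mean gate on the `log1p` scale.
#' @param b multiplicative dropout-excess gate.
#' @param target_n optional fixed output size.
#' @return character vector of gene symbols, with attributes `K` (fitted
#'   curve constant) and `stats` (per-gene mu, z, zhat).
#' @export
dropout_feature_filter <- function(sc, a = 1.5, b = 1.1, target_n = NULL) {
  if (value_kind(sc, "raw_counts") != "raw_counts")
    stop("dropout_feature_filter requires raw counts")
  x <- as_plain(sc)
  mu <- log1p(rowMeans(x))
  z <- rowMeans(x == 0)
  if (stats::sd(z) == 0) {
    warning("degenerate dropout fit (all dropout fractions equal); ",
            "falling back to the mean-only filter")
    keep <- which(mu >= a)
    genes <- names(sort(mu[keep], decreasing = TRUE))
    if (!is.null(target_n)) genes <- genes[seq_len(min(target_n, length(genes)))]
    return(genes)
  }
  K <- fit_dropout_curve(mu, z)
  zhat <- K / (mu + K)
  pass_mean <- mu >= a
  if (is.null(target_n)) {
    keep <- pass_mean & z >= pmin(1, b * zhat)
    genes <- rownames(x)[keep]
    genes <- genes[order(-(z - zhat)[keep], genes)]
  } else {
    cand <- rownames(x)[pass_mean]
    cand <- cand[order(-(z - zhat)[pass_mean], cand)]
    genes <- cand[seq_len(min(target_n, length(cand)))]
  }
  structure(genes, K = K,
            stats = data.frame(gene = rownames(x), mu = mu, z = z,
                               zhat = zhat, row.names = NULL))
}

#' Assemble a cell-type signature matrix from a balanced reference
#'
#' Each cell is normalized to counts per 10k; per-type profiles are the
#' `expm1` of the per-type mean of `log1p` normalized expression (a
#' depth-robust geometric-style average), over the requested genes. Genes zero
#' in every type are dropped.
#'
#' @param sc raw-count [expression_matrix()] (typically the balanced subset).
#' @param cell_types type label per cell.
#' @param genes gene list (typically from [dropout_feature_filter()]).
#' @return genes x types matrix of class `signature_matrix`, with attribute
#'   `n_cells` (cells per type used).
#' @export
build_signature_matrix <- function(sc, cell_types, genes = rownames(sc)) {
  cell_types <- as.character(cell_types)
  stopifnot(length(cell_types) == ncol(sc))
  genes <- intersect(genes, rownames(sc))
  if (!length(genes)) stop("empty gene list")
  cp10k <- t(t(as_plain(sc)) / pmax(colSums(sc), 1)) * 1e4
  lg <- log1p(cp10k[genes, , drop = FALSE])
  types <- sort(unique(cell_types))
  sig <- vapply(types, function(tp)
    expm1(rowMeans(lg[, cell_types == tp, drop = FALSE])),
    numeric(length(genes)))
  sig <- matrix(sig, nrow = length(genes),
                dimnames = list(genes, types))
  keep <- rowSums(sig) > 0
  sig <- sig[keep, , drop = FALSE]
  structure(sig, n_cells = table(cell_types),
            class = c("signature_matrix", "matrix", "array"))
}

solve_nnls_fractions <- function(X, y) {
  # intercept profiled out by centering; coefficients stay non-negative
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  fit <- pracma::lsqnonneg(Xc, yc)
  list(coef = fit$x, fitted = as.vector(Xc %*% fit$x) + mean(y))
}

solve_nusvr_fractions <- function(X, y, nus = c(0.25, 0.5, 0.75)) {
  best <- NULL
  for (nu in nus) {
    fit <- e1071::svm(x = X, y = y, type = "nu-regression",
                      kernel = "linear", nu = nu, scale = FALSE)
    w <- as.vector(t(fit$coefs) %*% fit$SV)
    fitted <- as.vector(stats::predict(fit, X))
    w[w < 0] <- 0
    rmse <- sqrt(mean((y - fitted)^2))
    if (is.null(best) || rmse < best$rmse)
      best <- list(coef = w, fitted = fitted, rmse = rmse, nu = nu)
  }
  best
}

#' Estimate cell-type fractions of bulk samples from a signature matrix
#'
#' Per sample, the bulk profile and the signature matrix are z-scored over
#' their shared genes (the bulk by its own mean/sd, so any common positive
#' scaling of a sample cancels; the signature by its overall mean/sd) and the
#' mixture is regressed on the signature columns by non-negative least squares
#' or by linear nu-support-vector regression (nu chosen from {0.25, 0.5, 0.75}
#' by lowest root-mean-square error, negative coefficients zeroed).
#' Coefficients are normalized to fractions summing to 1.
#'
#' @param bulk [expression_matrix()], samples as columns.
#' @param sig a `signature_matrix`.
#' @param method `"nnls"` or `"nu_svr"`.
#' @param min_overlap minimum fraction of signature genes that must be present
#'   in the bulk data.
#' @return list of class `mixture_fractions`: `fractions` (samples x types),
#'   `diagnostics` (per-sample RMSE and correlation of fitted vs observed),
#'   `method`, `n_shared_genes`.
#' @export
deconvolve <- function(bulk, sig, method = c("nnls", "nu_svr"),
                       min_overlap = 0.3) {
  method <- match.arg(method)
  shared <- intersect(rownames(sig), rownames(bulk))
  if (length(shared) < min_overlap * nrow(sig))
    stop(sprintf("gene overlap below threshold: %d of %d signature genes",
                 length(shared), nrow(sig)))
  X <- as_plain(sig)[shared, , drop = FALSE]
  X <- (X - mean(X)) / stats::sd(X)
  B <- as_plain(bulk)[shared, , drop = FALSE]
  types <- colnames(sig)
  frac <- matrix(0, ncol(B), length(types),
                 dimnames = list(colnames(B), types))
  diag_df <- data.frame(sample_id = colnames(B), rmse = NA_real_,
                        correlation = NA_real_)
  for (s in seq_len(ncol(B))) {
    y <- B[, s]
    y <- (y - mean(y)) / stats::sd(y)
    fit <- if (method == "nnls") solve_nnls_fractions(X, y)
           else solve_nusvr_fractions(X, y)
    w <- fit$coef
    frac[s, ] <- if (sum(w) > 0) w / sum(w) else rep(1 / length(types),
                                                     length(types))
    diag_df$rmse[s] <- sqrt(mean((y - fit$fitted)^2))
    diag_df$correlation[s] <- suppressWarnings(stats::cor(y, fit$fitted))
  }
  structure(list(fractions = frac, diagnostics = diag_df, method = method,
                 n_shared_genes = length(shared)),
            class = "mixture_fractions")
}

#' @export
print.mixture_fractions <- function(x, ...) {
  cat(sprintf("mixture_fractions: %d samples x %d cell types (%s, %d genes)\n",
              nrow(x$fractions), ncol(x$fractions), x$method,
              x$n_shared_genes))
  invisible(x)
}

#' Moderated group test of cell-type abundance
#'
#' Per cell type, an ordinary least-squares fit of fraction on the group
#' indicator with limma empirical-Bayes variance moderation across cell types
#' (moderated t, two-sided p, Benjamini-Hochberg adjustment). Cell types with
#' constant fractions are flagged and given p = 1.
#'
#' @param fractions a `mixture_fractions` or a samples x types matrix.
#' @param groups two-level label per sample; the reported effect is second
#'   level minus first.
#' @return `data.frame`: cell_type, effect, t, pvalue, adj_pvalue, flagged.
#' @export
test_abundance <- function(fractions, groups) {
  f <- if (inherits(fractions, "mixture_fractions")) fractions$fractions
       else as.matrix(fractions)
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2L, nrow(f) == length(groups))
  if (any(table(groups) < 3L)) stop("need >= 3 samples per group")
  y <- t(f)                               # cell types as rows
  design <- stats::model.matrix(~groups)
  fit <- limma::eBayes(limma::lmFit(y, design))
  tt <- limma::topTable(fit, coef = 2L, number = Inf, sort.by = "none")
  flagged <- apply(y, 1L, function(r) stats::var(r) == 0)
  p <- tt$P.Value
  p[flagged | is.na(p)] <- 1
  data.frame(cell_type = rownames(y), effect = tt$logFC, t = tt$t,
             pvalue = p, adj_pvalue = stats::p.adjust(p, "BH"),
             flagged = flagged, row.names = NULL)
}
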