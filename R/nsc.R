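new_nsc_model <- function(genes, classes, centroids, overall_centroid,
                          pooled_sd, s0, delta, dprime, priors, n_per_class,
                          cv = NULL) {
  structure(list(genes = genes, classes = classes, centroids = centroids,
                 overall_centroid = overall_centroid, pooled_sd = pooled_sd,
                 s0 = s0, delta = delta, dprime = dprime, priors = priors,
                 n_per_class = n_per_class, cv = cv),
            class = "nsc_model")
}

m_k_factor <- function(n_per_class) {
  n <- sum(n_per_class)
  sqrt(1 / n_per_class - 1 / n)
}

# shrunken class centroids reconstructed from the stored pieces
shrunken_centroids <- function(model) {
  mk <- m_k_factor(model$n_per_class)
  sw <- model$pooled_sd + model$s0
  model$overall_centroid + sweep(model$dprime, 2L, mk, `*`) * sw
}

#' Train a nearest-shrunken-centroid classifier
#'
#' Standardized class-vs-overall centroid differences
#' `d_kj = (xbar_kj - xbar_j) / (m_k (s_j + s0))` are soft-thresholded by the
#' shrinkage `delta`; genes whose differences shrink to zero in every class
#' drop out of the discriminant. `s_j` is the pooled within-class standard
#' deviation, `s0` its median (guards near-zero-variance genes),
#' `m_k = sqrt(1/n_k - 1/n)`. With `delta = "cv"` the shrinkage is chosen by
#' stratified K-fold cross-validated error over a 30-point grid from 0 to
#' `max |d_kj|`, ties resolved toward the larger (sparser) value.
#'
#' @param expr log-normalized [expression_matrix()] restricted to (or
#'   containing) the signature genes.
#' @param labels class label per sample (e.g. LAR / non-LAR); >= 2 per class.
#' @param delta non-negative shrinkage, or `"cv"`.
#' @param genes genes to train on (default all rows).
#' @param priors class prior probabilities; default training proportions.
#' @param cv_folds,seed cross-validation folds and fold-assignment seed.
#' @return an `nsc_model`.
#' @export
train_nsc <- function(expr, labels, delta = 0, genes = rownames(expr),
                      priors = NULL, cv_folds = 10, seed = 1) {
  labels <- factor(labels)
  stopifnot(length(labels) == ncol(expr))
  if (any(table(labels) < 2L)) stop("every class needs >= 2 samples")
  x <- as_plain(expr)[genes, , drop = FALSE]
  classes <- levels(labels)
  n_per_class <- as.integer(table(labels))
  names(n_per_class) <- classes
  n <- sum(n_per_class)
  if (is.null(priors)) priors <- n_per_class / n
  priors <- priors / sum(priors)

  centroids <- vapply(classes, function(k)
    rowMeans(x[, labels == k, drop = FALSE]), numeric(nrow(x)))
  overall <- rowMeans(x)
  ss <- 0
  for (k in classes) {
    xk <- x[, labels == k, drop = FALSE]
    ss <- ss + rowSums((xk - centroids[, k])^2)
  }
  pooled_sd <- sqrt(ss / (n - length(classes)))
  if (any(pooled_sd == 0))
    warning(sum(pooled_sd == 0), " zero-variance gene(s); s0 guards them")
  s0 <- stats::median(pooled_sd)
  mk <- m_k_factor(n_per_class)
  d <- sweep(centroids - overall, 1L, pooled_sd + s0, `/`)
  d <- sweep(d, 2L, mk, `/`)

  cv <- NULL
  if (identical(delta, "cv")) {
    grid <- seq(0, max(abs(d)), length.out = 30)
    cv <- cv_nsc_delta(x, labels, grid, priors, cv_folds, seed)
    delta <- cv$best_delta
  }
  stopifnot(is.numeric(delta), delta >= 0)
  dprime <- sign(d) * pmax(abs(d) - delta, 0)
  new_nsc_model(genes = rownames(x), classes = classes, centroids = centroids,
                overall_centroid = overall, pooled_sd = pooled_sd, s0 = s0,
                delta = delta, dprime = dprime,
                priors = stats::setNames(as.numeric(priors), classes),
                n_per_class = n_per_class, cv = cv)
}

cv_nsc_delta <- function(x, labels, grid, priors, folds, seed) {
  restore <- local_seed(seed); on.exit(restore())
  fold_id <- integer(length(labels))
  for (k in levels(labels)) {        # stratified fold assignment
    idx <- which(labels == k)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  n_eval <- 0L
  errs <- numeric(length(grid))
  for (f in seq_len(folds)) {
    test <- fold_id == f
    if (!any(test) || any(table(labels[!test]) < 2L)) next
    fit0 <- train_nsc(expression_matrix(x[, !test, drop = FALSE],
                                        "log_normalized"),
                      labels[!test], delta = 0, priors = priors)
    for (i in seq_along(grid)) {
      fit0$delta <- grid[i]
      d <- sweep(fit0$centroids - fit0$overall_centroid, 1L,
                 fit0$pooled_sd + fit0$s0, `/`)
      d <- sweep(d, 2L, m_k_factor(fit0$n_per_class), `/`)
      fit0$dprime <- sign(d) * pmax(abs(d) - grid[i], 0)
      pred <- predict(fit0, expression_matrix(x[, test, drop = FALSE],
                                              "log_normalized"))
      errs[i] <- errs[i] + sum(pred$label != as.character(labels[test]))
    }
    n_eval <- n_eval + sum(test)
  }
  errs <- errs / n_eval
  best <- max(grid[errs == min(errs)])  # ties -> larger delta
  list(grid = grid, cv_error = errs, best_delta = best)
}

#' Classify samples with a shrunken-centroid model
#'
#' Discriminant `delta_k(x) = sum_j (x_j - xbar'_kj)^2 / (s_j + s0)^2 -
#' 2 log pi_k` over the model genes present in the data; posterior
#' probabilities are proportional to `exp(-delta_k / 2)`. Model genes missing
#' from the data are dropped from the discriminant (an error below 50%
#' coverage). Discriminant ties are broken toward non-LAR when that class is
#' present, otherwise toward the later class label.
#'
#' @param object an `nsc_model`.
#' @param expr [expression_matrix()] of samples to classify.
#' @param min_coverage minimum fraction of model genes required.
#' @param ... unused.
#' @return `data.frame` of class `subtype_calls`: `sample_id`, `label`,
#'   one discriminant and one posterior column per class.
#' @export
predict.nsc_model <- function(object, expr, min_coverage = 0.5, ...) {
  shared <- intersect(object$genes, rownames(expr))
  if (length(shared) < min_coverage * length(object$genes))
    stop(sprintf("insufficient signature coverage: %d of %d genes",
                 length(shared), length(object$genes)))
  if (length(shared) < length(object$genes))
    message(sprintf("dropping %d model gene(s) absent from the data",
                    length(object$genes) - length(shared)))
  cent <- shrunken_centroids(object)[shared, , drop = FALSE]
  sw <- (object$pooled_sd + object$s0)[shared]
  x <- as_plain(expr)[shared, , drop = FALSE]
  disc <- vapply(object$classes, function(k)
    colSums(((x - cent[, k]) / sw)^2) - 2 * log(object$priors[k]),
    numeric(ncol(x)))
  disc <- matrix(disc, ncol = length(object$classes),
                 dimnames = list(colnames(expr), object$classes))
  post <- exp(-(disc - apply(disc, 1L, min)) / 2)
  post <- post / rowSums(post)
  # tie-break order: non-LAR (conservative) ahead of LAR, else later label
  pref <- if ("non-LAR" %in% object$classes)
    order(object$classes != "non-LAR") else rev(seq_along(object$classes))
  label <- object$classes[pref][apply(disc[, pref, drop = FALSE], 1L,
                                      which.min)]
  out <- data.frame(sample_id = colnames(expr), label = label,
                    row.names = NULL)
  colnames(disc) <- paste0("disc_", object$classes)
  colnames(post) <- paste0("post_", object$classes)
  out <- cbind(out, disc, post)
  class(out) <- c("subtype_calls", "data.frame")
  out
}

#' @rdname predict.nsc_model
#' @param model an `nsc_model`.
#' @export
predict_nsc <- function(model, expr, min_coverage = 0.5)
  predict(model, expr, min_coverage = min_coverage)

#' @export
print.nsc_model <- function(x, ...) {
  nonzero <- sum(rowSums(x$dprime != 0) > 0)
  cat(sprintf("nsc_model: %d genes (%d surviving shrinkage), classes %s\n",
              length(x$genes), nonzero, paste(x$classes, collapse = "/")))
  cat(sprintf("delta = %.4g, s0 = %.4g, priors = %s\n", x$delta, x$s0,
              paste(sprintf("%.3f", x$priors), collapse = ", ")))
  invisible(x)
}

#' Collapse multi-class subtype calls to LAR vs non-LAR
#'
#' Labels matching `lar_aliases` after case-folding map to `"LAR"`, everything
#' else to `"non-LAR"`.
#'
#' @param calls character vector of subtype labels.
#' @param lar_aliases labels to treat as LAR.
#' @return character vector of `"LAR"` / `"non-LAR"`.
#' @export
binarize_labels <- function(calls, lar_aliases = c("LAR")) {
  ifelse(tolower(as.character(calls)) %in% tolower(lar_aliases),
         "LAR", "non-LAR")
}
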