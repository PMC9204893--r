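#' Cohen's kappa between two categorical labelings
#'
#' Unweighted kappa `(p_o - p_e) / (1 - p_e)` with the expected agreement
#' `p_e` from the product of marginal frequencies. `p_e = 1` only happens when
#' both raters are constant on the same label, in which case the labelings
#' are identical and kappa is defined as 1.
#'
#' @param a,b equal-length label vectors (length >= 2) on a shared label
#'   space.
#' @return list with `kappa`, `observed` (p_o) and `expected` (p_e).
#' @export
cohens_kappa <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (length(a) != length(b)) stop("labelings must have equal length")
  if (length(a) < 2L) stop("need at least 2 rated items")
  lev <- sort(unique(c(a, b)))
  ta <- table(factor(a, lev)) / length(a)
  tb <- table(factor(b, lev)) / length(b)
  p_o <- mean(a == b)
  p_e <- sum(as.numeric(ta) * as.numeric(tb))
  if (abs(1 - p_e) < 1e-12)
    return(list(kappa = 1, observed = 1, expected = p_e))
  list(kappa = (p_o - p_e) / (1 - p_e), observed = p_o, expected = p_e)
}

#' Pairwise kappa concordance across subtype-calling methods
#'
#' Computes Cohen's kappa for every pair of methods within every dataset, on
#' the intersection of samples both methods labeled. Pairs with an empty
#' intersection in a dataset are skipped with a warning.
#'
#' @param calls_by_method named list; each element a named character vector of
#'   labels (names = sample ids).
#' @param dataset named character vector mapping sample ids to datasets; if
#'   `NULL` all samples form one dataset.
#' @return list of class `concordance_report`: `per_dataset` (data.frame:
#'   method_a, method_b, dataset, n, kappa, observed, expected) and `summary`
#'   (median and mean kappa per method pair).
#' @export
pairwise_kappa <- function(calls_by_method, dataset = NULL) {
  stopifnot(length(calls_by_method) >= 2L, !is.null(names(calls_by_method)))
  methods <- names(calls_by_method)
  all_ids <- unique(unlist(lapply(calls_by_method, names)))
  if (is.null(dataset))
    dataset <- stats::setNames(rep("all", length(all_ids)), all_ids)
  rows <- list()
  for (i in seq_len(length(methods) - 1L)) for (j in (i + 1L):length(methods)) {
    ca <- calls_by_method[[i]]; cb <- calls_by_method[[j]]
    shared <- intersect(names(ca), names(cb))
    for (ds in unique(dataset[shared])) {
      ids <- shared[dataset[shared] == ds]
      if (length(ids) < 2L) {
        warning(sprintf("pair %s/%s skipped in dataset %s (too few samples)",
                        methods[i], methods[j], ds))
        next
      }
      k <- cohens_kappa(ca[ids], cb[ids])
      rows[[length(rows) + 1L]] <- data.frame(
        method_a = methods[i], method_b = methods[j], dataset = ds,
        n = length(ids), kappa = k$kappa, observed = k$observed,
        expected = k$expected)
    }
  }
  if (!length(rows)) stop("no method pair shares labeled samples")
  per_dataset <- do.call(rbind, rows)
  pair <- paste(per_dataset$method_a, per_dataset$method_b, sep = " vs ")
  summary <- data.frame(
    pair = unique(pair),
    median_kappa = as.numeric(tapply(per_dataset$kappa, pair, stats::median)[unique(pair)]),
    mean_kappa = as.numeric(tapply(per_dataset$kappa, pair, mean)[unique(pair)]),
    row.names = NULL)
  structure(list(per_dataset = per_dataset, summary = summary),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("pairwise kappa concordance\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
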