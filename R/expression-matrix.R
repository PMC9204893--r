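#' Construct an expression matrix
#'
#' The common currency of the package: a genes x samples numeric matrix with a
#' declared value kind. Raw counts must be non-negative integers; normalized
#' matrices may contain any finite values. Gene identifiers are uppercase
#' symbols and duplicates are rejected here (readers collapse duplicates
#' before construction).
#'
#' @param values numeric matrix, genes as rows, samples as columns; rownames
#'   are gene symbols, colnames are sample identifiers.
#' @param value_kind one of `"raw_counts"`, `"log_normalized"`, `"scaled"`.
#' @return a numeric matrix of class `expr_matrix` carrying a `value_kind`
#'   attribute.
#' @export
expression_matrix <- function(values,
                              value_kind = c("raw_counts", "log_normalized",
                                             "scaled")) {
  value_kind <- match.arg(value_kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || any(!nzchar(rownames(values))))
    stop("gene identifiers (rownames) are required and must be non-empty")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers; collapse duplicates before construction")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers")
  if (value_kind == "raw_counts") {
    if (anyNA(values))
      stop("missing values are not allowed in raw counts")
    if (any(values < 0))
      stop("negative values are not allowed in raw counts")
    if (any(abs(values - round(values)) > 1e-8))
      stop("raw counts must be integers")
    values <- round(values)
  } else if (anyNA(values)) {
    # impute missing normalized values as the gene median
    warning("missing values imputed as per-gene medians")
    med <- apply(values, 1L, stats::median, na.rm = TRUE)
    idx <- which(is.na(values), arr.ind = TRUE)
    values[idx] <- med[idx[, 1L]]
  }
  structure(values, value_kind = value_kind,
            class = c("expr_matrix", "matrix", "array"))
}

#' Value kind of an expression matrix
#' @param x an `expr_matrix` (or plain matrix, in which case `default` is
#'   returned).
#' @param default kind assumed when `x` carries no declaration.
#' @return character scalar.
#' @export
value_kind <- function(x, default = "log_normalized") {
  vk <- attr(x, "value_kind")
  if (is.null(vk)) default else vk
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s]\n",
              nrow(x), ncol(x), value_kind(x)))
  n <- min(5L, nrow(x)); m <- min(5L, ncol(x))
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE])
  if (nrow(x) > n || ncol(x) > m) cat("...\n")
  invisible(x)
}

#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = TRUE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    attr(out, "value_kind") <- attr(x, "value_kind")
    class(out) <- class(x)
  }
  out
}

# internal: strip class for linear algebra
as_plain <- function(x) {
  attr(x, "value_kind") <- NULL
  class(x) <- NULL
  x
}

#' Sample annotation table
#'
#' Validates a per-sample annotation data frame: unique `sample_id`, a
#' `group_label` restricted to LAR / non-LAR / unknown and a `pcr` outcome
#' restricted to yes / no / missing. Extra columns (dataset, arm, external
#' subtype calls) pass through untouched.
#'
#' @param sample_id character vector of unique identifiers.
#' @param dataset_id,arm_id optional provenance columns.
#' @param group_label LAR / non-LAR / unknown per sample.
#' @param pcr yes / no / missing per sample.
#' @param ... further per-sample columns, recycled by `data.frame()` rules.
#' @return a `data.frame` with validated columns.
#' @export
sample_table <- function(sample_id, dataset_id = NA_character_,
                         arm_id = NA_character_,
                         group_label = "unknown", pcr = "missing", ...) {
  if (anyDuplicated(sample_id)) stop("sample_id values must be unique")
  tab <- data.frame(sample_id = as.character(sample_id),
                    dataset_id = dataset_id, arm_id = arm_id,
                    group_label = group_label, pcr = pcr, ...,
                    stringsAsFactors = FALSE)
  if (!all(tab$group_label %in% c("LAR", "non-LAR", "unknown")))
    stop("group_label must be one of LAR, non-LAR, unknown")
  if (!all(tab$pcr %in% c("yes", "no", "missing")))
    stop("pcr must be one of yes, no, missing")
  tab
}
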