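#' Read a gene x sample expression matrix
#'
#' Dense TSV/CSV (first column gene symbol, header row of sample ids) or a
#' Matrix Market triplet file with companion one-column gene and cell label
#' files. Duplicate gene symbols are collapsed: summed for raw counts,
#' averaged otherwise, with a warning.
#'
#' @param path file path; for `format = "mtx_triplet"` the `.mtx` file.
#' @param format `"tsv"`, `"csv"` or `"mtx_triplet"`.
#' @param value_kind declared kind of the stored values.
#' @param genes_path,cells_path label files for the triplet format; default to
#'   `<path>.genes.tsv` / `<path>.cells.tsv` next to the matrix.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, format = c("tsv", "csv", "mtx_triplet"),
                            value_kind = "raw_counts",
                            genes_path = NULL, cells_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx_triplet") {
    if (is.null(genes_path)) genes_path <- paste0(path, ".genes.tsv")
    if (is.null(cells_path)) cells_path <- paste0(path, ".cells.tsv")
    if (!file.exists(genes_path) || !file.exists(cells_path))
      stop("companion gene/cell label files not found for ", path)
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(genes_path)
    cells <- readLines(cells_path)
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
      stop(sprintf("dimension mismatch: matrix %dx%d vs %d genes, %d cells",
                   nrow(m), ncol(m), length(genes), length(cells)))
    rownames(m) <- genes
    colnames(m) <- cells
  } else {
    sep <- if (format == "tsv") "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, quote = "",
                            stringsAsFactors = FALSE, comment.char = "")
    if (ncol(df) < 2L) stop("malformed header: need a gene column plus >=1 sample")
    genes <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric expression values in ", path)
    rownames(m) <- genes
  }
  m <- collapse_duplicate_genes(m, value_kind)
  expression_matrix(m, value_kind)
}

# duplicate symbols: sum counts, average normalized values
collapse_duplicate_genes <- function(m, value_kind) {
  if (!anyDuplicated(rownames(m))) return(m)
  warning(sprintf("%d duplicate gene symbol(s) collapsed by %s",
                  sum(duplicated(rownames(m))),
                  if (value_kind == "raw_counts") "sum" else "mean"))
  f <- factor(rownames(m), levels = unique(rownames(m)))
  agg <- rowsum(m, f, reorder = FALSE)
  if (value_kind != "raw_counts")
    agg <- agg / as.vector(table(f)[levels(f)])
  agg
}

#' Write an expression matrix as TSV
#'
#' @param x matrix with gene rownames and sample colnames.
#' @param path output path.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene = rownames(x), as_plain(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description (discarded), then gene symbols. Symbols
#' are deduplicated within a set; duplicate set names and empty files are
#' errors.
#'
#' @param path GMT file.
#' @param collection_name name attached to the collection; defaults to the
#'   file name.
#' @return named list of character vectors with attribute `collection_name`.
#' @export
read_gmt <- function(path, collection_name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no gene sets in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("GMT line ", bad[1L], " has fewer than 3 tab-separated fields")
  nms <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nms))
    stop("duplicate gene-set name: ", nms[duplicated(nms)][1L])
  sets <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
  names(sets) <- nms
  gene_set_collection(sets, collection_name)
}

#' Assemble a gene-set collection from a named list
#' @param sets named list of character vectors.
#' @param collection_name label for the collection.
#' @return the validated list, classed `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, collection_name = "sets") {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must be uniquely named")
  if (any(lengths(sets) == 0L)) stop("empty gene set not allowed")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  structure(sets, collection_name = collection_name,
            class = c("gene_set_collection", "list"))
}

#' Write / read a trained shrunken-centroid model
#'
#' The TSV layout stores per-gene rows (class centroids, overall centroid,
#' pooled within-class deviation, shrunken differences) followed by `#`-prefixed
#' header lines for the scalar fields (priors, fudge constant, shrinkage).
#' `read_signature(write_signature(m))` reproduces every numeric field to full
#' stored precision (17 significant digits).
#'
#' @param model an `nsc_model` from [train_nsc()].
#' @param path output TSV path.
#' @rdname signature_io
#' @export
write_signature <- function(model, path) {
  stopifnot(inherits(model, "nsc_model"))
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) format(x, digits = 17)
  writeLines(sprintf("# classes\t%s", paste(model$classes, collapse = "\t")), con)
  writeLines(sprintf("# priors\t%s", paste(num(model$priors), collapse = "\t")), con)
  writeLines(sprintf("# s0\t%s", num(model$s0)), con)
  writeLines(sprintf("# delta\t%s", num(model$delta)), con)
  writeLines(sprintf("# n_per_class\t%s",
                     paste(model$n_per_class, collapse = "\t")), con)
  df <- data.frame(gene = model$genes,
                   overall_centroid = model$overall_centroid,
                   pooled_sd = model$pooled_sd)
  for (k in seq_along(model$classes)) {
    df[[paste0("centroid_", model$classes[k])]] <- model$centroids[, k]
    df[[paste0("dprime_", model$classes[k])]] <- model$dprime[, k]
  }
  utils::write.table(format(df, digits = 17), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param path TSV path written by `write_signature`.
#' @rdname signature_io
#' @export
read_signature <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  take <- function(key) {
    ln <- grep(paste0("^# ", key, "\t"), hdr, value = TRUE)
    if (length(ln) != 1L) stop("signature file missing '", key, "' header row")
    strsplit(sub(paste0("^# ", key, "\t"), "", ln), "\t")[[1L]]
  }
  classes <- take("classes")
  priors <- as.numeric(take("priors"))
  s0 <- as.numeric(take("s0"))
  delta <- as.numeric(take("delta"))
  n_per_class <- as.integer(take("n_per_class"))
  body <- lines[!startsWith(lines, "# ")]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("gene", "overall_centroid", "pooled_sd",
            paste0("centroid_", classes), paste0("dprime_", classes))
  if (!all(need %in% names(df)))
    stop("signature file missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  centroids <- as.matrix(df[, paste0("centroid_", classes)])
  dprime <- as.matrix(df[, paste0("dprime_", classes)])
  dimnames(centroids) <- dimnames(dprime) <- list(df$gene, classes)
  new_nsc_model(genes = df$gene, classes = classes,
                centroids = centroids,
                overall_centroid = stats::setNames(df$overall_centroid, df$gene),
                pooled_sd = stats::setNames(df$pooled_sd, df$gene),
                s0 = s0, delta = delta, dprime = dprime,
                priors = stats::setNames(priors, classes),
                n_per_class = stats::setNames(n_per_class, classes))
}

#' Read per-arm 2x2 pCR count tables
#'
#' Expected columns: `trial`, `arm`, `lar_yes`, `lar_no`, `nonlar_yes`,
#' `nonlar_no`. Extra columns pass through.
#'
#' @param path TSV file.
#' @return data.frame of class `arm_table`.
#' @export
read_arm_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  arm_table(df)
}

#' Validate an arm-level count table
#' @param df data.frame with columns trial, arm, lar_yes, lar_no, nonlar_yes,
#'   nonlar_no.
#' @return `df`, classed `arm_table`.
#' @export
arm_table <- function(df) {
  need <- c("trial", "arm", "lar_yes", "lar_no", "nonlar_yes", "nonlar_no")
  if (!all(need %in% names(df)))
    stop("arm table missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  cnt <- as.matrix(df[, need[3:6]])
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("arm counts must be non-negative integers")
  if (any(df$lar_yes + df$lar_no < 1) || any(df$nonlar_yes + df$nonlar_no < 1))
    stop("each group must have at least one subject per arm")
  class(df) <- c("arm_table", "data.frame")
  df
}

#' Built-in neoadjuvant-chemotherapy arm counts
#'
#' The 13 treatment-arm 2x2 tables of pCR by LAR status (seven trials) used by
#' the meta-analysis stage, as published. `printed_or` is the odds ratio as
#' printed in the source table; `printed_consistent` flags the 11 entries whose
#' printed value equals the cross-product of the printed counts at 2-decimal
#' rounding.
#'
#' @return an `arm_table` with 13 rows.
#' @export
nac_arms <- function() {
  path <- system.file("extdata", "nac_arms.tsv", package = "larsig",
                      mustWork = TRUE)
  read_arm_table(path)
}
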