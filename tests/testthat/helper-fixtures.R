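# shared fixture builders; all randomness is seeded by the caller

toy_expr <- function(genes = 50, samples = 20, seed = 1, kind = "log_normalized",
                     mean = 8, sd = 1) {
  set.seed(seed)
  x <- matrix(rnorm(genes * samples, mean, sd), genes, samples,
              dimnames = list(sprintf("G%03d", seq_len(genes)),
                              sprintf("S%03d", seq_len(samples))))
  expression_matrix(x, kind)
}

toy_counts <- function(genes = 50, samples = 10, seed = 1, mu = 100,
                       phi = 0.2) {
  set.seed(seed)
  x <- matrix(rnbinom(genes * samples, size = 1 / phi, mu = mu),
              genes, samples,
              dimnames = list(sprintf("G%03d", seq_len(genes)),
                              sprintf("S%03d", seq_len(samples))))
  expression_matrix(x, "raw_counts")
}

# two Gaussian blobs in expression space, samples as columns
two_blob_expr <- function(n_per = 15, genes = 40, sep = 10, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(genes * 2 * n_per), genes, 2 * n_per)
  x[, seq_len(n_per)] <- x[, seq_len(n_per)] + sep
  dimnames(x) <- list(sprintf("G%03d", seq_len(genes)),
                      sprintf("S%03d", seq_len(2 * n_per)))
  list(expr = expression_matrix(x, "log_normalized"),
       labels = rep(c("A", "B"), each = n_per))
}

# printed-value rounding: half away from zero at 2 decimals
round_half_up2 <- function(x) floor(x * 100 + 0.5) / 100

# independent two-sided Fisher oracle for a 2x2 table: enumerate all tables
# with the observed margins, sum probabilities <= observed
fisher_2x2_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n); hi <- min(k, m)
  a <- lo:hi
  p <- dhyper(a, m, n, k)
  sum(p[p <= dhyper(tab[1, 1], m, n, k) * (1 + 1e-7)])
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  exp_idx <- sum_a * sum_b / comb2(n)
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

as_plain_mat <- function(x) {
  attr(x, "value_kind") <- NULL
  attr(x, "tmm_factors") <- NULL
  unclass(x)
}
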