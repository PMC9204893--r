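test_that("balanced reference takes exactly k cells per type, matching a sort oracle", {
  sc <- simulate_single_cell(sc_sim_params(n_types = 5, cells_per_type = 30,
                                           n_genes = 120, seed = 51))
  ref <- build_balanced_reference(sc$expr, sc$cell_types, k = 12,
                                  embedding = sc$embedding)
  expect_length(ref, 60L)
  expect_true(all(table(sc$cell_types[ref]) == 12L))

  # brute-force oracle: full distance sort from each type centroid
  for (tp in levels(sc$cell_types)) {
    members <- names(sc$cell_types)[sc$cell_types == tp]
    pts <- sc$embedding[members, , drop = FALSE]
    d <- sqrt(colSums((t(pts) - colMeans(pts))^2))
    oracle <- members[order(d, members)][1:12]
    expect_setequal(intersect(ref, members), oracle)
  }

  # k equal to the smallest type size selects that whole type
  all_t1 <- build_balanced_reference(sc$expr, sc$cell_types, k = 30,
                                     embedding = sc$embedding)
  expect_setequal(intersect(all_t1, names(sc$cell_types)[sc$cell_types == "T1"]),
                  names(sc$cell_types)[sc$cell_types == "T1"])
  expect_error(build_balanced_reference(sc$expr, sc$cell_types, k = 31,
                                        embedding = sc$embedding),
               "fewer than k")
  # expression-PCA fallback also returns a balanced subset
  ref_pc <- build_balanced_reference(sc$expr, sc$cell_types, k = 10)
  expect_true(all(table(sc$cell_types[ref_pc]) == 10L))
})

test_that("dropout filter keeps genes with excess zeros at high mean", {
  set.seed(52)
  n_cells <- 600; g <- 400
  mu <- exp(rnorm(g, log(8), 1))
  counts <- matrix(rpois(g * n_cells, mu), g, n_cells)
  # baseline dropout on the reference curve, plus 60 genes with inflated dropout
  K <- 4
  base_drop <- K / (log1p(mu) + K) * 0.4
  inflated <- 1:60
  drop <- base_drop; drop[inflated] <- pmin(0.95, base_drop[inflated] + 0.5)
  keep <- matrix(rbinom(g * n_cells, 1, 1 - drop), g, n_cells)
  counts <- counts * keep
  dimnames(counts) <- list(sprintf("G%04d", 1:g), sprintf("C%04d", 1:n_cells))
  ex <- expression_matrix(counts, "raw_counts")
  sel <- dropout_feature_filter(ex, a = 1.0, b = 1.1)
  infl_names <- rownames(counts)[inflated]
  stats <- attr(sel, "stats")
  eligible <- stats$gene[stats$mu >= 1.0]
  expect_gte(mean(intersect(infl_names, eligible) %in% sel), 0.9)
  others <- setdiff(eligible, infl_names)
  expect_lte(mean(others %in% sel), 0.1)

  # a gene with no dropout at high mean can never pass
  hi <- counts; hi[100, ] <- 50
  sel2 <- dropout_feature_filter(expression_matrix(hi, "raw_counts"),
                                 a = 1.0, b = 1.1)
  expect_false("G0100" %in% sel2)

  # target_n returns exactly n when enough genes pass the mean gate
  sel3 <- dropout_feature_filter(ex, a = 1.0, target_n = 50)
  expect_length(sel3, 50L)
})

test_that("signature matrix is depth-invariant and reduces to type means", {
  sc <- simulate_single_cell(sc_sim_params(n_types = 4, cells_per_type = 25,
                                           n_genes = 100, seed = 53))
  sig <- build_signature_matrix(sc$expr, sc$cell_types)
  doubled <- expression_matrix(2 * as_plain_mat(sc$expr), "raw_counts")
  sig2 <- build_signature_matrix(doubled, sc$cell_types)
  expect_equal(unname(sig2), unname(sig), tolerance = 1e-12)

  one <- sc$cell_types == "T1"
  sig1 <- build_signature_matrix(sc$expr[, one], sc$cell_types[one])
  expect_equal(sig1[rownames(sig1), "T1"], sig[rownames(sig1), "T1"])
  expect_error(build_signature_matrix(sc$expr, sc$cell_types,
                                      genes = character(0)), "empty gene")
})

test_that("NNLS recovers exactly-expressible mixtures to machine precision", {
  sc <- simulate_single_cell(sc_sim_params(n_types = 6, cells_per_type = 40,
                                           n_genes = 300,
                                           type_profile_separation = 1.5,
                                           seed = 54))
  sig <- build_signature_matrix(sc$expr, sc$cell_types)
  set.seed(55)
  f_true <- t(vapply(1:8, function(i) {
    w <- rexp(6); w / sum(w)
  }, numeric(6)))
  colnames(f_true) <- colnames(sig)
  bulk <- expression_matrix(
    unclass(sig) %*% t(f_true) |>
      `dimnames<-`(list(rownames(sig), sprintf("M%02d", 1:8))), "scaled")
  dc <- deconvolve(bulk, sig, method = "nnls")
  expect_lt(max(abs(dc$fractions - f_true)), 1e-6)
  expect_equal(unname(rowSums(dc$fractions)), rep(1, 8), tolerance = 1e-9)
  # common positive scaling of a bulk sample changes nothing
  dc2 <- deconvolve(expression_matrix(5 * as_plain_mat(bulk), "scaled"), sig,
                    method = "nnls")
  expect_equal(dc2$fractions, dc$fractions, tolerance = 1e-8)
  # deconvolving the signature's own columns is near one-hot
  self <- deconvolve(expression_matrix(unclass(sig), "scaled"), sig, "nnls")
  expect_gte(min(diag(self$fractions[colnames(sig), ])), 0.9)
})

test_that("nu-SVR deconvolution recovers simulated mixtures", {
  sc <- simulate_single_cell(sc_sim_params(n_types = 5, cells_per_type = 40,
                                           n_genes = 250,
                                           type_profile_separation = 1.5,
                                           seed = 56))
  sig <- build_signature_matrix(sc$expr, sc$cell_types)
  fr <- rbind(c(1, 0, 0, 0, 0), c(0.7, 0.3, 0, 0, 0), c(0.2, 0.2, 0.2, 0.2, 0.2))
  colnames(fr) <- colnames(sig)
  mx <- simulate_mixtures(sc$expr, sc$cell_types, fr, noise_sd = 0, seed = 2)
  dsvr <- deconvolve(mx$bulk, sig, method = "nu_svr")
  expect_gte(dsvr$fractions[1, "T1"], 0.9)
  expect_lt(max(abs(dsvr$fractions[2, ] - fr[2, ])), 0.1)
  expect_equal(unname(rowSums(dsvr$fractions)), rep(1, 3), tolerance = 1e-9)
  expect_error(deconvolve(mx$bulk[1:20, ], sig), "overlap below")
})

test_that("abundance testing flags planted shifts and stays calm under the null", {
  set.seed(57)
  n <- 60
  groups <- rep(c("LAR", "non-LAR"), each = n / 2)
  f <- matrix(abs(rnorm(n * 8, 0.1, 0.02)), n, 8,
              dimnames = list(sprintf("S%02d", 1:n), sprintf("T%d", 1:8)))
  f[groups == "LAR", 3] <- f[groups == "LAR", 3] + 0.15
  f <- f / rowSums(f)
  res <- test_abundance(f, groups)
  expect_true(all(res$adj_pvalue >= res$pvalue - 1e-12))
  expect_lt(res$adj_pvalue[res$cell_type == "T3"], 0.01)
  expect_equal(res$cell_type[which.min(res$pvalue)], "T3")

  # permutation null: roughly nominal false-positive rate across reps
  rates <- vapply(1:10, function(r) {
    set.seed(100 + r)
    fn <- matrix(abs(rnorm(n * 20, 0.05, 0.01)), n, 20)
    colnames(fn) <- sprintf("T%d", 1:20)
    mean(test_abundance(fn / rowSums(fn), sample(groups))$pvalue <= 0.05)
  }, 0)
  expect_lte(mean(rates), 0.07)

  # constant fractions are flagged, not tested
  fc <- f; fc[, 5] <- 0.1
  resc <- test_abundance(fc, groups)
  expect_true(resc$flagged[resc$cell_type == "T5"])
  expect_equal(resc$pvalue[resc$cell_type == "T5"], 1)
})
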